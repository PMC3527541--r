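#' Merge overlapping intervals
#'
#' Per chromosome, returns the minimal set of disjoint intervals with the
#' same base union as the input.  Merging is what prevents overlapping
#' CNV records (e.g. repeatedly deposited variants of one locus) from
#' being double-counted in base coverage.  Idempotent; feature ids are
#' dropped because merged intervals no longer correspond to single
#' records.
#'
#' @param x a [feature_set()] or interval `data.frame`.
#' @return a [feature_set()] of disjoint intervals, sorted by chromosome
#'   and start.
#' @export
merge_features <- function(x) {
  df <- as_feature_frame(x)
  if (nrow(df) == 0L) {
    return(feature_set(df[, c("chrom", "start", "end")],
                       kind = if (inherits(x, "feature_set")) x$kind else "generic",
                       assembly = if (inherits(x, "feature_set")) x$assembly else NULL))
  }
  red <- GenomicRanges::reduce(as_granges(df))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1,
                    end = GenomicRanges::end(red),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  feature_set(out,
              kind = if (inherits(x, "feature_set")) x$kind else "generic",
              assembly = if (inherits(x, "feature_set")) x$assembly else NULL,
              label = if (inherits(x, "feature_set")) x$label else NULL)
}

#' Do two intervals overlap?
#'
#' TRUE iff both intervals are on the same chromosome and share at least
#' one base under the half-open convention; adjacency (`end == start`)
#' is not overlap.  No minimum reciprocal overlap is required.
#'
#' @param a,b single intervals: one-row `data.frame`s, lists with
#'   `chrom`/`start`/`end`, or locus strings.
#' @return logical scalar.
#' @examples
#' interval_overlaps("chr1:1-100", "chr1:101-200")  # FALSE: adjacent
#' @export
interval_overlaps <- function(a, b) {
  norm <- function(x) {
    if (is.character(x) && length(x) == 1L) x <- parse_locus(x)
    df <- as_feature_frame(x)
    if (nrow(df) != 1L) stop("expected a single interval")
    df
  }
  a <- norm(a)
  b <- norm(b)
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

#' Feature coverage: how many targets does a cover set hit?
#'
#' Counts target features overlapped by at least one cover interval.  A
#' target counts once no matter how many cover intervals hit it; the hit
#' list records every overlapping (target, cover) pair so that
#' per-enhancer reports can be generated.
#'
#' @param targets,cover [feature_set()]s on the same assembly (or
#'   unbound).
#' @return a list with `count` (targets overlapped), `fraction`
#'   (`count / n_targets`), and `hits`, a `data.frame` of overlapping
#'   pairs (`target`, `cover`, ids when available, and `overlap_bases`).
#' @export
feature_coverage <- function(targets, cover) {
  check_same_assembly(targets, cover)
  tdf <- as_feature_frame(targets)
  cdf <- as_feature_frame(cover)
  empty_hits <- data.frame(target = integer(), cover = integer(),
                           target_id = character(), cover_id = character(),
                           overlap_bases = numeric(),
                           stringsAsFactors = FALSE)
  if (nrow(tdf) == 0L || nrow(cdf) == 0L) {
    return(list(count = 0L, fraction = if (nrow(tdf)) 0 else NaN,
                hits = empty_hits))
  }
  tgr <- as_granges(tdf)
  cgr <- as_granges(cdf)
  fo <- suppressWarnings(GenomicRanges::findOverlaps(tgr, cgr))
  q <- S4Vectors::queryHits(fo)
  s <- S4Vectors::subjectHits(fo)
  ob <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(tgr)[q], GenomicRanges::ranges(cgr)[s]))
  getid <- function(df, i) {
    if ("id" %in% names(df)) as.character(df$id[i]) else as.character(i)
  }
  hits <- data.frame(target = q, cover = s,
                     target_id = getid(tdf, q), cover_id = getid(cdf, s),
                     overlap_bases = as.numeric(ob),
                     stringsAsFactors = FALSE)
  count <- length(unique(q))
  list(count = count, fraction = count / nrow(tdf), hits = hits)
}

#' Base coverage: what fraction of target bases is covered?
#'
#' The cover set is merged first, so overlapping cover intervals are not
#' double-counted; overlapping targets are likewise unioned, so the
#' denominator is the distinct target footprint.  With the whole
#' assembly as target this returns the genome coverage fraction used as
#' the expected value of the depletion analysis.
#'
#' @inheritParams feature_coverage
#' @return a list with `covered_bases`, `total_bases` and `fraction`.
#' @export
base_coverage <- function(targets, cover) {
  check_same_assembly(targets, cover)
  tdf <- as_feature_frame(targets)
  cdf <- as_feature_frame(cover)
  if (nrow(tdf) == 0L) stop("empty target set")
  tred <- GenomicRanges::reduce(as_granges(tdf))
  total <- sum(as.numeric(GenomicRanges::width(tred)))
  if (nrow(cdf) == 0L) {
    return(list(covered_bases = 0, total_bases = total, fraction = 0))
  }
  cred <- GenomicRanges::reduce(as_granges(cdf))
  ov <- suppressWarnings(GenomicRanges::intersect(tred, cred))
  covered <- sum(as.numeric(GenomicRanges::width(ov)))
  list(covered_bases = covered, total_bases = total,
       fraction = covered / total)
}

#' Feature set spanning a whole assembly
#'
#' One interval per chromosome, covering every base; convenient as the
#' target of [base_coverage()] to obtain genome coverage fractions.
#'
#' @param assembly a [genome_assembly()].
#' @return a [feature_set()].
#' @export
assembly_as_features <- function(assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  feature_set(data.frame(chrom = assembly$chromosomes$chrom,
                         start = 0,
                         end = assembly$chromosomes$length,
                         stringsAsFactors = FALSE),
              kind = "generic", assembly = assembly, label = assembly$name)
}
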