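#' Construct a probe-level log2-ratio track
#'
#' An ordered table of aCGH probes: chromosome, position (bp, 1-based
#' probe midpoint) and log2 test/reference ratio.  Positions must be
#' strictly increasing within each chromosome and ratios finite.
#'
#' @param x a `data.frame` with columns `chrom`, `pos`, `log2`.
#' @return an object of class `probe_track` (a validated `data.frame`).
#' @export
probe_track <- function(x) {
  stopifnot(is.data.frame(x))
  if (!all(c("chrom", "pos", "log2") %in% names(x))) {
    stop("probe track needs 'chrom', 'pos' and 'log2' columns")
  }
  x$chrom <- as.character(x$chrom)
  x$pos <- as.numeric(x$pos)
  x$log2 <- as.numeric(x$log2)
  if (any(!is.finite(x$log2))) stop("log2 ratios must be finite")
  if (any(!is.finite(x$pos) | x$pos < 1)) stop("probe positions must be >= 1")
  for (ch in unique(x$chrom)) {
    p <- x$pos[x$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("probe positions must be strictly increasing on ", ch)
    }
  }
  rownames(x) <- NULL
  class(x) <- c("probe_track", "data.frame")
  x
}

#' Read a probe track from TSV
#' @param path TSV with header columns `chrom`, `pos`, `log2`.
#' @return a [probe_track()].
#' @export
read_probe_track <- function(path) {
  if (!file.exists(path)) stop("probe track not found: ", path)
  probe_track(utils::read.table(path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE,
                                comment.char = "#"))
}

#' Derivative log ratio spread (DLRSpread)
#'
#' The standard aCGH probe-to-probe noise metric: the robust spread of
#' consecutive-probe log2 differences, `IQR(diff) / (1.349 * sqrt(2))`.
#' Differences are taken within each chromosome and pooled before the
#' IQR, so chromosome boundaries never contribute.  For i.i.d. Gaussian
#' probe noise of standard deviation sigma the differences have spread
#' `sigma * sqrt(2)` and the normalization recovers sigma.  Adding a
#' constant to all ratios leaves it unchanged.
#'
#' @param track a [probe_track()].
#' @return the DLRSpread value (>= 0).
#' @export
dlr_spread <- function(track) {
  track <- if (inherits(track, "probe_track")) track else probe_track(track)
  d <- unlist(lapply(split(track$log2, track$chrom), diff), use.names = FALSE)
  if (!length(d)) {
    stop("DLRSpread needs at least two probes on some chromosome")
  }
  stats::IQR(d) / (1.349 * sqrt(2))
}

# Best contiguous window of x (by two-sample t of window vs the rest).
# Scans widths wmin..wmax at every start; returns list(start, width, t)
# of the maximal |t|, or NULL when nothing is scannable.  Cumulative-sum
# arithmetic keeps it O(n * wmax).
best_window <- function(x, wmin = 1L, wmax = length(x) - 1L) {
  n <- length(x)
  if (n < 2L) return(NULL)
  wmax <- min(wmax, n - 1L)
  if (wmax < wmin) return(NULL)
  csp <- c(0, cumsum(x))
  cssp <- c(0, cumsum(x * x))
  tot <- csp[n + 1L]
  stot <- cssp[n + 1L]
  best <- list(start = NA_integer_, width = NA_integer_, t = 0)
  for (w in wmin:wmax) {
    i0 <- 0:(n - w)                       # window = x[(i0+1)..(i0+w)]
    sum_in <- csp[i0 + w + 1L] - csp[i0 + 1L]
    ss_in <- cssp[i0 + w + 1L] - cssp[i0 + 1L]
    n_out <- n - w
    sum_out <- tot - sum_in
    mean_in <- sum_in / w
    mean_out <- sum_out / n_out
    ss1 <- pmax(ss_in - sum_in^2 / w, 0)
    ss2 <- pmax((stot - ss_in) - sum_out^2 / n_out, 0)
    sp2 <- (ss1 + ss2) / max(n - 2L, 1L)
    se <- sqrt(sp2 * (1 / w + 1 / n_out))
    dmean <- mean_in - mean_out
    tt <- ifelse(se > 0, dmean / se,
                 ifelse(dmean == 0, 0, sign(dmean) * Inf))
    k <- which.max(abs(tt))
    if (abs(tt[k]) > abs(best$t)) {
      best <- list(start = i0[k] + 1L, width = w, t = tt[k])
    }
  }
  if (is.na(best$start)) NULL else best
}

# Recursive mean-shift segmentation of one chromosome's log2 vector.
# Returns integer vector of segment end indices.
segment_indices <- function(x, t_threshold, min_probes, max_width) {
  n <- length(x)
  bounds <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- seg[1L]; hi <- seg[2L]
    len <- hi - lo + 1L
    if (len < 2L * min_probes || len < 2L) {
      bounds <- c(bounds, hi)
      next
    }
    bw <- best_window(x[lo:hi], wmin = min_probes,
                      wmax = min(max_width, len - min_probes))
    if (is.null(bw) || is.na(bw$t) || abs(bw$t) < t_threshold) {
      bounds <- c(bounds, hi)
      next
    }
    a <- lo + bw$start - 2L              # end of left flank (may be < lo)
    b <- lo + bw$start + bw$width - 2L   # end of window
    if (a >= lo) stack[[length(stack) + 1L]] <- c(lo, a)
    stack[[length(stack) + 1L]] <- c(max(lo, a + 1L), b)
    if (b < hi) stack[[length(stack) + 1L]] <- c(b + 1L, hi)
  }
  sort(unique(bounds))
}

#' Segment a probe track into constant-mean calls
#'
#' Recursive mean-shift segmentation per chromosome: at each step the
#' contiguous probe window whose mean differs most from the rest of the
#' current segment (largest two-sample t statistic, window boundaries
#' scanned exhaustively up to `max_width` probes) is split out iff
#' `|t| >= t_threshold`, and the resulting parts are segmented
#' recursively.  Deterministic for fixed input.  Every leaf becomes a
#' segment call with its probe count and mean log2 ratio; direction is
#' the sign of the mean.  Calls are *not* filtered here — apply
#' [aberration_filter()] with the track's [dlr_spread()] downstream.
#'
#' @param track a [probe_track()].
#' @param t_threshold minimum |t| to accept a split.  The default 6
#'   controls false splits when scanning all windows of chromosomes with
#'   a few thousand probes (the null maximum grows like
#'   `sqrt(2 log n_windows)`).
#' @param min_probes smallest window considered by the scan (default 1).
#' @param max_width widest window considered by the scan, in probes.
#' @return a `segment_calls` `data.frame`: `chrom`, `start`, `end`
#'   (0-based half-open bp span of the probes), `probe_count`,
#'   `mean_log2`, `direction`, `passes_filter` (NA until filtered).
#' @export
segment_track <- function(track, t_threshold = 6, min_probes = 1L,
                          max_width = 500L) {
  track <- if (inherits(track, "probe_track")) track else probe_track(track)
  if (nrow(track) == 0L) stop("empty probe track")
  out <- list()
  for (ch in unique(track$chrom)) {
    sub <- track[track$chrom == ch, , drop = FALSE]
    ends <- segment_indices(sub$log2, t_threshold, as.integer(min_probes),
                            as.integer(max_width))
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    out[[ch]] <- data.frame(
      chrom = ch,
      start = sub$pos[starts] - 1,
      end = sub$pos[ends],
      probe_count = ends - starts + 1L,
      mean_log2 = vapply(seq_along(ends), function(i) {
        mean(sub$log2[starts[i]:ends[i]])
      }, numeric(1)),
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  calls$direction <- ifelse(calls$mean_log2 >= 0, "gain", "loss")
  calls$passes_filter <- NA
  class(calls) <- c("segment_calls", "data.frame")
  calls
}

#' The aberration filter
#'
#' The published rule for credible aCGH aberrations: keep exactly the
#' calls supported by at least 3 probes of consistent direction whose
#' absolute mean log2 ratio is at least the track's DLRSpread.  The
#' mean-ratio rule is applied on the absolute value so that deletions
#' (negative means) are judged symmetrically with duplications.  The
#' filter is a pure predicate: the output is a subset of the input and
#' re-applying it changes nothing.
#'
#' @param calls a `segment_calls` `data.frame` (see [segment_track()]).
#' @param dlrs the track's [dlr_spread()] value (>= 0).
#' @param min_probes minimum probes per aberration (default 3).
#' @param keep_all if TRUE, return every input call with its
#'   `passes_filter` flag set instead of the passing subset.
#' @return the filtered `segment_calls` (or all calls flagged).
#' @export
aberration_filter <- function(calls, dlrs, min_probes = 3L,
                              keep_all = FALSE) {
  stopifnot(is.data.frame(calls))
  if (!is.finite(dlrs) || dlrs < 0) stop("dlrs must be >= 0")
  pass <- calls$probe_count >= min_probes & abs(calls$mean_log2) >= dlrs
  calls$passes_filter <- pass
  if (keep_all) return(calls)
  out <- calls[pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate and classify CNV calls against reference interval sets
#'
#' Each call is labeled with every overlapping feature from the supplied
#' sets, then classified with fixed precedence: overlap with a disease
#' (syndrome) region wins, then overlap with known polymorphic
#' variation, then overlap with an enhancer locus; calls hitting nothing
#' are `"uncertain"`.  The precedence encodes interpretation priority —
#' a call inside a known microdeletion syndrome region is reported as
#' such even when it also covers an enhancer.
#'
#' @param calls a `segment_calls` `data.frame`, a [feature_set()], or a
#'   plain interval `data.frame` (e.g. externally validated deletions).
#' @param enhancers,known_cnvs,syndrome_regions optional
#'   [feature_set()]s to annotate against.
#' @return an object of class `annotated_calls`: `$calls` (the input
#'   intervals plus a `classification` column) and `$annotations`
#'   (`data.frame` of call index, set label, feature id, overlap bases).
#' @export
annotate_calls <- function(calls, enhancers = NULL, known_cnvs = NULL,
                           syndrome_regions = NULL) {
  cdf <- as_feature_frame(calls)
  if (nrow(cdf) == 0L) stop("no calls to annotate")
  sets <- list(enhancer = enhancers, known_cnv = known_cnvs,
               syndrome_region = syndrome_regions)
  sets <- sets[!vapply(sets, is.null, TRUE)]
  for (s in sets) {
    if (inherits(calls, "feature_set")) check_same_assembly(calls, s)
    for (s2 in sets) check_same_assembly(s, s2)
  }
  cgr <- as_granges(cdf)
  ann <- data.frame(call = integer(), set = character(),
                    feature_id = character(), overlap_bases = numeric(),
                    stringsAsFactors = FALSE)
  hit_by <- list()
  for (nm in names(sets)) {
    fdf <- as_feature_frame(sets[[nm]])
    if (nrow(fdf) == 0L) { hit_by[[nm]] <- integer(0); next }
    fgr <- as_granges(fdf)
    fo <- suppressWarnings(GenomicRanges::findOverlaps(cgr, fgr))
    q <- S4Vectors::queryHits(fo)
    s <- S4Vectors::subjectHits(fo)
    if (!length(q)) { hit_by[[nm]] <- integer(0); next }
    ob <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(cgr)[q], GenomicRanges::ranges(fgr)[s]))
    ids <- if ("id" %in% names(fdf)) as.character(fdf$id[s]) else
      as.character(s)
    ann <- rbind(ann, data.frame(call = q, set = nm, feature_id = ids,
                                 overlap_bases = as.numeric(ob),
                                 stringsAsFactors = FALSE))
    hit_by[[nm]] <- unique(q)
  }
  classification <- rep("uncertain", nrow(cdf))
  if (!is.null(hit_by$enhancer)) {
    classification[hit_by$enhancer] <- "enhancer-CNV"
  }
  if (!is.null(hit_by$known_cnv)) {
    classification[hit_by$known_cnv] <- "known-polymorphic"
  }
  if (!is.null(hit_by$syndrome_region)) {
    classification[hit_by$syndrome_region] <- "disease-region"
  }
  cdf$classification <- classification
  structure(list(calls = cdf, annotations = ann),
            class = "annotated_calls")
}

#' @export
print.annotated_calls <- function(x, ...) {
  cat(sprintf("<annotated_calls: %d calls, %d annotations>\n",
              nrow(x$calls), nrow(x$annotations)))
  print(table(x$calls$classification))
  invisible(x)
}
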