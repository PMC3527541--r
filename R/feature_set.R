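#' Parse genomic locus strings
#'
#' Parses strings of the form `"chr16:22684122-22685282"` as printed in
#' genome-browser output and published coordinate tables.  The separator
#' may be `":"` or the ratio character `"∶"`; the dash may be a
#' hyphen, en-dash or minus sign; digits may contain thousands commas
#' (`"chr12:16,610,045–16,611,936"`).  Printed coordinates are taken
#' as 1-based inclusive and converted to the internal 0-based half-open
#' convention, so an interval's length is `end - start`.
#'
#' @param text character vector of locus strings.
#' @param convention `"inclusive"` (1-based inclusive, the printed form;
#'   default) or `"bed"` (already 0-based half-open).
#' @param assembly optional [genome_assembly()]; when given, chromosome
#'   names are checked and intervals must fit on their chromosome.
#' @return a `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open), one row per input string.
#' @examples
#' parse_locus("chr16:22684122-22685282")   # length 1161
#' @seealso [format_locus()] for the inverse.
#' @export
parse_locus <- function(text, convention = c("inclusive", "bed"),
                        assembly = NULL) {
  convention <- match.arg(convention)
  text <- as.character(text)
  # separators ":" or ratio U+2236; dash "-", en-dash U+2013 or minus U+2212
  sep <- "[:\u2236]"
  dash <- "[-\u2013\u2212]"
  pat <- paste0("^\\s*([^\\s:\u2236]+)\\s*", sep, "\\s*([0-9][0-9,]*)",
                "\\s*", dash, "\\s*([0-9][0-9,]*)\\s*$")
  m <- regmatches(text, regexec(pat, text, perl = TRUE))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed locus string: '", text[which(bad)[1L]], "'")
  }
  chrom <- vapply(m, `[[`, "", 2L)
  a <- as.numeric(gsub(",", "", vapply(m, `[[`, "", 3L), fixed = TRUE))
  b <- as.numeric(gsub(",", "", vapply(m, `[[`, "", 4L), fixed = TRUE))
  if (convention == "inclusive") {
    if (any(a > b)) {
      i <- which(a > b)[1L]
      stop("start exceeds end in locus '", text[i], "'")
    }
    if (any(a < 1)) stop("1-based coordinates must be >= 1")
    start <- a - 1
    end <- b
  } else {
    if (any(a >= b)) {
      i <- which(a >= b)[1L]
      stop("start must be < end in half-open locus '", text[i], "'")
    }
    start <- a
    end <- b
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (!is.null(assembly)) validate_on_assembly(out, assembly)
  out
}

#' Serialize intervals back to printed locus strings
#'
#' The inverse of [parse_locus()]: internal 0-based half-open intervals
#' are printed as 1-based inclusive `chrom:start-end` strings (separator
#' and dash normalized to ASCII).
#'
#' @param x a `data.frame` with `chrom`, `start`, `end` columns or a
#'   [feature_set()].
#' @param big_mark thousands separator, default none.
#' @return character vector of locus strings.
#' @export
format_locus <- function(x, big_mark = "") {
  df <- as_feature_frame(x)
  sprintf("%s:%s-%s", df$chrom,
          formatC(df$start + 1, format = "d", big.mark = big_mark),
          formatC(df$end, format = "d", big.mark = big_mark))
}

validate_on_assembly <- function(df, assembly) {
  lens <- chrom_lengths(assembly)
  unknown <- setdiff(unique(df$chrom), names(lens))
  if (length(unknown)) {
    stop("unknown chromosome '", unknown[1L], "' for assembly '",
         assembly$name, "'")
  }
  over <- df$end > lens[df$chrom]
  if (any(over)) {
    i <- which(over)[1L]
    stop("interval ", format_locus(df[i, , drop = FALSE]),
         " extends beyond chromosome end on assembly '", assembly$name, "'")
  }
  invisible(TRUE)
}

#' Construct a set of named genomic features
#'
#' A feature set holds intervals of one kind (enhancers, CNVs, Indels,
#' syndrome regions) in the internal 0-based half-open convention,
#' optionally bound to an assembly.  Extra columns (bracketing genes,
#' expression status, ...) are carried along as attributes of each
#' feature.
#'
#' @param features a `data.frame` with columns `chrom`, `start`, `end`,
#'   optionally `id`, plus any attribute columns.
#' @param kind one of `"generic"`, `"enhancer"`, `"cnv"`, `"indel"`,
#'   `"syndrome_region"`.
#' @param assembly optional [genome_assembly()].
#' @param label optional display label for the set.
#' @return an object of class `feature_set`.
#' @export
feature_set <- function(features,
                        kind = c("generic", "enhancer", "cnv", "indel",
                                 "syndrome_region"),
                        assembly = NULL, label = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(features))
  if (!all(c("chrom", "start", "end") %in% names(features))) {
    stop("features need 'chrom', 'start' and 'end' columns")
  }
  features$chrom <- as.character(features$chrom)
  features$start <- as.numeric(features$start)
  features$end <- as.numeric(features$end)
  bad <- !is.finite(features$start) | !is.finite(features$end) |
    features$start < 0 | features$start >= features$end
  if (any(bad)) {
    stop("invalid interval at row ", which(bad)[1L],
         ": need 0 <= start < end")
  }
  if ("id" %in% names(features)) {
    ids <- features$id[!is.na(features$id)]
    if (anyDuplicated(ids)) {
      stop("duplicate feature id: '", ids[duplicated(ids)][1L], "'")
    }
  }
  if (!is.null(assembly)) validate_on_assembly(features, assembly)
  rownames(features) <- NULL
  if (is.null(label)) label <- kind
  structure(list(features = features, kind = kind,
                 assembly = assembly, label = label),
            class = "feature_set")
}

#' Number of features in a set
#' @param x a [feature_set()].
#' @export
n_features <- function(x) {
  stopifnot(inherits(x, "feature_set"))
  nrow(x$features)
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set '%s' (%s): %d intervals%s>\n",
              x$label, x$kind, n_features(x),
              if (is.null(x$assembly)) "" else
                paste0(" on ", x$assembly$name)))
  invisible(x)
}

# Coerce a feature_set or bare data.frame to the internal interval frame.
as_feature_frame <- function(x) {
  if (inherits(x, "feature_set")) return(x$features)
  if (is.data.frame(x)) return(x)
  if (is.list(x) && all(c("chrom", "start", "end") %in% names(x))) {
    return(data.frame(chrom = x$chrom, start = x$start, end = x$end,
                      stringsAsFactors = FALSE))
  }
  stop("cannot interpret object as genomic intervals")
}

# GRanges view of a feature set (1-based closed, as IRanges requires).
as_granges <- function(x) {
  df <- as_feature_frame(x)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
  if ("id" %in% names(df)) S4Vectors::mcols(gr)$id <- df$id
  gr
}

#' Read a feature table with a declared schema
#'
#' Reads a TSV (or other delimited) table and builds a [feature_set()],
#' either from a single locus-string column (parsed with [parse_locus()])
#' or from separate chromosome/start/end columns.  All remaining columns
#' are preserved as feature attributes.
#'
#' @param path file path.
#' @param locus name of a locus-string column, or `NULL`.
#' @param chrom,start,end column names used when `locus` is `NULL`.
#' @param id optional name of the feature-id column.
#' @param coords coordinate dialect of the input: `"inclusive"` (1-based
#'   inclusive, the printed-table norm) or `"bed"` (0-based half-open).
#' @param kind,assembly,label passed to [feature_set()].
#' @param sep field separator, default tab.
#' @return a [feature_set()].
#' @export
read_feature_table <- function(path, locus = NULL, chrom = "chrom",
                               start = "start", end = "end", id = NULL,
                               coords = c("inclusive", "bed"),
                               kind = "generic", assembly = NULL,
                               label = NULL, sep = "\t") {
  coords <- match.arg(coords)
  if (!file.exists(path)) stop("feature table not found: ", path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "#",
                           encoding = "UTF-8")
  need <- c(if (!is.null(locus)) locus else c(chrom, start, end), id)
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("column '", miss[1L], "' not found in ", path)
  }
  if (nrow(tab) == 0L) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE)
    return(feature_set(out, kind = kind, assembly = assembly, label = label))
  }
  used <- character()
  if (!is.null(locus)) {
    if (!locus %in% names(tab)) {
      stop("column '", locus, "' not found in ", path)
    }
    ivl <- tryCatch(parse_locus(tab[[locus]], convention = coords),
                    error = function(e) {
                      # pinpoint the offending line for the user
                      for (i in seq_len(nrow(tab))) {
                        ok <- tryCatch({
                          parse_locus(tab[[locus]][i], convention = coords)
                          TRUE
                        }, error = function(e2) FALSE)
                        if (!ok) stop("line ", i + 1L, " of ", path, ": ",
                                      conditionMessage(e), call. = FALSE)
                      }
                      stop(e)
                    })
    used <- locus
  } else {
    miss <- setdiff(c(chrom, start, end), names(tab))
    if (length(miss)) {
      stop("missing column(s) in ", path, ": ",
           paste(miss, collapse = ", "))
    }
    s <- as.numeric(tab[[start]])
    e <- as.numeric(tab[[end]])
    if (coords == "inclusive") s <- s - 1
    bad <- !is.finite(s) | !is.finite(e) | s < 0 | s >= e
    if (any(bad)) {
      stop("line ", which(bad)[1L] + 1L, " of ", path,
           ": invalid coordinates")
    }
    ivl <- data.frame(chrom = as.character(tab[[chrom]]),
                      start = s, end = e, stringsAsFactors = FALSE)
    used <- c(chrom, start, end)
  }
  if (!is.null(id)) {
    if (!id %in% names(tab)) stop("column '", id, "' not found in ", path)
    ivl$id <- as.character(tab[[id]])
    used <- c(used, id)
  }
  extra <- setdiff(names(tab), used)
  for (col in extra) ivl[[col]] <- tab[[col]]
  feature_set(ivl, kind = kind, assembly = assembly, label = label)
}

#' Read BED3/BED6 intervals
#'
#' BED input is already 0-based half-open and is passed through without
#' coordinate shifting.  Columns beyond the first three are mapped to
#' `id` (name), `score` and `strand` when present; strand is carried but
#' ignored by all analyses.
#'
#' @param path BED file path.
#' @inheritParams read_feature_table
#' @return a [feature_set()].
#' @export
read_bed <- function(path, kind = "generic", assembly = NULL, label = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  if (ncol(tab) < 3L) stop("BED needs at least 3 columns: ", path)
  names(tab)[1:3] <- c("chrom", "start", "end")
  if (ncol(tab) >= 4L) names(tab)[4L] <- "id"
  if (ncol(tab) >= 5L) names(tab)[5L] <- "score"
  if (ncol(tab) >= 6L) names(tab)[6L] <- "strand"
  feature_set(tab[, seq_len(min(ncol(tab), 6L)), drop = FALSE],
              kind = kind, assembly = assembly, label = label)
}

#' Write intervals as BED
#'
#' Emits BED3 (or BED6 when `id` is present: name = id, score = 0,
#' strand = ".") in the native half-open convention.
#'
#' @param x a [feature_set()] or interval `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- as_feature_frame(x)
  out <- data.frame(chrom = df$chrom,
                    start = format(df$start, scientific = FALSE, trim = TRUE),
                    end = format(df$end, scientific = FALSE, trim = TRUE),
                    stringsAsFactors = FALSE)
  if ("id" %in% names(df)) {
    out$name <- df$id
    out$score <- if ("score" %in% names(df)) df$score else 0
    out$strand <- if ("strand" %in% names(df)) df$strand else "."
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
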