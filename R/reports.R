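#' Path to a bundled coordinate fixture
#'
#' The package ships small plain-text transcriptions of published
#' coordinate tables: VISTA enhancer loci, the copy-number-polymorphism
#' (CNP) and "polymorphic-DC" CNV sets that overlap them, the DGV Indels
#' overlapping enhancers, three patient deletions validated to cover
#' enhancer loci, and UCSC hg18 chromosome sizes.
#'
#' @param file fixture file name; with no argument, lists the available
#'   fixtures.
#' @return a file path, or a character vector of fixture names.
#' @export
enhancer_fixture <- function(file = NULL) {
  dir <- system.file("extdata", package = "enhancerCNV", mustWork = TRUE)
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    stop("no fixture '", file, "'; available: ",
         paste(list.files(dir), collapse = ", "))
  }
  path
}

#' Load the bundled published coordinate sets
#'
#' Parses the bundled fixtures into [feature_set()]s.  The sets are not
#' bound to an assembly: the published tables mix genome builds, so
#' their coordinates are treated as opaque labels (no liftover).
#'
#' @return a list of feature sets: `enhancers` (all distinct enhancer
#'   loci appearing in the fixtures), `cnp` (validated copy-number
#'   polymorphisms), `polymorphic_dc` (the second highly polymorphic CNV
#'   set), `indels` (DGV Indels), `patient_deletions` (deletions
#'   validated in patients).
#' @export
published_loci <- function() {
  enh <- read_feature_table(enhancer_fixture("vista_enhancers.tsv"),
                            locus = "enhancer_position", id = "enhancer_id",
                            kind = "enhancer", label = "VISTA enhancer loci")
  cnp <- read_feature_table(enhancer_fixture("cnp_cnvs.tsv"),
                            locus = "cnv_position", id = "cnv_id",
                            kind = "cnv", label = "CNP")
  dc <- read_feature_table(enhancer_fixture("polymorphic_dc_cnvs.tsv"),
                           locus = "cnv_position", id = "cnv_id",
                           kind = "cnv", label = "polymorphic-DC")
  ind <- read_feature_table(enhancer_fixture("dgv_indels.tsv"),
                            locus = "indel_position", id = "indel_id",
                            kind = "indel", label = "DGV Indels")
  del <- read_feature_table(enhancer_fixture("patient_deletions.tsv"),
                            locus = "deletion_position", id = "sample",
                            kind = "cnv", label = "patient deletions")
  list(enhancers = enh, cnp = cnp, polymorphic_dc = dc, indels = ind,
       patient_deletions = del)
}

#' Write a coverage-comparison report as TSV
#'
#' The table of [coverage_table()] with `# `-prefixed header comments
#' recording parameters, so the file is self-describing.
#'
#' @param tab output of [coverage_table()].
#' @param path output path.
#' @param comments optional named list written as `# key: value` header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_coverage_report <- function(tab, path, comments = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(comments)) {
    writeLines(sprintf("# %s: %s", nm, format(comments[[nm]])), con)
  }
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a probe-design report as JSON
#'
#' Per-tier counts and achieved spacing/resolution statistics plus the
#' residual capacity, in machine-readable form.
#'
#' @param plan a `probe_plan` from [assemble_plan()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design_report <- function(plan, path) {
  stopifnot(inherits(plan, "probe_plan"))
  tiers <- lapply(plan$tiers, function(t) {
    a <- t$achieved
    a$per_feature <- NULL   # bulky; the BED carries per-probe detail
    a
  })
  out <- list(capacity = plan$capacity,
              per_tier = as.list(plan$per_tier),
              residual = plan$residual,
              residual_fraction = plan$residual_fraction,
              n_filler_placed = plan$n_filler_placed,
              seed = plan$seed,
              tiers = tiers)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write annotated calls as TSV (and optionally BED6)
#'
#' The TSV carries one row per call with its classification; the BED6
#' uses the classification as name and the probe count as score.
#'
#' @param annotated an `annotated_calls` object from [annotate_calls()].
#' @param path output TSV path.
#' @param bed optional BED6 output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(annotated, path, bed = NULL) {
  stopifnot(inherits(annotated, "annotated_calls"))
  utils::write.table(annotated$calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bed)) {
    df <- annotated$calls
    out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                      id = df$classification,
                      score = if ("probe_count" %in% names(df))
                        ifelse(is.na(df$probe_count), 0, df$probe_count)
                      else 0,
                      strand = ".", stringsAsFactors = FALSE)
    write_bed(out, bed)
  }
  invisible(path)
}

#' Record run provenance
#'
#' Writes a JSON file with the inputs, parameters, seed and package
#' version of a run, so outputs are traceable and reruns comparable.
#' No timestamps are written: identical configurations give
#' bit-identical provenance.
#'
#' @param path output path.
#' @param params named list of parameters and input descriptions.
#' @param seed the run seed (recorded even when `NULL`).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, params = list(), seed = NULL) {
  out <- list(package = "enhancerCNV",
              version = as.character(utils::packageVersion("enhancerCNV")),
              seed = seed,
              params = params)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
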