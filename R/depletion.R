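#' Expected coverage under random placement
#'
#' Under the null hypothesis that CNVs land on the genome independently
#' of enhancer positions, the fraction of target features overlapped is
#' the fraction of the genome covered by the (merged) cover set, and the
#' expected number of covered targets is `N_targets` times that
#' fraction.  This is the expectation against which observed enhancer
#' coverage is compared.
#'
#' @param targets target [feature_set()] (e.g. enhancer loci).
#' @param cover covering [feature_set()] (e.g. a CNV set).
#' @param assembly a [genome_assembly()] giving the genome denominator.
#' @return list with `expected_count` and `expected_base_fraction`.
#' @export
expected_counts <- function(targets, cover, assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  check_same_assembly(targets, assembly)
  check_same_assembly(cover, assembly)
  G <- genome_size(assembly)
  if (!is.finite(G) || G <= 0) stop("assembly has no usable genome size")
  cdf <- as_feature_frame(cover)
  frac <- if (nrow(cdf) == 0L) 0 else {
    sum(as.numeric(GenomicRanges::width(
      GenomicRanges::reduce(as_granges(cdf))))) / G
  }
  list(expected_count = n_features(targets) * frac,
       expected_base_fraction = frac)
}

#' Observed-vs-expected coverage comparison (the depletion statistic)
#'
#' Computes, for one target set against one cover set: the observed
#' number and base fraction of targets covered, the expectation from the
#' genome coverage fraction of the cover set, the fold ratio
#' observed/expected on base fractions, and count-based test p-values
#' (1-df chi-square goodness of fit and exact binomial, both reported).
#' Fold below 1 with a small p-value indicates depletion of the cover
#' class at the target loci, the signature of negative selection.
#'
#' Observed "fraction of targets" is deliberately reported both ways:
#' as the base fraction of target bases covered (what coverage tools
#' plot) and as the feature count covered (what the tests use).
#'
#' @inheritParams expected_counts
#' @param alternative alternative for the binomial test: `"less"`
#'   (depletion, default) or `"two.sided"`.
#' @return an object of class `coverage_comparison`.
#' @export
depletion_statistic <- function(targets, cover, assembly,
                                alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  fc <- feature_coverage(targets, cover)
  bc <- base_coverage(targets, cover)
  ec <- expected_counts(targets, cover, assembly)
  n <- n_features(targets)
  fold <- if (bc$fraction == 0 && ec$expected_base_fraction == 0) {
    0
  } else {
    bc$fraction / ec$expected_base_fraction
  }
  tests <- if (ec$expected_count > 0 && ec$expected_count < n) {
    test_counts(fc$count, ec$expected_count, n, alternative = alternative)
  } else {
    list(p_chisq = NA_real_, p_binomial = NA_real_)
  }
  structure(list(
    target_label = if (inherits(targets, "feature_set")) targets$label else "targets",
    cover_label = if (inherits(cover, "feature_set")) cover$label else "cover",
    n_targets = n,
    observed_count = fc$count,
    expected_count = ec$expected_count,
    observed_base_fraction = bc$fraction,
    expected_base_fraction = ec$expected_base_fraction,
    fold = fold,
    p_chisq = tests$p_chisq,
    p_binomial = tests$p_binomial,
    alternative = alternative,
    hits = fc$hits,
    permutation = NULL), class = "coverage_comparison")
}

#' @export
print.coverage_comparison <- function(x, ...) {
  cat(sprintf("<coverage_comparison: '%s' vs '%s'>\n",
              x$target_label, x$cover_label))
  cat(sprintf("  targets covered: %d / %d (expected %.2f)\n",
              x$observed_count, x$n_targets, x$expected_count))
  cat(sprintf("  base fraction:   observed %.4g, expected %.4g, fold %.3g\n",
              x$observed_base_fraction, x$expected_base_fraction, x$fold))
  cat(sprintf("  p (chi-square) = %.3g, p (binomial, %s) = %.3g\n",
              x$p_chisq, x$alternative, x$p_binomial))
  if (!is.null(x$permutation)) {
    cat(sprintf("  permutation p (count) = %.3g over %d permutations\n",
                x$permutation$p_count, x$permutation$n_permutations))
  }
  invisible(x)
}

#' Count-based tests of the depletion hypothesis
#'
#' Given the observed number of covered targets and the expectation from
#' the genome coverage fraction, computes a 1-df chi-square goodness of
#' fit on the {covered, uncovered} counts and an exact binomial test
#' with success probability `expected_count / n_targets`.  Both are
#' reported; neither p-value is ever floored or clamped.
#'
#' @param observed_count targets observed covered.
#' @param expected_count expectation under random placement (need not be
#'   an integer); must be strictly between 0 and `n_targets`.
#' @param n_targets total number of target features.
#' @param alternative `"less"` (one-sided toward depletion, default) or
#'   `"two.sided"` for the binomial test; the chi-square test is
#'   inherently two-sided.
#' @return list with `p_chisq` and `p_binomial`.
#' @examples
#' test_counts(0, 5, 10)$p_binomial   # 0.5^10
#' @export
test_counts <- function(observed_count, expected_count, n_targets,
                        alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (observed_count < 0 || observed_count > n_targets) {
    stop("observed_count must lie in [0, n_targets]")
  }
  if (expected_count <= 0 || expected_count >= n_targets) {
    stop("degenerate expectation: expected_count must be in (0, n_targets)")
  }
  p0 <- expected_count / n_targets
  exp_unc <- n_targets - expected_count
  stat <- (observed_count - expected_count)^2 / expected_count +
    (observed_count - expected_count)^2 / exp_unc
  p_chisq <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p_binomial <- stats::binom.test(observed_count, n_targets, p = p0,
                                  alternative = alternative)$p.value
  list(p_chisq = p_chisq, p_binomial = p_binomial)
}

#' Permutation null by random interval placement
#'
#' Each permutation re-places every cover interval uniformly at random
#' on its original chromosome, preserving its length (start drawn
#' uniformly from `[0, chrom_length - length]`), and recomputes the
#' covered-target count and covered-base fraction.  The empirical
#' p-value uses the add-one correction
#' `p = (1 + #\{null <= observed\}) / (1 + n_permutations)` so it can
#' never be zero.  An optional exclusion mask forbids re-placements that
#' overlap masked intervals (assembly gaps, centromeres); it is off by
#' default.
#'
#' @inheritParams expected_counts
#' @param n_permutations number of permutations (>= 1).
#' @param seed integer seed; the summary is fully reproducible from it.
#' @param alternative `"less"` (depletion, default) or `"two.sided"`.
#' @param mask optional [feature_set()] of excluded intervals.
#' @param max_tries resampling attempts per permutation when a mask is
#'   set.
#' @return an object of class `permutation_summary`: null statistic
#'   samples (`null_count`, `null_fraction`), empirical p-values
#'   (`p_count`, `p_fraction`), null means and 95% quantile intervals.
#' @export
permutation_null <- function(targets, cover, assembly, n_permutations = 999L,
                             seed = 1L, alternative = c("less", "two.sided"),
                             mask = NULL, max_tries = 100L) {
  alternative <- match.arg(alternative)
  stopifnot(n_permutations >= 1)
  check_same_assembly(targets, assembly)
  check_same_assembly(cover, assembly)
  tdf <- as_feature_frame(targets)
  cdf <- as_feature_frame(cover)
  if (nrow(tdf) == 0L || nrow(cdf) == 0L) {
    stop("permutation null needs non-empty target and cover sets")
  }
  lens <- chrom_lengths(assembly)
  unknown <- setdiff(unique(cdf$chrom), names(lens))
  if (length(unknown)) stop("cover chromosome not on assembly: ", unknown[1L])
  clen <- lens[cdf$chrom]
  ilen <- cdf$end - cdf$start
  if (any(ilen > clen)) {
    stop("cover interval longer than its chromosome: row ",
         which(ilen > clen)[1L])
  }
  tmerged <- merge_features(tdf)$features
  ttot <- sweep_merged_width(tmerged)
  mdf <- if (!is.null(mask)) as_feature_frame(mask) else NULL

  # covered-target count plus covered-base fraction; the intersection
  # width comes from inclusion-exclusion on union widths
  stat_pair <- function(cover) {
    cnt <- sum(sweep_overlap_any(tdf, cover))
    wB <- sweep_merged_width(cover)
    wAuB <- sweep_merged_width(rbind(tmerged[, c("chrom", "start", "end")],
                                     cover[, c("chrom", "start", "end")]))
    c(cnt, (ttot + wB - wAuB) / ttot)
  }
  obs <- stat_pair(cdf)

  n <- nrow(cdf)
  null_count <- numeric(n_permutations)
  null_fraction <- numeric(n_permutations)
  withr::with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      ns <- floor(stats::runif(n, 0, clen - ilen + 1))
      ns <- pmin(ns, clen - ilen)
      if (!is.null(mdf)) {
        for (try in seq_len(max_tries)) {
          perm <- data.frame(chrom = cdf$chrom, start = ns, end = ns + ilen,
                             stringsAsFactors = FALSE)
          hit <- sweep_overlap_any(perm, mdf)
          if (!any(hit)) break
          if (try == max_tries) {
            stop("could not place intervals outside the mask after ",
                 max_tries, " tries")
          }
          redo <- which(hit)
          ns[redo] <- pmin(
            floor(stats::runif(length(redo), 0, clen[redo] - ilen[redo] + 1)),
            clen[redo] - ilen[redo])
        }
      }
      st <- stat_pair(data.frame(chrom = cdf$chrom, start = ns,
                                 end = ns + ilen, stringsAsFactors = FALSE))
      null_count[b] <- st[1L]
      null_fraction[b] <- st[2L]
    }
  })

  emp_p <- function(null, observed) {
    p_lo <- (1 + sum(null <= observed)) / (1 + n_permutations)
    if (alternative == "less") return(p_lo)
    p_hi <- (1 + sum(null >= observed)) / (1 + n_permutations)
    min(1, 2 * min(p_lo, p_hi))
  }
  structure(list(
    n_permutations = as.integer(n_permutations),
    seed = seed,
    alternative = alternative,
    observed_count = obs[1L],
    observed_fraction = obs[2L],
    null_count = null_count,
    null_fraction = null_fraction,
    p_count = emp_p(null_count, obs[1L]),
    p_fraction = emp_p(null_fraction, obs[2L]),
    null_mean_count = mean(null_count),
    null_mean_fraction = mean(null_fraction),
    ci_count = stats::quantile(null_count, c(0.025, 0.975), names = FALSE),
    ci_fraction = stats::quantile(null_fraction, c(0.025, 0.975),
                                  names = FALSE)),
    class = "permutation_summary")
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat(sprintf("<permutation_summary: %d permutations, seed %s>\n",
              x$n_permutations, format(x$seed)))
  cat(sprintf("  observed count %g (null mean %.2f, 95%% [%g, %g]), p = %.4g\n",
              x$observed_count, x$null_mean_count,
              x$ci_count[1], x$ci_count[2], x$p_count))
  cat(sprintf("  observed fraction %.4g (null mean %.4g), p = %.4g\n",
              x$observed_fraction, x$null_mean_fraction, x$p_fraction))
  invisible(x)
}

#' Attach a permutation null to a comparison
#'
#' Convenience composition of [depletion_statistic()] and
#' [permutation_null()].
#'
#' @inheritParams permutation_null
#' @return a `coverage_comparison` with its `permutation` slot filled.
#' @export
depletion_with_permutation <- function(targets, cover, assembly,
                                       n_permutations = 999L, seed = 1L,
                                       alternative = c("less", "two.sided"),
                                       mask = NULL) {
  alternative <- match.arg(alternative)
  cmp <- depletion_statistic(targets, cover, assembly,
                             alternative = alternative)
  cmp$permutation <- permutation_null(targets, cover, assembly,
                                      n_permutations = n_permutations,
                                      seed = seed, alternative = alternative,
                                      mask = mask)
  cmp
}

#' Long-format table of coverage comparisons
#'
#' One row per comparison, with observed and expected counts and base
#' fractions, fold and p-values — the table behind the familiar
#' observed-vs-expected bar chart.
#'
#' @param comparisons a non-empty list of `coverage_comparison` objects
#'   (a single object is accepted).
#' @return a `data.frame` with one row per comparison.
#' @export
coverage_table <- function(comparisons) {
  if (inherits(comparisons, "coverage_comparison")) {
    comparisons <- list(comparisons)
  }
  if (!length(comparisons)) stop("no comparisons supplied")
  ok <- vapply(comparisons, inherits, TRUE, "coverage_comparison")
  if (!all(ok)) stop("all elements must be coverage_comparison objects")
  do.call(rbind, lapply(comparisons, function(x) {
    data.frame(
      targets = x$target_label,
      cover = x$cover_label,
      n_targets = x$n_targets,
      observed_count = x$observed_count,
      expected_count = x$expected_count,
      observed_base_fraction = x$observed_base_fraction,
      expected_base_fraction = x$expected_base_fraction,
      fold = x$fold,
      p_chisq = x$p_chisq,
      p_binomial = x$p_binomial,
      p_permutation = if (is.null(x$permutation)) NA_real_ else
        x$permutation$p_count,
      stringsAsFactors = FALSE)
  }))
}

#' Bar chart of observed vs expected coverage fractions
#'
#' Paired bars (observed grey, expected black) of the base fractions per
#' cover set.
#'
#' @param tab output of [coverage_table()].
#' @param ... passed to [graphics::barplot()].
#' @return the bar midpoints, invisibly.
#' @export
plot_coverage_table <- function(tab, ...) {
  stopifnot(is.data.frame(tab), nrow(tab) >= 1)
  m <- rbind(observed = tab$observed_base_fraction,
             expected = tab$expected_base_fraction)
  colnames(m) <- tab$cover
  mid <- graphics::barplot(m, beside = TRUE,
                           col = c("grey60", "black"),
                           ylab = "fraction covered",
                           legend.text = rownames(m), ...)
  invisible(mid)
}
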