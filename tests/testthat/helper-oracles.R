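# Per-base brute-force oracles: genomic intervals realized as boolean
# arrays, one cell per base.  Deliberately naive and independent of the
# package's IRanges-backed implementation; only usable on tiny genomes.

bf_mask <- function(df, chrom, len) {
  v <- logical(len)
  sub <- df[df$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    lo <- sub$start[i] + 1L
    hi <- min(sub$end[i], len)
    if (hi >= lo) v[lo:hi] <- TRUE
  }
  v
}

bf_merge <- function(df, lens) {
  out <- list()
  for (ch in names(lens)) {
    v <- bf_mask(df, ch, lens[[ch]])
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (any(keep)) {
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep] - 1,
                              end = ends[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

bf_base_coverage <- function(targets, cover, lens) {
  covered <- 0
  total <- 0
  for (ch in names(lens)) {
    tv <- bf_mask(targets, ch, lens[[ch]])
    cv <- bf_mask(cover, ch, lens[[ch]])
    covered <- covered + sum(tv & cv)
    total <- total + sum(tv)
  }
  list(covered = covered, total = total,
       fraction = if (total > 0) covered / total else NaN)
}

bf_feature_coverage <- function(targets, cover) {
  hit <- logical(nrow(targets))
  for (i in seq_len(nrow(targets))) {
    for (j in seq_len(nrow(cover))) {
      if (targets$chrom[i] == cover$chrom[j] &&
          targets$start[i] < cover$end[j] &&
          cover$start[j] < targets$end[i]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  sum(hit)
}

# A random tiny genome plus random interval frames, for oracle
# equivalence sweeps.  Caller controls the RNG state.
random_interval_case <- function(max_genome = 1e6) {
  n_chrom <- sample(1:3, 1)
  lens <- stats::setNames(sample(5000:50000, n_chrom, replace = TRUE),
                          paste0("c", seq_len(n_chrom)))
  stopifnot(sum(lens) <= max_genome)
  draw <- function(n_max) {
    n <- sample(0:n_max, 1)
    if (n == 0) {
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), stringsAsFactors = FALSE))
    }
    ch <- sample(names(lens), n, replace = TRUE)
    w <- sample(1:5000, n, replace = TRUE)
    w <- pmin(w, lens[ch])
    s <- floor(stats::runif(n, 0, lens[ch] - w + 1))
    data.frame(chrom = ch, start = s, end = s + w,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  list(lens = lens,
       assembly = genome_assembly(lens, name = "rnd"),
       targets = draw(20), cover = draw(25))
}

# Exact binomial lower-tail by log-binomial-coefficient summation;
# independent of pbinom/dbinom.
bf_binom_tail <- function(k, n, p) {
  kk <- 0:k
  sum(exp(lchoose(n, kk) + kk * log(p) + (n - kk) * log1p(-p)))
}
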