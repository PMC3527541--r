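# Internal plain-vector interval sweeps for the simulation and
# permutation hot loops, where per-call S4 container overhead dominates.
# Exact: chromosomes are mapped onto disjoint coordinate blocks so a
# single global cumulative-maximum sweep handles all of them at once.
# The user-facing interval operations stay on GenomicRanges; these
# helpers are never exported.

# Offset each chromosome into its own coordinate block.
chrom_offsets <- function(chroms, block) {
  lv <- sort(unique(chroms))
  stats::setNames((seq_along(lv) - 1) * block, lv)
}

# Total width of the union of intervals in df (chrom/start/end).
sweep_merged_width <- function(df) {
  n <- nrow(df)
  if (n == 0L) return(0)
  block <- max(df$end) + 1
  off <- chrom_offsets(df$chrom, block)
  s <- df$start + off[df$chrom]
  e <- df$end + off[df$chrom]
  o <- order(s)
  s <- s[o]
  e <- e[o]
  cme <- cummax(e)
  prev <- c(-Inf, cme[-n])
  sum(pmax(0, e - pmax(s, prev)))
}

# For each interval of q: does it overlap any interval of s?
sweep_overlap_any <- function(q, s) {
  if (nrow(q) == 0L) return(logical(0))
  if (nrow(s) == 0L) return(rep(FALSE, nrow(q)))
  block <- max(q$end, s$end) + 1
  off <- chrom_offsets(c(q$chrom, s$chrom), block)
  qs <- q$start + off[q$chrom]
  qe <- q$end + off[q$chrom]
  ss <- s$start + off[s$chrom]
  se <- s$end + off[s$chrom]
  o <- order(ss)
  ss <- ss[o]
  se <- se[o]
  cme <- cummax(se)
  # index of the last s interval with start < q end (block-local by
  # construction: other blocks cannot produce false hits)
  idx <- findInterval(qe - 0.5, ss)
  idx > 0 & cme[pmax(idx, 1L)] > qs
}

# Greedy left-to-right selection of mutually non-overlapping intervals
# (input need not be sorted); returns a logical keep mask.
sweep_keep_disjoint <- function(df) {
  n <- nrow(df)
  if (n <= 1L) return(rep(TRUE, n))
  block <- max(df$end) + 1
  off <- chrom_offsets(df$chrom, block)
  s <- df$start + off[df$chrom]
  e <- df$end + off[df$chrom]
  o <- order(s)
  keep <- logical(n)
  bound <- -Inf
  for (i in o) {
    if (s[i] >= bound) {
      keep[i] <- TRUE
      bound <- e[i]   # > s[i] >= old bound, so the bound is monotone
    }
  }
  keep
}
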