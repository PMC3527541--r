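#' Define a seeded synthetic scenario
#'
#' A scenario fixes everything the generator needs: the genome, the
#' enhancer set (count and length distribution), the CNV set (length
#' distribution and either a fixed count or a target genome-coverage
#' fraction), the enhancer-depletion parameter `delta`, probe noise and
#' planted aberrations.  All generated objects are reproducible from the
#' seed alone.
#'
#' Depletion is modeled as thinning: each candidate CNV that overlaps
#' any enhancer is retained with probability `delta`.  `delta = 1` means
#' CNVs land independently of enhancers (no selection); `delta = 0`
#' excludes enhancer-overlapping CNVs entirely.  Thinning is the
#' simplest generative mechanism whose expectation matches the fold
#' statistic of the depletion analysis.
#'
#' @param seed integer seed.
#' @param assembly a [genome_assembly()]; default two 50-Mb chromosomes.
#' @param n_enhancers number of enhancer loci.
#' @param enhancer_length length range in bp, drawn uniformly; the
#'   default 800–2200 bp matches published enhancer loci (~1–2 kb).
#' @param coverage target merged CNV genome-coverage fraction in (0,1),
#'   achieved to ±2% relative tolerance; or `NULL` to place exactly
#'   `n_cnvs` CNVs with no coverage targeting.
#' @param n_cnvs CNV count when `coverage` is `NULL` (required then).
#' @param cnv_length CNV length range in bp, drawn log-uniformly;
#'   default 1 kb – 500 kb.
#' @param delta depletion parameter in `[0, 1]`.
#' @param sigma probe log2-ratio noise SD.  Default 0.15, a good-quality
#'   aCGH run (DLRSpread in the accepted 0.1–0.2 QC band).
#' @param probe_spacing uniform probe spacing in bp for generated
#'   tracks.
#' @param aberrations planted copy-number events: either a count (events
#'   drawn by seed) or a `data.frame` with columns `chrom`,
#'   `start_index` (first probe, per-chromosome index), `n_probes`,
#'   `shift`.
#' @param aberration_probes event size range in probes when drawing.
#' @param aberration_shifts log2 shifts sampled when drawing; defaults
#'   are the single-copy loss `log2(1/2) = -1` and single-copy gain
#'   `log2(3/2) ~ 0.585`.
#' @return an object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed,
                               assembly = NULL,
                               n_enhancers = 200L,
                               enhancer_length = c(800, 2200),
                               coverage = 0.1,
                               n_cnvs = NULL,
                               cnv_length = c(1e3, 5e5),
                               delta = 1,
                               sigma = 0.15,
                               probe_spacing = 5000,
                               aberrations = 3L,
                               aberration_probes = c(5L, 15L),
                               aberration_shifts = c(loss = -1,
                                                     gain = log2(3 / 2))) {
  if (is.null(assembly)) {
    assembly <- genome_assembly(c(chrS1 = 5e7, chrS2 = 5e7),
                                name = "synthetic")
  }
  stopifnot(inherits(assembly, "genome_assembly"))
  if (length(seed) != 1L || !is.finite(seed)) stop("seed must be a number")
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]")
  if (is.null(coverage)) {
    if (is.null(n_cnvs) || n_cnvs < 1) {
      stop("need n_cnvs when coverage targeting is off")
    }
  } else if (coverage <= 0 || coverage >= 1) {
    stop("coverage must lie in (0, 1)")
  }
  if (n_enhancers < 1) stop("n_enhancers must be > 0")
  stopifnot(length(enhancer_length) == 2L, enhancer_length[1] > 0,
            diff(enhancer_length) >= 0,
            length(cnv_length) == 2L, cnv_length[1] > 0,
            diff(cnv_length) >= 0, sigma >= 0, probe_spacing > 0)
  structure(list(seed = as.integer(seed), assembly = assembly,
                 n_enhancers = as.integer(n_enhancers),
                 enhancer_length = enhancer_length,
                 coverage = coverage, n_cnvs = n_cnvs,
                 cnv_length = cnv_length, delta = delta, sigma = sigma,
                 probe_spacing = probe_spacing,
                 aberrations = aberrations,
                 aberration_probes = as.integer(aberration_probes),
                 aberration_shifts = aberration_shifts),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_scenario seed %d: %s, %d enhancers, ",
                     "%s, delta %.2g, sigma %.2g>\n"),
              x$seed, x$assembly$name, x$n_enhancers,
              if (is.null(x$coverage))
                sprintf("%d CNVs", x$n_cnvs) else
                  sprintf("CNV coverage %.3g", x$coverage),
              x$delta, x$sigma))
  invisible(x)
}

rlunif <- function(n, lo, hi) {
  if (lo == hi) rep(lo, n) else exp(stats::runif(n, log(lo), log(hi)))
}

# Draw n intervals uniformly on the genome: chromosome weighted by
# length, start uniform over valid placements for the drawn length.
draw_intervals <- function(assembly, n, len_lo, len_hi, log_uniform = TRUE) {
  lens <- chrom_lengths(assembly)
  L <- if (log_uniform) round(rlunif(n, len_lo, len_hi)) else
    round(stats::runif(n, len_lo, len_hi))
  L <- pmax(1, pmin(L, max(lens)))
  ch <- sample(names(lens), n, replace = TRUE, prob = lens)
  # redraw chromosomes too short for their interval
  for (it in 1:100) {
    bad <- L > lens[ch]
    if (!any(bad)) break
    ch[bad] <- sample(names(lens), sum(bad), replace = TRUE, prob = lens)
    if (it == 100) stop("interval length exceeds every chromosome")
  }
  s <- floor(stats::runif(n, 0, lens[ch] - L + 1))
  s <- pmin(s, lens[ch] - L)
  data.frame(chrom = ch, start = s, end = s + L,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate the enhancer and CNV feature sets of a scenario
#'
#' Enhancers are placed uniformly without mutual overlap.  CNV
#' candidates are drawn uniformly (chromosome weighted by length, start
#' uniform, length log-uniform); each candidate overlapping any enhancer
#' is retained with probability `delta`.  With coverage targeting on,
#' batches of candidates are accepted until the merged CNV footprint
#' reaches the target fraction within ±2% relative tolerance — near the
#' target, candidate lengths are capped by the remaining deficit so the
#' final coverage cannot overshoot the tolerance.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `enhancers` and `cnvs` [feature_set()]s.
#' @export
generate_features <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  withr::with_seed(scenario$seed, generate_features_impl(scenario))
}

generate_features_impl <- function(sc) {
  asm <- sc$assembly
  G <- genome_size(asm)

  # --- enhancers: uniform, non-overlapping ---
  placed <- NULL
  need <- sc$n_enhancers
  for (it in 1:1000) {
    cand <- draw_intervals(asm, need, sc$enhancer_length[1],
                           sc$enhancer_length[2], log_uniform = FALSE)
    if (!is.null(placed)) {
      cand <- cand[!sweep_overlap_any(cand, placed), , drop = FALSE]
    }
    cand <- cand[sweep_keep_disjoint(cand), , drop = FALSE]
    placed <- if (is.null(placed)) cand else rbind(placed, cand)
    need <- sc$n_enhancers - nrow(placed)
    if (need <= 0L) break
    if (it == 1000) stop("could not place non-overlapping enhancers")
  }
  placed <- placed[seq_len(sc$n_enhancers), , drop = FALSE]
  placed <- placed[order(placed$chrom, placed$start), , drop = FALSE]
  placed$id <- sprintf("enh%04d", seq_len(nrow(placed)))
  enhancers <- feature_set(placed, kind = "enhancer", assembly = asm,
                           label = "synthetic enhancers")

  # --- CNVs: uniform with delta-thinning at enhancers ---
  thin <- function(cand) {
    if (sc$delta >= 1) return(cand)
    hit <- sweep_overlap_any(cand, placed)
    drop <- hit & (stats::runif(nrow(cand)) >= sc$delta)
    cand[!drop, , drop = FALSE]
  }
  mean_len <- if (sc$cnv_length[1] == sc$cnv_length[2]) sc$cnv_length[1] else
    (sc$cnv_length[2] - sc$cnv_length[1]) /
      (log(sc$cnv_length[2]) - log(sc$cnv_length[1]))

  if (is.null(sc$coverage)) {
    acc <- NULL
    for (it in 1:10000) {
      need <- sc$n_cnvs - if (is.null(acc)) 0L else nrow(acc)
      if (need <= 0L) break
      cand <- thin(draw_intervals(asm, max(need, 1L), sc$cnv_length[1],
                                  sc$cnv_length[2]))
      acc <- if (is.null(acc)) cand else rbind(acc, cand)
      if (it == 10000) stop("could not accept the requested CNV count")
    }
    acc <- acc[seq_len(sc$n_cnvs), , drop = FALSE]
  } else {
    target <- sc$coverage * G
    lo <- sc$cnv_length[1]
    acc <- NULL
    cov <- 0
    last_cov <- 0
    stall <- 0L
    for (it in 1:10000) {
      deficit <- target - cov
      if (deficit <= 0) break
      # candidate lengths capped by the deficit so the target cannot be
      # overshot by more than the minimum CNV length
      hi <- min(sc$cnv_length[2], max(lo, deficit))
      mean_hi <- if (hi == lo) lo else (hi - lo) / (log(hi) - log(lo))
      nb <- max(1L, min(500L, floor(0.5 * deficit / mean_hi)))
      cand <- thin(draw_intervals(asm, nb, lo, hi))
      if (nrow(cand)) {
        keep <- cumsum(cand$end - cand$start) <= deficit + lo
        cand <- cand[keep, , drop = FALSE]
      }
      if (nrow(cand)) {
        acc <- if (is.null(acc)) cand else rbind(acc, cand)
        cov <- sweep_merged_width(acc)
      }
      stall <- if (cov - last_cov < 5e-4 * target) stall + 1L else 0L
      last_cov <- cov
      if (stall >= 50L || it == 10000) {
        stop("CNV coverage target unreachable on this genome")
      }
    }
    if (abs(cov - target) / target > 0.02) {
      stop("CNV coverage missed the target beyond tolerance")
    }
  }
  acc <- acc[order(acc$chrom, acc$start), , drop = FALSE]
  acc$id <- sprintf("cnv%05d", seq_len(nrow(acc)))
  cnvs <- feature_set(acc, kind = "cnv", assembly = asm,
                      label = "synthetic CNVs")
  list(enhancers = enhancers, cnvs = cnvs)
}

# Default probe positions of a scenario: uniform spacing per chromosome.
scenario_probe_positions <- function(sc) {
  lens <- chrom_lengths(sc$assembly)
  do.call(rbind, lapply(names(lens), function(ch) {
    data.frame(chrom = ch,
               pos = tile_chromosome(lens[[ch]], sc$probe_spacing),
               stringsAsFactors = FALSE)
  }))
}

# Draw the planted aberration table for a scenario (per-chromosome probe
# counts given); non-overlapping in probe-index space.
draw_aberrations <- function(sc, n_probes_by_chrom) {
  ab <- sc$aberrations
  if (is.data.frame(ab)) {
    stopifnot(all(c("chrom", "start_index", "n_probes", "shift") %in%
                    names(ab)))
    bad <- !(ab$chrom %in% names(n_probes_by_chrom)) |
      ab$start_index < 1 |
      ab$start_index + ab$n_probes - 1 > n_probes_by_chrom[ab$chrom]
    if (any(bad)) {
      stop("planted aberration outside the genome (row ",
           which(bad)[1L], ")")
    }
    return(ab)
  }
  k <- as.integer(ab)
  if (k == 0L) {
    return(data.frame(chrom = character(), start_index = integer(),
                      n_probes = integer(), shift = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- NULL
  for (it in 1:1000) {
    need <- k - if (is.null(out)) 0L else nrow(out)
    if (need <= 0L) break
    np <- sample(seq(sc$aberration_probes[1], sc$aberration_probes[2]),
                 need, replace = TRUE)
    ch <- sample(names(n_probes_by_chrom), need, replace = TRUE,
                 prob = n_probes_by_chrom)
    ok <- np < n_probes_by_chrom[ch]
    np <- np[ok]; ch <- ch[ok]
    if (!length(np)) next
    si <- floor(stats::runif(length(np), 1,
                             n_probes_by_chrom[ch] - np + 1))
    cand <- data.frame(chrom = ch, start_index = as.integer(si),
                       n_probes = as.integer(np),
                       shift = sample(sc$aberration_shifts, length(np),
                                      replace = TRUE),
                       stringsAsFactors = FALSE)
    pool <- if (is.null(out)) cand else rbind(out, cand)
    # keep events disjoint (with a 1-probe gap) in probe-index space
    gr <- GenomicRanges::GRanges(pool$chrom,
                                 IRanges::IRanges(pool$start_index - 1,
                                                  pool$start_index +
                                                    pool$n_probes))
    keep <- GenomicRanges::countOverlaps(gr, gr) == 1L
    keep[seq_len(if (is.null(out)) 0L else nrow(out))] <- TRUE
    out <- pool[keep, , drop = FALSE]
    if (it == 1000) stop("could not place non-overlapping aberrations")
  }
  out[seq_len(k), , drop = FALSE]
}

#' Generate a probe-level log2-ratio track with planted aberrations
#'
#' Probes sit at the scenario's uniform spacing (or at supplied
#' positions, e.g. from a [assemble_plan()] probe plan); the baseline is
#' Gaussian noise of SD `sigma`; each planted aberration adds its log2
#' shift over its probe span.  With `sigma = 0` the track is an exact
#' step function of the planted events.
#'
#' @param scenario a [synthetic_scenario()].
#' @param positions optional `data.frame` (`chrom`, `pos`) of probe
#'   positions.
#' @return a [probe_track()] with attribute `"events"`: the planted
#'   aberrations with their probe spans and bp intervals.
#' @export
generate_probe_track <- function(scenario, positions = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (is.null(positions)) positions <- scenario_probe_positions(scenario)
  stopifnot(all(c("chrom", "pos") %in% names(positions)))
  positions <- positions[order(positions$chrom, positions$pos), ,
                         drop = FALSE]
  npc <- table(positions$chrom)
  npc <- stats::setNames(as.integer(npc), names(npc))
  withr::with_seed(scenario$seed + 1L, {
    events <- draw_aberrations(scenario, npc)
    log2 <- stats::rnorm(nrow(positions), 0, scenario$sigma)
    ev_bp <- NULL
    if (nrow(events)) {
      ev_bp <- events
      ev_bp$start <- NA_real_
      ev_bp$end <- NA_real_
      for (i in seq_len(nrow(events))) {
        on_ch <- which(positions$chrom == events$chrom[i])
        idx <- on_ch[events$start_index[i]:
                       (events$start_index[i] + events$n_probes[i] - 1L)]
        log2[idx] <- log2[idx] + events$shift[i]
        ev_bp$start[i] <- positions$pos[idx[1L]] - 1
        ev_bp$end[i] <- positions$pos[idx[length(idx)]]
      }
    } else {
      ev_bp <- cbind(events, data.frame(start = numeric(),
                                        end = numeric()))
    }
    ev_bp$direction <- ifelse(ev_bp$shift >= 0, "gain", "loss")
    track <- probe_track(data.frame(chrom = positions$chrom,
                                    pos = positions$pos, log2 = log2,
                                    stringsAsFactors = FALSE))
    attr(track, "events") <- ev_bp
    track
  })
}

#' Ground truth of a scenario
#'
#' Regenerates the scenario's features and probe track (deterministic by
#' seed) and emits the truth tables used for scoring: every
#' (enhancer, CNV) overlapping pair, and every planted aberration with
#' its genomic span and direction.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `overlaps` (`data.frame` of `enhancer_id`,
#'   `cnv_id`) and `events` (planted aberrations).
#' @export
scenario_truth <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  feats <- generate_features(scenario)
  fc <- feature_coverage(feats$enhancers, feats$cnvs)
  overlaps <- data.frame(enhancer_id = fc$hits$target_id,
                         cnv_id = fc$hits$cover_id,
                         stringsAsFactors = FALSE)
  track <- generate_probe_track(scenario)
  list(overlaps = overlaps, events = attr(track, "events"))
}
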