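#' Specify one tier of a targeted aCGH design
#'
#' A design allocates a fixed feature budget across tiers: a genome-wide
#' `backbone` at coarse spacing, a `targeted` tier tiling regions of
#' interest at higher resolution, an `enhancer` tier with a minimum
#' probe count per element, reserved `normalization` and `replicate`
#' probe groups (opaque counts), and a `filler` tier absorbing residual
#' capacity.
#'
#' Resolution is formalized by the 3-probe detection rule: an aberration
#' is callable when at least 3 consecutive probes support it, so the
#' resolution of a tier equals 3 times its probe spacing (100 kb spacing
#' gives 300 kb resolution).
#'
#' @param name tier name: `"backbone"`, `"targeted"`, `"enhancer"`,
#'   `"normalization"`, `"replicate"` or `"filler"`.
#' @param budget probe budget for the tier (>= 0).
#' @param target_spacing desired probe spacing in bp (backbone,
#'   enhancer) — for the enhancer tier this is the per-element average
#'   spacing in nt.
#' @param resolution desired resolution in bp (targeted tier);
#'   equivalent to `3 * target_spacing`.
#' @param min_probes_per_feature minimum probes per feature (enhancer
#'   and targeted tiers; default 3, the detection rule).
#' @return an object of class `tier_spec`.
#' @export
tier_spec <- function(name = c("backbone", "targeted", "enhancer",
                               "normalization", "replicate", "filler"),
                      budget, target_spacing = NULL, resolution = NULL,
                      min_probes_per_feature = 3L) {
  name <- match.arg(name)
  if (!is.numeric(budget) || budget < 0) stop("budget must be >= 0")
  if (!is.null(target_spacing) && target_spacing <= 0) {
    stop("target_spacing must be > 0")
  }
  if (!is.null(resolution) && resolution <= 0) stop("resolution must be > 0")
  if (min_probes_per_feature < 1) {
    stop("min_probes_per_feature must be >= 1")
  }
  structure(list(name = name, budget = as.numeric(budget),
                 target_spacing = target_spacing, resolution = resolution,
                 min_probes_per_feature = as.integer(min_probes_per_feature)),
            class = "tier_spec")
}

new_tier <- function(spec, placements, achieved) {
  placements <- placements[, c("tier", "chrom", "pos", "feature_id"),
                           drop = FALSE]
  structure(list(spec = spec, placements = placements, achieved = achieved),
            class = "probe_tier")
}

#' @export
print.probe_tier <- function(x, ...) {
  cat(sprintf("<probe_tier '%s': %d probes>\n", x$spec$name,
              nrow(x$placements)))
  utils::str(x$achieved, give.attr = FALSE)
  invisible(x)
}

# Evenly spaced positions along one chromosome, first probe at spacing/2;
# a chromosome shorter than the spacing still gets one probe at its
# midpoint so no chromosome is left uncovered.
tile_chromosome <- function(len, spacing) {
  if (len < spacing) return(max(1, floor(len / 2)))
  seq.int(floor(spacing / 2), len, by = spacing)
}

#' Tile the genome backbone
#'
#' Places probes at uniform spacing on every chromosome.  If the spacing
#' implied by the request needs more probes than the budget allows, the
#' spacing is widened to `ceiling(genome_size / budget)` and the
#' achieved spacing is reported; the achieved resolution is 3 times the
#' achieved spacing (3-probe rule).
#'
#' @param assembly a [genome_assembly()].
#' @param spec a [tier_spec()] with `name = "backbone"`, a budget and a
#'   `target_spacing`.
#' @return a `probe_tier`: `$placements` (`tier`, `chrom`, `pos`,
#'   `feature_id`) and `$achieved` (counts, spacing, resolution).
#' @export
tile_backbone <- function(assembly, spec) {
  stopifnot(inherits(assembly, "genome_assembly"),
            inherits(spec, "tier_spec"))
  if (spec$budget < 1) stop("backbone budget must be >= 1")
  if (is.null(spec$target_spacing)) stop("backbone needs a target_spacing")
  lens <- chrom_lengths(assembly)
  if (spec$budget < length(lens)) {
    stop("budget smaller than the number of chromosomes")
  }
  tile_all <- function(spacing) {
    do.call(rbind, lapply(names(lens), function(ch) {
      data.frame(tier = "backbone", chrom = ch,
                 pos = tile_chromosome(lens[[ch]], spacing),
                 feature_id = NA_character_, stringsAsFactors = FALSE)
    }))
  }
  spacing <- spec$target_spacing
  pl <- tile_all(spacing)
  widened <- FALSE
  if (nrow(pl) > spec$budget) {
    spacing <- ceiling(genome_size(assembly) / spec$budget)
    pl <- tile_all(spacing)
    widened <- TRUE
  }
  new_tier(spec, pl, list(
    n_probes = nrow(pl),
    spacing_requested = spec$target_spacing,
    spacing_achieved = spacing,
    spacing_widened = widened,
    resolution = 3 * spacing))
}

#' Tile targeted regions of interest
#'
#' Within-region spacing is `resolution / 3` (3-probe detection rule)
#' with a minimum of 3 probes per region however short it is.  If the
#' implied total exceeds the budget, probes are thinned deterministically
#' (every k-th probe kept, `k = ceiling(total / budget)`) and the
#' coarser achieved resolution is reported.
#'
#' @param regions non-empty [feature_set()] of regions (telomeres,
#'   centromeres, disease loci).
#' @param spec a [tier_spec()] with `name = "targeted"`, a budget and a
#'   `resolution`.
#' @return a `probe_tier`.
#' @export
tile_regions <- function(regions, spec) {
  stopifnot(inherits(spec, "tier_spec"))
  rdf <- as_feature_frame(regions)
  if (nrow(rdf) == 0L) stop("empty region set")
  res <- spec$resolution
  if (is.null(res)) {
    if (is.null(spec$target_spacing)) stop("targeted tier needs a resolution")
    res <- 3 * spec$target_spacing
  }
  minp <- max(3L, spec$min_probes_per_feature)
  lens <- rdf$end - rdf$start
  # integer-exact form of ceiling(length / (resolution/3))
  n_i <- pmax(minp, ceiling(3 * lens / res))
  total <- sum(n_i)
  k <- 1L
  if (is.finite(spec$budget) && spec$budget >= 1 && total > spec$budget) {
    k <- ceiling(total / spec$budget)
  }
  pl <- do.call(rbind, lapply(seq_len(nrow(rdf)), function(i) {
    n <- n_i[i]
    keep <- seq.int(1L, n, by = k)
    pos <- rdf$start[i] + floor(lens[i] * (2 * keep - 1) / (2 * n)) + 1
    data.frame(tier = "targeted", chrom = rdf$chrom[i], pos = pos,
               feature_id = if ("id" %in% names(rdf))
                 as.character(rdf$id[i]) else as.character(i),
               stringsAsFactors = FALSE)
  }))
  ach_spacing <- sum(lens) / nrow(pl)
  new_tier(spec, pl, list(
    n_probes = nrow(pl),
    n_regions = nrow(rdf),
    resolution_requested = res,
    thinning = k,
    spacing_achieved = ach_spacing,
    resolution_achieved = 3 * ach_spacing))
}

#' Tile enhancer loci
#'
#' Each enhancer of length `L` receives
#' `n = max(min_probes_per_feature, ceiling(L / target_spacing))`
#' probes at the `n` evenly spaced interior positions, so longer
#' elements get proportionally more probes and nothing gets fewer than
#' the detection minimum.  When a candidate-probe list is supplied
#' (emulating a validated oligo catalogue), each ideal position snaps to
#' the nearest unused candidate inside the enhancer, ties resolved
#' toward the lower coordinate.
#'
#' @param enhancers non-empty [feature_set()] with unique ids.
#' @param spec a [tier_spec()] with `name = "enhancer"`,
#'   `target_spacing` (nt) and `min_probes_per_feature`.
#' @param candidates optional `data.frame` of allowed probe positions
#'   (`chrom`, `pos`).
#' @return a `probe_tier`; `$achieved$per_feature` reports each
#'   enhancer's probe count and achieved spacing.
#' @export
tile_enhancers <- function(enhancers, spec, candidates = NULL) {
  stopifnot(inherits(spec, "tier_spec"))
  edf <- as_feature_frame(enhancers)
  if (nrow(edf) == 0L) stop("empty enhancer set")
  if (is.null(spec$target_spacing)) stop("enhancer tier needs target_spacing")
  ids <- if ("id" %in% names(edf)) as.character(edf$id) else
    as.character(seq_len(nrow(edf)))
  lens <- edf$end - edf$start
  n_i <- pmax(spec$min_probes_per_feature,
              ceiling(lens / spec$target_spacing))
  short <- lens < n_i
  if (any(short)) {
    stop("enhancer '", ids[which(short)[1L]],
         "' too short for its probe allocation")
  }
  pl <- vector("list", nrow(edf))
  for (i in seq_len(nrow(edf))) {
    n <- n_i[i]
    ideal <- edf$start[i] + floor(lens[i] * (2 * seq_len(n) - 1) / (2 * n)) + 1
    pos <- ideal
    if (!is.null(candidates)) {
      cand <- candidates$pos[candidates$chrom == edf$chrom[i] &
                               candidates$pos > edf$start[i] &
                               candidates$pos <= edf$end[i]]
      cand <- sort(unique(cand))
      if (length(cand) < n) {
        stop("enhancer '", ids[i], "': only ", length(cand),
             " candidate probes for ", n, " placements")
      }
      used <- logical(length(cand))
      pos <- numeric(n)
      for (j in seq_len(n)) {
        d <- abs(cand - ideal[j])
        d[used] <- Inf
        # nearest candidate; tie toward the lower coordinate
        kbest <- which(d == min(d))[1L]
        used[kbest] <- TRUE
        pos[j] <- cand[kbest]
      }
      pos <- sort(pos)
    }
    pl[[i]] <- data.frame(tier = "enhancer", chrom = edf$chrom[i],
                          pos = pos, feature_id = ids[i],
                          stringsAsFactors = FALSE)
  }
  pl <- do.call(rbind, pl)
  per_feature <- data.frame(feature_id = ids, length = lens,
                            n_probes = n_i, spacing = lens / n_i,
                            stringsAsFactors = FALSE)
  new_tier(spec, pl, list(
    n_probes = nrow(pl),
    n_enhancers = nrow(edf),
    spacing_requested = spec$target_spacing,
    mean_spacing = mean(per_feature$spacing),
    per_feature = per_feature))
}

#' Reserve an opaque probe group
#'
#' Normalization and replicate probe groups are commercial catalogues
#' consumed as fixed counts; they occupy budget but contribute no
#' analyzable placements.
#'
#' @param spec a [tier_spec()] with `name` `"normalization"` or
#'   `"replicate"` and a budget.
#' @return a `probe_tier` with zero placements and `$achieved$n_probes`
#'   equal to the budget.
#' @export
reserve_tier <- function(spec) {
  stopifnot(inherits(spec, "tier_spec"),
            spec$name %in% c("normalization", "replicate"))
  empty <- data.frame(tier = character(), chrom = character(),
                      pos = numeric(), feature_id = character(),
                      stringsAsFactors = FALSE)
  new_tier(spec, empty, list(n_probes = spec$budget, reserved = TRUE))
}

tier_count <- function(tier) {
  if (isTRUE(tier$achieved$reserved)) tier$achieved$n_probes else
    nrow(tier$placements)
}

#' Assemble tiers into a complete probe plan
#'
#' Validates every tier against the array's feature capacity, computes
#' the residual free space, and (optionally) fills it by seeded uniform
#' sampling without replacement from a catalogue of candidate probes.
#' Budget conservation holds by construction: placements + reserved
#' counts + residual = capacity.
#'
#' @param tiers list of `probe_tier` objects ([tile_backbone()],
#'   [tile_regions()], [tile_enhancers()], [reserve_tier()]).
#' @param capacity total usable feature count of the array.
#' @param filler_catalogue optional `data.frame` (`chrom`, `pos`) from
#'   which filler probes are drawn.
#' @param seed seed for the filler draw.
#' @return an object of class `probe_plan`: `$placements` (all tiers
#'   plus filler), `$per_tier` counts, `$capacity`, `$residual`,
#'   `$residual_fraction`.
#' @export
assemble_plan <- function(tiers, capacity, filler_catalogue = NULL,
                          seed = 1L) {
  if (!length(tiers)) stop("no tiers supplied")
  stopifnot(all(vapply(tiers, inherits, TRUE, "probe_tier")))
  if (!is.numeric(capacity) || capacity <= 0) stop("capacity must be > 0")
  names(tiers) <- vapply(tiers, function(t) t$spec$name, "")
  if (anyDuplicated(names(tiers))) stop("duplicate tier names")
  counts <- vapply(tiers, tier_count, numeric(1))
  total <- sum(counts)
  if (total > capacity) {
    stop("placements exceed capacity ", capacity, ": ",
         paste(sprintf("%s=%g", names(counts), counts), collapse = ", "))
  }
  residual <- capacity - total
  placements <- do.call(rbind, c(lapply(unname(tiers), `[[`, "placements"),
                                 list(make.row.names = FALSE)))
  filler <- NULL
  if (residual > 0 && !is.null(filler_catalogue)) {
    stopifnot(all(c("chrom", "pos") %in% names(filler_catalogue)))
    take <- min(residual, nrow(filler_catalogue))
    idx <- withr::with_seed(seed,
      sample.int(nrow(filler_catalogue), take, replace = FALSE))
    filler <- data.frame(tier = "filler",
                         chrom = filler_catalogue$chrom[idx],
                         pos = filler_catalogue$pos[idx],
                         feature_id = NA_character_,
                         stringsAsFactors = FALSE)
    filler <- filler[order(filler$chrom, filler$pos), , drop = FALSE]
    placements <- rbind(placements, filler)
  }
  key <- paste(placements$tier, placements$chrom, placements$pos)
  if (anyDuplicated(key)) {
    stop("duplicate probe placement within a tier: ",
         key[duplicated(key)][1L])
  }
  plan <- structure(list(
    tiers = tiers,
    placements = placements,
    per_tier = counts,
    n_filler_placed = if (is.null(filler)) 0L else nrow(filler),
    capacity = capacity,
    residual = residual,
    residual_fraction = residual / capacity,
    seed = seed), class = "probe_plan")
  validate_plan(plan)
  plan
}

# Invariants: budget conservation, per-tier budgets, sorted distinct
# positions, enhancer minimum.
validate_plan <- function(plan) {
  stopifnot(sum(plan$per_tier) + plan$residual == plan$capacity)
  for (nm in names(plan$tiers)) {
    tier <- plan$tiers[[nm]]
    if (tier$spec$budget > 0 && tier_count(tier) > tier$spec$budget) {
      stop("tier '", nm, "' exceeds its own budget")
    }
    pl <- tier$placements
    for (ch in unique(pl$chrom)) {
      p <- pl$pos[pl$chrom == ch]
      if (any(diff(sort(p)) == 0)) {
        stop("duplicate probe position in tier '", nm, "' on ", ch)
      }
    }
    if (nm == "enhancer" && nrow(pl)) {
      cnt <- table(pl$feature_id)
      if (any(cnt < tier$spec$min_probes_per_feature)) {
        stop("an enhancer received fewer than the minimum probes")
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.probe_plan <- function(x, ...) {
  cat(sprintf("<probe_plan: capacity %g, %g placed + %g reserved, residual %g (%.2f%%)>\n",
              x$capacity, nrow(x$placements),
              sum(vapply(x$tiers, function(t)
                if (isTRUE(t$achieved$reserved)) t$achieved$n_probes else 0,
                numeric(1))),
              x$residual, 100 * x$residual_fraction))
  print(x$per_tier)
  invisible(x)
}

#' Write probe placements as BED4
#'
#' Probe placements are point positions (probe midpoints); each is
#' emitted as a 1-bp BED interval named `tier` or `tier:feature_id`.
#'
#' @param plan a `probe_plan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plan_bed <- function(plan, path) {
  stopifnot(inherits(plan, "probe_plan"))
  pl <- plan$placements
  nm <- ifelse(is.na(pl$feature_id), pl$tier,
               paste0(pl$tier, ":", pl$feature_id))
  df <- data.frame(chrom = pl$chrom, start = pl$pos - 1, end = pl$pos,
                   id = nm, stringsAsFactors = FALSE)
  write_bed(df, path)
}
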