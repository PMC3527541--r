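#!/usr/bin/env Rscript

# Stage 3 — tiered probe plan for an enhancer-targeted aCGH array.
#
# Builds the full-scale layout on hg18 chromosome sizes: a 25,000-probe
# genome backbone at 100-kb spacing (widened automatically when the
# genome demands it), an 18,000-probe targeted tier at 40-kb resolution
# over synthetic regions of interest standing in for telomeres,
# centromeres and disease loci, a per-enhancer tier (>= 3 probes each,
# 238-nt spacing ceiling) over the bundled enhancer loci, the two
# reserved commercial probe groups, and seeded filler into the residual
# capacity of a 59,905-feature array.
#
# Usage: Rscript analysis/03_probe_design.R [seed]

suppressMessages(library(enhancerCNV))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
out_dir <- "results"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

asm <- read_chrom_sizes(enhancer_fixture("hg18.chrom.sizes"), name = "hg18")
message("genome: ", format(genome_size(asm), big.mark = ","), " bp")

bb <- tile_backbone(asm, tier_spec("backbone", budget = 25000,
                                   target_spacing = 1e5))
message("backbone: ", nrow(bb$placements), " probes, spacing ",
        bb$achieved$spacing_achieved, " bp (widened: ",
        bb$achieved$spacing_widened, "), resolution ",
        bb$achieved$resolution / 1000, " kb")

# synthetic regions of interest: subtelomeric windows on every
# chromosome arm plus randomly drawn disease-locus stand-ins
lens <- chrom_lengths(asm)
tel <- rbind(
  data.frame(chrom = names(lens), start = 0, end = 5e5),
  data.frame(chrom = names(lens), start = lens - 5e5, end = lens))
dis <- withr::with_seed(seed, {
  ch <- sample(names(lens), 60, replace = TRUE, prob = lens)
  w <- sample(2e5:2e6, 60, replace = TRUE)
  s <- floor(runif(60, 5e5, lens[ch] - w - 5e5))
  data.frame(chrom = ch, start = s, end = s + w, row.names = NULL)
})
regions <- merge_features(feature_set(rbind(tel, dis), kind = "generic",
                                      assembly = asm))
tg <- tile_regions(regions, tier_spec("targeted", budget = 18000,
                                      resolution = 4e4))
message("targeted: ", nrow(tg$placements), " probes over ",
        n_features(regions), " regions, achieved resolution ",
        round(tg$achieved$resolution_achieved / 1000, 1), " kb")

enh <- published_loci()$enhancers
et <- tile_enhancers(enh, tier_spec("enhancer", budget = 500,
                                    target_spacing = 238))
message("enhancer tier: ", nrow(et$placements), " probes on ",
        n_features(enh), " loci (mean spacing ",
        round(et$achieved$mean_spacing), " nt)")

catalogue <- withr::with_seed(seed + 1L, {
  ch <- sample(names(lens), 20000, replace = TRUE, prob = lens)
  data.frame(chrom = ch, pos = floor(runif(20000, 1, lens[ch])),
             row.names = NULL)
})
plan <- assemble_plan(
  list(bb, tg, et,
       reserve_tier(tier_spec("normalization", budget = 1262)),
       reserve_tier(tier_spec("replicate", budget = 5000))),
  capacity = 59905, filler_catalogue = catalogue, seed = seed)
print(plan)

write_plan_bed(plan, file.path(out_dir, "probe_plan.bed"))
write_design_report(plan, file.path(out_dir, "design_report.json"))
write_provenance(file.path(out_dir, "03_provenance.json"),
                 params = list(stage = "probe_design", capacity = 59905,
                               assembly = "hg18"),
                 seed = seed)
message("residual: ", plan$residual, " features (",
        round(100 * plan$residual_fraction, 2), "% of capacity)")
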