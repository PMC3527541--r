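test_that("backbone tiling hits the requested spacing or widens to budget", {
  asm <- genome_assembly(c(chr1 = 1e7), name = "toy")
  bb <- tile_backbone(asm, tier_spec("backbone", budget = 1e4,
                                     target_spacing = 1e5))
  expect_equal(nrow(bb$placements), 100)
  expect_false(bb$achieved$spacing_widened)
  expect_equal(bb$achieved$resolution, 3e5)

  big <- genome_assembly(c(chr1 = 3.1e9), name = "big")
  bb2 <- tile_backbone(big, tier_spec("backbone", budget = 25000,
                                      target_spacing = 1e5))
  expect_true(bb2$achieved$spacing_widened)
  expect_equal(bb2$achieved$spacing_achieved, 124000)
  expect_lte(nrow(bb2$placements), 25000)

  # a chromosome shorter than the spacing still gets its midpoint probe
  small <- genome_assembly(c(chr1 = 5e4), name = "small")
  bb3 <- tile_backbone(small, tier_spec("backbone", budget = 10,
                                        target_spacing = 1e5))
  expect_equal(nrow(bb3$placements), 1)
  expect_equal(bb3$placements$pos, 2.5e4)
})

test_that("targeted regions follow the three-probe resolution rule", {
  reg <- feature_set(data.frame(chrom = "chr1", start = 0, end = 4e5))
  tg <- tile_regions(reg, tier_spec("targeted", budget = 1000,
                                    resolution = 4e4))
  expect_equal(nrow(tg$placements), 30)
  expect_equal(tg$achieved$spacing_achieved, 4e5 / 30, tolerance = 1e-9)

  tiny <- feature_set(data.frame(chrom = "chr1", start = 0, end = 1e4))
  expect_equal(nrow(tile_regions(tiny, tier_spec("targeted", budget = 100,
                                                 resolution = 4e4))$placements),
               3)

  # thinning under a tight budget coarsens the achieved resolution
  thin <- tile_regions(reg, tier_spec("targeted", budget = 10,
                                      resolution = 4e4))
  expect_lte(nrow(thin$placements), 10)
  expect_gt(thin$achieved$resolution_achieved, 4e4)
  expect_error(tile_regions(feature_set(
    data.frame(chrom = character(), start = numeric(), end = numeric())),
    tier_spec("targeted", budget = 10, resolution = 4e4)), "empty")
})

test_that("enhancer tiling scales with length above the three-probe floor", {
  # printed-length check: 1,124 bp at 238 nt spacing -> 5 probes
  enh <- feature_set(data.frame(chrom = "chr9", start = 159656,
                                end = 160780, id = "hs628"))
  et <- tile_enhancers(enh, tier_spec("enhancer", budget = 100,
                                      target_spacing = 238))
  expect_equal(nrow(et$placements), 5)
  expect_equal(et$achieved$per_feature$n_probes, 5)

  shorty <- feature_set(data.frame(chrom = "c", start = 0, end = 300,
                                   id = "s"))
  expect_equal(nrow(tile_enhancers(shorty,
                                   tier_spec("enhancer", budget = 10,
                                             target_spacing = 238))$placements),
               3)

  # placements inside the element, strictly increasing
  expect_true(all(et$placements$pos > 159656 & et$placements$pos <= 160780))
  expect_true(all(diff(et$placements$pos) > 0))

  too_short <- feature_set(data.frame(chrom = "c", start = 0, end = 2,
                                      id = "nub"))
  expect_error(tile_enhancers(too_short,
                              tier_spec("enhancer", budget = 10,
                                        target_spacing = 238)),
               "'nub' too short")
})

test_that("candidate lists snap placements to the nearest allowed position", {
  enh <- feature_set(data.frame(chrom = "c", start = 0, end = 300,
                                id = "e"))
  spec <- tier_spec("enhancer", budget = 10, target_spacing = 238)
  ideal <- tile_enhancers(enh, spec)$placements$pos   # 51, 151, 251
  expect_equal(ideal, c(51, 151, 251))
  cand <- data.frame(chrom = "c", pos = c(40, 60, 140, 260, 290))
  snapped <- tile_enhancers(enh, spec, candidates = cand)$placements$pos
  expect_equal(length(snapped), 3)
  expect_true(all(snapped %in% cand$pos))
  expect_equal(snapped, c(60, 140, 260))  # nearest candidate each

  # an exact tie resolves toward the lower coordinate
  tie <- data.frame(chrom = "c", pos = c(41, 61, 151, 251))
  snapped_tie <- tile_enhancers(enh, spec, candidates = tie)$placements$pos
  expect_equal(snapped_tie, c(41, 151, 251))

  few <- data.frame(chrom = "c", pos = c(10, 20))
  expect_error(tile_enhancers(enh, spec, candidates = few),
               "only 2 candidate")
})

test_that("monotonicity: longer enhancers never get fewer probes", {
  spec <- tier_spec("enhancer", budget = 1e4, target_spacing = 238)
  lens <- seq(300, 5000, by = 100)
  enh <- feature_set(data.frame(chrom = "c",
                                start = seq_along(lens) * 10000,
                                end = seq_along(lens) * 10000 + lens,
                                id = paste0("e", seq_along(lens))))
  per <- tile_enhancers(enh, spec)$achieved$per_feature
  expect_true(all(diff(per$n_probes[order(per$length)]) >= 0))
  expect_true(all(per$n_probes >= 3))
})

test_that("plans conserve budget and report the residual fraction", {
  # tier counts mirroring a published 60K-format design
  bbasm <- genome_assembly(c(chr1 = 2.5e9), name = "g")
  bb <- tile_backbone(bbasm, tier_spec("backbone", budget = 25000,
                                       target_spacing = 1e5))
  expect_equal(nrow(bb$placements), 25000)
  reg <- feature_set(data.frame(chrom = "chr1", start = 0, end = 2.4e8))
  tg <- tile_regions(reg, tier_spec("targeted", budget = 18000,
                                    resolution = 4e4))
  expect_equal(nrow(tg$placements), 18000)
  # 2,595 three-probe elements plus one five-probe element = 7,790
  n_e <- 2595
  enh <- feature_set(data.frame(
    chrom = "chr1",
    start = c(seq_len(n_e) * 4000, 2e9),
    end = c(seq_len(n_e) * 4000 + 700, 2e9 + 1124),
    id = c(paste0("e", seq_len(n_e)), "elong")))
  et <- tile_enhancers(enh, tier_spec("enhancer", budget = 7790,
                                      target_spacing = 238))
  expect_equal(nrow(et$placements), 7790)
  plan <- assemble_plan(
    list(bb, tg, et,
         reserve_tier(tier_spec("normalization", budget = 1262)),
         reserve_tier(tier_spec("replicate", budget = 5000))),
    capacity = 59905)
  expect_equal(plan$residual, 2853)
  expect_equal(plan$residual_fraction, 2853 / 59905)
  expect_equal(sum(plan$per_tier) + plan$residual, plan$capacity)

  expect_error(assemble_plan(list(bb, tg, et), capacity = 40000),
               "exceed capacity")
})

test_that("filler sampling is seeded and deterministic", {
  asm <- genome_assembly(c(c1 = 1e6), name = "f")
  bb <- tile_backbone(asm, tier_spec("backbone", budget = 100,
                                     target_spacing = 1e4))
  cat_df <- data.frame(chrom = "c1", pos = seq(17, 1e6, by = 997))
  p1 <- assemble_plan(list(bb), capacity = 150,
                      filler_catalogue = cat_df, seed = 9)
  p2 <- assemble_plan(list(bb), capacity = 150,
                      filler_catalogue = cat_df, seed = 9)
  expect_identical(p1$placements, p2$placements)
  expect_equal(p1$n_filler_placed, 50)
  expect_equal(sum(p1$placements$tier == "filler"), 50)
  p3 <- assemble_plan(list(bb), capacity = 150,
                      filler_catalogue = cat_df, seed = 10)
  expect_false(identical(p1$placements, p3$placements))
  # zero residual leaves the filler empty
  p4 <- assemble_plan(list(bb), capacity = 100,
                      filler_catalogue = cat_df, seed = 9)
  expect_equal(p4$n_filler_placed, 0)
  expect_equal(p4$residual, 0)
})
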