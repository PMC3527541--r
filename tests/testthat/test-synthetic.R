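test_that("scenario validation rejects out-of-range parameters", {
  expect_error(synthetic_scenario(seed = 1, delta = 1.2), "delta")
  expect_error(synthetic_scenario(seed = 1, coverage = 1.5), "coverage")
  expect_error(synthetic_scenario(seed = 1, coverage = NULL), "n_cnvs")
  expect_error(synthetic_scenario(seed = 1, n_enhancers = 0),
               "n_enhancers")
})

test_that("generation is fully reproducible from the seed alone", {
  sc <- synthetic_scenario(seed = 33, n_enhancers = 50, coverage = 0.05,
                           assembly = genome_assembly(c(A = 1e7, B = 1e7),
                                                      name = "synthetic"),
                           cnv_length = c(1e3, 5e4))
  f1 <- generate_features(sc)
  f2 <- generate_features(sc)
  expect_identical(f1$enhancers$features, f2$enhancers$features)
  expect_identical(f1$cnvs$features, f2$cnvs$features)
  t1 <- generate_probe_track(sc)
  t2 <- generate_probe_track(sc)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "events"), attr(t2, "events"))

  sc2 <- synthetic_scenario(seed = 34, n_enhancers = 50, coverage = 0.05,
                            assembly = sc$assembly,
                            cnv_length = c(1e3, 5e4))
  expect_false(identical(generate_features(sc2)$cnvs$features,
                         f1$cnvs$features))
})

test_that("enhancers are placed without mutual overlap at the stated lengths", {
  sc <- synthetic_scenario(seed = 8, n_enhancers = 300, coverage = 0.05)
  enh <- generate_features(sc)$enhancers$features
  expect_equal(nrow(enh), 300)
  lens <- enh$end - enh$start
  expect_true(all(lens >= 800 & lens <= 2200))
  m <- merge_features(feature_set(enh))
  expect_equal(n_features(m), nrow(enh))   # merge collapses nothing
})

test_that("coverage targeting lands within two percent relative", {
  sc <- synthetic_scenario(seed = 12,
                           assembly = genome_assembly(c(A = 5e7, B = 5e7),
                                                      name = "synthetic"),
                           n_enhancers = 100, coverage = 0.02,
                           delta = 1)
  cnv <- generate_features(sc)$cnvs
  got <- base_coverage(assembly_as_features(sc$assembly), cnv)$fraction
  expect_lt(abs(got - 0.02) / 0.02, 0.02)

  # infeasibly high target on a small genome errors out
  sc_bad <- synthetic_scenario(seed = 12,
                               assembly = genome_assembly(c(A = 5e4),
                                                          name = "synthetic"),
                               n_enhancers = 2, coverage = 0.999,
                               enhancer_length = c(800, 900),
                               cnv_length = c(10, 20))
  expect_error(generate_features(sc_bad), "target")
})

test_that("delta = 0 forbids enhancer-CNV overlaps entirely", {
  sc <- synthetic_scenario(seed = 5, n_enhancers = 150, coverage = 0.1,
                           delta = 0, cnv_length = c(1e3, 5e4))
  f <- generate_features(sc)
  expect_equal(feature_coverage(f$enhancers, f$cnvs)$count, 0)
  expect_equal(nrow(scenario_truth(sc)$overlaps), 0)
})

test_that("thinning scales truth overlaps in proportion to delta", {
  pair_count <- function(delta, seed) {
    sc <- synthetic_scenario(
      seed = seed,
      assembly = genome_assembly(c(A = 2.5e7, B = 2.5e7),
                                 name = "synthetic"),
      n_enhancers = 300, coverage = 0.15, delta = delta,
      cnv_length = c(1e3, 3e4))
    f <- generate_features(sc)
    nrow(feature_coverage(f$enhancers, f$cnvs)$hits)
  }
  seeds <- 100 + 1:20
  base <- sum(vapply(seeds, function(s) pair_count(1, s), numeric(1)))
  thin <- sum(vapply(seeds, function(s) pair_count(0.2, s), numeric(1)))
  expect_gt(base, 200)          # enough events for a stable ratio
  ratio <- thin / base
  expect_gt(ratio, 0.13)
  expect_lt(ratio, 0.30)
})

test_that("noiseless tracks are exact step functions of the planted events", {
  ab <- data.frame(chrom = "A", start_index = 50L, n_probes = 10L,
                   shift = -1)
  sc <- synthetic_scenario(seed = 3,
                           assembly = genome_assembly(c(A = 1e6),
                                                      name = "synthetic"),
                           n_enhancers = 5, coverage = 0.01,
                           cnv_length = c(100, 2000),
                           sigma = 0, probe_spacing = 1000,
                           aberrations = ab)
  tr <- generate_probe_track(sc)
  expect_setequal(unique(tr$log2), c(0, -1))
  expect_equal(sum(tr$log2 == -1), 10)
  ev <- attr(tr, "events")
  expect_equal(ev$direction, "loss")
  # the event's bp span covers exactly its probes
  on <- tr$pos[tr$log2 == -1]
  expect_equal(ev$start, min(on) - 1)
  expect_equal(ev$end, max(on))
})

test_that("track noise matches sigma via DLRSpread", {
  sc <- synthetic_scenario(seed = 19, n_enhancers = 5, coverage = 0.01,
                           sigma = 0.2, probe_spacing = 5000,
                           aberrations = 0L)
  tr <- generate_probe_track(sc)
  expect_equal(dlr_spread(tr), 0.2, tolerance = 0.05)
})

test_that("aberrations outside the genome are rejected", {
  ab <- data.frame(chrom = "A", start_index = 999999L, n_probes = 10L,
                   shift = -1)
  sc <- synthetic_scenario(seed = 3,
                           assembly = genome_assembly(c(A = 1e6),
                                                      name = "synthetic"),
                           n_enhancers = 5, coverage = 0.01,
                           cnv_length = c(100, 2000),
                           probe_spacing = 1000, aberrations = ab)
  expect_error(generate_probe_track(sc), "outside the genome")
})

test_that("truth tables carry one row per planted event", {
  sc <- synthetic_scenario(seed = 44, n_enhancers = 20, coverage = 0.05,
                           aberrations = 4L)
  tru <- scenario_truth(sc)
  expect_equal(nrow(tru$events), 4)
  expect_true(all(tru$events$n_probes >= 5 & tru$events$n_probes <= 15))
  expect_true(all(tru$events$direction %in% c("gain", "loss")))
})
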