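flat_track <- function(n = 200, value = 0, chrom = "c1", spacing = 1000) {
  probe_track(data.frame(chrom = chrom, pos = seq_len(n) * spacing,
                         log2 = rep(value, n)))
}

test_that("probe tracks enforce ordering and finiteness", {
  expect_error(probe_track(data.frame(chrom = "c", pos = c(10, 10),
                                      log2 = c(0, 0))),
               "strictly increasing")
  expect_error(probe_track(data.frame(chrom = "c", pos = c(10, 5),
                                      log2 = c(0, 0))),
               "strictly increasing")
  expect_error(probe_track(data.frame(chrom = "c", pos = c(1, 2),
                                      log2 = c(0, NA))),
               "finite")
})

test_that("DLRSpread recovers Gaussian probe noise and is shift-invariant", {
  expect_equal(dlr_spread(flat_track(100)), 0)

  set.seed(2024)
  x <- rnorm(10000, 0, 0.2)
  tr <- probe_track(data.frame(chrom = "c1", pos = seq_len(10000) * 100,
                               log2 = x))
  expect_equal(dlr_spread(tr), 0.2, tolerance = 0.05)

  shifted <- tr
  shifted$log2 <- shifted$log2 + 3.7
  expect_equal(dlr_spread(shifted), dlr_spread(tr))

  # chromosome boundaries contribute no differences
  two <- probe_track(data.frame(chrom = rep(c("a", "b"), each = 5000),
                                pos = rep(seq_len(5000) * 100, 2),
                                log2 = x))
  expect_equal(dlr_spread(two), 0.2, tolerance = 0.05)

  expect_error(dlr_spread(probe_track(data.frame(chrom = "c", pos = 1,
                                                 log2 = 0))),
               "at least two probes")
})

test_that("flat tracks yield a single segment per chromosome", {
  calls <- segment_track(flat_track(300))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$probe_count, 300)

  noisy <- flat_track(300)
  set.seed(5)
  noisy$log2 <- rnorm(300, 0, 0.15)
  expect_equal(nrow(segment_track(noisy)), 1)
})

test_that("noiseless planted events are recovered with exact boundaries", {
  tr <- flat_track(100)
  tr$log2[41:50] <- -1
  calls <- segment_track(tr)
  expect_equal(nrow(calls), 3)
  ev <- calls[calls$direction == "loss" & calls$mean_log2 < -0.5, ]
  expect_equal(ev$probe_count, 10)
  # a probe at position p occupies [p - 1, p): the call spans the probes
  expect_equal(ev$start, 41 * 1000 - 1)
  expect_equal(ev$end, 50 * 1000)
})

test_that("a planted deletion in noise is recovered within one probe", {
  set.seed(77)
  n <- 400
  x <- rnorm(n, 0, 0.2)
  x[201:210] <- x[201:210] - 1
  tr <- probe_track(data.frame(chrom = "c1", pos = seq_len(n) * 1000,
                               log2 = x))
  calls <- segment_track(tr)
  loss <- calls[calls$mean_log2 < -0.5, ]
  expect_equal(nrow(loss), 1)
  first_probe <- loss$start / 1000 + 1
  last_probe <- loss$end / 1000
  expect_lte(abs(first_probe - 201), 1)
  expect_lte(abs(last_probe - 210), 1)
})

test_that("two separated events give two distinct aberrant segments", {
  set.seed(78)
  n <- 300
  x <- rnorm(n, 0, 0.15)
  x[50:60] <- x[50:60] - 1
  x[120:131] <- x[120:131] + 0.585
  tr <- probe_track(data.frame(chrom = "c1", pos = seq_len(n) * 500,
                               log2 = x))
  calls <- aberration_filter(segment_track(tr), dlr_spread(tr))
  expect_equal(nrow(calls), 2)
  expect_setequal(calls$direction, c("loss", "gain"))
})

test_that("the aberration filter applies both published rules", {
  calls <- data.frame(
    chrom = "c1",
    start = c(0, 100, 200), end = c(50, 150, 250),
    probe_count = c(2L, 5L, 4L),
    mean_log2 = c(-1, 0.1, -0.8),
    direction = c("loss", "gain", "loss"),
    passes_filter = NA)
  kept <- aberration_filter(calls, dlrs = 0.2)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$probe_count, 4L)      # >=3 probes AND |mean| >= DLRS
  expect_true(all(kept$passes_filter))

  flagged <- aberration_filter(calls, dlrs = 0.2, keep_all = TRUE)
  expect_equal(flagged$passes_filter, c(FALSE, FALSE, TRUE))

  # pure predicate: subset of input, idempotent
  expect_equal(aberration_filter(kept, dlrs = 0.2), kept)
  expect_error(aberration_filter(calls, dlrs = -1), ">= 0")
})

test_that("classification precedence is disease > known > enhancer > uncertain", {
  calls <- data.frame(chrom = "c1",
                      start = c(0, 1000, 2000, 3000),
                      end = c(100, 1100, 2100, 3100))
  enh <- feature_set(data.frame(chrom = "c1", start = c(10, 3010),
                                end = c(60, 3060),
                                id = c("e1", "e2")), kind = "enhancer")
  known <- feature_set(data.frame(chrom = "c1", start = 1010, end = 1200,
                                  id = "k1"), kind = "cnv")
  syn <- feature_set(data.frame(chrom = "c1", start = c(0, 3000),
                                end = c(150, 3100), id = c("s1", "s2")),
                     kind = "syndrome_region")
  ann <- annotate_calls(calls, enhancers = enh, known_cnvs = known,
                        syndrome_regions = syn)
  expect_equal(ann$calls$classification,
               c("disease-region", "known-polymorphic", "uncertain",
                 "disease-region"))
  # every overlap is recorded even when outranked
  expect_setequal(
    ann$annotations$feature_id[ann$annotations$set == "enhancer"],
    c("e1", "e2"))

  only_enh <- annotate_calls(calls, enhancers = enh)
  expect_equal(only_enh$calls$classification,
               c("enhancer-CNV", "uncertain", "uncertain", "enhancer-CNV"))

  # a supplied set with no overlaps contributes nothing but breaks nothing
  far <- feature_set(data.frame(chrom = "c9", start = 0, end = 100,
                                id = "far"), kind = "cnv")
  with_far <- annotate_calls(calls, enhancers = enh, known_cnvs = far)
  expect_equal(with_far$calls$classification,
               only_enh$calls$classification)
})
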