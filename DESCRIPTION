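Package: enhancerCNV
Title: Copy-Number Variation at Enhancer Loci: Depletion Statistics,
    Targeted aCGH Design and CNV Call Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies depletion of copy-number variation (CNV) at
    enhancer loci by comparing observed interval coverage against the
    expectation from genome-wide CNV coverage, with exact binomial and
    chi-square tests and a length-preserving permutation null.  Plans a
    tiered array-CGH probe layout (genome backbone, targeted disease
    regions, per-enhancer tiling, reserved and filler tiers) under a fixed
    feature budget.  Segments probe-level log2-ratio tracks, applies the
    standard aberration filter (at least three probes per call and mean
    log2 ratio above the derivative log ratio spread), and annotates
    surviving calls against enhancer, known-polymorphic and disease-region
    interval sets.  A seeded synthetic-data generator emulates genomes,
    enhancer and CNV sets with a tunable enhancer-depletion parameter, and
    noisy probe tracks with planted aberrations, so the whole pipeline is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    graphics,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
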