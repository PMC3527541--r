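---
title: "Methods: enhancer CNV depletion, targeted array design, and call filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancer CNV depletion, targeted array design, and call filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerCNV)
```

# The scientific question

Enhancers are conserved non-coding elements that drive gene expression at
a distance; deleting or duplicating one can cause disease even when every
coding exon is intact.  If enhancer dosage matters, copy-number variation
(CNV) should be *depleted* at enhancer loci relative to the genomic
background — negative selection should have removed most CNVs that alter
enhancer copy number from the healthy population.  This package
implements the three computational pieces needed to ask and act on that
question:

1. **Depletion statistics** — compare the observed coverage of enhancer
   loci by a CNV catalogue with the coverage expected if CNVs ignored
   enhancers, and test the difference.
2. **Targeted array design** — allocate a fixed aCGH feature budget
   across a genome backbone, high-resolution disease regions, and a
   per-enhancer probe tier, so that enhancer-sized (~1–2 kb) events
   become detectable.
3. **Call filtering and interpretation** — segment probe-level log2
   ratios, apply the standard aberration filter, and classify surviving
   calls against enhancer, known-polymorphic and disease-region interval
   sets.

A seeded synthetic-data generator stands in for the external enhancer
and CNV catalogues so that every stage is testable at desk scale.

# Coordinate conventions

Printed coordinate tables and genome browsers use 1-based inclusive
positions; BED uses 0-based half-open.  Internally everything is 0-based
half-open, so `length = end - start` and adjacency is not overlap.
`parse_locus()` converts printed strings (tolerating the ratio character
"∶", en-dashes, minus signs and thousands commas that appear in
published tables) and `format_locus()` inverts it.  Coordinates are
treated as opaque labels on a declared assembly: published tables mix
genome builds, and this package performs no liftover.  Overlap means at
least one shared base; no minimum reciprocal overlap is imposed.
Strand is ignored throughout.

# The depletion statistic

Let $G$ be the genome size and $C$ the merged (union) footprint of a CNV
set.  Under the null hypothesis that CNVs land independently of
enhancers, the fraction of enhancer bases covered equals the genome
fraction $p = C/G$, and the expected number of covered enhancers among
$N$ is $Np$.  `depletion_statistic()` reports both views deliberately:

* the **base fraction** of enhancer bases covered (what coverage tools
  plot), with `fold = observed / expected`;
* the **feature count** of enhancers overlapped at least once (what the
  tests use).

Merging the cover set first is essential: variant catalogues deposit
overlapping records of the same locus, and counting them twice would
inflate the expectation.

Two count-based tests are computed and both are reported, neither
privileged: a 1-df chi-square goodness of fit on the
{covered, uncovered} counts, and an exact binomial test of the observed
count against $\mathrm{Bin}(N, p)$, one-sided toward depletion by
default (two-sided by flag).  P-values are never clamped or floored.

## The permutation null

Analytic expectations ignore interval geometry (length distributions,
chromosome ends).  `permutation_null()` therefore re-places every cover
interval uniformly at random on its *own* chromosome, preserving its
length — start drawn from $[0, L_{chrom} - \ell]$ — and recomputes both
statistics per permutation.  The empirical p-value uses the add-one
correction $p = (1 + \#\{T_{null} \le T_{obs}\}) / (1 + B)$, so it can
never be zero and is exactly uniform on its grid under exchangeability.
An exclusion mask (assembly gaps, centromeres) can be supplied but is
off by default: the packaged analyses make no claim about gap structure,
and enabling it is a deliberate modelling decision for real genomes.

# The synthetic-data generator

`synthetic_scenario()` fixes everything by a single seed: genome,
enhancer set, CNV set, probe noise and planted aberrations.  Its
defaults are the study conditions of the packaged analyses:

* **Enhancers**: uniform, mutually non-overlapping, lengths
  $U[800, 2200]$ bp — the range of published enhancer loci.
* **CNVs**: chromosome chosen proportional to length, start uniform,
  lengths log-uniform on $[1\,\mathrm{kb}, 500\,\mathrm{kb}]$ (CNV size
  distributions are heavy-tailed across orders of magnitude).  With a
  coverage target $c$, candidate batches are accepted until the merged
  footprint reaches $cG$ within ±2% relative tolerance; near the target
  candidate lengths are capped by the remaining deficit, which bounds
  the overshoot by the minimum CNV length.  A stall detector raises an
  error when the target is unreachable.
* **Depletion**: each candidate CNV overlapping any enhancer is retained
  with probability $\delta$ ("thinning").  $\delta = 1$ is the
  no-selection control, $\delta = 0$ total exclusion.  Thinning is the
  simplest generative mechanism whose expectation matches the fold
  statistic.
* **Probe tracks**: probes at uniform spacing (5 kb default), baseline
  log2 ratios $N(0, \sigma^2)$ with $\sigma = 0.15$ — a good-quality
  aCGH run; the accepted DLRSpread QC band is roughly 0.1–0.2.  Planted
  events add $\log_2(1/2) = -1$ (single-copy loss) or
  $\log_2(3/2) \approx 0.585$ (single-copy gain) over 5–15 consecutive
  probes.

Note that fold is not linear in $\delta$ once coverage is appreciable:
with multi-hit coverage the expected fold is approximately
$(1 - e^{-\delta\lambda})/c$ with $\lambda = -\ln(1-c)$, so at $c = 0.3$
a scenario with $\delta = 0.5$ yields fold $\approx 0.55$.  Monotonicity
in $\delta$ is exact, which is why the packaged checks assert *rank
order* recovery across $\delta \in \{0.1, 0.2, 0.5, 1.0\}$ rather than
numeric equality to $\delta$.

What the generator deliberately does **not** emulate: sequence content,
assembly gaps and centromere structure, allele frequencies, clustering
of real CNVs around segmental duplications, and probe response
artefacts (GC waves, dye bias).  Tests passing on these scenarios
demonstrate the statistics and the code, not robustness to those
real-data features.

# Probe design rules

Design follows a 3-probe detection rule: an aberration is callable when
at least three consecutive probes support it, so **resolution = 3 ×
probe spacing**.  This reconciles the familiar pairing of a 100-kb
backbone spacing with a 300-kb quoted resolution, and is applied
uniformly.

* `tile_backbone()` places probes at uniform spacing per chromosome,
  first probe at half the spacing; a chromosome shorter than the spacing
  still receives one probe at its midpoint.  If the implied count
  exceeds the budget, spacing widens to `ceiling(genome / budget)` and
  the achieved value is reported rather than silently accepted.
* `tile_regions()` tiles regions of interest at `resolution / 3`
  spacing with a 3-probe minimum per region; budget overflow is resolved
  by deterministic thinning (every k-th probe), reporting the coarser
  achieved resolution.
* `tile_enhancers()` gives each enhancer of length $L$
  $n = \max(3, \lceil L / 238 \rceil)$ probes at the $n$ evenly spaced
  interior positions.  The 238-nt spacing is treated as a per-element
  ceiling rule; the rounding is a design choice here, as is snapping to
  an optional candidate-probe catalogue (nearest candidate inside the
  element, ties toward the lower coordinate) which emulates restriction
  to validated oligos.
* `assemble_plan()` enforces budget conservation exactly: placements
  plus reserved probe groups plus residual equal the capacity, always.
  The default capacity in the packaged design, 59,905 usable features,
  is the sum implied by the published tier counts of an 8×60K-format
  array; it is configurable because physical capacity varies by
  platform.  Residual space is filled by seeded sampling from a
  catalogue, mirroring the practice of topping an array up with
  catalogue probes.

Probes are point positions (midpoints); oligo sequence selection,
thermodynamics and cross-hybridization screening are out of scope.

# Segmentation and the aberration filter

**DLRSpread** — the probe-to-probe noise estimate — is the robust spread
of consecutive-probe log2 differences: $\mathrm{IQR}(\Delta) /
(1.349\sqrt{2})$, differences taken within chromosomes and pooled.  For
i.i.d. Gaussian noise this recovers $\sigma$; it is invariant to level
shifts, so real aberrations barely perturb it.  The field names this
metric without fixing a formula; the IQR form is chosen here for
robustness to the aberrations themselves.

**Segmentation** is recursive mean-shift detection: within the current
segment, the scan considers every contiguous probe window up to
`max_width` probes and computes the two-sample t statistic between the
window and the rest of the segment; the best window is split out iff
$|t| \ge$ `t_threshold`, and the three resulting parts are segmented
recursively.  Scanning *windows* (two boundaries at once) rather than
single split points is essential: a short event in the interior of a
long segment moves the single-boundary statistic hardly at all (a
5-probe, 3σ event in a 1,000-probe chromosome gives $|t| \approx 0.5$
at the best single split), whereas the window statistic isolates it at
$|t| \approx 6.5$.  The default `t_threshold = 6` controls false splits
under the multiplicity of the window scan (the null maximum grows like
$\sqrt{2\log n_{windows}}$, about 5.3 for a few thousand probes);
thresholds in this family of algorithms are conventionally tuned per
assay, so the value is exposed as a parameter.  Cumulative-sum
arithmetic makes the scan $O(n \cdot \mathrm{max\_width})$ per split;
zero-variance segments (noiseless fixtures) are handled by sending the
t statistic to ±∞ when means differ and 0 otherwise, so step functions
are recovered exactly.

**The aberration filter** is the published rule pair, applied
downstream of any segmenter: keep calls with (i) at least 3 probes of
consistent direction and (ii) $|\bar{\ell}| \ge$ DLRSpread, where
$\bar{\ell}$ is the call's mean log2 ratio.  The mean-ratio rule is
interpreted on the absolute value — deletions have negative means, and a
signed reading would discard every deletion.  The filter is a pure
predicate: output ⊆ input, idempotent, and every call carries its
`passes_filter` flag.

**Classification** of surviving calls uses fixed precedence: overlap
with a disease (syndrome) region → `disease-region`; else overlap with
known polymorphic variation → `known-polymorphic`; else overlap with an
enhancer locus → `enhancer-CNV`; else `uncertain`.  The precedence
order is a design choice of this package (the comparison sources are
standard; their priority is not), encoding that a call inside a known
microdeletion syndrome region is reported as such even when it also
covers an enhancer.  Every overlap is still recorded in the annotation
table, so no information is lost to the precedence.

# Numerical and scale choices

Problem sizes in the packaged tests and analyses are chosen for desk
scale while keeping every estimate stable: oracle-equivalence sweeps use
random genomes up to 1 Mb against literal per-base boolean arrays;
permutation-calibration replicates use a 10-Mb genome with 100
enhancers and 99 permutations, whose add-one p-values are exactly
grid-uniform under exchangeability; depletion-recovery scenarios use a
100-Mb genome, 2,000 enhancers and ~30% CNV coverage, where the fold
gaps between adjacent $\delta$ values exceed their sampling noise by an
order of magnitude; segmentation sensitivity uses 2,000-probe tracks
with three planted 5–15-probe events each.  All randomness flows
through explicit seeds; identical seeds give bit-identical feature
sets, tracks, plans and permutation summaries.

# Known limitations

* The depletion analysis treats the CNV catalogue as exchangeable
  intervals; ascertainment structure in real catalogues (platform
  resolution, study mix) is not modelled.
* The permutation null preserves each interval's chromosome; it does
  not model inter-chromosomal placement biases.
* The segmenter is a documented mean-shift method, not a reimplementation
  of any vendor algorithm; its calls feed the same published filter
  rules, which are the tested surface.
* Sex-chromosome copy normalization and mosaicism are out of scope.
* Genome-build differences are handled by refusing to mix bound
  assemblies, not by converting coordinates.
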