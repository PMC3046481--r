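---
title: "Typed genomic tracks and null-model randomization tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typed genomic tracks and null-model randomization tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackperm)
```

## The problem

Two genome annotation tracks -- say a histone-modification domain track
and a repeat track -- often *look* associated: their elements overlap
more than a naive expectation suggests. Whether that association means
anything depends entirely on the null model: what is held fixed, and
what is randomized. Genomic elements are clustered, autocorrelated, and
unevenly spaced, so a null model that ignores this structure (for
example, scattering covered base pairs independently) will declare
almost any pair of realistic tracks significantly associated.

`trackperm` makes the null model an explicit, user-specified object. A
track pair is compared by (1) reducing each track to one of five
abstract genomic types, (2) choosing an analysis valid for that type
pair from a registry, (3) choosing a *preservation rule* per track plus
a randomization process for whatever is not preserved, and (4) computing
a p-value exactly, asymptotically, or by (sequential) Monte Carlo --
either globally over a region or locally per bin with
Benjamini-Hochberg FDR correction across bins.

## The five genomic types

Every one-dimensional annotation reduces to one of:

* **UP** -- unmarked points (e.g. SNP positions, integration sites);
* **MP** -- marked points (points with a numeric or categorical value);
* **US** -- unmarked segments (half-open bp intervals, e.g. genes,
  domains);
* **MS** -- marked segments (segments with e.g. an expression value);
* **F** -- functions (one value per bp, e.g. melting temperature or GC
  content).

Coordinates are 0-based half-open everywhere internally; user-facing
region strings (`"chr17:3m-"`, `"chr1:153,250,001-153,450,000"`) are
1-based inclusive and converted at the boundary. Information-*reducing*
coercions are allowed (marks dropped, segments to midpoints with
`floor((start+end)/2)` or to boundary points); information-increasing
ones are rejected. The unordered type pairs number 15; the registry
currently implements 13 analyses covering 8 pairs, each phrased as a
generic biological question ("are the points inside the segments more
than expected by chance?"). An `(MS, US)` query also surfaces `(US,
US)` analyses via the MS-to-US reduction, flagged `via_coercion`.

Normalization choices worth knowing: overlapping or touching input
segments are merged on load with a warning (the randomizers and overlap
statistics assume disjoint segments); marked segments cannot be merged
without destroying marks, so overlap there is an error; duplicate
points are rejected because the point randomizers sample positions
without replacement.

## Null models: preservation plus randomization

For unmarked segments the preservation hierarchy, strict to loose, is:

1. `preserve_all` -- the track is never altered;
2. `permute_lengths_gaps` -- keep the multisets of segment lengths *and*
   gap lengths (n segments give n+1 gaps, counting both flanks to the
   bin edges) and permute both orders independently;
3. `uniform_position` -- keep only the segment-length multiset and place
   the segments disjointly, uniformly over all disjoint arrangements
   (gaps drawn as a uniform composition of the free space);
4. `coverage_bp` -- keep only the covered-bp count k and resample
   exactly k covered bp without replacement (`coverage_bernoulli` is
   the iid per-bp variant at rate k/B, matching the analytic binomial
   null).

Rule 2 is deliberately coarser than rule 3: a single segment `[2,4)` in
a bin of 10 has gaps {2, 6}, so its permuted start can only be 2 or 6,
not uniform over 0..8. That coarseness is the point -- it preserves the
dependency between neighbouring base pairs. Points are either preserved,
resampled uniformly over the bin's *defined* (unmasked) bp, or resampled
with probability proportional to an intensity (below). Marks can be
permuted with positions fixed. Function tracks are always conserved:
there is no meaningful randomization of a per-bp function that respects
its structure, so F-F analyses fall back to the asymptotic tau route
(with the caveat that per-bp autocorrelation makes any per-bp
independence assumption optimistic; treat those p-values as
descriptive).

Gap permutation uses n+1 linear gaps including both flanks rather than a
circular permutation, so the bin edges stay boundaries. `coverage_bp`
resamples an exact count (hypergeometric marginals) because "preserve
the number of base pairs" is an exact statement; the Bernoulli variant
exists for the analytic binomial null. Randomization is confined to the
bin under test (local analyses) or the region (global), never across
chromosome boundaries.

## Intensities and confounders

A third track can induce association between two tracks of interest --
GC content, higher inside exons, carries exon-location information into
any GC-driven signal. The intensity algebra addresses this: an
`IntensityTrack` is a nonnegative per-bp function lambda(b) used as
sampling weights for point randomization, conditioned on the observed
point count. Constructors:

* `constant_intensity(c, region)` -- reduces to uniform randomization;
* `linear_combination(c, betas, covariates)` -- `max(0, c + sum beta_i
  g_i(b))`, clipped at zero with a logged count (the linear form cannot
  guarantee positivity);
* `kde_intensity(points, bandwidth, region)` -- Gaussian kernel density
  of observed points, renormalized over the region to the point count
  (which also absorbs edge truncation); bandwidth is user-supplied, no
  default rule is claimed;
* `gc_flank_functions(gc, window = 100)` -- per-bp left/right flank GC
  content with linearly decreasing weights `w_i = 2(w-i+1)/(w(w+1))`
  (normalized to sum to 1, the base itself excluded -- both choices are
  ours, as is linear-vs-other decay normalization);
* `fit_intensity(points, covariates, region, genome)` -- log-linear
  point-process regression, `log lambda = c + sum beta_i g_i`, fitted
  by Poisson maximum likelihood on per-bp presence. The log link was
  chosen over the clipped linear form for guaranteed positivity and
  standard ML theory; the fitted curve is normalized to the observed
  count and carries the coefficient table in `attr(, "fit")`.

Point randomization is invariant to positive rescaling of the
intensity, so normalization is cosmetic. Sampling without replacement
uses sequential weighted draws; for point counts far below the bin
length this is numerically indistinguishable from the conditioned
non-homogeneous Poisson process.

## Inference

The Monte Carlo p-value is `(r + 1) / (n + 1)` with `r` the number of
replicates whose statistic reaches the observed value (mirrored for
`"less"`); this add-one form is valid (never zero) regardless of `n`,
at the price of a small upward bias of order `1/(n+1)`. Two-sided MC
p-values double the smaller tail and cap at 1. Sequential Monte Carlo
keeps sampling until the observed statistic has been exceeded a preset
number of times (default 20) or a cap is reached: large p-values stop
after a couple of dozen draws while small ones get the full budget. For
a family of m bin tests we recommend `max(1000, 5m)` MC samples so the
FDR adjustment can resolve the relevant p-values.

Where the analysis/null pair admits it, the exact route is used
instead: points-in-segments under the uniform-point null is
Binomial(n, coverage fraction), and under the per-bp Bernoulli segment
null Binomial(n, k/B); bp-overlap against a Bernoulli-randomized track
is Binomial(k_fixed, k_rand/B). (Uniform point sampling is without
replacement, so the exact law is hypergeometric; at the point counts
and bin lengths used here the binomial is indistinguishable and is what
the exact route implements.) Kendall tau statistics between conserved
tracks use the tie-corrected normal approximation via `cor.test`. All
count correlations use tau-b because count data are tie-heavy.

Local analyses partition the region into fixed-size bins (last bin
truncated; bins never span chromosomes), test each bin with at least
`min_elements = 5` elements of every randomized track (others are
flagged untested, with the reason, and excluded from the FDR family),
and adjust the tested bins' p-values by Benjamini-Hochberg, calling
significance at `q = 0.10` by default. Per-bin RNG substreams are
derived as `seed + bin index`, so results are reproducible and
independent of evaluation order.

## The simulator and what the tests show

The generators produce every input the methods need: Poisson or
intensity-driven points, alternating gap/segment processes (geometric
lengths by default -- memoryless, matching the Markov coverage model;
fixed and empirical distributions are accepted), two-state Markov
per-bp coverage (geometric run lengths, stationary coverage
`p_enter / (p_enter + 1 - p_stay)`), circular-moving-average smooth
functions with optional thresholding into GC-like 0/1 indicators, and
marks tied linearly to a per-element covariate with known slope and
noise.

The calibration suite generates data *under* each null and checks the
empirical type-I error at alpha = 0.05 lies in [0.03, 0.07] over 1,000
runs per route, with 59 MC samples per test (59 makes 0.05 exactly
attainable, since p takes values k/60). One calibration per inference
route is run -- exact binomial (uniform points; Bernoulli coverage),
Monte Carlo under each of the three segment randomizations, uniform
points, and mark permutation -- because admissible (analysis, null)
combinations sharing a route share their calibration.

The false-positive demonstration draws two *independent* Markov
coverage tracks (stay probability 0.99, mean run 100 bp, stationary
coverage 0.2, 1 Mbp) and tests their overlap 200 times: under the
per-bp Bernoulli null the rejection rate is far above nominal (the
per-bp null ignores run-length autocorrelation, understating the null
variance roughly by the mean run length), while under the
lengths-and-gaps-preserving null -- which is exactly valid here, since
the alternating-renewal construction makes orderings exchangeable given
the length multisets -- it returns to about 0.05.

The confounder workflow study places ~150 points on 10 kbp in
proportion to `exp(1 + 2 g)` for a smooth unit-variance covariate `g`
(window 300 moving average) and tests "is `g` high at the points?"
against the uniform null (essentially always significant) and against
the null using `fit_intensity(points, list(g))` (calibrated:
non-significant at the nominal rate). Intensity fitting itself is
checked by slope recovery (within 3 standard errors of the true 2 at
~2,000 points over 100 kbp) and by the Kolmogorov-Smirnov distance
between normalized fitted and true intensity CDFs (< 0.05 at ~5,000
points).

What passing these tests does *not* show: the simulator draws
exchangeable-length processes and smooth Gaussian functions; real
tracks have long-range trends (centromeres, assembly gaps, mappability
artifacts), heavy-tailed segment lengths, and inter-chromosome
heterogeneity. Calibration under the simulator therefore validates the
machinery, not any particular biological null choice -- choosing a
defensible preservation rule for real data remains the analyst's
responsibility, and comparing results across several rules is good
practice precisely because conditional p-values need not be ordered
even when the preservation hierarchy is.

## Numerical and degenerate-input choices

* Segment midpoint ties floor; deterministic.
* Statistics return `NA` (propagated as "untested") on degenerate
  input: no points for a mean, fewer than two elements or zero variance
  for a correlation, an empty group for a group difference.
* Points on undefined function positions are excluded from
  `mean_function_at_points` with a logged count, not an error (mask
  semantics).
* `border_affinity` uses the length-normalized distance
  `min(p-s, e-1-p)/(e-s)` so segments of different lengths are
  comparable; uniform placement gives ~0.25.
* Effect sizes are observed/expected under the null where the null mean
  of a nonnegative statistic is positive, else the standardized
  difference `(obs - mean)/sd`.
* MC replicates with undefined statistics are dropped from `n`;
  a fully undefined replicate set is an error.
* Intensity-driven simulation and fitting assume per-bp intensities
  well below 1: points are distinct positions, so a bp whose intensity
  approaches 1 saturates and the discretized Poisson model degrades.
  The recovery studies keep the covariate amplitude at sd 0.5 (maximum
  per-bp intensity around 0.3) for this reason.
* Bin tests are seeded `seed + bin index`; the same configuration and
  seed reproduce results byte-identically, including the results TSV.

## Problem sizes used by the test and acceptance runs

Oracle equivalence uses 200 random instances on chromosomes up to
1,000 bp; exact-vs-MC agreement 50 cases at 2,000 replicates;
calibration 1,000 runs per route at 59 MC samples; the false-positive
demonstration 200 runs at 1 Mbp; the confounder study 100 runs at
10 kbp. These sizes give standard errors comfortably inside the
asserted bands while keeping a full run in the minutes range on one
core.
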