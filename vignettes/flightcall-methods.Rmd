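---
title: "Acoustic similarity analysis of flight calls: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic similarity analysis of flight calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: what the
synthetic generator emulates, how each measurement and statistic is
defined, which numerical choices were open and how they were resolved,
and what the package's passing tests do and do not establish about real
recordings.

## The scientific question

Nocturnal flight calls are very short (tens of milliseconds),
species-stereotyped vocalizations produced by songbirds during
migration. If their fine acoustic structure differs consistently between
individuals or between sexes, these calls could transmit identity
information within migrating flocks, and acoustic monitoring could
exploit that. The analysis this package implements asks three questions
of a set of per-call measurements: (1) are calls from the same
individual more similar to each other than to other individuals' calls,
(2) do calls separate by sex, and (3) do they separate by age — with the
expectation, for American Redstart-like data, that identity and sex
carry signal while age does not.

## The synthetic population generator

The generator exists so that every downstream stage has a ground truth.
Its defaults encode the study conditions the package emulates:

* **Population**: 36 birds (14 males, 22 females; 25 hatch-year, 11
  after-hatch-year), 5 analysed calls per bird, 180 calls in total.
  Counts are assigned exactly (by rounding the configured ratios) with
  randomised order.
* **Durations**: sex means 72 ms (male) and 66 ms (female), within-bird
  SD 3 ms, hard-clipped to 38–95 ms.
* **Frequency band**: all contour energy within 3.5–10.3 kHz at a
  44.1 kHz sample rate; female contours sit 300 Hz higher, a stylised
  version of the narrower female frequency range.
* **Variant shapes**: five piecewise-linear contour templates (A, G, M,
  S, V) follow the verbal descriptions of the qualitative variant
  classes — e.g. V is an acute, symmetric dip with its minimum at
  mid-call; S ends lower in frequency than it starts. The breakpoint
  tables are versioned calibration constants of this package, not
  measurements. Per-sex variant propensities come from the observed
  sex-by-variant call counts (males produce no G calls, only males
  produce M calls).
* **Individual signature**: each bird draws once-per-lifetime additive
  offsets for duration (SD 6 ms), contour frequency (SD 350 Hz) and
  tail-modulation depth/rate (SD 100 Hz / 250 Hz); each call re-draws
  smaller within-bird perturbations (3 ms, 80 Hz, 30 Hz, 50 Hz). The
  between > within ordering is what makes calls individually
  recognisable. No published within- vs between-bird variance estimates
  exist for these parameters, so the magnitudes are calibration
  choices: they are set so that, at the 36-bird study scale, the full
  pipeline recovers a significant sex effect, a strong individual
  signature, and no age effect — the qualitative pattern the analysis
  is designed to detect. They are fixed package defaults, not fitted
  quantities.
* **Age**: deliberately affects nothing; it exists to verify that the
  pipeline does not invent effects.
* **Synthesis**: the waveform is `sin(phase)` with phase the cumulative
  integral of the smoothed contour; the piecewise-linear contour is
  smoothed by a raised-cosine kernel whose half-width (per template)
  controls how acute each inflection is; the final part of the call
  carries sinusoidal frequency modulation (the "modulated tail");
  amplitude follows a Tukey envelope with 5 ms of near-silent padding on
  each side; white Gaussian noise is added at 20 dB SNR. Padding is
  converted to samples by rounding halves up, so 5 ms at 44.1 kHz is
  exactly 221 samples.

Whether variant identity belongs to the bird or to the call was an open
design question; the package draws the variant independently per call
from the bird's sex-specific propensities, which is the weaker (harder)
assumption for detecting individuality.

What the generator does *not* emulate: syrinx physiology, atmospheric
propagation and reverberation, overlapping or heterospecific calls, and
realistic ambient-noise spectra. Passing tests on synthetic data
therefore demonstrate the *pipeline's* statistical behaviour (power,
calibration, invariances), not field-data performance. Two visible
consequences: the five templates are more distinct than real variant
classes, so the variant pMANOVA R² on synthetic data (≈ 0.5) is far
above what real calls show (< 0.1); and the stereotyped synthesis makes
many of the 95 measurements mutually redundant, so pruning at |r| ≥ 0.95
keeps fewer features (≈ 50) than on real measurements (≈ 84 of 95).

## Spectrograms and the measurement registry

Spectrograms use a 256-point FFT with 256-sample Hann windows advancing
38 samples, one-sided squared magnitudes, and no zero-padding: frames
that would overrun the clip are dropped, so `n_frames =
floor((N − 256)/38) + 1`. Window-gain correction is omitted on purpose —
every measurement below is either scale-invariant or documented as
absolute-scale.

The 95 measurements (see `default_feature_spec()`) are defined on the
marginals of the spectrogram. The key definitional choices, which the
registry fixes as normative for this package:

* **Percentiles** are locations on the discrete cumulative energy of a
  marginal (step resolution: one hop in time, one bin in frequency).
  The 90% duration is t₉₅ − t₅, the 50% duration t₇₅ − t₂₅; bandwidths
  are the same on the spectrum.
* **Concentration** is the summed width of the smallest set of bins
  (taken in decreasing energy order) holding 50% of total energy;
  **modewidth** is the width of the maximal contiguous run around the
  modal bin with values at least half the mode.
* **Entropies** are Shannon entropies in bits of the normalised
  marginals and of the full normalised spectrogram.
* **Contour** statistics are computed on the per-frame peak frequency
  restricted to the 90%-energy time span; spread is the inter-quartile
  range; the inflection count is the number of sign changes of the first
  difference of the 3-frame-smoothed contour.
* **Correlation envelopes** are normalised autocorrelations of *e(t)*
  (over time lags) and *s(f)* (over frequency lags); the "median" is the
  area-median lag — the lag below which half of the area under the
  clamped-nonnegative envelope lies — chosen over the first half-max
  crossing for robustness to noise; the half-width at half maximum is
  also reported.
* Exactly two measurements (`mean_cell_power`, `peak_frame_energy`) are
  on the absolute power scale and scale with amplitude squared;
  everything else is invariant to amplitude scaling, and
  percentile-based durations/bandwidths move by at most one hop/bin
  under silent padding or time shifts. These invariances are asserted
  by tests.

## Feature pruning and subsampling

Pruning removes zero-variance columns first (reason `"constant"`), then
visits feature pairs with |r| ≥ 0.95 in decreasing |r|; in each pair the
member with the larger mean absolute correlation to the other surviving
features is removed (ties keep the earlier registry column). The paper
trail of removals is returned so the surviving count is auditable. The
threshold applies to |r|: a correlation of −0.96 is as redundant as
+0.96.

Subsampling keeps exactly five calls per bird (uniformly, without
replacement, seed-reproducible) among birds with at least five calls.
The subset-representativeness check compares the subset against the
*complement* rows with per-feature Welch t-tests plus a permutation
omnibus (mean squared t); comparing subset against the full table, which
contains the subset, would make the two samples overlap and the tests
miscalibrated.

## Random-forest similarity

`unsupervised_proximity()` uses the synthetic-contrast construction: a
contrast dataset of equal size is drawn by sampling each feature
independently from its empirical marginal, which preserves every
marginal but destroys the joint structure; a random-forest classifier
(default hyperparameters, `mtry = floor(sqrt(p))`, 4999 trees) separates
real from contrast, and the proximity of two real calls is the fraction
of trees in which they co-occupy a terminal node. Proximity is counted
over all trees (not just out-of-bag ones); the alternative is a switch.
Distance for ordination is `1 − proximity`.

The within/between comparison averages, per bird, the 10 within-bird
pairwise similarities and the 875 similarities to other birds' calls,
then applies a two-sample t-test to the 36 + 36 per-bird means. Welch's
test is the default and the pooled-variance test is also reported: on
36 + 36 means the pooled test has 70 degrees of freedom while Welch
gives ≈ 69, and published analyses of this design are ambiguous between
the two. The per-bird means are not strictly independent (they share
matrix entries), which makes the test anti-conservative in small
populations; simulation shows the size is ≈ 0.28 at 8 birds, ≈ 0.10 at
16 and nominal (≈ 0.05) by ≈ 28 birds, so conclusions from this test
should rest on study-scale populations. The package's calibration test
runs 200 null replicates at 28 birds.

## Permutational MANOVA

`permanova_single()` implements the distance-based one-way
decomposition: SS_total = (1/n)·Σ_{i<j} d²ᵢⱼ, within-group SS by the
same formula within groups, pseudo-F = [SS_A/(a−1)]/[SS_W/(n−a)], and
p = (1 + #{F* ≥ F}) / (1 + n_perm) — so the smallest attainable p at 999
permutations is 0.001. On univariate Euclidean data the pseudo-F equals
the classical ANOVA F exactly, which the tests assert to 1e-9, and an
exhaustive-enumeration oracle checks the permutation p on toy data.

`permanova_terms()` fits sequential (Type I) terms through the
Gower-centred inner-product matrix G = −½·J·A·J: each term's SS is the
increment of tr(HG) as its columns enter the model. Sums of squares,
pseudo-F and R² agree with `vegan::adonis2(by = "terms")`, which serves
as an independent cross-check in the test suite (the implementation here
is the package's own).

Two analysis choices deserve emphasis:

* **Distance metric.** The default is Euclidean distance on z-scored
  features. Acoustic measurements mix units (ms, Hz, bits) and are
  signed, which rules out the abundance-style Bray-Curtis default of
  community-ecology software; the metric is recorded in every result,
  and small discrepancies with published F values on real data can stem
  from exactly this unstated choice.
* **Nesting.** "Individual identity nested" is implemented as a
  permutation scheme: factors constant within a bird (sex, age) are
  tested by permuting whole birds as blocks; call-level factors
  (variant) permute calls freely. This matters: with per-bird
  signatures present and age truly inert, freely permuting calls
  rejects the age null about ten times too often (pseudo-replication),
  while block permutation holds the nominal level — both behaviours are
  asserted by tests. The free scheme remains available for comparison.

## Ordination

PCoA double-centres the squared distances and eigendecomposes;
coordinates are eigenvectors scaled by √eigenvalue, negative eigenvalues
(possible for non-Euclidean input such as 1 − proximity) are excluded
from coordinates but reported. NMDS minimises Kruskal stress-1 via
`vegan::metaMDS` with 20 seeded restarts by default. Group ellipses
follow the "standard error of the axis-score averages" construction
literally: the covariance of a group's scores divided by its n, scaled
by the χ²(2) quantile at the 99% level — these are centroid-uncertainty
ellipses, several times smaller than data ellipses. Both the
feature-distance and the RF-proximity ordination paths are supported,
since published figures of this design are ambiguous about which fed
the plots.

## Numerical and degenerate-input conventions

* Zero-energy clips raise an `"empty clip"` error; batch measurement
  reports and skips such clips rather than aborting.
* Weighted skewness/kurtosis return 0 for zero-variance marginals;
  contour statistics fall back to the full frame range when the
  90%-energy span holds fewer than two frames.
* A similarity matrix with zero variance in both within- and
  between-means yields t = 0, p = 1 (all-equal case) or ±Inf, p = 0
  (separated constant blocks).
* Permutation p-values always count the observed statistic
  (`(1 + exceed)/(1 + n_perm)`), and every seeded routine
  (`sample_population`, `subsample_calls`, `unsupervised_proximity`,
  permutation streams, NMDS restarts) is reproducible from its seed
  argument; the pipeline derives stage seeds from one master seed.

## Problem sizes used by the test suite

The test suite scales simulations to what the checks need rather than to
the full study everywhere: permutation-test calibration uses 1000 null
datasets of n = 20 at 199 permutations; the within/between null uses 200
replicates of 28-bird populations with 120-tree forests; parameter
recovery runs 12 replicates of the full 36-bird × 5-call design with
199 permutations and 300-tree forests, with a 99% binomial allowance on
the expected pass rate. `scripts/acceptance.R` runs the study-scale
analysis at full strength (999 permutations, 4999 trees).

## Known limitations

* The generator's effect sizes are calibration assumptions; real
  within-/between-bird variance components for these acoustic parameters
  are unknown.
* Synthetic variant classes separate far more cleanly than real ones,
  and synthetic feature redundancy is higher, so feature counts after
  pruning and variant R² are not comparable to real-data values.
* The within/between t-test is anti-conservative below ~25 birds (see
  above).
* No dispersion-homogeneity test accompanies the pMANOVA, and no
  multiple-testing correction is applied across factors; both follow the
  original analysis design.
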