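---
title: "Methods: time-resolved spectral pattern similarity and cluster inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved spectral pattern similarity and cluster inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectralrsa)
```

## The model

The unit of analysis is a single-subject 4-D power tensor: trials ×
electrodes × frequencies × time, typically obtained by multitaper or
wavelet decomposition of stimulus-locked EEG epochs (the decomposition
itself is out of scope here; `spectralrsa` starts from the power tensor).
The canonical grids are a two-band frequency axis — 2–20 Hz in 2-Hz steps
plus 25–125 Hz in 5-Hz steps, 31 bins — and a 326-sample time axis from
−0.6 s to 2 s at 8 ms. Neither is hard-coded: `build_frequency_grid()` and
`build_time_grid()` accept arbitrary band and step specifications.

A "spectral pattern" is the frequency vector of one trial at one electrode
and time point. Representational similarity between two trials is the
Pearson correlation of their frequency vectors, computed for every pair of
time points, yielding a time × time correlation matrix per electrode and
trial pair; each entry is Fisher-z transformed (`atanh`) before averaging
or testing, since z′ is approximately variance-stabilized with variance
1/(F − 3) for F frequency bins.

### Why the 1/f background must go

EEG power falls with frequency roughly as a power law. Two raw log-power
frequency vectors therefore correlate highly even for unrelated stimuli —
both follow the same downward slope. Before correlating we log10-transform
and subtract a per-channel background spectrum B(f). Two estimators are
offered:

* `mean_spectrum` (default): B(f) is the mean log-power over all trials
  and time points. This is the estimator behind the common
  "subtract the mean noise spectrum" step; it removes the empirical
  spectral profile exactly.
* `loglog_fit`: ordinary least squares of that mean spectrum on log10(f),
  as in the background step of the BOSC oscillation-detection framework;
  B(f) is the fitted line and the per-channel intercept/slope are
  retained. On a noiseless f^α tensor this recovers α exactly and leaves a
  numerically zero residual (tested).

The reference description does not pin down which of the two the original
analysis used, nor whether it is computed per trial or across trials; we
implement both, estimate across trials over the full epoch (maximizing
samples; no window is specified anywhere), default to `mean_spectrum`, and
record the choice in the result metadata. Log base 10 is used throughout;
the base only matters for `loglog_fit` interpretation, where the slope is
per-decade.

## Similarity levels and averaging units

With the encoding design categories × 2 exemplars × 2 presentations:

| level | pair per unit | unit |
|---|---|---|
| within-item | (exemplar 1, presentation 1) vs (exemplar 1, presentation 2) | category |
| within-category | (exemplar 1, presentation 1) vs (exemplar 2, presentation 1) | category |
| between-category | (e1, p1) of category i vs (e1, p1) of category j, i ≠ j | ordered pair (i, j) |

Between-category pairs are **ordered** — n(n−1) units — because each
comparison is genuinely computed twice, once in each direction, and the
two matrices are transposes of one another; averaging over all ordered
pairs therefore yields an exactly symmetric mean matrix (asserted to
1e-12 in the tests). A description that counts (n−1)² matrices per
electrode is inconsistent with computing each comparison twice; we follow
the ordered-pair reading and flag rather than reconcile the discrepancy.

Categories that lack a required trial (artifact rejection is uneven across
subjects) are skipped per level and reported in the pair list's `skipped`
attribute; how the original analysis handled such categories is
undocumented, so we make the skip explicit rather than claim equivalence.

## Numerical choices

* **r = ±1**: identical patterns occur (duplicated trials, degenerate
  simulations). |r| is clipped to 1 − 1e-12 before `atanh` so averages
  stay finite (z′ ≈ 14.2 at the clip); clip events are counted on the
  result.
* **Zero-variance frequency vectors** have no defined correlation; the
  entry is set to 0 and counted, with one warning, instead of propagating
  NaN through the tensors.
* **t with zero variance**: a paired difference that is constant at 0
  yields t = 0 (not NaN).
* **Permutation p counting**: the observed labeling counts as one of the
  `n_perm` draws, so p = #{draws with max mass ≥ observed}/n_perm and the
  smallest attainable p is 1/n_perm — 0.002 at the default 500 draws. The
  identity draw reuses the observed map bit-for-bit so the tie is exact.
* **Cluster-forming threshold**: the two-sided critical t at sample
  α = 0.05 with the degrees of freedom of the map being thresholded
  (subjects − 1 at the second level), rather than a fixed |t|; clusters
  are defined via sample p-values, so the threshold must track df.
* **Connectivity**: ±1 step along t₁ *or* t₂ within a channel — no
  diagonal moves in the time-time plane — plus spatial neighbours at the
  identical (t₁, t₂). Channel neighbourhoods come from a distance
  threshold on layout coordinates or an explicit pair list. The reference
  convention is undocumented; exact reproduction of its printed cluster
  counts is sensitive to both choices, which is why those counts are
  treated as stretch targets only.

## The permutation test and its discreteness

The second level tests subject t-maps against zero. Under the null the
maps are sign-symmetric and exchangeable, so flipping the sign of whole
subject maps generates the exact randomization distribution; we use the
one-sample sign-flip test directly rather than the equivalent trick of an
independent-samples test against a synthetic zero group. With n subjects
there are only 2ⁿ distinct sign patterns: at n = 6 the null has 64 atoms
and a 0.025 per-tail alpha is effectively unreachable (the identity
pattern alone recurs among random draws with probability 1/64 per draw).
From n = 10 (1024 atoms, the reference group size) the Monte Carlo p
resolves comfortably below 0.025. Simulation sizes in the test suite
follow this: error-control and power studies use 10-subject cohorts.

A related, deliberate property: the third-level masks are built per group
from that group's own significant clusters. Mask selection concentrates on
samples where the group's effect happened to be strong, so even for
identically configured groups the between-group t on extracted
specificity is somewhat overdispersed relative to t(n₁+n₂−2). Only the
within-person difference Δ = within-item − within-category crosses groups
— never absolute similarity values, which are confounded by montage and
anatomy differences between age groups.

## The synthetic generator

`synth_config()` describes a simulated encoding study; defaults mirror the
reference design: 40 categories × 2 exemplars × 2 presentations, 10
subjects per group, the 31-bin frequency grid, the 326-point time axis,
and a 1/f log-power background (default slope −2 per decade, intercept 2).
Log-power is

```
background(f) + w_cat · g_cat(ch, f; c) + w_item · g_item(ch, f; c, e) + σ · ε
```

inside the signal window (default 0.3–1.0 s, all channels) and
`background + σ·ε` elsewhere, with g-fields iid standard normal over
(channel, frequency), shared across presentations (and, for g_cat, across
exemplars). Because the signal is additive in log-power and the background
removal subtracts a per-channel-frequency constant, the planted population
correlations are available in closed form:

* ρ_item = (w_cat² + w_item²) / (w_cat² + w_item² + σ²)
* ρ_cat = w_cat² / (w_cat² + w_item² + σ²), ρ_between = 0.

Defaults w_cat = w_item = σ = 1 give ρ_item = 2/3, ρ_cat = 1/3. Patterns
are constant across the window (a block signal), so the true effect is a
rectangular channel × time × time cluster whose recovery can be checked
exactly. The generator is deterministic given the seed, and subject seeds
are derived from the base seed.

What it does **not** emulate: oscillatory burst dynamics, volume
conduction and channel covariance, non-stationary noise, autocorrelated
time courses, realistic montage geometry (channels sit on a circle).
Passing tests therefore demonstrate the statistical machinery — estimator
identities, error control under exchangeability, power against additive
signals — not robustness to every physiological nuisance in real EEG.

One subtlety the tests do absorb: the estimated background includes a
share of the planted signal (the signal window contributes to the time
mean), which attenuates recovered z′ slightly at small category counts.
At the design's 40 categories the bias is well inside the 4-standard-error
recovery band used by the tests.

## Problem sizes and containers

The test suite and the acceptance script run reduced grids — typically the
full 31-bin frequency axis with a 27- or 66-point time axis (100/40 ms
steps), 4 channels, and 8–40 categories — chosen so that a complete
three-level analysis of a 10-subject cohort takes about a second while
preserving every structural property of the full-scale problem (the
full-scale 326 × 326 similarity matrix is exercised once). Full-scale
grids are available through the same configuration objects.

Datasets and intermediate results round-trip through R's native RDS
serialization (`save_tfr()`/`load_tfr()`), which is lossless for the whole
container. FieldTrip-style MAT structures are imported by delegating MAT
parsing to the system Python (scipy.io for v7, h5py for v7.3) and
streaming the tensor to R as raw float64; a matching fixture writer makes
the round trip testable without MATLAB. Pipeline configuration is a YAML
file with `paths`, `data`, `rsa`, `stats`, `behavior` and `synth`
sections; every step of the CLI records a JSON provenance entry (config
hash, seed, package version) so artifacts are reproducible from
configuration alone.

## Known limitations

* Exact reproduction of reference cluster *counts* requires matching the
  undocumented neighbourhood/connectivity conventions; only scalar group
  statistics are robust to those choices.
* The pooled brain–behavior correlation mixes between-group mean
  differences with within-group association; a group-mean-centered variant
  exists behind `center_groups = TRUE` with an explicit warning.
* Memory use at full scale: a 40-unit × 60-channel × 326² Fisher-z tensor
  is ≈ 2 GB in doubles; per-subject tensors are computed channel-streamed,
  but keeping many subjects' full-scale tensors in memory simultaneously
  is the user's responsibility (average to channel × time × time first).
* Reinstatement, RDM export, global matching and subsequent-memory splits
  are natural extensions of the same pair-enumeration machinery but are
  not wired as pipeline defaults.
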