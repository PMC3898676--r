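---
title: "Methods: morphology similarity scoring and intracellular response statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphology similarity scoring and intracellular response statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pherocircuit)
```

This package implements the computational backbone of a joint
morphology–physiology study of identified higher olfactory neurons: a
point/tangent similarity score over registered neuron skeletons with Ward
hierarchical clustering, and the statistics pipeline for intracellular
odor-response data — spike extraction, exact Poisson response testing with
FDR control, lifetime sparseness, subthreshold permutation testing, and a
synaptic-latency estimator for direct glomerular stimulation. Because raw
recordings of this kind are rarely deposited, the package ships seeded
generators that emulate the statistical structure of both data types, so
every stage can be exercised, calibrated and regression-tested end to end.

## The morphology similarity score

A traced neuron is reduced to its *dot-property* representation: an
unordered cloud of 3D points (one per skeleton node, after resampling to
uniform cable density) with a unit tangent vector capturing the local
neurite heading. For a query neuron $Q$ with $n$ points and a target $T$,

$$S(Q,T) \;=\; \frac{1}{n}\sum_{i=1}^{n}
  \left| q_i \cdot t_{j(i)} \right|\,
  e^{-d_{ij}^2 / 2\sigma^2},$$

where $j(i)$ is the nearest neighbour of point $i$ in $T$, $d_{ij}$ their
Euclidean distance, and $q_i, t_j$ the unit tangents. Each matched pair
contributes the absolute tangent dot product (co-linear neurites score 1,
orthogonal ones 0) weighted by a Gaussian in distance. $S$ ranges from 1
(identical) to 0 (completely different) and is *not* symmetric: distances
are $D(Q,T) = 1 - S(Q,T)$, symmetrized before clustering.

Key parameters:

* `sigma` (μm, default **3**): how close two points must be to count as
  similar. The default matches the registration accuracy / biological
  variability of template-registered fly-brain material; at $5\sigma$
  displacement the Gaussian term is $\approx 4\times10^{-6}$, which is
  why well-separated arbours score essentially 0.
* `symmetrize` (default **mean**): how the two directed distances are
  reconciled. The directed score is well defined, but published work
  rarely states which reconciliation entered clustering; we default to
  the mean — the least informative symmetric combination that stays in
  $[0,1]$ — and expose `min`, `max` and `none`.
* `k_neighbors` (default **5**) for tangent estimation, and
  `resample_step` (μm, default **1**). Tracing software does not produce
  a canonical node density, and the original tangent estimator is not
  specified; we use local PCA over the `k` nearest nodes
  (sign-normalized to a deterministic hemisphere), which is
  deterministic and rotation-equivariant, and resample well below
  `sigma` so scores are insensitive to native node spacing.

Clustering uses classic Ward linkage on the unsquared distances
(`hclust`, `method = "ward.D"`), the behaviour of the R default at the
time this style of analysis was established; the linkage is selectable.
Nearest neighbours are found by a blocked vectorized exhaustive search
with a lowest-index tie break; the test suite checks it against a naive
double loop to $10^{-12}$ on clouds up to $10^3$ points. Two numerical
guards keep the score exact where it should be: squared distances from
the expanded bilinear form are snapped to zero below $10^{-6}\,\mu m^2$
(far below any meaningful separation), and tangent dot products within
$10^{-12}$ of 1 are clamped to 1, so $S(Q,Q) = 1$ holds exactly in
floating point.

## Spike extraction

Current-clamp traces (11.1 kHz) are smoothed with a binomial
(Pascal-row) kernel and spikes are detected on the *second central
difference* of the smoothed trace: a sharp transient has strongly
negative curvature at its apex. The original analyses quote a smoothing
band of 180–550 Hz chosen per cell but no mapping from band to kernel;
we adopt the convention that the kernel of order $m$ has magnitude
response $\cos^m(\pi f/f_s)$, and pick the shortest odd-length kernel
whose −3 dB point is at or below the requested cutoff (default
**400 Hz**). The detection threshold is unstated in the original
protocol; `auto` mode uses $-8 \times \mathrm{MAD}$ of the second
difference, which adapts to the noise floor and is reproducible across
traces (a fixed threshold is also available). Sub-threshold samples are
grouped into events with a 2 ms refractory gap, and each event is timed
at the raw trace's voltage maximum — consequently spikes closer than
2 ms merge by construction. On the synthetic benchmark (40 mV spikes,
0.5 mV noise, 3 ms refractory spacing) recall and precision both exceed
0.95.

## Odor-response statistics

For each cell × odor, spikes are counted in a half-open 500 ms window
starting 150 ms after valve opening (the odor-arrival latency of a
typical delivery system is 150–200 ms), the mean control (mineral-oil)
count is subtracted, and rates are reported as the difference divided by
0.5 s. Significance uses the **exact one-sided two-sample Poisson
test** in its conditional-binomial form: given totals $K_o$ and $K_c$
over equal numbers of trials, $p = P(X \ge K_o)$ for
$X \sim \mathrm{Binomial}(K_o + K_c, 1/2)$ (an exposure ratio handles
unequal trial counts; $K_o = K_c = 0$ gives $p = 1$). P-values are
FDR-adjusted by Benjamini–Hochberg — per cell across that cell's odors,
since the original grouping is not stated and per-cell adjustment is the
conservative reading for per-cell claims — and declared significant at
adjusted $p < 0.01$. Peak firing rates take the maximum over five
consecutive 200 ms windows starting 150 ms after valve opening.

Tuning sharpness is **lifetime sparseness**

$$S \;=\; \frac{1 - \left(\sum_i r_i / n\right)^2 \big/
  \left(\sum_i r_i^2 / n\right)}{1 - 1/n},$$

0 for uniform tuning and 1 for a single-odor response. The statistic is
undefined for negative rates, so control-subtracted responses are
rectified at zero first (configurable); an all-zero vector is defined
as 0. Whether the original computation used raw or baseline-subtracted
rates is not stated; we expose the choice and default to rectified
control-subtracted rates.

## Subthreshold responses and the pseudo-response null

The subthreshold response of a trial is the peak of the 45 ms
boxcar-smoothed membrane potential in a window +200 to +800 ms after
valve opening, minus the mean over the preceding second. Significance
comes from a **permutation test against pseudo responses**: the same
measurement applied to windows shifted into the pre-stimulus period of
every trace available for the cell. We tile two pseudo blocks per trace
at −1.8 s strides, so each (baseline + window) block is disjoint from
the real one and from the others — under the null all real and pseudo
responses are then exchangeable, and the test is exact. With the
standard four trials this gives $\binom{12}{4} = 495$ assignments and a
p-value floor of about 0.002, small enough to clear the FDR 0.01
threshold; a single pseudo window per trace would bottom out at ~0.014
and could never be declared significant. The two-sample statistic is
the **difference in means** (magnitude-sensitive, unlike a rank test),
enumerated exactly up to $10^5$ assignments and estimated by seeded
Monte Carlo (with the observed assignment counted in numerator and
denominator) beyond that. The same `group_comparison_test` serves for
between-genotype comparisons of response magnitudes.

The generator's default stimulus onset is 5.0 s into the trace: late
enough to fit the two tiled pseudo blocks (4.6 s of pre-stimulus
baseline) with margin.

## Glomerular stimulation and latency

Direct stimulation introduces a sustained artifact of roughly 1 mV per
stimulation volt. We model it as a constant in-window offset linear in
voltage, fit the gain per cell from control-glomerulus trials (last
100 ms plateau minus pre-onset baseline, averaged over trials) and
subtract it; the <2 ms transient edges are flagged in a mask rather
than modelled, and masked samples are excluded from window means. The
evoked depolarization is the artifact-corrected window mean minus the
500 ms pre-onset baseline.

Latency estimation boxcar-filters all traces at a 2.2 kHz-equivalent
cutoff (moving average with −3 dB point nearest 2.2 kHz — 3 taps at
11.1 kHz), normalizes each trace by its own mean over the first 0.5 ms
after onset, bins at 0.5 ms, and compares per-trial bin means between
test and control stimulation with a one-tailed Wilcoxon rank-sum test
per bin (exact for small samples). The latency is the start of the
earliest bin from which *every* later bin through the end of the pulse
stays below `alpha` — a persistence rule that rejects single-bin
flukes; with no such bin the estimate is `NA`. Whether the original
rule pooled samples or used per-trial bin means is unstated; per-trial
bin means treat trials as the independent replicates, which matches the
test's assumptions. With three trials per side the smallest achievable
one-tailed p is exactly 0.05, so the strict `p < 0.05` rule needs at
least four; the generator defaults to six.

## What the generators emulate — and what they do not

`simulate_skeleton_population` builds rooted trees with a soma, an axon
chain toward a (possibly shared) target, and a dendritic arbour of
radiating branches whose node cloud is centred on a group-specific
location, with isotropic Gaussian jitter (default 2 μm) — the geometry
that makes group membership readable from dendritic placement, as in
sexually dimorphic cell classes. It does not emulate realistic arbour
tortuosity, tapering, tracing errors, or registration distortion, so
perfect cluster recovery here shows the score separates displaced
arbours, not that it resolves subtle within-region differences.

`simulate_trialset` builds traces as baseline + Gaussian noise +
difference-of-exponentials EPSP (τ_rise 5 ms, τ_decay 40 ms, onset one
150–200 ms odor latency after valve opening) + triangular 2 ms spike
waveforms at inhomogeneous-Poisson times (background default 2 Hz,
odor-window default 40 Hz). By default spiking is exactly Poisson so
window counts are Poisson-distributed (verified by a χ² goodness-of-fit
property); an optional absolute refractory period spaces spikes for
detector benchmarking. Real membrane noise is not white, spike shapes
vary, and inhibition is absent — the calibration results bound the
pipeline's behaviour under its own assumptions, not under all
biological conditions.

`simulate_stimulation_pair` uses a saturating rise-to-plateau EPSP
(τ_rise 1 ms; plateau through the pulse; exponential decay after)
rather than the transient odor kernel, because stimulation-evoked
depolarizations are sustained for the pulse and the persistence rule
requires a response that lasts through the stimulation period.

All generators are pure functions of their specification and seed.

## Numerical choices and degenerate inputs

* Equidistant nearest neighbours break ties to the lowest target index.
* The binomial kernel's band→length mapping (above) is a documented
  convention; the original mapping is not derivable from the text.
* `poisson_response_test` with no spikes at all returns 1; the
  permutation test on zero-variance data returns 1.
* BH adjustment is `stats::p.adjust(method = "BH")` (the tests verify it
  against a hand-coded step-up); it is monotone and
  permutation-equivariant but not idempotent, and no such property is
  relied on.
* The ~5.5 mV depolarization level above which cells in this class
  reliably spike is an empirical observation, available as an annotation
  constant only — nothing in the package infers it.

## Problem sizes in the test suite

The suite exercises the acceptance-level properties at sizes chosen to
be statistically meaningful on a single CPU: oracle equivalence on
clouds up to $10^3$ points and exhaustive Poisson-test agreement for all
totals ≤ 50; cluster recovery over 20 seeded two-group populations
(ARI = 1 in all of them); detector recall/precision over 50 seeded
trials; latency recovery over 100 seeded pairs (≥ 90% within one bin at
SNR 10); Poisson+BH type-I error over 2000 null cells (≤ 0.015);
subthreshold null rejection over 500 seeded simulations (within
0.03–0.07 at α = 0.05); and power over 100 seeded 40 Hz vs 2 Hz cells
(≥ 0.95).

## Known limitations

* Registration itself is out of scope: skeletons are assumed to share a
  template space, and mismatched `space_tag`s only warn.
* The score has no size normalization beyond the per-point mean, so a
  small query contained in a large target can score high while the
  reverse direction scores low; the asymmetry is intentional and the
  symmetrization choice is explicit.
* Inhibitory (suppressive) odor responses are not tested for — the
  response test is one-sided by design.
* The latency rule inherits the discreteness of its 0.5 ms bins; its
  estimates are lower-edge bin times.
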