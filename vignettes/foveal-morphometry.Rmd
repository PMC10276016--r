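---
title: "Foveal morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foveal morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fovmorph)
```

This vignette is the package's own account of what it computes and why
the open design questions were settled the way they were. The package has
two halves: a *measurement* half that turns boundary annotations on a
macular B-scan into the six foveal parameters, and a *simulation* half
that generates cohorts and scans calibrated to published group summary
statistics so the measurement half can be validated end to end.

## The measurement model

A B-scan is a raster of A-scans (columns) with axial pixel 0 at the
vitreous. Boundary annotations give, per A-scan, the axial position of
ILM, GCL+ inner/outer, ONL inner/outer, IS/OS and the posterior RPE.
All thickness quantities are boundary separations times the axial scale
(default 2000/1024 ≈ 1.95 µm/px axially, 6000/512 ≈ 11.72 µm/px
laterally, the macular-cube convention).

**Flattening.** Scans are flattened to the posterior RPE before any
landmark detection, as tilt and curvature otherwise bias the IS/OS
elevation signal. We shift each A-scan by an *integer* pixel offset that
brings its (half-up-rounded) RPE row to the rounded median RPE row. Two
consequences are load-bearing: every pairwise boundary separation — and
hence every thickness — is preserved *bit-exactly*, and the operation is
idempotent (the half-up rounding makes the fixed-point argument exact;
banker's rounding would admit oscillating edge cases). The cost is a
sub-pixel residual (< 1 px) in the flattened RPE row, which no
downstream quantity reads.

**Foveal centre (FC).** The FC is the A-scan of maximal IS/OS elevation
above the RPE within ±750 µm of the scan centre. If the elevation range
in the window is below 2 µm — no usable photoreceptor peak — we fall
back to the A-scan of minimum smoothed retinal thickness. Ties break
toward the window centre; an exactly symmetric tie resolves to the
temporal candidate (an arbitrary but documented rule; it is exercised
only by constructed inputs, since real and simulated profiles have
unique maxima).

**Foveal wall maxima (FWM).** On each side of the FC, the rim is the
A-scan where the *smoothed* GCL+ thickness is maximal, searched between
300 and 3000 µm from the FC. The lower bound excludes the centre itself
in immature eyes whose central GCL+ is substantial; the upper bound
keeps the search inside a 6 mm scan. Ties break toward the FC; tied
plateaus and window-edge maxima are flagged rather than rejected —
mirroring the human scan-selection step of the original protocol, which
an automated pipeline cannot reproduce, quality decisions are surfaced,
not silently made.

**Parameters.** Point values are always read from the *unsmoothed*
profiles (smoothing exists only to stabilize argmax localization, and
raw reads keep degenerate cases exact — a zero-thickness central GCL+
reads back as exactly 0):

* `GCLp_FC`, `ONL_FC`, `RT_FC`: thicknesses at the FC A-scan;
* `RT_FWM_nasal`, `RT_FWM_temporal`: retinal thickness at the two rims;
* `FD = (RT_FWM_nasal + RT_FWM_temporal)/2 − RT_FC`, an identity that
  holds exactly on every output record;
* `GCLp_Q2Q`: the mean of GCL+ read at the two *quarter points*, each at
  25% of the FC→FWM index distance on its side (rounded to the nearest
  A-scan). The underlying footnote ("temporal quarter to nasal quarter
  distance from FC") admits other readings — e.g. a quarter of the
  rim-to-rim diameter — but those collapse to this one for a pit
  centred between its rims, and this reading needs no second landmark.

The smoothing default (5 A-scans ≈ 59 µm) is the smallest centred window
that suppresses speckle-scale jitter in the argmax without displacing
the rim of a smooth annulus; window 1 disables smoothing entirely.
Moving-average windows shrink symmetrically at the scan edges, so
smoothed profiles are defined everywhere without padding artifacts.

**Laterality.** The A-scan axis runs temporal→nasal for right eyes (OD)
and the reverse for left eyes; profiles carry a signed nasal-positive
lateral axis. Mirroring a scan and toggling OD/OS leaves all six
parameters unchanged (a tested invariant), so pooling both eyes of a
subject is representation-independent.

## The synthetic cohort model

`sample_cohort_metrics()` draws per-eye parameters from a multivariate
normal over five latent variables — `GCLp_FC`, `GCLp_Q2Q`, `ONL_FC`,
`FD` and a residual retinal-thickness component — truncated at zero (for
thicknesses; FD must stay positive for a pit to exist) by resampling
whole eyes. Central retinal thickness is the structural sum

`RT_FC = GCLp_FC + ONL_FC + residual`,

and rim thickness follows from the depth identity
`RT_FWM_mean = RT_FC + FD`, split nasal/temporal by a zero-mean normal
asymmetry (SD 8 µm). Two calibrations ship as defaults
(`cohort_defaults()`): full-term controls and extremely-preterm-no-ROP
eyes, with the published group means and SDs. The structural route was
chosen over drawing `RT_FC` marginally because the tabulated preterm
`RT_FC` SD (4.49 µm) is incompatible with the tabulated range
(192.72–303.95 µm) — an apparent misprint — whereas the implied residual
means (97.11 µm control, 82.62 µm preterm) are internally consistent;
residual SDs of 8 and 10 µm give realistic total-RT spreads.

The default correlation structure approximates the published pattern:
in the preterm group all thickness parameters correlate at 0.7 and
anticorrelate with FD at −0.7 (the coordinated-arrest signature —
algebraically this matrix is `0.3·I + 0.7·ss'` with `s = (1,1,1,−1)`,
hence positive definite); in controls the GCL+ parameters are decoupled
from everything (a mature fovea has essentially no central inner
retina), with GCL+@FC–GCL+@Q2Q at 0.5 and ONL–FD at −0.5. The residual
component is independent in both groups. These are configurable; the
sampler rejects non-positive-semi-definite matrices with the offending
eigenvalue named.

Truncation has a visible side-effect worth knowing: rejecting
negative-GCL+ draws elevates the preterm GCL+ mean by ≈ 2.5 µm and drags
the correlated ONL (+≈3 µm) and FD (−≈3 µm) marginals along. This is the
correct behaviour of a truncated MVN — the published means describe a
cohort that is itself bounded at zero — and the cohort-level quantities
the package is validated against (layer proportions, outside-limit
rates, correlation signs) absorb it comfortably.

**Boundary construction** (`build_boundaries()`) inverts the
morphometry: given one eye's targets it builds profiles whose extraction
reproduces them. The retinal-thickness profile is a *raised-cosine* pit,
`RT(u) = RT_FC + (RT_rim − RT_FC)·sin²(πu/2d)` for centre distance
`u ≤ d` (half-width `d`, default 1000 µm), decaying beyond `2d` to a
peripheral floor. The raised cosine was preferred over a
Gaussian-subtraction pit because it has zero slope at both the centre
and the rim: a landmark detected one A-scan off the true position then
costs O(curvature·Δx²) ≈ 0.01 µm in the read value rather than
O(slope·Δx) ≈ 1 µm, which is what makes the 1 µm round-trip tolerance
comfortable rather than marginal. The GCL+ annulus uses a `sin` (not
`sin²`) ramp from the central value to a rim peak solved from the Q2Q
target — the quarter-point leverage is then `1/sin(π/8) ≈ 2.6`, keeping
implied annulus peaks anatomically plausible, where the `sin²` leverage
of ≈ 6.8 produced infeasible geometry for a noticeable fraction of
sampled eyes. The ONL thins by 25% toward the rim; the residual bands
absorb the remainder, including a Gaussian outer-segment bump (σ 150 µm,
amplitude 12 µm) that creates the IS/OS elevation peak marking the FC.
The pit centre snaps to the nearest A-scan, so landmark reads on
synthetic eyes are grid-exact.

Infeasible targets are rejected with the violated constraint named
(`RT_FC < GCLp_FC + ONL_FC`, non-positive depth, negative residual
bands). One soft case is flagged instead of fatal: a sampled `GCLp_Q2Q`
at or below the central GCL+ (possible for ~5% of control eyes under the
default correlation) admits no rising annulus; the target is floored
just above the central value and `q2q_floor` recorded — Q2Q is a derived
shape parameter, not one of the round-trip-toleranced quantities.

**Rendering** (`render_bscan()`) paints piecewise-constant per-band
reflectivities and multiplies by unit-mean gamma speckle with
coefficient of variation `noise_level` — the standard parameter-light
stand-in for OCT speckle. It deliberately omits the point-spread
function, depth attenuation, vascular shadows and motion artifacts; the
rendered images exist to exercise image-path plumbing (flattening
shifts, export), not to train segmentation.

## What passing tests do and do not show

The synthetic generator realizes *exactly* the geometry the morphometry
assumes: single-minimum pits, single-peak annuli, noise-free boundaries.
Round-trip success therefore validates the internal consistency of the
measurement chain — windowing, tie-breaking, unit conversion, laterality
— and its landmark logic, but says nothing about segmentation quality on
real scans (boundaries are taken as input by design, reflecting the
manual-annotation protocol) nor about anatomies outside the model family
(multi-peak rims, asymmetric pit half-widths, pathology). The normative
and correlation results show the *statistical machinery* reproduces
tail rates and sign structure under the calibrated distributions;
published percentages that depend on the real cohort's empirical
distribution (e.g. the exact proportion of preterm eyes outside each
limit) are reproduced qualitatively (majority-outside), not numerically.

## Numerical choices and degenerate inputs

* Sample SD uses the n−1 denominator; limits are stored at full
  precision and printed one-decimal limits are treated as display
  rounding. Recomputing the reference control limits reproduces all of
  them to one decimal except the ONL limit, where the tabulated value
  (136.9) disagrees with tabulated mean + 2 SD (132.6);
  `verify_limit_consistency()` flags this instead of hard-coding either.
* Classification uses strict exceedance; equality with a limit is
  `within`. A zero-variance control column yields limit = mean with a
  warning, and any strictly larger value classifies outside.
* Outside-proportions carry exact Clopper–Pearson 95% CIs
  (`stats::binom.test`), labelled as such in output.
* Boundary ingestion interpolates interior gaps of ≤ 3 A-scans linearly
  (logged); longer or edge-touching gaps and crossing boundaries are
  rejected naming the A-scan index.
* Statistical tests are two-sided throughout; correlations use
  pairwise-complete observations, group comparisons listwise deletion.
  The summary-statistics Welch test (for reconstructing tabulated
  comparisons) implements the textbook Welch–Satterthwaite formulae and
  is cross-checked in the tests against `t.test` on vectors constructed
  to have the exact moments, and against a permutation test.
* Per-stage seeds are derived from the single pipeline seed by one
  `sample.int` call, so stages can be rerun independently while the
  whole pipeline stays deterministic; CSV outputs are bit-identical
  under a fixed config, figures are regenerable artifacts.

## Problem sizes

The validation suite simulates cohorts of 10,000 eyes for tail-rate and
proportion checks (standard errors ≈ 0.002 on proportions, an order
below the 0.02 acceptance bands), 100 eyes for the round-trip property,
and 20 replicates of n = 37 for the correlation sign pattern at the
published preterm sample size. These sizes make the stochastic checks
decisive at negligible cost; the full suite runs in a few minutes.

## Known limitations

Boundaries in, parameters out: there is no image-based segmentation.
One B-scan per eye; no en-face pit-surface fitting or volumetric
averaging. The normative model is mean ± 2 SD, not percentile- or
age-adjusted, and pools both eyes of preterm subjects without an
inter-eye correlation adjustment (eye ids are kept so a sensitivity
analysis is possible downstream). Rendering is a geometric phantom, not
a physical OCT model.
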