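---
title: "Methods: from two-channel image stacks to acidification times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from two-channel image stacks to acidification times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidtrace)
```

This vignette documents the models, parameter choices and numerical
conventions behind each stage of the pipeline, and what the synthetic
validation does and does not demonstrate about real microscopy data.

## The measurement model

A ratiometric pH microsensor emits in two channels: a pH-sensitive green
band and a pH-insensitive red reference band. Because both dyes sit in
the same probe, the green/red intensity ratio cancels probe-to-probe
brightness differences, illumination drift and focus changes to first
order; pH enters only through the ratio. The pipeline therefore needs,
per frame: where the probes are, what each one's ratio is, and — across
frames — which detection belongs to which probe.

## Detection

Each frame's channels are summed to grayscale. The band-pass filter
subtracts a boxcar smoothing at the object scale from a Gaussian
smoothing at the noise scale, `F = G(s_noise) − B(s_object)`. Both
kernels are normalized to unit sum, so a constant background maps to
exactly zero — the property the relative threshold relies on. Numerical
conventions:

* Gaussian kernel truncated at `3·s_noise`; boxcar of side
  `2·s_object + 1`; both applied separably with reflect padding, which
  avoids spurious maxima at the border (detections within `s_object` of
  the border are still flagged in the `edge` column).
* Local maxima use a 3×3 non-strict maximum filter. Equal-valued
  plateaus (possible in symmetric synthetic renders) keep the first
  pixel in row-major order, making output deterministic.
* A detection must exceed `threshold_lambda · max(F)`; the global
  maximum is additionally required to exceed a small absolute floor so
  that constant images, whose band-pass is zero only up to float
  epsilon, yield no detections.
* Defaults: `s_noise = 1` px, `s_object = 12` px (matching a probe of
  roughly 20–30 px apparent diameter), `threshold_lambda = 0.3`. These
  need retuning for probes of a different apparent size; the band-pass
  scale is the single most influential setting.

Positions are reported at pixel resolution (1-based row/column indices,
the R matrix convention); no sub-pixel refinement is attempted because
every downstream consumer (linking, windowed ratio extraction) operates
at or above the pixel scale.

## Ratio extraction

For a window of half-width `s` around a detection, each channel is
summarized by the intensity-weighted mean of its log-intensity,
`W_C = Σ I_C log I_C / Σ I_C`, and the ratio is `exp(W_G − W_R)`. Bright
probe pixels dominate the weights, so enlarging the window adds mostly
near-zero-weight background — which is why the read is nearly flat in
`s`, unlike the plain summed ratio `Σ I_G / Σ I_R`, which drifts toward
the background ratio as the window grows. The estimator is exactly
invariant under joint rescaling of both channels and exact on
constant-ratio windows; both properties are tested.

Conventions: square windows of side `2s + 1` (the window shape is not
critical at these scales); per-probe reads average the per-scale
estimates over `s = 20..30` px, bracketing the apparent probe size;
zero pixels carry zero weight and intensities are floored at one
quantization unit before the logarithm, so the `I log I` weights vanish
exactly where the logarithm would diverge.

## Calibration

Calibration data are (ratio, nominal pH) pairs from samples of known pH.
Duplicated levels are averaged, pH is smoothed against ratio with
`stats::lowess`, and the smooth is projected onto the nearest monotone
sequence (isotonic projection in the direction of the raw trend), which
guarantees an invertible curve. The ±1σ band is the standard deviation
of support-point residuals.

The smoother span defaults to 0.4. The smoother always runs on
level-averaged support points — typically about seven, one per
calibration sample — so a span of 0.4 keeps each local fit to 2–3
points, enough to follow the sigmoid's shoulders; wide spans flatten
them and can push round-trip errors to ~0.1 pH even on noiseless data.
Queries outside the calibrated ratio support are clamped to the nearest
end and flagged rather than extrapolated, because the sensor saturates
outside its quasi-linear segment and extrapolated pH values there would
be meaningless.

## Tracking

Frame-to-frame linking is a linear assignment problem on the
`(n+m) × (n+m)` four-block matrix: Euclidean link costs `L` (infinite
beyond `max_link_distance`), diagonal death/birth blocks `E` and `S`
with cost `b`, and the auxiliary block `T` carrying cost `c` on the
transposed sparsity pattern of `L`, which guarantees feasibility.
Choices:

* `b = 1.05 × max(finite L)` and `c = min(finite L)`, the usual
  convention for this family of trackers: death/birth is a last resort,
  marginally more expensive than any admissible link.
* Infinite entries become a finite sentinel (10·n times the largest
  cost) so a dense square solver applies; any optimal solution that
  selects a sentinel entry is reported as infeasible.
* The solver is a shortest-augmenting-path assignment algorithm with
  dual potentials (Jonker–Volgenant family) in C++, O(n³), augmenting
  rows in index order so ties resolve deterministically. It is checked
  against exhaustive permutation enumeration in the tests.
* `max_link_distance` defaults to 3× the 99th percentile of
  nearest-neighbour displacements over the first ten frame pairs. The
  inflation matters: for probes moving at a nearly constant speed the
  99th percentile sits *at* the typical displacement, and a threshold
  placed there cuts off true links through quantile interpolation alone.
* Gap closing runs a second LAP over fragments with cost `|Δr|²/Δt` for
  gaps of 1..`max_gap` frames (default 3). Squared displacement over
  elapsed time is the Brownian-consistent weighting: under diffusion,
  `|Δr|²` grows linearly with `Δt`, so the cost compares candidate
  merges on a common footing.
* An optional minimum-image metric supports scenes that live on a
  periodic box (the synthetic validation world).

## Event classification

Each track's reads, order discarded, are summarized by 10 empirical
quantiles at probabilities evenly spaced on [5%, 95%]. Outer and inner
events give monomodal read distributions — tight quantile vectors at
high or low pH — while a caging event's bimodal distribution stretches
its quantiles across both modes. PCA on the quantile matrix is centred
but *not* variance-scaled: all 10 coordinates share pH units, and
scaling would distort the interpretation of the components (PC1 tracks
the mean read level, PC2 the dispersion; signs are fixed to make both
correlations positive). k-means++ with k = 3 (best of 10 seedings by
within-cluster sum of squares, deterministic under a fixed seed)
separates the three groups in the 2-component projection.

Labelling is rule-based: the cluster with the largest mean inter-quantile
spread (Q95 − Q5) is CE; of the rest, the higher mean pH is OE, the
lower IE. If no cluster dominates in spread (largest/second-largest
below 2), the data contain no distinguishable caging class — for
example, an all-outer dataset forced into three clusters — and the
classifier raises an ambiguity error instead of guessing. Tracks
shorter than 20 reads are excluded as "unclassified": 10 quantiles need
reasonable support, and half-minute cadence makes 20 reads only 10
minutes of observation.

## Acidification kinetics

Caging tracks get a least-squares nonincreasing fit by
pool-adjacent-violators (PAVA) — monotone regression replaces the
parametric sigmoid fit, which is brittle when reads fluctuate. For a
remaining-drop fraction λ, `t(λ)` is the earliest frame at which the
fit has completed a fraction `1 − λ` of its total drop, and
`Δτ = t(0.1) − t(0.9)`, the 10%–90% drop time, reported in minutes via
the frame interval (default 30 s). The window is exposed rather than
hard-coded, and narrows `Δτ` monotonically as it closes toward
(0.5, 0.5).

The plateau levels that anchor the drop are medians of the first and
last 10% of the *raw* reads (at least 3 each), not the first/last values
of the isotonic fit. The extreme fitted values are the maximum prefix
mean and minimum suffix mean of the noise around the plateaus, so they
sit systematically outside them by roughly 0.6σ each; anchoring on them
inflates the estimated drop, widens both thresholds outward, and biased
recovered `Δτ` upward by over a minute at σ = 0.05 in simulation.
Terminal-segment medians are unbiased and equally robust to
single-frame outliers. Tracks whose fit shows no drop return no
estimate, flagged as likely misclassifications.

## Synthetic data: what it emulates, and what it does not

The generators exist so every stage has ground truth:

* **Vicsek trajectories** update each heading as the normalized mixture
  `θ(α·θ(v_i) + β·θ(⟨θ(v_j)⟩) + γ·η_i)` over the `k = 6` nearest
  (topological) neighbours, with 2-D standard-normal noise `η` and
  constant speed; positions advance by `speed` per frame. Defaults:
  512 px periodic box, speed 1 px/frame, α = 1, β = 0.5, γ = 0.2. The
  speed is deliberately small against the ~50 px mean spacing at
  N = 100: probes imaged every 30 s move little between frames.
  Determinism is strict: one seed, no global RNG state, bit-identical
  reruns.
* **Renders** draw each probe as a uniform disk convolved with a
  Gaussian point-spread function, identical profiles in both channels
  scaled by the true ratio, plus constant background and additive
  Gaussian noise, clipped to the bit depth. Defaults (radius 8 px,
  PSF σ 4 px) give a peaked, diffraction-dominated profile about
  25–30 px across. A flat-topped profile (blur much smaller than the
  disk) would be unfaithful to microscopy and also ill-posed for
  maximum-based detection: subtracting the boxcar mean from a plateau
  puts the band-pass maxima on a ring around the centre.
* **Archetype pH tracks** are i.i.d. noise around a high (7.2) or low
  (5.4) plateau, or a logistic drop between them centred at
  `drop_time` with scale `drop_duration/4` (so the 10–90% width is
  `log(81)/4 ≈ 1.1` times `drop_duration`;
  `caging_duration_for_tau()` inverts this).
* **Calibration fixtures** render one probe per pH level with the ratio
  set by a user-supplied monotone truth curve.

Not modelled: photon shot noise, bleaching, vignetting, probe shape
heterogeneity, out-of-focus drift, or any cell biology — the synthetic
tracks draw their reads directly from the archetype model rather than
through a rendered image of a moving probe in a cellular environment.
Passing tests on this material therefore demonstrates the correctness
of the algorithms under their stated models, and the tracker's accuracy
under Vicsek-like motion; it does not certify performance on any
particular microscope's noise or on probes far from the size the
detection defaults assume.

## The tracker validation study

`run_validation_study()` scores the tracker on simulated scenes where
identity is known. Design choices:

* Ground-truth positions are fed directly to the tracker, bypassing
  rendering and detection, so the study isolates linking errors; a
  through-images run is available by composing the stages manually.
* Scenes use the model's polar *ordered* phase: headings initialized
  around a common direction (jitter 0.1 rad) and a 20-step burn-in
  before recording. The ordered flock is the model's stationary regime
  and the analogue of slowly drifting probes; a disordered random-heading
  start spends its opening frames in a transient where point particles
  freely pass through each other — trajectories no physical probe can
  realize, since real probes are micron-sized solids that collide or
  deflect rather than overlap. For the same reason initial positions
  keep a hard-core-like exclusion distance of 8 px.
* The box is periodic (the standard convention for this model), and the
  tracker is given the matching minimum-image metric, so a wrap-around
  is an ordinary small displacement rather than an apparent teleport.
* Scoring counts, over consecutive observations in inferred tracks,
  links joining two different true particles (wrong links) and true
  consecutive-frame links reproduced by no track (missed links); the
  error fraction divides their sum by the `N·(T−1)` true links.

Problem sizes: the acceptance-scale study runs N = 100 particles,
100 frames, 20 repetitions (the full protocol of 100 repetitions over
N = 20..160 is available through the same function and the CLI
`validate` subcommand); unit tests use smaller grids. Every repetition
derives its seed from the master seed, so reports are reproducible
run to run.

## Known limitations

* The tracker handles appearance, disappearance and gap closing but not
  merging or splitting of tracks; probes that overlap for many frames
  resolve into a single detection and cannot be disambiguated.
* Classification assumes the three archetypes are all present (k = 3);
  datasets missing a class must lower `k` or expect the ambiguity error.
* The calibration curve is only as good as its support: queries are
  clamped at the calibrated ends, and pH values near the saturation
  regimes of the sigmoid carry little sensitivity (the curve exposes
  its derivative so users can see where the probe is informative).
* `Δτ` is defined on the isotonic fit of a single track; it has no
  meaning for tracks that enter the movie already acidified.
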