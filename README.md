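# acidtrace

Quantifying how fast cells acidify the compartments that engulf
micrometer-sized pH microsensors.

Ratiometric pH probes carry two dyes: a pH-sensitive green emitter (FITC)
and a pH-insensitive red reference (RBITC). The green/red intensity ratio
reports pH independently of probe brightness, so time-lapse two-channel
microscopy of probes around living cells records, per probe, a pH time
series. A probe that stays outside a cell reads the high extracellular pH
for the whole movie; one that was already inside reads the low
endo/lysosomal pH; and the interesting case — a probe captured by a cell
during the recording (a *caging* or uptake event) — reads a sigmoidal pH
drop whose duration is the acidification time of the compartment.

`acidtrace` implements the complete automated analysis chain for such
recordings, plus the synthetic data needed to validate every stage without
any external download:

1. **Detection** — each frame is summed to grayscale, band-pass filtered
   (`F = G(s_noise) − B(s_object)`, a unit-sum Gaussian minus a unit-sum
   boxcar), and probes are the 3×3 local maxima of `F` above a relative
   threshold `λ · max(F)`.
2. **Ratiometry** — per probe the green/red ratio is
   `exp(W_G − W_R)` with `W_C = Σ I_C log I_C / Σ I_C` over a window,
   averaged over window scales 20–30 px. Weighting the log-intensity by
   the intensity itself makes the read nearly scale-independent, unlike
   the legacy `Σ I_G / Σ I_R` (also provided for comparison). A monotone
   LOESS calibration curve fitted to (ratio, known-pH) pairs converts
   ratios to pH over its valid quasi-linear segment.
3. **Tracking** — detections are linked frame to frame by a linear
   assignment problem over a four-block cost matrix (link distances `L`,
   death `E`, birth `S`, auxiliary `T`); gap-free segments are
   concatenated, then a second LAP over track fragments closes gaps of up
   to `max_gap` frames with the Brownian-reference cost `|Δr|²/Δt`.
4. **Event classification** — each track's pH reads are compressed to 10
   quantiles (5%–95%), projected on the first two principal components,
   and clustered with k-means++ (k = 3). The high-spread cluster is the
   caging class CE; the remaining clusters are outer (OE, high mean pH)
   and inner (IE, low mean pH).
5. **Kinetics** — each CE track gets a nonincreasing isotonic fit
   (pool-adjacent-violators); the acidification time is
   `Δτ = t(λ=0.1) − t(λ=0.9)`, the time for the fit to go from 10% to
   90% of its total drop, in minutes.
6. **Synthetic data** — Vicsek self-propelled-particle trajectories
   (inertia α, topological-neighbour imitation β, noise γ), rendered
   two-channel image stacks with known ground truth, archetype pH tracks
   (outer/caging/inner), and calibration fixtures.

## Worked example

Classify a synthetic scene of 30 probes (12 outer, 12 inner, 6 caging
with a 16.3 min drop at 30 s cadence) and estimate acidification times:

```r
library(acidtrace)

tracks <- list()
lab <- c(rep("outer", 12), rep("inner", 12), rep("caging", 6))
for (i in seq_along(lab)) {
  tracks[[i]] <- generate_ph_track(archetype_track_config(
    lab[i], ph_high = 7.2, ph_low = 5.4, noise_sigma = 0.05,
    n_frames = 140, drop_time = 70,
    drop_duration = caging_duration_for_tau(16.3),
    seed = 1000 + i))
}

res <- run_pipeline(pipeline_config(tracks, seed = 1))
table(res$events$label)
#> CE IE OE
#>  6 12 12
attr(res$events, "explained_fraction")
#> [1] 0.9999508
res$summary
#>   cohort n mean       sd median  q25    q75
#> 1    all 6 16.5 1.414214     17 15.5 17.375
```

All 30 events are labelled correctly, the two retained principal
components carry >99% of the embedding variance, and the mean recovered
acidification time (16.5 min) sits within half a minute of the generating
truth. `run_validation_study()` runs the tracker-accuracy study (Vicsek
scenes tracked from ground-truth positions and scored link by link), and
`inst/cli/acidtrace.R` exposes the same stages as shell subcommands
(`simulate`, `render`, `detect`, `track`, `classify`, `kinetics`, `run`,
`validate`).

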