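# stimconsist

Cross-session consistency of intracranial EEG (iEEG) stimulation effects on
band power.

## What it does, and for whom

Direct electrical stimulation through implanted iEEG electrodes is used to
probe the epileptic brain and is a candidate therapeutic neuromodulation
tool. Any therapy presupposes that a stimulation design elicits a similar
electrophysiological response session after session — and that consistency
is exactly what this package measures. It is aimed at electrophysiologists
and methods researchers who have event-locked multichannel recordings with
stimulation logs (or want a faithful synthetic stand-in) and need a tested,
reproducible implementation of the full analysis chain:

1. **Preprocessing** — 1 s pre/post segments around each stimulation trial
   (50 ms buffers), matched baseline pseudo-trials from inter-stimulus
   intervals ≥ 20 s (5 s guards), per-segment detrending, rejection of
   channels with repeated stimulation artifacts, common-average
   re-referencing with the stimulation channels excluded from (but
   re-referenced by) the average.
2. **Spectral effect** — Welch log band power (delta 2–4, theta 4–8, alpha
   8–12, beta 12–25, gamma 25–55 Hz) per segment; the stimulation effect of
   a (channel, band) cell is the signed Wilcoxon signed-rank z statistic
   *U* over paired pre/post log powers,
   `U = (W⁺ − n(n+1)/4) / sqrt(n(n+1)(2n+1)/24 − Σ(t³−t)/48)`,
   positive for a power increase. The same statistic on baseline pairs
   quantifies spontaneous fluctuation.
3. **Consistency** — for a session pair, corresponding cells form points
   (s₁, s₂); consistency is the Fisher-transformed *zero-centred* Pearson
   correlation `r₀ = Σs₁s₂ / √(Σs₁² · Σs₂²)` (cosine similarity, detecting
   proportional agreement S₁ = kS₂ through the origin). The *consistency
   curve* recomputes it while an exclusion circle at the origin grows in
   steps of 0.2 until just before covering 98% of the points; its extreme
   value is the pair's *maximum consistency coefficient*, compared against
   a 95% percentile band built from baseline pairs.
4. **Attribution** — ten session-pair covariates (time difference, baseline
   mean/SD differences, average max/min effect, amplitude mean/difference,
   frequency, stimulation depth relative to the brain surface, task
   difference) explain maximum consistency by OLS, with per-term ANOVA F
   effects bootstrapped over 200 resamples.

A seeded synthetic generator (`generate_session()`,
`generate_session_pair()`, `generate_effect_tables()`) emulates RAM-style
stimulation sessions — 1/f background, trials in groups of three,
band-limited post-stimulation power injections of known magnitude,
artifact channels — so every claim the package makes is testable without
clinical data. Sessions round-trip to disk as EDF + TSV events + JSON
metadata.

## Worked example

Generate a session pair sharing a ×3 theta power injection on three
channels, run both sessions through the pipeline, and summarise their
consistency:

```r
library(stimconsist)

cfg <- generator_config(
  n_channels = 12, n_trials = 60, rng_seed = 42,
  effect_map = data.frame(channel = c("E05", "E06", "E07"),
                          band = "theta", factor = 3),
  cross_session_scale = 1, effect_noise_sd = 0)
pair <- generate_session_pair(cfg)
r1 <- process_session(pair[[1]])
r2 <- process_session(pair[[2]])
r1
#> Processed session S001/ses01: 60 stim pairs, 60 baseline pairs, 0 channel(s) excluded

round(r1$effect$stimulation$U["E05", ], 2)
#> delta theta alpha  beta gamma
#>  3.66  6.32  1.05 -0.85 -0.43

curve <- consistency_curve(effect_pair_points(r1$effect$stimulation,
                                              r2$effect$stimulation))
curve
#> Consistency curve: 60 points, radii 0..8.4 (step 0.2)
#>   max consistency 4.829 at radius 6.0 (n = 3)
```

The injected theta cells saturate U near its n = 60 ceiling (≈ 6.7) while
unstimulated cells fluctuate around 0 like the baseline condition. As the
exclusion circle removes the weak-effect cloud, only the three injected
cells remain and the coefficient rises to 4.83 — far above what baseline
pairs reach — so the pair is (correctly) called consistent. With an empty
`effect_map` the same maximum consistency stays inside the baseline band.

`run_pipeline()` chains everything (generation, processing, curves,
baseline band, exceedance fractions, amplitude/frequency screens,
regression and bootstrap) and writes the tables as CSV plus a seeded
manifest, so a study run is reproducible byte for byte.

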