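---
title: "Methods: band-power stimulation effects and their cross-session consistency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band-power stimulation effects and their cross-session consistency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimconsist)
```

## The problem

Direct electrical stimulation through intracranial EEG (iEEG) electrodes is
used both diagnostically and, increasingly, as a candidate neuromodulation
therapy. A therapy only makes sense if a given stimulation design elicits a
similar electrophysiological response every time it is applied. This package
measures the response as *band-power modulation* — how much spectral power
in the canonical delta/theta/alpha/beta/gamma bands changes from just before
to just after each stimulation train — and then asks how *consistent* that
modulation pattern is between two sessions of the same subject with the same
stimulation site.

The pipeline has four stages: event-locked preprocessing, spectral effect
estimation, consistency analysis for session pairs, and regression-based
attribution of consistency to session-pair covariates. A synthetic session
generator stands in for clinical recordings so that every stage is testable
end to end.

## Preprocessing

For every stimulation trial a 1 s **pre** segment ending 50 ms before
stimulation onset and a 1 s **post** segment starting 50 ms after
stimulation offset are extracted. Baseline fluctuation is measured the same
way from **baseline epochs**: inter-stimulus intervals at least 20 s long,
trimmed by 5 s on each side. Within an epoch, pseudo-trials are laid out in
groups of three to mimic the session's trial timing (pre/post gap equal to
the stimulation duration plus the two 50 ms buffers, start-to-start spacing
equal to the session's median intra-group trial spacing, and never less than
one pseudo-trial footprint so segments cannot overlap), until the number of
baseline pairs matches the number of stimulation pairs. Trials within 10 s
of each other (offset to onset) share a group; we read the grouping interval
as the stimulation-free gap, which is the same convention the baseline-epoch
definition uses.

Each segment is centred and detrended (subtracting the per-channel
least-squares line, an idempotent projection). Channels with repeated
stimulation artifacts are then excluded by two criteria, both computed on
the **raw** segments — the mean-voltage quantities they compare are exactly
what detrending removes, so detection must precede it:

1. the paired t statistic, across trials, of the mean voltage of the first
   half of the post segment against the second half of the pre segment
   exceeds a threshold `t1`, by default the Bonferroni-corrected two-sided
   critical value at family-wise alpha = 0.05 across channels;
2. the second half of the trial-averaged post signal shows a *slow return*:
   its regression slope differs from zero at p < 0.05, its fitted level
   starts displaced from the pre-segment mean by more than `t2_mult = 5`
   pre-segment standard deviations, and the slope points back toward the
   pre-segment mean.

Neither threshold has a canonical published value; both are exposed in
`pipeline_options()`. Criterion 1 deliberately runs at a 5% family-wise
false-positive rate, which the test suite checks by Monte Carlo.

Finally a common-average reference is applied: at each time point the mean
over valid, non-stimulating channels is subtracted from every retained
channel. The anode and cathode are excluded from the average but
re-referenced by it; artifact channels are dropped entirely.

## Spectral effect estimation

Each 1 s segment channel is analysed with Welch's method: window length half
the segment, overlap a quarter of the segment — three Hamming-tapered
windows, giving a 2 Hz frequency grid at the default 500 Hz sampling rate.
The taper is configurable because it shifts absolute levels, but any common
choice cancels in the paired pre/post statistics. Band power is the exact
integral of the piecewise-linear PSD interpolant over each band (edges at
2, 4, 8, 12, 25, 55 Hz; half-open membership so shared edges are
unambiguous; off-grid edges are interpolated so contiguous bands integrate
additively), floored at 1e-12 and natural-log transformed. The log base is a
free choice — it cancels in paired differences — and natural log is used
throughout.

The **effect U** of a (channel, band) cell is the signed z statistic of the
Wilcoxon signed-rank test over the paired pre/post log band powers:
zero differences are discarded (the classical treatment, as in MATLAB's
`signrank`), absolute differences are mid-ranked with the usual tie
correction in the variance, and

$$U = \frac{W^{+} - n(n+1)/4}{\sqrt{n(n+1)(2n+1)/24 - \sum_t (t^3-t)/48}},$$

positive when band power increases. A continuity correction is available
(`continuity = TRUE`; at n = 60 the two versions differ by < 0.06). Cells
with fewer than 10 usable pairs are flagged unusable and excluded
downstream — below that the normal approximation is poor. Applied to the
baseline pseudo-pairs, the same statistic quantifies spontaneous band-power
fluctuation, which is the reference everything else is compared against.

Session summaries compare the *extrema* of U across channels between the
stimulation and baseline conditions: the fraction of sessions whose
stimulation maximum exceeds the upper adjacent value (1.5 x IQR whisker
rule) of the baseline maxima, a paired t test on the per-session
differences, and Cohen's d for paired samples — the natural reading of an
unnamed "effect size" for a paired t test.

## Consistency of a session pair

Pairing the U values of corresponding cells (intersection of valid
channels only) gives points $(s_1, s_2)$. Consistency is the Fisher
transform of the **zero-centred** Pearson correlation

$$r_0 = \frac{\sum_i s_{1i} s_{2i}}{\sqrt{\sum_i s_{1i}^2 \sum_i s_{2i}^2}},$$

i.e. the cosine similarity: it detects proportional agreement through the
origin ($S_1 = k S_2$) rather than agreement up to an arbitrary intercept,
because "no effect" is a meaningful zero here. $r_0$ is clipped to
$\pm(1 - 10^{-10})$ before `atanh`, capping the coefficient at about 11.86;
perfectly collinear sets do occur (by construction in tests, and whenever
only two points survive exclusion).

The **consistency curve** recomputes the coefficient while an exclusion
circle at the origin grows in steps of 0.2, removing weak-effect cells that
would otherwise mask consistency carried by a few responsive channels.
Points exactly on the circle are retained (an arbitrary but fixed
convention). The enlargement stops just before the circle would cover 98%
of the points: every reported radius retains strictly more than 2% of them,
and never fewer than `min_points = 3`. The three-point floor matters: any
two points are almost collinear, so two-point tail radii produce
arbitrarily extreme coefficients that say nothing about consistency — they
would dominate both a pair's maximum and the upper edge of the baseline
band. (Setting `min_points = 2` admits them for degenerate constructions.)
The curve's summary, the **maximum consistency coefficient**,
is the value deviating most from zero; ties go to the smallest radius, which
favours the estimate computed from more data.

Baseline pairs processed identically yield a per-radius 95% two-sided
percentile band (the per-radius reading matches how such bands are drawn;
pooling across radii would mix very different point counts), and the
maximum of its upper bound over radii is the reference for calling a pair's
maximum consistency "above baseline". Three exceedance criteria are
reported per pair: at radius 0, at radius 3, and maximum against the band's
global upper bound.

## Attributing consistency

For each pair, ten covariates are assembled: absolute session start-time
difference; mean absolute per-cell differences of baseline log-power means
and SDs (over both pre and post cells); between-session averages of the
maximum and minimum effect; average stimulation amplitude and absolute
amplitude difference; stimulation frequency (common within a pair by
design); signed stimulation depth; and a 0/1 task-difference indicator.
Stimulation duration is deliberately absent: it co-varies with frequency,
so only frequency enters. Depth is the minimum distance from the
anode-cathode midpoint to the brain-surface point set, negative when the
midpoint falls outside the surface's convex hull; the inside test minimises
the distance to the hull with a pairwise Frank-Wolfe solver, which is exact
to well below a millimetre and adequate for convex-ish cortical hulls and
the spherical synthetic surfaces.

Maximum consistency is regressed on the ten covariates by OLS,
unstandardised (F tests are unaffected by standardisation). The "ANOVA
effect" of a term is its F statistic; with main effects only, every term
has one degree of freedom and the Type II F equals the squared t statistic,
which keeps the statistic order-invariant under covariate correlation and
makes the bootstrap cheap. The model is refitted on 200 bootstrap resamples
of the pairs (rank-deficient resamples are redrawn), and each term's F
distribution is summarised with box-plot statistics. Pearson correlation
between average maximum effect and maximum consistency is reported
alongside, with a matched null control: pairs of independent zero-mean
normal effect tables (SD 1, the scale of the z statistic under the null)
pushed through the identical curve machinery, where the correlation must
vanish.

## The synthetic generator

`generate_session()` emulates what the analysis assumes about a RAM-style
stimulation session, not the biophysics of stimulated cortex:

* background: per-channel $1/f$ pink noise (spectral exponent 1, SD 20 uV)
  plus a low-amplitude 10 Hz oscillator — the minimal model giving Welch
  estimates a realistic spectral slope and non-degenerate band powers;
* schedule: trials in groups of three; intra-group inter-stimulus gaps
  drawn from 4-6 s, between-group gaps from 25-35 s, with one gap forced
  long enough that its trimmed epoch hosts a full group of three baseline
  pseudo-trials (the real inter-trial distributions are not published;
  these are assumptions, exposed as configuration);
* trial count drawn as round(Normal(60, 13.9)) clipped to >= 18, matching
  the printed session-size distribution and minimum-session criterion;
* stimulation parameters constrained to the protocol: 0.25-3.5 mA,
  frequency in {10, 25, 50, 100, 200} Hz, duration 0.5 s or 4.6 s with
  4.6 s implying 50 Hz;
* effects: for each configured (channel, band), the band-passed component
  of the 1 s post window is scaled by sqrt(factor) under 50 ms cosine
  ramps, so band *power* scales by the factor without edge discontinuities
  that would trip artifact detection; the injected factor is recovered
  from the raw signal to within 25%;
* artifacts: configured channels get an additive 500 uV deflection at
  stimulation offset decaying with tau = 0.8 s, which triggers both
  rejection criteria by construction;
* pairs: sessions share geometry and stimulation site; session 2's effect
  map satisfies log f2 = k log f1 + Normal(0, sd). The scaling acts on the
  log power ratio because a multiplicative power factor cannot be
  negative, while the proportionality the consistency coefficient detects
  is signed; k = -1 with zero noise reverses every modulation exactly.

`generate_effect_tables()` bypasses signal processing entirely and draws
paired vectors of i.i.d. Normal(0, sd) "effect" values — the fast null for
calibration and control analyses.

What the generator does *not* emulate: evoked potentials, line noise,
epileptiform transients, non-stationary background state, correlated
channels (beyond what common-average referencing induces), or any
behavioural structure. Passing tests therefore demonstrate that the
*pipeline arithmetic and statistics* behave as specified under the stated
assumptions, not that the method is robust to every pathology of clinical
iEEG.

## Numerical choices and degenerate inputs

* Time convention: seconds from the first sample, half-open intervals;
  sample indices by rounding, so segment boundaries are reproducible.
* EDF persistence uses per-channel physical ranges set to the observed
  min/max (maximising 16-bit resolution); round trips are lossy only at
  quantisation level. The reader/writer is a minimal base-R implementation
  (one record per second, common rate) cross-checked against an
  independent Python reader in the test suite.
* Power floor 1e-12 before the log guards all-zero segments; zero-norm
  effect vectors make $r_0$ undefined and are flagged, not silently zero.
* A paired |U| comparison with constant nonzero differences has a
  divergent t statistic; it is reported capped at 1e3 with a `capped`
  flag.
* Recording edges count as epoch boundaries (with the 5 s guard), so a
  stimulation-free recording still yields baseline data.
* Trials too close to the recording edge are skipped, not zero-padded —
  padding would bias Welch estimates.
* Effect cells below 10 usable pairs are `NA` and excluded from pairing,
  extrema and covariates.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen once: synthetic sessions with
12-16 channels at 500 Hz and 12-60 trials; 50 seeds for the
parameter-recovery Monte Carlo (paired sessions with a x3 theta injection
on three channels against 50 matched null pairs); 101 simulated pairs of
40 x 5 effect tables for the null-correlation control; 100 replicates of
the planted-coefficient regression with 200 bootstrap samples each. The
headline clinical numbers of the motivating study depend on its 165-session
hospital dataset and are not reproducible from synthetic data; what the
package verifies instead is that every statistic is computed correctly
(against independent oracles and closed forms) and that the pipeline
recovers known ground truth planted by the generator.

## Known limitations

* The artifact thresholds `t1`/`t2_mult` are assumptions; real datasets
  may need tuning, and criterion 2's "slow return" is only meaningful when
  trial-averaged noise is small relative to the deflection.
* The convex-hull inside/outside test treats the brain surface as its
  convex hull; deep sulcal geometry is not represented.
* The EDF layer supports continuous recordings with a common sampling rate
  only (no EDF+ annotations, no discontinuous records).
* U's normal approximation is used throughout; exact permutation p-values
  are out of scope because U serves as an effect size, not a test.
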