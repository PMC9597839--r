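---
title: "Quantifying equine lameness from pose-estimation trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying equine lameness from pose-estimation trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equigait)
```

## The problem

Lameness — an asymmetric change of gait, usually from pain — is among the
most common problems in equine practice, yet its detection is largely
subjective and unreliable for subtle cases. Markerless pose estimation
offers an attractive middle ground between the naked eye and
instrumented gait labs: a single phone video of a horse trotting on a
lunging circle, run through a trained network, yields per-frame pixel
coordinates of dozens of anatomical reference points together with a
detection confidence ("likelihood") per point and frame.

`equigait` turns such keypoint trajectories into lameness calls. It
implements three complementary analyses of a trotting horse recorded for
about a minute on the left-hand (CL) and right-hand (CR) circle:

* **Forelimb — head nod.** A forelimb-lame horse unloads the painful leg:
  the head rises during the lame limb's stance and drops onto the sound
  one. We segment strides from the protraction maxima of a forelimb
  marker, average poll height over each limb's stance windows, and call
  the horse lame when the left/right difference (the *nod index*)
  exceeds a calibrated threshold.
* **Hindlimb — stifle.** A lame hindlimb protracts less, shortening that
  side's stride. The horizontal excursion span of the stifle point,
  measured separately on each circle (each circle exposes one body
  side), shrinks on the lame side. The score is
  `DSt = |span(CL) − span(CR)|`.
* **Hindlimb — tuber coxae.** The "hip hike": vertical tuber coxae
  excursion increases on the lame side, giving the analogous score
  `DTcox`. This statistic is retained for completeness; on circle videos
  it performed poorly in clinical validation (sensitivity 33%), mainly
  because left and right tuber coxae can never be seen simultaneously.

## Trimmed excursion statistics

All spans use percentile-band trimming rather than raw minima/maxima.
The values of a coordinate series are ranked; the extreme 5 % at each
end — overwhelmingly marker-placement errors on difficult frames — are
discarded, and the bands from the 90th–95th percentile (maxima) and
5th–10th percentile (minima) are averaged:

```
span = | mean(values in 90–95 band) − mean(values in 5–10 band) |
```

A value at 0-based sorted index `i` of `n` has rank-percentile
`100·(i + 0.5)/n` and belongs to band `[lo, hi)` by half-open
membership. This convention is arbitrary where the band boundary falls
between observations (no universal percentile estimator exists); it was
fixed once, is exactly reproducible by a sort-and-slice oracle, and with
~1700 usable frames per trial the alternatives differ by well under a
hundredth of a pixel. Robustness is the point: adding 4 % gross
outliers (10× the signal) to a 1000-frame sinusoid changes the span by
less than 5 % (tested).

Before any statistic, frames with detection likelihood strictly below
0.60 are marked missing (`filter_by_likelihood()`), never deleted, so
frame indices stay aligned across bodyparts. The 0.60 cut follows the
operating point at which the pose model's evaluation error drops
appreciably while retaining almost all frames.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `likelihood_threshold` | 0.60 | — | network-confidence exclusion cut |
| bands | (90, 95), (5, 10) | percentile | trim 5 % outliers per tail |
| `stifle_threshold` | 1.2 | px | midpoint between the largest ordinary sound score (0.87) and the smallest flagged score (1.23) in the clinical reference tables |
| `tcox_sound_threshold` | 1.0 | px | separates the reference controls' ordinary scores (≤ 0.69) from flagged ones (≥ 1.14) |
| `nod_threshold` | 0.5 | px | calibrated on a seeded sound cohort, see below |
| `expected_rate` | 74 | strides/min | sets minimum peak separation for stride detection |

The two hindlimb thresholds are package-derived operating points read
off the validation tables, not published constants; both are arguments
of `study_config()`. They are in pixels at the 768 × 432 export
resolution and should be rescaled (or recalibrated) for other
resolutions.

### The head-nod threshold

The clinical study assessed forelimb charts visually; a numeric decision
rule is therefore this package's own choice. We use
`|nod_index| > 0.5 px`, the value of `calibrate_nod_threshold()`: three
standard deviations of the *signed* nod index over 20 simulated sound
horses (seed 20221017) under the default recording conditions, 0.4985,
rounded up. Three signed SDs keep the per-circle false-alarm
probability near 0.3 % under an approximately normal null — a horse is
flagged if *either* circle trips, so per-circle rates roughly double. A
rule based on the SD of the *absolute* index would sit near 1.2 signed
SDs and flag over a fifth of sound horses; we considered and rejected
it. The threshold is configurable and should be recalibrated when frame
rate, duration, amplitude scale or noise differ materially from the
defaults.

## Stride segmentation

At trot the beginning of a forelimb's stance coincides with its maximal
protraction, so stance onsets are local maxima of the circle-facing os
carpi accessorium marker's horizontal coordinate. The detector accepts a
frame as an onset when it is the earliest maximiser of a centred window
of half-width half the expected stride period, and at least one lower
value follows within the window — the latter guard rejects a trace that
merely rises into the end of the recording. Missing frames are ignored
inside windows, so likelihood dropouts neither split nor shift peaks.
The contralateral forelimb, hidden behind the horse's body on a circle,
is inferred half a stride period later rather than tracked. The stance
window used for head-height averaging is the first half stride after
each onset; true stance duration is not derivable from single-camera 2D
data, and the half-stride convention keeps the two limbs' windows
complementary.

## The synthetic gait generator

No trajectory data are deposited with the clinical study, so
`simulate_trial()` / `simulate_cohort()` provide the test bed. The model
is deliberately minimal:

* a camera-follow world — the horse stays near frame centre, so
  horizontal keypoint motion encodes protraction/retraction with no net
  drift; coordinates are raw image pixels (y down);
* trot as a two-beat diagonal gait: limb markers are sinusoids at the
  stride frequency (default 74 strides/min, 30 fps, 60 s), diagonal
  pairs in phase, contralateral limbs half a period apart; poll and
  trunk bounce at twice the stride frequency;
* lameness as amplitude/phase perturbations: a forelimb-lame horse gains
  a stride-frequency poll component (gain 4 × `head_amp` per unit
  `grade_effect`) peaking mid-stance of the lame limb; a hindlimb-lame
  horse has its lame-side stifle amplitude shrunk by `(1 − δ)` and
  tuber coxae amplitude grown by `(1 + δ)`;
* noise applied last: Gaussian jitter (default SD 1 px) on every
  coordinate, and likelihood dropouts (default 5 % of frames below the
  0.60 cut, sub-threshold likelihoods Uniform(0, 0.6), confident ones
  Uniform(0.8, 1.0)).

Default amplitudes (stifle 21 px, tuber coxae 6.5 px, poll 15 px, limbs
25 px) were chosen so trimmed spans land in the clinically observed
ranges — stifle spans 30–55 px, tuber coxae spans 8–21 px — for a
centred subject at 768 × 432. For a sinusoid of amplitude A the trimmed
span is ≈ 1.943·A (the band mean of the arcsine value distribution), so
stifle spans sit near 41 px before per-horse scaling. The default
cohort mirrors the validation study: 13 forelimb-lame (7 left/6 right),
9 hindlimb-lame (5 left/4 right), 8 sound; mild cases (AAEP 1–2) get
`grade_effect` 0.05, moderate ones (AAEP 3–4) 0.15 — the study reports
no quantitative per-grade amplitudes, so this mapping is a modelling
choice, and absolute effect sizes in simulations should be read as
illustrative. Per-horse build/cadence variation is Uniform(0.85, 1.15)
amplitude scale and ±3 strides/min.

What the generator does *not* emulate — and hence what green tests do
not certify about real videos: perspective and lens distortion, camera
panning, irregular strides and head shaking, coat/lighting-dependent
error bursts (which are correlated across frames, not i.i.d.),
compensatory multi-limb kinematics, and any walk-gait motion. Passing
recovery tests show the analysis chain is correct under its stated
model, not that the model exhausts equine gait.

## Numerical conventions and degenerate inputs

* Excursion statistics require ≥ 20 usable frames (so every 5 % band is
  non-empty); fewer raise an `insufficient data` error naming the
  bodypart and trial. Fully dropped-out series therefore fail loudly,
  and `run_study()` records such horses under `$failures` instead of
  dropping them silently.
* Circle-difference scores are exact: `score = |span_cl − span_cr|`;
  the implicated side is the smaller-span side for the stifle and the
  larger-span side for the tuber coxae; equal spans give side `"none"`.
* Classification thresholds are strict (`>`): a score exactly at the
  threshold is sound.
* Reported scores, means and percentages round half away from zero
  (`round_half_up()`), matching how the clinical tables print (0.545 →
  0.55); plain `round()` would round half to even. One published NPV
  cell (5/11 → 45.45) appears truncated to 45.4 rather than rounded;
  the package reports 45.5.
* The 3 × 3 agreement table (forelimb / hindlimb / sound) uses
  stifle-based hindlimb predictions only; a lame horse the stifle test
  misses counts as predicted sound, a flagged control as predicted
  hindlimb-lame. Cohen's kappa and overall accuracy are computed from
  that table. The group summaries labelled "median" in the validation
  study's prose are arithmetic means — its own formula defines the mean
  and its printed 0.55 equals the mean, not the median (0.60), of the
  sound group's scores; the package implements the mean.
* Head-nod mirror symmetry (relabel left↔right ⇒ nod index negates) is
  exact for relabelled stance windows and holds to ~5 % between mirrored
  lameness simulations: stance windows are whole frames while the
  symmetric two-beat head bob's period generally is not, leaving a small
  deterministic residual. The calibration cohort includes this residual,
  so the threshold accounts for it.
* Tuber coxae reference-point indices are not fixed by the published
  58-point list available to us; the package maps them to indices 33/34
  by convention, overridable in the YAML bodypart map.

## Problem sizes

Simulated trials are 60 s at 30 fps (1800 frames, 13 bodyparts);
simulated cohorts are 30 horses × 2 circles. The test suite runs
reference-table reanalysis (30 horses), several single trials, and
cohorts of 6–30 horses; the acceptance script re-runs the full 30-horse
design plus a 20-horse sound cohort. These sizes match the validation
study's own scale and keep every statistic's Monte-Carlo error small
relative to the effects probed.

## Worked example

```{r example, eval = FALSE}
library(equigait)

# one hindlimb-lame horse, both circles
lam <- lameness_spec("hindlimb_lame", "left", grade_effect = 0.15)
cl <- simulate_trial(lameness = lam, circle = "CL",
                     noise = noise_spec(seed = 1), horse_id = "demo")
cr <- simulate_trial(lameness = lam, circle = "CR",
                     noise = noise_spec(seed = 2), horse_id = "demo")
analyze_horse(cl, cr)

# the full study design
study <- run_study(simulate_cohort(seed = 1))
study
```

## Known limitations

Single-camera circle videos see one body side per direction, so
left/right comparisons are always across-circle, confounding side with
direction; the tuber coxae statistic suffers most from this and is kept
mainly as a negative control. The pipeline assumes unilateral lameness
at trot; multi-limb lameness, walk analysis, straight-line trials and
ridden horses are out of scope. Pixel thresholds presume the default
export resolution and an approximately constant camera–horse distance.
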