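# equigait

Lameness detection for lunged horses from markerless pose-estimation
trajectories.

Lameness is among the most common problems in equine medicine, and its
assessment is notoriously subjective. Pose estimation (e.g. DeepLabCut)
turns an ordinary phone video of a horse trotting on a lunging circle
into per-frame pixel tracks of anatomical reference points. `equigait`
analyses such tracks — recorded on the left (CL) and right (CR) circle,
about a minute each at trot — and classifies the horse as sound,
forelimb-lame or hindlimb-lame with the affected side, then evaluates
the calls against clinical ground truth.

## Method

Frames with detection likelihood < 0.60 are excluded. Every excursion
statistic uses percentile-band trimming: with the series' values ranked,
the extreme 5 % per tail are discarded and the adjacent 5 % bands are
averaged,

    span = | mean(90–95 percentile band) − mean(5–10 percentile band) |,

which is robust to occasional gross marker misplacements.

* **Forelimb (head nod).** Stance onsets are the protraction maxima of
  the circle-facing forelimb marker; the contralateral limb is half a
  stride later. The nod index is the mean poll height during left-stance
  windows minus right-stance windows; `|nod| > 0.5 px` (calibrated on a
  seeded sound cohort) flags the horse, and the sign names the lame limb
  (head highest during its own stance).
* **Hindlimb (stifle).** Horizontal stifle span per circle (each circle
  sees one body side); `DSt = |span(CL) − span(CR)| > 1.2 px` flags the
  horse, the smaller-span side is lame (shortened stride).
* **Hindlimb (tuber coxae).** Vertical tuber coxae span;
  `DTcox = |span(CL) − span(CR)|`, larger-span side lame ("hip hike").
  Retained as implemented in the validation study, where it performed
  poorly on circle videos.

Cohort evaluation produces per-test 2×2 confusion tables with
sensitivity, specificity, accuracy, PPV and NPV, plus a 3×3
forelimb/hindlimb/sound agreement table with Cohen's kappa and overall
accuracy.

A synthetic trot generator (`simulate_trial()`, `simulate_cohort()`)
emulates the recording conditions — 74 strides/min, 30 fps, 60 s,
likelihood dropouts, controllable lameness asymmetries — so the entire
pipeline is testable without videos. See the vignette
(`vignettes/lameness-analysis.Rmd`) for the model, parameter defaults
and limitations.

## Worked example

```r
library(equigait)

lam <- lameness_spec("hindlimb_lame", "left", grade_effect = 0.15)
cl <- simulate_trial(lameness = lam, circle = "CL",
                     noise = noise_spec(seed = 1), horse_id = "demo")
cr <- simulate_trial(lameness = lam, circle = "CR",
                     noise = noise_spec(seed = 2), horse_id = "demo")
analyze_horse(cl, cr)
#> <horse_analysis> demo: hindlimb_lame (left)
#>   nod_index CL -0.114 / CR 0.063 px; DSt 5.63 px; DTcox 1.82 px
```

The nod indices sit well under the 0.5 px forelimb threshold (no head
nod), while the stifle score of 5.63 px exceeds the 1.2 px threshold and
the smaller stifle span on CL implicates the left hindlimb — the
condition the generator injected.

```r
study <- run_study(simulate_cohort(seed = 1))
study
#> <gait_study> 30 horses analysed
#>
#> Test                TP  FP  FN  TN    SE    SP   ACC   PPV   NPV
#> Forelimb nod        13   0   0   8 100.0 100.0 100.0 100.0 100.0
#> Hindlimb stifle      9   0   0   8 100.0 100.0 100.0 100.0 100.0
#> Hindlimb t. coxae    5   0   4   8  55.6 100.0  76.5 100.0  66.7
#>
#> kappa (3x3, stifle-based) 1.0000, overall accuracy 100.0%
```

Trajectories read and write the DeepLabCut CSV dialect
(`read_dlc_csv()` / `write_dlc_csv()`) with a YAML metadata sidecar and
a configurable YAML bodypart map. A thin command-line front end is
installed as `exec/equigait` (subcommands `simulate`, `analyze`,
`evaluate`).

`clinical_reference_tables()` ships the per-horse spans and verdicts of
a 30-horse clinical validation study; `reference_reanalysis()` re-derives
all of that study's scores, group means, diagnostic metrics and
agreement statistics from the printed span pairs.

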