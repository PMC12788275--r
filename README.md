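# frailtylog

Frailty assessment from smartphone digital lifelogs.

Frailty in community-dwelling older adults is conventionally scored in the
clinic — most rigorously as a deficit-accumulation **Frailty Index (FI)**
built from a comprehensive geriatric assessment. Smartphones offer a way to
observe the same construct ambiently: GPS traces yield a *usual* gait speed
from real-world walking rather than an instructed 6 m walk, the pedometer
yields daily activity volume, an in-app 30-second chair-stand task yields
lower-limb strength, and daily self-reports capture perceived exertion and
subjective health. `frailtylog` implements the full analysis path from those
raw streams to the FI and the statistical models that relate the two. It is
aimed at digital-phenotyping and geriatrics researchers who want a tested,
reproducible reference implementation of this pipeline, together with a
synthetic cohort generator that makes every stage verifiable against known
ground truth.

## What the package computes

**Usual gait speed from labeled GPS logs.** Points labeled `WALKING` are
clustered at temporal gaps ≤ 300 s, clusters with < 100 points are dropped,
instantaneous speeds are computed between consecutive points as haversine
great-circle distance (Earth radius 6,371,000 m) over the time gap, speeds
outside [0.3, 2.0] m/s are eliminated, clusters lasting < 10 min or with
radii < 100 m are excluded, an optional polygon mask removes clusters in
unsuitable environments, the surviving speeds are smoothed with a 50-point
trailing moving average, and their pooled mean is the usual gait speed.

**Frailty Index.** A 50-item registry (21 chronic conditions, ADL, IADL,
Nagi and Rosow–Breslau items, weight loss > 4.5 kg, BMI ≤ 18.5 kg/m², low
skeletal muscle mass, Mini-Cog graded 5→0 / 4→0.3 / 1–3→0.7 / 0→1, graded
gait-speed, chair-stand and balance performance, sex-specific grip
cutoffs). The score is

    FI = (sum of non-missing deficit values) / (number of non-missing items)

so missing items shrink the denominator rather than counting as healthy.

**Statistical suite.** Pearson correlations with Fisher *z* confidence
intervals; hierarchical OLS with the R²-change F test

    F_change = (ΔR² / Δk) / ((1 − R²₂) / (n − k₂ − 1)),

standardized slopes β and variance inflation factors; Huber M-estimation
(tuning 1.345, MAD scale) as a robust re-fit; and seeded 5-fold
cross-validated out-of-sample R². A sensitivity plan re-estimates the
hierarchy without daily steps, without gait speed, and with each lifelog
entered alone.

**Synthetic cohort.** A latent frailty factor drives all 50 deficit items
(probit item model, noise calibrated so the FI dispersion matches a
community cohort), the behavioural truths (Gaussian-copula links whose
loadings are calibrated so the planted FI–feature correlations are attained
exactly), clinical covariates, and per-feature availability. The GPS
simulator emits walking bouts at the participant's true speed along
great-circle tracks with temporally correlated (first-order Gauss–Markov)
positional noise, plus vehicle and stationary segments and activity-label
errors.

## Worked example

```r
library(frailtylog)

cfg <- cohort_config(n_participants = 300, seed = 42)  # two-week cohort
run <- run_pipeline(cfg)
print(run)
```

The correlation table this prints (abridged):

```
== FI x digital lifelog correlations ==
Feature                          n        r          p             95% CI
Usual gait speed (m/s)         100   -0.371 ***  0.000146 [-0.529, -0.188]
30 s STS counts                259   -0.303 ***  6.86e-07 [-0.409, -0.188]
Daily mean steps               291   -0.115    0.0502 [-0.227,  0.000]
Hourly mean steps              291   -0.102     0.081 [-0.215,  0.013]
RPE                            240    0.111    0.0874 [-0.016,  0.234]
Subjective health status       258    0.208 ***  0.000771 [ 0.088,  0.322]

== Hierarchical regression (FI ~ covariates, + lifelogs) ==
Step 1: R^2 = 0.199, F(7, 47) = 1.67
Step 2: R^2 = 0.440, F(12, 42) = 2.75 **
dR^2 = 0.241, F-change(5, 42) = 3.61 **
```

Reading it: each row correlates the Frailty Index with one lifelog feature
over the participants for whom that feature could be measured (`n` varies
because GPS-derived gait speed is only available for about a third of the
cohort). The planted generative correlation for gait speed is −0.370 and
the pipeline — raw GPS through clustering, banding, QC and smoothing —
recovers −0.371. Slower gait, fewer chair-stands and fewer steps all
associate with higher frailty; worse self-rated health (coded 1 = very
good … 4 = very bad) associates positively. The hierarchical block shows
that the five lifelog predictors add explanatory variance beyond the
clinical covariates (ΔR² = 0.241 on this cohort's 55 complete cases).

Individual stages are available directly:

```r
truths <- generate_cohort(cfg)
p      <- truths[truths$gait_available, ][1, ]   # first participant with GPS
gait_speed_pipeline(simulate_gps_log(p, cfg))
#> Usual gait speed: 1.278 m/s (33 clusters, 27780 speed samples)
p$true_gait_speed
#> [1] 1.241501

map_mini_cog(c(5, 4, 2, 0))
#> [1] 0.0 0.3 0.7 1.0
```

A command-line wrapper with `simulate`, `gait` and `analyze` subcommands is
in `inst/scripts/frailtylog-cli.R`.

## Limitations

The synthetic cohort is a single-latent-factor model: it reproduces the
marginal distributions, availability pattern and FI–feature correlation
structure of a two-week community lifelogging study, but not multi-domain
frailty, informative missingness, or real GPS artefacts such as multipath
in urban canyons. The methods vignette (`vignettes/frailtylog-methods.Rmd`)
discusses what passing the test suite does and does not establish about
real data.
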