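---
title: "Methods: lifelog-based frailty assessment and its synthetic validation cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifelog-based frailty assessment and its synthetic validation cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(frailtylog)
```

`frailtylog` turns raw smartphone lifelog streams — labeled GPS positions,
pedometer records, a 30-second chair-stand accelerometer trace, and daily
ordinal self-reports — into per-participant predictors, scores a
deficit-accumulation Frailty Index (FI), and fits the statistical models
that relate the two. Because cohort data of this kind are rarely shareable,
the package also contains a synthetic cohort generator with fully known
ground truth; this vignette explains the modelling choices in both halves,
what the generator does and does not emulate, and the numerical conventions
used throughout.

## 1. The Frailty Index

The FI follows the deficit-accumulation model: each of a fixed registry of
health deficits contributes a value in $[0,1]$, and

$$\mathrm{FI} \;=\; \frac{\sum_{i \in \text{observed}} d_i}{\#\{\text{observed items}\}},$$

so a missing item shrinks the denominator instead of counting as healthy.
The default registry has 50 items: 21 chronic conditions, 6 ADL (Katz) and
8 IADL (Lawton–Brody) items, 4 Nagi disablement and 3 Rosow–Breslau
mobility items, three anthropometric thresholds (weight loss > 4.5 kg in
the past year; BMI ≤ 18.5 kg/m²; low skeletal muscle mass), the Mini-Cog
screen graded 5→0, 4→0.3, 1–3→0.7, 0→1, and four physical-performance
items (graded gait speed and chair-stand time, sex-specific grip cutoffs,
graded balance). The item-by-item composition of 50-item CGA-based indices
is not standardized across studies, so the registry is configuration: every
item, level set and prevalence can be replaced.

Numerical conventions: grading cutpoints resolve ties to the *less frail*
side (a gait speed of exactly 1.0 m/s scores 0), matching the strict
"below / over" reading of the threshold items; grip cutoffs default to
< 28 kg (men) / < 18 kg (women), common Asian sarcopenia working-group
values; the skeletal-muscle-mass cutoff defaults to the sex-specific lowest
quintile of the input cohort because no absolute threshold is standard.
Chair-stand grading defaults use battery-style bands on completion time
(11.2 s / 16.7 s) rather than the implausibly fast ~3.7 s five-repetition
times sometimes reported for this population, which appear to reflect a
different timing convention.

## 2. GPS usual gait speed

The pipeline order is fixed: Walking-label filter → temporal clustering →
haversine speeds → physiological band → duration/radius QC → environment
mask → smoothing → pooled mean.

* Only points labeled exactly `WALKING` are retained; `ON_FOOT` is an
  umbrella label that includes running and is not trusted.
* Clusters are maximal runs with inter-point gaps ≤ 300 s; runs with fewer
  than 100 points are discarded. All thresholds are inclusive: a gap of
  exactly 300 s joins, a cluster of exactly 100 points / 600 s / 100 m
  survives, speeds of exactly 0.3 or 2.0 m/s are kept.
* Instantaneous speed between consecutive points is the haversine
  great-circle distance (Earth radius 6,371,000 m) over the time gap.
  Consecutive points with identical timestamps are degenerate; the pair is
  dropped and logged rather than failing the cluster.
* The speed band $[0.3, 2.0]$ m/s removes stationary jitter and vehicle
  contamination. The band is applied before duration/radius QC, and the QC
  duration is the time span of the *original* cluster, not of the
  band-surviving pairs.
* Cluster radius is the maximum great-circle distance from the unweighted
  coordinate centroid — the simplest rotation-invariant definition; a
  bounding-circle radius would differ by at most a factor ~1.15 on convex
  tracks and the QC outcome is insensitive to the choice at the 100 m
  threshold.
* Manual map-based environment verification is replaced by a reproducible
  polygon mask: a cluster is dropped when more than 50% of its points fall
  inside any mask polygon (GeoJSON outer rings; holes are ignored).
* Smoothing is a trailing (causal) 50-point moving average with partial
  windows at the start, so output length equals input length and the
  operation is trivially oracle-checkable.
* The usual gait speed is the mean over all smoothed samples pooled across
  valid clusters, each sample weighted equally; a participant with no
  valid cluster has an absent (not zero) gait speed.

Whether speeds should be recomputed after QC or reused from before is
ambiguous in practice; since the duration/radius QC does not alter point
sequences, the two readings coincide here by construction.

## 3. Lifelog features

*Daily mean steps* sums steps per local calendar day (configurable UTC
offset, default +09:00) and averages over days with at least one record;
a worn-but-inactive day counts as zero. *Hourly mean steps* averages over
**active hours** — clock hours with at least one step. This convention is
forced by internal consistency of reported cohort magnitudes: daily means
around 3,300 steps with hourly means around 760 imply ~4.4 active hours
per day, which division by 24 cannot produce. The two definitions satisfy
the exact identity
`hourly_mean × (active hours / recorded day) = daily_mean`,
which the test suite asserts.

*Chair-stand counting* de-means the vertical acceleration, smooths with a
0.5 s trailing mean, and counts peaks with topographic prominence ≥ 0.5
m/s² separated by ≥ 1.0 s (taller peaks win). The separation is enforced
with 10% slack because a 30-repetition trace has cycles at exactly the
1.0 s limit and noise jitters peak positions; without the slack such traces
are undercounted. All counting parameters are configuration — no standard
algorithm exists for this task.

*Self-reports*: RPE is a 15-point ordinal scale (1–15), subjective health
a 4-point scale coded 1 = very good … 4 = very bad, so larger values mean
worse self-rated health and correlate positively with the FI. Period means
over reported days are used (rather than last observations), and values
off the ordinal supports are validation errors.

## 4. Statistical suite

Correlations are product-moment with $p$ from the $t$ transform
($n-2$ df) and confidence intervals from Fisher's $z$ with standard error
$1/\sqrt{n-3}$ and the exact normal quantile (1.959964…, not 1.96 — the
published intervals this mirrors reproduce only with the exact quantile).
Analysis samples are defined by listwise deletion, which the printed
degrees of freedom of this study design imply; standardized slopes are
computed by z-scoring outcome and predictors on the analysis sample; sex is
coded 1 = female, 0 = male. VIFs come from auxiliary regressions of each
predictor on the others (tested against the inverse-correlation-matrix
identity). The R²-change test is

$$F_{\text{change}} = \frac{\Delta R^2/\Delta k}{(1-R^2_2)/(n-k_2-1)}
\quad \text{on } (\Delta k,\; n-k_2-1) \text{ df},$$

verified against the residual-sum-of-squares formulation to $10^{-10}$.
Step-2 additions lying in the step-1 column span are tolerated: the
increment is zero, not an error.

The Huber fit is iteratively reweighted least squares with tuning constant
1.345, scale re-estimated each iteration as the center-zero MAD of the
residuals ($\mathrm{median}|r|/0.6745$ — the regression convention, which
matches `MASS::rlm`), convergence tolerance $10^{-8}$, and a 500-iteration
cap. An exact fit (scale below $10^{-10}$) short-circuits to OLS. The
robust "R²" is the squared correlation between fitted and observed values
(no canonical robust R² exists), and the joint slope test is a Wald χ².
Cross-validation uses a seeded uniform shuffle into 5 folds without
stratification; out-of-fold R² is $1-\mathrm{SS}_{res}/\mathrm{SS}_{tot}$
about the held-out mean and can legitimately be negative.

## 5. The synthetic cohort

A standard-normal latent frailty factor $Z$ drives everything:

* **Deficit items** follow a probit item model: item $i$ takes the level
  whose threshold band contains $Z + s\,\varepsilon_i$, thresholds placed
  to reproduce each item's marginal prevalence (taken from published
  community-cohort domain frequencies; the implied mean FI is ≈ 0.091).
  The single item-noise scale $s$ is calibrated by quadrature so the
  implied FI standard deviation equals `fi_sd` (default 0.069); the
  calibrated link then implies a latent–FI correlation of about 0.81,
  retrievable via `fi_planted_moments()`.
* **Behavioural truths** (gait speed, chair-stand repetitions, daily
  steps, RPE and subjective-health levels) are Gaussian-copula transforms
  of $\lambda Z + \sqrt{1-\lambda^2}\,\varepsilon$ with marginals matching
  the cohort this emulates: truncated normals, and a lognormal for daily
  steps (mean 3,344, SD 3,049). Effect sizes are specified as the
  **FI-referenced** correlations a cohort exhibits (defaults: gait −0.370,
  chair-stands −0.224, daily steps −0.119, RPE 0.135, subjective health
  0.232). Because the FI is a noisy readout of $Z$ and the marginal
  transforms are nonlinear, the loading $\lambda$ is obtained by inverting
  the exact Hermite-polynomial expansion
  $\mathrm{Cov}(X, \mathrm{FI}) = \sum_k a_k b_k \lambda^k$ rather than a
  linear approximation (which biases the skewed steps marginal by ~0.06).
  The latent–feature correlation is consequently larger than the
  FI-referenced target (≈ −0.46 for gait). Hourly steps are not
  independently planted; their association emerges from daily steps
  divided among ~4.4 active hours.
* **GPS logs** contain walking bouts (piecewise-straight great-circle
  tracks at the participant's true speed, new bearing every 60 s),
  in-vehicle segments at 12 m/s, and stationary segments, each in its own
  clock hour so inter-event gaps exceed the clustering threshold.
  Positional error is a first-order Gauss–Markov process with stationary
  sd 5 m per axis and correlation time 300 s. The correlation time
  matters: *white* 5 m noise at 1 Hz would make 1-s displacement magnitudes
  Rice-distributed around ~9 m/s, the speed band would then select an
  essentially speed-independent subsample, and no pipeline of this design
  could recover gait speed — a property of the method worth knowing, and
  the reason consumer-GPS error correlation (atmospheric and multipath
  biases persisting for minutes) is modelled. Setting
  `gps_noise_corr_time = 0` restores white noise for experiments.
  Activity labels are corrupted at `mislabel_rate` in both directions
  (walking points lose the label; vehicle/still points gain it), which the
  band filter and cluster-size rules must — and do — absorb.
* **Pedometer records** use a lognormal day-level multiplier (SD 0.35),
  a Poisson day total with mean `true_daily_steps`, and a bursty
  allocation over ~4.4 active daytime hours; overnight hours carry no
  steps.
* **Chair-stand traces** are 30 s sinusoids with exactly the true number
  of cycles (amplitude 2 m/s², 50 Hz, Gaussian noise).
* **Missingness** is completely at random per feature, with availability
  defaulting to the observed counts of the emulated cohort (94, 253, 290,
  248, 255 of 300); no mechanism beyond MCAR is claimed. Adherence
  parameters (days recorded, diurnal coverage, per-day response
  probability) are free configuration, not study-matched values.
* **Determinism**: each participant × stream pair derives a private RNG
  stream from the cohort seed, so identical (config, seed) pairs give
  byte-identical cohorts, regeneration of any single stream is
  reproducible in isolation, and the caller's RNG state is never
  disturbed.

## 6. What passing the tests shows — and what it does not

The test suite demonstrates: exact recovery of noiseless synthetic walks
(error < 10⁻³ m/s across 0.4–1.9 m/s); recovery within 0.15 m/s under 5 m
correlated GPS noise; threshold compliance of every valid cluster on
corrupted inputs; FI bounds, monotonicity and denominator-adjustment
identities; oracle equivalence of the regression machinery to 10⁻¹⁰; and
recovery of the planted correlation structure — on a default 300-person
cohort the measured FI–gait-speed correlation lands within a few
thousandths of the planted −0.370.

Two honest caveats. First, the generator is a *single-factor* model: all
five lifelogs are noisy readouts of one latent score. Their joint
population R² on the FI is therefore capped at roughly (reliability of the
factor estimate, ≈ 0.3) × (latent–FI reliability, ≈ 0.65) ≈ 0.17, and the
power of the F-change(5, 59) test at 72 complete cases is ≈ 0.80–0.85 —
detection of the lifelog increment at α = 0.05 succeeds in about four of
five replicate cohorts, not more, and this is a property of the effect
sizes and sample size, not of the implementation (a hypothetical truth
equal to an observed F-change of 3.16 yields power 0.85). Real multi-domain
frailty, where different lifelogs tap partly independent deficits, can
support higher joint R² at the same marginal correlations. Second, passing
on synthetic data says nothing about real GPS artefacts (urban-canyon
multipath, indoor capture), informative missingness (sicker participants
plausibly record less), or label quality of real activity-recognition
APIs; the generator's corruption models are simple and unfavourable but
not adversarial.

## 7. Problem sizes and runtime

Default test-suite problem sizes were chosen so the whole suite runs in
well under a minute of CPU: planted-correlation checks at n = 5000 on
truths (no raw streams), full raw-stream pipeline at n = 300 × 14 days
(~20 s), 50 replicate cohorts at n = 72 for the hierarchical-gain
property, 20 seeds each for noise-robustness and robust-regression
dominance, and 1000 simulations for Fisher-interval coverage at n = 94.
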