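---
title: "Comparing RF-ablation stopping rules with surrogate lesion indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing RF-ablation stopping rules with surrogate lesion indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfablate)
```

## The problem

During catheter ablation of atrial arrhythmias, the operator delivers
radiofrequency (RF) energy lesion by lesion and must decide, for each lesion,
when to stop. Three stopping rules are in clinical use:

* **Ablation Index (AI)**: stop when a weighted integral of contact force
  (CF) and power reaches a target, here AI ≥ 400;
* **Lesion Size Index (LSI)**: stop when a saturating function of windowed
  CF, RF current, and time reaches a target, here LSI ≥ 4;
* **Local impedance (LI) drop plateau**: stop when the impedance measured at
  the catheter tip stops falling — operationally, the (local) minimum of the
  filtered LI trace.

AI and LSI belong to different mapping systems and their coefficients are
proprietary, while LI is measured by a third; no system reports all three.
The workflow implemented here compares the RF application duration each rule
would have demanded *on the same lesion*: train per-timepoint regression
models ("surrogates") that predict AI and LSI from trace features, apply
them to LI-guided ablation traces, and compare the three per-lesion
durations with paired nonparametric tests.

Because the original clinical exports are not public and the true index
coefficients are proprietary, the package ships a synthetic-cohort generator
whose ground truth is produced by configurable stand-in formulas. Every
pipeline stage is therefore verifiable by parameter recovery: the generator
knows the answer, and the tests check that the pipeline finds it.

## The index formulas and their stand-in constants

The reference AI implementation is

$$AI(\tau) = K \left( \int_0^{\tau} CF(s)^a \, P(s)^b \, ds \right)^{c},$$

with the cumulative integral evaluated by a cubic-exact composite Simpson
scheme on the uniform grid. The LSI implementation is

$$LSI(\tau) = \left[ b_0\!\left(1 - e^{-F/b_1}\right) +
  b_2\!\left(1 - e^{-I^2/b_3}\right) \right]
  \left[ (1 - b_4) + b_4 \,
  \frac{1 - e^{-\tau/b_5}}{1 - e^{-60/b_5}} \right],$$

where $F$ and $I$ are 6 s trailing-window means of CF (g) and RF current
(mA). The published rendering of this formula is typographically flattened
and admits more than one grouping; the grouping above — a sum of two
saturating terms times a time factor normalised to 1 at 60 s — is adopted as
the canonical reading because it is the only one in which the 60 s term acts
as a normaliser and every factor is dimensionless. The formula is exposed as
a single pluggable expression (`lsi_pointwise()`), so an alternative grouping
can be swapped in. Similarly, the AI rendering is read as "outer exponent on
the integral, scale outside" ($K(\int \cdot)^c$), the nesting used across the
AI literature.

The true coefficients being proprietary, `calibrate_constants()` solves for
the free scales — $K$ given $(a, b, c)$, and $(b_0, b_2)$ jointly given the
shape constants — so that each index crosses its clinical target at a
requested time under constant reference inputs. The package defaults
(`default_metric_constants()`) pin AI = 400 at 7.3 s and LSI = 4 at 19.9 s
at the cohort's typical operating point (CF 18 g, 40 W, 540 mA). Those
crossing times are taken from the published clinical medians of the three
stopping rules, so the synthetic cohort reproduces the qualitative ordering
*AI target before LI plateau before LSI target* **by construction**: this is
a modelling choice that makes the ordering testable, not a discovered fact.

RF current is derived from power and local impedance by the AC analogue of
Ohm's law, $I = \sqrt{P/Z}$ (reported in mA).

## What the synthetic generator emulates — and what it does not

Each lesion's trace is generated as:

* **LI**: exponential drop plus linear rebound,
  $LI(t) = LI_0 - d(1 - e^{-t/\tau_d}) + r\,t + \varepsilon(t)$. This is the
  simplest shape with a guaranteed, tunable interior minimum, located in
  closed form at $t^\ast = \tau_d \log(d / (\tau_d r))$ — the analytic
  oracle for plateau-recovery tests.
* **CF**: mean plus an AR(1)-smoothed wobble (lag-1 coefficient 0.95),
  floored at zero, so 6 s windowed means genuinely differ from instantaneous
  values.
* **Power**: a constant setting (40 W by default).
* **Tip position**: Gaussian wobble around the lesion centre; centres sit at
  equal angles on a ring (radius 18.5 mm, 30 lesions by default, placement
  jitter 0.4 mm), the geometry of an encircling lesion set, which puts the
  median nearest-neighbour interlesion distance near 3.6 mm.
* **Raw sampling** is irregular (uniform jitter on inter-sample gaps) so the
  resampling stage is genuinely exercised. The cohort default is a 50 Hz
  nominal raw rate, which keeps desk-scale simulations fast; signal-level
  recovery tests use the clinical export-like native rate (997 Hz nominal),
  where the LI noise within the 1.5 s filter window is effectively
  independent sample-to-sample.

Per-lesion parameters are drawn by `default_trace_sampler()` with marginals
matched to the published cohort summaries (CF lognormal, median 18 g;
starting LI normal around 147 Ω; asymptotic drop lognormal with median
36 Ω so the *realised* drop at the plateau sits near 20 Ω; plateau times
lognormal around 12 s). Only medians/IQRs of the clinical cohort are
published, so only marginals are matched; the generator makes no claim to
reproduce joint distributions, atrial geometry, catheter stability,
temperature dynamics, or steam pops. Passing tests therefore demonstrate
*pipeline correctness* (the method recovers known ground truth), not
clinical validity on real exports.

Missing LSI durations arise naturally as censoring — lesions whose predicted
LSI never reaches 4 within the trace — which is the package's reading of the
missing-data problem this analysis faces; `inject_missingness()` additionally
produces controlled MCAR/MAR deletion with a truth mask for imputation
recovery tests.

## Trace processing choices

* **Resampling**: linear interpolation of every channel onto a uniform
  997 Hz grid, no extrapolation.
* **LI filter**: centered moving mean, window 1.5 s, sample count forced
  odd. The published description states only that the left edge is trimmed;
  a centered window is chosen (a trailing variant is available via
  `align = "trailing"`). The trimmed region is the first half-window, where
  the filter's support is incomplete; the right edge keeps shrinking-window
  means so a plateau near trace end stays defined.
* **Plateau**: the *global* minimum of the filtered LI (first sample on
  ties). For a drop-then-rebound trace this is exactly the curve's single
  interior local minimum, and it is deterministic; a strict local-minimum
  detector with a prominence threshold is available (`method = "local"`).
  When the minimum falls on the last sample, the trace never rebounded and a
  `no_rebound` flag stands in for the chart reviewer's visual confirmation.
  Note the centered moving mean shifts the minimum of an asymmetric valley
  by $\tau_d \log(\sinh x / x)$ with $x = w/(2\tau_d)$ — about 0.02 s at the
  defaults, far below the filter's half-window.
* **Durations**: first grid sample at or above target, no sub-sample
  interpolation (error ≤ 1 ms at 997 Hz); all three durations are measured
  from the same (trimmed) trace origin, so the paired comparison is
  internally consistent.
* **Start CF** is the mean CF over the first second: a single first sample
  would be noise-dominated, and the published table does not define it.
* **Interlesion distance**: Euclidean distance between mean tip positions,
  1-nearest-neighbour within a procedure ("adjacent" read spatially, as the
  kNN citation implies; a temporal-predecessor variant is available).

## Surrogate models

Training tables hold one row per retained timepoint. Feature sets mirror
each formula's inputs: AI uses elapsed time, CF, the Simpson force–time
integral, and power; LSI uses elapsed time, the 6 s windowed CF and current,
and power. Five families are supported (random forest, gradient boosting,
ridge, lasso, elastic net) behind one interface with exhaustive grid search
scored by 10-fold cross-validated R². Three choices deserve comment:

* **Lesion-grouped splits.** Neighbouring timepoints of one lesion are
  near-duplicates; row-level splits would leak them across partitions and
  inflate metrics. Folds and the 30% holdout are therefore grouped by lesion
  (row-level splits remain available for faithfulness experiments).
* **Quantile transform** of the skewed LSI target: a rank-based monotone map
  to a standard normal, inverted before metrics, implemented in-package as a
  subsampled empirical-quantile map with linear interpolation.
* **Stride-10 downsampling** (about 100 rows per ablation second) keeps the
  200-lesion training table around 5×10⁵ rows and desk-scale runtimes; full
  997 Hz tables are supported.

On the synthetic cohort the surrogates are near-oracles (holdout R² above
0.99), unsurprisingly: the target is a deterministic function of the
features. The value of the exercise is the round trip — surrogate-predicted
time-to-target durations agree with oracle durations to well under half a
second at the median, so duration comparisons downstream are insensitive to
the surrogate stage.

## Cohort statistics

Exclusions drop lesions with delivered RF duration over 30 s or interlesion
distance over 6 mm ("over" strict, boundaries retained; undefined ILDs in
singleton procedures are not excluded). Missing LSI durations are handled by
chained-equations imputation with predictive mean matching (5 sweeps, 5
chains pooled cell-wise), compared against mean/median/kNN completions;
Little's MCAR test (EM-based, chi-square with $\sum_j p_j - p$ degrees of
freedom) screens the missingness mechanism. Little's statistic matches its
nominal chi-square well in the asymptotic regime (the calibration test uses
1000 rows, where the empirical size is ~0.045 at α = 0.05); at a few hundred
rows it is mildly conservative (~0.03), a known finite-sample property of
the test rather than an implementation artefact.

The headline comparison is a Friedman test on within-lesion ranks of the
three durations, then three pairwise Wilcoxon signed-rank tests with
Bonferroni factor 3, exact enumeration when 25 or fewer untied non-zero
differences and the continuity-corrected normal approximation otherwise,
zeros dropped. Effect sizes are $r = Z/\sqrt{n}$, signed by the median
paired difference of (first-listed − second-listed); the published contrasts
print negative $r$ without defining orientation, so the orientation here is
explicit: listing the faster rule first yields a negative $r$.

The end-to-end ordering check runs on oracle index series from the
calibrated constants rather than surrogate predictions: it tests the
engineered duration ordering and the statistical engine, while
surrogate-vs-oracle agreement is established separately by the recovery
check. (The analysis drivers, by contrast, run the full surrogate path the
clinical workflow would use.)

Predictor analyses regress each rule's duration on the five lesion
covariates the comparison reports (mean CF, start CF, LI drop, LI start,
ILD): GAMs with one penalised thin-plate smooth per covariate (basis
dimension 5, REML smoothing) for per-term significance, and a random forest
(500 trees, all covariates candidate at each split — the regression default
of the stack whose importances these mirror) for impurity importances
normalised to sum 1. A cross-validated R² below 0.2 triggers an explicit
low-reliability warning, reproducing the caveat that importances from a
forest that cannot predict rank noise. Under a global null the GAM per-term
p-values are approximately uniform; the test suite checks this with a
Kolmogorov–Smirnov distance below 0.1 over 200 replicates at n = 300, which
sits close to the pure-sampling-noise boundary for 200 replicates and is
run at a fixed seed.

## Problem sizes and determinism

The analysis drivers and tests use 200 training lesions (~5×10⁵
per-timepoint rows at stride 10, mirroring the scale of the original AI
training set) and a 300-lesion LI-guided cohort; Monte-Carlo calibration
checks use 100–500 replicates. These sizes were chosen so the full workflow
runs on a single desktop core in minutes while keeping every statistical
check well-powered. All randomness flows through explicit integer seeds;
identical seeds give bit-identical cohorts, fits, and reports
(single-threaded forests and boosters).

## Known limitations

* The stand-in constants are calibrated, not estimated: absolute index
  values and effect sizes are not comparable to any clinical cohort, only
  the qualitative structure is.
* The LI trace model has one drop and one rebound; double-drop or
  non-monotone-rebound morphologies (catheter dislodgement, intermittent
  contact) are out of scope, as are multi-electrode catheters and
  temperature dynamics.
* Little's test and the imputation sensitivity analysis assume the lesion
  covariates are jointly well-approximated by a multivariate normal after
  the EM step; heavy-tailed covariates would weaken that screen.
* The cohort generator matches published marginals only; correlations among
  covariates arise implicitly from the trace model and are not calibrated.
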