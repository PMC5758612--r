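---
title: "Lateral masking at the preferred retinal locus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lateral masking at the preferred retinal locus: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latmask)
```

## The scientific question

Macular degeneration (MD) destroys central vision; patients adopt a
*preferred retinal locus* (PRL), an eccentric fixation spot, in its place.
Whether the cortex formerly serving the fovea reorganises around the PRL —
spontaneously, or under perceptual-learning training — can be probed
psychophysically with **lateral masking**: contrast sensitivity for a low
contrast Gabor target is modulated by two collinear flanking Gabors. At
short target-to-flanker separations the flankers *suppress* detection
(collinear inhibition, a within-perceptual-field effect); at larger
separations they *facilitate* it. The separation at which suppression turns
into facilitation estimates the size of the perceptual field (PF), the
psychophysical analogue of a receptive field; in normal peripheral vision
at around 4° of eccentricity this border sits near 8 wavelengths of the
carrier. Changes in the strength of inhibition, at fixed PF border, are the
signature of neural plasticity this package is built to quantify.

`latmask` implements the complete measurement and analysis chain as
reusable, tested code: the stimulus model, a simulated forced-choice
observer, the adaptive staircase, the threshold-elevation statistic, the
small-sample nonparametric battery, and a synthetic-cohort generator — plus
the packaged individual threshold tables of a 5-patient / 5-control study
(with a 4 + 3 trained subgroup), so the published group statistics are
recomputed rather than quoted.

## Stimulus model

A display is three Gabor patches (cosine carrier under an isotropic
Gaussian envelope) on a uniform field of mean luminance $L_m$:

$$L(x,y) = L_m\left(1 + c\,e^{-(x^2+y^2)/2\sigma^2}\cos(2\pi f u + \phi)\right)$$

with $u$ the coordinate along the modulation axis. The target sits at the
display centre; flankers sit at $\pm d\lambda$ along the global axis, where
$\lambda = 1/f$ is the carrier wavelength and $d \in \{3, 4, 6, 8\}$.
Collinear flankers share the target's orientation; orthogonal flankers are
rotated 90° and serve as the baseline that controls for spatial
uncertainty. Default geometry: 1024 × 768 pixels at 2.14 arcmin/pixel,
$L_m = 47.6$ cd/m², $f = 1$ cycle/deg.

Choices the display description leaves open, fixed here once:

* **Envelope width** $\sigma = \lambda/2$ (0.5° at 1 cpd), configurable. A
  common value in lateral-masking work; it keeps the three elements
  non-overlapping at the shortest separation (3λ).
* **Carrier phase** $\phi = 0$ (even-symmetric cosine phase), configurable.
* **Pixel mapping**: offsets are computed in degrees and rounded to the
  nearest integer pixel (error ≤ half a pixel); at 1 cpd and 2.14
  arcmin/pixel, 3λ → 84 px.
* **Quantisation** to the display bit depth happens only on PNG export;
  the internal luminance field is continuous.
* **Contrast measurement**: `measure_michelson()` recovers the carrier's
  Michelson contrast from the peak symmetric luminance excursion about the
  mean, $\max|L - L_m|/L_m$. The raw max/min ratio over a windowed region
  under-reads the carrier contrast because the Gaussian envelope attenuates
  the troughs nearest the peak (by $e^{-\lambda^2/8\sigma^2} \approx 0.61$
  at the defaults); the peak-excursion form is exact for cosine phase.

Timing (133 ms intervals, 500 ms ISI) is metadata only: the simulation is
response-level, not frame-level. No gamma/monitor calibration is modelled.

## The simulated observer

Human observers are replaced by a Weibull 2AFC observer,

$$P(\text{correct} \mid c) = \tfrac12 + \left(\tfrac12 - \ell\right)
  \left(1 - e^{-(c/\alpha)^\beta}\right),$$

with guess rate 0.5, slope $\beta = 3$ and lapse rate $\ell = 0.02$ by
default (typical empirical values for contrast detection; both
configurable). The Weibull on linear contrast is standard for this task and
closed-form invertible.

Observers are **parameterised by their 79.37 %-correct contrast** — the
3-down/1-up equilibrium — rather than by $\alpha$ directly, and $\alpha$ is
derived per condition. This makes staircase recovery unbiased by
construction. Condition dependence enters through a
**lateral-interaction profile** $TE(d)$ in log10 units: the collinear
threshold at separation $d$ is the orthogonal threshold times $10^{TE(d)}$,
positive inside the PF (inhibition), negative outside (facilitation). The
profile is piecewise-linear between tabulated separations, and its zero
crossing is reported as the PF border. The shape between 4λ and 6λ is not
constrained by data; group defaults leave $TE(4\lambda)$ near zero for MD.
Profiles are phenomenological: no crowding, fixation instability or
cortical-magnification model stands behind them.

## The 3-down/1-up staircase

Target contrast moves in 0.1 log10 steps: down after three consecutive
correct responses, up after each error; termination after 120 trials or 14
reversals, whichever comes first; threshold = mean of the last 6 reversal
contrasts. The rule equilibrates where down- and up-step rates match,
$p^3 = 0.5$, i.e. at $p = 0.5^{1/3} = 0.7937$ — the "79 % correct" level.

Numerical conventions:

* **Reversal averaging** is done in log10 and exponentiated (the track is
  log-spaced); a linear-mean option exists because "mean of the reversals"
  is ambiguous in common usage.
* **Start contrast** 0.5 (clearly visible), **floor** $10^{-4}$ (keeps log
  arithmetic finite), **ceiling** 1; none of these is data, all are
  configurable.
* The consecutive-correct counter resets on every error *and* on every
  executed down-step; a step fully blocked by the floor/ceiling clamp is
  not a step and cannot log a phantom reversal.
* Fewer than 6 reversals at termination yields an invalid marker plus a
  warning — never a silent number.

`convergence_report()` measures, over seeded replicate staircases, the
estimate distribution and the percent correct across trials after each
run's first reversal. With a lapse-free $\beta = 3$ observer this
post-first-reversal proportion sits at ~80.5 %, bracketing the analytic
79.37 % equilibrium; estimator bias is below 0.02 log10. One caveat worth
knowing: with a nonzero lapse rate, occasional errors during the initial
descent log an early reversal, which places easy high-contrast trials
inside the measurement window and inflates the proportion by ~0.5–1 point.
The convergence checks therefore use the lapse-free observer, while the
bias checks use the default lapsing one; `analysis/01_staircase_validation.R`
prints both.

## Threshold elevation and the statistical battery

For each participant, phase and separation with both orientations measured,

$$TE = \log_{10}\frac{CT_{\text{collinear}}}{CT_{\text{orthogonal}}},$$

positive for inhibition, negative for facilitation; no imputation — a
missing partner is an error naming the cell. Group cells are summarised by
arithmetic mean and sample SD.

The inferential battery mirrors small-sample practice in this field:

* one-sample t-tests of TE against zero per group × separation;
* pooled-variance two-sample t-tests between groups per separation (the
  pooled form is identified by the published df of 8 with two groups of
  five); paired t-tests for pre/post training. All p two-tailed.
* an **aligned rank transform (ART)** factorial analysis: for each effect,
  all other effects (estimated from unweighted cell means; balanced designs
  only, unbalanced input errors out) are subtracted from every response,
  the aligned values are ranked with midranks, and an ANOVA is run on the
  ranks — with subject error strata for within factors, giving the
  split-plot df (F(1,8) between, F(3,24) within/interaction for a 2 × 4
  mixed design with 5 per group).
* the between × within **interaction** uses a repeated-measures aligned-rank
  test: subject means (which absorb all between-subject variation) and
  within-level means are removed, the residual interaction-plus-error
  values are ranked, and the interaction F is read from the within
  stratum. It is implemented for exactly one within and one between
  factor; designs with two within factors expose main effects only and
  *refuse* interaction requests rather than approximate them.
* post-hoc tests on the interaction compare **differences of differences**
  (e.g. group difference at 3λ vs at 8λ) on the interaction-aligned mean
  ranks, against the interaction stratum's error variance, Holm-adjusted
  within the family. Direct pairwise cell comparisons on aligned ranks are
  not meaningful and are not offered.

Type-I calibration of the ART (1000 null mixed designs, 2 × 4, n = 5 per
group) keeps each effect's rejection rate within [0.03, 0.07] at
α = 0.05; the t-tests are verified against longhand formula oracles to
1e-10. Published ART F values are reproduced only approximately (e.g.
interaction F(3,24) = 5.7 here vs 5.39 published): alignment pipelines
differ across implementations in documented, inconsequential ways, so the
suite asserts calibration and significance structure rather than exact F
values.

## Packaged tables and the two reproduction pipelines

The baseline table (10 participants × 2 orientations × 4 separations) and
the training-difference table (7 trained participants × 8 conditions) ship
as CSV fixtures, checksum-verified, with each value also kept as its exact
printed string so transcription fidelity is testable at the string level.

`reproduce_experiment1()` is fully deterministic and recovers the published
pattern: significant TE at exactly {3λ, 6λ, 8λ} in both groups (positive at
3λ, negative beyond), MD mean TE 0.213 at 3λ vs 0.468 in controls, −0.084
at 8λ vs −0.168, and the interaction post-hocs concentrating the group
difference at the short separation.

`reproduce_experiment2()` reconstructs post-training thresholds as baseline
plus printed difference. Three control cells (C1 orthogonal 6λ, C2
collinear 4λ, C2 orthogonal 8λ) reconstruct to negative contrast — the
printed difference exceeds the baseline, so pre-training performance cannot
have equalled the baseline measurement for those cells. The raw
reconstruction is preserved (`threshold_raw`), the cells are reported in
`nonphysical_cells`, and only the ratio statistics use a 0.001 floor, under
a warning. All 16 MD collinear differences are negative (improvement), the
pattern the training analysis turns on; the affected control cells do not
touch it.

## The synthetic cohort: what it emulates, and what it does not

`cohort_spec_from_table()` estimates, at runtime and never hard-coded,
per-group per-separation mean log10 orthogonal thresholds and mean TE, plus
pooled within-cell SDs, from a measured table. `make_cohort()` draws
individual log10 thresholds and TE profiles Normal around those means
(lognormal thresholds: contrasts are positive and the staircase is
log-stepped). `simulate_experiment1()` runs one staircase per observer ×
condition; `simulate_training()` draws per-condition threshold shifts from
group effect sizes estimated from the training table and re-measures both
phases through full staircases. Everything is deterministic under a seed.

The generator reproduces the *statistical structure* the analysis assumes —
group mean profiles, between-subject spread, staircase measurement noise,
training effect sizes — and nothing finer: no session-level learning
curves (effects are drawn per condition, the 12 sessions are metadata), no
fixation instability, no eccentricity gradients, independent draws across
separations. Passing recovery tests therefore certifies the measurement
and analysis chain, not the biology of real cohorts.

Parameter recovery is assessed against the cohort's *realised* drawn TE
values (the observers' true parameters), the quantity a measurement
pipeline can be asked to recover; at 50 observers per group the recovered
group-mean TE is within ±0.03 log10 of it in every group × separation cell
(measured maximum ≈ 0.021). Against the population means the
between-subject draw noise alone (≈ 0.019 SE) would dominate.

## Problem sizes and runtimes

Sizes used throughout were chosen so a full run stays comfortable on a
laptop: 500-run staircase Monte-Carlos, 1000 null datasets for ART
calibration, 50 observers per group (800 staircases) for recovery, the full
test suite in ~25 s. The deterministic reproductions are instantaneous.

## Known limitations

* The ART alignment follows the documented cell-means procedure; exact
  agreement with other implementations' F values is not a goal and not
  claimed.
* The interaction test is deliberately restricted to one within × one
  between factor; richer repeated-measures interactions are refused.
* The observer's lapse parameter is capped at 0.1; the 79.37 % point is
  unreachable for lapse ≥ 0.206 and the derivation errors out there.
* TE profiles interpolate linearly between measured separations; the true
  profile shape between 4λ and 6λ is unconstrained.
* The training model is a pre/post shift; it cannot address questions about
  learning dynamics.
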