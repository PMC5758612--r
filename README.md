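# latmask

Lateral-masking psychophysics for studying cortical plasticity in macular
degeneration (MD): stimulus model, simulated forced-choice observer,
3-down/1-up staircase threshold estimation, the threshold-elevation
statistic, and the small-sample nonparametric analysis battery — together
with packaged individual contrast-threshold tables from a 5-patient /
5-control study and a synthetic-cohort generator, so the entire
measurement-and-analysis chain runs end to end without human data.

## The science in one paragraph

MD patients lose central vision and fixate with a *preferred retinal locus*
(PRL). Contrast sensitivity for a Gabor target flanked by two collinear
Gabors is suppressed when the flankers fall within the *perceptual field*
(short separations, e.g. 3λ of the carrier) and enhanced when they fall
outside it (6–8λ at ~4° eccentricity). Sensitivity changes are quantified
by the threshold-elevation log ratio

    TE = log10(CT_collinear / CT_orthogonal)

(positive = inhibition, negative = facilitation), where thresholds are the
79.4%-correct points of a temporal 2AFC detection task, estimated by a
3-down/1-up staircase (0.1 log-unit steps, 120 trials or 14 reversals, mean
of the last 6 reversals; the rule converges where p³ = 0.5, i.e. p =
0.794). Reduced inhibition at 3λ with an unchanged inhibition/facilitation
border is the signature of cortical plasticity at the PRL; the packaged
tables show exactly that pattern at baseline, and a further reduction in
patients after 12 sessions of collinear training.

## Worked example

```r
library(latmask)

## a simulated observer with inhibition at 3 lambda, measured by staircase
obs <- observer_model(
  orthogonal_threshold = c("3" = 0.2, "8" = 0.2),
  profile = lateral_profile(c("3" = 0.2, "8" = -0.15)),
  psychometric = psychometric_params(beta = 3, lapse = 0.02))

true_threshold(obs, list(orientation = "collinear", separation_lambda = 3))
#> [1] 0.3169786          # 0.2 * 10^0.2

set.seed(1)
res <- measure_threshold(obs, list(orientation = "collinear",
                                   separation_lambda = 3))
res$threshold
#> [1] 0.3154787          # staircase estimate of the 79.4% point
length(res$reversal_contrasts)
#> [1] 14

## the published baseline analysis, recomputed from the packaged table
b <- reproduce_experiment1()
subset(b$group_summary, separation %in% c(3, 8))
#>     group separation     mean_te      sd_te n
#> 1      MD          3  0.21252179 0.15669061 5
#> 4      MD          8 -0.08422634 0.04023646 5
#> 5 control          3  0.46767597 0.17262873 5
#> 8 control          8 -0.16842396 0.11148987 5
subset(b$one_sample, group == "MD" & separation == 3)
#>   group separation        t df          p significant
#> 1    MD          3 3.032812  4 0.03867373        TRUE
```

MD observers show collinear inhibition at 3λ (mean TE 0.213, one-sample
t(4) = 3.03, p = 0.039) but less than controls (0.468), and facilitation at
8λ (−0.084 vs −0.168): reduced suppression inside the perceptual field with
a preserved field border.

## Analysis workflow

The `analysis/` scripts are thin narrative drivers over the package, in
order; each prints what it finds and writes tables under `results/`:

| script | what it does |
|---|---|
| `01_staircase_validation.R` | analytic equilibrium, step-oracle run, Monte-Carlo convergence/bias |
| `02_reproduce_baseline.R`   | full deterministic baseline battery from the packaged table |
| `03_reproduce_training.R`   | post-training reconstruction (baseline + printed difference) and pre/post tests |
| `04_synthetic_cohort.R`     | cohort simulation through the staircase engine; TE-profile recovery |
| `05_stimulus_gallery.R`     | renders the collinear/orthogonal triplets to PNG |

Run any of them from the repository root, e.g.
`Rscript analysis/02_reproduce_baseline.R`.

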