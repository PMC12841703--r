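# preecv

Breech or transverse presentation at term can often be corrected by
external cephalic version (ECV) — a manual transabdominal manoeuvre that
turns the fetus to cephalic presentation and, when it succeeds, removes
the most common indication for a planned cesarean. Success rates vary
widely (roughly 35–86%), so candidate selection and counseling benefit
from a transparent estimate of the chance of success.

`preecv` implements the **PRE-ECV score**, an additive 8-variable points
system (total 0–13) combining clinical and ultrasonographic predictors
assessed immediately before the attempt:

| Factor | Condition | Points |
|---|---|---|
| Parity | multiparous | 2 |
| Fetal presentation | transverse / complete breech / frank breech | 2 / 1 / 0 |
| Non-engagement of presenting part | yes | 2 |
| Palpable fetal head | yes | 2 |
| Estimated fetal weight | ≥ 10th percentile | 1 |
| Maximum vertical pocket | ≥ 4 cm | 1 |
| Placental location | posterior wall | 1 |
| Tocolysis before the attempt | yes | 2 |

Around the score, the package provides the full internal-validation
toolkit used for point-based clinical prediction models:

* the univariable logistic mapping from score to success probability,
  `logit P(success) = α + β·score`, fitted by Newton–Raphson with typed
  degenerate-outcome and separation errors;
* discrimination: Mann–Whitney AUC with DeLong variance and Wald or
  bootstrap-percentile confidence intervals;
* calibration: logistic recalibration (calibration-in-the-large intercept
  via an offset model, calibration slope), equal-count decile bins, and a
  LOESS-smoothed calibration curve;
* bootstrap optimism correction (Harrell internal validation) of AUC,
  calibration intercept and calibration slope;
* clinical utility: decision-curve analysis (net benefit vs. treat-all /
  treat-none), Youden-index cutoff selection, confusion-matrix metrics and
  prespecified score strata (0–4, 5–8, ≥ 9) with Wilson intervals;
* a deterministic 100-patient fixture cohort reconstructed from published
  marginal counts, and a Gaussian-copula synthetic-cohort generator so
  every analysis is exercisable without patient-level data.

Everything is tibble-in / tibble-out: analysis functions take a cohort
data frame first, return tibbles, and fitted objects support broom-style
`tidy()` / `glance()`. `plot_roc()`, `plot_calibration()`,
`plot_decision_curve()` and `plot_strata()` give ggplot2 views.

## Worked example

```r
library(preecv)

cohort <- ecv_fixture_cohort()        # 100 attempts, 69 successful
fit <- fit_score_model(cohort)        # logistic: success ~ score
fit
#> Logistic score-to-probability model (n = 100)
#>   logit P(success) = 0.2631 + 0.0794 * score
#>   SEs: intercept 0.4459, slope 0.0592; logLik -60.998; 5 Newton iterations

round(predict_prob(fit, c(0, 4, 9, 13)), 3)
#> [1] 0.565 0.641 0.727 0.785

opt <- optimism_correct(cohort, n_resamples = 2000, seed = 1)
tidy(opt)
#> # A tibble: 3 × 8
#>   metric         apparent mean_optimism corrected conf.low conf.high ...
#> 1 auc            6.19e- 1       0.0201    0.599      0.380     0.619
#> 2 cal_intercept -3.95e-10       0.00640  -0.00640   -0.457     0.417
#> 3 cal_slope      1.00e+ 0      -0.0706    1.07      -4.82      8.32
```

The apparent AUC (0.619 here) is the probability that a random successful
attempt scores higher than a random unsuccessful one; the corrected column
subtracts the bootstrap-estimated optimism. Apparent calibration of a
model evaluated on its own training data is perfect by construction
(intercept 0, slope 1) — which is exactly why only the corrected
calibration numbers are informative.

```r
scored <- ecv_score(cohort)
strata_rates(scored$score, scored$success)
#> # A tibble: 3 × 8
#>   stratum    lo    hi     n successes  rate conf.low conf.high
#> 1 0-4         0     4    35        24 0.686   0.520      0.814
#> 2 5-8         5     8    17         3 0.176   0.0619     0.410
#> 3 >=9         9    13    48        42 0.875   0.753      0.941

youden_cutoff(scored$score, scored$success)[, c("cutoff", "sensitivity",
                                                "specificity", "youden_j")]
#> # A tibble: 1 × 4
#>   cutoff sensitivity specificity youden_j
#> 1      9       0.609       0.806    0.415
```

Note the fixture fixes only the published *margins*; its joint
predictor arrangement is an arbitrary deterministic construction, so
score-level quantities computed on it (AUC, strata rates, the cutoff
report) characterize the fixture, not the original cohort — see the
methods vignette (`vignettes/score-validation.Rmd`).

A thin command-line front end ships in `inst/cli/preecv`
(`score`, `summarize`, `validate`, `dca`, `thresholds`, `simulate`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "preecv", package = "preecv"))')" \
  validate cohort.csv --resamples 2000 --seed 1
```

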