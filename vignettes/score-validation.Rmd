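---
title: "Validating an additive ECV success score: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating an additive ECV success score: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preecv)
```

## The score and its domain

The PRE-ECV score sums points over eight predictors of external cephalic
version (ECV) success assessed immediately before the attempt: parity
(multiparous, 2), fetal presentation (transverse 2 / complete breech 1 /
frank breech 0), non-engagement of the presenting part (2), palpable
fetal head (2), estimated fetal weight at or above the 10th percentile
(1), a maximum vertical amniotic-fluid pocket of at least 4 cm (1),
posterior placenta (1), and tocolysis (2). The domain is finite — 384
distinct profiles — so the package never hard-codes the 0–13 range:
`ecv_score_bounds()` enumerates every profile through the scoring
function, and the test suite checks per-factor weights, completeness of
the achievable score set, and monotonicity (flipping any factor from its
zero level never lowers the total) by the same exhaustive route.

Two binning gaps in the score's published definition are resolved at the
interface: estimated-weight percentiles and fluid pockets are booleans
decided upstream by the caller (`efw_ge_10th`, `mvp_ge_4cm`), with the
convention that anything below the positive threshold scores 0 —
percentiles are integer-binned in obstetric practice, and a pocket in the
3–4 cm gap maps to the conservative 0-point side. Placental location is
binary posterior / not-posterior; lateral or fundal placentas must be
dichotomized by the caller because the score itself offers no third
category. No cross-field constraints are imposed (a transverse lie with
an "engaged" flag is clinically odd but accepted): the score treats
factors as independent, and so do we. Missing values are input errors,
never categories — there is no imputation.

## Score to probability

The score is prespecified, so the only fitted object is the univariable
logistic mapping

$$\operatorname{logit} P(\text{success}) = \alpha + \beta \cdot \text{score},$$

fitted by Newton–Raphson (equivalently IRLS) with step-halving whenever a
step would lower the likelihood. Convergence requires a maximum absolute
score-function component below 1e-8 or a parameter step below 1e-10,
within 100 iterations. Standard errors come from the inverse observed
information. Failure modes are first-class, typed conditions because the
bootstrap engine must catch and count them: one-class outcomes raise a
degenerate-outcome error; a coefficient passing 50 in absolute value
(e^50 is numerically saturated), a structurally separated predictor, a
singular information matrix, or non-convergence raise a separation error.
The fit is started at $(\operatorname{logit}(\bar y),\, 0)$, which is the
exact MLE in the no-association case.

## Discrimination and calibration

The AUC is the Mann–Whitney probability that a random success outranks a
random failure, ties counted one-half; it is computed from midranks and
therefore invariant to any strictly increasing transform of the
predictions. Its variance uses the DeLong placement-value estimator. The
published interval for this kind of analysis conflates two constructions
(a "bootstrap-derived" interval attributed to the DeLong method), so
`delong_ci()` exposes both: the default Wald interval on the AUC scale
truncated to [0, 1], a logit-scale variant behind `scale = "logit"`, and
a case-resampling bootstrap-percentile variant behind
`method = "bootstrap_percentile"`.

Calibration is summarized by logistic recalibration. The calibration
slope is the MLE slope of the outcome regressed on the prediction
log-odds (ideal 1). The calibration intercept is deliberately *not* taken
from that joint fit: it is the intercept of a logistic model with the
prediction log-odds entered as a fixed offset — calibration-in-the-large,
the standard definition when the published source does not specify one.
Binned calibration uses equal-count bins of predicted risk ("deciles" at
the default 10): bins are formed from minimum-ranks so tied predictions
stay together, which can leave bins empty; those are returned flagged
rather than silently dropped. The smoothed curve is local-linear
regression with tricube weights (span 0.75, no robustness iterations,
exact "direct" surface) — delegated to `stats::loess`, which implements
precisely this smoother; the tests pin it to an independent single-point
weighted-least-squares solve. Whether the original decile plot used
equal-width or equal-count bins is unstated; equal-count matches the
phrase "deciles of predicted risk".

## Bootstrap optimism correction

Apparent performance is computed on the data that fitted the mapping, so
apparent calibration is (0, 1) by construction. `optimism_correct()`
runs the standard optimism bootstrap: draw a resample with replacement
(unstratified — the procedure is described only as "bootstrap
resamples"), refit the mapping, evaluate each metric within the resample
and, with the resample-fitted model's predictions, on the original
cohort; optimism is the difference, and the corrected metric is apparent
minus mean optimism. Resamples with one-class outcomes or separation are
skipped and counted, never redrawn — redrawing would bias the resample
distribution. The generator is seeded explicitly, the seed is recorded in
the report, and the caller's RNG state is left untouched, so a fixed seed
gives a bit-identical report.

No CI construction for corrected metrics is specified by the source this
score comes from, and its printed intervals cannot be reproduced without
the raw cohort; we report a percentile interval of the test-performance
distribution shifted to the corrected location, with the raw percentile
interval of per-resample corrected values exposed alongside, and both
full distributions retained for auditing.

**What optimism correction can show here.** For a *prespecified* score
feeding a univariable mapping, the prediction ranking is fixed before any
fitting, so refitting intercept and slope cannot overfit discrimination:
simulation at n = 100 (40 cohorts, 100 resamples each) gives a mean AUC
optimism of −0.0004 (sd 0.005) — centered at zero with random sign, its
magnitude shrinking roughly as 1/n. Likewise the corrected calibration
slope equals $\hat\beta \, E[1/\beta^*]$ over resamples, which Jensen's
inequality pushes slightly *above* 1 (measured mean 1.03 at n = 100)
rather than below it as in refitted multi-predictor models. Large
corrected-slope departures from 1 in a small cohort therefore say more
about resampling noise in $\beta^*$ than about overfitting. The tests
assert these truthful behaviors — near-zero mean AUC optimism, shrinking
magnitude, corrected metrics approaching their ideals at large n — not
the multi-predictor folklore.

## Clinical utility

Decision-curve analysis computes, on a default grid of thresholds 0.01
to 0.99 in steps of 0.01 (clinically interesting subranges are outputs,
not inputs), the net benefit
$NB(t) = TP(t)/n - FP(t)/n \cdot t/(1-t)$ of treating when the
*predicted probability* (not the raw score) is at least $t$ — net benefit
is defined on probability thresholds. The comparators follow their
closed forms: treat-none is identically 0 and treat-all is
$\pi - (1-\pi)\,t/(1-t)$ at prevalence $\pi$. The treatment rule at
exactly $t$ uses $\ge$, which fixes the step locations.

Cutoff selection scans every integer cutoff from the minimum score to one
above the maximum with the rule "positive if score ≥ c" and maximizes the
Youden index $J = \text{sens} + \text{spec} - 1$, breaking ties toward
the largest (most specific) cutoff. Confusion-matrix metrics each carry a
Wilson score interval on their own denominator; a zero-denominator metric
is reported `NA`, never 0. Wilson intervals are used throughout for
binomial proportions, including the prespecified strata 0–4 / 5–8 / ≥ 9,
which must partition the score range (misconfiguration is an error, and
empty strata report n = 0 with an undefined rate).

One numerical fact worth recording: the Wilson interval's exact coverage
at n = 30, p = 0.7 — obtainable by enumeration over the 31 binomial
outcomes — is 0.92979, about 2 points below nominal, and simulation
estimates of it straddle 93%. The coverage test therefore compares the
Monte-Carlo estimate against the enumerated exact value (within 3
simulation SEs) rather than against a round-number band.

## The fixture cohort

No patient-level data accompany the published validation, so the package
ships a deterministic 100-record cohort whose per-predictor-by-outcome
counts equal the published baseline-table cells (69 successes, 31
failures). Two cells required reconciliation. The successful-column
presentation counts print as 7 transverse + 11 complete + 50 frank = 68,
one short of 69 (and the unsuccessful column one over); the frank-breech
cell — the largest, where a unit change distorts percentages least —
absorbs the difference (51/25, totals preserved at 8/16/76). The
palpable-head row's printed percentages are inconsistent with its printed
counts; the counts (69 overall; 63 successful; 6 unsuccessful) are used.
Only margins are published, so the joint arrangement is this package's
own: within each outcome group every predictor's score-positive value is
stacked onto the leading rows, maximizing concordance among
non-engagement, palpable head and the other favorable factors, consistent
with the near-deterministic published margins. Consequences follow:
score-level results on the fixture (apparent AUC 0.62, the 0.686 / 0.176
/ 0.875 strata gradient, the ≥ 9 Youden cutoff) characterize this
arrangement, not the unobservable original cohort, and the published
headline performance numbers are not reproduction targets anywhere in the
package. Descriptive summaries round percentages half-up to one decimal,
matching the published table's formatting.

## The synthetic generator

`generate_cohort()` draws predictor profiles with the published overall
marginal prevalences (multiparity 0.55; transverse 0.08 / complete 0.16 /
frank 0.76; non-engagement 0.36; palpable head 0.69; EFW ≥ 10th 0.80;
MVP ≥ 4 cm 0.86; posterior placenta 0.49; tocolysis 0.65). True joint
correlations are unknowable from margins, so association is reduced to
one knob: a Gaussian copula with exchangeable latent correlation `rho`
(default 0.6, a documented guess) over the clinically linked trio
non-engagement / palpable head / adequate fluid; all other predictors are
independent. The outcome is Bernoulli with
$\operatorname{logit} p = a + b \cdot \text{score}$; the default slope
b = 0.55 per point is chosen so 100-patient cohorts give apparent AUCs
broadly in the 0.7–0.8 band — a harness-realism choice, explicitly not an
estimate of any real data-generating truth. By default the intercept is
solved by bisection so the expected success rate over the realized scores
matches the published overall 0.69 within 1e-6; alternatively an explicit
intercept may be supplied (exactly one of the two). What the generator
does *not* emulate: real predictor interactions beyond the single trio,
non-logistic score-outcome shapes, measurement error in the predictors,
or site effects — so green tests demonstrate the machinery is correct
under a known model, not that the score performs at any level on new
patients.

`recovery_experiment()` closes the loop: generate, score, fit, and
summarize bias/RMSE of both coefficients. At n = 5000 over 100
replicates the slope bias is below 0.02.

## Problem sizes and numerical conventions

Test and script sizes are chosen to make Monte-Carlo noise negligible
relative to each assertion: marginal checks at n = 100,000 (3 binomial
SEs), recovery at n = 5000 × 100 replicates, Wilson coverage at 20,000
replicates, optimism behavior at 100-patient cohorts with 100–2000
resamples. The bundled acceptance script uses the full 2000 resamples of
the published procedure. Other conventions: percentages round half-up
(away from zero) to one decimal; equal-count bins keep ties together;
LOESS ordinates are clipped to [0, 1]; bootstrap skip reasons are
reported, and a skipped fraction above a few percent on a fixture-scale
cohort would itself be a red flag.

## Known limitations

The fixture's joint structure is a convention, not data. The copula
default `rho = 0.6` is a guess. The score's handling of non-posterior,
non-anterior placentation and of discordant engagement/palpable-head
combinations is inherited from the score's binary definitions, not
resolved here. Decision curves carry no confidence bands. And internal
validation — bootstrap or not — remains "testing on ourselves": nothing
in this package substitutes for external, multicenter validation of the
score.
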