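---
title: "Mapping EPIC scores to EQ-5D-3L utilities: models, estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping EPIC scores to EQ-5D-3L utilities: models, estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicmapr)
```

## The problem

Cost-utility analyses of prostate-cancer treatments need health-state
*utilities* — preference weights anchored at 0 (dead) and 1 (full health) —
to compute quality-adjusted life-years. Most prostate-cancer trials collect
the Expanded Prostate Cancer Index Composite (EPIC), a descriptive
patient-reported outcome with four summary domains (Urinary, Bowel, Sexual,
Hormonal) and function/bother sub-scales, each scored 0–100 with higher
scores meaning better health-related quality of life. EPIC scores are not
utilities. A *mapping* (crosswalk) model predicts the utility a
preference-based measure — here the EQ-5D-3L — would have produced, from the
EPIC scores that were actually collected.

`epicmapr` provides three layers:

1. **Scoring** — a generic additive EQ-5D-3L tariff engine plus the linear
   0–100 transform used for EPIC scale scores.
2. **Application** — published EPIC→EQ5D mapping equations as frozen,
   registered models that score patient tables.
3. **Re-estimation** — the full model-development battery behind such
   equations (OLS, upper-censored Tobit, two-part estimation, forward
   stepwise selection, 70/30 splitting, 5-fold cross-validation, RMSE
   ranking, Bland–Altman agreement), together with a synthetic cohort
   generator so the whole workflow can be exercised without patient-level
   trial data.

## The tariff engine

An EQ-5D-3L state is five dimensions (mobility, self-care, usual activities,
pain/discomfort, anxiety/depression) at three levels each; 3^5 = 243 states
exist. A value set converts a state to a utility by the additive rule

$$U = 1 + \sum_{d} \delta_{d,\ell_d} + \sum_{t} \gamma_t \, g_t(\ell),$$

where $\delta_{d,\ell}$ are per-dimension level decrements (zero at level 1
by convention, so full health scores exactly 1) and the $g_t$ are the
derived regressors that published valuation models add: indicators and
counts of dimensions at level 2/3, "beyond the first" counts, and their
squares. Coefficients live in JSON configuration files, not code, so any 3L
value set can be loaded; the packaged US societal tariff is a transcription
at the published rounded precision (its file says so). Utilities below 0 are
legitimate — states can be valued worse than dead — and the only hard bound
the engine enforces is $U \le 1$. A state with any missing dimension is
unscorable and rejected; how trial analyses handled partially answered
EQ-5D questionnaires is generally not reported, and silently imputing a
level would manufacture utilities.

## Mapping models

A mapping model is a frozen linear scoring rule
$\hat u = \beta_0 + \sum_j \beta_j x_j$ whose regressors are EPIC scores,
age powers, race, Zubrod performance status, a PSA indicator, and
score-by-Zubrod products. Two published equations ship as built-ins: a
parsimonious group-6 model (urinary/hormonal function and bother, Zubrod,
and a urinary-function-by-Zubrod product) and the full group-6 model with
all ten sub-domain scores, an age cubic, race, Zubrod, ten Zubrod products
and PSA. Coefficients are stored at full printed precision and never rounded
at evaluation time.

Two design choices deserve emphasis:

* **Predictions are not clipped by default.** The published OLS algorithms
  report prediction maxima slightly above 1, so the authors evidently did
  not truncate; fidelity to the published algorithm comes first, and
  clipping at 1 is an explicit opt-in (`clip_predictions`) for downstream
  QALY arithmetic.
* **Age enters as raw years.** The printed equation shows no centering, so
  none is applied; the large intercept and the cubic in age are evaluated
  literally.

## Estimation battery

Specifications come in six groups: domains only (1), sub-domains only (2),
plus demographics age/race (3, 4), plus clinical covariates Zubrod/PSA
(5, 6); odd groups use domain scores, even groups sub-domain scores.
Score and age polynomials (powers 2–3) and race- or Zubrod-by-score
products extend a group's design. Design-matrix columns follow a documented
canonical order (scores by power, age powers, race, Zubrod, products, PSA),
which also fixes stepwise tie-breaking, and records failing the group's
complete-case rule are dropped and counted.

Three functional forms address the ceiling-inflated utility distribution:

* **OLS** via QR; the reported residual scale is the maximum-likelihood
  $\sqrt{RSS/n}$ so that the censoring-free Tobit reduces to it exactly.
* **Tobit**, maximum likelihood for a latent normal outcome observed only up
  to the ceiling: uncensored observations contribute the normal density,
  ceiling observations the upper-tail probability
  $\Phi((x'\beta - 1)/\sigma)$. $\sigma$ is optimised on the log scale to
  stay positive, with analytic gradients and BFGS; standard errors come from
  the numerically differentiated Hessian. Ceiling status is exact equality
  with 1 — tariff scoring returns exactly 1 only for full health, so no
  tolerance band is needed or used. Three prediction policies are exposed:
  the latent mean $x'\beta$, the latent mean truncated at 1 (default,
  consistent with published Tobit prediction maxima of exactly 1.00), and
  the closed-form censored expectation $E[\min(Y^*, 1)]$. Published reports
  do not state which rule their Tobit predictions used; their reported means
  are consistent with either of the latter two.
* **Two-part**: a logistic model for being at the ceiling, OLS strictly
  below it, recombined as $p \cdot 1 + (1 - p)\,\hat y_2$. The recombination
  rule is rarely stated in mapping studies; this expectation form is the
  package's documented choice. With no ceiling cases part 1 degenerates to
  $p \equiv 0$ and the combined prediction equals the part-2 OLS prediction
  exactly; complete separation in part 1 is flagged as non-convergence.

**Forward stepwise selection** adds the candidate with the smallest entry
p-value below 0.25 and, after each addition, removes any term whose p-value
exceeds the stay threshold 0.25 — the conventional permissive thresholds for
building prediction (rather than inference) models. The test statistic is
not usually printed alongside such procedures; the package uses the
conventional defaults — a partial t test for OLS and Wald tests for Tobit
and for each part of the two-part model, a candidate's two-part p-value
being the smaller of its two parts' (a term is worth keeping if either part
needs it). Ties break by canonical column order, so selection is
deterministic. Weak hierarchy is enforced by default — a product enters only
after both parents — with an override flag, since batteries of this era
sometimes let products compete freely.

## Validation machinery

The estimation/validation split assigns `ceiling(0.7 n)` records to
estimation — the convention that reproduces the canonical 1,092 → 765/327
accounting. K-fold cross-validation (default $k = 5$) predicts each record
exactly once from a model that never saw it, accumulates the per-fold
predicted residual sum of squares (PRESS), and reports
$RMSE = \sqrt{\sum_f PRESS_f / n}$ — summing PRESS before dividing, which
differs from averaging per-fold RMSEs when folds are unequal. Fold
assignment is a seeded random permutation sliced into contiguous blocks,
remainder records going one-per-fold to the first folds. A fold whose model
cannot be fitted (e.g. a two-part fold with no below-ceiling variation) is
flagged and the report marked incomplete rather than crashing the battery.
Models rank by ascending RMSE with ties broken by fewer regressors, then
label. Rendered tables show cross-validation RMSE to 5 decimals and
external-validation RMSE to 6, the precisions such studies print; full
precision is kept internally. MAE is computed and reported alongside RMSE
but has no published anchor values to compare against.

## The synthetic cohort generator

The generator exists because the trial data behind published EPIC→EQ5D
mappings are not deposited. It reproduces the *statistical structure* the
mapping problem exhibits, with defaults frozen to the published baseline
description of a low-risk prostate-cancer trial cohort:

* **Utility margin**: a point mass at 1 with weight 0.55 (the ceiling), else
  a Beta on [0.28, 1) — 0.28 being the observed utility floor. The Beta
  shapes (6.66, 2.97) were derived once by moment-matching: given the
  ceiling mass and floor, they are the unique shapes whose mixture has mean
  0.90 and SD 0.13, and they place the continuous mode at ≈ 0.81 —
  reproducing the published bimodal shape peaking at full health and near
  0.8.
* **Score margins**: scaled Beta on [0, 100], moment-matched to each
  domain/sub-domain's published mean and SD. A truncated normal cannot
  represent these margins — at a mean of ~93 its SD tops out near 7 (the
  tilted-uniform limit), while the targets run up to 14 — whereas the Beta
  family reaches every feasible (mean, SD) pair on a bounded interval and
  naturally yields the left-skewed shape with a pile-up at 100 that bounded
  instrument scores show.
* **Dependence**: a Gaussian copula ties utility to all scores. Because only
  utility-score Pearson correlations are published, score-score latent
  correlations default to 0.4 within instrument — a placeholder assumption,
  flagged here and user-overridable. Targets are stated on the observed
  scale, so the generator calibrates each latent correlation by bisection on
  a fixed common-random-numbers sample (2^14 draws, 20 iterations) so that
  the observed correlation hits the target despite the attenuation induced
  by the ceiling mass; the calibration is deterministic, cached per
  parameter set, and independent of the cohort seed. If the assembled
  matrix is not positive definite it is projected to the nearest correlation
  matrix; a projection that moves any calibrated utility-score entry by more
  than 0.025 aborts with the nearest feasible values, since silently
  generating off-target cohorts would invalidate downstream claims.
* **Demographics**: age normal (66.4, 7.3) years floored at 18, and
  Bernoulli indicators at the published rates (non-White 0.175, Zubrod 1
  0.062, PSA ≥ 4 0.797), drawn independently of the scores — the published
  tables give no joint structure to respect.

What the generator does *not* emulate: domain scores are not aggregates of
their sub-domain scores (each margin is drawn from the copula directly);
demographics are uncorrelated with health status; and there is no
item-level, longitudinal or treatment-arm structure. Tests passing on
synthetic cohorts therefore demonstrate that the estimation and validation
machinery is correct and that the published qualitative findings (e.g. OLS
out-predicting Tobit under a 55% ceiling) are properties of this data
*shape* — they do not re-validate the published coefficient values, which
would require the original trial data.

## Numerical choices and degenerate inputs

* OLS matches the normal-equation solution to 1e-8 relative tolerance (QR
  solves, no explicit inverse); rank deficiency errors, naming the collinear
  columns.
* Tobit starts from the all-data OLS solution with `reltol = 1e-12` and a
  500-iteration budget; non-convergence is flagged and prediction from a
  non-converged fit refuses. All-censored data is rejected as unidentified.
* The stepwise loop is capped at four passes over the candidate pool to
  exclude add/remove cycles; a candidate whose addition makes the design
  singular is treated as uninformative (p-value 1) rather than fatal.
* The 243-state enumeration and the monotonicity property (raising any one
  dimension's level never increases utility when all decrements and extra
  terms are nonpositive) are checked exhaustively, not sampled.

## Problem sizes in the test suite

The suite exercises the battery at the scales a desk check needs: cohorts of
50–2,000 records for oracle comparisons (leave-one-out identities,
grid-search and Monte-Carlo oracles), 2,000 records for Tobit parameter
recovery, 10,000 records for generator calibration, and 50 seeded
replicates of 565-record cohorts — the published estimation-cohort size —
for the OLS-versus-Tobit cross-validation comparison. These sizes keep the
full suite to a few minutes on one core while leaving each statistical
assertion comfortably powered.

## Known limitations

* The packaged US tariff is a rounded-precision transcription; analyses
  needing the exact published index values for every one of the 243 states
  should load a verified value-set file.
* Only the two equations printed in full ship as built-ins; other published
  candidate algorithms (known only from supplementary material) can be added
  as JSON model files but are not bundled.
* Mapping predictions compress the utility distribution (SD ≈ 0.07–0.08
  against an observed 0.13): utilities are under-predicted for the healthiest
  patients and over-predicted for the sickest. Mapped utilities are suited
  to estimating cohort means for economic models, not individual-level
  prediction — a caveat that applies to the published algorithms themselves.
* Two-part fits cannot be frozen into the portable linear model format; they
  participate in estimation and cross-validation but not in the JSON model
  exchange.
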