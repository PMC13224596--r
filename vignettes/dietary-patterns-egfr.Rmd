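---
title: "Dietary patterns and kidney function: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dietary patterns and kidney function: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietkidney)
```

## The scientific problem

Chronic kidney disease develops silently, and diet is one of its few
modifiable risk factors. Two complementary ways of summarising diet are in
common use: *a priori* adherence indices such as the DASH (Dietary
Approaches to Stop Hypertension) score, and *hybrid* data-driven patterns
from reduced-rank regression (RRR), which extract the food-group
combinations most predictive of a chosen set of intermediate biomarkers on
the presumed diet–disease pathway. This package implements both, together
with the downstream association models against creatinine-based estimated
glomerular filtration rate (eGFR), with sex-specific fits and effect
modification by menstrual status in women.

Because individual-level cohort data of this kind are access-restricted,
the package ships a seeded synthetic cohort generator that reproduces the
statistical *structure* the analysis assumes — not any real population's
distributions — so that every stage is testable end to end and recovery of
planted effects can be verified exactly.

## Pipeline overview

1. **Cohort preparation** (`compute_egfr()`, `apply_exclusions()`,
   `impute_menstrual_status()`): eGFR from the race-free CKD-EPI 2021
   creatinine equation,
   $\mathrm{eGFR} = 142 \cdot \min(\mathrm{Scr}/\kappa, 1)^{\alpha} \cdot
   \max(\mathrm{Scr}/\kappa, 1)^{-1.200} \cdot 0.9938^{\mathrm{age}} \cdot
   1.012[\mathrm{female}]$ with $\kappa = 0.9/0.7$ and
   $\alpha = -0.302/-0.241$ for males/females. The exclusion cascade runs
   in a fixed order: disease/medication self-reports; >80% missing
   biomarkers; >20% missing FFQ items; total energy intake (TEI) to basal
   metabolic rate (BMR) ratio outside the closed [0.5th, 99.5th] percentile
   interval of the sample surviving the FFQ step. Remaining missing FFQ
   entries are read as non-consumption (zero). Missing menstrual status is
   assigned "ceased" strictly above age 50.
2. **Diet processing** (`build_diet_matrix()`, `energy_adjust()`): the 229
   food-frequency items (7 ordered categories) are converted to portions
   per day with a fixed midpoint map, to grams per day through portion
   sizes, and aggregated into 32 food groups (RRR side) and 8 DASH
   components (servings/week; sodium in mg/day). Energy adjustment uses
   the nutrient residual method within sex: the residual from an
   intake-on-TEI regression plus the predicted intake at the sex-mean TEI,
   which keeps units and within-sex means while removing the TEI
   correlation exactly.
3. **DASH score** (`dash_score()`): sex-specific quintile ranks for five
   healthy components (ascending) and two unhealthy ones (descending), and
   tertile ranks for sugar-sweetened beverages, whose intake is too sparse
   in Alpine-style diets for stable quintiles. The total is the sum of the
   eight ranks.
4. **RRR patterns** (`rrr()` and friends): mediator biomarkers are
   quantile-normalized across assay batches onto the last batch, then
   adjusted for age and household clustering with a random-intercept REML
   model; the RRR fit extracts, per sex, the linear combinations of
   standardized food-group intakes that maximize explained mediator
   variance.
5. **Association models** (`fit_linear()`, `fit_smooth()`,
   `fit_interactions()`, `run_analysis_grid()`): adjusted linear models on
   z-standardized scores, penalized-spline generalized additive models
   (GAMs) with REML-selected smoothing, menstrual-status and age
   interaction models in women, stratified fits, and a "Healthy+"
   sensitivity repeat that drops subjects with sub-clinical disease
   (HbA1c > 6.5%, eGFR < 60 ml/min/1.73 m², or UACR > 30 mg/g).

## The reduced-rank regression model

With standardized predictors $X$ ($n \times p$ food groups) and
standardized responses $Y$ ($n \times q$ mediators), let
$B = (X'X)^{-1}X'Y$ and $\hat Y = XB$. The $k$-th response weight $v_k$ is
the $k$-th right singular vector of $\hat Y$; the predictor weights are
$a_k = B v_k$; the pattern score is $s_k = X a_k = \hat Y v_k$ with
eigenvalue $\lambda_k = s_k's_k$, and the share of total response variance
explained by pattern $k$ is $\lambda_k / \operatorname{tr}(Y'Y)$. Retained
scores are mutually uncorrelated by construction (they are scaled left
singular vectors of $\hat Y$), and with $K = q$ the cumulative share equals
the unreduced multivariate OLS $R^2$ — both properties are asserted in the
test suite against independent numeric maximization.

Numerical choices: the eigendecomposition is taken via the SVD of $\hat Y$
rather than forming $\hat Y'\hat Y$; a rank-deficient $X'X$ is an error
(no silent ridge regularization); eigenvector sign indeterminacy is fixed
by making each pattern's largest-magnitude predictor weight positive;
training means and SDs are stored so `predict()` scores new subjects on
the training scale.

Rank selection: visual scree inspection is not reproducible, so
`select_rank()` automates it as the largest $K$ with
$\lambda_K/\lambda_1 \ge 0.10$, capped at 2 — the two-pattern
configuration used throughout — with a `"fixed"` policy that always
returns the cap. The scree table is emitted for human inspection either
way.

## Mediator pre-adjustment

Batch effects are removed by mapping each earlier assay batch through its
empirical distribution onto the last batch's empirical quantile function
(linear interpolation at mid-rank plotting positions); the reference batch
is untouched and within-batch ranks are preserved. Age and shared
household environment are then removed with
$y = \beta_0 + \beta_1\,\mathrm{age} + u_{\mathrm{household}} +
\varepsilon$, fitted by REML (`lme4`), taking the conditional residuals
$y - \hat\beta_0 - \hat\beta_1\,\mathrm{age} - \mathrm{BLUP}(u)$. Mixed-model
residuals are exactly orthogonal to the fixed-effect columns, so the
adjusted mediators carry no age signal. Whether the household BLUP should
be subtracted or merely modelled is genuinely ambiguous; both modes are
implemented (`subtract_blup`), with subtraction the default since the goal
is to purge family-level lifestyle from the responses before pattern
extraction. Variance components are returned so intraclass correlations
can be checked; a household variance estimated at the zero boundary is
reported as a note, not an error.

## Association models

Scores are z-standardized within the analysis stratum, so effects are in
ml/min/1.73 m² per 1 SD. Covariates are age, TEI, physical activity,
smoking, education, BMI and special diet; categorical covariates are
dummy-coded against the alphabetically first level. The smooth models are
`egfr ~ s(score) + s(age) + covariates` with cubic regression splines
(basis dimension 10, reduced automatically in small strata), smoothing
parameters by REML via `mgcv`, covariates entering linearly. The penalty
null space is the linear function, so forcing the smoothing parameters to
infinity collapses the GAM onto the linear model — asserted to 1e-6 in the
tests — and an effective degrees of freedom (edf) near 1 certifies an
essentially linear relation. The reported smooth p-value is `mgcv`'s
approximate test. Significance is taken at 0.05 with no multiplicity
correction, matching common practice for this design; the grid reports
all cells so readers can apply their own correction.

The interaction analysis is female-only: one linear model per score with
`score x menstrual_status` and `score x age` terms. The status interaction
coefficient is the additional effect per 1 SD in the ceased stratum
(reference "yes"); recoding the reference flips its sign exactly.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` plants, per sex, one designated true pattern: a unit
direction $w$ over the 32 standardized energy-adjusted food groups drawn
once from the config seed. Mediators follow
`age effect + household intercept + (Z w) x mediator weight + noise`, i.e.
a rank-1 group-effect matrix by default (an arbitrary matrix can be
supplied). eGFR is built as `baseline(age, sex) + beta x true score +
interaction x 1[ceased] x true score + noise` and creatinine is
back-solved through the inverse CKD-EPI equation, so the planted effects
survive the package's own outcome computation. Item intakes are scaled so
that FFQ-derived TEI matches per-subject targets, then discretized into
the seven frequency categories with cutpoints midway between the category
values — reproducing the instrument's coarseness.

Default study conditions (chosen once, as plausible for a European adult
cohort): sex ratio 53.4% female; ages uniform 18–80; TEI mean (SD)
2000 (500) kcal/day in males and 1850 (450) in females; mediator effect
weights of magnitude 0.30–0.50 SD per SD of the true score (moderate
noise); household and residual mediator SDs both 1, i.e. intraclass
correlation 0.5; planted eGFR effect 1.0 ml/min/1.73 m² per 1 SD in both
sexes with a +2.0 interaction in the ceased-menstruation stratum; eGFR
residual SD 9; two assay batches with a location/scale distortion on the
earlier one; ~1% sporadic FFQ missingness; disease-flag prevalences 1–4%,
independent of diet so exclusions can be exercised without confounding
recovery tests. Menstrual status is deterministic below 45 and above 55
with a stochastic transition band between.

The generator does **not** emulate measurement-error models, seasonality,
correlated food-choice behaviour beyond the energy factor, or any real
population's marginal distributions. Passing recovery tests therefore
demonstrates the estimators' correctness under the assumed structure, not
robustness to real FFQ error.

## Problem sizes and tolerances in the test suite

Pattern recovery is checked at n = 5000 (|r| > 0.9 between the fitted
first pattern score and the planted truth; observed ≈ 0.99); effect
recovery averages stratified estimates over 10 regenerated cohorts of
n = 20000 (planted 1.0 recovered within ±0.2; planted interaction +2.0
within ±0.4 — the interaction's model SE is ≈ 0.35 per cohort, hence the
Monte-Carlo average); null calibration uses 200 replicates (CI coverage
and 5% type-I error); the balanced REML oracle uses a 40 x 5 design
against the ANOVA closed form (1e-4) and a 3 x 3 grid search on the
profiled criterion (1e-6); the RRR optimizer oracle runs at
n = 50, p = 3, q = 2 (1e-6). These sizes keep the default suite under a
minute or two while leaving the statistical checks well-powered.

## Known limitations and open decisions

* The DASH total's achievable range is 8–38 under this scheme (five
  healthy quintile components, two unhealthy quintile, one unhealthy
  tertile). Published food-group DASH variants sometimes state 8–36; this
  implementation documents its own range and does not rescale.
* The Healthy+ HbA1c threshold is applied on the percent scale (6.5), the
  diagnostic convention; a `"mmol/mol"` switch (cutoff 48) is available.
* The BMR equation is not standardized across cohorts; Schofield
  weight-based age–sex bands are the default and the only implemented
  choice, behind a configuration switch that rejects unknown names.
* Quantile cutpoints use linear interpolation (quantile type 7) with ties
  falling into the lower category; scores are invariant to strictly
  monotone transforms of component intakes, which the suite asserts.
* The 229-to-32 item-to-group and item-to-DASH-component mappings live in
  the composition table; the packaged `toy_composition()` table is
  synthetic and deterministic from its seed.
* Multiple imputation is out of scope; `impute_simple()` is plumbing for
  sporadic covariate missingness only. Genotype-based relatedness
  adjustment is likewise out of scope — the covariate slot accepts generic
  continuous confounders instead.
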