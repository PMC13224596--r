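# dietkidney

Dietary-pattern analysis of kidney function for epidemiologists: DASH
adherence scoring, reduced-rank-regression (RRR) dietary patterns driven by
cardio-renal-metabolic biomarkers, and sex- and menstrual-status-stratified
association models against creatinine-based eGFR — with a seeded synthetic
cohort generator so the whole pipeline is testable without access-restricted
cohort data.

## What it computes

**eGFR** from serum creatinine with the race-free CKD-EPI 2021 equation,

```
eGFR = 142 · min(Scr/κ, 1)^α · max(Scr/κ, 1)^−1.200 · 0.9938^age · 1.012[female]
```

with κ = 0.9/0.7 and α = −0.302/−0.241 for males/females.

**DASH score**: eight food components energy-adjusted by the nutrient
residual method within sex, then ranked into sex-specific quintiles —
ascending for the five healthy components (fruits, vegetables, whole
grains, low-fat dairy, nuts/legumes), descending for red/processed meat and
sodium — and tertiles for sugar-sweetened beverages; the total is the sum
of the eight ranks (achievable range 8–38).

**RRR dietary patterns**: with standardized food-group intakes X (n × 32)
and batch-normalized, age/household-adjusted mediators Y (n × 9: HbA1c,
MAP, CRP, uric acid, total cholesterol, ferritin, fibrinogen, potassium,
haemoglobin), let B = (X′X)⁻¹X′Y and Ŷ = XB. The k-th response weight v_k
is the k-th right singular vector of Ŷ, the predictor weights are
a_k = B v_k, and the pattern score s_k = X a_k has eigenvalue λ_k = s_k′s_k
and explained-variance share λ_k / tr(Y′Y). Retained scores are mutually
uncorrelated by construction.

**Association models**: adjusted linear models on z-standardized scores
(effects in ml/min/1.73 m² per 1 SD), penalized-spline GAMs with
REML-selected smoothing (edf ≈ 1 certifies linearity), menstrual-status and
age interaction models in women, and a "Healthy+" sensitivity repeat
excluding sub-clinical disease (HbA1c > 6.5 %, eGFR < 60, or UACR > 30 mg/g).

## Worked example

```r
library(dietkidney)
run <- run_pipeline(list(n_subjects = 3000, seed = 7))
print(run)
```

```
dietkidney pipeline run: /tmp/.../dietkidney_run_...
Exclusion cascade (n = 3000 )
  disease_or_medication  -196
  biomarker_missing      -0
  ffq_missing            -0
  tei_bmr_outlier        -30
  remaining               2774

Association grid (main sample):
          stratum score    beta   ci_lo   ci_hi        p    n
            males  dash  0.5653  0.0599  1.0708 2.84e-02 1254
            males   DP1  1.1610  0.6624  1.6595 5.40e-06 1254
            males   DP2  0.3828 -0.1209  0.8866 1.36e-01 1254
          females  dash -0.1224 -0.6038  0.3591 6.18e-01 1520
          females   DP1 -1.7905 -2.2599 -1.3210 1.24e-13 1520
          females   DP2 -0.5270 -1.0020 -0.0519 2.97e-02 1520
 menstruation_yes  dash -0.2100 -0.8824  0.4624 5.40e-01  781
 menstruation_yes   DP1 -0.6776 -1.3412 -0.0141 4.53e-02  781
 menstruation_yes   DP2 -0.3294 -0.9932  0.3344 3.30e-01  781
  menstruation_no  dash -0.0163 -0.7147  0.6820 9.63e-01  739
  menstruation_no   DP1 -2.9406 -3.6021 -2.2791 1.78e-17  739
  menstruation_no   DP2 -0.7146 -1.4020 -0.0271 4.16e-02  739
```

Reading this: the generator planted an eGFR effect of 1.0 ml/min/1.73 m²
per 1 SD of the true pattern in both sexes, plus +2.0 in the
ceased-menstruation stratum. The fitted first pattern (DP1) picks up the
planted direction — in males the estimate is 1.16 (0.66, 1.66); in females
the *sign* of DP1 is fixed by the loading convention, not by the planted
direction, so its estimate may appear with either sign (here the fitted
pattern is anti-aligned with the truth: −0.68 while menstruating versus
−2.94 after cessation, the planted 1 : 3 effect contrast). The DASH column
behaves as a partially correlated a priori index. Each fit is also
available per cell:

```r
print(run$rrr_fits$female)
#> Reduced-rank regression: 32 food groups -> 9 mediators, n = 1520
#> Retained patterns: 2 (explained response variance 9.7%)
#> Per-pattern shares: 9.3%, 0.4%

run$interactions[, c("score", "interaction_beta", "ci_lo", "ci_hi", "p")]
#>   score interaction_beta      ci_lo      ci_hi          p
#> 1  dash        1.2051488 -0.6453958  3.0556934 0.20164583
#> 2   DP1       -1.9015125 -3.6871036 -0.1159214 0.03688567
#> 3   DP2       -0.1850319 -2.0083953  1.6383315 0.84224736

compute_egfr(0.9, 40, "male")
#> [1] 110.7256
```

The run directory additionally holds `analysis_sample.csv`,
`exclusion_report.json`, per-sex loadings/scree tables, `results.tsv`,
`interactions.csv`, a markdown report and a manifest with a results
checksum; re-running the same config reproduces identical numbers.

## Vignette

`vignettes/dietary-patterns-egfr.Rmd` documents the models, the synthetic
generator's design (what it emulates and what it deliberately does not),
numerical conventions (quantile types, tie handling, sign conventions) and
known limitations.
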