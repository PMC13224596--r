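#' CKD-EPI 2021 equation parameters
#'
#' Constants of the race-free CKD-EPI 2021 creatinine equation. Exposed so
#' that alternative calibrations can be supplied to [compute_egfr()].
#'
#' @param kappa Named numeric, sex-specific creatinine knot (mg/dL).
#' @param alpha Named numeric, sex-specific exponent below the knot.
#' @param beta Exponent above the knot (shared between sexes).
#' @param age_decay Multiplicative per-year age factor.
#' @param female_multiplier Multiplier applied to females.
#' @param level_constant Scale constant (ml/min/1.73 m^2).
#'
#' @return A list of class `"egfr_params"`.
#' @export
egfr_params <- function(kappa = c(male = 0.9, female = 0.7),
                        alpha = c(male = -0.302, female = -0.241),
                        beta = -1.200,
                        age_decay = 0.9938,
                        female_multiplier = 1.012,
                        level_constant = 142) {
  stopifnot(all(kappa > 0), age_decay > 0, age_decay < 1,
            level_constant > 0, female_multiplier > 0)
  structure(list(kappa = kappa, alpha = alpha, beta = beta,
                 age_decay = age_decay,
                 female_multiplier = female_multiplier,
                 level_constant = level_constant),
            class = "egfr_params")
}

#' Estimated glomerular filtration rate (CKD-EPI 2021)
#'
#' Computes creatinine-based eGFR with the race-free 2021 CKD-EPI equation:
#' \deqn{eGFR = 142 \cdot \min(Scr/\kappa, 1)^{\alpha} \cdot
#'   \max(Scr/\kappa, 1)^{-1.200} \cdot 0.9938^{age} \cdot
#'   1.012[\mathrm{female}]}
#' with sex-specific \eqn{\kappa} (0.9 male, 0.7 female) and \eqn{\alpha}
#' (-0.302 male, -0.241 female).
#'
#' @param creatinine Serum creatinine, mg/dL. Vectorised.
#' @param age Age in years.
#' @param sex Character vector, `"male"` or `"female"`.
#' @param params An [egfr_params()] object.
#'
#' @return eGFR in ml/min/1.73 m^2; strictly decreasing in creatinine and age.
#' @examples
#' compute_egfr(0.9, 40, "male")   # ~110.7
#' compute_egfr(0.7, 50, "female") # ~105.3
#' @export
compute_egfr <- function(creatinine, age, sex, params = egfr_params()) {
  sex <- check_sex(sex)
  if (any(!is.finite(creatinine)) || any(creatinine <= 0))
    stop("'creatinine' must be positive and finite")
  if (any(!is.finite(age)) || any(age <= 0))
    stop("'age' must be positive and finite")
  kappa <- unname(params$kappa[sex])
  alpha <- unname(params$alpha[sex])
  r <- creatinine / kappa
  out <- params$level_constant *
    pmin(r, 1)^alpha * pmax(r, 1)^params$beta *
    params$age_decay^age
  out[sex == "female"] <- out[sex == "female"] * params$female_multiplier
  out
}

#' Invert the CKD-EPI 2021 equation
#'
#' Serum creatinine that yields a target eGFR for given age and sex. Used by
#' the synthetic cohort generator to plant eGFR effects.
#'
#' @inheritParams compute_egfr
#' @param egfr Target eGFR, ml/min/1.73 m^2 (positive).
#' @return Creatinine in mg/dL, `compute_egfr(result, age, sex) == egfr`.
#' @export
invert_egfr <- function(egfr, age, sex, params = egfr_params()) {
  sex <- check_sex(sex)
  if (any(!is.finite(egfr)) || any(egfr <= 0))
    stop("'egfr' must be positive and finite")
  kappa <- unname(params$kappa[sex])
  alpha <- unname(params$alpha[sex])
  base <- params$level_constant * params$age_decay^age
  base[sex == "female"] <- base[sex == "female"] * params$female_multiplier
  f <- egfr / base           # = (scr/kappa)^alpha or ^beta
  scr <- ifelse(f >= 1,
                kappa * f^(1 / alpha),   # low creatinine branch (scr <= kappa)
                kappa * f^(1 / params$beta))
  scr
}

check_sex <- function(sex) {
  sex <- as.character(sex)
  bad <- !sex %in% c("male", "female")
  if (any(bad))
    stop("'sex' must be \"male\" or \"female\"; got: ",
         paste(unique(sex[bad]), collapse = ", "))
  sex
}

#' Basal metabolic rate (Schofield weight-based equations)
#'
#' BMR in kcal/day from the Schofield age-sex band equations
#' (bands <18, 18-30, 30-60, >=60 years). Used to screen implausible
#' dietary reports through the TEI/BMR ratio.
#'
#' @param sex `"male"` or `"female"`.
#' @param age Years.
#' @param weight kg.
#' @param equation Only `"schofield"` is implemented; the argument exists so
#'   callers can request (and be told about) unsupported alternatives.
#' @return kcal/day.
#' @export
compute_bmr <- function(sex, age, weight, equation = "schofield") {
  if (!identical(equation, "schofield"))
    stop("unsupported BMR equation: ", equation)
  sex <- check_sex(sex)
  if (any(age <= 0) || any(weight <= 0))
    stop("'age' and 'weight' must be positive")
  n <- max(length(sex), length(age), length(weight))
  sex <- rep_len(sex, n); age <- rep_len(age, n); weight <- rep_len(weight, n)
  # Schofield (1985) weight-only coefficients, kcal/day
  slope <- ifelse(sex == "male",
                  ifelse(age < 18, 17.686,
                  ifelse(age < 30, 15.057,
                  ifelse(age < 60, 11.472, 11.711))),
                  ifelse(age < 18, 13.384,
                  ifelse(age < 30, 14.818,
                  ifelse(age < 60, 8.126, 9.082))))
  inter <- ifelse(sex == "male",
                  ifelse(age < 18, 658.2,
                  ifelse(age < 30, 692.2,
                  ifelse(age < 60, 873.1, 587.7))),
                  ifelse(age < 18, 692.6,
                  ifelse(age < 30, 486.6,
                  ifelse(age < 60, 845.6, 658.5))))
  slope * weight + inter
}

#' Impute menstrual status from age
#'
#' Missing menstrual status is assigned "no" (ceased) if the woman is
#' strictly older than 50 years and "yes" otherwise; non-missing values pass
#' through unchanged.
#'
#' @param status Character vector in `{"yes","no",NA}` (or `"missing"`).
#' @param age Years.
#' @return Character vector in `{"yes","no"}`.
#' @export
impute_menstrual_status <- function(status, age) {
  if (any(age <= 0)) stop("'age' must be positive")
  status <- as.character(status)
  status[status %in% "missing"] <- NA_character_
  bad <- !is.na(status) & !status %in% c("yes", "no")
  if (any(bad)) stop("invalid menstrual status: ",
                     paste(unique(status[bad]), collapse = ", "))
  miss <- is.na(status)
  status[miss] <- ifelse(age[miss] > 50, "no", "yes")
  status
}

#' Exclusion cascade for the analysis sample
#'
#' Applies, in fixed order: (1) self-reported kidney disease, hypertension or
#' diabetes, or corresponding medication; (2) >80% missing biomarker columns;
#' (3) >20% missing FFQ items; (4) TEI/BMR ratio outside the closed
#' \[0.5th, 99.5th\] percentile interval computed on the sample surviving
#' step 3. Remaining missing FFQ frequencies are interpreted as
#' non-consumption and set to zero.
#'
#' @param cohort A cohort list as returned by [generate_cohort()] /
#'   [read_cohort()]: components `ffq`, `biomarkers`, `covariates`,
#'   `creatinine` keyed by `subject_id`.
#' @param ffq_missing_max Maximum tolerated proportion of missing FFQ items
#'   (default 0.20, exclusive bound: >20% excluded).
#' @param biomarker_missing_max Maximum proportion of missing biomarker
#'   columns (default 0.80).
#' @param tei_bmr_quantiles Lower/upper percentile bounds for the TEI/BMR
#'   plausibility filter.
#' @param tei Optional per-subject TEI (kcal/day) aligned with
#'   `cohort$covariates`; defaults to the `tei` covariate column.
#'
#' @return List with `sample` (the surviving cohort, FFQ missing set to 0)
#'   and `report` (class `"exclusion_report"`: per-step counts and
#'   remaining n).
#' @export
apply_exclusions <- function(cohort,
                             ffq_missing_max = 0.20,
                             biomarker_missing_max = 0.80,
                             tei_bmr_quantiles = c(0.005, 0.995),
                             tei = NULL) {
  cov <- cohort$covariates
  n0 <- nrow(cov)
  keep <- rep(TRUE, n0)
  counts <- c(disease_or_medication = 0L, biomarker_missing = 0L,
              ffq_missing = 0L, tei_bmr_outlier = 0L)

  flag_cols <- intersect(
    c("kidney_disease", "hypertension", "diabetes",
      "kidney_medication", "hypertension_medication", "diabetes_medication"),
    names(cov))
  if (length(flag_cols)) {
    flagged <- Reduce(`|`, lapply(cov[flag_cols], function(x) x %in% c(TRUE, 1L, "yes")))
    counts["disease_or_medication"] <- sum(flagged & keep)
    keep <- keep & !flagged
  }
  if (!any(keep)) stop("empty sample after step 'disease_or_medication'")

  bio <- cohort$biomarkers
  med_cols <- setdiff(names(bio), c("subject_id", grep("^batch", names(bio), value = TRUE)))
  bio_miss <- rowMeans(is.na(bio[, med_cols, drop = FALSE]))
  drop2 <- keep & bio_miss > biomarker_missing_max
  counts["biomarker_missing"] <- sum(drop2)
  keep <- keep & !drop2
  if (!any(keep)) stop("empty sample after step 'biomarker_missing'")

  ffq <- cohort$ffq
  item_cols <- grep("^item_", names(ffq), value = TRUE)
  ffq_miss <- rowMeans(is.na(ffq[item_cols]))
  drop3 <- keep & ffq_miss > ffq_missing_max
  counts["ffq_missing"] <- sum(drop3)
  keep <- keep & !drop3
  if (!any(keep)) stop("empty sample after step 'ffq_missing'")

  if (is.null(tei)) tei <- cov$tei
  ratio <- tei / cov$bmr
  qs <- stats::quantile(ratio[keep], probs = tei_bmr_quantiles,
                        type = 7, names = FALSE)
  drop4 <- keep & (ratio < qs[1] | ratio > qs[2])
  counts["tei_bmr_outlier"] <- sum(drop4)
  keep <- keep & !drop4
  if (!any(keep)) stop("empty sample after step 'tei_bmr_outlier'")

  sample <- cohort
  for (blk in c("ffq", "biomarkers", "covariates", "creatinine")) {
    if (!is.null(sample[[blk]]) && is.data.frame(sample[[blk]]))
      sample[[blk]] <- sample[[blk]][keep, , drop = FALSE]
  }
  # residual FFQ missingness means non-consumption
  sample$ffq[item_cols] <- lapply(sample$ffq[item_cols], function(x) {
    x[is.na(x)] <- 0L
    x
  })
  report <- structure(
    list(counts = counts, input_n = n0, remaining_n = sum(keep),
         tei_bmr_bounds = qs),
    class = "exclusion_report")
  stopifnot(sum(counts) + report$remaining_n == n0)
  list(sample = sample, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion cascade (n =", x$input_n, ")\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-22s -%d\n", nm, x$counts[[nm]]))
  cat("  remaining              ", x$remaining_n, "\n")
  invisible(x)
}

#' Healthy+ sensitivity mask
#'
#' Flags participants with sub-clinical diabetes, reduced kidney function or
#' increased albuminuria: HbA1c > 6.5 (percent scale), eGFR < 60
#' ml/min/1.73 m^2, or UACR > 30 mg/g — all strict inequalities. The flagged
#' subjects are *excluded* from the Healthy+ sample.
#'
#' @param hba1c Glycated haemoglobin. Interpreted on the `%` scale by
#'   default; `hba1c_scale = "mmol/mol"` switches the cutoff to 48.
#' @param egfr ml/min/1.73 m^2.
#' @param uacr Urinary albumin-to-creatinine ratio, mg/g. Required.
#' @param hba1c_scale `"percent"` or `"mmol/mol"`.
#' @return Logical mask, `TRUE` = excluded from Healthy+.
#' @export
flag_healthy_plus <- function(hba1c, egfr, uacr, hba1c_scale = "percent") {
  if (missing(uacr) || is.null(uacr))
    stop("UACR is required for the Healthy+ sensitivity analysis")
  cut_a1c <- switch(match.arg(hba1c_scale, c("percent", "mmol/mol")),
                    "percent" = 6.5, "mmol/mol" = 48)
  hba1c > cut_a1c | egfr < 60 | uacr > 30
}

#' Median/mode fallback imputer
#'
#' Plumbing-grade single imputation: numeric columns get the median,
#' categorical columns the most frequent level. Intended only for residual
#' sporadic missingness in covariates.
#'
#' @param df A data.frame.
#' @return The data.frame with missing entries filled.
#' @export
impute_simple <- function(df) {
  for (nm in names(df)) {
    x <- df[[nm]]
    if (!anyNA(x)) next
    if (is.numeric(x)) {
      x[is.na(x)] <- stats::median(x, na.rm = TRUE)
    } else {
      tab <- sort(table(x), decreasing = TRUE)
      x[is.na(x)] <- names(tab)[1]
    }
    df[[nm]] <- x
  }
  df
}
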