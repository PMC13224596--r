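#' Standard covariate set for the eGFR models
#'
#' Age, total energy intake, physical activity, smoking habit, education,
#' BMI and special diet — the confounder set used by every association
#' model. Optional extra continuous confounders (e.g. ancestry components on
#' real data) can be appended by name.
#' @keywords internal
default_covariates <- c("age", "tei", "physical_activity", "smoking",
                        "education", "bmi", "special_diet")

z_standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-standardize a constant exposure")
  (x - mean(x)) / s
}

prep_model_frame <- function(data, exposure, covariates) {
  miss <- setdiff(c(exposure, covariates, "egfr"), names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- data[c("egfr", exposure, covariates)]
  # categorical covariates dummy-coded against the alphabetically first level
  for (nm in names(df)) {
    if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]], levels = sort(unique(df[[nm]])))
  }
  df$.score <- z_standardize(df[[exposure]])
  df
}

#' Linear DP-eGFR association in one stratum
#'
#' OLS of eGFR on a z-standardized dietary score (mean 0, SD 1 within the
#' analysis stratum) plus the standard covariates. The reported effect is
#' ml/min/1.73 m^2 per 1-SD of the score, with a t-based 95% CI.
#'
#' @param data Data.frame for one stratum, containing `egfr`, the exposure
#'   column and the covariates.
#' @param exposure Name of the score column (`"dash"`, `"DP1"`, ...).
#' @param covariates Covariate column names; defaults to the standard set.
#' @param conf_level Confidence level.
#' @return List of class `"association_result"`: `beta`, `ci`, `p`, `se`,
#'   `n`, `exposure`, `model = "lm"`.
#' @export
fit_linear <- function(data, exposure, covariates = default_covariates,
                       conf_level = 0.95) {
  df <- prep_model_frame(data, exposure, covariates)
  form <- stats::reformulate(c(".score", covariates), response = "egfr")
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  est <- sm[".score", ]
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
  structure(list(beta = unname(est["Estimate"]), se = unname(est["Std. Error"]),
                 ci = unname(est["Estimate"] + c(-1, 1) * tq * est["Std. Error"]),
                 p = unname(est["Pr(>|t|)"]), n = nrow(df),
                 exposure = exposure, model = "lm", fit = fit),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  if (x$model == "lm") {
    cat(sprintf("%s [LM, n = %d]: beta = %.3f (%.3f, %.3f), p = %.4g\n",
                x$exposure, x$n, x$beta, x$ci[1], x$ci[2], x$p))
  } else {
    cat(sprintf("%s [GAM, n = %d]: edf = %.2f, p = %.4g\n",
                x$exposure, x$n, x$edf, x$p))
  }
  invisible(x)
}

#' Penalized-spline DP-eGFR association in one stratum
#'
#' Generalized additive model `egfr ~ s(score) + s(age) + covariates` with
#' penalized cubic regression splines and smoothing parameters chosen by
#' REML. Reports the score smooth's effective degrees of freedom (edf ~ 1
#' means an essentially linear relation) and its approximate p-value.
#'
#' @inheritParams fit_linear
#' @param k Basis dimension per smooth (default 10; reduced automatically
#'   when the stratum is small).
#' @param sp Optional fixed smoothing parameters `c(score, age)`; e.g. very
#'   large values force both smooths to their linear null space, collapsing
#'   the fit onto the linear model.
#' @return `"association_result"` with `edf`, `p` (smooth test), `n`,
#'   and the underlying `mgcv` fit.
#' @export
fit_smooth <- function(data, exposure, covariates = default_covariates,
                       k = 10, sp = NULL) {
  df <- prep_model_frame(data, exposure, covariates)
  k_use <- min(k, max(4, floor(nrow(df) / 4)))
  lin_cov <- setdiff(covariates, "age")
  form <- stats::as.formula(paste(
    "egfr ~ s(.score, bs = \"cr\", k = ", k_use,
    ") + s(age, bs = \"cr\", k = ", k_use, ")",
    if (length(lin_cov)) paste(" +", paste(lin_cov, collapse = " + "))))
  fit <- mgcv::gam(form, data = df, method = "REML", sp = sp)
  sm <- summary(fit)
  structure(list(edf = unname(sm$edf[1]), p = unname(sm$s.pv[1]),
                 edf_age = unname(sm$edf[2]), n = nrow(df),
                 beta = NA_real_, ci = c(NA_real_, NA_real_),
                 exposure = exposure, model = "gam", fit = fit),
            class = "association_result")
}

#' Effect modification by menstrual status and age
#'
#' Female-only models adding `score x menstrual_status` and `score x age`
#' interaction terms to the adjusted linear model, one model per score.
#' The menstrual-status interaction coefficient is the additional
#' ml/min/1.73 m^2 per 1-SD of the score in the ceased-menstruation group
#' (reference level "yes", i.e. still menstruating).
#'
#' @param data Female stratum with columns `egfr`, the scores,
#'   `menstrual_status` in `{"yes","no"}` and the covariates.
#' @param scores Character vector of score column names.
#' @param covariates Covariates; defaults to the standard set.
#' @param reference Reference level of menstrual status (default "yes").
#' @return Data.frame: one row per score with the status-interaction
#'   estimate, CI, p, plus the age-interaction estimate and p.
#' @export
fit_interactions <- function(data, scores, covariates = default_covariates,
                             reference = "yes") {
  if (!"menstrual_status" %in% names(data))
    stop("'menstrual_status' column required")
  lev <- unique(data$menstrual_status)
  if (length(lev) < 2) stop("menstrual_status has a single level in data")
  out <- vector("list", length(scores))
  for (i in seq_along(scores)) {
    df <- prep_model_frame(data, scores[i], covariates)
    df$menstrual_status <- factor(data$menstrual_status,
                                  levels = c(reference,
                                             setdiff(sort(lev), reference)))
    form <- stats::reformulate(
      c(".score * menstrual_status", ".score:age", covariates),
      response = "egfr")
    fit <- stats::lm(form, data = df)
    sm <- summary(fit)$coefficients
    int_row <- grep("^\\.score:menstrual_status", rownames(sm))
    age_row <- grep("^\\.score:age$", rownames(sm))
    est <- sm[int_row, ]
    tq <- stats::qt(0.975, df = fit$df.residual)
    out[[i]] <- data.frame(
      score = scores[i],
      interaction_beta = unname(est["Estimate"]),
      ci_lo = unname(est["Estimate"] - tq * est["Std. Error"]),
      ci_hi = unname(est["Estimate"] + tq * est["Std. Error"]),
      p = unname(est["Pr(>|t|)"]),
      age_interaction_beta = unname(sm[age_row, "Estimate"]),
      age_interaction_p = unname(sm[age_row, "Pr(>|t|)"]),
      n = nrow(df), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Full stratified association grid
#'
#' Runs every score through the linear and the penalized-spline model in
#' each analysis stratum (males; all females; females by menstrual status),
#' optionally repeating the whole grid on the Healthy+ subsample (subjects
#' without sub-clinical diabetes, reduced kidney function or albuminuria).
#' Failures in individual cells are recorded and do not stop the grid.
#'
#' @param data Analysis sample with `egfr`, `sex`, `menstrual_status`,
#'   the score columns and covariates; for `healthy_plus = TRUE` also
#'   `hba1c` and `uacr`.
#' @param scores Score column names (default `c("dash", "DP1", "DP2")`).
#' @param covariates Covariates for every model.
#' @param healthy_plus Also run the sensitivity repeat.
#' @return Data.frame (tidy): `sample`, `stratum`, `score`, `model`, `beta`,
#'   `ci_lo`, `ci_hi`, `p`, `edf`, `n`, `error`.
#' @export
run_analysis_grid <- function(data, scores = c("dash", "DP1", "DP2"),
                              covariates = default_covariates,
                              healthy_plus = FALSE) {
  strata <- list(
    males = data$sex == "male",
    females = data$sex == "female",
    menstruation_yes = data$sex == "female" & data$menstrual_status == "yes",
    menstruation_no = data$sex == "female" & data$menstrual_status == "no")
  samples <- list(main = rep(TRUE, nrow(data)))
  if (healthy_plus) {
    excl <- flag_healthy_plus(data$hba1c, data$egfr, data$uacr)
    samples$healthy_plus <- !excl
  }
  rows <- list()
  for (sa in names(samples)) {
    for (st in names(strata)) {
      idx <- samples[[sa]] & strata[[st]]
      sub <- data[idx, , drop = FALSE]
      for (sc in scores) {
        for (mo in c("lm", "gam")) {
          res <- tryCatch({
            r <- if (mo == "lm") fit_linear(sub, sc, covariates)
                 else fit_smooth(sub, sc, covariates)
            data.frame(sample = sa, stratum = st, score = sc, model = mo,
                       beta = r$beta, ci_lo = r$ci[1], ci_hi = r$ci[2],
                       p = r$p, edf = if (mo == "gam") r$edf else NA_real_,
                       n = r$n, error = NA_character_,
                       stringsAsFactors = FALSE)
          }, error = function(e)
            data.frame(sample = sa, stratum = st, score = sc, model = mo,
                       beta = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                       p = NA_real_, edf = NA_real_, n = sum(idx),
                       error = conditionMessage(e), stringsAsFactors = FALSE))
          rows[[length(rows) + 1L]] <- res
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
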