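#' Mediator panel layout
#'
#' Names, measurement units, typical centres and spreads of the nine
#' cardio-renal-metabolic mediators used as RRR responses.
#' @keywords internal
mediator_layout <- function() {
  data.frame(
    mediator = c("hba1c", "map", "crp", "uric_acid", "tc",
                 "ferritin", "fibrinogen", "potassium", "hgb"),
    unit = c("%", "mmHg", "mg/dL", "mg/dL", "mg/dL",
             "ng/mL", "mg/dL", "mmol/L", "g/dL"),
    center = c(5.3, 88, 0.2, 5.2, 203, 80, 290, 3200, 14.8),
    unit_sd = c(0.35, 9, 0.15, 1.0, 35, 60, 45, 900, 1.2),
    stringsAsFactors = FALSE)
}

#' Configuration of the synthetic cohort generator
#'
#' Defines the statistical structure the analysis pipeline assumes:
#' TEI-correlated FFQ intakes discretized into the seven frequency
#' categories, a food-group-to-mediator linear structure (rank-1 by
#' default, i.e. one designated true dietary pattern per sex),
#' household-clustered mediators, assay-batch distortions, and an eGFR that
#' depends on the true pattern score with a planted menstrual-status
#' interaction.
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param seed Integer seed; fixed seed + config gives identical output.
#' @param n_items,n_groups FFQ items (229) and food groups (32).
#' @param sex_ratio Proportion of females, in (0, 1).
#' @param age_range Years, `c(min, max)`.
#' @param household_size_dist Named numeric: probabilities of household
#'   sizes (names = sizes).
#' @param tei_mean_sd_by_sex List `male = c(mean, sd)`, `female = c(mean,
#'   sd)` of target total energy intake, kcal/day.
#' @param mediator_weights Length-9 numeric: effect (in mediator SD units
#'   per SD of the true pattern score) of the designated pattern on each
#'   mediator. Used to build the default rank-1 group-effect matrix.
#' @param group_effect_matrix Optional explicit `n_groups x 9` matrix of
#'   linear effects of standardized group intakes on mediators (overrides
#'   the rank-1 default).
#' @param household_sd,noise_sd Between-household and residual mediator SDs
#'   (z scale); defaults 1 and 1, i.e. intraclass correlation 0.5.
#' @param dp_effect_on_egfr Named numeric `c(male=, female=)`:
#'   ml/min/1.73 m^2 per 1-SD of the true pattern score.
#' @param interaction_effect Additional ml/min/1.73 m^2 per 1-SD in the
#'   ceased-menstruation stratum.
#' @param egfr_noise_sd Residual eGFR SD.
#' @param batch_count Assay batches per biomarker (last = reference).
#' @param missing_rates List: `ffq`, `menstrual` proportions.
#' @param disease_flag_prevalence Named numeric prevalences for
#'   `kidney_disease`, `hypertension`, `diabetes` (medication flags are
#'   generated at 60% of each).
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 2000,
                          seed = 1L,
                          n_items = 229L,
                          n_groups = 32L,
                          sex_ratio = 0.534,
                          age_range = c(18, 80),
                          household_size_dist = c("1" = 0.30, "2" = 0.40,
                                                  "3" = 0.20, "4" = 0.10),
                          tei_mean_sd_by_sex = list(male = c(2000, 500),
                                                    female = c(1850, 450)),
                          mediator_weights = c(hba1c = -0.45, map = -0.50,
                                               crp = -0.40, uric_acid = -0.45,
                                               tc = -0.50, ferritin = -0.35,
                                               fibrinogen = -0.40,
                                               potassium = -0.30, hgb = -0.35),
                          group_effect_matrix = NULL,
                          household_sd = 1.0,
                          noise_sd = 1.0,
                          dp_effect_on_egfr = c(male = 1.0, female = 1.0),
                          interaction_effect = 2.0,
                          egfr_noise_sd = 9,
                          batch_count = 2L,
                          missing_rates = list(ffq = 0.01, menstrual = 0.01),
                          disease_flag_prevalence = c(kidney_disease = 0.01,
                                                      hypertension = 0.04,
                                                      diabetes = 0.02)) {
  cfg <- list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
              n_items = as.integer(n_items), n_groups = as.integer(n_groups),
              sex_ratio = sex_ratio, age_range = age_range,
              household_size_dist = household_size_dist,
              tei_mean_sd_by_sex = tei_mean_sd_by_sex,
              mediator_weights = mediator_weights,
              group_effect_matrix = group_effect_matrix,
              household_sd = household_sd, noise_sd = noise_sd,
              dp_effect_on_egfr = dp_effect_on_egfr,
              interaction_effect = interaction_effect,
              egfr_noise_sd = egfr_noise_sd,
              batch_count = as.integer(batch_count),
              missing_rates = missing_rates,
              disease_flag_prevalence = disease_flag_prevalence)
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, why) stop("invalid config field '", field, "': ",
                                    why, call. = FALSE)
  if (is.na(cfg$n_subjects) || cfg$n_subjects < 4)
    fail("n_subjects", "must be >= 4")
  if (is.na(cfg$seed)) fail("seed", "must be an integer")
  if (cfg$n_items < 8) fail("n_items", "must be >= 8")
  if (cfg$n_groups < 2 || cfg$n_groups > cfg$n_items)
    fail("n_groups", "must be in 2..n_items")
  if (!is.numeric(cfg$sex_ratio) || cfg$sex_ratio <= 0 || cfg$sex_ratio >= 1)
    fail("sex_ratio", "must be in (0, 1)")
  if (diff(cfg$age_range) <= 0 || cfg$age_range[1] <= 0)
    fail("age_range", "must be an increasing positive interval")
  if (any(cfg$household_size_dist < 0) ||
      abs(sum(cfg$household_size_dist) - 1) > 1e-8)
    fail("household_size_dist", "probabilities must be >= 0 and sum to 1")
  for (s in c("male", "female")) {
    ms <- cfg$tei_mean_sd_by_sex[[s]]
    if (is.null(ms) || length(ms) != 2 || ms[1] <= 0 || ms[2] < 0)
      fail("tei_mean_sd_by_sex", paste0("need positive c(mean, sd) for ", s))
  }
  if (length(cfg$mediator_weights) != 9 || any(!is.finite(cfg$mediator_weights)))
    fail("mediator_weights", "must be 9 finite values")
  if (!is.null(cfg$group_effect_matrix)) {
    gem <- cfg$group_effect_matrix
    if (!is.matrix(gem) || nrow(gem) != cfg$n_groups || ncol(gem) != 9 ||
        any(!is.finite(gem)))
      fail("group_effect_matrix", "must be a finite n_groups x 9 matrix")
  }
  if (cfg$household_sd < 0) fail("household_sd", "must be >= 0")
  if (cfg$noise_sd < 0) fail("noise_sd", "must be >= 0")
  if (cfg$egfr_noise_sd < 0) fail("egfr_noise_sd", "must be >= 0")
  if (!all(c("male", "female") %in% names(cfg$dp_effect_on_egfr)))
    fail("dp_effect_on_egfr", "needs named elements male and female")
  if (cfg$batch_count < 1) fail("batch_count", "must be >= 1")
  rates <- unlist(cfg$missing_rates)
  if (any(rates < 0 | rates >= 1)) fail("missing_rates", "must be in [0, 1)")
  if (any(cfg$disease_flag_prevalence < 0 | cfg$disease_flag_prevalence > 1))
    fail("disease_flag_prevalence", "must be in [0, 1]")
  structure(cfg, class = "cohort_config")
}

#' Synthetic food composition and mapping table
#'
#' Deterministic *synthetic* stand-in for a food-composition/portion table:
#' grams per portion, energy and sodium densities, item-to-group assignment
#' (each item belongs to exactly one of `n_groups` groups) and
#' item-to-DASH-component assignment for a fixed subset of groups.
#'
#' @param n_items,n_groups Counts.
#' @param seed Integer seed.
#' @return Data.frame: `item_id`, `grams_per_portion`, `group_id`,
#'   `dash_component`, `sodium_mg_per_100g`, `kcal_per_100g`.
#' @export
toy_composition <- function(n_items = 229L, n_groups = 32L, seed = 1L) {
  rng <- local_rng(seed)
  on.exit(rng())
  item_id <- sprintf("item_%03d", seq_len(n_items))
  group_id <- rep(seq_len(n_groups), length.out = n_items)
  dash_map <- c("1" = "fruits", "2" = "fruits", "3" = "vegetables",
                "4" = "vegetables", "5" = "whole_grains", "6" = "whole_grains",
                "7" = "low_fat_dairy", "8" = "nuts_legumes",
                "9" = "red_processed_meat", "10" = "red_processed_meat",
                "11" = "ssb")
  data.frame(
    item_id = item_id,
    grams_per_portion = round(stats::runif(n_items, 15, 250), 1),
    group_id = group_id,
    dash_component = unname(dash_map[as.character(group_id)]),
    sodium_mg_per_100g = round(stats::runif(n_items, 1, 900), 1),
    kcal_per_100g = round(stats::runif(n_items, 20, 450), 1),
    stringsAsFactors = FALSE)
}

# run code under a private RNG state, restoring the caller's stream
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a seeded synthetic cohort
#'
#' Simulates FFQ frequencies, a composition table, mediator biomarkers with
#' household clustering and assay-batch distortions, covariates and serum
#' creatinine with the generating truth attached. Mediators follow
#' `age effect + household intercept + group-effect x (standardized
#' energy-adjusted group intake) + noise`; creatinine is back-solved so that
#' the CKD-EPI 2021 equation returns `baseline(age, sex) + beta_sex x (true
#' score) + interaction x 1[ceased menstruation] x (true score) + noise`.
#'
#' @param config A [cohort_config()].
#' @return List of class `"synthetic_cohort"`: `ffq`, `composition`,
#'   `biomarkers`, `creatinine`, `covariates` data.frames keyed by
#'   `subject_id`, plus `truth` (generating parameters: per-sex true
#'   direction vectors, true scores, planted betas).
#' @export
generate_cohort <- function(config) {
  config <- validate_cohort_config(unclass(config))
  rng <- local_rng(config$seed)
  on.exit(rng())
  n <- config$n_subjects
  subject_id <- sprintf("S%05d", seq_len(n))

  sex <- ifelse(stats::runif(n) < config$sex_ratio, "female", "male")
  # ensure both sexes present (tiny-n edge)
  if (!any(sex == "male")) sex[1] <- "male"
  if (!any(sex == "female")) sex[1] <- "female"
  age <- stats::runif(n, config$age_range[1], config$age_range[2])

  sizes <- as.integer(names(config$household_size_dist))
  hh_sizes <- sample(sizes, n, replace = TRUE,
                     prob = config$household_size_dist)
  hh_id <- integer(n); cur <- 0L; i <- 1L
  while (i <= n) {
    cur <- cur + 1L
    k <- min(hh_sizes[cur %% n + 1L], n - i + 1L)
    hh_id[i:(i + k - 1L)] <- cur
    i <- i + k
  }
  household_id <- sprintf("H%05d", hh_id)

  weight <- ifelse(sex == "male", stats::rnorm(n, 78, 10),
                   stats::rnorm(n, 65, 9))
  weight <- pmax(weight, 40)
  height <- ifelse(sex == "male", stats::rnorm(n, 176, 7),
                   stats::rnorm(n, 163, 6))
  bmi <- weight / (height / 100)^2
  bmr <- compute_bmr(sex, age, weight)

  tei_pars <- config$tei_mean_sd_by_sex
  tei_target <- ifelse(sex == "male",
                       stats::rnorm(n, tei_pars$male[1], tei_pars$male[2]),
                       stats::rnorm(n, tei_pars$female[1], tei_pars$female[2]))
  tei_target <- pmax(tei_target, 800)

  composition <- toy_composition(config$n_items, config$n_groups,
                                 seed = config$seed + 1L)

  # latent item portions/day: item base level x subject energy factor x noise
  base <- stats::rlnorm(config$n_items, meanlog = log(0.12), sdlog = 1.0)
  efac <- tei_target / mean(tei_target)
  lambda <- outer(efac, base) *
    matrix(stats::rlnorm(n * config$n_items, 0, 0.8), n, config$n_items)
  kcal_per_portion <- composition$grams_per_portion *
    composition$kcal_per_100g / 100
  implied <- drop(lambda %*% kcal_per_portion)
  lambda <- lambda * (tei_target / implied)

  # discretize to the 7 frequency categories: cutpoints midway between the
  # category portion/day values
  f <- unname(ffq_frequency_map)
  cuts <- (utils::head(f, -1) + utils::tail(f, -1)) / 2
  codes <- matrix(findInterval(lambda, cuts), n, config$n_items)
  if (config$missing_rates$ffq > 0) {
    miss <- matrix(stats::runif(n * config$n_items) < config$missing_rates$ffq,
                   n, config$n_items)
    codes[miss] <- NA_integer_
  }
  ffq <- data.frame(subject_id = subject_id, codes, stringsAsFactors = FALSE)
  names(ffq) <- c("subject_id", composition$item_id)

  # self-consistent diet matrix (as the pipeline will recompute it)
  dm <- build_diet_matrix(ffq, composition)
  tei_obs <- pmax(dm$tei, 1)
  g_adj <- energy_adjust(dm$groups, tei_obs, sex)

  med <- mediator_layout()
  if (is.null(config$group_effect_matrix)) {
    dir_m <- stats::rnorm(config$n_groups)
    dir_f <- stats::rnorm(config$n_groups)
    dir_m <- dir_m / sqrt(sum(dir_m^2))
    dir_f <- dir_f / sqrt(sum(dir_f^2))
    direction <- list(male = dir_m, female = dir_f)
    eff <- list(male = outer(dir_m, config$mediator_weights),
                female = outer(dir_f, config$mediator_weights))
  } else {
    sv <- svd(config$group_effect_matrix)
    direction <- list(male = sv$u[, 1], female = sv$u[, 1])
    eff <- list(male = config$group_effect_matrix,
                female = config$group_effect_matrix)
  }

  true_score <- numeric(n)
  signal <- matrix(0, n, 9)
  for (s in c("male", "female")) {
    idx <- sex == s
    Z <- scale(g_adj[idx, , drop = FALSE])
    Z[!is.finite(Z)] <- 0
    raw <- drop(Z %*% direction[[s]])
    true_score[idx] <- if (stats::sd(raw) > 0) (raw - mean(raw)) / stats::sd(raw) else raw
    signal[idx, ] <- Z %*% eff[[s]]
  }

  hh_eff <- matrix(stats::rnorm(length(unique(household_id)) * 9,
                                sd = config$household_sd),
                   ncol = 9,
                   dimnames = list(unique(household_id), med$mediator))
  age_coef <- seq(0.01, 0.03, length.out = 9) * rep(c(1, -1), length.out = 9)
  z_med <- signal + hh_eff[household_id, ] +
    outer(age - mean(age), age_coef) +
    matrix(stats::rnorm(n * 9, sd = config$noise_sd), n, 9)
  values <- sweep(sweep(z_med, 2, med$unit_sd, `*`), 2, med$center, `+`)
  colnames(values) <- med$mediator

  # assay batches: earlier batches carry a location/scale distortion
  batches <- matrix(sample(seq_len(config$batch_count), n * 9, replace = TRUE),
                    n, 9)
  if (config$batch_count > 1) {
    for (j in seq_len(9)) {
      old <- batches[, j] < config$batch_count
      values[old, j] <- values[old, j] * 1.08 + 0.25 * med$unit_sd[j]
    }
  }
  biomarkers <- data.frame(subject_id = subject_id, values,
                           stringsAsFactors = FALSE)
  bcols <- as.data.frame(batches)
  names(bcols) <- paste0("batch_", med$mediator)
  biomarkers <- cbind(biomarkers, bcols)

  # menstrual status: deterministic below/above a 45-55 y transition band
  menstrual_status <- rep(NA_character_, n)
  fem <- sex == "female"
  p_ceased <- pmin(pmax((age - 45) / 10, 0), 1)
  menstrual_status[fem] <- ifelse(stats::runif(sum(fem)) < p_ceased[fem],
                                  "no", "yes")
  if (config$missing_rates$menstrual > 0) {
    mm <- fem & stats::runif(n) < config$missing_rates$menstrual
    menstrual_status[mm] <- NA_character_
  }

  prev <- config$disease_flag_prevalence
  flags <- data.frame(
    kidney_disease = stats::runif(n) < prev["kidney_disease"],
    hypertension = stats::runif(n) < prev["hypertension"],
    diabetes = stats::runif(n) < prev["diabetes"])
  flags$kidney_medication <- flags$kidney_disease & stats::runif(n) < 0.6
  flags$hypertension_medication <- flags$hypertension & stats::runif(n) < 0.6
  flags$diabetes_medication <- flags$diabetes & stats::runif(n) < 0.6

  covariates <- data.frame(
    subject_id = subject_id, age = age, sex = sex, bmi = bmi,
    weight = weight, height = height,
    physical_activity = stats::rlnorm(n, log(3000), 0.6),
    smoking = sample(c("never", "current", "past"), n, TRUE,
                     prob = c(0.56, 0.20, 0.24)),
    education = sample(c("primary", "lower_secondary", "vocational",
                         "upper_secondary", "university"), n, TRUE,
                       prob = c(0.05, 0.15, 0.42, 0.27, 0.11)),
    special_diet = ifelse(stats::runif(n) < 0.038, "yes", "no"),
    household_id = household_id,
    menstrual_status = menstrual_status,
    uacr = stats::rlnorm(n, log(8), 0.9),
    tei = tei_obs, bmr = bmr,
    flags, stringsAsFactors = FALSE)

  beta <- config$dp_effect_on_egfr
  baseline <- ifelse(sex == "male", 107, 103) - 0.45 * (age - 40)
  ceased <- fem & !is.na(menstrual_status) & menstrual_status == "no"
  egfr_true <- baseline + unname(beta[sex]) * true_score +
    config$interaction_effect * ceased * true_score +
    stats::rnorm(n, sd = config$egfr_noise_sd)
  egfr_true <- pmax(egfr_true, 5)
  creatinine <- data.frame(subject_id = subject_id,
                           creatinine = invert_egfr(egfr_true, age, sex),
                           stringsAsFactors = FALSE)

  truth <- list(
    direction = direction,
    true_score = stats::setNames(true_score, subject_id),
    dp_effect_on_egfr = as.list(config$dp_effect_on_egfr),
    interaction_effect = config$interaction_effect,
    mediator_weights = as.list(config$mediator_weights),
    household_sd = config$household_sd, noise_sd = config$noise_sd,
    egfr_noise_sd = config$egfr_noise_sd,
    egfr_baseline = list(male = 107, female = 103, age_slope = -0.45),
    seed = config$seed)

  structure(list(ffq = ffq, composition = composition,
                 biomarkers = biomarkers, creatinine = creatinine,
                 covariates = covariates, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort: n =", nrow(x$covariates), "subjects,",
      x$config$n_items, "FFQ items,", x$config$n_groups, "food groups\n")
  cat("  females:", sum(x$covariates$sex == "female"),
      " households:", length(unique(x$covariates$household_id)), "\n")
  cat("  planted eGFR effect (per 1-SD):",
      sprintf("male %.2f, female %.2f; interaction %.2f\n",
              x$truth$dp_effect_on_egfr$male, x$truth$dp_effect_on_egfr$female,
              x$truth$interaction_effect))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes `ffq.csv`, `composition.tsv`, `biomarkers.csv`, `covariates.csv`,
#' `creatinine.csv` and `truth.json` into `directory`. The files round-trip
#' losslessly through [read_cohort()].
#'
#' @param cohort A `"synthetic_cohort"`.
#' @param directory Existing writable directory.
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, directory) {
  if (!dir.exists(directory))
    stop("directory does not exist: ", directory)
  paths <- c(
    ffq = file.path(directory, "ffq.csv"),
    composition = file.path(directory, "composition.tsv"),
    biomarkers = file.path(directory, "biomarkers.csv"),
    covariates = file.path(directory, "covariates.csv"),
    creatinine = file.path(directory, "creatinine.csv"),
    truth = file.path(directory, "truth.json"))
  utils::write.csv(cohort$ffq, paths["ffq"], row.names = FALSE)
  utils::write.table(cohort$composition, paths["composition"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$biomarkers, paths["biomarkers"], row.names = FALSE)
  utils::write.csv(cohort$covariates, paths["covariates"], row.names = FALSE)
  utils::write.csv(cohort$creatinine, paths["creatinine"], row.names = FALSE)
  truth <- cohort$truth
  truth$direction <- lapply(truth$direction, as.numeric)
  truth$true_score <- as.list(truth$true_score)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory Directory holding the cohort files.
#' @return A `"synthetic_cohort"`-shaped list (without the generator
#'   config); `truth` is `NULL` when `truth.json` is absent, as for a real
#'   data export.
#' @export
read_cohort <- function(directory) {
  need <- c("ffq.csv", "composition.tsv", "biomarkers.csv",
            "covariates.csv", "creatinine.csv")
  missing_f <- need[!file.exists(file.path(directory, need))]
  if (length(missing_f))
    stop("missing cohort file(s) in ", directory, ": ",
         paste(missing_f, collapse = ", "))
  ffq <- utils::read.csv(file.path(directory, "ffq.csv"),
                         stringsAsFactors = FALSE, check.names = FALSE)
  covariates <- utils::read.csv(file.path(directory, "covariates.csv"),
                                stringsAsFactors = FALSE)
  for (nm in grep("disease|medication|hypertension|diabetes",
                  names(covariates), value = TRUE))
    covariates[[nm]] <- as.logical(covariates[[nm]])
  truth_path <- file.path(directory, "truth.json")
  truth <- if (file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    tr$true_score <- unlist(tr$true_score)
    tr
  } else NULL
  structure(list(
    ffq = ffq,
    composition = utils::read.table(file.path(directory, "composition.tsv"),
                                    sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE),
    biomarkers = utils::read.csv(file.path(directory, "biomarkers.csv"),
                                 stringsAsFactors = FALSE),
    creatinine = utils::read.csv(file.path(directory, "creatinine.csv"),
                                 stringsAsFactors = FALSE),
    covariates = covariates, truth = truth),
    class = "synthetic_cohort")
}
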