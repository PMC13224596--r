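test_that("config validation names the offending field", {
  expect_error(cohort_config(n_subjects = 2), "n_subjects")
  expect_error(cohort_config(sex_ratio = 1.2), "sex_ratio")
  expect_error(cohort_config(household_sd = -1), "household_sd")
  expect_error(cohort_config(group_effect_matrix = matrix(Inf, 32, 9)),
               "group_effect_matrix")
  expect_error(cohort_config(missing_rates = list(ffq = 1, menstrual = 0)),
               "missing_rates")
})

test_that("identical config and seed give identical cohorts; seeds differ", {
  a <- tiny_cohort(n = 150, seed = 21)
  b <- tiny_cohort(n = 150, seed = 21)
  for (blk in c("ffq", "composition", "biomarkers", "creatinine", "covariates"))
    expect_identical(a[[blk]], b[[blk]])
  expect_identical(a$truth$true_score, b$truth$true_score)
  c <- tiny_cohort(n = 150, seed = 22)
  expect_false(identical(a$ffq, c$ffq))
  # generation leaves the caller's RNG stream untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(tiny_cohort(n = 50, seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("zero effect matrices leave mediators unlinked to food-group intakes", {
  n <- 2500
  co <- generate_cohort(cohort_config(
    n_subjects = n, seed = 23, group_effect_matrix = matrix(0, 32, 9),
    missing_rates = list(ffq = 0, menstrual = 0)))
  dm <- build_diet_matrix(co$ffq, co$composition)
  med <- as.matrix(co$biomarkers[c("hba1c", "map", "crp", "tc", "hgb")])
  # pre-chosen pairs stay within a 3/sqrt(n) null band
  picked <- cbind(group = c(1, 7, 13, 22, 30), mediator = c(1, 2, 3, 4, 5))
  for (i in seq_len(nrow(picked))) {
    r <- cor(dm$groups[, picked[i, 1]], med[, picked[i, 2]])
    expect_lt(abs(r), 3 / sqrt(n))
  }
  # and even the largest of all 32 x 5 correlations is null-compatible
  allcor <- abs(cor(dm$groups, med))
  expect_lt(max(allcor), 4.5 / sqrt(n))
})

test_that("cohort structure matches its documented schema and truth is complete", {
  co <- tiny_cohort(n = 200, seed = 24)
  expect_length(grep("^item_", names(co$ffq)), 229)
  expect_identical(nrow(co$composition), 229L)
  expect_identical(sort(unique(co$composition$group_id)), 1:32)
  # every item maps to exactly one group
  expect_false(anyNA(co$composition$group_id))
  expect_true(all(co$creatinine$creatinine > 0))
  expect_true(all(table(co$ffq$subject_id) == 1))
  med <- c("hba1c", "map", "crp", "uric_acid", "tc", "ferritin",
           "fibrinogen", "potassium", "hgb")
  expect_true(all(med %in% names(co$biomarkers)))
  expect_true(all(paste0("batch_", med) %in% names(co$biomarkers)))
  # truth carries everything needed for recovery checks
  expect_named(co$truth$dp_effect_on_egfr, c("male", "female"))
  expect_length(co$truth$direction$female, 32)
  expect_length(co$truth$true_score, 200)
  # FFQ categories restricted to the 7-level set
  codes <- unlist(co$ffq[grep("^item_", names(co$ffq))])
  expect_true(all(is.na(codes) | codes %in% 0:6))
  # menstrual status only defined for females, deterministic outside 45-55
  cv <- co$covariates
  expect_true(all(is.na(cv$menstrual_status[cv$sex == "male"])))
  young <- cv$sex == "female" & cv$age < 45 & !is.na(cv$menstrual_status)
  old <- cv$sex == "female" & cv$age > 55 & !is.na(cv$menstrual_status)
  expect_true(all(cv$menstrual_status[young] == "yes"))
  expect_true(all(cv$menstrual_status[old] == "no"))
})

test_that("cohorts round-trip through disk unchanged and truth JSON lists planted betas", {
  co <- tiny_cohort(n = 60, seed = 25)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  for (blk in c("ffq", "biomarkers", "creatinine"))
    expect_equal(back[[blk]], co[[blk]], tolerance = 1e-10,
                 ignore_attr = TRUE)
  expect_equal(back$covariates$tei, co$covariates$tei, tolerance = 1e-10)
  expect_identical(back$covariates$menstrual_status,
                   co$covariates$menstrual_status)
  tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  expect_true(all(c("dp_effect_on_egfr", "interaction_effect",
                    "mediator_weights", "direction") %in% names(tr)))
  expect_equal(tr$dp_effect_on_egfr[["male"]], 1)
  expect_equal(tr$interaction_effect, 2)
  expect_error(write_cohort(co, file.path(dir, "does_not_exist")),
               "does_not_exist")
})

test_that("household clustering yields the configured intraclass correlation", {
  co <- generate_cohort(cohort_config(
    n_subjects = 10000, seed = 26, group_effect_matrix = matrix(0, 32, 9),
    household_sd = 1, noise_sd = 1, batch_count = 1L,
    household_size_dist = c("2" = 0.5, "3" = 0.3, "4" = 0.2)))
  adj <- adjust_mediators(cbind(m = co$biomarkers$tc), co$covariates$age,
                          co$covariates$household_id)
  icc <- adj$varcomp$sd_household^2 /
    (adj$varcomp$sd_household^2 + adj$varcomp$sd_residual^2)
  expect_equal(icc, 0.5, tolerance = 0.05)
})
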