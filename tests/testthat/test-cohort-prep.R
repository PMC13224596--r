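test_that("eGFR matches independent evaluation of the CKD-EPI 2021 closed form", {
  cases <- list(list(0.9, 40, "male"), list(0.7, 50, "female"),
                list(1.4, 65, "male"), list(0.5, 25, "female"),
                list(2.3, 71, "female"))
  for (cs in cases) {
    expect_equal(compute_egfr(cs[[1]], cs[[2]], cs[[3]]),
                 oracle_egfr(cs[[1]], cs[[2]], cs[[3]]), tolerance = 1e-12)
  }
  # frozen hand values: 142 * 0.9938^40 = 110.73...; female case ~105.3
  expect_equal(compute_egfr(0.9, 40, "male"), 110.7256, tolerance = 1e-4)
  expect_equal(compute_egfr(0.7, 50, "female"), 105.2976, tolerance = 1e-4)
  # at the knot with age -> 0, male value approaches the level constant 142
  expect_equal(compute_egfr(0.9, 1e-9, "male"), 142, tolerance = 1e-6)
})

test_that("eGFR is continuous at the creatinine knot and monotone decreasing", {
  eps <- 1e-12
  for (s in c("male", "female")) {
    kappa <- if (s == "male") 0.9 else 0.7
    expect_equal(compute_egfr(kappa - eps, 45, s),
                 compute_egfr(kappa + eps, 45, s), tolerance = 1e-9)
  }
  scr <- seq(0.3, 3, by = 0.05)
  expect_true(all(diff(compute_egfr(scr, 50, rep("female", length(scr)))) < 0))
  ages <- seq(20, 90, by = 1)
  expect_true(all(diff(compute_egfr(rep(1, length(ages)), ages,
                                    rep("male", length(ages)))) < 0))
  expect_error(compute_egfr(-1, 40, "male"), "creatinine")
  expect_error(compute_egfr(1, 0, "male"), "age")
})

test_that("inverting the eGFR equation round-trips on both branches", {
  age <- c(25, 40, 60, 75); sex <- c("male", "female", "male", "female")
  egfr <- c(130, 95, 60, 25)  # spans both creatinine branches
  scr <- invert_egfr(egfr, age, sex)
  expect_equal(compute_egfr(scr, age, sex), egfr, tolerance = 1e-10)
  expect_true(all(scr > 0))
})

test_that("menstrual status imputation follows the strict >50 years rule", {
  expect_identical(impute_menstrual_status("missing", 51), "no")
  expect_identical(impute_menstrual_status(NA_character_, 51), "no")
  expect_identical(impute_menstrual_status("missing", 50), "yes")
  expect_identical(impute_menstrual_status("yes", 70), "yes")
  expect_identical(impute_menstrual_status("no", 30), "no")
  expect_identical(impute_menstrual_status(c("yes", NA, "no", NA),
                                           c(60, 49, 20, 50.01)),
                   c("yes", "yes", "no", "no"))
})

test_that("Schofield BMR matches published band constants and is monotone in weight", {
  # 30-60 y male band: 11.472 * W + 873.1
  expect_equal(compute_bmr("male", 30, 70), 11.472 * 70 + 873.1)
  # 18-30 female band: 14.818 * W + 486.6
  expect_equal(compute_bmr("female", 22, 60), 14.818 * 60 + 486.6)
  expect_identical(compute_bmr("male", 45, 80), compute_bmr("male", 50, 80))
  expect_gt(compute_bmr("female", 40, 75), compute_bmr("female", 40, 60))
  expect_error(compute_bmr("male", 30, 70, equation = "harris"),
               "unsupported")
})

test_that("exclusion cascade removes flagged, incomplete and implausible reports in order", {
  co <- tiny_cohort(n = 10, seed = 3,
                    disease_flag_prevalence = c(kidney_disease = 0,
                                                hypertension = 0, diabetes = 0),
                    missing_rates = list(ffq = 0, menstrual = 0))
  co$covariates$hypertension[4] <- TRUE
  res <- apply_exclusions(co, tei_bmr_quantiles = c(0, 1))
  expect_identical(unname(res$report$counts["disease_or_medication"]), 1L)
  expect_identical(res$report$remaining_n, 9L)
  expect_false("S00004" %in% res$sample$covariates$subject_id)

  # 47/229 missing items (20.5%) excluded, 45/229 (19.7%) retained
  co2 <- tiny_cohort(n = 12, seed = 4,
                     disease_flag_prevalence = c(kidney_disease = 0,
                                                 hypertension = 0, diabetes = 0),
                     missing_rates = list(ffq = 0, menstrual = 0))
  item_cols <- grep("^item_", names(co2$ffq), value = TRUE)
  expect_length(item_cols, 229)
  co2$ffq[1, item_cols[1:47]] <- NA
  co2$ffq[2, item_cols[1:45]] <- NA
  res2 <- apply_exclusions(co2, tei_bmr_quantiles = c(0, 1))
  expect_identical(unname(res2$report$counts["ffq_missing"]), 1L)
  expect_false(co2$ffq$subject_id[1] %in% res2$sample$ffq$subject_id)
  expect_true(co2$ffq$subject_id[2] %in% res2$sample$ffq$subject_id)
  # residual missingness imputed as zero consumption
  expect_false(anyNA(res2$sample$ffq[item_cols]))
  expect_true(all(res2$sample$ffq[res2$sample$ffq$subject_id ==
                                    co2$ffq$subject_id[2], item_cols[1:45]] == 0))
})

test_that("TEI/BMR percentile filter matches a brute-force percentile check", {
  co <- tiny_cohort(n = 1000, seed = 11,
                    disease_flag_prevalence = c(kidney_disease = 0,
                                                hypertension = 0, diabetes = 0),
                    missing_rates = list(ffq = 0, menstrual = 0))
  res <- apply_exclusions(co)
  ratio <- co$covariates$tei / co$covariates$bmr
  qs <- quantile(ratio, c(0.005, 0.995), type = 7, names = FALSE)
  outside <- co$covariates$subject_id[ratio < qs[1] | ratio > qs[2]]
  expect_identical(unname(res$report$counts["tei_bmr_outlier"]),
                   length(outside))
  expect_true(all(!outside %in% res$sample$covariates$subject_id))
  expect_lte(res$report$counts["tei_bmr_outlier"], 12)  # ~1% of n
  # counts form a partition of the input
  expect_identical(sum(res$report$counts) + res$report$remaining_n, 1000L)
})

test_that("Healthy+ mask applies the three strict clauses row-wise", {
  tab <- data.frame(
    hba1c = c(6.6, 6.5, 5.4, 5.4, 5.4, 5.4, 5.2, 5.0),
    egfr = c(95, 60, 59, 60, 95, 95, 100, 110),
    uacr = c(10, 30, 10, 30, 31, 30, 5, 29))
  mask <- flag_healthy_plus(tab$hba1c, tab$egfr, tab$uacr)
  expect_identical(mask, c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(sum(mask), 3L)  # one violation per clause
  expect_error(flag_healthy_plus(tab$hba1c, tab$egfr, NULL), "UACR")
  # mmol/mol switch moves the HbA1c cutoff to 48
  expect_true(flag_healthy_plus(49, 95, 10, hba1c_scale = "mmol/mol"))
  expect_false(flag_healthy_plus(48, 95, 10, hba1c_scale = "mmol/mol"))
})

test_that("median/mode fallback imputer fills residual missingness", {
  df <- data.frame(a = c(1, NA, 3), b = c("x", "x", NA),
                   stringsAsFactors = FALSE)
  out <- impute_simple(df)
  expect_identical(out$a, c(1, 2, 3))
  expect_identical(out$b, c("x", "x", "x"))
})
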