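# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# CKD-EPI 2021 closed form, written out literally
oracle_egfr <- function(scr, age, sex) {
  if (sex == "male") {
    kappa <- 0.9; alpha <- -0.302; mult <- 1
  } else {
    kappa <- 0.7; alpha <- -0.241; mult <- 1.012
  }
  142 * min(scr / kappa, 1)^alpha * max(scr / kappa, 1)^(-1.200) *
    0.9938^age * mult
}

# Profiled REML deviance for y = Xb + Z u + e, u ~ N(0, theta^2 sigma^2 I),
# as a function of theta = sd_u / sd_e (one-dimensional criterion).
oracle_reml_deviance <- function(theta, y, xmat, group) {
  Z <- outer(group, sort(unique(group)), `==`) * 1
  n <- length(y); p <- ncol(xmat)
  V <- theta^2 * tcrossprod(Z) + diag(n)
  Vi <- solve(V)
  XtVi <- crossprod(xmat, Vi)
  beta <- solve(XtVi %*% xmat, XtVi %*% y)
  r <- y - xmat %*% beta
  s2 <- drop(crossprod(r, Vi %*% r)) / (n - p)
  as.numeric(determinant(V)$modulus + determinant(XtVi %*% xmat)$modulus +
               (n - p) * log(s2) + (n - p))
}

# small self-consistent cohort for pipeline-level tests
tiny_cohort <- function(n = 400, seed = 7, ...) {
  generate_cohort(cohort_config(n_subjects = n, seed = seed, ...))
}

# planted-effect data frame for association-module tests (no FFQ machinery)
planted_frame <- function(n, beta = 0, interaction = 0, noise_sd = 9,
                          curvature = 0, females_only = FALSE) {
  sex <- if (females_only) rep("female", n)
         else sample(c("male", "female"), n, TRUE)
  age <- runif(n, 18, 80)
  score <- rnorm(n)
  status <- ifelse(sex == "female" & runif(n) < pmin(pmax((age - 45) / 10, 0), 1),
                   "no", "yes")
  egfr <- 100 - 0.4 * (age - 40) + beta * score +
    interaction * (status == "no") * score + curvature * score^2 +
    rnorm(n, sd = noise_sd)
  data.frame(
    egfr = egfr, score = score, age = age, sex = sex,
    menstrual_status = status,
    tei = rnorm(n, 2000, 400),
    physical_activity = rlnorm(n, 8, 0.5),
    smoking = sample(c("never", "current", "past"), n, TRUE),
    education = sample(c("primary", "vocational", "university"), n, TRUE),
    bmi = rnorm(n, 25, 3),
    special_diet = sample(c("yes", "no"), n, TRUE, prob = c(0.05, 0.95)),
    stringsAsFactors = FALSE)
}
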