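test_that("quantile normalization maps batches onto the reference distribution", {
  x <- c(10, 20, 30, 40, 50)
  expect_identical(quantile_normalize_batches(x, rep("b1", 5)), x)

  # batch A = reference + constant shift, same n: normalized A equals the
  # reference's values at matched ranks (hand mapping, n = 5)
  ref <- c(1, 3, 5, 7, 9)
  shifted <- ref + 100
  values <- c(shifted, ref)
  batch <- rep(c("a", "b"), each = 5)
  out <- quantile_normalize_batches(values, batch, reference = "b")
  # mid-rank positions p = (1:5 - 0.5)/5 on the reference ecdf (type 7):
  hand <- quantile(ref, probs = (1:5 - 0.5) / 5, type = 7, names = FALSE)
  expect_equal(out[1:5], hand)
  expect_identical(out[6:10], ref)
  # monotone map: within-batch rank order preserved
  set.seed(5)
  v <- rnorm(60); b <- rep(c("a", "z"), each = 30)
  o <- quantile_normalize_batches(v, b)
  expect_identical(rank(o[b == "a"]), rank(v[b == "a"]))
  expect_error(quantile_normalize_batches(v, b, reference = "q"), "empty")
})

test_that("mediator adjustment reduces to OLS residuals when there is no household variance", {
  set.seed(2)
  n <- 300
  age <- runif(n, 20, 70)
  hh <- rep(sprintf("H%03d", 1:100), each = 3)
  e <- rnorm(n)
  e <- e - ave(e, hh)                      # no between-household variance
  y <- 5 + 0.1 * age + e                   # sigma_u estimate pinned at 0
  adj <- adjust_mediators(cbind(m = y), age, hh)
  ols <- residuals(lm(y ~ age))
  expect_equal(unname(adj$adjusted[, 1]), unname(ols), tolerance = 1e-6)
  # residuals orthogonal to age in every case
  expect_lt(abs(cor(adj$adjusted[, 1], age)), 1e-6)
})

test_that("balanced one-way REML variance components match the ANOVA closed form", {
  set.seed(3)
  k <- 40; m <- 5                          # 40 households x 5 members
  hh <- rep(sprintf("H%02d", 1:k), each = m)
  u <- rep(rnorm(k, sd = 1.3), each = m)
  y <- 10 + u + rnorm(k * m, sd = 0.8)
  grand <- mean(y)
  gm <- tapply(y, hh, mean)
  msb <- m * sum((gm - grand)^2) / (k - 1)
  msw <- sum((y - gm[hh])^2) / (k * (m - 1))
  sigma_e2 <- msw
  sigma_u2 <- (msb - msw) / m
  fit <- adjust_mediators(cbind(m1 = y), age = NULL, household_id = hh)
  expect_equal(fit$varcomp$sd_residual^2, sigma_e2, tolerance = 1e-4)
  expect_equal(fit$varcomp$sd_household^2, sigma_u2, tolerance = 1e-4)
})

test_that("REML optimum matches a brute-force grid search on tiny data", {
  set.seed(4)
  hh <- rep(c("a", "b", "c"), each = 3)    # 3 households x 3 members
  age <- rnorm(9, 40, 10)
  y <- 3 + 0.05 * age + rep(rnorm(3, sd = 1), each = 3) + rnorm(9, 0.7)
  fit <- adjust_mediators(cbind(m1 = y), age, hh)
  theta_hat <- fit$varcomp$sd_household / fit$varcomp$sd_residual
  xmat <- cbind(1, age)
  dev_hat <- oracle_reml_deviance(theta_hat, y, xmat, hh)
  grid <- seq(0, 5, by = 0.001)
  dev_grid <- vapply(grid, oracle_reml_deviance, numeric(1), y = y,
                     xmat = xmat, group = hh)
  expect_lte(dev_hat, min(dev_grid) + 1e-6)
})

test_that("rrr recovers a noiseless single-pattern structure exactly", {
  set.seed(6)
  n <- 120
  X <- matrix(rnorm(n * 6), n, 6)
  w <- c(2, -1, 0.5, 0, 1, -2)
  y1 <- drop(X %*% w)
  # single noiseless response: the one pattern is exactly X w
  fit1 <- rrr(X, cbind(y1 = y1), rank = 1)
  expect_gt(abs(cor(fit1$scores[, 1], y1)), 1 - 1e-10)
  expect_equal(sum(fit1$explained_share), 1, tolerance = 1e-10)
  # alongside a noise response, the retained score space still carries the
  # noiseless column completely
  fit2 <- rrr(X, cbind(y1 = y1, y2 = rnorm(n)), rank = 2)
  proj <- qr.fitted(qr(cbind(1, fit2$scores)), drop(scale(y1)))
  r2_y1 <- sum((proj - mean(proj))^2) / sum(scale(y1)^2)
  expect_equal(r2_y1, 1, tolerance = 1e-10)
})

test_that("rrr eigen solution matches numeric maximization of explained response variance", {
  set.seed(8)
  n <- 50; p <- 3; q <- 2
  X <- matrix(rnorm(n * p), n, p)
  Y <- cbind(X %*% c(1, 0.5, -0.5) + rnorm(n, sd = 0.8),
             X %*% c(-0.5, 1, 0.2) + rnorm(n, sd = 0.8))
  fit <- rrr(X, Y, rank = q)
  Xs <- scale(X); Ys <- scale(Y)
  # oracle: maximize a'X'YY'Xa / a'X'Xa over unit predictor weights
  f <- function(a) {
    s <- Xs %*% a
    -drop(crossprod(crossprod(Ys, s))) / drop(crossprod(s))
  }
  best <- Inf; best_a <- NULL
  for (i in 1:20) {
    st <- rnorm(p)
    o <- optim(st / sqrt(sum(st^2)), f, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
    if (o$value < best) { best <- o$value; best_a <- o$par }
  }
  expect_equal(-best, fit$eigenvalues[1], tolerance = 1e-6)
  a1 <- fit$a[, 1] / sqrt(sum(fit$a[, 1]^2))
  best_a <- best_a / sqrt(sum(best_a^2))
  expect_gt(abs(sum(a1 * best_a)), 1 - 1e-6)

  # with K = q the explained share equals the multivariate OLS R^2
  expect_equal(sum(fit$explained_share),
               sum(fitted(lm(Ys ~ Xs))^2) / sum(Ys^2), tolerance = 1e-10)
  expect_equal(sum(fit$explained_share), fit$total_r2, tolerance = 1e-12)
})

test_that("retained pattern scores are uncorrelated and shares non-increasing", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200
    X <- matrix(rnorm(n * 10), n, 10)
    Y <- X %*% matrix(rnorm(10 * 4), 10, 4) + matrix(rnorm(n * 4, sd = 2), n, 4)
    fit <- rrr(X, Y, rank = 3)
    cors <- cor(fit$scores)
    expect_lt(max(abs(cors[upper.tri(cors)])), 1e-8)
    expect_true(all(diff(fit$explained_share) <= 1e-12))
    expect_lte(sum(fit$explained_share), 1 + 1e-12)
    # sign convention: dominant predictor weight positive
    for (k in seq_len(fit$rank))
      expect_gt(fit$a[which.max(abs(fit$a[, k])), k], 0)
  }
})

test_that("rank selection implements the scree ratio rule with a cap", {
  expect_identical(as.integer(select_rank(c(10, 5, 0.1, 0.05))), 2L)
  expect_identical(as.integer(select_rank(c(10, 0.5, 0.1))), 1L)
  expect_identical(as.integer(select_rank(rep(4, 6))), 2L)         # cap
  expect_identical(as.integer(select_rank(c(9, 8, 7), policy = "fixed")), 2L)
  expect_identical(as.integer(select_rank(c(10, 5, 4, 3),
                                          threshold = 0.1, cap = 4L)), 4L)
  expect_error(select_rank(5), "at least 2")
  expect_s3_class(attr(select_rank(c(3, 1)), "scree"), "data.frame")
})

test_that("scoring new subjects uses training standardization", {
  set.seed(9)
  X <- matrix(rnorm(80 * 5), 80, 5,
              dimnames = list(NULL, paste0("g", 1:5)))
  Y <- X %*% matrix(rnorm(10), 5, 2) + matrix(rnorm(160), 80, 2)
  fit <- rrr(X, Y, rank = 2)
  expect_equal(predict(fit, X), fit$scores, tolerance = 1e-12)
  at_mean <- matrix(colMeans(X), 1, dimnames = list(NULL, colnames(X)))
  expect_equal(unname(drop(predict(fit, at_mean))), c(0, 0), tolerance = 1e-12)
  perm <- sample(80)
  expect_equal(predict(fit, X[perm, ]), fit$scores[perm, ], tolerance = 1e-12)
  bad <- X[, -2]
  expect_error(predict(fit, bad), "g2")
})
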