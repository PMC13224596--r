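#' Quantile-normalize assay batches to a reference batch
#'
#' Maps each non-reference batch's values through its empirical distribution
#' onto the reference batch's empirical quantile function (linear
#' interpolation), so that batches measured with different assays share the
#' reference batch's marginal distribution. Within-batch rank order is
#' preserved; the reference batch is returned unchanged.
#'
#' @param values Numeric vector.
#' @param batch Batch labels aligned with `values`.
#' @param reference Reference batch label; defaults to the last batch in
#'   sorted label order ("normalization to the last assay").
#' @return Normalized values.
#' @export
quantile_normalize_batches <- function(values, batch, reference = NULL) {
  batch <- as.character(batch)
  labs <- sort(unique(batch))
  if (is.null(reference)) reference <- labs[length(labs)]
  if (!reference %in% labs) stop("reference batch '", reference, "' is empty")
  ref <- values[batch == reference]
  if (length(ref) < 2) stop("reference batch '", reference,
                            "' has fewer than 2 values")
  out <- values
  for (b in setdiff(labs, reference)) {
    idx <- batch == b
    nb <- sum(idx)
    if (nb < 2) stop("batch '", b, "' has fewer than 2 values")
    # mid-rank plotting positions -> reference empirical quantiles
    p <- (rank(values[idx], ties.method = "average") - 0.5) / nb
    out[idx] <- stats::quantile(ref, probs = p, type = 7, names = FALSE)
  }
  out
}

#' Adjust mediators for age and household clustering
#'
#' For each mediator, fits the random-intercept model
#' \eqn{y = \beta_0 + \beta_1 age + u_{household} + \epsilon} by REML and
#' returns the conditional residuals \eqn{y - \hat\beta_0 - \hat\beta_1 age -
#' BLUP(u)} (option `subtract_blup = FALSE` keeps the household intercept in
#' the adjusted value). Mixed-model residuals are exactly orthogonal to the
#' fixed-effect columns, so the adjusted values are uncorrelated with age.
#'
#' @param panel Numeric matrix or data.frame of mediator columns.
#' @param age Years; `NULL` fits an intercept-only fixed part (useful for
#'   variance-component diagnostics on balanced designs).
#' @param household_id Household labels.
#' @param subtract_blup Subtract the household BLUP (default) or only the
#'   fixed effects.
#' @return List: `adjusted` (matrix), `varcomp` (per-mediator data.frame with
#'   `sd_household`, `sd_residual`), `notes` (character, e.g. boundary fits).
#' @export
adjust_mediators <- function(panel, age, household_id, subtract_blup = TRUE) {
  panel <- as.matrix(panel)
  if (length(unique(household_id)) < 2) stop("need at least 2 households")
  has_age <- !is.null(age)
  if (has_age && stats::var(age) == 0) stop("age variance is zero")
  adjusted <- panel
  vc <- data.frame(mediator = colnames(panel),
                   sd_household = NA_real_, sd_residual = NA_real_)
  notes <- character(0)
  df <- data.frame(hh = factor(household_id))
  if (has_age) df$age <- age
  form <- if (has_age) y ~ age + (1 | hh) else y ~ 1 + (1 | hh)
  for (j in seq_len(ncol(panel))) {
    df$y <- panel[, j]
    fit <- suppressMessages(
      lme4::lmer(form, data = df, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")))
    vcs <- as.data.frame(lme4::VarCorr(fit))
    sd_u <- vcs$sdcor[vcs$grp == "hh"]
    sd_e <- vcs$sdcor[vcs$grp == "Residual"]
    vc$sd_household[j] <- sd_u
    vc$sd_residual[j] <- sd_e
    if (sd_u < 1e-8)
      notes <- c(notes, paste0(colnames(panel)[j],
                               ": household variance at zero boundary"))
    if (subtract_blup) {
      adjusted[, j] <- stats::residuals(fit)
    } else {
      X <- if (has_age) cbind(1, age) else cbind(rep(1, nrow(df)))
      adjusted[, j] <- df$y - drop(X %*% lme4::fixef(fit))
    }
  }
  list(adjusted = adjusted, varcomp = vc, notes = notes)
}

#' Reduced-rank regression of mediators on food-group intakes
#'
#' Finds linear combinations of (standardized) food-group intakes that
#' explain the maximum variation in a set of (standardized) response
#' mediators. With \eqn{B = (X'X)^{-1}X'Y} and \eqn{\hat Y = XB}, the k-th
#' response weight \eqn{v_k} is the k-th right singular vector of
#' \eqn{\hat Y}, the predictor weights are \eqn{a_k = B v_k}, and the
#' pattern score is \eqn{s_k = X a_k = \hat Y v_k} with eigenvalue
#' \eqn{\lambda_k = s_k's_k}. Retained scores are mutually uncorrelated by
#' construction. Signs are fixed so that each pattern's largest-magnitude
#' predictor weight is positive.
#'
#' @param x Predictor matrix (subjects x food groups), e.g. energy-adjusted
#'   group intakes. Standardized internally (training means/SDs are stored
#'   and reused by [predict.rrr()]).
#' @param y Response matrix (subjects x mediators), e.g. batch-normalized,
#'   age/household-adjusted biomarkers. Standardized internally.
#' @param rank Number of dietary patterns to retain, `K <= min(p, q)`.
#' @return Object of class `"rrr"` with components `a` (p x K predictor
#'   weights), `v` (q x K unit-norm response weights), `eigenvalues`,
#'   `explained_share` (per pattern, as a share of total response variance),
#'   `loadings` (correlations of each predictor with each score), `scores`
#'   (n x K), `centers`/`scales` for x, `total_r2` (multivariate OLS R^2).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 100, 3)
#' y <- cbind(x %*% c(1, -1, 0) + rnorm(100, sd = 0.1), rnorm(100))
#' fit <- rrr(x, y, rank = 2)
#' fit
#' @export
rrr <- function(x, y, rank = 2) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x); p <- ncol(x); q <- ncol(y)
  if (nrow(y) != n) stop("x and y must have the same number of rows")
  if (n <= p) stop("need more subjects than predictors (n > p)")
  if (anyNA(x) || anyNA(y)) stop("x and y must be complete")
  if (rank < 1 || rank > min(p, q))
    stop("rank must be in 1..min(p, q) = ", min(p, q))
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  if (is.null(colnames(y))) colnames(y) <- paste0("y", seq_len(q))

  centers <- colMeans(x)
  scales <- apply(x, 2, stats::sd)
  if (any(scales == 0)) stop("constant predictor column(s): ",
                             paste(colnames(x)[scales == 0], collapse = ", "))
  Xs <- scale(x, center = centers, scale = scales)
  ysd <- apply(y, 2, stats::sd)
  if (any(ysd == 0)) stop("constant response column(s): ",
                          paste(colnames(y)[ysd == 0], collapse = ", "))
  Ys <- scale(y, center = TRUE, scale = ysd)

  qrX <- qr(Xs)
  if (qrX$rank < p)
    stop("X'X is rank deficient (rank ", qrX$rank, " < ", p, "); drop or ",
         "combine collinear food groups, or add a ridge jitter upstream")
  B <- qr.coef(qrX, Ys)                      # p x q
  Yhat <- Xs %*% B
  sv <- svd(Yhat)                            # eigen of Yhat'Yhat via SVD
  K <- as.integer(rank)
  v <- sv$v[, seq_len(K), drop = FALSE]
  a <- B %*% v
  scores <- Xs %*% a
  eig <- sv$d^2
  # sign convention: largest-|a| element positive
  for (k in seq_len(K)) {
    i <- which.max(abs(a[, k]))
    if (a[i, k] < 0) {
      a[, k] <- -a[, k]; v[, k] <- -v[, k]; scores[, k] <- -scores[, k]
    }
  }
  dimnames(a) <- list(colnames(x), paste0("DP", seq_len(K)))
  dimnames(v) <- list(colnames(y), paste0("DP", seq_len(K)))
  colnames(scores) <- paste0("DP", seq_len(K))
  tot_var <- sum(Ys^2)
  loadings <- stats::cor(Xs, scores)
  structure(list(
    a = a, v = v, eigenvalues = eig[seq_len(min(p, q))],
    explained_share = eig[seq_len(K)] / tot_var,
    loadings = loadings, scores = scores,
    centers = centers, scales = scales,
    total_r2 = sum(Yhat^2) / tot_var,
    n = n, p = p, q = q, rank = K,
    response_names = colnames(y)
  ), class = "rrr")
}

#' @export
print.rrr <- function(x, ...) {
  cat("Reduced-rank regression: ", x$p, " food groups -> ", x$q,
      " mediators, n = ", x$n, "\n", sep = "")
  cat("Retained patterns: ", x$rank,
      sprintf(" (explained response variance %.1f%%)",
              100 * sum(x$explained_share)), "\n", sep = "")
  cat("Per-pattern shares:",
      paste(sprintf("%.1f%%", 100 * x$explained_share), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.rrr <- function(object, ...) {
  structure(list(fit = object,
                 scree = data.frame(
                   pattern = seq_along(object$eigenvalues),
                   eigenvalue = object$eigenvalues,
                   ratio_to_first = object$eigenvalues / object$eigenvalues[1])),
            class = "summary.rrr")
}

#' @export
print.summary.rrr <- function(x, ...) {
  print(x$fit)
  cat("\nScree table:\n")
  print(x$scree, row.names = FALSE, digits = 4)
  cat("\nResponse weights (eigenvectors):\n")
  print(round(x$fit$v, 3))
  invisible(x)
}

#' @export
coef.rrr <- function(object, type = c("predictor", "response"), ...) {
  switch(match.arg(type), predictor = object$a, response = object$v)
}

#' Score new subjects on fitted dietary patterns
#'
#' Standardizes new food-group intakes with the training means/SDs and
#' projects onto the fitted predictor weights. Applying to the training
#' matrix reproduces the training scores exactly.
#'
#' @param object An `"rrr"` fit.
#' @param newdata Matrix/data.frame with the training predictor columns.
#' @param ... Unused.
#' @return n x K score matrix.
#' @export
predict.rrr <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$scores)
  newdata <- as.matrix(newdata)
  nm <- colnames(newdata)
  want <- rownames(object$a)
  if (!is.null(nm)) {
    missing_g <- setdiff(want, nm)
    extra_g <- setdiff(nm, want)
    if (length(missing_g) || length(extra_g))
      stop("column mismatch; missing: ",
           paste(missing_g, collapse = ", "), "; extra: ",
           paste(extra_g, collapse = ", "))
    newdata <- newdata[, want, drop = FALSE]
  } else if (ncol(newdata) != length(want)) {
    stop("newdata has ", ncol(newdata), " columns; expected ", length(want))
  }
  Xs <- scale(newdata, center = object$centers, scale = object$scales)
  Xs %*% object$a
}

#' Scree plot of RRR eigenvalues
#'
#' @param x An `"rrr"` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rrr <- function(x, ...) {
  graphics::plot(seq_along(x$eigenvalues), x$eigenvalues, type = "b",
                 xlab = "Pattern", ylab = "Eigenvalue",
                 main = "RRR scree plot", ...)
  invisible(x)
}

#' Choose the number of dietary patterns from the scree
#'
#' Automated stand-in for visual scree-plot inspection: the largest K with
#' \eqn{\lambda_K/\lambda_1 \ge} `threshold`, capped (default cap 2 patterns,
#' the configuration used throughout the package). `policy = "fixed"` always
#' returns the cap.
#'
#' @param eigenvalues Non-increasing eigenvalues.
#' @param policy `"ratio"` (threshold rule) or `"fixed"`.
#' @param threshold Ratio cutoff for the ratio rule.
#' @param cap Hard upper bound on K.
#' @return Integer K >= 1, plus a `"scree"` attribute with the scree table.
#' @export
select_rank <- function(eigenvalues, policy = c("ratio", "fixed"),
                        threshold = 0.10, cap = 2L) {
  policy <- match.arg(policy)
  if (length(eigenvalues) < 2) stop("need at least 2 eigenvalues")
  scree <- data.frame(pattern = seq_along(eigenvalues),
                      eigenvalue = eigenvalues,
                      ratio_to_first = eigenvalues / eigenvalues[1])
  K <- if (policy == "fixed") cap
       else max(1L, min(cap, max(which(scree$ratio_to_first >= threshold))))
  structure(as.integer(K), scree = scree)
}
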