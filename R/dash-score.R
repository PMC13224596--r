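#' DASH component definitions
#'
#' The eight Fung-style components: five healthy (quintile-ranked 1..5,
#' ascending with intake), two unhealthy quintile-ranked 5..1, and
#' sugar-sweetened beverages (SSB) tertile-ranked 3..1 because their intake
#' is generally low in Alpine populations.
#'
#' @return Data.frame with columns `component`, `direction`, `scheme`.
#' @export
dash_components <- function() {
  data.frame(
    component = c("fruits", "vegetables", "whole_grains", "low_fat_dairy",
                  "nuts_legumes", "red_processed_meat", "sodium", "ssb"),
    direction = c(rep("healthy", 5), "unhealthy", "unhealthy", "unhealthy"),
    scheme = c(rep("quintile", 7), "tertile"),
    stringsAsFactors = FALSE
  )
}

#' Quantile-rank one DASH component
#'
#' Computes empirical quantile cutpoints (linear interpolation, within one
#' sex stratum) and assigns category membership by half-open intervals
#' \eqn{(-\infty, c_1], (c_1, c_2], \ldots}; ties at a cutpoint fall in the
#' lower category. Healthy components are ranked ascending with intake
#' (1..k), unhealthy components descending (k..1).
#'
#' @param x Energy-adjusted intake vector (one sex).
#' @param direction `"healthy"` or `"unhealthy"`.
#' @param scheme `"quintile"` (k = 5) or `"tertile"` (k = 3).
#' @return Integer ranks in 1..k.
#' @export
rank_component <- function(x, direction = c("healthy", "unhealthy"),
                           scheme = c("quintile", "tertile")) {
  direction <- match.arg(direction)
  scheme <- match.arg(scheme)
  k <- if (scheme == "quintile") 5L else 3L
  if (length(x) < k) stop("need at least ", k, " subjects for ", scheme, "s")
  if (length(unique(x)) == 1L) {
    warning("all intakes equal; every subject assigned category 1")
    cat_idx <- rep(1L, length(x))
  } else {
    cuts <- stats::quantile(x, probs = seq_len(k - 1) / k, type = 7,
                            names = FALSE)
    cat_idx <- 1L + as.integer(rowSums(outer(x, cuts, `>`)))
  }
  if (direction == "healthy") cat_idx else (k + 1L) - cat_idx
}

#' DASH adherence score
#'
#' Sum of sex-specific quantile ranks over the eight DASH components of a
#' [build_diet_matrix()] result, after nutrient-residual energy adjustment.
#' Achievable range 8 (worst) to 38 (best) under the implemented scheme
#' (5 healthy quintile components, 2 unhealthy quintile, 1 unhealthy
#' tertile).
#'
#' @param diet A `"diet_matrix"` object (or a matrix/data.frame with the 8
#'   component columns named as in [dash_components()]).
#' @param sex Character vector aligned with subjects.
#' @param energy_adjusted If `FALSE` (default) the components are first
#'   energy-adjusted against `diet$tei` within sex.
#' @return Data.frame of class `"dash_score"`: `subject_id`, the 8 per-
#'   component ranks, and `total`.
#' @export
dash_score <- function(diet, sex, energy_adjusted = FALSE) {
  comps <- dash_components()
  if (inherits(diet, "diet_matrix")) {
    values <- diet$dash
    subject_id <- diet$subject_id
    tei <- diet$tei
  } else {
    values <- as.matrix(diet)
    subject_id <- rownames(values)
    if (is.null(subject_id)) subject_id <- seq_len(nrow(values))
    tei <- NULL
  }
  missing_comp <- setdiff(comps$component, colnames(values))
  if (length(missing_comp))
    stop("missing DASH component column(s): ",
         paste(missing_comp, collapse = ", "))
  values <- values[, comps$component, drop = FALSE]
  if (!energy_adjusted) {
    if (is.null(tei))
      stop("raw component matrix supplied without TEI; pass a diet_matrix ",
           "or set energy_adjusted = TRUE")
    values <- energy_adjust(values, tei, sex)
  }
  ranks <- matrix(NA_integer_, nrow(values), ncol(values),
                  dimnames = list(NULL, paste0("rank_", comps$component)))
  for (j in seq_len(nrow(comps))) {
    for (s in unique(sex)) {
      idx <- sex == s
      ranks[idx, j] <- rank_component(values[idx, j],
                                      comps$direction[j], comps$scheme[j])
    }
  }
  total <- total_dash(ranks)
  out <- data.frame(subject_id = subject_id, ranks, total = total,
                    stringsAsFactors = FALSE)
  class(out) <- c("dash_score", "data.frame")
  out
}

#' Sum component ranks into the total DASH score
#'
#' @param ranks Matrix or data.frame of the 8 per-component rank columns
#'   (named `rank_<component>` or `<component>`).
#' @return Integer totals; invariant to component column order.
#' @export
total_dash <- function(ranks) {
  comps <- dash_components()$component
  ranks <- as.data.frame(ranks)
  nm <- sub("^rank_", "", names(ranks))
  missing_comp <- setdiff(comps, nm)
  if (length(missing_comp))
    stop("missing rank column(s) for component(s): ",
         paste(missing_comp, collapse = ", "))
  m <- as.matrix(ranks[match(comps, nm)])
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop("missing rank for subject ", bad[1, 1], ", component ",
         comps[bad[1, 2]])
  }
  as.integer(rowSums(m))
}
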