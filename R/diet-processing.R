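#' FFQ frequency categories
#'
#' The seven ordered response categories of the FFQ and their conversion to
#' portions per day. The "2-4/week" and "5-6/week" categories use interval
#' midpoints (3 and 5.5 per week); one month is 30.44 days.
#'
#' @format Named numeric vector, portions/day, in category order 0..6.
#' @export
ffq_frequency_map <- c(
  "rarely/never" = 0,
  "1/month"      = 1 / 30.44,
  "1/week"       = 1 / 7,
  "2-4/week"     = 3 / 7,
  "5-6/week"     = 5.5 / 7,
  "1/day"        = 1,
  "2+/day"       = 2
)

#' Convert FFQ frequency categories to portions per day
#'
#' @param category Integer codes 0..6 (category order), or character labels
#'   matching `names(ffq_frequency_map)`.
#' @param map Conversion map; defaults to [ffq_frequency_map].
#' @return Portions/day, monotone in the category order.
#' @export
frequency_to_daily <- function(category, map = ffq_frequency_map) {
  if (is.numeric(category)) {
    bad <- !is.na(category) & !(category %in% 0:(length(map) - 1))
    if (any(bad))
      stop("unknown FFQ category code(s): ",
           paste(unique(category[bad]), collapse = ", "))
    out <- unname(map[category + 1L])
  } else {
    category <- as.character(category)
    bad <- !is.na(category) & !category %in% names(map)
    if (any(bad))
      stop("unknown FFQ category label(s): ",
           paste(unique(category[bad]), collapse = ", "))
    out <- unname(map[category])
  }
  out
}

#' Build the per-subject diet matrix
#'
#' Converts item frequencies to grams/day through portion sizes, aggregates
#' items into food groups (g/day) for the RRR side and into DASH components
#' (servings/week; sodium as mg/day) for the DASH side, and computes total
#' energy intake (TEI, kcal/day) and sodium from composition densities.
#'
#' @param ffq Data.frame: `subject_id` plus `item_*` columns of category
#'   codes 0..6 (NA allowed; treated as zero consumption here — the
#'   exclusion cascade handles heavy missingness first).
#' @param composition Data.frame with columns `item_id`, `grams_per_portion`,
#'   `group_id`, `dash_component` (NA for items outside the DASH score),
#'   `sodium_mg_per_100g`, `kcal_per_100g`.
#' @return List of class `"diet_matrix"`: `subject_id`; `groups` (n x
#'   n_groups g/day matrix); `dash` (n x 8 matrix: 7 components in
#'   servings/week + `sodium` in mg/day); `tei` kcal/day; `item_grams`.
#' @export
build_diet_matrix <- function(ffq, composition) {
  item_cols <- grep("^item_", names(ffq), value = TRUE)
  if (!length(item_cols)) stop("no 'item_*' columns in ffq")
  missing_items <- setdiff(item_cols, composition$item_id)
  if (length(missing_items))
    stop("items absent from composition table: ",
         paste(utils::head(missing_items, 5), collapse = ", "),
         if (length(missing_items) > 5) ", ...")
  comp <- composition[match(item_cols, composition$item_id), ]
  if (any(comp$grams_per_portion < 0) || any(comp$kcal_per_100g < 0) ||
      any(comp$sodium_mg_per_100g < 0))
    stop("negative densities in composition table")

  codes <- as.matrix(ffq[item_cols])
  codes[is.na(codes)] <- 0L
  portions <- matrix(frequency_to_daily(as.vector(codes)),
                     nrow = nrow(codes), ncol = ncol(codes),
                     dimnames = list(NULL, item_cols))
  grams <- sweep(portions, 2, comp$grams_per_portion, `*`)   # g/day
  tei <- drop(grams %*% (comp$kcal_per_100g / 100))
  sodium <- drop(grams %*% (comp$sodium_mg_per_100g / 100))  # mg/day

  group_ids <- sort(unique(comp$group_id))
  G <- outer(comp$group_id, group_ids, `==`) * 1
  groups <- grams %*% G
  colnames(groups) <- sprintf("group_%02d", group_ids)

  dash_levels <- c("fruits", "vegetables", "whole_grains", "low_fat_dairy",
                   "nuts_legumes", "red_processed_meat", "ssb")
  D <- outer(ifelse(is.na(comp$dash_component), "", comp$dash_component),
             dash_levels, `==`) * 1
  dash <- 7 * (portions %*% D)                               # servings/week
  colnames(dash) <- dash_levels
  dash <- cbind(dash, sodium = sodium)

  structure(list(subject_id = ffq$subject_id, groups = groups, dash = dash,
                 tei = tei, item_grams = grams),
            class = "diet_matrix")
}

#' Nutrient residual energy adjustment
#'
#' Within each sex separately, regresses an intake on total energy intake and
#' replaces it by the residual plus the predicted intake at the sex-specific
#' mean TEI (which equals the sex-mean intake under OLS). The adjusted values
#' are uncorrelated with TEI within sex and keep the original units and
#' within-sex mean.
#'
#' @param values Numeric vector or matrix (subjects x intakes).
#' @param tei Total energy intake, kcal/day.
#' @param sex Character vector, `"male"`/`"female"` (a single-level vector
#'   adjusts one stratum).
#' @return Adjusted values, same shape as `values`.
#' @export
energy_adjust <- function(values, tei, sex) {
  vec_in <- is.null(dim(values))
  values <- as.matrix(values)
  if (length(tei) != nrow(values) || length(sex) != nrow(values))
    stop("'tei' and 'sex' must match rows of 'values'")
  out <- values
  for (s in unique(sex)) {
    idx <- sex == s
    if (sum(idx) < 3) stop("need at least 3 subjects per sex stratum")
    t_s <- tei[idx]
    if (stats::var(t_s) == 0)
      stop("zero TEI variance in stratum '", s, "': slope undefined")
    tc <- t_s - mean(t_s)
    denom <- sum(tc^2)
    for (j in seq_len(ncol(values))) {
      y <- values[idx, j]
      slope <- sum(tc * (y - mean(y))) / denom
      out[idx, j] <- y - slope * tc   # residual + fit at mean TEI
    }
  }
  if (vec_in) drop(out) else out
}
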