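# Nutrient Rich Food Index (NRFI): per-100-g nutrient-density score
# from 8 qualifying and 3 disqualifying nutrients, and its aggregation
# to participant-basket food groups.

#' Default nutrient reference table
#'
#' Daily reference values for the 11 NRFI nutrients: 8 qualifying
#' ("positive") and 3 disqualifying ("negative"). The salt reference is
#' the Finnish recommendation of 5 g/day; the other ten values are
#' illustrative round numbers in the range of Nordic recommendations
#' and should be replaced with an authoritative table for substantive
#' use (the scoring code takes any reference table of this shape).
#'
#' @return A tibble with columns `nutrient`, `role`
#'   (`"positive"`/`"negative"`), `reference_value`, `unit`.
#' @export
default_nutrient_references <- function() {
  tibble::tibble(
    nutrient = nutrient_names(),
    role = c(rep("positive", 8), rep("negative", 3)),
    reference_value = c(50, 25, 11, 900, 12, 10, 75, 300, 20, 50, 5),
    unit = c("g", "g", "g", "mg", "mg", "ug", "mg", "ug", "g", "g", "g"))
}

validate_nutrient_references <- function(refs) {
  need <- c("nutrient", "role", "reference_value")
  if (!all(need %in% names(refs))) {
    stop("reference table must have columns nutrient, role, reference_value",
         call. = FALSE)
  }
  if (sum(refs$role == "positive") != 8 || sum(refs$role == "negative") != 3) {
    stop("reference table must contain exactly 8 positive and 3 negative ",
         "nutrients", call. = FALSE)
  }
  if (any(refs$reference_value <= 0)) {
    stop("reference values must be positive", call. = FALSE)
  }
  invisible(refs)
}

#' NRFI score of one item per 100 g
#'
#' Score = sum over qualifying nutrients of
#' `min(amount / reference, 1) * 100` minus sum over disqualifying
#' nutrients of `(amount / reference) * 100`. Qualifying contributions
#' are capped at 100% of the daily reference (the standard
#' Drewnowski-Fulgoni convention, recorded in the result's
#' attributes); disqualifying contributions are uncapped, so the score
#' may be negative. The maximum attainable positive subscore is 800.
#'
#' @param nutrients_per_100g Named numeric vector of 11 non-negative
#'   amounts per 100 g; names must match the reference table
#'   (case-insensitively).
#' @param refs Reference table, see [default_nutrient_references()].
#' @return A single numeric score with attribute `basis = "per 100 g"`.
#' @export
compute_item_nrfi <- function(nutrients_per_100g,
                              refs = default_nutrient_references()) {
  validate_nutrient_references(refs)
  x <- nutrients_per_100g
  nm <- tolower(names(x))
  ref_nm <- tolower(refs$nutrient)
  if (is.null(names(x)) || !all(ref_nm %in% nm)) {
    stop("missing nutrient(s): ",
         paste(refs$nutrient[!ref_nm %in% nm], collapse = ", "),
         call. = FALSE)
  }
  x <- as.numeric(x[match(ref_nm, nm)])
  if (anyNA(x) || any(x < 0)) {
    stop("nutrient amounts must be non-negative and non-missing",
         call. = FALSE)
  }
  ratio <- x / refs$reference_value
  pos <- refs$role == "positive"
  value <- sum(pmin(ratio[pos], 1)) * 100 - sum(ratio[!pos]) * 100
  structure(value, basis = "per 100 g", positive_cap = 100)
}

# vectorized scoring of a catalog's nutrient columns; returns one score
# per row without per-item validation overhead
catalog_nrfi <- function(catalog, refs = default_nutrient_references()) {
  validate_nutrient_references(refs)
  ref_nm <- tolower(refs$nutrient)
  cols <- match(ref_nm, tolower(names(catalog)))
  if (anyNA(cols)) {
    stop("catalog is missing nutrient column(s): ",
         paste(refs$nutrient[is.na(cols)], collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(catalog[, cols])
  if (any(m < 0) || anyNA(m)) {
    stop("nutrient amounts must be non-negative and non-missing",
         call. = FALSE)
  }
  ratio <- sweep(m, 2, refs$reference_value, "/")
  pos <- refs$role == "positive"
  rowSums(pmin(ratio[, pos, drop = FALSE], 1)) * 100 -
    rowSums(ratio[, !pos, drop = FALSE]) * 100
}

#' Energy content of a purchase
#'
#' Purchase volume times the food's energy density. 1 MJ corresponds
#' to 239 kcal; [mj_to_kcal()] converts for any kcal reporting.
#'
#' @param quantity Purchase weight in kg (>= 0).
#' @param energy_density Energy density in MJ/kg (>= 0).
#' @return Energy in MJ.
#' @export
item_energy <- function(quantity, energy_density) {
  if (any(quantity < 0) || any(energy_density < 0)) {
    stop("quantity and energy density must be non-negative", call. = FALSE)
  }
  quantity * energy_density
}

#' @rdname item_energy
#' @param mj Energy in MJ.
#' @export
mj_to_kcal <- function(mj) mj * 239

#' Volume-weighted basket NRFI for a food group
#'
#' Aggregates item scores over one participant's purchases in a group.
#' Two variants are returned: the volume-weighted sum
#' `sum(score * kg)` and the volume-weighted mean
#' `sum(score * kg) / sum(kg)`. The pipeline uses the weighted mean
#' for between-level comparisons (it stays on the per-100-g score
#' scale); the variant used is recorded in the result.
#'
#' @param item_scores Numeric NRFI scores, one per purchased item.
#' @param volumes Purchase volumes in kg, same length, non-negative.
#' @return A list with `weighted_sum`, `weighted_mean` (NA when total
#'   volume is zero), and `pipeline_variant = "weighted_mean"`.
#' @export
basket_group_nrfi <- function(item_scores, volumes) {
  if (length(item_scores) != length(volumes)) {
    stop("item_scores and volumes must have equal length", call. = FALSE)
  }
  if (any(volumes < 0)) stop("volumes must be non-negative", call. = FALSE)
  ws <- sum(as.numeric(item_scores) * volumes)
  total <- sum(volumes)
  list(weighted_sum = ws,
       weighted_mean = if (total > 0) ws / total else NA_real_,
       pipeline_variant = "weighted_mean")
}
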