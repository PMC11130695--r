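# Inclusion filters and per-participant, per-food-group aggregation:
# expenditure, volume, energy, prices, shares, basket NRFI, and
# medians by PIA level.

#' Apply the cohort inclusion filters
#'
#' Retains participants with self-estimated loyalty of at least 41%,
#' total annual expenditure of at least 100 euro (both bounds
#' inclusive: the exclusions are "<41%" and "<100 euro"), and a
#' substantive PIA answer (levels 1-5; level 6 is "cannot/do not want
#' to say"). Each excluded participant is logged with the first rule
#' that removed them, in the order loyalty, expenditure, PIA.
#'
#' @param participants Participant table.
#' @param transactions Transaction table; every `participant_id` must
#'   resolve against `participants`.
#' @param loyalty_min Minimum loyalty percent (default 41).
#' @param expenditure_min Minimum annual expenditure in euro
#'   (default 100).
#' @return A list with `included` (participant rows that pass, with a
#'   `total_expenditure` column) and `exclusions` (tibble `id`, `rule`).
#' @export
apply_inclusion_filters <- function(participants, transactions,
                                    loyalty_min = 41,
                                    expenditure_min = 100) {
  orphan <- setdiff(unique(transactions$participant_id), participants$id)
  if (length(orphan)) {
    stop("transactions reference unknown participant id(s): ",
         paste(head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  totals <- transactions |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(total_expenditure = sum(.data$expenditure),
                     .groups = "drop")
  p <- participants |>
    dplyr::select(-dplyr::any_of("total_expenditure")) |>
    dplyr::left_join(totals, by = c(id = "participant_id")) |>
    dplyr::mutate(total_expenditure =
                    dplyr::coalesce(.data$total_expenditure, 0))
  rule <- dplyr::case_when(
    p$loyalty_pct < loyalty_min ~ "loyalty_below_min",
    p$total_expenditure < expenditure_min ~ "expenditure_below_min",
    !p$pia %in% 1:5 ~ "pia_not_stated",
    TRUE ~ NA_character_)
  list(included = p[is.na(rule), , drop = FALSE],
       exclusions = tibble::tibble(id = p$id[!is.na(rule)],
                                   rule = rule[!is.na(rule)]))
}

#' Aggregate transactions into per-participant, per-group baskets
#'
#' Sums expenditure (euro), volume (kg) and energy (MJ, volume times
#' the item's energy density) over each participant's purchases in
#' each food group, and derives unit prices
#' `price_per_kg = expenditure / volume` and
#' `price_per_mj = expenditure / energy` (missing when the denominator
#' is zero). The basket NRFI per group is the volume-weighted mean of
#' the purchased items' per-100-g scores; the volume-weighted sum is
#' kept alongside as `nrfi_volume_sum`.
#'
#' @param transactions Transaction table.
#' @param catalog Food catalog; every `item_id` must resolve.
#' @param refs Nutrient reference table for the NRFI.
#' @return A tibble with one row per (participant, group) with any
#'   purchase: `participant_id`, `group`, `expenditure`, `volume`,
#'   `energy`, `price_per_kg`, `price_per_mj`, `nrfi`,
#'   `nrfi_volume_sum`.
#' @export
aggregate_baskets <- function(transactions, catalog,
                              refs = default_nutrient_references()) {
  unknown <- setdiff(unique(transactions$item_id), catalog$item_id)
  if (length(unknown)) {
    stop("transactions reference item id(s) absent from the catalog: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  cat_scores <- catalog |>
    dplyr::mutate(item_nrfi = catalog_nrfi(catalog, refs)) |>
    dplyr::select("item_id", "group", "energy_density", "item_nrfi")
  transactions |>
    dplyr::inner_join(cat_scores, by = "item_id") |>
    dplyr::group_by(.data$participant_id, .data$group) |>
    dplyr::summarise(
      expenditure = sum(.data$expenditure),
      volume = sum(.data$quantity),
      energy = sum(.data$quantity * .data$energy_density),
      nrfi_volume_sum = sum(.data$item_nrfi * .data$quantity),
      .groups = "drop") |>
    dplyr::mutate(
      price_per_kg = ifelse(.data$volume > 0,
                            .data$expenditure / .data$volume, NA_real_),
      price_per_mj = ifelse(.data$energy > 0,
                            .data$expenditure / .data$energy, NA_real_),
      nrfi = ifelse(.data$volume > 0,
                    .data$nrfi_volume_sum / .data$volume, NA_real_))
}

#' Fill in energy and expenditure shares
#'
#' Adds `energy_share` and `expenditure_share` (percent of the
#' participant's totals across all groups) to a basket summary. Within
#' each participant the shares sum to 100. A participant with zero
#' total energy gets missing energy shares (logged via a warning).
#'
#' @param summaries Output of [aggregate_baskets()].
#' @return The summaries with `energy_share` and `expenditure_share`.
#' @export
compute_shares <- function(summaries) {
  out <- summaries |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      energy_share = if (sum(.data$energy) > 0)
        100 * .data$energy / sum(.data$energy) else NA_real_,
      expenditure_share = if (sum(.data$expenditure) > 0)
        100 * .data$expenditure / sum(.data$expenditure) else NA_real_) |>
    dplyr::ungroup()
  if (anyNA(out$energy_share)) {
    warning("participants with zero total energy: energy shares missing",
            call. = FALSE)
  }
  out
}

#' Drop food groups with only marginal purchases
#'
#' A group is excluded when its population-wide share of expenditure is
#' below `expenditure_threshold` percent or its share of energy is
#' below `energy_threshold` percent (below either bound suffices).
#'
#' @param summaries Basket summaries (all participants pooled).
#' @param expenditure_threshold Percent of total expenditure
#'   (default 1).
#' @param energy_threshold Percent of total energy (default 0.2).
#' @return Character vector of retained group labels.
#' @export
select_major_groups <- function(summaries, expenditure_threshold = 1,
                                energy_threshold = 0.2) {
  tot <- summaries |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(expenditure = sum(.data$expenditure),
                     energy = sum(.data$energy), .groups = "drop") |>
    dplyr::mutate(
      exp_share = 100 * .data$expenditure / sum(.data$expenditure),
      energy_share = 100 * .data$energy / sum(.data$energy))
  tot$group[tot$exp_share >= expenditure_threshold &
              tot$energy_share >= energy_threshold]
}

#' Medians of an outcome per food group and PIA level
#'
#' For the share outcomes (`energy_share`, `expenditure_share`) a
#' participant with no purchases in a group contributes a true zero;
#' for `price_per_kg`, `price_per_mj` and `nrfi` the outcome is
#' undefined without a purchase, so medians run over purchasers only.
#' Even-sized cells use the midpoint convention.
#'
#' @param summaries Basket summaries with shares filled in.
#' @param participants Included participants (PIA 1-5).
#' @param outcome One of `"energy_share"`, `"expenditure_share"`,
#'   `"price_per_kg"`, `"price_per_mj"`, `"nrfi"`.
#' @param groups Food groups to tabulate (default: all present).
#' @return A tibble `group`, `level` (1-5), `value` (cell median, NA
#'   with a warning when a cell is empty), `n` (cell size), with
#'   attribute `outcome`.
#' @export
median_by_pia <- function(summaries, participants, outcome,
                          groups = sort(unique(summaries$group))) {
  outcome <- match.arg(outcome, c("energy_share", "expenditure_share",
                                  "price_per_kg", "price_per_mj", "nrfi"))
  zero_fill <- outcome %in% c("energy_share", "expenditure_share")
  pia <- participants |>
    dplyr::filter(.data$pia %in% 1:5) |>
    dplyr::select("id", "pia")
  cells <- tidyr::expand_grid(group = groups, level = 1:5)
  obs <- summaries |>
    dplyr::inner_join(pia, by = c(participant_id = "id")) |>
    dplyr::select("participant_id", "group", level = "pia",
                  value = dplyr::all_of(outcome))
  if (zero_fill) {
    # every included participant contributes to every group's share
    full <- tidyr::expand_grid(pia, group = groups) |>
      dplyr::rename(participant_id = "id", level = "pia") |>
      dplyr::left_join(obs, by = c("participant_id", "group", "level")) |>
      dplyr::mutate(value = dplyr::coalesce(.data$value, 0))
    obs <- full
  }
  out <- obs |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$group, .data$level) |>
    dplyr::summarise(value = median(.data$value), n = dplyr::n(),
                     .groups = "drop")
  out <- cells |>
    dplyr::left_join(out, by = c("group", "level")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  if (anyNA(out$value)) {
    warning("empty (group, PIA level) cell(s): median missing",
            call. = FALSE)
  }
  attr(out, "outcome") <- outcome
  out
}

#' Default monthly household income category midpoints
#'
#' Midpoints in euro/month for the 7 reporting categories. The
#' open-ended classes are assigned 750 (lowest, "<1500") and 11250
#' (top, 1.25 times the 9000 lower bound); interior midpoints follow a
#' plausible category grid and are configurable.
#'
#' @return Named numeric vector of length 7.
#' @export
default_income_midpoints <- function() {
  setNames(c(750, 2000, 3000, 4000, 5250, 7500, 11250), as.character(1:7))
}

#' OECD square-root equivalised income
#'
#' Category midpoint divided by the square root of household size.
#'
#' @param income_category Ordinal category 1-7 (vectorised).
#' @param household_size Positive integer household size.
#' @param midpoints Named midpoint table covering all categories.
#' @return Scaled income in euro/month.
#' @export
scale_income <- function(income_category, household_size,
                         midpoints = default_income_midpoints()) {
  key <- as.character(income_category)
  if (any(!key %in% names(midpoints))) {
    stop("unknown income category: ",
         paste(unique(key[!key %in% names(midpoints)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(household_size < 1)) {
    stop("household_size must be >= 1", call. = FALSE)
  }
  unname(midpoints[key]) / sqrt(household_size)
}
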