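# Synthetic loyalty-card data with known PIA gradients and
# education/sex confounding, so that every downstream pipeline stage
# has a verifiable ground truth.

#' The 17-group food panel
#'
#' Fixed food-group labels used throughout the pipeline: vegetables,
#' fruits and berries, potatoes, three cereal groups (bread, bakery,
#' grain-based foods), edible fats, fish and seafood, red and processed
#' meat, poultry, two dairy groups (liquid dairy, cheeses), and five
#' discretionary groups (snacks, sweets and chocolate, sugar-sweetened
#' beverages, coffee, alcohol).
#'
#' @return Character vector of 17 group labels.
#' @export
food_groups <- function() {
  c("Vegetables", "Fruits and berries", "Potatoes",
    "Bread", "Bakery", "Grain-based foods",
    "Edible fats", "Fish and seafood", "Red and processed meat", "Poultry",
    "Milk and other liquid dairy", "Cheeses",
    "Snacks", "Sweets and chocolate", "Sugar-sweetened beverages",
    "Coffee", "Alcohol")
}

#' Names of the 11 NRFI nutrients
#'
#' Eight qualifying nutrients (protein, fiber, polyunsaturated fatty
#' acids, calcium, iron, vitamin D, vitamin C, folate) and three
#' disqualifying ones (saturated fatty acids, saccharose, salt).
#'
#' @return Character vector of 11 nutrient column names.
#' @export
nutrient_names <- function() {
  c("protein", "fiber", "pufa", "calcium", "iron",
    "vitamin_d", "vitamin_c", "folate",
    "sfa", "saccharose", "salt")
}

# Per-group generator parameters: base unit price (euro/kg), energy
# density interval (MJ/kg), baseline volume share, default gradients,
# typical purchase-line weight, and illustrative mean nutrient
# composition per 100 g. Values are plausible Finnish retail figures,
# not estimates from any proprietary source.
group_defaults <- function() {
  g <- food_groups()
  tb <- tibble::tibble(
    group = g,
    base_price = c(2.6, 3.2, 1.0, 3.4, 6.5, 2.2, 6.0, 13.0, 9.0, 8.5,
                   1.4, 10.5, 8.5, 9.5, 1.6, 11.0, 4.5),
    ed_lo = c(0.8, 1.5, 2.8, 9.0, 11.0, 6.0, 25.0, 3.5, 7.0, 4.5,
              1.5, 11.0, 17.0, 15.0, 1.2, 3.0, 1.5),
    ed_hi = c(2.5, 3.5, 3.6, 11.0, 16.0, 15.0, 33.0, 8.0, 12.0, 8.0,
              3.0, 16.0, 22.0, 22.0, 2.0, 6.0, 4.0),
    base_share = c(0.12, 0.09, 0.04, 0.08, 0.04, 0.04, 0.03, 0.04, 0.08,
                   0.05, 0.12, 0.05, 0.04, 0.04, 0.05, 0.04, 0.05),
    # positive price trend in every group except potatoes
    price_gradient = ifelse(g == "Potatoes", 1.00, 1.05),
    # volume shifts: produce-type groups up, discretionary groups down
    volume_gradient = c(0.006, 0.006, -0.002, 0.001, -0.002, -0.002,
                        0, 0.004, 0, 0.001, 0.001, 0.002,
                        -0.004, -0.003, -0.004, 0, -0.002),
    typical_kg = c(0.5, 0.5, 1.0, 0.4, 0.3, 0.5, 0.4, 0.35, 0.5, 0.5,
                   1.0, 0.3, 0.25, 0.2, 1.5, 0.5, 1.0),
    protein   = c(1.5, 0.8, 2.0, 9.0, 7.0, 11.0, 0.5, 18.0, 17.0, 19.0,
                  3.4, 25.0, 6.0, 5.0, 0.0, 0.2, 0.5),
    fiber     = c(2.5, 2.2, 1.8, 6.0, 2.5, 3.5, 0.0, 0.0, 0.3, 0.2,
                  0.0, 0.0, 4.0, 2.0, 0.0, 0.0, 0.0),
    pufa      = c(0.1, 0.2, 0.1, 1.5, 2.0, 1.0, 25.0, 3.0, 1.5, 2.5,
                  0.1, 0.8, 8.0, 2.0, 0.0, 0.0, 0.0),
    calcium   = c(40, 20, 10, 40, 60, 25, 10, 30, 15, 12,
                  120, 750, 30, 120, 5, 5, 8),
    iron      = c(0.8, 0.4, 0.7, 2.5, 1.5, 1.8, 0.1, 0.7, 1.8, 0.8,
                  0.05, 0.3, 1.2, 2.0, 0.05, 0.05, 0.05),
    vitamin_d = c(0, 0, 0, 0, 0.3, 0, 8.0, 8.0, 0.5, 0.3,
                  1.0, 0.6, 0, 0, 0, 0, 0),
    vitamin_c = c(30, 40, 15, 0, 0, 0, 0, 1, 1, 1,
                  1, 0, 5, 0, 5, 0, 0),
    folate    = c(60, 20, 20, 50, 30, 30, 1, 15, 8, 10,
                  6, 25, 25, 10, 1, 1, 5),
    sfa       = c(0.1, 0.1, 0.1, 0.5, 6.0, 0.6, 25.0, 1.5, 6.0, 2.0,
                  1.5, 19.0, 8.0, 12.0, 0.0, 0.0, 0.0),
    saccharose = c(2, 8, 0.5, 2, 15, 1, 0.5, 0.5, 0.5, 0.3,
                   4, 0.5, 2, 45, 9, 0, 2),
    salt      = c(0.05, 0.01, 0.02, 1.1, 0.9, 0.3, 1.2, 0.8, 1.5, 1.0,
                  0.1, 1.5, 1.6, 0.2, 0.02, 0.01, 0.01)
  )
  tb
}

#' Default PIA distribution per (education, sex) stratum
#'
#' Probability of each substantive PIA level (1-5) within the 8
#' education-by-sex strata. Higher education shifts PIA upward, with a
#' smaller shift for men, so PIA is confounded with both covariates by
#' default; pass a matrix with identical rows to switch confounding
#' off. Rows are named `"<education>:<sex>"`.
#'
#' @return An 8 x 5 row-stochastic matrix.
#' @export
default_pia_by_stratum <- function() {
  strata <- expand.grid(education = 1:4, sex = c("female", "male"),
                        stringsAsFactors = FALSE)
  probs <- t(apply(strata, 1, function(s) {
    e <- as.numeric(s[["education"]])
    mu <- 1.3 + 0.55 * e + 0.25 * (s[["sex"]] == "male")
    p <- exp(-0.5 * ((1:5 - mu) / 1.15)^2)
    p / sum(p)
  }))
  rownames(probs) <- paste(strata$education, strata$sex, sep = ":")
  colnames(probs) <- paste0("pia", 1:5)
  probs
}

#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic loyalty-card
#' generator. Defaults encode the study conditions the pipeline is
#' designed around: a 5-level ordinal PIA whose distribution depends on
#' education and sex, a small fraction of participants who decline the
#' PIA question (level 6), a positive multiplicative price gradient per
#' PIA level in every food group except potatoes, and volume-share
#' gradients of mixed sign across groups.
#'
#' @param n_participants Number of participants to generate.
#' @param seed Integer seed; the same config and seed reproduce all
#'   three tables byte-identically.
#' @param pia_by_stratum Numeric matrix (8 strata x 5 levels) of PIA
#'   probabilities; row names `"<education>:<sex>"`. Each row must sum
#'   to 1 (within 1e-9).
#' @param pia6_fraction Fraction of participants assigned PIA level 6
#'   ("cannot/do not want to say"); their purchasing behaves like a
#'   random mixture of levels 1-5.
#' @param price_gradient Named numeric vector (one per food group):
#'   multiplicative unit-price step per PIA level; must be positive.
#' @param volume_gradient Named numeric vector: additive shift in a
#'   group's expected volume share per PIA level.
#' @param n_items_per_group Catalog items per food group.
#' @param base_price_per_kg Named positive numeric vector, euro/kg at
#'   PIA level 1.
#' @param energy_density_range Two-column matrix (per-group lower and
#'   upper MJ/kg bounds), rows named by group.
#' @param loyalty_distribution List with beta shape parameters
#'   `shape1`, `shape2`; loyalty percent is drawn as
#'   `100 * rbeta(shape1, shape2)`.
#' @param annual_expenditure_scale Target mean annual expenditure
#'   (euro) per participant; sets the expected number of purchase lines.
#' @param light_user_fraction Fraction of participants whose annual
#'   expenditure is scaled down ~30-fold, so the minimum-expenditure
#'   inclusion filter has something to remove.
#' @param allow_dropouts If `TRUE`, participants may end up with zero
#'   transactions; by default every participant gets at least one line.
#' @param price_sdlog Log-scale standard deviation of lognormal unit
#'   prices (prices are positive and right-skewed).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 1000,
                       seed = 1L,
                       pia_by_stratum = default_pia_by_stratum(),
                       pia6_fraction = 0.05,
                       price_gradient = NULL,
                       volume_gradient = NULL,
                       n_items_per_group = 5,
                       base_price_per_kg = NULL,
                       energy_density_range = NULL,
                       loyalty_distribution = list(shape1 = 3, shape2 = 1.5),
                       annual_expenditure_scale = 1600,
                       light_user_fraction = 0.03,
                       allow_dropouts = FALSE,
                       price_sdlog = 0.25) {
  gd <- group_defaults()
  g <- gd$group
  if (is.null(price_gradient)) {
    price_gradient <- setNames(gd$price_gradient, g)
  }
  if (is.null(volume_gradient)) {
    volume_gradient <- setNames(gd$volume_gradient, g)
  }
  if (is.null(base_price_per_kg)) {
    base_price_per_kg <- setNames(gd$base_price, g)
  }
  if (is.null(energy_density_range)) {
    energy_density_range <- cbind(lo = gd$ed_lo, hi = gd$ed_hi)
    rownames(energy_density_range) <- g
  }
  cfg <- structure(
    list(n_participants = n_participants,
         seed = as.integer(seed),
         pia_by_stratum = pia_by_stratum,
         pia6_fraction = pia6_fraction,
         price_gradient = price_gradient,
         volume_gradient = volume_gradient,
         n_items_per_group = n_items_per_group,
         base_price_per_kg = base_price_per_kg,
         energy_density_range = energy_density_range,
         loyalty_distribution = loyalty_distribution,
         annual_expenditure_scale = annual_expenditure_scale,
         light_user_fraction = light_user_fraction,
         allow_dropouts = allow_dropouts,
         price_sdlog = price_sdlog,
         groups = g),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_participants < 1) {
    stop("configuration error: n_participants must be >= 1", call. = FALSE)
  }
  p <- cfg$pia_by_stratum
  if (!is.matrix(p) || ncol(p) != 5 || nrow(p) != 8) {
    stop("configuration error: pia_by_stratum must be an 8 x 5 matrix",
         call. = FALSE)
  }
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-9)) {
    stop("configuration error: each pia_by_stratum row must be a ",
         "probability vector summing to 1", call. = FALSE)
  }
  if (cfg$pia6_fraction < 0 || cfg$pia6_fraction > 1) {
    stop("configuration error: pia6_fraction must lie in [0, 1]",
         call. = FALSE)
  }
  for (nm in c("price_gradient", "volume_gradient", "base_price_per_kg")) {
    v <- cfg[[nm]]
    if (!all(cfg$groups %in% names(v))) {
      stop("configuration error: ", nm, " must be named by all 17 groups",
           call. = FALSE)
    }
  }
  if (any(cfg$price_gradient <= 0)) {
    stop("configuration error: price_gradient must be positive for every ",
         "group", call. = FALSE)
  }
  if (any(cfg$base_price_per_kg <= 0)) {
    stop("configuration error: base_price_per_kg must be positive",
         call. = FALSE)
  }
  ed <- cfg$energy_density_range
  if (!all(cfg$groups %in% rownames(ed)) || any(ed < 0) ||
      any(ed[, 2] < ed[, 1])) {
    stop("configuration error: energy_density_range must give a ",
         "non-negative [lo, hi] interval per group", call. = FALSE)
  }
  if (length(cfg$groups) == 0) {
    stop("configuration error: empty group configuration", call. = FALSE)
  }
  invisible(cfg)
}

#' Generate the participant table
#'
#' Draws education and sex first, then PIA from the configured
#' per-stratum distribution (so any configured confounding is baked
#' in), and overrides a configured fraction with PIA level 6
#' (declined to answer). Income category is drawn around PIA so that
#' self-assessed adequacy and reported income are positively
#' correlated, as they are in real cohorts.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per participant: `id`, `sex`, `age`,
#'   `education` (1-4), `income_category` (1-7), `household_size`,
#'   `pia` (1-6), `loyalty_pct`.
#' @export
generate_population <- function(config) {
  validate_sim_config(config)
  n <- config$n_participants
  withr::with_seed(config$seed, {
    education <- sample(1:4, n, replace = TRUE,
                        prob = c(0.06, 0.37, 0.33, 0.24))
    sex <- sample(c("female", "male"), n, replace = TRUE,
                  prob = c(0.65, 0.35))
    stratum <- paste(education, sex, sep = ":")
    pia <- integer(n)
    for (s in unique(stratum)) {
      idx <- which(stratum == s)
      pia[idx] <- sample(1:5, length(idx), replace = TRUE,
                         prob = config$pia_by_stratum[s, ])
    }
    declined <- runif(n) < config$pia6_fraction
    pia[declined] <- 6L
    # income tracks PIA (level-6 participants get a level-like draw)
    pia_eff <- ifelse(pia == 6L, sample(1:5, n, replace = TRUE), pia)
    income_category <- pmin(7L, pmax(1L, as.integer(
      round(0.8 + 0.95 * pia_eff + rnorm(n, 0, 1.1)))))
    age <- pmin(90L, pmax(18L, as.integer(round(rnorm(n, 45 + 2 * pia_eff,
                                                      14)))))
    household_size <- sample(1:5, n, replace = TRUE,
                             prob = c(0.33, 0.35, 0.13, 0.13, 0.06))
    loyalty_pct <- 100 * rbeta(n, config$loyalty_distribution$shape1,
                               config$loyalty_distribution$shape2)
    tibble::tibble(
      id = sprintf("P%05d", seq_len(n)),
      sex = sex, age = age, education = as.integer(education),
      income_category = income_category,
      household_size = as.integer(household_size),
      pia = as.integer(pia),
      loyalty_pct = round(loyalty_pct, 1))
  })
}

#' Generate the food catalog
#'
#' Emits `n_items_per_group` items per food group. Energy density is
#' uniform over the configured per-group interval; nutrient amounts per
#' 100 g vary around illustrative per-group means; each item carries a
#' price multiplier (mean 1) that spreads item-level prices around the
#' group's base price.
#'
#' @param config A [sim_config()].
#' @return A tibble with `item_id`, `group`, `energy_density` (MJ/kg),
#'   `price_multiplier`, and the 11 nutrient columns ([nutrient_names()],
#'   amounts per 100 g).
#' @export
generate_catalog <- function(config) {
  validate_sim_config(config)
  gd <- group_defaults()
  m <- config$n_items_per_group
  if (m < 1) stop("configuration error: n_items_per_group must be >= 1",
                  call. = FALSE)
  withr::with_seed(config$seed + 1L, {
    cat <- gd[rep(seq_len(nrow(gd)), each = m), ]
    n <- nrow(cat)
    lo <- config$energy_density_range[cat$group, 1]
    hi <- config$energy_density_range[cat$group, 2]
    out <- tibble::tibble(
      item_id = sprintf("I%02d_%02d", rep(seq_len(nrow(gd)), each = m),
                        rep(seq_len(m), nrow(gd))),
      group = cat$group,
      energy_density = round(runif(n, lo, hi), 3),
      price_multiplier = round(runif(n, 0.75, 1.25), 3))
    for (nm in nutrient_names()) {
      out[[nm]] <- round(cat[[nm]] * runif(n, 0.7, 1.3), 4)
    }
    out
  })
}

#' Generate the transaction table
#'
#' One row per purchase line (participant, item, kg, euro, date).
#' For a group with price gradient g, the expected unit price paid by a
#' PIA-level-l participant is `base_price * g^(l-1)` (marginally over
#' items); prices are lognormal around that location so they are
#' positive and right-skewed. Volume shares shift additively by the
#' per-group volume gradient per PIA level. PIA level 6 purchases
#' follow a randomly drawn effective level 1-5.
#'
#' @param participants Output of [generate_population()].
#' @param catalog Output of [generate_catalog()].
#' @param config The same [sim_config()].
#' @return A tibble: `participant_id`, `item_id`, `quantity` (kg),
#'   `expenditure` (euro), `timestamp` (date within the study year).
#' @export
generate_transactions <- function(participants, catalog, config) {
  validate_sim_config(config)
  if (nrow(participants) == 0 || nrow(catalog) == 0) {
    stop("participants and catalog must be non-empty", call. = FALSE)
  }
  gd <- group_defaults()
  groups <- config$groups
  k <- length(groups)
  base_share <- setNames(gd$base_share, gd$group)[groups]
  typical_kg <- setNames(gd$typical_kg, gd$group)[groups]
  # expected euros per line at baseline, to convert the annual
  # expenditure scale into an expected number of purchase lines
  mean_line_value <- sum(base_share * config$base_price_per_kg[groups] *
                           typical_kg)

  withr::with_seed(config$seed + 2L, {
    n <- nrow(participants)
    eff_level <- ifelse(participants$pia == 6L,
                        sample(1:5, n, replace = TRUE), participants$pia)
    scale_i <- config$annual_expenditure_scale *
      ifelse(runif(n) < config$light_user_fraction, 0.03, 1) *
      rlnorm(n, -0.045, 0.3)  # mild person-to-person variation, mean ~1
    lambda <- scale_i / mean_line_value
    n_lines <- rpois(n, lambda)
    if (!config$allow_dropouts) n_lines <- pmax(1L, n_lines)

    pid <- rep(participants$id, n_lines)
    lvl <- rep(eff_level, n_lines)
    m <- length(pid)
    grp_idx <- integer(m)
    for (l in 1:5) {
      sel <- which(lvl == l)
      if (!length(sel)) next
      share <- base_share + config$volume_gradient[groups] * (l - 1)
      share <- pmax(share, 1e-4)
      grp_idx[sel] <- sample.int(k, length(sel), replace = TRUE,
                                 prob = share / sum(share))
    }
    grp <- groups[grp_idx]
    # uniform item choice within the group
    item_no <- sample.int(config$n_items_per_group, m, replace = TRUE)
    item_id <- sprintf("I%02d_%02d", grp_idx, item_no)
    mult <- setNames(catalog$price_multiplier, catalog$item_id)[item_id]
    quantity <- rlnorm(m, log(typical_kg[grp]), 0.5)
    loc <- config$base_price_per_kg[grp] *
      config$price_gradient[grp]^(lvl - 1) * mult
    unit_price <- rlnorm(m, log(loc) - config$price_sdlog^2 / 2,
                         config$price_sdlog)
    tibble::tibble(
      participant_id = pid,
      item_id = item_id,
      quantity = round(quantity, 4),
      expenditure = round(quantity * unit_price, 4),
      timestamp = as.Date("2018-01-01") +
        sample(0:364, m, replace = TRUE))
  })
}

#' Simulate a complete dataset
#'
#' Runs [generate_population()], [generate_catalog()] and
#' [generate_transactions()] under one configuration and optionally
#' writes `participants.csv`, `catalog.csv`, `transactions.csv`.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory for the three CSV files.
#' @return A list with `participants`, `catalog`, `transactions`.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
  participants <- generate_population(config)
  catalog <- generate_catalog(config)
  transactions <- generate_transactions(participants, catalog, config)
  out <- list(participants = participants, catalog = catalog,
              transactions = transactions)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(participants, file.path(out_dir, "participants.csv"))
    readr::write_csv(catalog, file.path(out_dir, "catalog.csv"))
    readr::write_csv(transactions, file.path(out_dir, "transactions.csv"))
  }
  invisible(out)
}

#' Read a dataset written by [simulate_dataset()]
#'
#' Real-world inputs in the same three-table schema can be read the
#' same way.
#'
#' @param dir Directory containing `participants.csv`, `catalog.csv`,
#'   `transactions.csv`.
#' @return A list with `participants`, `catalog`, `transactions`.
#' @export
read_dataset <- function(dir) {
  paths <- file.path(dir, c("participants.csv", "catalog.csv",
                            "transactions.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input validation: missing input file(s): ",
         paste(basename(missing), collapse = ", "), call. = FALSE)
  }
  list(participants = readr::read_csv(paths[1], show_col_types = FALSE),
       catalog = readr::read_csv(paths[2], show_col_types = FALSE),
       transactions = readr::read_csv(paths[3], show_col_types = FALSE))
}
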