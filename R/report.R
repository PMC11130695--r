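# Pipeline orchestration: end-to-end run, bivariate PIA trajectories,
# and a reproducibility manifest.

#' Bivariate PIA trajectories for a pair of outcomes
#'
#' Joins two median matrices into per-group series of 5 ordered points
#' (PIA levels 1 to 5), the plotting data behind price-versus-share
#' trajectory figures. The descriptive `span` is the total Euclidean
#' path length over consecutive levels (longer lines mean larger
#' between-level differences); `direction` is the sign of the x change
#' from level 1 to 5 (+1 means the arrow points right, towards higher
#' price).
#'
#' @param mm_x,mm_y [median_by_pia()] matrices for the x and y
#'   outcomes (for example `price_per_kg` and `energy_share`).
#' @return A list with `points` (tibble `group`, `level`, `x_outcome`,
#'   `x`, `y_outcome`, `y`) and `series` (tibble `group`, `span`,
#'   `direction`, `partial`).
#' @export
make_trajectories <- function(mm_x, mm_y) {
  xo <- attr(mm_x, "outcome") %||% "x"
  yo <- attr(mm_y, "outcome") %||% "y"
  pts <- dplyr::inner_join(
    dplyr::select(mm_x, "group", "level", x = "value"),
    dplyr::select(mm_y, "group", "level", y = "value"),
    by = c("group", "level")) |>
    dplyr::arrange(.data$group, .data$level) |>
    dplyr::mutate(x_outcome = xo, y_outcome = yo) |>
    dplyr::relocate("x_outcome", .before = "x")
  series <- pts |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      span = {
        ok <- !is.na(.data$x) & !is.na(.data$y)
        xs <- .data$x[ok]; ys <- .data$y[ok]
        if (length(xs) >= 2) sum(sqrt(diff(xs)^2 + diff(ys)^2)) else NA_real_
      },
      direction = {
        ok <- !is.na(.data$x)
        if (sum(ok) >= 2) sign(.data$x[ok][sum(ok)] - .data$x[ok][1])
        else NA_real_
      },
      partial = anyNA(.data$x) | anyNA(.data$y),
      .groups = "drop")
  if (any(series$partial)) {
    warning("trajectory series with missing cells flagged partial",
            call. = FALSE)
  }
  list(points = pts, series = series)
}

#' Run the full pipeline
#'
#' Simulates (or reads) the three input tables, applies the inclusion
#' filters, aggregates baskets, computes shares, drops marginal food
#' groups, tabulates medians by PIA level, runs the trend analysis and
#' price correlations, builds price-versus-share trajectories, and
#' writes every stage's output plus a run manifest to `out_dir`.
#'
#' @param config A [sim_config()] (used both to simulate and for the
#'   analysis settings), or the `sim` element of [read_config()].
#' @param out_dir Output directory; created if needed. `NULL` skips
#'   all file output.
#' @param input_dir Optional directory with pre-existing
#'   `participants.csv`, `catalog.csv`, `transactions.csv` (for
#'   example from a previous `simulate` run, or real data in the same
#'   schema); when `NULL` the tables are simulated from `config`.
#' @param n_perm Permutations for the IPW null.
#' @param q FDR level.
#' @param refs Nutrient reference table.
#' @return (Invisibly) a list with all intermediate and final objects:
#'   `data`, `included`, `exclusions`, `summaries`, `major_groups`,
#'   `medians`, `trends`, `correlations`, `trajectories`, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         input_dir = NULL, n_perm = 2000, q = 0.05,
                         refs = default_nutrient_references()) {
  data <- if (is.null(input_dir)) simulate_dataset(config)
          else read_dataset(input_dir)

  flt <- apply_inclusion_filters(data$participants, data$transactions)
  included <- flt$included
  if (nrow(included) == 0) {
    stop("inclusion filters removed every participant", call. = FALSE)
  }
  tx <- data$transactions[data$transactions$participant_id %in% included$id, ]
  summaries <- aggregate_baskets(tx, data$catalog, refs = refs) |>
    compute_shares()
  major <- select_major_groups(summaries)
  summaries_major <- summaries[summaries$group %in% major, , drop = FALSE]

  outcomes <- c("energy_share", "expenditure_share", "price_per_kg",
                "price_per_mj", "nrfi")
  medians <- lapply(setNames(outcomes, outcomes), function(oc)
    median_by_pia(summaries_major, included, oc, groups = major))
  trends <- run_trend_analysis(summaries_major, included, groups = major,
                               outcomes = outcomes, n_perm = n_perm,
                               seed = config$seed, q = q)
  correlations <- price_correlations(summaries_major)
  traj <- list(
    energy = make_trajectories(medians$price_per_kg, medians$energy_share),
    expenditure = make_trajectories(medians$price_per_kg,
                                    medians$expenditure_share))

  manifest <- list(
    package_version = as.character(utils::packageVersion("baskettrend")),
    seed = config$seed,
    n_perm = n_perm,
    fdr_level = q,
    counts = list(
      participants_in = nrow(data$participants),
      included = nrow(included),
      exclusions = as.list(table(flt$exclusions$rule)),
      transactions = nrow(data$transactions),
      major_groups = length(major)),
    config = config[c("n_participants", "seed", "pia6_fraction",
                      "n_items_per_group", "annual_expenditure_scale",
                      "light_user_fraction", "allow_dropouts",
                      "price_sdlog")],
    timestamp = format(Sys.time(), tz = "UTC"))

  result <- list(data = data, included = included,
                 exclusions = flt$exclusions, summaries = summaries,
                 major_groups = major, medians = medians, trends = trends,
                 correlations = correlations, trajectories = traj,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(data$participants,
                     file.path(out_dir, "participants.csv"))
    readr::write_csv(data$catalog, file.path(out_dir, "catalog.csv"))
    readr::write_csv(data$transactions,
                     file.path(out_dir, "transactions.csv"))
    readr::write_csv(summaries, file.path(out_dir, "basket_summaries.csv"))
    mm <- dplyr::bind_rows(lapply(outcomes, function(oc)
      dplyr::mutate(medians[[oc]], outcome = oc, .before = 1)))
    readr::write_csv(mm, file.path(out_dir, "median_matrix.csv"))
    readr::write_csv(trends, file.path(out_dir, "trend_results.csv"))
    readr::write_csv(correlations$within,
                     file.path(out_dir, "correlations.csv"))
    tpts <- dplyr::bind_rows(traj$energy$points, traj$expenditure$points)
    readr::write_csv(tpts, file.path(out_dir, "trajectories.csv"))
    manifest$file_digests <- as.list(tools::md5sum(
      file.path(out_dir, c("participants.csv", "catalog.csv",
                           "transactions.csv", "basket_summaries.csv",
                           "median_matrix.csv", "trend_results.csv",
                           "correlations.csv", "trajectories.csv"))))
    names(manifest$file_digests) <- basename(names(manifest$file_digests))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    result$manifest <- manifest
  }
  invisible(result)
}

#' Read a YAML pipeline configuration
#'
#' Maps a YAML file onto [sim_config()] (under `sim:`), filter
#' thresholds (under `filters:`) and statistical settings (under
#' `inference:`); anything omitted takes the package default.
#'
#' @param path YAML file path.
#' @return A list with `sim` (a `sim_config`), `filters`, `inference`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  for (nm in c("price_gradient", "volume_gradient", "base_price_per_kg")) {
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
  }
  if (!is.null(sim_args$pia_by_stratum)) {
    sim_args$pia_by_stratum <- do.call(rbind, sim_args$pia_by_stratum)
  }
  if (!is.null(sim_args$energy_density_range)) {
    sim_args$energy_density_range <- do.call(rbind,
                                             sim_args$energy_density_range)
  }
  list(sim = do.call(sim_config, sim_args),
       filters = utils::modifyList(list(loyalty_min = 41,
                                        expenditure_min = 100,
                                        expenditure_threshold = 1,
                                        energy_threshold = 0.2),
                                   y$filters %||% list()),
       inference = utils::modifyList(list(n_perm = 2000, q = 0.05,
                                          bh_family = "per_outcome"),
                                     y$inference %||% list()))
}
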