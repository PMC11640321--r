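#' Line through two temperature anchors
#'
#' Builds the slope and intercept of a cluster-size vs temperature line
#' from its values at two temperatures, as `y = slope * T + intercept`.
#' This is how the published per-site equations are derived from the values
#' reported at the ends of the temperature range.
#'
#' @param anchor_low,anchor_high Numeric length-2 vectors `(temperature,
#'   individuals per cluster)` with distinct temperatures.
#' @return A list with `slope` (individuals per degree) and `intercept`
#'   (individuals at temperature 0).
#' @examples
#' line_from_anchors(c(1, 3), c(10, 0)) # slope -1/3, intercept 10/3
#' @export
line_from_anchors <- function(anchor_low, anchor_high) {
  stopifnot(length(anchor_low) == 2, length(anchor_high) == 2)
  if (anchor_low[1] == anchor_high[1]) {
    abort("anchor temperatures must be distinct.")
  }
  slope <- (anchor_high[2] - anchor_low[2]) / (anchor_high[1] - anchor_low[1])
  intercept <- anchor_low[2] - slope * anchor_low[1]
  list(slope = slope, intercept = intercept)
}

#' The four built-in empirical site lines
#'
#' Cluster-size vs temperature lines for the four field sites, constructed
#' by [line_from_anchors()] from the published anchor values at
#' temperatures 1 and 10: Arashiyama falls from 3 individuals per cluster
#' to none, Katsuyama is a constant 2.2, Takasakiyama falls from 4.8 to
#' 2.8, and Shodoshima from 30 to 20.
#'
#' @return A tibble with columns `site`, `t_low`, `y_low`, `t_high`,
#'   `y_high`, `slope`, `intercept`.
#' @export
builtin_site_lines <- function() {
  anchors <- tibble::tribble(
    ~site,           ~t_low, ~y_low, ~t_high, ~y_high,
    "Arashiyama",     1,      3,      10,      0,
    "Katsuyama",      1,      2.2,    10,      2.2,
    "Takasakiyama",   1,      4.8,    10,      2.8,
    "Shodoshima",     1,      30,     10,      20
  )
  coefs <- purrr::pmap(anchors, function(site, t_low, y_low, t_high, y_high) {
    line_from_anchors(c(t_low, y_low), c(t_high, y_high))
  })
  dplyr::mutate(
    anchors,
    slope = purrr::map_dbl(coefs, "slope"),
    intercept = purrr::map_dbl(coefs, "intercept")
  )
}

#' Fit a cluster-size vs temperature line to simulated runs
#'
#' Ordinary least squares of the per-run mean cluster size on temperature
#' for one (group size, joining threshold) combination, pooling leaving
#' thresholds and replicates. Runs without clusters carry no cluster-size
#' signal and are excluded.
#'
#' @param table A sweep result table.
#' @param group_size,join_threshold The combination to fit.
#' @return A one-row tibble: `group_size`, `join_threshold`, `slope`,
#'   `intercept`, `n_points`.
#' @export
fit_temperature_line <- function(table, group_size, join_threshold) {
  tb <- dplyr::filter(
    table,
    .data$group_size == .env$group_size,
    .data$join_threshold == .env$join_threshold,
    !.data$no_cluster
  )
  if (dplyr::n_distinct(tb$temperature) < 2L) {
    abort(sprintf(
      "need clustered runs at >= 2 temperatures for N=%d, J=%d.",
      group_size, join_threshold
    ))
  }
  fit <- lm(mean_cluster_size ~ temperature, data = tb)
  tibble::tibble(
    group_size = as.integer(group_size),
    join_threshold = as.integer(join_threshold),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    n_points = nrow(tb)
  )
}

#' Fit temperature lines for every (group size, J) combination in a table
#'
#' @param table A sweep result table (may pool several group sizes).
#' @return A tibble of [fit_temperature_line()] rows, one per combination
#'   with sufficient temperature coverage.
#' @export
fit_temperature_lines <- function(table) {
  combos <- dplyr::distinct(table, .data$group_size, .data$join_threshold) |>
    dplyr::arrange(.data$group_size, .data$join_threshold)
  purrr::pmap(combos, function(group_size, join_threshold) {
    tryCatch(
      fit_temperature_line(table, group_size, join_threshold),
      error = function(e) {
        warn(sprintf("skipping N=%d, J=%d: %s", group_size, join_threshold,
                     conditionMessage(e)))
        NULL
      }
    )
  }) |>
    dplyr::bind_rows()
}

#' Rank simulated lines against an empirical site line
#'
#' For each fitted line, takes the absolute difference to the site's
#' intercept and to its slope, ranks the fits on each criterion separately
#' (ascending, average ranks on ties), and orders them by the mean of the
#' two ranks -- smallest first, i.e. best agreement first.
#'
#' @param fits A tibble of fitted lines (from [fit_temperature_lines()]).
#' @param site One row of [builtin_site_lines()] (or any list with `slope`
#'   and `intercept`).
#' @return `fits` with `abs_diff_intercept`, `abs_diff_slope`,
#'   `rank_intercept`, `rank_slope`, `mean_rank`, sorted by `mean_rank`.
#' @export
rank_against_site <- function(fits, site) {
  if (nrow(fits) == 0L) abort("no fitted lines to rank.")
  fits |>
    dplyr::mutate(
      abs_diff_intercept = abs(.data$intercept - site$intercept),
      abs_diff_slope = abs(.data$slope - site$slope),
      rank_intercept = rank(.data$abs_diff_intercept, ties.method = "average"),
      rank_slope = rank(.data$abs_diff_slope, ties.method = "average"),
      mean_rank = (.data$rank_intercept + .data$rank_slope) / 2
    ) |>
    dplyr::arrange(.data$mean_rank, .data$group_size, .data$join_threshold)
}

#' Rank every (group size, J) line against every built-in site
#'
#' @param fits A tibble of fitted lines.
#' @param sites Site lines (default [builtin_site_lines()]).
#' @return A tibble of rankings with a leading `site` column.
#' @export
rank_all_sites <- function(fits, sites = builtin_site_lines()) {
  purrr::map(seq_len(nrow(sites)), function(i) {
    dplyr::mutate(rank_against_site(fits, sites[i, ]),
                  site = sites$site[i], .before = 1)
  }) |>
    dplyr::bind_rows()
}
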