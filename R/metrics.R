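#' Fraction of runs that ended with no cluster
#'
#' @param table A sweep result table (possibly several sweeps bound
#'   together).
#' @return The fraction of rows with `no_cluster = TRUE`.
#' @export
no_cluster_fraction <- function(table) {
  if (nrow(table) == 0L) abort("empty sweep table.")
  mean(table$no_cluster)
}

#' Pool the cluster sizes of many runs
#'
#' @param table A sweep result table.
#' @return An integer vector of all cluster sizes across the rows.
#' @export
pooled_cluster_sizes <- function(table) {
  unlist(parse_cluster_sizes(table$cluster_sizes), use.names = FALSE) %||%
    integer()
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Proportion of pooled clusters exceeding a size threshold
#'
#' The published categories use strict thresholds: "extra-large" clusters
#' have more than 51 members, and the largest huddle ever observed (on
#' Shodoshima) motivates the > 137 screen used to discard implausible group
#' sizes.
#'
#' @param sizes Integer vector of pooled cluster sizes.
#' @param threshold Strict lower bound (default 51).
#' @return Fraction of clusters strictly larger than `threshold`; 0 with a
#'   warning when `sizes` is empty.
#' @examples
#' extra_large_proportion(c(60, 10, 52, 3)) # 0.5
#' @export
extra_large_proportion <- function(sizes, threshold = 51L) {
  if (threshold < 0) abort("`threshold` must be non-negative.")
  if (length(sizes) == 0L) {
    warn("no clusters pooled; returning 0.")
    return(0)
  }
  mean(sizes > threshold)
}

#' Per-combination summaries of a sweep table
#'
#' Groups the runs by the given keys and reports, per group: the number of
#' runs, the mean over runs of the per-run mean cluster size (runs with at
#' least one cluster only), the mean number of clusters, the fraction of
#' runs with no cluster, and -- over the pooled clusters of the group -- the
#' proportions of large (20--51 members), extra-large (> 51) and
#' over-observed-maximum (> 137) clusters.
#'
#' @param table A sweep result table.
#' @param keys Grouping columns (default `c("group_size",
#'   "join_threshold")`, the resolution at which the simulated lines are
#'   compared with the empirical sites).
#' @return A tibble with one row per key combination.
#' @export
combination_summaries <- function(table,
                                  keys = c("group_size", "join_threshold")) {
  if (nrow(table) == 0L) abort("empty sweep table.")
  if (!all(keys %in% names(table))) {
    abort(sprintf(
      "unknown grouping key(s): %s",
      paste(setdiff(keys, names(table)), collapse = ", ")
    ))
  }
  table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(g, key) {
      pooled <- pooled_cluster_sizes(g)
      has_cluster <- !g$no_cluster
      prop_of <- function(cond) {
        if (length(pooled) == 0L) NA_real_ else mean(cond)
      }
      tibble::tibble(
        n_runs = nrow(g),
        mean_of_mean_cluster_size = if (any(has_cluster)) {
          mean(g$mean_cluster_size[has_cluster])
        } else {
          NA_real_
        },
        mean_n_clusters = mean(g$n_clusters),
        prop_no_cluster = mean(g$no_cluster),
        prop_large = prop_of(pooled >= 20L & pooled <= 51L),
        prop_extra_large = prop_of(pooled > 51L),
        prop_over_observed_max = prop_of(pooled > 137L)
      )
    }) |>
    dplyr::ungroup()
}

#' Write per-combination summaries as CSV
#' @param summaries Output of [combination_summaries()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summaries, path) {
  readr::write_csv(summaries, path, na = "")
  invisible(path)
}
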