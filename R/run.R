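#' Execute one simulation run to termination
#'
#' Initialises a world from `params` and `seed` and ticks it until either
#' every agent is huddled (`termination = "all_joined"`) or the tick cap is
#' reached (`termination = "step_cap"`). The outcome records the clusters
#' present at termination (all of size >= 2 by construction), their count
#' and mean size, and whether the run ended with no cluster at all.
#' Identical `(params, seed)` always yield an identical record.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed for the run.
#' @param engine `"cpp"` (default, compiled) or `"r"` (the reference
#'   stepper; identical trajectories, far slower -- intended for tests).
#' @return A one-row tibble with columns `group_size`, `temperature`,
#'   `join_threshold`, `leave_threshold`, `seed`, `n_clusters`,
#'   `cluster_sizes` (semicolon-joined, `""` when none),
#'   `mean_cluster_size` (`NA` when no cluster), `no_cluster`,
#'   `termination`, `steps_elapsed`.
#' @examples
#' run_simulation(sim_params(20, 1, 1, 10, step_cap = 500), seed = 1)
#' @export
run_simulation <- function(params, seed, engine = c("cpp", "r")) {
  stopifnot(inherits(params, "sim_params"))
  engine <- match.arg(engine)
  set.seed(seed)
  if (engine == "cpp") {
    res <- .sim_run_cpp(unclass(params), -1L, FALSE)
    sizes <- as.integer(res$cluster_sizes)
    steps <- res$steps_elapsed
    termination <- if (res$n_lone > 0L) "step_cap" else "all_joined"
  } else {
    world <- init_world(params, seed = NULL)
    while (any(world$agents$cluster_id == -1L) &&
           world$tick < params$step_cap) {
      world <- tick_world(world)
    }
    sizes <- cluster_sizes(world)
    steps <- world$tick
    termination <- if (any(world$agents$cluster_id == -1L)) {
      "step_cap"
    } else {
      "all_joined"
    }
  }
  run_record(params, seed, sizes, termination, steps)
}

# Assemble a one-row RunRecord tibble from a terminated run.
run_record <- function(params, seed, sizes, termination, steps) {
  n_clusters <- length(sizes)
  tibble::tibble(
    group_size = params$group_size,
    temperature = params$temperature,
    join_threshold = params$join_threshold,
    leave_threshold = params$leave_threshold,
    seed = as.integer(seed),
    n_clusters = n_clusters,
    mean_cluster_size = if (n_clusters > 0) mean(sizes) else NA_real_,
    no_cluster = n_clusters == 0L,
    termination = termination,
    steps_elapsed = as.integer(steps),
    cluster_sizes = paste(sizes, collapse = ";")
  )
}

#' Advance a fresh world by a fixed number of ticks
#'
#' Runs exactly `ticks` ticks from a newly initialised world, with no
#' termination check, and returns the full world state. Both engines follow
#' the same random-number protocol, so for a given seed they return the
#' same trajectory; this is the hook the test suite uses to check the
#' compiled engine against the reference stepper.
#'
#' @inheritParams run_simulation
#' @param ticks Number of ticks to run (>= 0).
#' @return A [huddle_world] object at tick `ticks`.
#' @export
simulate_ticks <- function(params, seed, ticks, engine = c("cpp", "r")) {
  stopifnot(inherits(params, "sim_params"), ticks >= 0)
  engine <- match.arg(engine)
  set.seed(seed)
  if (engine == "r") {
    world <- init_world(params, seed = NULL)
    for (t in seq_len(ticks)) world <- tick_world(world)
    return(world)
  }
  res <- .sim_run_cpp(unclass(params), as.integer(ticks), TRUE)
  structure(
    list(
      params = params,
      agents = tibble::as_tibble(res$agents),
      clusters = tibble::tibble(
        cluster_id = as.integer(res$cluster_ids),
        anchor_x = as.numeric(res$anchor_x),
        anchor_y = as.numeric(res$anchor_y),
        members = lapply(res$members, as.integer)
      ),
      tick = as.integer(res$steps_elapsed),
      next_cluster_id = as.integer(res$next_cluster_id)
    ),
    class = "huddle_world"
  )
}

#' Parse a semicolon-joined `cluster_sizes` field
#'
#' @param x Character vector as stored in run records ("" for no cluster).
#' @return A list of integer vectors, one per element of `x`.
#' @examples
#' parse_cluster_sizes(c("12;3;2", ""))
#' @export
parse_cluster_sizes <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(s) as.integer(s[nzchar(s)]))
}
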