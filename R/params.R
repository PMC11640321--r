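#' Parameters for a single simulation run
#'
#' Bundles and validates the parameter vector of one run: the group size
#' (which is also the maximum attainable cluster size), the temperature on
#' the model's 1--10 scale, the joining and leaving thresholds, the toroidal
#' grid dimensions, the sensing radius and the tick cap after which a run is
#' cut off.
#'
#' @param group_size Number of agents (>= 2).
#' @param temperature Integer temperature, 1--10.
#' @param join_threshold Joining threshold J, integer >= 1.
#' @param leave_threshold Leaving threshold L, integer >= 10.
#' @param grid_width,grid_height Grid dimensions in patches (default 16 x 16,
#'   wrapping in both directions).
#' @param sensing_radius Radius (in patch units) within which an agent can
#'   detect conspecifics (default 2).
#' @param step_cap Maximum number of ticks before a run is terminated
#'   (default 20000).
#' @return An object of class `sim_params` (a named list).
#' @examples
#' sim_params(group_size = 70, temperature = 3, join_threshold = 2,
#'            leave_threshold = 10)
#' @export
sim_params <- function(group_size, temperature, join_threshold,
                       leave_threshold, grid_width = 16L, grid_height = 16L,
                       sensing_radius = 2, step_cap = 20000L) {
  chk_int <- function(x, nm) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x)) {
      abort(sprintf("`%s` must be a single integer-valued number.", nm))
    }
    as.integer(x)
  }
  group_size <- chk_int(group_size, "group_size")
  temperature <- chk_int(temperature, "temperature")
  join_threshold <- chk_int(join_threshold, "join_threshold")
  leave_threshold <- chk_int(leave_threshold, "leave_threshold")
  grid_width <- chk_int(grid_width, "grid_width")
  grid_height <- chk_int(grid_height, "grid_height")
  step_cap <- chk_int(step_cap, "step_cap")
  if (group_size < 2) abort("`group_size` must be >= 2.")
  if (temperature < 1 || temperature > 10) {
    abort("`temperature` must lie in 1..10.")
  }
  if (join_threshold < 1) abort("`join_threshold` must be >= 1.")
  if (leave_threshold < 10) abort("`leave_threshold` must be >= 10.")
  if (grid_width < 1 || grid_height < 1) abort("grid dimensions must be >= 1.")
  if (!is.numeric(sensing_radius) || length(sensing_radius) != 1L ||
      sensing_radius <= 0) {
    abort("`sensing_radius` must be a positive number.")
  }
  if (step_cap < 0) abort("`step_cap` must be >= 0.")
  structure(
    list(
      group_size = group_size, temperature = temperature,
      join_threshold = join_threshold, leave_threshold = leave_threshold,
      grid_width = grid_width, grid_height = grid_height,
      sensing_radius = as.numeric(sensing_radius),
      step_cap = step_cap
    ),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> N=%d T=%d J=%d L=%d grid=%dx%d radius=%g step_cap=%d\n",
    x$group_size, x$temperature, x$join_threshold, x$leave_threshold,
    x$grid_width, x$grid_height, x$sensing_radius, x$step_cap
  ))
  invisible(x)
}
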