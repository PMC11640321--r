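#' Build a validated pipeline configuration
#'
#' The configuration drives [run_pipeline()]: which group sizes to sweep,
#' any overrides of the default factorial grid, the replicate count, the
#' base seed every run seed derives from, the tick cap, the output
#' directory, which stages to run, and the worker count. Defaults reproduce
#' the published sweep design (six group sizes, temperatures 1--10, joining
#' thresholds 1--8, 100 replicates, per-size leaving-threshold grids, tick
#' cap 20000).
#'
#' @param group_sizes Group sizes to sweep.
#' @param temperatures,join_thresholds Grid overrides.
#' @param leave_thresholds Leaving-threshold override; `NULL` uses the
#'   per-size defaults of [default_grid()].
#' @param replicates Replicates per combination.
#' @param base_seed Base seed; all randomness in the pipeline flows from it
#'   (run seeds are `base_seed + ordinal`, offset per group size).
#' @param step_cap Tick cap per run.
#' @param output_dir Directory for all written artefacts.
#' @param stages Named logical vector/list switching stages on or off
#'   (names among `sweep`, `metrics`, `glm`, `comparison`).
#' @param worker_count Parallel workers for the sweep stage.
#' @return A validated `pipeline_config` object.
#' @export
pipeline_config <- function(group_sizes = c(70L, 100L, 130L, 160L, 300L,
                                            400L),
                            temperatures = 1:10, join_thresholds = 1:8,
                            leave_thresholds = NULL, replicates = 100L,
                            base_seed = 1L, step_cap = 20000L,
                            output_dir = "sarudango-output",
                            stages = c(sweep = TRUE, metrics = TRUE,
                                       glm = TRUE, comparison = TRUE),
                            worker_count = 1L) {
  stages <- as.list(stages)
  known_stages <- c("sweep", "metrics", "glm", "comparison")
  if (!all(names(stages) %in% known_stages)) {
    abort(sprintf("unknown stage(s): %s",
                  paste(setdiff(names(stages), known_stages), collapse = ", ")))
  }
  st <- stats::setNames(rep(TRUE, 4), known_stages)
  st[names(stages)] <- vapply(stages, isTRUE, logical(1))
  # domain validation is delegated to the same checks each run will apply
  for (gs in group_sizes) {
    sweep_grid(gs, temperatures, join_thresholds, leave_thresholds,
               replicates, base_seed, step_cap)
    sim_params(gs, min(temperatures), min(join_thresholds),
               if (is.null(leave_thresholds)) 10L else min(leave_thresholds),
               step_cap = step_cap)
  }
  stopifnot(length(worker_count) == 1L, worker_count >= 1)
  structure(
    list(
      group_sizes = as.integer(group_sizes),
      temperatures = as.integer(temperatures),
      join_thresholds = as.integer(join_thresholds),
      leave_thresholds = if (is.null(leave_thresholds)) NULL
                         else as.integer(leave_thresholds),
      replicates = as.integer(replicates),
      base_seed = as.integer(base_seed),
      step_cap = as.integer(step_cap),
      output_dir = output_dir,
      stages = as.list(st),
      worker_count = as.integer(worker_count)
    ),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' An empty file yields the full default configuration. Unknown keys and
#' out-of-domain values are rejected with the offending key named.
#'
#' @param path Path to a YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      abort(sprintf("malformed config file %s: %s", path,
                    conditionMessage(e)))
    }
  )
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) abort("config file must contain a YAML mapping.")
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  tryCatch(
    do.call(pipeline_config, raw),
    error = function(e) {
      abort(sprintf("invalid config %s: %s", path, conditionMessage(e)))
    }
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "<pipeline_config> N in {%s}; T %s; J %s; L %s; %d reps; seed %d; stages: %s\n",
    paste(x$group_sizes, collapse = ","),
    paste(range(x$temperatures), collapse = "-"),
    paste(range(x$join_thresholds), collapse = "-"),
    if (is.null(x$leave_thresholds)) "per-size default"
    else paste(x$leave_thresholds, collapse = ","),
    x$replicates, x$base_seed,
    paste(names(Filter(isTRUE, x$stages)), collapse = "+")
  ))
  invisible(x)
}
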