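#' Define a factorial parameter sweep
#'
#' A sweep crosses temperatures, joining thresholds and leaving thresholds
#' for one group size, runs every combination `replicates` times, and binds
#' one seed to each run (`base_seed + ordinal`), so results never depend on
#' scheduling or worker count.
#'
#' @param group_size Number of agents.
#' @param temperatures Integer temperatures (each in 1..10).
#' @param join_thresholds Integer joining thresholds (each >= 1).
#' @param leave_thresholds Integer leaving thresholds (each >= 10).
#' @param replicates Replicates per combination (>= 1).
#' @param base_seed Seed for the first run of the sweep.
#' @param step_cap Tick cap applied to every run (default 20000).
#' @return An object of class `sweep_grid`.
#' @seealso [default_grid()], [enumerate_runs()], [execute_sweep()]
#' @export
sweep_grid <- function(group_size, temperatures = 1:10,
                       join_thresholds = 1:8, leave_thresholds = NULL,
                       replicates = 100L, base_seed = 1L,
                       step_cap = 20000L) {
  if (is.null(leave_thresholds)) {
    leave_thresholds <- default_leave_thresholds(group_size)
  }
  stopifnot(
    length(temperatures) >= 1, length(join_thresholds) >= 1,
    length(leave_thresholds) >= 1, replicates >= 1
  )
  if (any(temperatures < 1 | temperatures > 10)) {
    abort("all `temperatures` must lie in 1..10.")
  }
  if (any(join_thresholds < 1)) abort("all `join_thresholds` must be >= 1.")
  if (any(leave_thresholds < 10)) {
    abort("all `leave_thresholds` must be >= 10.")
  }
  n_total <- length(temperatures) * length(join_thresholds) *
    length(leave_thresholds) * replicates
  if (base_seed + n_total >= 2^31) {
    abort("`base_seed` too large: run seeds would overflow integer range.")
  }
  structure(
    list(
      group_size = as.integer(group_size),
      temperatures = as.integer(temperatures),
      join_thresholds = as.integer(join_thresholds),
      leave_thresholds = as.integer(leave_thresholds),
      replicates = as.integer(replicates),
      base_seed = as.integer(base_seed),
      step_cap = as.integer(step_cap)
    ),
    class = "sweep_grid"
  )
}

# Leaving-threshold grids used in the published experiment: steps of 10 up
# to 70 for N = 70; steps of 40 from 10, truncated at min(N, 170), for the
# other sizes.
default_leave_thresholds <- function(group_size) {
  if (group_size == 70L) {
    seq(10L, 70L, by = 10L)
  } else {
    seq(10L, min(group_size, 170L), by = 40L)
  }
}

#' The default sweep for a given group size
#'
#' Temperatures 1--10, joining thresholds 1--8, 100 replicates, and the
#' leaving-threshold grid used in the published experiment: 10, 20, ..., 70
#' for a group of 70 (56,000 runs in total), and 10, 50, 90, ... truncated
#' at `min(group_size, 170)` for the other sizes.
#'
#' @param group_size Number of agents; the study sizes are 70, 100, 130,
#'   160, 300 and 400 (other values are allowed with a warning).
#' @param ... Overrides passed on to [sweep_grid()] (e.g. `replicates`,
#'   `base_seed`, `step_cap`).
#' @return A `sweep_grid`.
#' @examples
#' count_runs(default_grid(70)) # 56000
#' @export
default_grid <- function(group_size, ...) {
  if (!group_size %in% c(70L, 100L, 130L, 160L, 300L, 400L)) {
    warn(sprintf("group size %d is not one of the study sizes.", group_size))
  }
  sweep_grid(group_size, ...)
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat(sprintf(
    "<sweep_grid> N=%d | T: %s | J: %s | L: %s | %d reps | %d runs\n",
    x$group_size, paste(range(x$temperatures), collapse = "-"),
    paste(range(x$join_thresholds), collapse = "-"),
    paste(x$leave_thresholds, collapse = ","), x$replicates, count_runs(x)
  ))
  invisible(x)
}

#' Number of runs a sweep will execute
#'
#' @param grid A [sweep_grid()].
#' @return `|temperatures| * |join_thresholds| * |leave_thresholds| *
#'   replicates`.
#' @export
count_runs <- function(grid) {
  stopifnot(inherits(grid, "sweep_grid"))
  length(grid$temperatures) * length(grid$join_thresholds) *
    length(grid$leave_thresholds) * grid$replicates
}

#' Enumerate the runs of a sweep
#'
#' Deterministic lexicographic order over (temperature, join threshold,
#' leave threshold, replicate), with `seed = base_seed + ordinal` (ordinal
#' starting at 0). The same grid always yields the same list.
#'
#' @param grid A [sweep_grid()].
#' @return A tibble with one row per run: the parameter vector, `replicate`
#'   (0-based) and `seed`.
#' @export
enumerate_runs <- function(grid) {
  stopifnot(inherits(grid, "sweep_grid"))
  specs <- tidyr::expand_grid(
    temperature = grid$temperatures,
    join_threshold = grid$join_thresholds,
    leave_threshold = grid$leave_thresholds,
    replicate = seq_len(grid$replicates) - 1L
  )
  dplyr::mutate(specs,
    group_size = grid$group_size,
    seed = grid$base_seed + dplyr::row_number() - 1L,
    .before = 1
  )
}

#' Execute a sweep
#'
#' Runs every enumerated spec with the compiled engine. Each run's seed is
#' bound to its spec, so the result table is identical whatever
#' `worker_count` is (workers only split the embarrassingly parallel run
#' list via forked processes).
#'
#' @param grid A [sweep_grid()].
#' @param worker_count Number of parallel workers (default 1).
#' @param progress Print progress messages at a fixed cadence (default
#'   `FALSE`).
#' @return A tibble with one row per run: parameter vector, `replicate`,
#'   `seed`, and the outcome fields of [run_simulation()].
#' @examples
#' \donttest{
#' g <- sweep_grid(20, temperatures = 1, join_thresholds = 1,
#'                 leave_thresholds = 10, replicates = 2, step_cap = 500)
#' execute_sweep(g)
#' }
#' @export
execute_sweep <- function(grid, worker_count = 1L, progress = FALSE) {
  stopifnot(inherits(grid, "sweep_grid"), worker_count >= 1)
  specs <- enumerate_runs(grid)
  n <- nrow(specs)
  cadence <- max(1L, n %/% 20L)
  run_one <- function(i) {
    sp <- specs[i, ]
    rec <- tryCatch(
      run_simulation(
        sim_params(sp$group_size, sp$temperature, sp$join_threshold,
                   sp$leave_threshold, step_cap = grid$step_cap),
        seed = sp$seed
      ),
      error = function(e) {
        abort(sprintf(
          "sweep run failed (N=%d T=%d J=%d L=%d replicate=%d seed=%d): %s",
          sp$group_size, sp$temperature, sp$join_threshold,
          sp$leave_threshold, sp$replicate, sp$seed, conditionMessage(e)
        ))
      }
    )
    if (progress && worker_count == 1L && i %% cadence == 0L) {
      message(sprintf("sweep: run %d/%d (seed %d)", i, n, sp$seed))
    }
    rec
  }
  recs <- if (worker_count == 1L) {
    lapply(seq_len(n), run_one)
  } else {
    out <- parallel::mclapply(seq_len(n), run_one,
                              mc.cores = worker_count,
                              mc.preschedule = TRUE)
    bad <- vapply(out, inherits, logical(1), "try-error")
    if (any(bad)) abort(paste(unlist(out[bad]), collapse = "\n"))
    out
  }
  dplyr::bind_rows(recs) |>
    dplyr::mutate(replicate = specs$replicate, .after = "leave_threshold")
}

sweep_csv_cols <- c(
  "group_size", "temperature", "join_threshold", "leave_threshold",
  "replicate", "seed", "n_clusters", "mean_cluster_size", "no_cluster",
  "termination", "steps_elapsed", "cluster_sizes"
)

#' Write / read a sweep result table as CSV
#'
#' The on-disk schema has a fixed header (`group_size`, `temperature`,
#' `join_threshold`, `leave_threshold`, `replicate`, `seed`, `n_clusters`,
#' `mean_cluster_size` -- empty when no cluster --, `no_cluster` as 0/1,
#' `termination`, `steps_elapsed`, and the semicolon-joined
#' `cluster_sizes`). Reading a written file reproduces the in-memory table
#' exactly.
#'
#' @param table A sweep result table.
#' @param path File path.
#' @return `write_sweep_csv()` returns `path` invisibly; `read_sweep_csv()`
#'   returns the table.
#' @export
write_sweep_csv <- function(table, path) {
  stopifnot(all(sweep_csv_cols %in% names(table)))
  out <- dplyr::mutate(
    table[, sweep_csv_cols],
    no_cluster = as.integer(.data$no_cluster)
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  tb <- readr::read_csv(
    path,
    col_types = readr::cols(
      group_size = "i", temperature = "i", join_threshold = "i",
      leave_threshold = "i", replicate = "i", seed = "i", n_clusters = "i",
      mean_cluster_size = "d", no_cluster = "i", termination = "c",
      steps_elapsed = "i", cluster_sizes = "c"
    )
  )
  dplyr::mutate(
    tb,
    no_cluster = .data$no_cluster == 1L,
    cluster_sizes = dplyr::coalesce(.data$cluster_sizes, "")
  )
}
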