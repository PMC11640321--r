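# Hand-built sweep-table rows for the summary and regression operations.
fake_row <- function(gs, t, j, l, sizes, seed = 1L, rep = 0L) {
  tibble::tibble(
    group_size = as.integer(gs), temperature = as.integer(t),
    join_threshold = as.integer(j), leave_threshold = as.integer(l),
    replicate = as.integer(rep), seed = as.integer(seed),
    n_clusters = length(sizes),
    cluster_sizes = paste(sizes, collapse = ";"),
    mean_cluster_size = if (length(sizes)) mean(sizes) else NA_real_,
    no_cluster = length(sizes) == 0L,
    termination = if (sum(sizes) == gs) "all_joined" else "step_cap",
    steps_elapsed = 100L
  )
}

# A reduced regeneration of the study sweep, shared by the acceptance
# tests: group sizes 70-160, the default factorial grids, few replicates.
# Built once per test run and cached on disk under tempdir().
acceptance_sweep <- local({
  cache <- NULL
  function(replicates = 1L) {
    if (!is.null(cache)) return(cache)
    path <- file.path(tempdir(), sprintf("acc_sweep_r%d.rds", replicates))
    if (file.exists(path)) {
      cache <<- readRDS(path)
      return(cache)
    }
    offset <- 424200L
    tabs <- lapply(c(70L, 100L, 130L, 160L), function(gs) {
      g <- default_grid(gs, replicates = replicates, base_seed = offset)
      offset <<- offset + count_runs(g)
      execute_sweep(g)
    })
    cache <<- dplyr::bind_rows(tabs)
    saveRDS(cache, path)
    cache
  }
})

# Thinned sweeps at the large group sizes used only by the exclusion
# diagnostic (temperatures subsampled, single replicate).
large_size_sweep <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    path <- file.path(tempdir(), "acc_sweep_large.rds")
    if (file.exists(path)) {
      cache <<- readRDS(path)
      return(cache)
    }
    offset <- 777000L
    tabs <- lapply(c(300L, 400L), function(gs) {
      g <- sweep_grid(gs, temperatures = c(1L, 5L, 9L),
                      replicates = 1L, base_seed = offset)
      offset <<- offset + count_runs(g)
      execute_sweep(g)
    })
    cache <<- dplyr::bind_rows(tabs)
    saveRDS(cache, path)
    cache
  }
})
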