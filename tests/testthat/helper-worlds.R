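# Construct a valid huddle_world by hand for operation-level tests.
# `agents` is a tibble/data.frame with agent_id, x, y and optionally
# cluster_id; clusters are derived from the cluster_id column, with the
# anchor at the mean member position (positions are taken as given, not
# re-spaced).
make_world <- function(params, agents, next_cluster_id = NULL) {
  n <- params$group_size
  stopifnot(nrow(agents) == n)
  ag <- tibble::tibble(
    agent_id = as.integer(agents$agent_id),
    x = as.numeric(agents$x),
    y = as.numeric(agents$y),
    heading = if ("heading" %in% names(agents)) agents$heading else rep(0, n),
    cluster_id = if ("cluster_id" %in% names(agents)) {
      as.integer(agents$cluster_id)
    } else {
      rep(-1L, n)
    },
    huddle_time = if ("huddle_time" %in% names(agents)) {
      as.integer(agents$huddle_time)
    } else {
      rep(0L, n)
    }
  )
  ag <- ag[order(ag$agent_id), ]
  cids <- sort(unique(ag$cluster_id[ag$cluster_id >= 0L]))
  clusters <- tibble::tibble(
    cluster_id = cids,
    anchor_x = vapply(cids, function(cid) mean(ag$x[ag$cluster_id == cid]),
                      numeric(1)),
    anchor_y = vapply(cids, function(cid) mean(ag$y[ag$cluster_id == cid]),
                      numeric(1)),
    members = lapply(cids, function(cid) which(ag$cluster_id == cid))
  )
  structure(
    list(
      params = params, agents = ag, clusters = clusters, tick = 0L,
      next_cluster_id = as.integer(
        next_cluster_id %||% (if (length(cids)) max(cids) + 1L else 0L)
      )
    ),
    class = "huddle_world"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Compare two worlds field by field (positions to floating-point identity).
expect_same_world <- function(w1, w2) {
  expect_equal(as.data.frame(w1$agents), as.data.frame(w2$agents),
               tolerance = 0)
  expect_identical(as.integer(w1$clusters$cluster_id),
                   as.integer(w2$clusters$cluster_id))
  expect_equal(w1$clusters$anchor_x, w2$clusters$anchor_x, tolerance = 0)
  expect_equal(w1$clusters$anchor_y, w2$clusters$anchor_y, tolerance = 0)
  expect_identical(lapply(w1$clusters$members, as.integer),
                   lapply(w2$clusters$members, as.integer))
  expect_identical(as.integer(w1$tick), as.integer(w2$tick))
  expect_identical(as.integer(w1$next_cluster_id),
                   as.integer(w2$next_cluster_id))
}

# toroidal distance helper mirroring the package metric, for assertions
torus_dist <- function(x1, y1, x2, y2, w, h) {
  dx <- pmin(abs(x1 - x2), w - abs(x1 - x2))
  dy <- pmin(abs(y1 - y2), h - abs(y1 - y2))
  sqrt(dx^2 + dy^2)
}
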