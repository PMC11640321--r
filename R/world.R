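#' @section World representation:
#' A `huddle_world` is a list with elements `params` (a [sim_params()]
#' object), `agents` (a tibble with one row per agent: `agent_id`, `x`, `y`,
#' `heading`, `cluster_id`, `huddle_time`), `clusters` (a tibble with one
#' row per active cluster: `cluster_id`, `anchor_x`, `anchor_y` and a
#' `members` list-column of agent ids), `tick`, and `next_cluster_id`, the
#' monotone counter from which cluster ids are allocated (starting at 0).
#' Lone agents carry `cluster_id = -1` and `huddle_time = 0`.
#' @name huddle_world
NULL

# Toroidal wrap into [0, width). Shared, branch-for-branch, with the
# compiled engine so that both consume identical floating-point paths.
wrap_coord <- function(x, width) {
  w <- x - floor(x / width) * width
  w[w < 0] <- w[w < 0] + width
  w[w >= width] <- w[w >= width] - width
  w
}

# Shortest toroidal separation along one axis.
torus_delta <- function(d, width) {
  d <- abs(d)
  pmin(d, width - d)
}

#' Squared toroidal distance between points
#' @noRd
torus_dist2 <- function(x1, y1, x2, y2, width, height) {
  dx <- torus_delta(x1 - x2, width)
  dy <- torus_delta(y1 - y2, height)
  dx * dx + dy * dy
}

#' Initialise a world of lone agents
#'
#' Places `group_size` agents uniformly at random on the toroidal grid with
#' uniform headings. Every agent starts lone (`cluster_id = -1`,
#' `huddle_time = 0`), the cluster registry starts empty and the tick
#' counter at zero. The same `seed` always reproduces the same world.
#'
#' Random draws are consumed in a fixed documented order (per agent: x, y,
#' heading), which the compiled run engine follows identically.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed, or `NULL` to continue the current RNG stream.
#' @return A [huddle_world] object.
#' @examples
#' w <- init_world(sim_params(70, 3, 2, 10), seed = 1)
#' nrow(w$agents)
#' @export
init_world <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$group_size
  x <- numeric(n)
  y <- numeric(n)
  heading <- numeric(n)
  for (i in seq_len(n)) {
    x[i] <- runif(1) * params$grid_width
    y[i] <- runif(1) * params$grid_height
    heading[i] <- runif(1) * 2 * pi
  }
  structure(
    list(
      params = params,
      agents = tibble::tibble(
        agent_id = seq_len(n), x = x, y = y, heading = heading,
        cluster_id = rep(-1L, n), huddle_time = rep(0L, n)
      ),
      clusters = tibble::tibble(
        cluster_id = integer(), anchor_x = numeric(), anchor_y = numeric(),
        members = list()
      ),
      tick = 0L,
      next_cluster_id = 0L
    ),
    class = "huddle_world"
  )
}

#' @export
print.huddle_world <- function(x, ...) {
  cat(sprintf(
    "<huddle_world> tick %d: %d agents, %d cluster(s), %d lone\n",
    x$tick, nrow(x$agents), nrow(x$clusters),
    sum(x$agents$cluster_id == -1L)
  ))
  invisible(x)
}

#' Move a lone agent one step of its random walk
#'
#' Resamples the agent's heading uniformly on the circle and advances it one
#' patch unit along the new heading, wrapping toroidally. Consumes exactly
#' one uniform draw.
#'
#' @param world A [huddle_world].
#' @param agent_id Id of a lone agent (`cluster_id = -1`).
#' @return The updated world.
#' @export
move_lone_agent <- function(world, agent_id) {
  i <- agent_id
  if (world$agents$cluster_id[i] != -1L) {
    abort("move_lone_agent() called on a clustered agent.")
  }
  h <- runif(1) * 2 * pi
  world$agents$heading[i] <- h
  world$agents$x[i] <- wrap_coord(world$agents$x[i] + .sim_cos(h),
                                  world$params$grid_width)
  world$agents$y[i] <- wrap_coord(world$agents$y[i] + .sim_sin(h),
                                  world$params$grid_height)
  world
}

#' Find the candidate a lone agent would try to join
#'
#' Scans all other agents within the sensing radius (toroidal Euclidean
#' distance). If any huddled agent is in range, the candidate is the largest
#' cluster represented (ties broken by lowest cluster id). Otherwise, if any
#' lone agent is in range, the one with the lowest agent id is returned as a
#' size-1 candidate (a successful join on it nucleates a new cluster).
#' Deterministic: consumes no random draws.
#'
#' @param world A [huddle_world].
#' @param agent_id Id of a lone agent.
#' @return A list with `type` ("cluster", "lone" or "none"), `id` (cluster
#'   id or partner agent id, `NA` for none) and `size` (current candidate
#'   size, 1 for a lone partner).
#' @export
find_candidate_cluster <- function(world, agent_id) {
  a <- world$agents
  p <- world$params
  i <- agent_id
  d2 <- torus_dist2(a$x[i], a$y[i], a$x, a$y, p$grid_width, p$grid_height)
  in_range <- d2 <= p$sensing_radius^2
  in_range[i] <- FALSE
  if (!any(in_range)) {
    return(list(type = "none", id = NA_integer_, size = NA_integer_))
  }
  cids <- a$cluster_id[in_range]
  if (any(cids >= 0L)) {
    cand <- sort(unique(cids[cids >= 0L]))
    sizes <- vapply(cand, function(cid) {
      length(world$clusters$members[[match(cid, world$clusters$cluster_id)]])
    }, integer(1))
    best <- cand[which.max(sizes)] # which.max takes first => lowest id on tie
    return(list(type = "cluster", id = best, size = max(sizes)))
  }
  lone_ids <- a$agent_id[in_range & a$cluster_id == -1L]
  list(type = "lone", id = min(lone_ids), size = 1L)
}

#' Evenly re-space the members of a cluster around its anchor
#'
#' Places the members (in ascending agent-id order) at equal angular spacing
#' on a circle of radius `min(1, sensing_radius / 2)` around the cluster
#' anchor, so huddled agents stay tightly packed and within sensing range of
#' the anchor. Deterministic.
#'
#' @param world A [huddle_world].
#' @param cluster_id Id of an existing cluster.
#' @return The updated world.
#' @export
update_cluster_positions <- function(world, cluster_id) {
  k <- match(cluster_id, world$clusters$cluster_id)
  if (is.na(k)) abort("update_cluster_positions(): unknown cluster id.")
  members <- sort(world$clusters$members[[k]])
  m <- length(members)
  r <- min(1, world$params$sensing_radius / 2)
  ax <- world$clusters$anchor_x[k]
  ay <- world$clusters$anchor_y[k]
  for (j in seq_len(m)) {
    theta <- 2 * pi * (j - 1) / m
    id <- members[j]
    world$agents$x[id] <- wrap_coord(ax + r * .sim_cos(theta),
                                     world$params$grid_width)
    world$agents$y[id] <- wrap_coord(ay + r * .sim_sin(theta),
                                     world$params$grid_height)
  }
  world
}

#' Let a lone agent attempt to join its candidate
#'
#' Draws one uniform number and joins the candidate if the draw falls below
#' [p_join()] evaluated at the candidate's current size. Joining an existing
#' cluster adds the agent to it; joining a lone partner allocates a fresh
#' cluster id for the pair, with the joiner's current position as the
#' anchor. Joined agents have `huddle_time` restarted at 0 and become
#' stationary. On a failed draw the world is unchanged apart from the
#' consumed draw.
#'
#' @param world A [huddle_world].
#' @param agent_id Id of a lone agent.
#' @param candidate A candidate descriptor from [find_candidate_cluster()].
#' @return The updated world.
#' @export
attempt_join <- function(world, agent_id, candidate) {
  u <- runif(1)
  p <- world$params
  pj <- p_join(candidate$size, p$group_size, p$temperature, p$join_threshold)
  if (u >= pj) return(world)
  i <- agent_id
  if (candidate$type == "cluster") {
    k <- match(candidate$id, world$clusters$cluster_id)
    world$clusters$members[[k]] <- sort(c(world$clusters$members[[k]], i))
    world$agents$cluster_id[i] <- candidate$id
    world$agents$huddle_time[i] <- 0L
    world <- update_cluster_positions(world, candidate$id)
  } else if (candidate$type == "lone") {
    partner <- candidate$id
    nid <- world$next_cluster_id
    world$next_cluster_id <- nid + 1L
    world$clusters <- tibble::add_row(
      world$clusters,
      cluster_id = nid,
      anchor_x = world$agents$x[i], anchor_y = world$agents$y[i],
      members = list(sort(c(i, partner)))
    )
    world$agents$cluster_id[c(i, partner)] <- nid
    world$agents$huddle_time[c(i, partner)] <- 0L
    world <- update_cluster_positions(world, nid)
  } else {
    abort("attempt_join(): candidate must not be 'none'.")
  }
  world
}

#' Let a huddled agent attempt to leave its cluster
#'
#' Draws one uniform number and leaves if the draw falls below [p_leave()]
#' evaluated at the agent's current cluster size. A leaver keeps its current
#' position, becomes lone and resumes the random walk next tick. If the
#' abandoned cluster drops to a single member, that member is released too
#' and the cluster dissolves (a huddle of one is not a cluster). If the
#' agent stays, its `huddle_time` increments.
#'
#' @param world A [huddle_world].
#' @param agent_id Id of a clustered agent.
#' @return The updated world.
#' @export
attempt_leave <- function(world, agent_id) {
  i <- agent_id
  cid <- world$agents$cluster_id[i]
  if (cid < 0L) abort("attempt_leave() called on a lone agent.")
  k <- match(cid, world$clusters$cluster_id)
  size <- length(world$clusters$members[[k]])
  u <- runif(1)
  pl <- p_leave(size, world$params$group_size, world$params$leave_threshold)
  if (u >= pl) {
    world$agents$huddle_time[i] <- world$agents$huddle_time[i] + 1L
    return(world)
  }
  world$agents$cluster_id[i] <- -1L
  world$agents$huddle_time[i] <- 0L
  remaining <- setdiff(world$clusters$members[[k]], i)
  if (length(remaining) == 1L) {
    world$agents$cluster_id[remaining] <- -1L
    world$agents$huddle_time[remaining] <- 0L
    world$clusters <- world$clusters[-k, ]
  } else {
    world$clusters$members[[k]] <- remaining
    world <- update_cluster_positions(world, cid)
  }
  world
}

#' Advance the world by one tick
#'
#' Processes every agent exactly once, in a freshly shuffled order
#' (Fisher-Yates on the agent ids). A lone agent moves one random-walk step,
#' senses its candidate, and consumes one decision draw which is compared to
#' [p_join()] when a candidate exists; a huddled agent consumes one decision
#' draw compared to [p_leave()]. Agents act on the world as it stands
#' mid-pass. Increments the tick counter.
#'
#' @param world A [huddle_world].
#' @return The updated world.
#' @export
tick_world <- function(world) {
  n <- world$params$group_size
  # Fisher-Yates shuffle, consuming draws identically to the compiled engine
  perm <- seq_len(n)
  for (i in seq(n, 2L)) {
    j <- min(floor(runif(1) * i), i - 1) + 1L
    tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
  }
  for (id in perm) {
    if (world$agents$cluster_id[id] == -1L) {
      world <- move_lone_agent(world, id)
      cand <- find_candidate_cluster(world, id)
      if (cand$type == "none") {
        runif(1) # decision draw consumed even without a candidate
      } else {
        world <- attempt_join(world, id, cand)
      }
    } else {
      world <- attempt_leave(world, id)
    }
  }
  world$tick <- world$tick + 1L
  world
}

#' Cluster sizes recorded in the registry
#'
#' Returns the size of every active cluster (in ascending cluster-id order)
#' and cross-checks the registry against a brute-force grouping of the
#' agents by `cluster_id`; any inconsistency signals state corruption.
#'
#' @param world A [huddle_world].
#' @return An integer vector of cluster sizes (empty when no clusters).
#' @export
cluster_sizes <- function(world) {
  reg <- world$clusters[order(world$clusters$cluster_id), ]
  sizes <- vapply(reg$members, length, integer(1))
  names(sizes) <- NULL
  # brute-force oracle over the agents table
  cid <- world$agents$cluster_id
  bf <- table(cid[cid >= 0L])
  bf_ids <- as.integer(names(bf))
  if (!identical(bf_ids, reg$cluster_id) ||
      !identical(as.integer(bf), sizes)) {
    abort("cluster registry inconsistent with agent cluster ids.")
  }
  for (k in seq_along(reg$cluster_id)) {
    mem <- sort(reg$members[[k]])
    if (!identical(mem, which(cid == reg$cluster_id[k]))) {
      abort("cluster membership lists inconsistent with agent cluster ids.")
    }
  }
  sizes
}
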