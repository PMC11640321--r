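p70 <- sim_params(70, 3, 2, 10)

test_that("initialisation is reproducible, lone, and inside the torus", {
  w1 <- init_world(p70, seed = 1)
  w2 <- init_world(p70, seed = 1)
  expect_same_world(w1, w2)
  expect_true(all(w1$agents$cluster_id == -1L))
  expect_true(all(w1$agents$huddle_time == 0L))
  expect_identical(nrow(w1$clusters), 0L)
  expect_identical(w1$tick, 0L)
  expect_true(all(w1$agents$x >= 0 & w1$agents$x < 16))
  expect_true(all(w1$agents$y >= 0 & w1$agents$y < 16))
  w3 <- init_world(sim_params(2, 1, 1, 10), seed = 5)
  expect_identical(nrow(w3$agents), 2L)
  expect_true(all(w3$agents$cluster_id == -1L))
})

test_that("parameter validation enforces the model domains", {
  expect_error(sim_params(1, 1, 1, 10), "group_size")
  expect_error(sim_params(70, 0, 1, 10), "temperature")
  expect_error(sim_params(70, 11, 1, 10), "temperature")
  expect_error(sim_params(70, 1, 0, 10), "join_threshold")
  expect_error(sim_params(70, 1, 1, 9), "leave_threshold")
  expect_error(sim_params(70, 1, 1, 10, sensing_radius = 0), "sensing_radius")
  expect_error(sim_params(70.5, 1, 1, 10), "integer")
})

test_that("a lone agent's move is a unit step with toroidal wrap", {
  w <- make_world(sim_params(2, 1, 1, 10),
                  data.frame(agent_id = 1:2, x = c(15.5, 5), y = c(8, 8)))
  set.seed(11)
  for (i in 1:200) {
    old <- c(w$agents$x[1], w$agents$y[1])
    w <- move_lone_agent(w, 1L)
    expect_equal(
      torus_dist(old[1], old[2], w$agents$x[1], w$agents$y[1], 16, 16),
      1, tolerance = 1e-12
    )
    expect_true(w$agents$x[1] >= 0 && w$agents$x[1] < 16)
    expect_true(w$agents$y[1] >= 0 && w$agents$y[1] < 16)
  }
  # clustered agents never random-walk
  wc <- make_world(sim_params(3, 1, 1, 10),
                   data.frame(agent_id = 1:3, x = c(1, 2, 9),
                              y = c(1, 1, 9), cluster_id = c(0, 0, -1)))
  expect_error(move_lone_agent(wc, 1L), "clustered")
})

test_that("resampled headings are uniform on the circle", {
  w <- make_world(sim_params(2, 1, 1, 10),
                  data.frame(agent_id = 1:2, x = c(8, 1), y = c(8, 1)))
  set.seed(99)
  headings <- replicate(10000, {
    w <<- move_lone_agent(w, 1L)
    w$agents$heading[1]
  })
  counts <- table(cut(headings, breaks = seq(0, 2 * pi, length.out = 13)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("candidate selection prefers the largest cluster and breaks ties by id", {
  p <- sim_params(12, 3, 2, 10)
  # nobody in range
  w <- make_world(p, data.frame(agent_id = 1:12,
                                x = c(1, rep(8, 11)), y = c(1, rep(8, 11))))
  expect_identical(find_candidate_cluster(w, 1L)$type, "none")

  # a 5-cluster at distance 1.5 beats a lone agent at distance 0.5
  ag <- data.frame(
    agent_id = 1:12,
    x = c(5, 5.5, rep(6.5, 5), rep(12, 5)),
    y = c(5, 5,   rep(5, 5),   rep(12, 5)),
    cluster_id = c(-1, -1, rep(3, 5), rep(-1, 5))
  )
  w <- make_world(p, ag)
  cand <- find_candidate_cluster(w, 1L)
  expect_identical(cand$type, "cluster")
  expect_identical(cand$id, 3L)
  expect_identical(cand$size, 5L)

  # two 3-clusters in range, ids 7 and 9: lowest id wins
  ag <- data.frame(
    agent_id = 1:12,
    x = c(5, rep(4.5, 3), rep(5.5, 3), rep(12, 5)),
    y = c(5, rep(5, 3), rep(5, 3), rep(12, 5)),
    cluster_id = c(-1, rep(9, 3), rep(7, 3), rep(-1, 5))
  )
  w <- make_world(p, ag)
  cand <- find_candidate_cluster(w, 1L)
  expect_identical(cand$id, 7L)

  # only lone agents in range: lowest agent id, size-1 candidate
  ag <- data.frame(agent_id = 1:12, x = c(5, 5.5, 4.5, rep(12, 9)),
                   y = rep(c(5, 12), c(3, 9)))
  w <- make_world(p, ag)
  cand <- find_candidate_cluster(w, 1L)
  expect_identical(cand$type, "lone")
  expect_identical(cand$id, 2L)
  expect_identical(cand$size, 1L)
})

test_that("cluster members are evenly spaced on a circle near the anchor", {
  p <- sim_params(6, 1, 1, 10)
  ag <- data.frame(agent_id = 1:6, x = c(8, 8, 8, 8, 2, 2),
                   y = c(8, 8, 8, 8, 2, 2), cluster_id = c(0, 0, 0, 0, -1, -1))
  w <- make_world(p, ag)
  w$clusters$anchor_x[1] <- 8
  w$clusters$anchor_y[1] <- 8
  # 4 members: successive angular gaps of 90 degrees, radius min(1, r/2) = 1
  w4 <- update_cluster_positions(w, 0L)
  ang <- atan2(w4$agents$y[1:4] - 8, w4$agents$x[1:4] - 8) %% (2 * pi)
  gaps <- diff(sort(ang))
  expect_equal(gaps, rep(pi / 2, 3), tolerance = 1e-10)
  d <- torus_dist(w4$agents$x[1:4], w4$agents$y[1:4], 8, 8, 16, 16)
  expect_equal(d, rep(1, 4), tolerance = 1e-12)
  expect_true(all(d <= p$sensing_radius))

  # 2 members: diametrically opposite
  w$clusters$members[[1]] <- 1:2
  w$agents$cluster_id[3:4] <- -1L
  w2 <- update_cluster_positions(w, 0L)
  expect_equal(
    torus_dist(w2$agents$x[1], w2$agents$y[1],
               w2$agents$x[2], w2$agents$y[2], 16, 16),
    2, tolerance = 1e-12
  )
  expect_error(update_cluster_positions(w, 42L), "unknown cluster")
})

test_that("registry sizes agree with brute-force grouping and detect corruption", {
  w <- make_world(sim_params(10, 1, 1, 10),
                  data.frame(agent_id = 1:10, x = 1:10, y = 1:10,
                             cluster_id = c(0, 0, 0, 2, 2, rep(-1, 5))))
  expect_identical(cluster_sizes(w), c(3L, 2L))
  expect_identical(cluster_sizes(init_world(p70, 1)), integer())
  w70 <- make_world(sim_params(70, 1, 1, 10),
                    data.frame(agent_id = 1:70, x = rep(8, 70),
                               y = rep(8, 70), cluster_id = rep(0, 70)))
  expect_identical(cluster_sizes(w70), 70L)
  # corrupt one agent's membership
  w$agents$cluster_id[1] <- 2L
  expect_error(cluster_sizes(w), "inconsistent")
})
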