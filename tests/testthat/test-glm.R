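# synthetic negative-binomial tables with known coefficients (log link)
simulate_nb_table <- function(n, beta0, beta, theta, seed) {
  set.seed(seed)
  x1 <- runif(n, -1, 1)
  x2 <- runif(n, -1, 1)
  mu <- exp(beta0 + beta[1] * x1 + beta[2] * x2)
  tibble::tibble(response = stats::rnbinom(n, size = theta, mu = mu),
                 x1 = x1, x2 = x2)
}

test_that("model-table preparation filters, rounds and screens group sizes", {
  rows <- dplyr::bind_rows(
    lapply(1:94, function(i) fake_row(70, 1, 1, 10, c(2, 3), seed = i)),
    lapply(95:100, function(i) fake_row(70, 9, 8, 10, integer(), seed = i)),
    fake_row(100, 1, 1, 10, c(4, 5), seed = 101),
    fake_row(130, 1, 1, 10, c(4, 5), seed = 102),
    fake_row(160, 1, 1, 10, c(4, 5), seed = 103),
    fake_row(300, 1, 1, 10, c(200), seed = 104)
  )
  per <- prepare_glm_table(rows, "individuals_per_cluster")
  expect_identical(nrow(per), 97L)              # 6 empty runs + N=300 dropped
  expect_true(all(per$group_size <= 160))
  # round half to even: mean 2.5 -> 2; 4.5 -> 4
  expect_true(all(per$response[per$group_size == 70] == 2L))
  expect_true(all(per$response[per$group_size > 70] == 4L))
  cnt <- prepare_glm_table(rows, "n_clusters")
  expect_identical(nrow(cnt), 103L)             # empty runs kept as zeros
  expect_identical(sum(cnt$response == 0L), 6L)
  expect_error(prepare_glm_table(rows[rows$group_size == 70, ], "n_clusters"),
               "group size")
})

test_that("an intercept-only log-link fit recovers the log of the mean", {
  tab <- simulate_nb_table(500, 1.2, c(0, 0), theta = 5, seed = 8)
  fit <- fit_nb_glm(tab, predictors = character())
  expect_equal(unname(coef(fit$fit)[1]), log(mean(tab$response)),
               tolerance = 1e-6)
})

test_that("negative-binomial fits recover known coefficients with nominal coverage", {
  beta0 <- 0.8
  beta <- c(0.7, -0.5)
  covered <- matrix(FALSE, nrow = 100, ncol = 3)
  for (r in 1:100) {
    tab <- simulate_nb_table(5000, beta0, beta, theta = 3, seed = 6000 + r)
    fit <- fit_nb_glm(tab, predictors = c("x1", "x2"))
    ci <- tidy(fit, conf.int = TRUE)
    covered[r, ] <- ci$conf.low <= c(beta0, beta) &
      c(beta0, beta) <= ci$conf.high
  }
  # 95% Wald intervals: expect at least 90/100 coverage per coefficient
  expect_true(all(colSums(covered) >= 90))
})

test_that("theta is estimated and reported with the fit summaries", {
  tab <- simulate_nb_table(20000, 1, c(0.5, -0.3), theta = 2, seed = 99)
  fit <- fit_nb_glm(tab, predictors = c("x1", "x2"))
  expect_equal(fit$theta, 2, tolerance = 0.15)
  g <- glance(fit)
  expect_identical(nrow(g), 1L)
  expect_lte(g$deviance, g$null.deviance)
  expect_identical(g$nobs, 20000L)
  expect_true(is.finite(g$AIC) && is.finite(g$BIC) && g$BIC > g$AIC)
})

test_that("a negative binomial with huge theta agrees with the Poisson fit", {
  set.seed(31)
  n <- 5000
  x1 <- runif(n, -1, 1)
  x2 <- runif(n, -1, 1)
  tab <- tibble::tibble(
    response = stats::rpois(n, exp(1 + 0.4 * x1 - 0.6 * x2)),
    x1 = x1, x2 = x2
  )
  nb <- fit_nb_glm(tab, predictors = c("x1", "x2"), family = "negbin")
  po <- fit_nb_glm(tab, predictors = c("x1", "x2"), family = "poisson")
  expect_equal(nb$coefficients$estimate, po$coefficients$estimate,
               tolerance = 1e-3)
})

test_that("variance inflation factors flag collinearity and clear balanced designs", {
  set.seed(5)
  orth <- tidyr::expand_grid(a = 1:4, b = 1:5, c = 1:3)
  v <- compute_vif(orth, c("a", "b", "c"))
  expect_equal(v$vif, rep(1, 3), tolerance = 1e-10)
  dup <- dplyr::mutate(orth, d = a)
  expect_warning(vd <- compute_vif(dup, c("a", "b", "d")), "collinear")
  expect_true(any(is.infinite(vd$vif)))
  # the actual published sweep design: balanced enough that all VIFs < 5
  design <- dplyr::bind_rows(lapply(c(70, 100, 130, 160), function(gs) {
    enumerate_runs(default_grid(gs, replicates = 1))
  }))
  vs <- compute_vif(design, c("join_threshold", "leave_threshold",
                              "temperature", "group_size"))
  expect_true(all(vs$vif >= 1))
  expect_true(all(vs$vif < 5))
})

test_that("stepwise selection keeps strong effects and BIC drops pure noise", {
  gen <- function(seed) {
    set.seed(seed)
    n <- 10000
    tibble::tibble(
      x1 = runif(n, -1, 1), x2 = runif(n, -1, 1), noise = runif(n, -1, 1)
    ) |>
      dplyr::mutate(response = stats::rnbinom(
        n, size = 4, mu = exp(1 + 0.6 * x1 - 0.5 * x2)
      ))
  }
  drops <- vapply(1:5, function(r) {
    sel <- stepwise_select(gen(300 + r), predictors = c("x1", "x2", "noise"),
                           criterion = "BIC")
    !"noise" %in% sel$fit$predictors
  }, logical(1))
  expect_gte(sum(drops), 3) # dropped in most replications
  sel <- stepwise_select(gen(1), predictors = c("x1", "x2"),
                         criterion = "AIC")
  expect_setequal(sel$fit$predictors, c("x1", "x2")) # strong effects kept
  expect_true(all(c("step", "criterion") %in% names(sel$trace)))
  # single predictor: the trace is at most <start> plus one removal attempt
  one <- stepwise_select(gen(2), predictors = "x1", criterion = "AIC")
  expect_lte(nrow(one$trace), 2L)
})

test_that("coefficient summaries carry 95 percent Wald intervals", {
  tab <- simulate_nb_table(2000, 1, c(0.5, -0.3), theta = 3, seed = 55)
  fit <- fit_nb_glm(tab, predictors = c("x1", "x2"))
  cs <- coefficient_summary(fit)
  expect_identical(nrow(cs), nrow(fit$coefficients))
  expect_equal(cs$conf.low, cs$estimate - 1.96 * cs$std.error)
  expect_equal(cs$conf.high, cs$estimate + 1.96 * cs$std.error)
  # frozen arithmetic: estimate 0.1, SE 0.05 -> (0.002, 0.198)
  expect_equal(0.1 + c(-1.96, 1.96) * 0.05, c(0.002, 0.198))
  path <- withr::local_tempfile(fileext = ".csv")
  coefficient_summary(fit, path = path)
  expect_identical(nrow(readr::read_csv(path, show_col_types = FALSE)),
                   nrow(cs))
})
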