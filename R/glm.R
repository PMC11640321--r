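#' Prepare a sweep table for count regression
#'
#' Builds the model table for one of the two published responses. For the
#' number of clusters every run is kept (runs without clusters contribute a
#' zero count). For the number of individuals per cluster, runs without
#' clusters are dropped and the per-run mean cluster size is rounded to the
#' nearest integer (round-half-to-even) so a count family applies. Group
#' sizes outside `group_sizes` (by default 300 and 400 are absent) are
#' excluded, mirroring the screening of implausibly large simulated
#' clusters.
#'
#' @param table A sweep result table.
#' @param response `"n_clusters"` or `"individuals_per_cluster"`.
#' @param group_sizes Group sizes to keep (default `c(70, 100, 130, 160)`).
#' @return A tibble with columns `response`, `join_threshold`,
#'   `leave_threshold`, `temperature`, `group_size`.
#' @export
prepare_glm_table <- function(table,
                              response = c("n_clusters",
                                           "individuals_per_cluster"),
                              group_sizes = c(70L, 100L, 130L, 160L)) {
  response <- match.arg(response)
  missing_sizes <- setdiff(group_sizes, unique(table$group_size))
  if (length(missing_sizes) > 0L) {
    abort(sprintf("sweep table has no runs for group size(s): %s",
                  paste(missing_sizes, collapse = ", ")))
  }
  tb <- dplyr::filter(table, .data$group_size %in% .env$group_sizes)
  if (response == "individuals_per_cluster") {
    tb <- dplyr::filter(tb, !.data$no_cluster)
    if (nrow(tb) == 0L) abort("no runs with clusters left after filtering.")
    resp <- as.integer(round(tb$mean_cluster_size))
  } else {
    if (nrow(tb) == 0L) abort("no runs left after filtering.")
    resp <- tb$n_clusters
  }
  tibble::tibble(
    response = resp,
    join_threshold = tb$join_threshold,
    leave_threshold = tb$leave_threshold,
    temperature = tb$temperature,
    group_size = tb$group_size
  )
}

#' Fit a count GLM to a prepared model table
#'
#' Negative-binomial regression with a log link (dispersion theta estimated
#' by maximum likelihood, via [MASS::glm.nb()]) is the primary family; a
#' Poisson fit is available as a cross-check. Main effects only by default;
#' `interactions = TRUE` adds all two-way interactions (the published
#' analysis removed them after they inflated the variance inflation
#' factors).
#'
#' @param data A model table from [prepare_glm_table()] (column `response`
#'   plus predictors).
#' @param predictors Predictor columns to include.
#' @param family `"negbin"` (default) or `"poisson"`.
#' @param interactions Include two-way interactions (default `FALSE`).
#' @return An object of class `huddle_glm`; see [tidy()], [glance()],
#'   [coefficient_summary()].
#' @export
fit_nb_glm <- function(data,
                       predictors = c("join_threshold", "leave_threshold",
                                      "temperature", "group_size"),
                       family = c("negbin", "poisson"),
                       interactions = FALSE) {
  family <- match.arg(family)
  stopifnot(all(predictors %in% names(data)))
  if (!"response" %in% names(data)) abort("`data` must have a `response` column.")
  if (nrow(data) < 10 * (length(predictors) + 2)) {
    abort("too few rows to fit the model reliably.")
  }
  if (all(data$response == data$response[1])) {
    abort("degenerate response: all values identical.")
  }
  rhs <- if (length(predictors) == 0L) {
    "1" # intercept-only fit
  } else {
    paste(predictors, collapse = if (interactions) " * " else " + ")
  }
  fml <- stats::as.formula(paste("response ~", rhs))
  notes <- character()
  fit <- withCallingHandlers(
    if (family == "negbin") {
      MASS::glm.nb(fml, data = data)
    } else {
      stats::glm(fml, data = data, family = stats::poisson())
    },
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (!isTRUE(fit$converged)) {
    abort(sprintf(
      "GLM did not converge after %s iterations (%s).",
      fit$iter %||% "?", paste(notes, collapse = "; ")
    ))
  }
  new_huddle_glm(fit, family, predictors, notes)
}

new_huddle_glm <- function(fit, family, predictors, notes = character()) {
  sm <- summary(fit)
  co <- sm$coefficients
  structure(
    list(
      fit = fit,
      family = family,
      predictors = predictors,
      coefficients = tibble::tibble(
        term = rownames(co),
        estimate = co[, 1], std.error = co[, 2],
        statistic = co[, 3], p.value = co[, 4]
      ),
      theta = if (family == "negbin") fit$theta else NA_real_,
      se_theta = if (family == "negbin") fit$SE.theta else NA_real_,
      log_lik = as.numeric(logLik(fit)),
      null_deviance = fit$null.deviance,
      df_null = fit$df.null,
      deviance = fit$deviance,
      df_residual = fit$df.residual,
      aic = AIC(fit),
      bic = BIC(fit),
      nobs = stats::nobs(fit),
      notes = notes
    ),
    class = "huddle_glm"
  )
}

#' @export
print.huddle_glm <- function(x, ...) {
  cat(sprintf(
    "<huddle_glm> %s, %d obs; deviance %.1f (null %.1f); AIC %.1f\n",
    if (x$family == "negbin") {
      sprintf("negative binomial (theta = %.3g)", x$theta)
    } else {
      "Poisson"
    },
    x$nobs, x$deviance, x$null_deviance, x$aic
  ))
  print(x$coefficients)
  invisible(x)
}

#' Tidy a fitted huddle GLM
#'
#' @param x A `huddle_glm`.
#' @param conf.int Add 95 percent Wald intervals (default `FALSE`).
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @export
tidy.huddle_glm <- function(x, conf.int = FALSE, ...) {
  out <- x$coefficients
  if (conf.int) {
    out <- dplyr::mutate(
      out,
      conf.low = .data$estimate - 1.96 * .data$std.error,
      conf.high = .data$estimate + 1.96 * .data$std.error
    )
  }
  out
}

#' One-row model summary of a fitted huddle GLM
#'
#' @param x A `huddle_glm`.
#' @param ... Unused.
#' @return A one-row tibble: theta and its SE (NA for Poisson),
#'   log-likelihood, null and residual deviance with their degrees of
#'   freedom, AIC, BIC and the number of observations.
#' @export
glance.huddle_glm <- function(x, ...) {
  tibble::tibble(
    theta = x$theta, se.theta = x$se_theta, logLik = x$log_lik,
    null.deviance = x$null_deviance, df.null = x$df_null,
    deviance = x$deviance, df.residual = x$df_residual,
    AIC = x$aic, BIC = x$bic, nobs = x$nobs
  )
}

#' Variance inflation factors of the model predictors
#'
#' `VIF_k = 1 / (1 - R^2_k)`, where `R^2_k` comes from the ordinary
#' least-squares regression of predictor k on the other predictors (main
#' effects only). Exactly collinear predictors are reported as `Inf` with a
#' warning.
#'
#' @param data A model table (predictors as columns).
#' @param predictors At least two predictor columns.
#' @return A tibble with columns `predictor` and `vif`.
#' @export
compute_vif <- function(data,
                        predictors = c("join_threshold", "leave_threshold",
                                       "temperature", "group_size")) {
  stopifnot(length(predictors) >= 2, all(predictors %in% names(data)))
  vif <- vapply(predictors, function(pk) {
    fml <- stats::as.formula(
      paste(pk, "~", paste(setdiff(predictors, pk), collapse = " + "))
    )
    r2 <- summary(lm(fml, data = data))$r.squared
    if (r2 > 1 - 1e-10) {
      warn(sprintf("predictor `%s` is exactly collinear (unbounded VIF).", pk))
      Inf
    } else {
      1 / (1 - r2)
    }
  }, numeric(1))
  tibble::tibble(predictor = predictors, vif = unname(vif))
}

#' Backward-forward stepwise model selection
#'
#' Starts from the full main-effects model and steps over the predictor
#' subsets with [MASS::stepAIC()], minimising AIC (`k = 2`) or BIC
#' (`k = log n`). Returns the selection trace and the re-wrapped final fit.
#'
#' @param data A model table from [prepare_glm_table()].
#' @param predictors Predictors of the full model.
#' @param criterion `"AIC"` (default) or `"BIC"`.
#' @param family Passed to [fit_nb_glm()].
#' @return A list with `trace` (a tibble: one row per accepted step, with
#'   the criterion value) and `fit` (the final `huddle_glm`).
#' @export
stepwise_select <- function(data,
                            predictors = c("join_threshold",
                                           "leave_threshold", "temperature",
                                           "group_size"),
                            criterion = c("AIC", "BIC"),
                            family = c("negbin", "poisson")) {
  criterion <- match.arg(criterion)
  family <- match.arg(family)
  full <- fit_nb_glm(data, predictors = predictors, family = family)
  k <- if (criterion == "AIC") 2 else log(nrow(data))
  stepped <- withCallingHandlers(
    MASS::stepAIC(full$fit, direction = "both", trace = 0, k = k),
    warning = function(w) invokeRestart("muffleWarning")
  )
  an <- as.data.frame(stepped$anova)
  trace <- tibble::tibble(
    step = ifelse(an$Step == "", "<start>", as.character(an$Step)),
    df_residual = an$`Resid. Df`,
    deviance = an$`Resid. Dev`,
    criterion = an$AIC # stepAIC reports the k-penalised criterion here
  )
  kept <- attr(stats::terms(stepped), "term.labels")
  final <- if (length(kept) == 0L) {
    abort("stepwise selection removed every predictor.")
  } else {
    new_huddle_glm(stepped, family, kept)
  }
  list(trace = trace, fit = final, criterion = criterion)
}

#' Coefficient estimates with 95 percent Wald intervals
#'
#' @param fit A `huddle_glm`.
#' @param path Optional CSV path to write the table to.
#' @return A tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @export
coefficient_summary <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "huddle_glm"))
  out <- tidy(fit, conf.int = TRUE)[
    , c("term", "estimate", "std.error", "conf.low", "conf.high")
  ]
  if (any(out$std.error == 0)) {
    warn("degenerate fit: zero-width confidence interval(s).")
  }
  if (!is.null(path)) readr::write_csv(out, path, na = "")
  out
}
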