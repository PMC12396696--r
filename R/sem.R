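#' Build the driver series for the state-model regression
#'
#' The state-model regression explains the next step's angle by the current
#' angle (retention term) and a shared group-level driver (learning term). The
#' driver is either the filter-estimated group mean from [run_filter()] or the
#' observed per-step sample mean.
#'
#' @param trials A trial table.
#' @param type `"filter"` uses `filter$m_hat`; `"sample"` uses the observed
#'   group mean.
#' @param filter A `filter_estimate` (required for `type = "filter"`).
#' @return A tibble with columns `group`, `step`, `y_bar`, `driver` and
#'   attribute `driver_type`.
#' @export
driver_series <- function(trials, type = c("sample", "filter"), filter = NULL) {
  type <- match.arg(type)
  gm <- group_means(trials)
  if (type == "filter") {
    if (is.null(filter)) abort("`filter` is required for type = \"filter\".")
    fe <- dplyr::select(tibble::as_tibble(filter), "group", "step", "m_hat")
    gm <- dplyr::left_join(gm, fe, by = c("group", "step"))
    if (anyNA(gm$m_hat)) abort("Filter estimate does not cover every (group, step).")
    gm <- dplyr::rename(gm, driver = "m_hat")
  } else {
    gm$driver <- gm$y_bar
  }
  attr(gm, "driver_type") <- type
  gm
}

# Assemble the (response, lag, driver) regression rows.
state_model_rows <- function(trials, driver, level) {
  trials <- as_gait_trials(trials)
  drv <- tibble::as_tibble(driver)
  if (!all(c("group", "step", "driver") %in% names(drv))) {
    abort("`driver` must have columns group, step, driver (see driver_series()).")
  }
  if (level == "group") {
    base <- group_means(trials)
    base <- dplyr::rename(base, series = "y_bar")
    base$participant <- base$group
  } else {
    base <- dplyr::select(tibble::as_tibble(trials),
                          "group", "participant", "step", series = "angle")
  }
  base <- dplyr::arrange(base, .data$group, .data$participant, .data$step)
  rows <- dplyr::mutate(
    dplyr::group_by(base, .data$group, .data$participant),
    response = dplyr::lead(.data$series),
    lag = .data$series
  )
  rows <- dplyr::ungroup(rows)
  rows <- dplyr::filter(rows, !is.na(.data$response))
  rows <- dplyr::left_join(rows, dplyr::select(drv, "group", "step", "driver"),
                           by = c("group", "step"))
  if (anyNA(rows$driver)) abort("Driver series does not cover every used step.")
  rows
}

check_group_rank <- function(rows) {
  bad <- dplyr::group_map(
    dplyr::group_by(rows, .data$group),
    function(d, key) {
      X <- cbind(d$lag, d$driver)
      xx <- crossprod(X)
      if (rcond(xx) < 1e-12) as.character(key$group) else NA_character_
    }
  )
  bad <- unlist(bad)
  bad <- bad[!is.na(bad)]
  if (length(bad) > 0) {
    abort(paste0(
      "Lag and driver are collinear (rank-deficient design) in group(s): ",
      paste(bad, collapse = ", "),
      ". At group level the sample-mean driver is identical to the lag; ",
      "use the filter driver or the individual level."
    ))
  }
  invisible(rows)
}

#' Fit the state-model regression for retention and learning rates
#'
#' Gaussian maximum-likelihood fit of the no-intercept regression
#' `response_{t+1} = A_j * response_t + B_j * driver_t + error`, with
#' group-specific residual variances. Equality constraints across groups may be
#' imposed on the retention factor `A`, the learning rate `B`, or both; the
#' constrained and unconstrained fits are compared with
#' [lr_difference_test()]. Estimation iterates closed-form generalized least
#' squares with ML variance updates to convergence, so the fit is
#' deterministic; standard errors come from the observed information at the
#' optimum.
#'
#' @param trials A trial table.
#' @param driver A driver tibble from [driver_series()].
#' @param level `"individual"` regresses each participant's series on its own
#'   lag and the shared group driver; `"group"` regresses the group mean series
#'   (only identified with the filter driver — the sample-mean driver is then
#'   collinear with the lag and raises an error).
#' @param constrain Which coefficients are constrained equal across groups:
#'   `"none"`, `"A"`, `"B"`, or `"both"`.
#' @param tol Convergence tolerance on the deviance.
#' @return An object of class `rate_fit`: estimates (via [tidy()]), deviance
#'   and fit info (via [glance()]).
#' @examples
#' trials <- generate_cohort(synth_config(n_per_group = 4, n_steps = 80,
#'                                        jump_step = 41, seed = 1))
#' fit <- fit_state_model(trials, driver_series(trials, "sample"))
#' tidy(fit)
#' @export
fit_state_model <- function(trials, driver,
                            level = c("individual", "group"),
                            constrain = c("none", "A", "B", "both"),
                            tol = 1e-10) {
  level <- match.arg(level)
  constrain <- match.arg(constrain)
  rows <- state_model_rows(trials, driver, level)
  if (dplyr::n_distinct(rows$step) < 2) abort("At least 3 steps are required.")
  check_group_rank(rows)
  groups <- sort(unique(rows$group))
  G <- length(groups)
  g_idx <- match(rows$group, groups)
  n_rows <- nrow(rows)

  A_free <- constrain %in% c("none", "B")
  B_free <- constrain %in% c("none", "A")
  make_block <- function(v, free, prefix) {
    if (free) {
      X <- matrix(0, n_rows, G)
      X[cbind(seq_len(n_rows), g_idx)] <- v
      colnames(X) <- paste0(prefix, "_", groups)
      X
    } else {
      matrix(v, ncol = 1, dimnames = list(NULL, prefix))
    }
  }
  X <- cbind(make_block(rows$lag, A_free, "A"),
             make_block(rows$driver, B_free, "B"))
  r <- rows$response
  n_g <- tabulate(g_idx, G)

  sigma2 <- rep(1, G)
  dev_old <- Inf
  for (iter in seq_len(500)) {
    w <- 1 / sigma2[g_idx]
    XtWX <- crossprod(X * w, X)
    XtWr <- crossprod(X * w, r)
    beta <- solve(XtWX, XtWr)
    res <- r - as.vector(X %*% beta)
    rss <- tapply(res^2, g_idx, sum)
    sigma2 <- as.numeric(rss) / n_g
    dev <- sum(n_g * (log(2 * pi * sigma2) + 1))
    if (abs(dev_old - dev) < tol) break
    dev_old <- dev
  }
  se <- sqrt(diag(solve(XtWX)))
  names(se) <- colnames(X)
  est <- as.numeric(beta)
  names(est) <- colnames(X)

  expand <- function(prefix, free) {
    if (free) {
      tibble::tibble(group = groups, term = prefix,
                     estimate = unname(est[paste0(prefix, "_", groups)]),
                     std.error = unname(se[paste0(prefix, "_", groups)]))
    } else {
      tibble::tibble(group = groups, term = prefix,
                     estimate = unname(est[prefix]),
                     std.error = unname(se[prefix]))
    }
  }
  estimates <- dplyr::arrange(
    dplyr::bind_rows(expand("A", A_free), expand("B", B_free)),
    .data$term, .data$group
  )
  structure(
    list(
      estimates = estimates,
      minus2ll = dev,
      n_coef = ncol(X),
      sigma2 = setNames(sigma2, groups),
      n_obs = setNames(n_g, groups),
      constrain = constrain, level = level,
      driver_type = attr(driver, "driver_type") %||% "unknown",
      groups = groups,
      response_sum = sum(r)
    ),
    class = "rate_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf(
    "State-model rate fit (level = %s, driver = %s, constrain = %s)\n",
    x$level, x$driver_type, x$constrain
  ))
  cat(sprintf("-2 log-likelihood: %.3f on %d coefficient(s)\n",
              x$minus2ll, x$n_coef))
  print(x$estimates, ...)
  invisible(x)
}

#' Chi-square difference test between nested rate fits
#'
#' Likelihood-ratio comparison of two [fit_state_model()] fits on the same
#' data, where the null fit imposes a superset of the full fit's equality
#' constraints. The statistic is the difference of the deviances (`-2` log
#' likelihoods) and is referred to a chi-square distribution with degrees of
#' freedom equal to the number of extra constraints.
#'
#' @param fit_full,fit_null `rate_fit` objects; `fit_null` must be nested in
#'   `fit_full`.
#' @return A one-row tibble with `chi2_diff`, `df`, `p_value`.
#' @export
lr_difference_test <- function(fit_full, fit_null) {
  if (!inherits(fit_full, "rate_fit") || !inherits(fit_null, "rate_fit")) {
    abort("Both arguments must be rate_fit objects.")
  }
  same_data <- identical(fit_full$level, fit_null$level) &&
    identical(fit_full$driver_type, fit_null$driver_type) &&
    identical(fit_full$n_obs, fit_null$n_obs) &&
    isTRUE(all.equal(fit_full$response_sum, fit_null$response_sum))
  if (!same_data) abort("Fits were not computed on the same data.")
  rank_of <- c(none = 0, A = 1, B = 1, both = 2)
  nested <- switch(fit_full$constrain,
    none = TRUE,
    A = fit_null$constrain %in% c("A", "both"),
    B = fit_null$constrain %in% c("B", "both"),
    both = fit_null$constrain == "both"
  )
  if (!nested || rank_of[fit_null$constrain] < rank_of[fit_full$constrain]) {
    abort("`fit_null` must impose a superset of `fit_full`'s constraints.")
  }
  df <- fit_full$n_coef - fit_null$n_coef
  stat <- fit_null$minus2ll - fit_full$minus2ll
  if (stat < -1e-6) {
    abort("Constrained fit has higher likelihood than unconstrained: not converged.")
  }
  stat <- max(stat, 0)
  tibble::tibble(
    chi2_diff = stat, df = df,
    p_value = if (df > 0) pchisq(stat, df, lower.tail = FALSE) else NA_real_
  )
}

#' Per-participant retention and learning rates
#'
#' Fits the same no-intercept lag/driver regression separately to each
#' participant's series (ordinary least squares, which is the per-series ML
#' fit). Participants whose design is rank-deficient (e.g. a constant series
#' collinear with a constant driver) are flagged and returned with `NA`
#' estimates rather than aborting the whole table.
#'
#' @param trials A trial table.
#' @param driver A driver tibble from [driver_series()].
#' @return A tibble with one row per participant: `group`, `participant`,
#'   `A`, `B`, `se_A`, `se_B`, `sigma2`, `rank_ok`.
#' @export
fit_individual_rates <- function(trials, driver) {
  rows <- state_model_rows(trials, driver, level = "individual")
  fit_one <- function(d, key) {
    X <- cbind(A = d$lag, B = d$driver)
    xx <- crossprod(X)
    if (rcond(xx) < 1e-12) {
      return(tibble::tibble(group = d$group[1], participant = key$participant,
                            A = NA_real_, B = NA_real_, se_A = NA_real_,
                            se_B = NA_real_, sigma2 = NA_real_,
                            rank_ok = FALSE))
    }
    b <- solve(xx, crossprod(X, d$response))
    res <- d$response - as.vector(X %*% b)
    s2 <- sum(res^2) / length(res)
    se <- sqrt(diag(solve(xx)) * s2)
    tibble::tibble(group = d$group[1], participant = key$participant,
                   A = b[1], B = b[2], se_A = se[1], se_B = se[2],
                   sigma2 = s2, rank_ok = TRUE)
  }
  out <- dplyr::group_map(dplyr::group_by(rows, .data$participant), fit_one)
  dplyr::arrange(dplyr::bind_rows(out), .data$group, .data$participant)
}
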