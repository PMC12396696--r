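#' Tidy and glance methods
#'
#' Broom-style accessors for the package's fitted objects. `tidy()` returns
#' one row per estimated quantity; `glance()` returns a one-row model summary.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name gaitadapt-tidiers
NULL

#' @rdname gaitadapt-tidiers
#' @method tidy rate_fit
#' @export
tidy.rate_fit <- function(x, ...) {
  x$estimates
}

#' @rdname gaitadapt-tidiers
#' @method glance rate_fit
#' @export
glance.rate_fit <- function(x, ...) {
  tibble::tibble(
    minus2ll = x$minus2ll,
    n_coef = x$n_coef,
    n_obs = sum(x$n_obs),
    n_groups = length(x$groups),
    constrain = x$constrain,
    level = x$level,
    driver = x$driver_type,
    AIC = x$minus2ll + 2 * (x$n_coef + length(x$groups))
  )
}

#' @rdname gaitadapt-tidiers
#' @method tidy filter_estimate
#' @export
tidy.filter_estimate <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname gaitadapt-tidiers
#' @method glance filter_estimate
#' @export
glance.filter_estimate <- function(x, ...) {
  d <- attr(x, "diagnostics")
  tibble::tibble(
    n_groups = dplyr::n_distinct(x$group),
    n_steps = dplyr::n_distinct(x$step),
    final_particles = d$n_particles[nrow(d)],
    min_particles = min(d$n_particles),
    max_particles = max(d$n_particles),
    cum_log_weight = d$cum_log_weight[nrow(d)]
  )
}

#' @rdname gaitadapt-tidiers
#' @method tidy spline_posterior
#' @export
tidy.spline_posterior <- function(x, ...) {
  curves <- curve_and_derivative_samples(x)
  G <- length(x$groups)
  out <- vector("list", G)
  for (j in seq_len(G)) {
    f_j <- curves$f[, , j, drop = FALSE]
    dim(f_j) <- dim(curves$f)[1:2]
    qs <- apply(f_j, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
    out[[j]] <- tibble::tibble(
      group = x$groups[j], step = x$steps,
      f = colMeans(f_j), f_lo = qs[1, ], f_hi = qs[2, ]
    )
  }
  dplyr::bind_rows(out)
}

#' @rdname gaitadapt-tidiers
#' @method glance spline_posterior
#' @export
glance.spline_posterior <- function(x, ...) {
  tibble::tibble(
    S = x$S, burn_in = x$burn_in,
    n_groups = length(x$groups), n_steps = length(x$steps),
    n_basis = ncol(x$X),
    sigma_e2 = mean(x$sigma_e2),
    mean_sigma_d2 = mean(x$sigma_d2),
    mean_alpha_star = mean(x$alpha_star)
  )
}

#' @rdname gaitadapt-tidiers
#' @method tidy tv_rates
#' @export
tidy.tv_rates <- function(x, ...) {
  tibble::as_tibble(x)
}
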