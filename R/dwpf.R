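#' Priors and fixed constants of the sequential state-space track
#'
#' The sequential track treats the per-step group mean with a vague Normal
#' prior, the initial perturbation variance with a conjugate inverse-Gamma
#' prior, and advances the variance through the stochastic log-AR(1) transition
#' with fixed coefficient `a_j` and disturbance variance `sigma_u2`.
#'
#' @param A_mjt Prior mean of the group mean at each step.
#' @param B_mjt Prior SD of the group mean (vague by default).
#' @param A_sj Inverse-Gamma shape for the initial variance (> 1).
#' @param B_sj Inverse-Gamma rate for the initial variance (> 0).
#' @param a_j Log-variance transition coefficient.
#' @param sigma_u2 Log-variance disturbance variance (>= 0).
#' @param sigma_0_2 Nominal initial variance (used by the generator and as a
#'   fallback starting value).
#' @return A list of class `ssm_priors`.
#' @export
ssm_priors <- function(A_mjt = 0, B_mjt = 10, A_sj = 2, B_sj = 1,
                       a_j = 1, sigma_u2 = 0.01, sigma_0_2 = 1) {
  check_number(A_mjt, "A_mjt")
  check_number(B_mjt, "B_mjt", lower = 0, allow_equal_lower = FALSE)
  check_number(A_sj, "A_sj", lower = 1, allow_equal_lower = FALSE)
  check_number(B_sj, "B_sj", lower = 0, allow_equal_lower = FALSE)
  check_number(a_j, "a_j")
  check_number(sigma_u2, "sigma_u2", lower = 0)
  check_number(sigma_0_2, "sigma_0_2", lower = 0, allow_equal_lower = FALSE)
  structure(list(A_mjt = A_mjt, B_mjt = B_mjt, A_sj = A_sj, B_sj = B_sj,
                 a_j = a_j, sigma_u2 = sigma_u2, sigma_0_2 = sigma_0_2),
            class = "ssm_priors")
}

#' Full-conditional draw of a group mean
#'
#' Draws from the Normal full conditional of the group mean `m_jt` given that
#' step's observations and perturbation variance: variance
#' `V = (n/sigma2 + 1/B_m^2)^-1`, mean `M = (sum(y)/sigma2 + A_m/B_m^2) V`.
#'
#' @param y_jt Numeric vector of the group's angles at one step.
#' @param sigma2_jt Perturbation variance (> 0).
#' @param priors An [ssm_priors()] list.
#' @param n Number of draws.
#' @return Numeric vector of `n` draws.
#' @export
sample_group_mean <- function(y_jt, sigma2_jt, priors = ssm_priors(), n = 1) {
  if (length(y_jt) < 1) abort("Empty group: at least one observation needed.")
  check_number(sigma2_jt, "sigma2_jt", lower = 0, allow_equal_lower = FALSE)
  V <- 1 / (length(y_jt) / sigma2_jt + 1 / priors$B_mjt^2)
  M <- (sum(y_jt) / sigma2_jt + priors$A_mjt / priors$B_mjt^2) * V
  rnorm(n, M, sqrt(V))
}

#' Full-conditional draw of the initial perturbation variance
#'
#' Draws from the inverse-Gamma full conditional of the first-step variance:
#' shape `n/2 + A_sj`, rate `sum((y - m)^2)/2 + B_sj` (with the default priors
#' these are the `n/2 + 2` and `+1` constants).
#'
#' @param y_j1 Numeric vector of first-step angles for the group.
#' @param m_j1 Current group mean at the first step.
#' @param priors An [ssm_priors()] list.
#' @param n Number of draws.
#' @return Numeric vector of `n` positive draws.
#' @export
sample_initial_variance <- function(y_j1, m_j1, priors = ssm_priors(), n = 1) {
  if (length(y_j1) < 1) abort("Empty group: at least one observation needed.")
  shape <- length(y_j1) / 2 + priors$A_sj
  rate <- sum((y_j1 - m_j1)^2) / 2 + priors$B_sj
  1 / rgamma(n, shape = shape, rate = rate)
}

#' Advance particle variances through the log-AR(1) transition
#'
#' @param lambda Current particle state: a positive numeric vector (one
#'   variance per group) or a particles-by-groups matrix.
#' @param priors An [ssm_priors()] list supplying `a_j` and `sigma_u2`.
#' @return Object of the same shape with each log-variance advanced by
#'   `a_j * log(sigma2) + u`, `u ~ Normal(0, sigma_u2)`.
#' @export
propagate_particle <- function(lambda, priors = ssm_priors()) {
  if (any(lambda <= 0)) abort("All particle variances must be positive.")
  u <- if (priors$sigma_u2 > 0) {
    rnorm(length(lambda), 0, sqrt(priors$sigma_u2))
  } else {
    0
  }
  out <- exp(priors$a_j * log(lambda) + u)
  if (is.matrix(lambda)) dim(out) <- dim(lambda)
  out
}

#' Likelihood update of a particle weight
#'
#' Multiplies a particle weight by the Gaussian likelihood of one step's
#' observations under the particle's means and variances. The product is
#' accumulated in log space so repeated updates never underflow to zero.
#'
#' @param weight Current positive weight.
#' @param y_t Observations at the step: a numeric vector (one group) or a list
#'   of numeric vectors (one per group).
#' @param m_t Group mean(s), one per group.
#' @param lambda_t Perturbation variance(s), one per group.
#' @return Updated weight (positive, finite on the log scale).
#' @export
update_weight <- function(weight, y_t, m_t, lambda_t) {
  if (any(weight <= 0)) abort("`weight` must be positive.")
  if (!is.list(y_t)) y_t <- list(y_t)
  if (length(m_t) != length(y_t) || length(lambda_t) != length(y_t)) {
    abort("`m_t` and `lambda_t` must have one entry per group in `y_t`.")
  }
  ll <- sum(vapply(seq_along(y_t), function(j) {
    sum(dnorm(y_t[[j]], m_t[j], sqrt(lambda_t[j]), log = TRUE))
  }, numeric(1)))
  exp(log(weight) + ll)
}

# Gaussian log-likelihood of one step for all particles, from sufficient
# statistics: s1 = sum(y), s2 = sum(y^2), nv = n per group; m, sig2 are
# particles-by-groups matrices.
step_loglik <- function(s1, s2, nv, m, sig2) {
  ll <- 0
  for (j in seq_along(nv)) {
    ss <- s2[j] - 2 * m[, j] * s1[j] + nv[j] * m[, j]^2
    ll <- ll - 0.5 * nv[j] * log(2 * pi * sig2[, j]) - ss / (2 * sig2[, j])
  }
  ll
}

log_sum_exp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

# Core split/prune move on normalized weights. Returns the surviving/duplicated
# particle indices and their new (normalized-scale) weights.
weight_control_core <- function(w, n_min, n_max, theta_low, theta_high,
                                max_rounds = 30) {
  stopifnot(all(w > 0))
  W <- sum(w)
  wn <- w / W
  th_hi0 <- theta_high / length(w)
  th_lo0 <- theta_low / length(w)
  th_hi <- th_hi0
  th_lo <- th_lo0
  for (round in seq_len(max_rounds)) {
    heavy <- wn > th_hi
    k <- rep(1L, length(wn))
    k[heavy] <- as.integer(ceiling(wn[heavy] / th_hi))
    idx <- rep(seq_along(wn), k)
    new_w <- rep(wn / k, k)
    light <- new_w < th_lo
    if (any(light)) {
      keep_prob <- new_w[light] / th_lo
      kept <- runif(sum(light)) < keep_prob
      new_w[light][kept] <- th_lo
      drop <- logical(length(new_w))
      drop[light][!kept] <- TRUE
      idx <- idx[!drop]
      new_w <- new_w[!drop]
    }
    size <- length(new_w)
    if (size == 0) {
      abort("Particle population collapsed to zero particles during weight control.")
    }
    if (size > n_max) {
      th_hi <- th_hi * 2
      next
    }
    if (size < n_min) {
      th_lo <- th_lo / 2
      if (th_lo < .Machine$double.xmin) break
      next
    }
    break
  }
  list(index = idx, weights = new_w * W)
}

#' Dynamically weighted population control
#'
#' Splits particles whose (normalized) weight exceeds `theta_high / N` into
#' equal-weight copies — conserving total weight exactly — and prunes particles
#' below `theta_low / N` by keeping each with probability `w / theta_low` at
#' weight `theta_low` — conserving total weight in expectation. Thresholds are
#' adjusted automatically until the resulting population size lies within
#' `[n_min, n_max]`.
#'
#' @param population A list with elements `weights` (positive numeric) and
#'   optionally `values` (a particles-by-groups matrix of states, rearranged
#'   along with the weights).
#' @param n_min,n_max Population size bounds.
#' @param theta_low,theta_high Pruning / splitting thresholds, in units of the
#'   mean normalized weight `1/N`.
#' @return A list with rearranged `values`, new `weights`, and `index` mapping
#'   each output particle to its source.
#' @export
dynamic_weight_control <- function(population, n_min = 1000, n_max = 10000,
                                   theta_low = 0.2, theta_high = 5) {
  if (is.null(population$weights)) abort("`population$weights` is required.")
  ctl <- weight_control_core(population$weights, n_min, n_max,
                             theta_low, theta_high)
  values <- population$values
  if (!is.null(values)) {
    values <- if (is.matrix(values)) {
      values[ctl$index, , drop = FALSE]
    } else {
      values[ctl$index]
    }
  }
  list(values = values, weights = ctl$weights, index = ctl$index)
}

#' Sequential estimation of group means and variances (DWPF)
#'
#' Runs the dynamically weighted particle filter over a trial table. Each
#' particle carries the per-group perturbation variances; at every step the
#' filter (i) advances each particle's variances through the log-AR(1)
#' transition, (ii) draws each group mean from its Normal full conditional
#' given that particle's variance, (iii) multiplies the particle weight by the
#' step's Gaussian likelihood (in log space), and (iv) applies split/prune
#' population control. Point estimates are simple (unweighted) particle means;
#' the 95% bands are 2.5/97.5 particle percentiles.
#'
#' @param trials A trial table (see [as_gait_trials()]).
#' @param priors An [ssm_priors()] list.
#' @param n_particles Initial population size (>= 100).
#' @param n_min,n_max Population bounds for weight control.
#' @param theta_low,theta_high Weight-control thresholds (units of `1/N`).
#' @param init_sigma2 `NULL` (default) draws each particle's first-step
#'   variance from its inverse-Gamma prior and refreshes it from the
#'   full conditional after the first mean draw; a positive number (or vector,
#'   one per group) instead fixes every particle's variance at that value and
#'   skips the refresh — useful for fixed-variance calibration checks.
#' @param seed Optional RNG seed; identical seeds give identical estimates.
#' @return A tibble of class `filter_estimate` with columns `group`, `step`,
#'   `m_hat`, `m_lo`, `m_hi`, `sigma2_hat`, `sigma2_lo`, `sigma2_hi`, plus
#'   attribute `diagnostics` (per-step population size and cumulative
#'   log-weight).
#' @examples
#' trials <- generate_cohort(synth_config(n_per_group = 4, n_steps = 30,
#'                                        jump_step = 16, seed = 1))
#' est <- run_filter(trials, n_particles = 200, n_min = 100, n_max = 400,
#'                   seed = 2)
#' head(est)
#' @export
run_filter <- function(trials, priors = ssm_priors(), n_particles = 5000,
                       n_min = 1000, n_max = 10000,
                       theta_low = 0.2, theta_high = 5,
                       init_sigma2 = NULL, seed = NULL) {
  trials <- as_gait_trials(trials)
  n_particles <- check_count(n_particles, "n_particles", lower = 100)
  if (n_min > n_particles || n_max < n_particles) {
    abort("`n_particles` must lie within [n_min, n_max].")
  }
  y <- angle_matrix(trials)
  grp <- attr(y, "group")
  groups <- unique(grp)
  G <- length(groups)
  T_len <- nrow(y)
  if (T_len < 2) abort("At least two steps are required.")
  nv <- vapply(groups, function(g) sum(grp == g), numeric(1))
  S1 <- vapply(groups, function(g) rowSums(y[, grp == g, drop = FALSE]),
               numeric(T_len))
  S2 <- vapply(groups, function(g) rowSums(y[, grp == g, drop = FALSE]^2),
               numeric(T_len))
  with_seed_if(seed, {
    P <- n_particles
    if (is.null(init_sigma2)) {
      sig2 <- matrix(1 / rgamma(P * G, shape = priors$A_sj, rate = priors$B_sj),
                     nrow = P, ncol = G)
    } else {
      sig2 <- matrix(rep_len(init_sigma2, G), nrow = P, ncol = G, byrow = TRUE)
    }
    logw <- rep(-log(P), P)
    m_hat <- m_lo <- m_hi <- matrix(NA_real_, T_len, G)
    s2_hat <- s2_lo <- s2_hi <- matrix(NA_real_, T_len, G)
    sizes <- integer(T_len)
    log_total <- numeric(T_len)
    cum_log <- 0
    for (t in seq_len(T_len)) {
      if (t > 1) sig2 <- propagate_particle(sig2, priors)
      V <- 1 / (matrix(nv, nrow(sig2), G, byrow = TRUE) / sig2 +
                  1 / priors$B_mjt^2)
      M <- (matrix(S1[t, ], nrow(sig2), G, byrow = TRUE) / sig2 +
              priors$A_mjt / priors$B_mjt^2) * V
      m <- matrix(rnorm(length(M), M, sqrt(V)), nrow(sig2), G)
      if (t == 1 && is.null(init_sigma2)) {
        shape <- matrix(nv / 2 + priors$A_sj, nrow(sig2), G, byrow = TRUE)
        ss <- matrix(S2[1, ], nrow(sig2), G, byrow = TRUE) -
          2 * m * matrix(S1[1, ], nrow(sig2), G, byrow = TRUE) +
          m^2 * matrix(nv, nrow(sig2), G, byrow = TRUE)
        rate <- ss / 2 + priors$B_sj
        sig2 <- matrix(1 / rgamma(length(shape), shape = shape, rate = rate),
                       nrow(sig2), G)
      }
      ll <- step_loglik(S1[t, ], S2[t, ], nv, m, sig2)
      logw <- logw + ll
      lse <- log_sum_exp(logw)
      cum_log <- cum_log + lse
      logw <- logw - lse
      m_hat[t, ] <- colMeans(m)
      s2_hat[t, ] <- colMeans(sig2)
      for (j in seq_len(G)) {
        qm <- quantile(m[, j], c(0.025, 0.975), names = FALSE)
        qs <- quantile(sig2[, j], c(0.025, 0.975), names = FALSE)
        m_lo[t, j] <- qm[1]; m_hi[t, j] <- qm[2]
        s2_lo[t, j] <- qs[1]; s2_hi[t, j] <- qs[2]
      }
      ctl <- weight_control_core(exp(logw), n_min, n_max, theta_low, theta_high)
      sig2 <- sig2[ctl$index, , drop = FALSE]
      logw <- log(ctl$weights) - log(sum(ctl$weights))
      sizes[t] <- length(ctl$weights)
      log_total[t] <- cum_log
    }
    steps <- as.integer(rownames(y))
    out <- tibble::tibble(
      group = rep(groups, each = T_len),
      step = rep(steps, times = G),
      m_hat = as.vector(m_hat), m_lo = as.vector(m_lo), m_hi = as.vector(m_hi),
      sigma2_hat = as.vector(s2_hat), sigma2_lo = as.vector(s2_lo),
      sigma2_hi = as.vector(s2_hi)
    )
    attr(out, "diagnostics") <- tibble::tibble(
      step = steps, n_particles = sizes, cum_log_weight = log_total
    )
    attr(out, "priors") <- priors
    class(out) <- unique(c("filter_estimate", class(out)))
    out
  })
}

#' Centered moving-average smoothing of a mean series
#'
#' @param x Numeric series.
#' @param window Odd window width (>= 1); the window is truncated at the
#'   series edges. `window = 1` returns the input unchanged.
#' @return Smoothed numeric series of the same length.
#' @export
smooth_mean_curve <- function(x, window = 1) {
  window <- check_count(window, "window", lower = 1)
  if (window %% 2 == 0) abort("`window` must be odd.")
  if (window > length(x)) abort("`window` must not exceed the series length.")
  if (window == 1) return(x)
  h <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}
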