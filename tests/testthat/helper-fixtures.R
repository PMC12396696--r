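# Fixtures and independent oracles used across the suite. Everything is
# generated in code; nothing is read from disk.

# Small cohort for smoke tests.
tiny_cohort <- function(seed = 1, n = 4, T = 40, jump = 21, ...) {
  generate_cohort(synth_config(n_per_group = n, n_steps = T, jump_step = jump,
                               seed = seed, ...))
}

# Noiseless trials evolving exactly as y_{t+1} = A y_t + B d_t, with a custom
# driver distinct from the lag so both coefficients are identified. Returns
# the trial table and the driver tibble.
exact_recursion_trials <- function(A, B, T = 30, n = 3, y0 = c(10, 20, 30),
                                   group = "G1") {
  d <- 5 + 3 * sin(seq_len(T) / 3)
  y <- matrix(0, T, n)
  y[1, ] <- y0[seq_len(n)]
  for (t in seq_len(T - 1)) y[t + 1, ] <- A * y[t, ] + B * d[t]
  trials <- as_gait_trials(tibble::tibble(
    group = group,
    participant = rep(sprintf("p%02d", seq_len(n)), each = T),
    step = rep(seq_len(T), n),
    angle = as.vector(y)
  ))
  driver <- tibble::tibble(group = group, step = seq_len(T), driver = d)
  attr(driver, "driver_type") <- "custom"
  list(trials = trials, driver = driver)
}

# Closed-form posterior mean of the group mean under known variance: the
# conjugate Normal oracle the filter must match when variances are frozen.
conjugate_mean_oracle <- function(y_jt, sigma2, priors = ssm_priors()) {
  V <- 1 / (length(y_jt) / sigma2 + 1 / priors$B_mjt^2)
  (sum(y_jt) / sigma2 + priors$A_mjt / priors$B_mjt^2) * V
}

# A smooth truth lying exactly in the span of the cubic truncated-power
# basis: a logistic ramp projected onto the basis by least squares.
smooth_truth_in_span <- function(T = 200, n_knots = 9, baseline = 60,
                                 rise = 30, center = T / 2, scale = T / 12) {
  X <- build_basis(seq_len(T), spline_model(T, n_knots)$knots)
  target <- baseline + rise / (1 + exp(-(seq_len(T) - center) / scale))
  Xs <- sweep(X, 2, sqrt(colSums(X^2)), `/`)
  qrX <- qr(Xs)
  as.vector(Xs %*% qr.coef(qrX, target))
}

# Fabricate a single-draw spline posterior from explicit coefficients, for
# algebraic tests of the curve/derivative/rate transforms.
fake_posterior <- function(beta, T, knots, group = "G1") {
  X <- build_basis(seq_len(T), knots)
  p <- ncol(X)
  stopifnot(length(beta) == p)
  structure(
    list(beta = array(beta, c(1, p, 1)),
         m = array(as.vector(X %*% beta), c(1, T, 1)),
         alpha_star = matrix(1, 1, 1), sigma_d2 = matrix(1, 1, 1),
         sigma_e2 = 1,
         model = spline_model(T, knots = knots), X = X, groups = group,
         steps = seq_len(T),
         y_bar = matrix(as.vector(X %*% beta), T, 1),
         n_j = 1, S = 1, burn_in = 0, seed = NULL),
    class = "spline_posterior"
  )
}
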