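# Joint-distribution ("getting it right") machinery for the P-spline Gibbs
# sampler: compare parameter draws obtained (a) directly from the prior and
# (b) by alternating data simulation with one Gibbs sweep. If every full
# conditional is correct the two samplers share the same parameter marginals.
# Run with a full-rank penalty and proper hyperpriors so the prior is
# samplable and all test statistics have finite variance.

geweke_model <- function(T = 60, n_knots = 4) {
  # full-rank penalty scaled by the squared basis column norms: every prior is
  # proper and prior curves live on the same scale as the data, so the
  # successive-conditional chain mixes across the whole prior
  sm0 <- spline_model(n_steps = T, n_knots = n_knots)
  X <- build_basis(seq_len(T), sm0$knots)
  spline_model(n_steps = T, n_knots = n_knots,
               penalty = colSums(X^2),
               A_t = 3, B_t = 3, A_d = 3, B_d = 2, A_e = 3, B_e = 2)
}

geweke_setup <- function(model, n_per_group = 2) {
  T <- model$n_steps
  X <- build_basis(seq_len(T), model$knots)
  col_scale <- sqrt(colSums(X^2))
  list(
    X = X, Xs = sweep(X, 2, col_scale, `/`), col_scale = col_scale,
    penalty = model$penalty,
    pen_half_scaled = sqrt(model$penalty) / col_scale,
    rank_penalty = sum(model$penalty > 0),
    n_j = n_per_group, T = T, p = ncol(X)
  )
}

geweke_prior_draw <- function(setup, model) {
  alpha_star <- rgamma(1, model$A_t, rate = model$B_t)
  beta <- rnorm(setup$p, 0, 1 / sqrt(alpha_star * setup$penalty))
  sigma_d2 <- 1 / rgamma(1, model$A_d, rate = model$B_d)
  m <- as.vector(setup$X %*% beta) + rnorm(setup$T, 0, sqrt(sigma_d2))
  sigma_e2 <- 1 / rgamma(1, model$A_e, rate = model$B_e)
  list(beta = matrix(beta, setup$p, 1), m = matrix(m, setup$T, 1),
       alpha_star = alpha_star, sigma_d2 = sigma_d2, sigma_e2 = sigma_e2)
}

geweke_simulate_y <- function(state, setup) {
  matrix(state$m[, 1], setup$T, setup$n_j) +
    matrix(rnorm(setup$T * setup$n_j, 0, sqrt(state$sigma_e2)), setup$T)
}

# One statistic per Gibbs block; positive quantities are tested on the log
# scale so every statistic has light tails and a stable Monte-Carlo variance.
geweke_stats <- function(state, setup) {
  c(beta_pen = log(sum(setup$penalty * state$beta[, 1]^2)),
    alpha_star = log(state$alpha_star),
    m_mean = mean(state$m[, 1]),
    sigma_d2 = log(state$sigma_d2),
    sigma_e2 = log(state$sigma_e2))
}

# z-scores comparing the two samplers' means of each test statistic; the
# successive-conditional chain's variance is estimated by batch means.
geweke_zscores <- function(n_draws = 20000, seed = 42, model = geweke_model(),
                           n_per_group = 2) {
  setup <- geweke_setup(model, n_per_group)
  withr::with_seed(seed, {
    prior_stats <- t(replicate(n_draws, {
      geweke_stats(geweke_prior_draw(setup, model), setup)
    }))
    state <- geweke_prior_draw(setup, model)
    succ_stats <- matrix(NA_real_, n_draws, ncol(prior_stats))
    data <- setup
    for (i in seq_len(n_draws)) {
      y <- geweke_simulate_y(state, setup)
      data$Ysum <- matrix(rowSums(y), setup$T, 1)
      data$Ysq <- sum(y^2)
      state <- gaitadapt:::fda_gibbs_sweep(state, data, model)
      succ_stats[i, ] <- geweke_stats(state, setup)
    }
    colnames(succ_stats) <- colnames(prior_stats)
    # conservative long-run variance for the autocorrelated chain: the larger
    # of a batch-means estimate (long batches) and an initial-positive-
    # sequence estimate from the autocorrelation function
    chain_var <- function(x, n_batch = 25) {
      bm <- tapply(x, rep(seq_len(n_batch), each = length(x) / n_batch), mean)
      v_batch <- var(bm) / n_batch
      rho <- acf(x, lag.max = min(300, length(x) %/% 10),
                 plot = FALSE)$acf[-1, 1, 1]
      first_neg <- which(rho < 0)[1]
      if (!is.na(first_neg)) rho <- rho[seq_len(first_neg - 1)]
      v_acf <- var(x) * (1 + 2 * sum(rho)) / length(x)
      max(v_batch, v_acf)
    }
    vapply(colnames(prior_stats), function(s) {
      v1 <- var(prior_stats[, s]) / n_draws
      v2 <- chain_var(succ_stats[, s])
      (mean(prior_stats[, s]) - mean(succ_stats[, s])) / sqrt(v1 + v2)
    }, numeric(1))
  })
}
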