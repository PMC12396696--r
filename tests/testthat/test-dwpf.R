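test_that("group-mean full conditional matches its closed form", {
  withr::local_seed(1)
  pr <- ssm_priors()
  # symmetry: zero data, zero prior mean
  draws <- sample_group_mean(c(0, 0, 0), 1, pr, n = 1e5)
  expect_lt(abs(mean(draws)), 3 * sd(draws) / sqrt(1e5))
  # closed-form moments: y = four tens, sigma2 = 1, B_m = 10
  V <- 1 / (4 / 1 + 1 / 100)
  M <- (40 / 1) * V
  expect_equal(V, 1 / 4.01)
  expect_equal(M, 9.97506, tolerance = 1e-5)
  draws <- sample_group_mean(rep(10, 4), 1, pr, n = 1e5)
  expect_lt(abs(mean(draws) - M), 3 * sqrt(V / 1e5))
  expect_equal(sd(draws), sqrt(V), tolerance = 0.02)
  # flat-prior limit: posterior collapses to sample mean with variance s2/n
  flat <- ssm_priors(B_mjt = 1e8)
  draws <- sample_group_mean(c(2, 4, 6), 3, flat, n = 1e5)
  expect_equal(mean(draws), 4, tolerance = 3 * sqrt(1 / 1e5) + 1e-3)
  expect_equal(var(draws), 1, tolerance = 0.03)
  expect_error(sample_group_mean(numeric(0), 1), "Empty group")
  expect_error(sample_group_mean(1:3, 0), "sigma2")
})

test_that("initial-variance full conditional has the stated inverse-Gamma form", {
  withr::local_seed(2)
  pr <- ssm_priors() # A_sj = 2, B_sj = 1 give the +2 / +1 constants
  # residuals (1, -1): shape 3, rate 2, posterior mean 2 / (3 - 1) = 1
  draws <- sample_initial_variance(c(1, -1), 0, pr, n = 1e5)
  expect_lt(abs(mean(draws) - 1), 3 * sqrt(1 / 1e5))
  # zero residuals with n = 2: shape 3, rate 1, mean 1/2
  draws0 <- sample_initial_variance(c(0, 0), 0, pr, n = 1e5)
  expect_equal(mean(draws0), 0.5, tolerance = 0.01)
  expect_true(all(draws0 > 0))
})

test_that("particle propagation obeys the log-AR(1) transition", {
  withr::local_seed(3)
  pr0 <- ssm_priors(sigma_u2 = 0, a_j = 1)
  lam <- matrix(c(0.5, 1, 2, 4), 2, 2)
  expect_identical(propagate_particle(lam, pr0), lam)
  pr <- ssm_priors(sigma_u2 = 0.01, a_j = 1)
  out <- propagate_particle(matrix(2, 1e5, 1), pr)
  expect_lt(abs(mean(log(out)) - log(2)), 3 * 0.1 / sqrt(1e5))
  # a = 0.5 from sigma2 = 1: conditional median stays 1
  out_half <- propagate_particle(matrix(1, 1e5, 1), ssm_priors(a_j = 0.5))
  expect_equal(median(out_half), 1, tolerance = 0.01)
  expect_error(propagate_particle(c(-1, 1)), "positive")
})

test_that("weight update multiplies by the Gaussian likelihood in log space", {
  expect_equal(update_weight(1, c(0, 0), 0, 1), 1 / (2 * pi))
  # zero residuals, k observations: multiplier (2 pi)^(-k/2)
  expect_equal(update_weight(1, rep(3, 5), 3, 1), (2 * pi)^(-5 / 2))
  # multiplicativity and multi-group product
  w1 <- update_weight(2, list(c(0, 0), 1), c(0, 1), c(1, 2))
  expect_equal(w1, 2 * update_weight(1, list(c(0, 0), 1), c(0, 1), c(1, 2)))
  expect_error(update_weight(0, 1, 0, 1), "positive")
})

test_that("weight control splits exactly and prunes unbiasedly", {
  # a particle at twice the split threshold becomes two at the threshold
  out <- dynamic_weight_control(list(values = matrix(1, 1, 1), weights = 2),
                                n_min = 1, n_max = 10,
                                theta_low = 0.2, theta_high = 0.5)
  # one particle with normalized weight 1 > 0.5: split into two halves
  expect_equal(length(out$weights), 2)
  expect_equal(sum(out$weights), 2)
  # all weights inside the band: population unchanged
  mid <- list(values = matrix(1:5, 5, 1), weights = rep(0.2, 5))
  out_mid <- dynamic_weight_control(mid, n_min = 1, n_max = 100)
  expect_identical(out_mid$weights, mid$weights)
  expect_identical(out_mid$values, mid$values)
  # expected total weight conserved over many randomized control steps
  withr::local_seed(4)
  ratios <- vapply(1:2000, function(i) {
    w <- rexp(200)
    out <- dynamic_weight_control(list(weights = w), n_min = 50, n_max = 2000)
    sum(out$weights) / sum(w)
  }, numeric(1))
  expect_equal(mean(ratios), 1, tolerance = 0.01)
  # bounds respected
  sizes <- vapply(1:50, function(i) {
    w <- rexp(200)^3
    length(dynamic_weight_control(list(weights = w),
                                  n_min = 100, n_max = 300)$weights)
  }, numeric(1))
  expect_true(all(sizes >= 100 & sizes <= 300))
})

test_that("the filter matches the conjugate oracle when variances are frozen", {
  cfg <- synth_config(n_per_group = 11, n_steps = 20, jump_step = 10,
                      true_A = 1, true_B = 0, dynamics = "shared",
                      participant_offset_sd = 0, sigma_u2 = 0, sigma_0_2 = 1,
                      seed = 5)
  tr <- generate_cohort(cfg)
  pr <- ssm_priors(sigma_u2 = 0)
  est <- run_filter(tr, priors = pr, n_particles = 5000, n_min = 2000,
                    n_max = 10000, init_sigma2 = 1, seed = 6)
  y <- angle_matrix(tr)
  grp <- attr(y, "group")
  for (g in unique(grp)) {
    oracle <- apply(y[, grp == g, drop = FALSE], 1, conjugate_mean_oracle,
                    sigma2 = 1, priors = pr)
    got <- dplyr::arrange(dplyr::filter(tibble::as_tibble(est), group == g),
                          step)$m_hat
    expect_lt(max(abs(got - oracle) / abs(oracle)), 0.005)
  }
})

test_that("filter output is seeded-deterministic with valid band ordering", {
  tr <- tiny_cohort(seed = 7, n = 5, T = 30, jump = 16)
  a <- run_filter(tr, n_particles = 300, n_min = 150, n_max = 600, seed = 1)
  b <- run_filter(tr, n_particles = 300, n_min = 150, n_max = 600, seed = 1)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_true(all(a$m_lo <= a$m_hat & a$m_hat <= a$m_hi))
  expect_true(all(a$sigma2_lo <= a$sigma2_hat & a$sigma2_hat <= a$sigma2_hi))
  expect_true(all(a$sigma2_hat > 0))
  d <- attr(a, "diagnostics")
  expect_true(all(d$n_particles >= 150 & d$n_particles <= 600))
  expect_true(all(is.finite(d$cum_log_weight)))
})

test_that("long filter runs keep weights and variances finite and positive", {
  tr <- generate_cohort(synth_config(seed = 9))
  est <- run_filter(tr, n_particles = 400, n_min = 200, n_max = 800, seed = 10)
  expect_false(anyNA(tibble::as_tibble(est)))
  expect_true(all(est$sigma2_hat > 0))
  expect_true(all(is.finite(attr(est, "diagnostics")$cum_log_weight)))
})

test_that("moving-average smoothing handles edges and trivial windows", {
  expect_identical(smooth_mean_curve(c(5, 7, 9), 1), c(5, 7, 9))
  expect_equal(smooth_mean_curve(rep(4, 10), 5), rep(4, 10))
  expect_equal(smooth_mean_curve(c(0, 3, 6), 3)[2], 3)
  expect_equal(smooth_mean_curve(c(0, 3, 6), 3), c(1.5, 3, 4.5))
  expect_error(smooth_mean_curve(1:5, 4), "odd")
  expect_error(smooth_mean_curve(1:3, 5), "length")
})
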