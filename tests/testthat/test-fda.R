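test_that("the truncated-power basis has the stated structure", {
  X <- build_basis(1:500, spline_model(500)$knots)
  expect_equal(dim(X), c(500L, 23L))
  # plus-function boundary: zero at the knot, cubic beyond it
  Xk <- build_basis(c(25, 27), c(25, 100))
  expect_equal(Xk[1, "k1"], 0, ignore_attr = TRUE)
  expect_equal(Xk[2, "k1"], 8, ignore_attr = TRUE)
  expect_equal(Xk[, "k2"], c(0, 0), ignore_attr = TRUE)
  expect_equal(Xk[2, 1:4], c(1, 27, 27^2, 27^3), ignore_attr = TRUE)
  expect_error(build_basis(1:10, c(3, 3)), "distinct")
  # default model invariants: penalty rank K, dimension K + 4
  sm <- spline_model(500)
  expect_equal(sm$knots, seq(25, 475, by = 25))
  expect_equal(sum(sm$penalty), 19)
  expect_equal(length(sm$penalty), 23)
  expect_error(spline_model(500, knots = c(0, 100)), "inside")
})

test_that("curve draws and first differences follow the algebra", {
  # linear curve: every unit-step difference equals the slope
  post <- fake_posterior(c(2, 3, 0, 0, 0, 0), T = 20, knots = c(8, 14))
  cv <- curve_and_derivative_samples(post)
  expect_equal(as.vector(cv$f[1, , 1]), 2 + 3 * (1:20))
  expect_equal(as.vector(cv$fprime[1, , 1]), rep(3, 19))
  # constant curve: derivative identically zero
  post0 <- fake_posterior(c(7, 0, 0, 0, 0, 0), T = 20, knots = c(8, 14))
  expect_equal(as.vector(curve_and_derivative_samples(post0)$fprime), rep(0, 19))
  # quadratic curve: difference at t equals 2t + 1 exactly
  post2 <- fake_posterior(c(0, 0, 1, 0, 0, 0), T = 20, knots = c(8, 14))
  expect_equal(as.vector(curve_and_derivative_samples(post2)$fprime[1, , 1]),
               2 * (1:19) + 1)
})

test_that("rate functions implement the derivative/ratio transform", {
  # f = 1, f' = 0: learning rate equals the next-step observed mean
  post <- fake_posterior(c(1, 0, 0, 0, 0, 0), T = 10, knots = c(4, 7))
  yb <- tibble::tibble(group = "G1", step = 1:10, y_bar = 0.05)
  tv <- rate_functions(post, yb)
  expect_equal(tv$A, rep(0, 9))
  expect_equal(tv$B, rep(0.05, 9))
  # observed mean equal to the derivative: learning rate zero
  post_lin <- fake_posterior(c(2, 3, 0, 0, 0, 0), T = 10, knots = c(4, 7))
  yb3 <- tibble::tibble(group = "G1", step = 1:10, y_bar = 3)
  tv3 <- rate_functions(post_lin, yb3)
  expect_equal(tv3$B, rep(0, 9), tolerance = 1e-12)
  # single-draw reconstruction: y_bar_{t+1} = A + B * f exactly
  tr <- tiny_cohort(seed = 8, T = 40, jump = 21)
  post_s1 <- gibbs_fda(tr, spline_model(40, n_knots = 3), S = 1, burn_in = 20,
                       seed = 3)
  tv1 <- rate_functions(post_s1)
  yb1 <- dplyr::arrange(group_means(tr), group, step)
  for (g in unique(tv1$group)) {
    d <- dplyr::filter(tv1, group == g)
    y_next <- dplyr::filter(yb1, group == g)$y_bar[-1]
    expect_equal(d$A + d$B * d$f, y_next, tolerance = 1e-9)
  }
})

test_that("the division guard flags near-zero fitted curves", {
  post <- fake_posterior(c(1e-9, 0, 0, 0, 0, 0), T = 10, knots = c(4, 7))
  yb <- tibble::tibble(group = "G1", step = 1:10, y_bar = 1)
  expect_warning(tv <- rate_functions(post, yb), "floor")
  expect_true(all(is.na(tv$B)))
  expect_true(all(!tv$B_ok))
  expect_false(anyNA(tv$A))
})

test_that("the Gibbs sampler is seed-deterministic and recovers a cubic", {
  tr <- tiny_cohort(seed = 9, T = 50, jump = 26)
  sm <- spline_model(50, n_knots = 3)
  a <- gibbs_fda(tr, sm, S = 30, burn_in = 30, seed = 4)
  b <- gibbs_fda(tr, sm, S = 30, burn_in = 30, seed = 4)
  expect_identical(a$beta, b$beta)
  expect_identical(a$sigma_e2, b$sigma_e2)
  expect_true(all(a$sigma_d2 > 0) && all(a$alpha_star > 0))

  # data from a known cubic polynomial: posterior mean curve within 3
  # posterior SDs of the truth at every interior step
  withr::local_seed(5)
  T <- 80
  truth <- 50 + 0.5 * (1:T) - 0.004 * (1:T)^2
  yl <- tibble::tibble(
    group = "g", participant = rep(sprintf("p%d", 1:6), each = T),
    step = rep(1:T, 6), angle = rep(truth, 6) + rnorm(6 * T, 0, 1)
  )
  post <- gibbs_fda(as_gait_trials(yl), spline_model(T, n_knots = 4),
                    S = 400, burn_in = 200, seed = 6)
  cv <- curve_and_derivative_samples(post)
  f_hat <- colMeans(cv$f[, , 1])
  f_sd <- apply(cv$f[, , 1], 2, sd)
  interior <- 5:(T - 5)
  expect_true(all(abs(f_hat - truth)[interior] <
                    3 * pmax(f_sd[interior], 0.05)))
})

test_that("posterior curves are shift-equivariant with matched seeds", {
  tr <- tiny_cohort(seed = 10, T = 40, jump = 21)
  shifted <- tibble::as_tibble(tr)
  shifted$angle <- shifted$angle + 100
  shifted <- as_gait_trials(shifted)
  sm <- spline_model(40, n_knots = 3)
  p1 <- gibbs_fda(tr, sm, S = 40, burn_in = 40, seed = 7)
  p2 <- gibbs_fda(shifted, sm, S = 40, burn_in = 40, seed = 7)
  c1 <- curve_and_derivative_samples(p1)
  c2 <- curve_and_derivative_samples(p2)
  expect_equal(c2$f, c1$f + 100, tolerance = 1e-5)
  expect_equal(c2$fprime, c1$fprime, tolerance = 1e-5)
})

test_that("posterior mean curve equals the curve of mean coefficients", {
  tr <- tiny_cohort(seed = 11, T = 40, jump = 21)
  post <- gibbs_fda(tr, spline_model(40, n_knots = 3), S = 50, burn_in = 20,
                    seed = 8)
  cv <- curve_and_derivative_samples(post)
  for (j in seq_along(post$groups)) {
    expect_equal(colMeans(cv$f[, , j]),
                 as.vector(post$X %*% colMeans(post$beta[, , j])),
                 tolerance = 1e-9)
  }
})

test_that("weakening the smoothing prior tightens the spline fit", {
  tr <- tiny_cohort(seed = 12, T = 60, jump = 31, n = 5)
  sm_strong <- spline_model(60, n_knots = 4, A_t = 1, B_t = 1e-4)
  sm_weak <- spline_model(60, n_knots = 4, A_t = 1, B_t = 100)
  disc <- function(sm) {
    post <- gibbs_fda(tr, sm, S = 100, burn_in = 100, seed = 9)
    mean(vapply(seq_len(post$S), function(s) {
      sqrt(sum((post$m[s, , ] - post$X %*% post$beta[s, , ])^2))
    }, numeric(1)))
  }
  expect_lt(disc(sm_weak), disc(sm_strong) * 1.05)
})

test_that("band overlap flags disjoint intervals per step and pair", {
  base <- tibble::tibble(
    group = "a", step = 1:5, f = 1, f_lo = 0.9, f_hi = 1.1,
    A = 0, A_lo = -1, A_hi = 1, B = 0.5, B_lo = 0, B_hi = 1, B_ok = TRUE
  )
  same <- dplyr::bind_rows(base, dplyr::mutate(base, group = "b"))
  ov_same <- band_overlap(same)
  expect_false(any(ov_same$disjoint))
  apart <- dplyr::mutate(base, group = "b", A_lo = 2, A_hi = 3)
  ov <- band_overlap(dplyr::bind_rows(base, apart))
  expect_true(all(ov$disjoint[ov$parameter == "A"]))
  expect_false(any(ov$disjoint[ov$parameter == "B"]))
  runs <- attr(ov, "runs")
  expect_equal(runs$longest_run[runs$parameter == "A"], 5L)
  bad <- dplyr::mutate(base, group = "b", step = 2:6)
  expect_error(band_overlap(dplyr::bind_rows(base, bad)), "grid")
  expect_error(band_overlap(base), "two groups")
})

test_that("all five Gibbs blocks pass the joint-distribution check", {
  z <- geweke_zscores(n_draws = 12000, seed = 21,
                      model = geweke_model(T = 40, n_knots = 3))
  expect_true(all(abs(z) < qnorm(0.995)))
})
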