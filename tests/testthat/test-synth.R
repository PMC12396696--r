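test_that("variance path follows the log-AR(1) law and its degenerate cases", {
  # zero disturbance: variance stays put exactly
  expect_identical(generate_variance_path(1, 0, 1, 10), rep(1, 11))
  # decay of the log under |a| < 1 with no noise
  path <- generate_variance_path(0.5, 0, 4, 3)
  expect_equal(log(path), log(4) * 0.5^(0:3))
  # seeded determinism
  expect_identical(generate_variance_path(1, 0.01, 1, 50, seed = 9),
                   generate_variance_path(1, 0.01, 1, 50, seed = 9))
  # under a = 1 the log-increments are iid Normal(0, sigma_u2)
  long <- generate_variance_path(1, 0.01, 1, 20000, seed = 2)
  incr <- diff(log(long))
  expect_lt(abs(mean(incr)), 3 * 0.1 / sqrt(length(incr)))
  expect_equal(sd(incr), 0.1, tolerance = 0.03)
  # the median of sigma2_1 is exp of the median log, i.e. the previous value
  reps <- vapply(1:2000, function(s) {
    generate_variance_path(1, 0.01, 1, 1, seed = 10000 + s)[2]
  }, numeric(1))
  expect_equal(median(reps), 1, tolerance = 0.02)
  expect_error(generate_variance_path(1, 0.01, 0, 5), "sigma_0_2")
  expect_error(generate_variance_path(1, -1, 1, 5), "sigma_u2")
})

test_that("cohort generation is deterministic and respects the study layout", {
  cfg <- synth_config(seed = 5, n_steps = 60, jump_step = 31, n_per_group = 4)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_identical(attr(a, "truth"), attr(b, "truth"))

  full <- generate_cohort(synth_config(seed = 1))
  expect_equal(dplyr::n_distinct(full$group), 3)
  expect_equal(dplyr::n_distinct(full$participant), 33)
  expect_equal(sort(unique(full$step)), 1:500)
  expect_setequal(unique(full$group), c("Control", "Punishment", "Reward"))
  expect_false(anyNA(full$angle))
})

test_that("degenerate noise-free cohorts decay at the retention factor", {
  base <- list(n_per_group = 2, n_steps = 20, jump_step = 10,
               true_B = 0, participant_offset_sd = 0, retention_jitter_sd = 0,
               sigma_u2 = 0, sigma_0_2 = 1e-18, seed = 3)
  # A = 1: every trajectory constant at the baseline mean
  cfg1 <- do.call(synth_config, c(base, list(true_A = 1)))
  y1 <- angle_matrix(generate_cohort(cfg1))
  expect_equal(as.vector(y1), rep(60, length(y1)), tolerance = 1e-6)
  # A = 0.9: geometric decay of the baseline
  cfg2 <- do.call(synth_config, c(base, list(true_A = 0.9)))
  y2 <- angle_matrix(generate_cohort(cfg2))
  expect_equal(y2[, 1], 60 * 0.9^(0:19), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("group means approach the adaptation target fixed point", {
  trials <- generate_cohort(synth_config(seed = 11))
  late <- dplyr::filter(group_means(trials), step >= 450)
  late_means <- tapply(late$y_bar, late$group, mean)
  # late-phase mean within 3 SD of the group-mean's own dispersion around the
  # 90 degree fixed point (offset averaging dominates: sd ~ 3/sqrt(11))
  expect_true(all(abs(late_means - 90) < 3 * 3 / sqrt(11) + 1))
})

test_that("sample group means are unbiased for the latent mean trajectory", {
  reps <- purrr::map_dfr(1:200, function(s) {
    cfg <- synth_config(n_per_group = 6, n_steps = 40, jump_step = 21,
                        participant_offset_sd = 2, retention_jitter_sd = 0,
                        seed = 4000 + s)
    tr <- generate_cohort(cfg)
    truth <- attr(tr, "truth")
    dplyr::mutate(
      dplyr::left_join(group_means(tr), truth, by = c("group", "step")),
      err = y_bar - m, rep = s
    )
  })
  # persistent participant offsets correlate the error within a replicate, so
  # the Monte-Carlo SE comes from independent per-replicate means
  per_rep <- dplyr::summarise(
    dplyr::group_by(reps, group, rep), err = mean(err), .groups = "drop"
  )
  pooled <- dplyr::summarise(
    dplyr::group_by(per_rep, group),
    bias = mean(err), se = sd(err) / sqrt(dplyr::n())
  )
  expect_true(all(abs(pooled$bias) < 3 * pooled$se))
})

test_that("shared-mode cross-sectional variance matches the variance path", {
  cfg <- synth_config(n_per_group = 11, n_steps = 50, jump_step = 26,
                      dynamics = "shared", participant_offset_sd = 0,
                      sigma_u2 = 0, sigma_0_2 = 2, seed = 8)
  tr <- generate_cohort(cfg)
  v <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(tr), group, step),
    s2 = var(angle), .groups = "drop"
  )
  # (n-1) s^2 / sigma2 ~ chi-square(n-1): 99% coverage check over all cells
  stat <- (11 - 1) * v$s2 / 2
  inside <- stat > qchisq(0.005, 10) & stat < qchisq(0.995, 10)
  expect_gt(mean(inside), 0.97)
})

test_that("baseline convention returns re-centred angles and matching truth", {
  cfg <- synth_config(seed = 2, n_steps = 80, jump_step = 41,
                      convention = "baseline")
  tr <- generate_cohort(cfg)
  window_means <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(tibble::as_tibble(tr), step <= 40), participant
    ),
    m = mean(angle)
  )
  expect_equal(window_means$m, rep(0, nrow(window_means)), tolerance = 1e-12)
  truth <- attr(tr, "truth")
  # adjusted truth keeps the jump size but loses the baseline level
  expect_equal(unique(truth$target), c(0, 30), tolerance = 1e-6)
  gm <- dplyr::left_join(group_means(tr), truth, by = c("group", "step"))
  expect_lt(max(abs(tapply(gm$y_bar - gm$m, gm$group, mean))), 1.5)
})

test_that("configuration invariants are validated", {
  expect_error(synth_config(n_per_group = 1), "n_per_group")
  expect_error(synth_config(jump_step = 500, n_steps = 500), "jump_step")
  expect_error(synth_config(true_A = 1.6), "true_A")
  expect_error(synth_config(sigma_0_2 = 0), "sigma_0_2")
  expect_error(synth_config(group_labels = c("a", "b")), "label")
})

test_that("smooth cohorts carry their generating curve as truth", {
  f <- cbind(smooth_truth_in_span(100, 4), smooth_truth_in_span(100, 4) + 5)
  tr <- generate_smooth_cohort(f, n_per_group = 3, sigma_d2 = 0.1,
                               sigma_e2 = 0.5, seed = 6)
  truth <- attr(tr, "truth")
  expect_equal(nrow(truth), 200)
  expect_equal(truth$f[truth$group == "Group1"], f[, 1])
  gm <- dplyr::left_join(group_means(tr), truth, by = c("group", "step"))
  expect_lt(sd(gm$y_bar - gm$f), 3 * sqrt(0.1 + 0.5 / 3))
})
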