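#' Configuration for the synthetic cohort generator
#'
#' Bundles the generative ground truth for [generate_cohort()]: the study
#' layout (groups, participants, steps, phase structure), the per-group
#' retention factors and learning rates of the state model, and the stochastic
#' log-variance transition governing the perturbation variance. Defaults mirror
#' the study design the package targets: 3 feedback groups
#' (Control/Punishment/Reward) of 11 participants, 500 stride steps with a
#' baseline phase over steps 1-250 and a +30 degree target jump at step 251,
#' and retention/learning rates in the range reported for such experiments.
#'
#' @param n_groups Number of groups.
#' @param n_per_group Participants per group (scalar, recycled).
#' @param n_steps Number of stride steps `T`.
#' @param baseline_mean Baseline target angle (degrees).
#' @param adaptation_increment Added to the target at the jump (degrees).
#' @param jump_step First step of the adaptation phase.
#' @param true_A Per-group retention factor, in (0, 1.5).
#' @param true_B Per-group learning rate, >= 0. The latent driver is the phase
#'   target rescaled by `(1 - true_A) / true_B`, so the fixed point of the
#'   recursion `m_{t+1} = A m_t + B driver_t` is the phase target itself.
#' @param a_j Log-variance transition coefficient (one value, all groups).
#' @param sigma_u2 Variance of the log-variance disturbance.
#' @param sigma_0_2 Initial perturbation variance.
#' @param participant_offset_sd SD (degrees) of per-participant asymptote
#'   offsets (constant across phases; removable by [baseline_adjust()]).
#' @param retention_jitter_sd SD of per-participant retention-factor jitter in
#'   `"individual"` dynamics. Each participant's learning rate is rescaled so
#'   their asymptote is unchanged, so the jitter varies adaptation speed, not
#'   the adapted level: the cross-sectional spread widens transiently after
#'   the target jump and then restabilises. Ignored when `true_A >= 1` or
#'   `true_B = 0`.
#' @param dynamics `"individual"` (default) evolves each participant's angle by
#'   the state model `y_{i,t+1} = A_i y_{it} + B driver_t + e_{i,t+1}`;
#'   `"shared"` evolves only the latent group mean and adds an independent
#'   perturbation plus a constant participant offset to every observation.
#' @param convention `"raw"` returns angles in degrees; `"baseline"` returns
#'   them baseline-adjusted (participant baseline-window mean subtracted).
#' @param group_labels Group names; defaults to Control/Punishment/Reward.
#' @param seed RNG seed; identical configurations (including seed) generate
#'   identical cohorts.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_groups = 3,
                         n_per_group = 11,
                         n_steps = 500,
                         baseline_mean = 60,
                         adaptation_increment = 30,
                         jump_step = 251,
                         true_A = c(0.96, 0.95, 0.88),
                         true_B = c(0.04, 0.05, 0.12),
                         a_j = 1,
                         sigma_u2 = 0.01,
                         sigma_0_2 = 1,
                         participant_offset_sd = 3,
                         retention_jitter_sd = 0.01,
                         dynamics = c("individual", "shared"),
                         convention = c("raw", "baseline"),
                         group_labels = NULL,
                         seed = NULL) {
  n_groups <- check_count(n_groups, "n_groups", lower = 1)
  n_per_group <- check_count(n_per_group, "n_per_group", lower = 2)
  n_steps <- check_count(n_steps, "n_steps", lower = 3)
  jump_step <- check_count(jump_step, "jump_step", lower = 2)
  if (jump_step >= n_steps) abort("`jump_step` must satisfy 1 < jump_step < n_steps.")
  check_number(sigma_u2, "sigma_u2", lower = 0)
  check_number(sigma_0_2, "sigma_0_2", lower = 0, allow_equal_lower = FALSE)
  check_number(participant_offset_sd, "participant_offset_sd", lower = 0)
  check_number(retention_jitter_sd, "retention_jitter_sd", lower = 0)
  check_number(baseline_mean, "baseline_mean")
  check_number(adaptation_increment, "adaptation_increment")
  check_number(a_j, "a_j")
  true_A <- rep_len(as.numeric(true_A), n_groups)
  true_B <- rep_len(as.numeric(true_B), n_groups)
  if (any(true_A <= 0 | true_A >= 1.5)) abort("`true_A` must lie in (0, 1.5).")
  if (any(true_B < 0)) abort("`true_B` must be >= 0.")
  dynamics <- match.arg(dynamics)
  convention <- match.arg(convention)
  if (is.null(group_labels)) {
    group_labels <- if (n_groups == 3) {
      c("Control", "Punishment", "Reward")
    } else {
      paste0("Group", seq_len(n_groups))
    }
  }
  if (length(group_labels) != n_groups) {
    abort("`group_labels` must have one label per group.")
  }
  structure(
    list(
      n_groups = n_groups, n_per_group = n_per_group, n_steps = n_steps,
      baseline_mean = baseline_mean,
      adaptation_increment = adaptation_increment, jump_step = jump_step,
      true_A = true_A, true_B = true_B, a_j = a_j, sigma_u2 = sigma_u2,
      sigma_0_2 = sigma_0_2, participant_offset_sd = participant_offset_sd,
      retention_jitter_sd = retention_jitter_sd,
      dynamics = dynamics, convention = convention,
      group_labels = as.character(group_labels), seed = seed
    ),
    class = "synth_config"
  )
}

#' Simulate a stochastic log-variance path
#'
#' The perturbation variance follows `log(s2_t) = a_j * log(s2_{t-1}) + u_t`
#' with `u_t ~ Normal(0, sigma_u2)`, started at `s2_0 = sigma_0_2`.
#'
#' @param a_j Transition coefficient.
#' @param sigma_u2 Disturbance variance (>= 0).
#' @param sigma_0_2 Initial variance (> 0).
#' @param n_steps Number of transitions `T`.
#' @param seed Optional RNG seed.
#' @return Numeric vector of length `n_steps + 1`: the variances at
#'   t = 0, 1, ..., T. All entries are strictly positive.
#' @examples
#' generate_variance_path(1, 0, 1, 5) # all ones
#' @export
generate_variance_path <- function(a_j, sigma_u2, sigma_0_2, n_steps,
                                   seed = NULL) {
  check_number(a_j, "a_j")
  check_number(sigma_u2, "sigma_u2", lower = 0)
  check_number(sigma_0_2, "sigma_0_2", lower = 0, allow_equal_lower = FALSE)
  n_steps <- check_count(n_steps, "n_steps", lower = 1)
  with_seed_if(seed, {
    log_s2 <- numeric(n_steps + 1)
    log_s2[1] <- log(sigma_0_2)
    u <- if (sigma_u2 > 0) rnorm(n_steps, 0, sqrt(sigma_u2)) else numeric(n_steps)
    for (t in seq_len(n_steps)) {
      log_s2[t + 1] <- a_j * log_s2[t] + u[t]
    }
    exp(log_s2)
  })
}

phase_target <- function(config) {
  ifelse(seq_len(config$n_steps) >= config$jump_step,
         config$baseline_mean + config$adaptation_increment,
         config$baseline_mean)
}

#' Generate a synthetic adaptation cohort
#'
#' Simulates stride-by-stride angle series for `n_groups` feedback groups with
#' known ground truth. The latent group mean follows the first-order recursion
#' `m_{t+1} = A_j m_t + B_j d_t`, where the driver `d_t` is the phase target
#' rescaled so the recursion's fixed point equals the target; the perturbation
#' variance follows the stochastic log-variance transition of
#' [generate_variance_path()].
#'
#' With `dynamics = "individual"` (default) each participant's angle itself
#' obeys the state model,
#' `y_{i,t+1} = A_i y_{it} + B_i d_t + (1 - A_i) o_i + e_{i,t+1}`:
#' `o_i ~ N(0, participant_offset_sd^2)` shifts the participant's asymptote by
#' a constant (visible as persistent scatter in raw angles, removed exactly by
#' baseline adjustment), and `A_i = A_j + jitter` with the learning rate
#' rescaled (`B_i = B_j (1 - A_i)/(1 - A_j)`) varies adaptation speed without
#' moving the asymptote. Successive perturbations of one participant are then
#' serially dependent, and the cross-sectional spread bumps up after the
#' target jump before restabilising. With `dynamics = "shared"` observations
#' are the latent mean plus a constant participant offset plus independent
#' noise, so perturbations are independent across steps.
#'
#' @param config A [synth_config()].
#' @return A trial table (see [as_gait_trials()]) with attributes `truth`
#'   (tibble: `group`, `step`, `m` latent mean, `sigma2` perturbation variance,
#'   `target`, `driver`), `truth_participants` (per-participant offsets and
#'   retention factors) and `config`.
#' @examples
#' trials <- generate_cohort(synth_config(n_per_group = 3, n_steps = 60,
#'                                        jump_step = 31, seed = 1))
#' head(attr(trials, "truth"))
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synth_config")) {
    abort("`config` must be created by synth_config().")
  }
  n_steps <- config$n_steps
  target <- phase_target(config)
  with_seed_if(config$seed, {
    per_group <- lapply(seq_len(config$n_groups), function(j) {
      A <- config$true_A[j]
      B <- config$true_B[j]
      n <- config$n_per_group
      driver <- if (B > 0) (1 - A) / B * target else rep(0, n_steps)
      s2 <- generate_variance_path(config$a_j, config$sigma_u2,
                                   config$sigma_0_2, n_steps)[-1]
      m <- numeric(n_steps)
      m[1] <- config$baseline_mean
      for (t in seq_len(n_steps - 1)) m[t + 1] <- A * m[t] + B * driver[t]
      offsets <- if (config$participant_offset_sd > 0) {
        rnorm(n, 0, config$participant_offset_sd)
      } else {
        rep(0, n)
      }
      eps <- matrix(rnorm(n * n_steps), nrow = n_steps, ncol = n)
      eps <- eps * sqrt(s2) # recycle by row: scales each step's noise
      jitter_ok <- config$dynamics == "individual" && A < 1 && B > 0 &&
        config$retention_jitter_sd > 0
      A_i <- if (jitter_ok) {
        pmin(pmax(A + rnorm(n, 0, config$retention_jitter_sd), 0.01), 0.999)
      } else {
        rep(A, n)
      }
      B_i <- if (jitter_ok) B * (1 - A_i) / (1 - A) else rep(B, n)
      if (config$dynamics == "individual") {
        k_i <- (1 - A_i) * offsets # constant shifting the asymptote by o_i
        y <- matrix(0, nrow = n_steps, ncol = n)
        y[1, ] <- config$baseline_mean + offsets + eps[1, ]
        for (t in seq_len(n_steps - 1)) {
          y[t + 1, ] <- A_i * y[t, ] + B_i * driver[t] + k_i + eps[t + 1, ]
        }
      } else {
        y <- matrix(m, nrow = n_steps, ncol = n) +
          matrix(offsets, nrow = n_steps, ncol = n, byrow = TRUE) + eps
      }
      ids <- sprintf("%s_%02d", config$group_labels[j], seq_len(n))
      list(
        long = tibble::tibble(
          group = config$group_labels[j],
          participant = rep(ids, each = n_steps),
          step = rep(seq_len(n_steps), times = n),
          angle = as.vector(y)
        ),
        truth = tibble::tibble(
          group = config$group_labels[j], step = seq_len(n_steps),
          m = m, sigma2 = s2, target = target, driver = driver
        ),
        participants = tibble::tibble(
          group = config$group_labels[j], participant = ids,
          offset = offsets, A_i = A_i, B_i = B_i
        )
      )
    })
    trials <- as_gait_trials(
      dplyr::bind_rows(lapply(per_group, `[[`, "long")),
      truth = dplyr::bind_rows(lapply(per_group, `[[`, "truth")),
      config = config
    )
    attr(trials, "truth_participants") <-
      dplyr::bind_rows(lapply(per_group, `[[`, "participants"))
    if (config$convention == "baseline") {
      baseline_window <- seq_len(config$jump_step - 1)
      trials <- baseline_adjust(trials, baseline_window)
      # shift the ground truth to the adjusted scale: each group's latent mean
      # loses its baseline-window average, and the driver loses the matching
      # constant so the recursion still holds on adjusted angles
      truth <- attr(trials, "truth")
      truth <- dplyr::mutate(
        dplyr::group_by(truth, .data$group),
        m_shift = mean(.data$m[.data$step %in% baseline_window]),
        m = .data$m - .data$m_shift,
        target = .data$target - .data$m_shift
      )
      truth <- dplyr::ungroup(truth)
      shift_d <- rep((1 - config$true_A) / ifelse(config$true_B > 0,
                                                  config$true_B, 1),
                     each = config$n_steps)
      truth$driver <- truth$driver - truth$m_shift * shift_d
      truth$m_shift <- NULL
      attr(trials, "truth") <- truth
    }
    trials
  })
}

#' Generate a cohort from a known smooth mean function
#'
#' Simulates data directly from the functional-data model: the latent group
#' mean at each step is a known smooth curve plus a Normal discrepancy with
#' variance `sigma_d2`, and each participant observes it with independent
#' Normal error of variance `sigma_e2`. Used to check calibration of the
#' P-spline posterior against a truth the spline can represent.
#'
#' @param f_true Numeric matrix (`n_steps` x `n_groups`) of true mean-function
#'   values, or a vector recycled to one group.
#' @param n_per_group Participants per group.
#' @param sigma_d2 Discrepancy variance between mean function and latent mean.
#' @param sigma_e2 Observation error variance.
#' @param group_labels Optional group names.
#' @param seed Optional RNG seed.
#' @return A trial table with attribute `truth` (tibble: `group`, `step`, `f`
#'   true curve, `m` latent mean realisation).
#' @export
generate_smooth_cohort <- function(f_true, n_per_group, sigma_d2 = 0.25,
                                   sigma_e2 = 1, group_labels = NULL,
                                   seed = NULL) {
  f_true <- as.matrix(f_true)
  n_steps <- nrow(f_true)
  n_groups <- ncol(f_true)
  n_per_group <- check_count(n_per_group, "n_per_group", lower = 1)
  check_number(sigma_d2, "sigma_d2", lower = 0)
  check_number(sigma_e2, "sigma_e2", lower = 0, allow_equal_lower = FALSE)
  if (is.null(group_labels)) group_labels <- paste0("Group", seq_len(n_groups))
  with_seed_if(seed, {
    parts <- lapply(seq_len(n_groups), function(j) {
      m <- f_true[, j] + rnorm(n_steps, 0, sqrt(sigma_d2))
      y <- matrix(m, n_steps, n_per_group) +
        matrix(rnorm(n_steps * n_per_group, 0, sqrt(sigma_e2)), n_steps)
      ids <- sprintf("%s_%02d", group_labels[j], seq_len(n_per_group))
      list(
        long = tibble::tibble(
          group = group_labels[j],
          participant = rep(ids, each = n_steps),
          step = rep(seq_len(n_steps), times = n_per_group),
          angle = as.vector(y)
        ),
        truth = tibble::tibble(group = group_labels[j], step = seq_len(n_steps),
                               f = f_true[, j], m = m)
      )
    })
    as_gait_trials(dplyr::bind_rows(lapply(parts, `[[`, "long")),
                   truth = dplyr::bind_rows(lapply(parts, `[[`, "truth")))
  })
}
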