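#' Cubic P-spline model specification
#'
#' Defines the truncated-power cubic spline basis and penalty used by the
#' functional track. The basis row at time `t` is
#' `[1, t, t^2, t^3, (t - mu_1)+^3, ..., (t - mu_K)+^3]`; the penalty is a
#' diagonal matrix with zeros on the four polynomial coefficients and ones on
#' the `K` knot coefficients, so smoothing shrinks the knot terms but never the
#' global cubic. By default `K = 19` knots are spaced evenly over the step
#' range (25, 50, ..., 475 for 500 steps).
#'
#' @param n_steps Number of steps the model will be applied to.
#' @param n_knots Number of interior knots `K`.
#' @param knots Optional explicit knot positions (overrides `n_knots`).
#' @param penalty Optional explicit penalty diagonal of length `K + 4`.
#' @param A_t,B_t Gamma hyperparameters of the scaled smoothing parameter.
#' @param A_d,B_d Inverse-Gamma hyperparameters of the discrepancy variances.
#' @param A_e,B_e Inverse-Gamma hyperparameters of the observation variance.
#' @return A list of class `spline_model`.
#' @export
spline_model <- function(n_steps = 500, n_knots = 19, knots = NULL,
                         penalty = NULL,
                         A_t = 0.01, B_t = 0.01, A_d = 0.01, B_d = 0.01,
                         A_e = 0.01, B_e = 0.01) {
  n_steps <- check_count(n_steps, "n_steps", lower = 5)
  if (is.null(knots)) {
    n_knots <- check_count(n_knots, "n_knots", lower = 1)
    knots <- seq_len(n_knots) * n_steps / (n_knots + 1)
  }
  knots <- as.numeric(knots)
  if (any(duplicated(knots))) abort("Knots must be distinct.")
  if (is.unsorted(knots)) knots <- sort(knots)
  if (knots[1] <= 0 || knots[length(knots)] >= n_steps) {
    abort("Knots must lie strictly inside (0, n_steps).")
  }
  K <- length(knots)
  if (is.null(penalty)) penalty <- c(rep(0, 4), rep(1, K))
  if (length(penalty) != K + 4 || any(penalty < 0)) {
    abort("`penalty` must be a nonnegative diagonal of length K + 4.")
  }
  for (nm in c("A_t", "B_t", "A_d", "B_d", "A_e", "B_e")) {
    check_number(get(nm), nm, lower = 0, allow_equal_lower = FALSE)
  }
  structure(list(n_steps = n_steps, knots = knots, penalty = penalty,
                 A_t = A_t, B_t = B_t, A_d = A_d, B_d = B_d,
                 A_e = A_e, B_e = B_e),
            class = "spline_model")
}

#' Truncated-power cubic basis matrix
#'
#' @param times Numeric vector of evaluation times.
#' @param knots Strictly increasing knot positions.
#' @return A `length(times)` by `length(knots) + 4` matrix with columns
#'   `1, t, t^2, t^3, (t - mu_k)+^3`.
#' @examples
#' build_basis(1:10, knots = c(3, 7))[1:3, ]
#' @export
build_basis <- function(times, knots) {
  if (any(duplicated(knots))) abort("Knots must be distinct.")
  knots <- sort(as.numeric(knots))
  X <- cbind(1, times, times^2, times^3)
  trunc_cols <- vapply(knots, function(mu) pmax(times - mu, 0)^3,
                       numeric(length(times)))
  X <- cbind(X, trunc_cols)
  colnames(X) <- c("c0", "c1", "c2", "c3", paste0("k", seq_along(knots)))
  X
}

# One full Gibbs sweep over the five conditional blocks. `state` and the
# returned value are lists with elements beta (p x G), m (T x G), alpha_star
# (G), sigma_d2 (G), sigma_e2 (scalar). `data` carries X, XtX, the penalty
# diagonal and its rank, per-group sizes n_j, per-group data sums Ysum (T x G)
# and total squares Ysq (G).
fda_gibbs_sweep <- function(state, data, model) {
  G <- length(data$n_j)
  T_len <- nrow(data$X)
  p <- ncol(data$X)
  for (j in seq_len(G)) {
    # beta_j | m_j, alpha*_j, sigma_jd2. The truncated-power basis is badly
    # conditioned at T = 500, so the Normal draw is taken in a
    # column-equilibrated parameterisation through a stacked QR factor of
    # rbind(X, sqrt(alpha) D^1/2): R^T R equals the conditional precision
    # without ever forming the squared matrix.
    alpha_j <- state$alpha_star[j] * state$sigma_d2[j]
    Mstack <- rbind(data$Xs,
                    diag(sqrt(alpha_j) * data$pen_half_scaled, p))
    R <- qr.R(qr(Mstack))
    gamma_mean <- backsolve(R, forwardsolve(t(R),
                                            crossprod(data$Xs, state$m[, j])))
    gamma <- gamma_mean + sqrt(state$sigma_d2[j]) * backsolve(R, rnorm(p))
    state$beta[, j] <- gamma / data$col_scale
    fit_j <- as.vector(data$Xs %*% gamma)
    # alpha*_j | beta_j
    state$alpha_star[j] <- rgamma(
      1, shape = model$A_t + data$rank_penalty / 2,
      rate = model$B_t + 0.5 * sum(data$penalty * state$beta[, j]^2)
    )
    # m_j | beta_j, y, sigma_jd2, sigma_e2
    prec_m <- data$n_j[j] / state$sigma_e2 + 1 / state$sigma_d2[j]
    mean_m <- (data$Ysum[, j] / state$sigma_e2 + fit_j / state$sigma_d2[j]) / prec_m
    state$m[, j] <- mean_m + rnorm(T_len) / sqrt(prec_m)
    # sigma_jd2 | m_j, beta_j
    state$sigma_d2[j] <- 1 / rgamma(
      1, shape = model$A_d + T_len / 2,
      rate = model$B_d + 0.5 * sum((state$m[, j] - fit_j)^2)
    )
  }
  # sigma_e2 | m, y (all groups)
  ss <- 0
  for (j in seq_len(G)) {
    ss <- ss + data$Ysq[j] - 2 * sum(state$m[, j] * data$Ysum[, j]) +
      data$n_j[j] * sum(state$m[, j]^2)
  }
  state$sigma_e2 <- 1 / rgamma(
    1, shape = model$A_e + T_len * sum(data$n_j) / 2,
    rate = model$B_e + 0.5 * ss
  )
  state
}

fda_data <- function(trials, model) {
  y <- angle_matrix(trials)
  grp <- attr(y, "group")
  groups <- unique(grp)
  T_len <- nrow(y)
  X <- build_basis(seq_len(T_len), model$knots)
  if (T_len < ncol(X)) abort("Need at least K + 4 steps to fit the spline.")
  col_scale <- sqrt(colSums(X^2))
  list(
    X = X, Xs = sweep(X, 2, col_scale, `/`), col_scale = col_scale,
    penalty = model$penalty,
    pen_half_scaled = sqrt(model$penalty) / col_scale,
    rank_penalty = sum(model$penalty > 0),
    groups = groups,
    n_j = vapply(groups, function(g) sum(grp == g), numeric(1)),
    Ysum = vapply(groups, function(g) rowSums(y[, grp == g, drop = FALSE]),
                  numeric(T_len)),
    Ysq = vapply(groups, function(g) sum(y[, grp == g, drop = FALSE]^2),
                 numeric(1)),
    steps = as.integer(rownames(y))
  )
}

#' Gibbs sampler for the Bayesian P-spline functional model
#'
#' Fits, per group, the hierarchical model `y_ijt = m_jt + e_ijt`,
#' `m_jt = f_j(t) + d_jt` with `f_j` a penalized truncated-power cubic spline,
#' by cycling the five conjugate full conditionals: spline coefficients
#' `beta_j`, scaled smoothing parameter `alpha*_j`, latent means `m_j`,
#' discrepancy variances `sigma_jd^2`, and the common observation variance
#' `sigma_e^2`.
#'
#' @param trials A trial table.
#' @param model A [spline_model()]; its `n_steps` must match the data.
#' @param S Retained posterior draws.
#' @param burn_in Discarded warm-up sweeps.
#' @param seed Optional RNG seed (identical seeds give identical posteriors).
#' @return An object of class `spline_posterior` holding the draw arrays
#'   (`beta`: S x (K+4) x G, `m`: S x T x G, `alpha_star`, `sigma_d2`:
#'   S x G, `sigma_e2`: S), the basis matrix and group/step labels.
#' @examples
#' trials <- generate_cohort(synth_config(n_per_group = 3, n_steps = 60,
#'                                        jump_step = 31, seed = 1))
#' post <- gibbs_fda(trials, spline_model(n_steps = 60, n_knots = 4),
#'                   S = 50, burn_in = 50, seed = 2)
#' dim(post$beta)
#' @export
gibbs_fda <- function(trials, model = spline_model(), S = 1000,
                      burn_in = 1000, seed = NULL) {
  trials <- as_gait_trials(trials)
  S <- check_count(S, "S", lower = 1)
  burn_in <- check_count(burn_in, "burn_in", lower = 0)
  data <- fda_data(trials, model)
  G <- length(data$groups)
  p <- ncol(data$X)
  T_len <- nrow(data$X)
  with_seed_if(seed, {
    y_bar <- sweep(data$Ysum, 2, data$n_j, `/`)
    state <- list(
      beta = matrix(0, p, G), m = y_bar,
      alpha_star = rep(1, G), sigma_d2 = rep(1, G), sigma_e2 = 1
    )
    for (j in seq_len(G)) {
      R0 <- qr.R(qr(rbind(data$Xs, diag(data$pen_half_scaled, p))))
      state$beta[, j] <- backsolve(R0, forwardsolve(
        t(R0), crossprod(data$Xs, y_bar[, j])
      )) / data$col_scale
    }
    beta_s <- array(NA_real_, c(S, p, G))
    m_s <- array(NA_real_, c(S, T_len, G))
    alpha_s <- matrix(NA_real_, S, G)
    sd2_s <- matrix(NA_real_, S, G)
    se2_s <- numeric(S)
    for (it in seq_len(burn_in + S)) {
      state <- fda_gibbs_sweep(state, data, model)
      if (it > burn_in) {
        s <- it - burn_in
        beta_s[s, , ] <- state$beta
        m_s[s, , ] <- state$m
        alpha_s[s, ] <- state$alpha_star
        sd2_s[s, ] <- state$sigma_d2
        se2_s[s] <- state$sigma_e2
      }
    }
    structure(
      list(beta = beta_s, m = m_s, alpha_star = alpha_s, sigma_d2 = sd2_s,
           sigma_e2 = se2_s, model = model, X = data$X, groups = data$groups,
           steps = data$steps, y_bar = y_bar, n_j = data$n_j,
           S = S, burn_in = burn_in, seed = seed),
      class = "spline_posterior"
    )
  })
}

#' @export
print.spline_posterior <- function(x, ...) {
  cat(sprintf(
    "P-spline posterior: %d draws (%d burn-in), %d groups, %d steps, %d basis columns\n",
    x$S, x$burn_in, length(x$groups), length(x$steps), ncol(x$X)
  ))
  invisible(x)
}

#' Per-draw fitted curves and first-difference derivatives
#'
#' Evaluates every posterior draw of the mean function, `f^(s) = X beta^(s)`,
#' and its derivative approximated by the unit-step first difference
#' `f'(t) = f(t+1) - f(t)` (degrees per step).
#'
#' @param posterior A `spline_posterior` from [gibbs_fda()].
#' @return A list of class `curve_samples` with arrays `f` (S x T x G) and
#'   `fprime` (S x (T-1) x G), plus `groups` and `steps`.
#' @export
curve_and_derivative_samples <- function(posterior) {
  if (!inherits(posterior, "spline_posterior")) {
    abort("`posterior` must come from gibbs_fda().")
  }
  S <- posterior$S
  G <- length(posterior$groups)
  T_len <- nrow(posterior$X)
  f <- array(NA_real_, c(S, T_len, G))
  for (j in seq_len(G)) {
    f[, , j] <- posterior$beta[, , j, drop = TRUE] %*% t(posterior$X)
  }
  if (S == 1) { # drop=TRUE collapses the draw dimension
    for (j in seq_len(G)) {
      f[1, , j] <- posterior$X %*% posterior$beta[1, , j]
    }
  }
  fprime <- f[, -1, , drop = FALSE] - f[, -T_len, , drop = FALSE]
  structure(list(f = f, fprime = fprime, groups = posterior$groups,
                 steps = posterior$steps),
            class = "curve_samples")
}

#' Time-varying retention and learning-rate functions
#'
#' Converts posterior curve draws into the time-varying retention factor
#' `A_j(t) = f_j'(t)` and learning rate
#' `B_j(t) = (ybar_{j,t+1} - f_j'(t)) / f_j(t)`, with pointwise 95% credible
#' bands taken as 2.5/97.5% quantiles of the same transforms applied to each
#' draw. Steps where the fitted curve's magnitude falls below `f_floor` have
#' their learning rate flagged unavailable (division guard) with a warning.
#'
#' @param curves A `curve_samples` object (or a `spline_posterior`, converted
#'   automatically).
#' @param y_bar Observed group means: tibble with `group`, `step`, `y_bar`
#'   (e.g. from [group_means()]). Taken from the posterior if omitted.
#' @param f_floor Minimum `|f|` for reporting the learning rate.
#' @return A tibble of class `tv_rates` with one row per group and step
#'   `t = 1..T-1`: fitted curve (`f`, `f_lo`, `f_hi`), retention function
#'   (`A`, `A_lo`, `A_hi`), learning-rate function (`B`, `B_lo`, `B_hi`) and
#'   the guard flag `B_ok`.
#' @export
rate_functions <- function(curves, y_bar = NULL, f_floor = 1e-6) {
  if (inherits(curves, "spline_posterior")) {
    if (is.null(y_bar)) {
      y_bar <- tibble::tibble(
        group = rep(curves$groups, each = length(curves$steps)),
        step = rep(curves$steps, times = length(curves$groups)),
        y_bar = as.vector(curves$y_bar)
      )
    }
    curves <- curve_and_derivative_samples(curves)
  }
  if (!inherits(curves, "curve_samples")) {
    abort("`curves` must be curve_samples or a spline_posterior.")
  }
  if (is.null(y_bar)) abort("`y_bar` is required when passing curve_samples.")
  G <- length(curves$groups)
  T_len <- dim(curves$f)[2]
  steps <- curves$steps
  out <- vector("list", G)
  guard_hits <- 0L
  for (j in seq_len(G)) {
    yb <- y_bar$y_bar[match(
      paste(curves$groups[j], steps), paste(y_bar$group, y_bar$step)
    )]
    if (anyNA(yb)) abort("`y_bar` must cover every (group, step).")
    f_j <- curves$f[, , j, drop = FALSE]; dim(f_j) <- dim(curves$f)[1:2]
    fp_j <- curves$fprime[, , j, drop = FALSE]
    dim(fp_j) <- c(dim(curves$fprime)[1], T_len - 1)
    f_hat <- colMeans(f_j)
    fp_hat <- colMeans(fp_j)
    y_next <- yb[-1]
    # per-draw learning-rate transform
    B_draw <- sweep(-fp_j, 2, y_next, `+`) / f_j[, -T_len, drop = FALSE]
    f_q <- apply(f_j[, -T_len, drop = FALSE], 2, quantile,
                 probs = c(0.025, 0.975), names = FALSE)
    A_q <- apply(fp_j, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
    B_q <- apply(B_draw, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
    B_ok <- abs(f_hat[-T_len]) >= f_floor
    guard_hits <- guard_hits + sum(!B_ok)
    B_hat <- ifelse(B_ok, (y_next - fp_hat) / f_hat[-T_len], NA_real_)
    out[[j]] <- tibble::tibble(
      group = curves$groups[j], step = steps[-T_len],
      f = f_hat[-T_len], f_lo = f_q[1, ], f_hi = f_q[2, ],
      A = fp_hat, A_lo = A_q[1, ], A_hi = A_q[2, ],
      B = B_hat,
      B_lo = ifelse(B_ok, B_q[1, ], NA_real_),
      B_hi = ifelse(B_ok, B_q[2, ], NA_real_),
      B_ok = B_ok
    )
  }
  if (guard_hits > 0) {
    warn(sprintf(
      "Learning rate unavailable at %d step(s): |fitted curve| below the %g floor (baseline-adjusted data near zero will do this).",
      guard_hits, f_floor
    ))
  }
  res <- dplyr::bind_rows(out)
  class(res) <- unique(c("tv_rates", class(res)))
  res
}

#' Pointwise credible-band overlap between groups
#'
#' Flags, for every step, group pair and parameter, whether the two 95%
#' credible intervals are strictly disjoint — the package's analogue of
#' reading group differences off overlaid bands.
#'
#' @param rates A `tv_rates` tibble covering two or more groups on the same
#'   step grid.
#' @param parameters Which rate functions to compare.
#' @return A tibble with `parameter`, `group1`, `group2`, `step`, `disjoint`;
#'   attribute `runs` summarises contiguous disjoint step runs.
#' @export
band_overlap <- function(rates, parameters = c("A", "B")) {
  rates <- tibble::as_tibble(rates)
  groups <- unique(rates$group)
  if (length(groups) < 2) abort("Need at least two groups to compare.")
  grids <- split(rates$step, rates$group)
  if (length(unique(vapply(grids, paste, character(1), collapse = ","))) != 1) {
    abort("All groups must share the same step grid.")
  }
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pr) {
    a <- dplyr::arrange(dplyr::filter(rates, .data$group == pr[1]), .data$step)
    b <- dplyr::arrange(dplyr::filter(rates, .data$group == pr[2]), .data$step)
    purrr::map_dfr(parameters, function(p) {
      lo_a <- a[[paste0(p, "_lo")]]; hi_a <- a[[paste0(p, "_hi")]]
      lo_b <- b[[paste0(p, "_lo")]]; hi_b <- b[[paste0(p, "_hi")]]
      disjoint <- (hi_a < lo_b) | (hi_b < lo_a)
      disjoint[is.na(disjoint)] <- FALSE
      tibble::tibble(parameter = p, group1 = pr[1], group2 = pr[2],
                     step = a$step, disjoint = disjoint)
    })
  })
  runs <- dplyr::summarise(
    dplyr::group_by(res, .data$parameter, .data$group1, .data$group2),
    n_disjoint = sum(.data$disjoint),
    longest_run = {
      r <- rle(.data$disjoint)
      if (any(r$values)) max(r$lengths[r$values]) else 0L
    },
    .groups = "drop"
  )
  attr(res, "runs") <- runs
  res
}
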