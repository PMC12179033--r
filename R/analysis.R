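# Diagnostics and analytic predictions: population summaries, threshold
# conflict strengths for the survival of cooperation, steady-state success
# against the all-cooperator group, Hoelder tail-exponent estimation, and
# steady-state residuals.

#' Mean level of cooperation
#'
#' `Int x f(x) dx`, by midpoint quadrature over cell centres.
#'
#' @param f A `density_state`.
#' @return A number in `[0, 1]`.
#' @export
mean_cooperation <- function(f) {
  stopifnot(inherits(f, "density_state"))
  sum(f$grid$centers * f$f) * f$grid$dx
}

#' Average success against the all-cooperator group
#'
#' `Int rho(y, 1) f(y) dy`: the mean probability that a group drawn from
#' the population defeats an all-cooperator group in a pairwise conflict.
#'
#' @param f A `density_state`.
#' @param k A `victory_kernel`.
#' @return A number in `[0, 1]`.
#' @export
success_vs_all_cooperators <- function(f, k) {
  stopifnot(inherits(f, "density_state"))
  xs <- f$grid$centers
  sum(rho_victory(k, xs, rep(1, length(xs))) * f$f) * f$grid$dx
}

#' Predicted steady-state success against the all-cooperator group
#'
#' For a steady-state density with Hoelder exponent `theta` near `x = 1`,
#' the average victory probability against the all-cooperator group must be
#' `1/2 - theta * pi(1) / (2 lambda)`; it approaches the fifty-fifty limit
#' as `lambda` grows (the shadow of lower-level selection).
#'
#' @param lambda Positive conflict strength.
#' @param pi1 Defector advantage `pi(1)` in the all-cooperator group.
#' @param theta Hoelder exponent of the steady state near `x = 1`
#'   (default 1, a density bounded away from 0 at `x = 1`).
#' @return The predicted success probability.
#' @export
steady_success_prediction <- function(lambda, pi1, theta = 1) {
  if (any(lambda <= 0)) stop("lambda must be positive", call. = FALSE)
  0.5 - theta * pi1 / (2 * lambda)
}

#' Threshold conflict strength for cooperation, PD scenario
#'
#' `lambda*_PD(theta) = theta * pi(1) / (rho(1, 0) - rho(0, 1))`: the
#' conjectured minimal relative strength of between-group conflict for a
#' steady state with Hoelder exponent `theta` near `x = 1` to outperform
#' the all-defector population.
#'
#' @param theta Hoelder exponent (linear factor).
#' @param pi1 Defector advantage `pi(1)`.
#' @param k A `victory_kernel` with `rho(1, 0) > rho(0, 1)`.
#' @return The threshold strength.
#' @export
lambda_star_pd <- function(theta, pi1, k) {
  denom <- rho_victory(k, 1, 0) - rho_victory(k, 0, 1)
  if (denom <= 0) {
    stop("lambda_star_pd requires rho(1, 0) > rho(0, 1)", call. = FALSE)
  }
  theta * pi1 / denom
}

#' Threshold conflict strength for extra cooperation, HD scenario
#'
#' `lambda*_HD(theta) = theta * pi(1) / (rho(1, x_eq) - rho(x_eq, 1))`:
#' above this strength a steady state can support cooperation beyond the
#' within-group Hawk-Dove equilibrium `x_eq`.
#'
#' @inheritParams lambda_star_pd
#' @param x_eq Interior within-group equilibrium.
#' @return The threshold strength.
#' @export
lambda_star_hd <- function(theta, pi1, k, x_eq) {
  denom <- rho_victory(k, 1, x_eq) - rho_victory(k, x_eq, 1)
  if (denom <= 0) {
    stop("lambda_star_hd requires rho(1, x_eq) > rho(x_eq, 1)",
         call. = FALSE)
  }
  theta * pi1 / denom
}

#' Does the provable extinction bound hold?
#'
#' Defectors provably take over (weak convergence to a point mass at
#' `x = 0`) in the PD scenario when
#' `lambda * (2 ||rho||_inf - 1) < theta_bar * pi(1)`, where `theta_bar`
#' is the infimum Hoelder exponent of the initial measure near `x = 1`.
#' The sup norm of the kernel is estimated by maximisation on an
#' `n_grid` x `n_grid` lattice.
#'
#' @param lambda Conflict strength.
#' @param theta_bar Infimum Hoelder exponent of the initial measure.
#' @param pi1 Defector advantage `pi(1)` (must be positive: PD case).
#' @param k A `victory_kernel`.
#' @param n_grid Lattice size (default 201).
#' @return `TRUE` if the sufficient extinction condition holds.
#' @export
extinction_bound_holds <- function(lambda, theta_bar, pi1, k,
                                   n_grid = 201) {
  stopifnot(pi1 > 0)
  xs <- seq(0, 1, length.out = n_grid)
  rho_max <- max(kernel_matrix(k, xs))
  lambda * (2 * rho_max - 1) < theta_bar * pi1
}

#' Tail mass above a composition threshold
#'
#' `Int_z^1 f(x) dx`, with linear proration of the cell containing `z`.
#' For a `particle_measure` the atom weights at or above `z` are summed.
#'
#' @param f A `density_state` or `particle_measure`.
#' @param z Threshold in `[0, 1]`.
#' @return The tail mass.
#' @export
tail_mass_above <- function(f, z) {
  check_unit_interval(z, "z")
  if (inherits(f, "particle_measure")) {
    return(sum(f$weights[f$positions >= z]))
  }
  stopifnot(inherits(f, "density_state"))
  g <- f$grid
  if (z >= 1) return(0)
  i <- findInterval(z, g$edges, rightmost.closed = TRUE)
  i <- min(max(i, 1L), g$N)
  full <- if (i < g$N) sum(f$f[(i + 1):g$N]) * g$dx else 0
  full + f$f[i] * (g$edges[i + 1] - z)
}

#' Estimate the Hoelder tail exponent near the all-cooperator state
#'
#' Fits the power law `mu([1 - x, 1]) ~ C x^theta` by least squares on
#' log tail mass against log distance-from-1.
#'
#' For a `density_state` the tail mass is evaluated at `n_points`
#' geometrically spaced distances spanning `window` (default
#' `c(2 * dx, 0.2)`: below two cells the grid cannot resolve the tail,
#' and the power-law description is asymptotic near `x = 1`). For a
#' `particle_measure` each atom inside the window contributes the exact
#' point (distance of the atom, cumulative weight from the top), with a
#' self-consistent correction for the share of the atom's own mass lying
#' above its centroid (`(theta / (theta + 1))^theta`, iterated).
#'
#' @param mu A `density_state` or `particle_measure`.
#' @param window Numeric `c(lower, upper)` of distances from 1; the upper
#'   end must not exceed 0.5.
#' @param n_points Number of geometric evaluation points for densities
#'   (minimum 8).
#' @return A list of class `tail_estimate`: `theta_hat`, `window`,
#'   `n_points`, `r_squared`, and `reliable` (FALSE when the tail is
#'   empty or nearly so).
#' @export
tail_exponent_estimate <- function(mu, window = NULL, n_points = 12) {
  n_points <- max(8L, as.integer(n_points))
  if (inherits(mu, "density_state")) {
    if (is.null(window)) window <- c(2 * mu$grid$dx, 0.2)
    stopifnot(window[1] > 0, window[1] < window[2], window[2] <= 0.5)
    xs <- exp(seq(log(window[1]), log(window[2]), length.out = n_points))
    tm <- vapply(xs, function(u) tail_mass_above(mu, 1 - u), numeric(1))
    keep <- tm > 0
    if (sum(keep) < 3) {
      return(structure(list(theta_hat = 0, window = window,
                            n_points = sum(keep), r_squared = NA_real_,
                            reliable = FALSE), class = "tail_estimate"))
    }
    fit <- stats::lm(log(tm[keep]) ~ log(xs[keep]))
    return(structure(list(theta_hat = unname(stats::coef(fit)[2]),
                          window = window, n_points = sum(keep),
                          r_squared = suppressWarnings(summary(fit))$r.squared,
                          reliable = sum(keep) >= 8),
                     class = "tail_estimate"))
  }
  stopifnot(inherits(mu, "particle_measure"))
  d <- 1 - mu$positions
  o <- order(d)
  d <- d[o]
  w <- mu$weights[o]
  cum <- cumsum(w)
  if (is.null(window)) window <- c(max(min(d[d > 0]), 1e-12), 0.2)
  stopifnot(window[1] > 0, window[1] < window[2], window[2] <= 0.5)
  theta_hat <- 1
  sel <- d >= window[1] & d <= window[2] & cum > 0 & d > 0
  if (sum(sel) < 3) {
    return(structure(list(theta_hat = 0, window = window,
                          n_points = sum(sel), r_squared = NA_real_,
                          reliable = FALSE), class = "tail_estimate"))
  }
  fit <- NULL
  for (it in 1:4) {
    frac_above <- (theta_hat / (theta_hat + 1))^theta_hat
    tm <- cum - (1 - frac_above) * w
    keep <- sel & tm > 0
    fit <- stats::lm(log(tm[keep]) ~ log(d[keep]))
    theta_hat <- unname(stats::coef(fit)[2])
  }
  structure(list(theta_hat = theta_hat, window = window,
                 n_points = sum(sel), r_squared = suppressWarnings(summary(fit))$r.squared,
                 reliable = sum(sel) >= 8),
            class = "tail_estimate")
}

#' @export
print.tail_estimate <- function(x, ...) {
  cat(sprintf(paste0("tail exponent estimate: theta_hat = %.4f ",
                     "(window [%.4g, %.4g], %d points, R^2 = %.4f%s)\n"),
              x$theta_hat, x$window[1], x$window[2], x$n_points,
              x$r_squared, if (x$reliable) "" else ", UNRELIABLE"))
  invisible(x)
}

#' Conjectured long-time success against the all-cooperator group
#'
#' Piecewise in `lambda`: below the scenario threshold the population
#' collapses onto the within-group attractor (`rho(0, 1)` for PD,
#' `rho(x_eq, 1)` for HD); at or above it, the steady-state prediction
#' `1/2 - theta * pi(1) / (2 lambda)` applies. The two branches agree at
#' the threshold.
#'
#' @param lambda Conflict strength.
#' @param game A [payoff_matrix()] or [game_coefficients()].
#' @param k A `victory_kernel`.
#' @param theta Hoelder exponent of the initial measure (default 1).
#' @param scenario `"PD"` or `"HD"`.
#' @return The predicted long-time success probability.
#' @export
long_time_prediction <- function(lambda, game, k, theta = 1,
                                 scenario = c("PD", "HD")) {
  scenario <- match.arg(scenario)
  g <- as_game(game)
  pi1 <- pi_advantage(1, g$coef)
  if (scenario == "PD") {
    lstar <- lambda_star_pd(theta, pi1, k)
    floor_val <- rho_victory(k, 0, 1)
  } else {
    x_eq <- interior_equilibrium(g$coef)
    if (is.null(x_eq)) stop("HD scenario requires an interior equilibrium",
                            call. = FALSE)
    lstar <- lambda_star_hd(theta, pi1, k, x_eq)
    floor_val <- rho_victory(k, x_eq, 1)
  }
  ifelse(lambda < lstar, floor_val,
         steady_success_prediction(lambda, pi1, theta))
}

#' Discrete steady-state residual
#'
#' L1 norm of `d/dx [x (1 - x) pi(x) f] + lambda f (2 Int rho f - 1)`,
#' the right-hand side of the PDE, using centred differences of the flux
#' (edge flux from averaged neighbouring cells, zero at the boundary) and
#' the solver's midpoint quadrature for the nonlocal term. Zero for an
#' exact steady state; `O(dx)` for a converged finite-volume state.
#'
#' @param f A `density_state`.
#' @param game A [payoff_matrix()] or [game_coefficients()].
#' @param k A `victory_kernel`.
#' @param lambda Conflict strength.
#' @return The nonnegative residual.
#' @export
steady_state_residual <- function(f, game, k, lambda) {
  stopifnot(inherits(f, "density_state"))
  g <- as_game(game)
  grid <- f$grid
  v <- edge_velocities(grid, g$coef)
  N <- grid$N
  flux <- numeric(N + 1)
  flux[2:N] <- v[2:N] * (f$f[1:(N - 1)] + f$f[2:N]) / 2
  ddx <- (flux[2:(N + 1)] - flux[1:N]) / grid$dx
  K <- kernel_matrix(k, grid$centers)
  r <- reaction_rates(f, K, lambda)
  # PDE right-hand side: f_t = -d/dx (v f) + f r; residual is its L1 norm
  sum(abs(-ddx + f$f * r)) * grid$dx
}

#' Detect a steady state along a trajectory
#'
#' Finds the first snapshot time at which the per-unit-time L1 change
#' between consecutive snapshots drops below `tol`.
#'
#' @param traj An `mls_trajectory` with at least two snapshots.
#' @param tol Threshold on `||f(t2) - f(t1)||_L1 / (t2 - t1)`.
#' @return A list with `detected` (logical) and `time` (or `NULL`).
#' @export
detect_steady_state <- function(traj, tol) {
  stopifnot(inherits(traj, "mls_trajectory"), length(traj$states) >= 2)
  dx <- traj$config$grid$dx
  for (i in 2:length(traj$states)) {
    dtt <- traj$times[i] - traj$times[i - 1]
    change <- sum(abs(traj$states[[i]]$f - traj$states[[i - 1]]$f)) * dx / dtt
    if (change < tol) {
      return(list(detected = TRUE, time = traj$times[i]))
    }
  }
  list(detected = FALSE, time = NULL)
}

#' Analytic threshold report
#'
#' Bundles the kernel evaluations and threshold strengths relevant to the
#' PD and HD scenarios for a given game, kernel, and Hoelder exponent.
#'
#' @param game A [payoff_matrix()] or [game_coefficients()].
#' @param k A `victory_kernel`.
#' @param theta Hoelder exponent of the initial measure (default 1).
#' @return A list of class `threshold_report` with `pi1`, the kernel
#'   evaluations `rho_10`, `rho_01`, and (when an interior equilibrium
#'   exists) `rho_1xeq`, `rho_xeq1`, plus `lambda_star_pd`,
#'   `lambda_star_hd`, `x_eq`, and `theta`.
#' @export
threshold_report <- function(game, k, theta = 1) {
  g <- as_game(game)
  pi1 <- pi_advantage(1, g$coef)
  x_eq <- interior_equilibrium(g$coef)
  rep <- list(game = g$label, kernel = k$family, theta = theta,
              pi1 = pi1,
              rho_10 = rho_victory(k, 1, 0),
              rho_01 = rho_victory(k, 0, 1),
              x_eq = x_eq)
  rep$lambda_star_pd <- tryCatch(lambda_star_pd(theta, pi1, k),
                                 error = function(e) NA_real_)
  if (!is.null(x_eq)) {
    rep$rho_1xeq <- rho_victory(k, 1, x_eq)
    rep$rho_xeq1 <- rho_victory(k, x_eq, 1)
    rep$lambda_star_hd <- tryCatch(lambda_star_hd(theta, pi1, k, x_eq),
                                   error = function(e) NA_real_)
  }
  structure(rep, class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf("threshold report (%s game, %s kernel, theta = %g):\n",
              x$game, x$kernel, x$theta))
  cat(sprintf("  pi(1) = %g, rho(1,0) = %.4f, rho(0,1) = %.4f\n",
              x$pi1, x$rho_10, x$rho_01))
  cat(sprintf("  lambda*_PD = %.4f\n", x$lambda_star_pd))
  if (!is.null(x$x_eq)) {
    cat(sprintf("  x_eq = %.4f, rho(1,x_eq) = %.4f, lambda*_HD = %.4f\n",
                x$x_eq, x$rho_1xeq, x$lambda_star_hd))
  }
  invisible(x)
}
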