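# Measure-valued solver: the within-group replicator flow (the PDE's
# characteristics) moves particle positions, and Picard iteration on the
# implicit representation formula
#
#   mu_t[v] = Int v(phi_t(x)) exp( 2 lambda Int_0^t Int rho(phi_s(x), y)
#                                  mu_s(dy) ds - lambda t ) mu_0(dx)
#
# updates the particle weights. Because the characteristic flow does not
# depend on the measure, positions are propagated once and only the weight
# exponents are iterated to a fixed point.

#' Weighted-atom probability measure
#'
#' @param positions Atom positions in `[0, 1]`.
#' @param weights Nonnegative weights summing to 1 (tolerance `1e-6`).
#' @param time Time stamp.
#' @return An object of class `particle_measure`.
#' @export
particle_measure <- function(positions, weights, time = 0) {
  stopifnot(length(positions) == length(weights))
  check_unit_interval(positions, "positions")
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-6) {
    stop("weights must sum to 1", call. = FALSE)
  }
  structure(list(positions = positions, weights = weights, time = time),
            class = "particle_measure")
}

#' @export
print.particle_measure <- function(x, ...) {
  cat(sprintf("particle measure: %d atoms at t = %g (total weight %.6f)\n",
              length(x$positions), x$time, sum(x$weights)))
  invisible(x)
}

replicator_rhs <- function(x, c) x * (1 - x) * (c$beta + c$alpha * x)

#' Characteristic (within-group replicator) flow
#'
#' Solves `dx/dt = -x (1 - x) pi(x) = x (1 - x) (beta + alpha x)` from
#' `x0` over time `t` with an adaptive Cash-Karp Runge-Kutta integrator.
#' The endpoints 0 and 1 are exact fixed points; negative `t` gives the
#' backward flow (the inverse characteristics).
#'
#' @param x0 Initial composition(s) in `[0, 1]` (vectorised).
#' @param t Flow time (may be negative).
#' @param c A [game_coefficients()].
#' @param rtol,atol Relative and absolute local error tolerances.
#' @return The flowed composition(s), clipped to `[0, 1]`.
#' @export
characteristic_flow <- function(x0, t, c, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(c, "game_coefficients"), is.finite(t))
  check_unit_interval(x0, "x0")
  if (t == 0) return(x0)
  sgn <- sign(t)
  Tend <- abs(t)
  f <- function(x) sgn * replicator_rhs(x, c)
  # Cash-Karp RK4(5) coefficients
  a <- list(c2 = 1 / 5,
            c3 = c(3 / 40, 9 / 40),
            c4 = c(3 / 10, -9 / 10, 6 / 5),
            c5 = c(-11 / 54, 5 / 2, -70 / 27, 35 / 27),
            c6 = c(1631 / 55296, 175 / 512, 575 / 13824,
                   44275 / 110592, 253 / 4096))
  b5 <- c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771)
  b4 <- c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296,
          277 / 14336, 1 / 4)
  x <- x0
  tcur <- 0
  h <- min(Tend, 0.1)
  max_steps <- 100000L
  for (step in seq_len(max_steps)) {
    if (tcur >= Tend) break
    h <- min(h, Tend - tcur)
    k1 <- f(x)
    k2 <- f(x + h * a$c2 * k1)
    k3 <- f(x + h * (a$c3[1] * k1 + a$c3[2] * k2))
    k4 <- f(x + h * (a$c4[1] * k1 + a$c4[2] * k2 + a$c4[3] * k3))
    k5 <- f(x + h * (a$c5[1] * k1 + a$c5[2] * k2 + a$c5[3] * k3 +
                       a$c5[4] * k4))
    k6 <- f(x + h * (a$c6[1] * k1 + a$c6[2] * k2 + a$c6[3] * k3 +
                       a$c6[4] * k4 + a$c6[5] * k5))
    x5 <- x + h * (b5[1] * k1 + b5[3] * k3 + b5[4] * k4 + b5[6] * k6)
    x4 <- x + h * (b4[1] * k1 + b4[3] * k3 + b4[4] * k4 + b4[5] * k5 +
                     b4[6] * k6)
    err <- max(abs(x5 - x4) / (atol + rtol * pmax(abs(x), abs(x5))))
    if (err <= 1) {
      tcur <- tcur + h
      x <- x5
    }
    h <- h * min(5, max(0.2, 0.9 * (1 / max(err, 1e-16))^(1 / 5)))
    if (step == max_steps) stop("characteristic_flow: integrator failure",
                                call. = FALSE)
  }
  pmin(pmax(x, 0), 1)
}

# Fixed-step classical RK4 propagation of all particle positions over the
# Picard time mesh; returns the (n_steps + 1) x M matrix of positions.
flow_path <- function(x0, Tend, dt, c) {
  n <- round(Tend / dt)
  pos <- matrix(0, n + 1, length(x0))
  pos[1, ] <- x0
  x <- x0
  for (i in seq_len(n)) {
    k1 <- replicator_rhs(x, c)
    k2 <- replicator_rhs(x + dt / 2 * k1, c)
    k3 <- replicator_rhs(x + dt / 2 * k2, c)
    k4 <- replicator_rhs(x + dt * k3, c)
    x <- pmin(pmax(x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0), 1)
    pos[i + 1, ] <- x
  }
  pos
}

#' Particles quadrature of a density
#'
#' One particle per grid cell, located at the cell's mass centroid with
#' weight equal to the exact cell mass. For the theta-family and uniform
#' initial conditions the centroids and masses are computed in closed
#' form; for a `density_state` the cell average is used. Optionally the
#' top cell region near `x = 1` is subdivided geometrically
#' (`refine_tail`), which resolves the tail of the measure far below the
#' grid scale - needed for Hoelder-exponent diagnostics.
#'
#' @param spec An initial-condition spec (see [initial_density()]) or a
#'   `density_state`.
#' @param grid An [fv_grid()].
#' @param refine_tail Number of geometric subdivisions of the top cell
#'   region (0 = none). Subdivision edges descend to within `1e-7` of 1.
#' @return A `particle_measure` at time 0.
#' @export
particles_from_density <- function(spec, grid, refine_tail = 0) {
  stopifnot(inherits(grid, "fv_grid"))
  edges <- grid$edges
  if (refine_tail > 0) {
    sub <- 1 - grid$dx * exp(seq(0, log(1e-7 / grid$dx),
                                 length.out = refine_tail))
    edges <- sort(unique(c(edges, sub)))
  }
  n <- length(edges) - 1L
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  if (inherits(spec, "density_state")) {
    # piecewise-constant density: centroid = cell midpoint of each piece
    idx <- findInterval(pmin(lo, 1 - 1e-15), spec$grid$edges,
                        rightmost.closed = TRUE)
    w <- spec$f[idx] * (hi - lo)
    cx <- (lo + hi) / 2
  } else {
    if (is.character(spec)) spec <- list(kind = spec)
    th <- switch(spec$kind %||% "", uniform = 1, theta = spec$theta, NULL)
    if (is.null(th)) {
      f0 <- initial_density(spec, grid)
      return(particles_from_density(f0, grid, refine_tail = refine_tail))
    }
    tail0 <- function(x) (1 - x)^th                      # mass of [x, 1]
    m1 <- function(x) -x * (1 - x)^th - (1 - x)^(th + 1) / (th + 1)
    w <- tail0(lo) - tail0(hi)
    cx <- (m1(hi) - m1(lo)) / w
    zero <- !is.finite(cx) | w <= 0
    cx[zero] <- (lo + hi)[zero] / 2
    w[zero] <- pmax(w[zero], 0)
  }
  particle_measure(cx, w / sum(w))
}

#' Wasserstein-1 distance between measures on the unit interval
#'
#' Both arguments may be `particle_measure` or `density_state` objects
#' (densities are converted to atoms at their cell centres). The distance
#' is the L1 norm of the difference of cumulative distribution functions,
#' computed exactly on the merged breakpoint set.
#'
#' @param mu,nu Normalised measures.
#' @return A nonnegative number.
#' @export
measure_distance <- function(mu, nu) {
  as_atoms <- function(m) {
    if (inherits(m, "density_state")) {
      list(p = m$grid$centers, w = m$f * m$grid$dx)
    } else if (inherits(m, "particle_measure")) {
      list(p = m$positions, w = m$weights)
    } else stop("measure_distance needs density_state or particle_measure",
                call. = FALSE)
  }
  a <- as_atoms(mu)
  b <- as_atoms(nu)
  for (m in list(a, b)) {
    if (abs(sum(m$w) - 1) > 1e-3) {
      stop("measure_distance: input measure is not normalised",
           call. = FALSE)
    }
  }
  p <- c(a$p, b$p)
  w <- c(a$w, -b$w)
  o <- order(p)
  p <- p[o]
  cdf_diff <- cumsum(w[o])
  n <- length(p)
  if (n < 2) return(0)
  sum(abs(cdf_diff[-n]) * diff(p))
}

#' Bin a particle measure onto a finite-volume grid
#'
#' Weights are accumulated per cell (half-open cells, the final cell
#' closed at 1) and divided by `dx`; total mass is preserved exactly.
#'
#' @param mu A `particle_measure`.
#' @param grid An [fv_grid()].
#' @return A `density_state`.
#' @export
to_density <- function(mu, grid) {
  stopifnot(inherits(mu, "particle_measure"), inherits(grid, "fv_grid"))
  idx <- findInterval(mu$positions, grid$edges, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx > grid$N] <- grid$N
  w <- vapply(seq_len(grid$N),
              function(i) sum(mu$weights[idx == i]), numeric(1))
  density_state(w / grid$dx, grid, time = mu$time)
}

#' Picard solver for the measure-valued multilevel dynamics
#'
#' Iterates the representation-formula map to a fixed point on the time
#' mesh `0, dt, ..., T`: particle positions follow the characteristic flow
#' (independent of the measure), and the weight of particle `k` at time
#' `t` is `w_k(0) * exp(2 lambda I_k(t) - lambda t)` where `I_k(t)`
#' integrates (trapezoid rule) the particle's victory probability against
#' the previous iterate's measure. The initial guess is pure transport
#' (constant weights). Iteration stops when successive iterates differ by
#' less than `tol` in [measure_distance()] at every mesh time. Long
#' horizons are handled by restarting the Picard solve on consecutive
#' windows of length `window` (the map is a contraction on short windows).
#'
#' @param mu0 A `particle_measure` approximating the initial measure.
#' @param T Final time.
#' @param dt Mesh spacing.
#' @param kernel A `victory_kernel`.
#' @param lambda Conflict strength.
#' @param c A [game_coefficients()] driving the characteristic flow.
#' @param max_iter Maximum Picard iterations per window.
#' @param tol Convergence tolerance in Wasserstein-1 distance.
#' @param window Window length for restarted solves (default `min(T, 1)`).
#' @return An object of class `flow_iterate`: `times`, `positions`
#'   ((n+1) x M matrix), `weights` ((n+1) x M matrix), `iterations`
#'   (per window), and the final-state `particle_measure` in `measure`.
#' @export
picard_solve <- function(mu0, T, dt, kernel, lambda, c,
                         max_iter = 50, tol = 1e-8, window = NULL) {
  stopifnot(inherits(mu0, "particle_measure"),
            inherits(kernel, "victory_kernel"),
            inherits(c, "game_coefficients"),
            T > 0, dt > 0, lambda >= 0)
  if (is.null(window)) window <- min(T, 1)
  n_total <- round(T / dt)
  if (abs(n_total * dt - T) > 1e-9) {
    stop("T must be an integer multiple of dt", call. = FALSE)
  }
  M <- length(mu0$positions)
  times <- (0:n_total) * dt
  positions <- matrix(0, n_total + 1, M)
  weights <- matrix(0, n_total + 1, M)
  positions[1, ] <- mu0$positions
  weights[1, ] <- mu0$weights
  iterations <- integer(0)

  start <- 1L  # row index of current window start
  while (start <= n_total) {
    n_win <- min(round(window / dt), n_total - start + 1L)
    rows <- start:(start + n_win)
    pos <- flow_path(positions[start, ], n_win * dt, dt, c)
    w0 <- weights[start, ]
    ts <- (0:n_win) * dt
    W <- matrix(w0, n_win + 1, M, byrow = TRUE)  # transport initial guess
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      integrand <- matrix(0, n_win + 1, M)
      for (i in seq_len(n_win + 1)) {
        R <- outer(pos[i, ], pos[i, ], function(a, b) kernel$rho(a, b))
        integrand[i, ] <- as.vector(R %*% W[i, ])
      }
      I <- apply(integrand, 2,
                 function(col) c(0, cumsum((col[-1] + col[-(n_win + 1)]) /
                                             2 * dt)))
      Wn <- matrix(w0, n_win + 1, M, byrow = TRUE) *
        exp(2 * lambda * I - lambda * ts)
      # same atom positions: W1 distance between iterates reduces to the
      # integral of |cumsum of weight differences| over position gaps
      dmax <- 0
      for (i in seq_len(n_win + 1)) {
        o <- order(pos[i, ])
        cd <- cumsum((Wn[i, ] - W[i, ])[o])
        ps <- pos[i, o]
        dmax <- max(dmax, sum(abs(cd[-M]) * diff(ps)))
        if (dmax >= tol && it < max_iter) break
      }
      W <- Wn
      if (dmax < tol) {
        converged <- TRUE
        iterations <- c(iterations, it)
        break
      }
    }
    if (!converged) {
      stop(sprintf("picard_solve: no convergence in %d iterations (window %g)",
                   max_iter, window), call. = FALSE)
    }
    positions[rows, ] <- pos
    weights[rows, ] <- W
    start <- start + n_win
  }
  final <- particle_measure(positions[n_total + 1, ],
                            weights[n_total + 1, ] /
                              sum(weights[n_total + 1, ]),
                            time = T)
  structure(list(times = times, positions = positions, weights = weights,
                 iterations = iterations, measure = final,
                 kernel = kernel, lambda = lambda, coef = c),
            class = "flow_iterate")
}

#' @export
print.flow_iterate <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf(paste0(
    "picard flow: %d atoms on %d mesh times, windows converged in ",
    "%s iterations\n  final total weight %.6f\n"),
    ncol(x$positions), n, paste(x$iterations, collapse = "/"),
    sum(x$weights[n, ])))
  invisible(x)
}

#' Extract the measure at a mesh time
#'
#' @param flow A `flow_iterate` from [picard_solve()].
#' @param t A mesh time (rounded to the nearest mesh point).
#' @return A `particle_measure` (weights renormalised).
#' @export
measure_at <- function(flow, t) {
  stopifnot(inherits(flow, "flow_iterate"))
  i <- which.min(abs(flow$times - t))
  w <- flow$weights[i, ]
  particle_measure(flow$positions[i, ], w / sum(w), time = flow$times[i])
}
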