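# Two-player, two-strategy games: payoff matrices, shorthand coefficients,
# within-group defector advantage pi(x), group average payoff G(x), and the
# distinguished cooperation levels used throughout the multilevel dynamics.

#' Payoff matrix of a symmetric 2x2 game
#'
#' The four entries are the reward for mutual cooperation `R`, the sucker
#' payoff `S` for cooperating against a defector, the temptation payoff `T`
#' for defecting against a cooperator, and the punishment `P` for mutual
#' defection.
#'
#' @param R,S,T,P Finite numeric payoffs.
#' @return An object of class `payoff_matrix`.
#' @seealso [game_coefficients()], [classify_game()]
#' @examples
#' payoff_matrix(R = 1.5, S = 0, T = 3.5, P = 1)
#' @export
payoff_matrix <- function(R, S, T, P) {
  vals <- c(R = R, S = S, T = T, P = P)
  if (!all(is.finite(vals))) {
    stop("all payoff entries must be finite", call. = FALSE)
  }
  structure(as.list(vals), class = "payoff_matrix")
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat(sprintf("2x2 game payoffs: R = %g, S = %g, T = %g, P = %g (%s)\n",
              x$R, x$S, x$T, x$P, classify_game(x)))
  invisible(x)
}

#' Shorthand game coefficients
#'
#' The multilevel dynamics depend on the payoff matrix only through the
#' combinations `alpha = R - S - T + P`, `beta = S - P`,
#' `gamma = S + T - 2P`, together with the punishment payoff `P`. In these
#' coordinates the defector advantage is `pi(x) = -(beta + alpha * x)` and
#' the group average payoff is `G(x) = P + gamma * x + alpha * x^2`.
#'
#' @param alpha,beta,gamma,P Finite numeric coefficients.
#' @return An object of class `game_coefficients`.
#' @seealso [coefficients_from_payoffs()], [payoffs_from_coefficients()]
#' @examples
#' game_coefficients(alpha = -1, beta = -1, gamma = 1.5, P = 1)
#' @export
game_coefficients <- function(alpha, beta, gamma, P) {
  vals <- c(alpha = alpha, beta = beta, gamma = gamma, P = P)
  if (!all(is.finite(vals))) {
    stop("all game coefficients must be finite", call. = FALSE)
  }
  structure(as.list(vals), class = "game_coefficients")
}

#' @export
print.game_coefficients <- function(x, ...) {
  cat(sprintf("game coefficients: alpha = %g, beta = %g, gamma = %g, P = %g\n",
              x$alpha, x$beta, x$gamma, x$P))
  invisible(x)
}

#' Convert a payoff matrix to shorthand coefficients
#'
#' @param m A [payoff_matrix()].
#' @return A [game_coefficients()] object with `alpha = R - S - T + P`,
#'   `beta = S - P`, `gamma = S + T - 2P`.
#' @examples
#' coefficients_from_payoffs(payoff_matrix(1.5, 0, 3.5, 1))
#' @export
coefficients_from_payoffs <- function(m) {
  stopifnot(inherits(m, "payoff_matrix"))
  game_coefficients(alpha = m$R - m$S - m$T + m$P,
                    beta  = m$S - m$P,
                    gamma = m$S + m$T - 2 * m$P,
                    P     = m$P)
}

#' Recover the payoff matrix from shorthand coefficients
#'
#' Exact inverse of [coefficients_from_payoffs()]: `S = beta + P`,
#' `T = gamma + 2P - S`, `R = alpha + S + T - P`.
#'
#' @param c A [game_coefficients()].
#' @return A [payoff_matrix()].
#' @export
payoffs_from_coefficients <- function(c) {
  stopifnot(inherits(c, "game_coefficients"))
  S <- c$beta + c$P
  T <- c$gamma + 2 * c$P - S
  R <- c$alpha + S + T - c$P
  payoff_matrix(R = R, S = S, T = T, P = c$P)
}

#' Normalise a game specification
#'
#' Accepts either a payoff matrix or shorthand coefficients and returns a
#' list holding both representations, so downstream code can use whichever
#' is convenient.
#'
#' @param game A [payoff_matrix()] or [game_coefficients()].
#' @return A list with elements `payoffs`, `coef`, and `label`.
#' @export
as_game <- function(game) {
  if (inherits(game, "payoff_matrix")) {
    list(payoffs = game, coef = coefficients_from_payoffs(game),
         label = classify_game(game))
  } else if (inherits(game, "game_coefficients")) {
    m <- payoffs_from_coefficients(game)
    list(payoffs = m, coef = game, label = classify_game(m))
  } else {
    stop("game must be a payoff_matrix or game_coefficients", call. = FALSE)
  }
}

#' Classify a 2x2 game by its payoff ranking
#'
#' Strict orderings only; any tie or non-listed ordering yields `"other"`.
#' The recognised classes are the Prisoners' Dilemma (`T > R > P > S`),
#' Hawk-Dove (`T > R > S > P`), Stag Hunt (`R > T > P > S`), and
#' Prisoners' Delight (`R > T > S > P`).
#'
#' @param m A [payoff_matrix()] (or [game_coefficients()], converted first).
#' @return One of `"PD"`, `"HD"`, `"SH"`, `"PDel"`, `"other"`.
#' @export
classify_game <- function(m) {
  if (inherits(m, "game_coefficients")) m <- payoffs_from_coefficients(m)
  stopifnot(inherits(m, "payoff_matrix"))
  with(m, {
    if (T > R && R > P && P > S) return("PD")
    if (T > R && R > S && S > P) return("HD")
    if (R > T && T > P && P > S) return("SH")
    if (R > T && T > S && S > P) return("PDel")
    "other"
  })
}

check_unit_interval <- function(x, what = "x") {
  if (any(x < 0 | x > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}

#' Within-group advantage of defectors
#'
#' `pi(x) = -(beta + alpha * x)`, the payoff advantage of defectors over
#' cooperators in a group with cooperator fraction `x`.
#'
#' @param x Cooperator fraction(s) in `[0, 1]` (vectorised).
#' @param c A [game_coefficients()].
#' @return Numeric vector of advantages.
#' @export
pi_advantage <- function(x, c) {
  stopifnot(inherits(c, "game_coefficients"))
  check_unit_interval(x)
  -(c$beta + c$alpha * x)
}

#' Average payoff of group members
#'
#' `G(x) = P + gamma * x + alpha * x^2` for a group with cooperator
#' fraction `x`.
#'
#' @inheritParams pi_advantage
#' @return Numeric vector of group payoffs.
#' @export
group_payoff <- function(x, c) {
  stopifnot(inherits(c, "game_coefficients"))
  check_unit_interval(x)
  c$P + c$gamma * x + c$alpha * x^2
}

#' Range of the group payoff on the unit interval
#'
#' Closed-form maximum and minimum of the quadratic `G` on `[0, 1]`
#' (candidates are the endpoints and the vertex `-gamma / (2 alpha)`).
#'
#' @param c A [game_coefficients()].
#' @return Named numeric vector `c(min = G_*, max = G^*)`.
#' @export
group_payoff_range <- function(c) {
  stopifnot(inherits(c, "game_coefficients"))
  cand <- c(0, 1)
  if (c$alpha != 0) {
    v <- -c$gamma / (2 * c$alpha)
    if (v > 0 && v < 1) cand <- c(cand, v)
  }
  g <- group_payoff(cand, c)
  c(min = min(g), max = max(g))
}

#' Interior equilibrium of the within-group replicator dynamics
#'
#' The root `x_eq = beta / (-alpha)` of `pi(x)`, returned only when it lies
#' strictly inside `(0, 1)`; otherwise `NULL` (in particular for
#' `alpha = 0`, where `pi` is constant).
#'
#' @param c A [game_coefficients()].
#' @return A number in `(0, 1)` or `NULL`.
#' @export
interior_equilibrium <- function(c) {
  stopifnot(inherits(c, "game_coefficients"))
  if (c$alpha == 0) return(NULL)
  xeq <- c$beta / (-c$alpha)
  if (xeq > 0 && xeq < 1) xeq else NULL
}

#' Cooperation level maximising the group payoff
#'
#' Piecewise characterisation of the argmax of `G` on `[0, 1]`:
#' `x* = 1` when `gamma + 2 alpha >= 0`, else `x* = gamma / (-2 alpha)`,
#' clipped to `[0, 1]`.
#'
#' @param c A [game_coefficients()].
#' @return The maximiser `x*` in `[0, 1]`.
#' @export
optimal_cooperation <- function(c) {
  stopifnot(inherits(c, "game_coefficients"))
  if (c$gamma + 2 * c$alpha >= 0) return(1)
  min(max(c$gamma / (-2 * c$alpha), 0), 1)
}

#' Interior cooperation level with the all-cooperator payoff
#'
#' The non-unit root `xbar = -gamma / alpha - 1` of `G(x) = G(1)`, returned
#' only when it lies strictly inside `(0, 1)`. When `G` is non-decreasing
#' up to 1 (`gamma + 2 alpha >= 0`) no interior match exists and `NULL` is
#' returned.
#'
#' @param c A [game_coefficients()] with `alpha != 0`.
#' @return A number in `(0, 1)` or `NULL`.
#' @export
payoff_matching_cooperation <- function(c) {
  stopifnot(inherits(c, "game_coefficients"))
  if (c$alpha == 0) return(NULL)
  xbar <- -c$gamma / c$alpha - 1
  if (xbar > 0 && xbar < 1) xbar else NULL
}
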