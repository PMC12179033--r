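# Pairwise group-level victory-probability kernels rho(x, y): the chance
# that an x-cooperator group defeats a y-cooperator group in a single
# conflict. Every kernel satisfies 0 <= rho <= 1 and the complementarity
# identity rho(y, x) = 1 - rho(x, y), so rho(x, x) = 1/2.

new_victory_kernel <- function(family, rho, params = list(), coef = NULL) {
  structure(list(family = family, rho = rho, params = params, coef = coef),
            class = "victory_kernel")
}

#' @export
print.victory_kernel <- function(x, ...) {
  p <- if (length(x$params)) {
    paste0(" (", paste(names(x$params), unlist(x$params), sep = " = ",
                       collapse = ", "), ")")
  } else ""
  cat(sprintf("victory kernel: %s%s\n", x$family, p))
  invisible(x)
}

#' Evaluate a victory kernel
#'
#' @param k A `victory_kernel`.
#' @param x,y Cooperator fractions in `[0, 1]`; recycled to a common length.
#' @return Victory probabilities `rho(x, y)` in `[0, 1]`.
#' @export
rho_victory <- function(k, x, y) {
  stopifnot(inherits(k, "victory_kernel"))
  check_unit_interval(x)
  check_unit_interval(y, "y")
  k$rho(x, y)
}

#' Pre-tabulate a kernel on a set of compositions
#'
#' Returns the matrix `K[i, j] = rho(x[i], x[j])`. The kernels are
#' time-independent, so the finite-volume solver tabulates this once per run.
#'
#' @param k A `victory_kernel`.
#' @param x Numeric vector of compositions.
#' @return A square matrix.
#' @export
kernel_matrix <- function(k, x) {
  stopifnot(inherits(k, "victory_kernel"))
  outer(x, x, function(a, b) k$rho(a, b))
}

#' Fraction-difference victory kernel
#'
#' `rho(x, y) = 1/2 + (x - y) / 2`: the advantage in conflict is
#' proportional to the difference in cooperator fractions.
#'
#' @return A `victory_kernel`.
#' @export
fraction_kernel <- function() {
  new_victory_kernel("fraction", function(x, y) 0.5 + 0.5 * (x - y))
}

#' Local-update victory kernel
#'
#' `rho(x, y) = 1/2 * (1 + (G(x) - G(y)) / (G^* - G_*))` where `G^*` and
#' `G_*` are the extrema of the group payoff on `[0, 1]`; the group-level
#' analogue of the local update rule for individual learning. A constant
#' `G` gives the degenerate convention `rho = 1/2`. This kernel is
#' additively separable with `G(x)/(G^* - G_*)` as the net group-level
#' replication rate.
#'
#' @param c A [game_coefficients()].
#' @return A `victory_kernel`.
#' @export
local_update_kernel <- function(c) {
  stopifnot(inherits(c, "game_coefficients"))
  rng <- group_payoff_range(c)
  denom <- rng[["max"]] - rng[["min"]]
  rho <- if (denom == 0) {
    function(x, y) rep_len(0.5, length(x + y))
  } else {
    function(x, y) 0.5 * (1 + (group_payoff(x, c) - group_payoff(y, c)) / denom)
  }
  new_victory_kernel("local_update", rho, coef = c)
}

#' Fermi (pairwise-comparison) victory kernel
#'
#' `rho(x, y) = 1/2 * (1 + tanh(s * (G(x) - G(y))))`: a group-level
#' version of the Fermi update rule, with sensitivity `s >= 0` controlling
#' how strongly payoff differences translate into victory odds.
#'
#' @param c A [game_coefficients()].
#' @param s Sensitivity, a nonnegative number.
#' @return A `victory_kernel`.
#' @export
fermi_kernel <- function(c, s) {
  stopifnot(inherits(c, "game_coefficients"))
  if (!is.numeric(s) || length(s) != 1 || s < 0) {
    stop("sensitivity s must be a nonnegative number", call. = FALSE)
  }
  rho <- function(x, y) {
    0.5 * (1 + tanh(s * (group_payoff(x, c) - group_payoff(y, c))))
  }
  new_victory_kernel("fermi", rho, params = list(s = s), coef = c)
}

#' Normalized payoff-difference victory kernel
#'
#' `rho(x, y) = 1/2 + 1/2 * (G(x) - G(y)) / (|G(x)| + |G(y)|)`, the payoff
#' difference normalized by the absolute payoffs of the competing groups;
#' when both payoffs vanish the complementarity-preserving convention
#' `rho = 1/2` applies.
#'
#' @param c A [game_coefficients()].
#' @return A `victory_kernel`.
#' @export
normalized_diff_kernel <- function(c) {
  stopifnot(inherits(c, "game_coefficients"))
  rho <- function(x, y) {
    gx <- group_payoff(x, c)
    gy <- group_payoff(y, c)
    denom <- abs(gx) + abs(gy)
    out <- rep_len(0.5, length(denom))
    ok <- denom > 0
    out[ok] <- 0.5 + 0.5 * (gx - gy)[ok] / denom[ok]
    out
  }
  new_victory_kernel("normalized", rho, coef = c)
}

#' Tullock contest victory kernel
#'
#' `rho(x, y) = (G(x) - G_*)^(1/a) / ((G(x) - G_*)^(1/a) + (G(y) - G_*)^(1/a))`
#' with `G_*` the minimum group payoff on `[0, 1]` and contest sensitivity
#' `a > 0`. When both groups sit at the payoff minimum the convention is
#' `rho = 1/2`; when exactly one does, it loses with certainty.
#'
#' @param c A [game_coefficients()].
#' @param a Contest sensitivity, a positive number.
#' @return A `victory_kernel`.
#' @export
tullock_kernel <- function(c, a) {
  stopifnot(inherits(c, "game_coefficients"))
  if (!is.numeric(a) || length(a) != 1 || a <= 0) {
    stop("contest sensitivity a must be positive", call. = FALSE)
  }
  gmin <- group_payoff_range(c)[["min"]]
  rho <- function(x, y) {
    ex <- (group_payoff(x, c) - gmin)^(1 / a)
    ey <- (group_payoff(y, c) - gmin)^(1 / a)
    denom <- ex + ey
    out <- rep_len(0.5, length(denom))
    ok <- denom > 0
    out[ok] <- ex[ok] / denom[ok]
    out
  }
  new_victory_kernel("tullock", rho, params = list(a = a), coef = c)
}

#' Additively separable victory kernel
#'
#' `rho(x, y) = 1/2 * (1 + gcal(x) - gcal(y))` for a net group-level
#' replication rate `gcal` with `|gcal| <= 1` on `[0, 1]`. For this family
#' the multilevel dynamics reduce to a frequency-independent two-level
#' replicator equation.
#'
#' @param gcal A vectorised function from `[0, 1]` to `[-1, 1]`.
#' @return A `victory_kernel` with the function stored in `params$gcal`.
#' @export
separable_kernel <- function(gcal) {
  stopifnot(is.function(gcal))
  probe <- gcal(seq(0, 1, length.out = 101))
  if (any(!is.finite(probe)) || any(abs(probe) > 1 + 1e-12)) {
    stop("gcal must map [0, 1] into [-1, 1]", call. = FALSE)
  }
  rho <- function(x, y) 0.5 * (1 + gcal(x) - gcal(y))
  new_victory_kernel("separable", rho, params = list(gcal = gcal))
}

#' Build a kernel from a config-style specification
#'
#' @param spec A list with element `family` (one of `fraction`,
#'   `local_update`, `fermi`, `normalized`, `tullock`, `separable`) and the
#'   family's parameters (`s` for `fermi`, `a` for `tullock`, a function
#'   `gcal` for `separable`).
#' @param c A [game_coefficients()] for the payoff-dependent families.
#' @return A `victory_kernel`.
#' @export
make_kernel <- function(spec, c = NULL) {
  stopifnot(is.list(spec), !is.null(spec$family))
  switch(spec$family,
    fraction     = fraction_kernel(),
    local_update = local_update_kernel(c),
    fermi        = fermi_kernel(c, spec$s %||% 1),
    normalized   = normalized_diff_kernel(c),
    tullock      = tullock_kernel(c, spec$a %||% 1),
    separable    = separable_kernel(spec$gcal),
    stop(sprintf("unknown kernel family '%s'", spec$family), call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a victory kernel on a lattice
#'
#' Checks the kernel axioms on an `n_grid` x `n_grid` lattice over
#' `[0, 1]^2`: range `0 <= rho <= 1`, complementarity
#' `rho(x, y) + rho(y, x) = 1`, and - when a dominance threshold `z_min`
#' is supplied - the Stag-Hunt-type assumptions that `rho(x, y) > rho(y, x)`
#' whenever `x > z_min > y`, and that `rho(., y)` is dominated by values
#' above `z_min` (monotone dominance: `rho(x, y) > rho(u, y)` for
#' `x > z_min`, `x > u`).
#'
#' @param k A `victory_kernel`.
#' @param n_grid Lattice size per axis, at least 2.
#' @param z_min Optional dominance threshold in `(0, 1)`.
#' @return A list report with the maximal violations (zero when the kernel
#'   passes) and a logical `ok`.
#' @export
validate_kernel <- function(k, n_grid = 101, z_min = NULL) {
  stopifnot(inherits(k, "victory_kernel"), n_grid >= 2)
  xs <- seq(0, 1, length.out = n_grid)
  K <- kernel_matrix(k, xs)
  range_violation <- max(0, max(K - 1), max(-K))
  complementarity_violation <- max(abs(K + t(K) - 1))
  report <- list(family = k$family,
                 n_grid = n_grid,
                 range_violation = range_violation,
                 complementarity_violation = complementarity_violation)
  if (!is.null(z_min)) {
    above <- xs > z_min
    below <- xs < z_min
    # rho(x, y) > rho(y, x) for x > z_min > y
    net <- K - t(K)
    report$dominance_violation <-
      if (any(above) && any(below)) max(0, max(-net[above, below, drop = FALSE]))
      else 0
    # rho(x, y) > rho(u, y) for x > z_min, x > u: columns of K restricted to
    # rows above z_min must dominate all lower rows
    mono <- 0
    for (i in which(above)) {
      lower <- seq_len(i - 1L)
      if (length(lower)) {
        mono <- max(mono, max(K[lower, , drop = FALSE] -
                                matrix(K[i, ], length(lower), n_grid,
                                       byrow = TRUE)))
      }
    }
    report$monotone_dominance_violation <- max(0, mono)
  }
  tol <- 1e-12
  report$ok <- report$range_violation <= tol &&
    report$complementarity_violation <= tol &&
    (is.null(z_min) || (report$dominance_violation <= tol &&
                          report$monotone_dominance_violation <= tol))
  report
}
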