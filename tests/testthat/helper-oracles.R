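# Independent oracles used across the test suite. These deliberately do
# NOT reuse the package's solver internals.

# Reference games used throughout: coefficient sets matching the published
# simulation scenarios.
pd_game <- function() game_coefficients(alpha = -1, beta = -1, gamma = 1.5, P = 1)
pd_game_x1 <- function() game_coefficients(alpha = -1, beta = -1, gamma = 2, P = 1)
hd_game <- function() game_coefficients(alpha = -2, beta = 1, gamma = 3.5, P = 1)
hd_game_x1 <- function() game_coefficients(alpha = -2, beta = 1, gamma = 4, P = 1)
sh_game <- function() game_coefficients(alpha = 2, beta = -1, gamma = 0, P = 2)
pdel_game <- function() {
  # R > T > S > P: e.g. R = 4, T = 3, S = 2, P = 1
  coefficients_from_payoffs(payoff_matrix(R = 4, S = 2, T = 3, P = 1))
}
all_test_games <- function() {
  list(PD = pd_game(), HD = hd_game(), SH = sh_game(), PDel = pdel_game())
}
all_test_kernels <- function(coef) {
  list(fraction = fraction_kernel(),
       local_update = local_update_kernel(coef),
       fermi = fermi_kernel(coef, s = 1),
       normalized = normalized_diff_kernel(coef),
       tullock = tullock_kernel(coef, a = 1))
}

# Two-level replicator equation with frequency-independent group rate
# gcal(x): f_t = d/dx[v f] + lambda f (gcal(x) - Int gcal f). Independent
# discretisation (same grid geometry, separately coded loop) used as the
# oracle for the separable-kernel equivalence.
replicator2_solve <- function(gcal, coef, lambda, N, dt, n_steps,
                              f0 = NULL) {
  dx <- 1 / N
  xc <- (seq_len(N) - 0.5) * dx
  xe <- (0:N) * dx
  v <- -xe * (1 - xe) * (-(coef$beta + coef$alpha * xe))
  v[1] <- 0; v[N + 1] <- 0
  gc_vals <- gcal(xc)
  f <- if (is.null(f0)) rep(1, N) else f0
  for (k in seq_len(n_steps)) {
    flux <- numeric(N + 1)
    for (e in 2:N) {
      flux[e] <- if (v[e] >= 0) v[e] * f[e - 1] else v[e] * f[e]
    }
    fa <- f - dt / dx * (flux[2:(N + 1)] - flux[1:N])
    gbar <- sum(gc_vals * f) * dx / (sum(f) * dx)
    f <- fa + dt * lambda * f * (gc_vals - gbar)
  }
  f
}

# Closed-form logistic flow for constant pi (alpha = 0, beta = -pi0):
# dx/dt = -x(1-x) pi0 has solution x0 e^{-pi0 t} / (1 - x0 + x0 e^{-pi0 t}).
logistic_flow <- function(x0, t, pi0 = 1) {
  e <- exp(-pi0 * t)
  x0 * e / (1 - x0 + x0 * e)
}
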