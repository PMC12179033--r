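test_that("grid and initial densities have exact unit mass", {
  g <- fv_grid(64)
  expect_equal(g$dx, 1 / 64)
  expect_true(all(diff(g$centers) > 0))
  expect_equal(g$edges[c(1, 65)], c(0, 1))

  f_unif <- initial_density(list(kind = "uniform"), g)
  expect_equal(total_mass(f_unif), 1)
  expect_equal(f_unif$f, rep(1, 64))

  # theta family: theta = 1 is uniform, exact telescoping masses otherwise
  f_th1 <- initial_density(list(kind = "theta", theta = 1), g)
  expect_equal(f_th1$f, f_unif$f)
  for (th in c(0.5, 2, 3.7)) {
    f_th <- initial_density(list(kind = "theta", theta = th), g)
    expect_equal(total_mass(f_th), 1)
    # tail mass above 1/2 is exactly (1/2)^theta
    expect_equal(tail_mass_above(f_th, 0.5), 0.5^th)
  }
  expect_error(initial_density(list(kind = "theta", theta = 0), g), "theta")
  expect_error(initial_density(list(kind = "bogus"), g), "unknown")
})

test_that("edge velocities vanish at the boundary and at x_eq", {
  g <- fv_grid(100)
  v <- edge_velocities(g, pd_game())
  expect_identical(v[c(1, 101)], c(0, 0))
  # pi = 1 (alpha = 0, beta = -1): v(1/2) = -1/4
  v1 <- edge_velocities(g, game_coefficients(0, -1, 0, 1))
  expect_equal(v1[51], -0.25)
  # HD: velocity vanishes at the interior equilibrium x_eq = 0.5
  vhd <- edge_velocities(g, hd_game())
  expect_equal(vhd[51], 0)
})

test_that("advection is conservative, exact for v = 0, and transports", {
  g <- fv_grid(128)
  f <- initial_density(list(kind = "theta", theta = 2), g)
  f2 <- advection_update(f, rep(0, 129), 0.01)
  expect_identical(f2$f, f$f)

  # mass is conserved for arbitrary velocities and densities
  set.seed(5)
  for (i in 1:10) {
    vals <- runif(128)
    vals <- vals / (sum(vals) / 128)
    fr <- density_state(vals, g)
    v <- c(0, runif(127, -1, 1), 0)
    out <- advection_update(fr, v, 0.005)
    expect_equal(sum(out$f), sum(fr$f), tolerance = 1e-13)
  }

  # a step profile advected under constant interior velocity moves by v*t
  # (within one-cell smearing of the front)
  v0 <- 0.2
  v <- c(0, rep(v0, 127), 0)
  vals <- as.numeric(g$centers < 0.25) ; vals <- vals / (sum(vals) / 128)
  f <- density_state(vals, g)
  n <- 100; dt <- 0.005
  for (k in seq_len(n)) f <- advection_update(f, v, dt)
  shift <- v0 * n * dt  # 0.1: block occupies [0.1, 0.35], half-mass at 0.225
  cdf <- cumsum(f$f) * g$dx
  half <- g$centers[which.min(abs(cdf - 0.5))]
  expect_lt(abs(half - 0.225), 2 * g$dx)
  expect_error(advection_update(f, 300 * v, 0.01), "CFL")
})

test_that("reaction rates: closed forms and exact zero-sum", {
  g <- fv_grid(64)
  f <- initial_density("uniform", g)
  half <- structure(list(family = "half",
                         rho = function(x, y) rep_len(0.5, length(x + y)),
                         params = list()), class = "victory_kernel")
  expect_equal(reaction_rates(f, kernel_matrix(half, g$centers), 3),
               rep(0, 64))
  # uniform density with the fraction kernel: r_i = lambda (x_i - 1/2)
  K <- kernel_matrix(fraction_kernel(), g$centers)
  expect_equal(reaction_rates(f, K, 2), 2 * (g$centers - 0.5),
               tolerance = 1e-12)
})

test_that("per-step mass conservation across kernels and game classes", {
  # the complementarity identity makes conflict gains equal losses, and
  # upwind fluxes telescope with zero boundary flux: both sub-steps must
  # conserve mass to ~1e-12 relative even on rough random densities
  g <- fv_grid(96)
  set.seed(8)
  for (game in all_test_games()) {
    v <- edge_velocities(g, game)
    dt <- min(0.002, 0.9 * g$dx / max(abs(v)))
    for (k in all_test_kernels(game)) {
      K <- kernel_matrix(k, g$centers)
      vals <- runif(96) + 0.05
      vals <- vals / (sum(vals) / 96)
      f <- density_state(vals, g)
      fa <- advection_update(f, v, dt)
      expect_lt(abs(total_mass(fa) - 1), 1e-12)
      r <- reaction_rates(f, K, 5)
      expect_lt(abs(sum(f$f * r) * g$dx), 1e-12)
      f1 <- fv_step(f, v, K, 5, dt)
      expect_lt(abs(total_mass(f1) - 1), 1e-12)
    }
  }
})

test_that("a single step matches the hand-computed 4-cell update", {
  # N = 4, uniform f, fraction kernel, lambda = 1, pi = 1, dt = 0.1:
  # frozen from explicit flux arithmetic (edges v = -x(1-x): all left-going;
  # reaction r_i = x_i - 1/2)
  g <- fv_grid(4)
  coef <- game_coefficients(alpha = 0, beta = -1, gamma = 0, P = 1)
  f <- initial_density("uniform", g)
  v <- edge_velocities(g, coef)
  K <- kernel_matrix(fraction_kernel(), g$centers)
  out <- fv_step(f, v, K, lambda = 1, dt = 0.1)
  expect_equal(out$f, c(1.0375, 1.0125, 0.9875, 0.9625), tolerance = 1e-14)
  expect_equal(out$time, 0.1)
})

test_that("identity dynamics and trajectory bookkeeping", {
  cfg <- sim_config(game = game_coefficients(0, 0, 0, 1),
                    kernel = fraction_kernel(), lambda = 0,
                    dt = 0.01, n_steps = 20, N = 32)
  traj <- run_simulation(cfg)
  expect_equal(traj$states[[length(traj$states)]]$f, rep(1, 32))
  expect_true(all(diff(traj$times) > 0))
  expect_equal(traj$diagnostics$mean_coop[1], 0.5)
  expect_lt(traj$mass_drift, 1e-13)
})

test_that("lambda = 0 reproduces pure replicator transport (flow oracle)", {
  # smooth bump advected by the characteristic flow vs the FV solver
  N <- 128
  g <- fv_grid(N)
  coef <- pd_game()
  cfg <- sim_config(game = coef, kernel = fermi_kernel(coef, 1), lambda = 0,
                    dt = 0.004, n_steps = 125, N = N,
                    init = list(kind = "theta", theta = 2))
  traj <- run_simulation(cfg)
  mu0 <- particles_from_density(list(kind = "theta", theta = 2), g)
  pos <- characteristic_flow(mu0$positions, 0.5, coef)
  mu_t <- particle_measure(pos, mu0$weights, time = 0.5)
  d <- measure_distance(traj$states[[length(traj$states)]], mu_t)
  expect_lt(d, 5 * g$dx)
})

test_that("separable kernel trajectory equals the two-level replicator oracle", {
  coef <- pd_game()
  gcal <- function(x) 0.8 * x - 0.4
  N <- 64; dt <- 0.005; n_steps <- 100; lambda <- 3
  cfg <- sim_config(game = coef, kernel = separable_kernel(gcal),
                    lambda = lambda, dt = dt, n_steps = n_steps, N = N)
  traj <- run_simulation(cfg)
  oracle <- replicator2_solve(gcal, coef, lambda, N, dt, n_steps)
  expect_equal(traj$states[[length(traj$states)]]$f, oracle,
               tolerance = 1e-10)
})

test_that("grid refinement converges at first order", {
  coef <- pd_game()
  run_at <- function(N) {
    cfg <- sim_config(game = coef, kernel = fermi_kernel(coef, 1),
                      lambda = 2, dt = 0.32 / N, n_steps = round(N / 0.32),
                      N = N)
    traj <- run_simulation(cfg)
    traj$diagnostics$mean_coop[nrow(traj$diagnostics)]
  }
  m <- vapply(c(64, 128, 256), run_at, numeric(1))
  err <- abs(m[1:2] - m[3])
  # halving dx should roughly halve the deviation from the finest grid
  expect_lt(err[2], err[1])
  expect_lt(err[2] / err[1], 0.75)
})

test_that("CFL violations and invalid configs are rejected", {
  expect_error(sim_config(game = pd_game(), kernel = fraction_kernel(),
                          lambda = 1, dt = 0.5, n_steps = 10, N = 256),
               "CFL")
  expect_error(sim_config(game = pd_game(), kernel = fraction_kernel(),
                          lambda = -1, dt = 0.001, n_steps = 10),
               "lambda")
})
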