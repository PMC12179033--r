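test_that("population summaries match closed-form integrals", {
  g <- fv_grid(128)
  unif <- initial_density("uniform", g)
  expect_equal(mean_cooperation(unif), 0.5)

  top <- density_state(c(rep(0, 127), 128), g)
  expect_gt(mean_cooperation(top), 0.99)

  # f(x) = 2x discretised: mean = 2/3 within O(dx^2)
  f2x <- density_state(2 * g$centers, g)
  expect_equal(mean_cooperation(f2x), 2 / 3, tolerance = 1e-4)

  # tail masses with proration
  expect_equal(tail_mass_above(unif, 0.5), 0.5)
  expect_equal(tail_mass_above(top, 0.3), 1)
  expect_equal(tail_mass_above(f2x, 0.5), 0.75, tolerance = 1e-4)
  expect_equal(tail_mass_above(unif, 0.503), 0.497, tolerance = 1e-12)

  # success against all-cooperators
  fr <- fraction_kernel()
  expect_equal(success_vs_all_cooperators(unif, fr), 0.25)
  bottom <- density_state(c(128, rep(0, 127)), g)
  expect_lt(success_vs_all_cooperators(bottom, fr), 0.01)
  expect_equal(success_vs_all_cooperators(top, fr), 0.5, tolerance = 1e-2)
})

test_that("steady-state success prediction and its limits", {
  expect_equal(steady_success_prediction(14, 2, 1), 0.5 - 1 / 14)
  # monotone increasing in lambda, approaching 1/2 from below
  lams <- c(5, 10, 50, 1000, 1e8)
  preds <- steady_success_prediction(lams, 2, 1)
  expect_true(all(diff(preds) > 0))
  expect_lt(abs(preds[5] - 0.5), 1e-7)
  expect_error(steady_success_prediction(0, 2), "positive")
})

test_that("threshold strengths: closed forms, separable reduction, linearity", {
  pd <- pd_game()
  fe <- fermi_kernel(pd, 1)
  expect_equal(lambda_star_pd(1, pi_advantage(1, pd), fe), 2 / tanh(0.5))
  expect_equal(lambda_star_pd(2, pi_advantage(1, pd), fe),
               2 * lambda_star_pd(1, pi_advantage(1, pd), fe))

  hd <- hd_game()
  fh <- fermi_kernel(hd, 1)
  xeq <- interior_equilibrium(hd)
  expect_equal(lambda_star_hd(1, pi_advantage(1, hd), fh, xeq),
               1 / tanh(0.25))
  expect_equal(lambda_star_hd(3, 1, fh, xeq), 3 * lambda_star_hd(1, 1, fh, xeq))

  # separable kernel: lambda* = theta pi(1) / (gcal(1) - gcal(0)) and
  # pi(1) / (gcal(1) - gcal(xeq)) respectively
  gcal <- function(x) 0.6 * x^2 - 0.3
  sep <- separable_kernel(gcal)
  expect_equal(lambda_star_pd(1, 2, sep), 2 / (gcal(1) - gcal(0)))
  expect_equal(lambda_star_hd(1, 1, sep, 0.5), 1 / (gcal(1) - gcal(0.5)))

  # at lambda = lambda*_PD the steady prediction meets rho(0, 1)
  lstar <- lambda_star_pd(1, 2, fe)
  expect_equal(steady_success_prediction(lstar, 2, 1),
               rho_victory(fe, 0, 1))
  expect_error(lambda_star_pd(1, 2, structure(
    list(family = "x", rho = function(x, y) rep_len(0.5, length(x + y)),
         params = list()), class = "victory_kernel")), "requires")
})

test_that("long-time prediction is piecewise with a continuous join", {
  pd <- pd_game()
  fe <- fermi_kernel(pd, 1)
  lstar <- lambda_star_pd(1, pi_advantage(1, pd), fe)
  expect_equal(long_time_prediction(1e-6, pd, fe, scenario = "PD"),
               rho_victory(fe, 0, 1))
  eps <- 1e-9
  expect_equal(long_time_prediction(lstar - eps, pd, fe, scenario = "PD"),
               long_time_prediction(lstar + eps, pd, fe, scenario = "PD"),
               tolerance = 1e-6)
  hd <- hd_game()
  fh <- fermi_kernel(hd, 1)
  expect_equal(long_time_prediction(15, hd, fh, scenario = "HD"),
               0.5 - 1 / 30)
})

test_that("extinction bound: neutral kernel always, Fermi PD by lambda", {
  pd <- pd_game()
  half <- structure(list(family = "half",
                         rho = function(x, y) rep_len(0.5, length(x + y)),
                         params = list()), class = "victory_kernel")
  expect_true(extinction_bound_holds(1e6, 1, 2, half))
  fe <- fermi_kernel(pd, 1)
  expect_true(extinction_bound_holds(0.01, 1, 2, fe))
  expect_false(extinction_bound_holds(14, 1, 2, fe))
})

test_that("tail exponent estimation on analytic densities", {
  g <- fv_grid(256)
  for (th in c(0.5, 1, 2)) {
    f <- initial_density(list(kind = "theta", theta = th), g)
    est <- tail_exponent_estimate(f)
    expect_equal(est$theta_hat, th, tolerance = 0.02)
    expect_true(est$reliable)
  }
  # all mass in the top cell: flat tail, exponent near 0
  top <- density_state(c(rep(0, 255), 256), g)
  est0 <- tail_exponent_estimate(top)
  expect_lt(abs(est0$theta_hat), 0.05)
  # empty tail is flagged unreliable
  bottom <- density_state(c(256, rep(0, 255)), g)
  estb <- tail_exponent_estimate(bottom)
  expect_false(estb$reliable)
})

test_that("steady-state residual vanishes for exact steady states", {
  g <- fv_grid(64)
  unif <- initial_density("uniform", g)
  # pi = 0 and rho = 1/2: everything is steady
  czero <- game_coefficients(0, 0, 0, 1)
  half <- structure(list(family = "half",
                         rho = function(x, y) rep_len(0.5, length(x + y)),
                         params = list()), class = "victory_kernel")
  expect_equal(steady_state_residual(unif, czero, half, 3), 0)
  # lambda = 0, uniform f, PD: residual equals Int |d/dx(x(1-x)pi)| > 0
  res <- steady_state_residual(unif, pd_game(), half, 0)
  expect_gt(res, 0.5)
})

test_that("steady-state detection on trajectories", {
  cfg <- sim_config(game = game_coefficients(0, 0, 0, 1),
                    kernel = fraction_kernel(), lambda = 0,
                    dt = 0.01, n_steps = 40, N = 32)
  traj <- run_simulation(cfg)  # constant trajectory
  det <- detect_steady_state(traj, tol = 1e-10)
  expect_true(det$detected)
  expect_equal(det$time, traj$times[2])

  # a decaying transient: detection time shrinks as tol grows
  cfg2 <- scenario_preset("fig1-left", n_steps = 400)
  traj2 <- run_simulation(cfg2)
  d_tight <- detect_steady_state(traj2, tol = 0.05)
  d_loose <- detect_steady_state(traj2, tol = 5)
  expect_true(d_loose$detected)
  if (d_tight$detected) expect_gte(d_tight$time, d_loose$time)
})

test_that("threshold report bundles the analytic quantities", {
  rep <- threshold_report(hd_game(), fermi_kernel(hd_game(), 1))
  expect_equal(rep$pi1, 1)
  expect_equal(rep$x_eq, 0.5)
  expect_equal(rep$lambda_star_hd, 1 / tanh(0.25))
  expect_equal(rep$rho_10 + rep$rho_01, 1)
})
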