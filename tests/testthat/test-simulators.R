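# Normal-form and Ricker simulators: determinism, deterministic skeletons,
# stationary moments against the analytic forms, bifurcation points.

test_that("time series container validates its invariants", {
  expect_error(time_series(1, 1), "at least 2")
  expect_error(time_series(c(0, 1, 3), c(1, 2, 3)), "uniform")
  expect_error(time_series(0:2, c(1, NA, 3)), "missing")
  ts <- time_series(seq(0, 1, 0.1), rnorm(11))
  expect_equal(attr(ts, "dt"), 0.1)
})

test_that("parameter schedules ramp linearly and clamp outside", {
  s <- parameter_schedule(0, 2.7, 0, 500)
  expect_equal(schedule_value(s, c(-10, 0, 250, 500, 600)),
               c(0, 0, 1.35, 2.7, 2.7))
  expect_equal(schedule_value(1.5, c(0, 10)), c(1.5, 1.5))
  expect_error(parameter_schedule(0, 1, 5, 5), "end_time")
})

test_that("noise-free continuous fold sits at or relaxes to its fixed point", {
  at_fp <- simulate_normal_form_continuous("fold", alpha = 1, sigma = 0,
                                           dt = 0.01, t_end = 5, x0 = 1)
  expect_true(all(abs(at_fp$values - 1) < 1e-12))

  relax <- simulate_normal_form_continuous("fold", alpha = 1, sigma = 0,
                                           dt = 1e-3, t_end = 10, x0 = 0)
  expect_true(all(diff(relax$values) > -1e-15))
  expect_lt(abs(relax$values[length(relax$values)] - 1), 1e-3)
  # against a high-accuracy ODE oracle
  sol <- deSolve::ode(y = c(x = 0), times = relax$times,
                      func = function(t, y, p) list(1 - y^2), parms = NULL,
                      method = "ode45", rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(relax$values - sol[, "x"])), 5e-3)
})

test_that("continuous fold stationary variance matches the analytic form", {
  # alpha = 1: equilibrium x* = 1, lambda = -2x* = -2
  v <- mean(sapply(1:10, function(s) {
    ts <- simulate_normal_form_continuous("fold", alpha = 1, sigma = 0.05,
                                          dt = 0.01, t_end = 100, x0 = 1,
                                          seed = s)
    tail_vals <- ts$values[ts$times > 10]
    mean((tail_vals - mean(tail_vals))^2)
  }))
  target <- analytic_variance(bifurcation_spec("fold", lam = -2, sigma = 0.05))
  expect_lt(abs(v - target) / target, 0.15)
})

test_that("noise-free discrete fold holds its fixed point and decays geometrically", {
  fp <- simulate_normal_form_discrete("fold", alpha = 0.25, sigma = 0,
                                      n_steps = 50, x0 = 0.5)
  expect_true(all(fp$values == 0.5))
  # linearized multiplier is 1 - 2*sqrt(alpha)
  alpha <- 0.04
  pert <- simulate_normal_form_discrete("fold", alpha = alpha, sigma = 0,
                                        n_steps = 20, x0 = sqrt(alpha) + 1e-5)
  dev <- pert$values - sqrt(alpha)
  ratios <- dev[-1] / dev[-length(dev)]
  expect_true(all(abs(ratios - (1 - 2 * sqrt(alpha))) < 1e-3))
})

test_that("discrete fold stationary variance matches the analytic form", {
  alpha <- 0.04  # lambda = 0.6
  lam <- 1 - 2 * sqrt(alpha)
  v <- mean(sapply(1:10, function(s) {
    ts <- simulate_normal_form_discrete("fold", alpha = alpha, sigma = 0.01,
                                        n_steps = 10000, x0 = sqrt(alpha),
                                        seed = s)
    w <- ts$values[-(1:500)]
    mean((w - mean(w))^2)
  }))
  target <- analytic_variance(bifurcation_spec("fold", "discrete", lam = lam,
                                               sigma = 0.01))
  expect_lt(abs(v - target) / target, 0.15)
})

test_that("stationary lag-1 autocorrelation matches the analytic form", {
  alpha <- 0.04
  lam <- 1 - 2 * sqrt(alpha)
  ac <- mean(sapply(1:20, function(s) {
    ts <- simulate_normal_form_discrete("fold", alpha = alpha, sigma = 0.01,
                                        n_steps = 10000, x0 = sqrt(alpha),
                                        seed = s)
    lag_autocorrelation(ts$values[-(1:500)], 1)
  }))
  expect_lt(abs(ac - lam), 0.05)
})

test_that("simulators are deterministic in the seed and blow-ups are reported", {
  a <- simulate_ricker(n_steps = 200, seed = 42)
  b <- simulate_ricker(n_steps = 200, seed = 42)
  expect_identical(a$values, b$values)
  c1 <- simulate_normal_form_continuous("fold", alpha = 0.5, sigma = 0.1,
                                        dt = 0.01, t_end = 10, x0 = 0.7,
                                        seed = 9)
  c2 <- simulate_normal_form_continuous("fold", alpha = 0.5, sigma = 0.1,
                                        dt = 0.01, t_end = 10, x0 = 0.7,
                                        seed = 9)
  expect_identical(c1$values, c2$values)
  # starting far outside the basin diverges and reports the crossing time
  err <- tryCatch(
    simulate_normal_form_continuous("fold", alpha = 1, sigma = 0, dt = 0.01,
                                    t_end = 10, x0 = -5),
    ewspec_blowup = function(e) e)
  expect_s3_class(err, "ewspec_blowup")
  expect_true(is.numeric(err$time) && err$time > 0)
})

test_that("Ricker fixed point, nonnegativity and clamping", {
  fp <- simulate_ricker(ricker_params(r = 0.75, K = 10, F = 0, sigma = 0),
                        n_steps = 100, N0 = 10)
  expect_true(all(fp$values == 10))
  # strong harvesting with noise drives collapse; values never negative
  hs <- simulate_ricker(ricker_params(F = 3, sigma = 0.2), n_steps = 300,
                        N0 = 10, seed = 1)
  expect_true(all(hs$values >= 0))
  expect_true(any(hs$values == 0))  # clamp engaged after collapse
})

test_that("bifurcation points of the deterministic skeleton", {
  bp <- ricker_bifurcation_points(ricker_params())
  expect_equal(round(bp$F_fold, 2), 2.36)
  expect_equal(bp$r_flip, 2, tolerance = 1e-6)
  # closed form: multiplier at N* = K is 1 - r for any K
  bp2 <- ricker_bifurcation_points(ricker_params(K = 12))
  expect_equal(bp2$r_flip, 2, tolerance = 1e-6)
  # shallow harvesting saturation: no fold in range is reported as an error
  expect_error(ricker_bifurcation_points(ricker_params(K = 3.7)),
               "no fold bifurcation")
})

test_that("scenarios carry the prescribed ramps and truncation steps", {
  sc <- make_scenario("fold_forced", seed = 1)
  expect_length(sc$ts$values, 500)
  Fs <- sc$ts$meta$F_schedule
  expect_equal(schedule_value(Fs, 0), 0)
  expect_equal(schedule_value(Fs, 500), 2.7)
  expect_true(abs(sc$truncation_time - 437) <= 1)

  sc2 <- make_scenario("flip_forced", seed = 1)
  rs <- sc2$ts$meta$r_schedule
  expect_equal(schedule_value(rs, 0), 0.5)
  expect_equal(schedule_value(rs, 500), 2.3)
  expect_equal(sc2$truncation_time, 417)

  # nulls hold the ramped parameter at its initial value
  sc3 <- make_scenario("fold_null", seed = 1)
  expect_equal(schedule_value(sc3$ts$meta$F_schedule, c(0, 250, 500)),
               rep(0, 3))
  expect_equal(sc3$truncation_time, sc$truncation_time)
})

test_that("chemostat-style fixture yields damped-oscillation series", {
  fx <- make_chemostat_fixture(mus = c(-0.5, -0.05), omega0 = 1 / 3,
                               n_days = 60, sigma = 0.1, seed = 2)
  expect_length(fx, 2)
  expect_true(all(vapply(fx, function(z) length(z$values), numeric(1)) > 50))
  # fluctuations grow as the Hopf bifurcation nears
  v <- vapply(fx, function(z) mean((z$values - mean(z$values))^2), numeric(1))
  expect_gt(v[2], v[1])
})
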