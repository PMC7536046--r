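# Detrending, block bootstrap, window metrics, Kendall tau and the rolling
# pipeline.

test_that("lowess detrending removes constants and linear ramps", {
  flat <- time_series(1:100, rep(3.2, 100))
  d <- lowess_detrend(flat, span = 0.3)
  expect_true(all(abs(d$residuals$values) < 1e-10))

  ramp <- time_series(1:200, seq(0, 10, length.out = 200))
  d2 <- lowess_detrend(ramp, span = 0.3)
  expect_lt(sd(d2$residuals$values), 0.01 * 10)

  # absolute span in time units (e.g. an 80-day window on daily data)
  set.seed(31)
  daily <- time_series(0:159, rnorm(160) + 0.05 * (0:159))
  d3 <- lowess_detrend(daily, span_time = 80)
  expect_equal(d3$residuals$meta$lowess_span, 80 / 159)
  expect_error(lowess_detrend(daily, span = 0.001), "span too small")
})

test_that("stationary block bootstrap honours its contract and limits", {
  set.seed(32)
  x <- rnorm(100)
  bs <- stationary_block_bootstrap(x, mean_block_length = 10,
                                   n_samples = 100, seed = 1)
  expect_length(bs, 100)
  expect_true(all(lengths(bs) == 100))
  expect_true(all(unlist(bs) %in% x))

  # mean block length >> n: every sample is a circular rotation
  bs2 <- stationary_block_bootstrap(x, mean_block_length = 1e9,
                                    n_samples = 20, seed = 2)
  rotations <- sapply(0:99, function(k) paste(x[(((0:99) + k) %% 100) + 1],
                                              collapse = ","))
  expect_true(all(sapply(bs2, function(s)
    paste(s, collapse = ",") %in% rotations)))
})

test_that("bootstrap intervals cover the true lag-1 autocorrelation", {
  # AR(1) with coefficient 0.8; percentile intervals reach nominal coverage
  # in the long-series regime where block-join bias is negligible
  lam <- 0.8
  covered <- sum(sapply(1:50, function(i) {
    set.seed(1000 + i)
    x <- as.numeric(arima.sim(list(ar = lam), n = 8000))
    bs <- stationary_block_bootstrap(x, mean_block_length = 300,
                                     n_samples = 100, seed = i)
    acs <- sapply(bs, lag_autocorrelation, tau = 1)
    ci <- quantile(acs, c(0.025, 0.975))
    ci[1] <= lam && lam <= ci[2]
  }))
  expect_gte(covered / 50, 0.9)
})

test_that("window variance and lag autocorrelation match brute force", {
  alt <- rep(c(1, -1), 10)
  expect_equal(lag_autocorrelation(alt, 1), -1, tolerance = 1e-12)
  expect_equal(lag_autocorrelation(alt, 0), 1)
  expect_true(is.na(lag_autocorrelation(rep(2, 10), 1)))
  expect_error(lag_autocorrelation(1:3, 2), "too short")

  set.seed(33)
  for (i in 1:10) {
    x <- rnorm(sample(20:60, 1))
    expect_equal(window_variance(x), mean((x - mean(x))^2))
    for (tau in 1:3)
      expect_equal(lag_autocorrelation(x, tau), oracle_lag_ac(x, tau),
                   tolerance = 1e-12)
  }
})

test_that("Kendall tau matches the pair-counting oracle", {
  expect_equal(kendall_tau(1:10), 1)
  expect_equal(kendall_tau(10:1), -1)
  expect_equal(kendall_tau(rep(5, 8)), 0)
  set.seed(34)
  for (i in 1:10) {
    x <- sample(rnorm(15), 20, replace = TRUE)  # ties likely
    expect_equal(kendall_tau(x), oracle_kendall_tau(x), tolerance = 1e-12)
  }
})

test_that("rolling pipeline produces coherent windows, CIs and trends", {
  sc <- make_scenario("fold_forced", seed = 3)
  cfg <- ews_config(n_bootstrap = 100, metrics = c("variance", "ac", "smax"),
                    seed = 5)
  ews <- compute_ews(sc$ts, cfg, truncation_time = sc$truncation_time)
  d <- as.data.frame(ews)

  w <- attr(ews, "window_length")
  expect_equal(w, round(0.4 * sum(sc$ts$times <= sc$truncation_time)))
  expect_true(all(d$time <= sc$truncation_time))
  expect_true(all(d$ci_lo <= d$boot_mean + 1e-12 &
                    d$boot_mean <= d$ci_hi + 1e-12))
  # point estimate inside its own bootstrap interval almost always
  expect_gte(mean(d$point >= d$ci_lo & d$point <= d$ci_hi), 0.9)
  taus <- attr(ews, "kendall_tau")
  expect_named(taus, c("variance", "ac_1", "ac_2", "smax"))
  expect_true(all(abs(taus) <= 1))
})

test_that("forced fold scenarios show rising autocorrelation; flip alternates by lag", {
  cfg <- ews_config(n_bootstrap = 0, metrics = c("variance", "ac", "smax"))
  fold_taus <- sapply(1:20, function(s) {
    sc <- make_scenario("fold_forced", seed = 500 + s)
    attr(compute_ews(sc$ts, cfg, sc$truncation_time), "kendall_tau")
  })
  expect_gte(mean(fold_taus["ac_1", ] > 0), 0.85)

  flip_taus <- sapply(1:20, function(s) {
    sc <- make_scenario("flip_forced", seed = 600 + s)
    attr(compute_ews(sc$ts, cfg, sc$truncation_time), "kendall_tau")
  })
  # lag 1 = half the incipient period 2: trend decreases; lag 2 increases
  expect_gte(mean(flip_taus["ac_1", ] < 0), 0.85)
  expect_gte(mean(flip_taus["ac_2", ] > 0), 0.85)
})

test_that("analytic flip autocorrelation alternates in sign with the lag", {
  sp <- bifurcation_spec("flip", lam = -0.95, sigma = 1)
  rho <- analytic_autocorrelation(sp, 0:6)
  expect_equal(sign(rho), c(1, -1, 1, -1, 1, -1, 1))
})

test_that("null scenarios carry no systematic trend", {
  cfg <- ews_config(n_bootstrap = 0, metrics = c("variance", "ac", "smax"))
  null_taus <- sapply(1:20, function(s) {
    sc <- make_scenario("fold_null", seed = 300 + s)
    attr(compute_ews(sc$ts, cfg, sc$truncation_time), "kendall_tau")
  })
  expect_true(all(abs(apply(null_taus, 1, median)) < 0.3))
})

test_that("S_max rises faster than variance before the flip bifurcation", {
  cfg <- ews_config(n_bootstrap = 0, metrics = c("variance", "smax"))
  wins <- sapply(1:20, function(s) {
    sc <- make_scenario("flip_forced", seed = 400 + s)
    d <- as.data.frame(compute_ews(sc$ts, cfg, sc$truncation_time))
    ft <- min(d$time); lt <- max(d$time)
    ratio <- function(m) d$point[d$time == lt & d$metric == m] /
      d$point[d$time == ft & d$metric == m]
    ratio("smax") > ratio("variance")
  })
  expect_gt(mean(wins), 0.5)
})

test_that("AIC-weight metrics flow through the bootstrap pipeline", {
  sc <- make_scenario("flip_forced", seed = 8)
  cfg <- ews_config(n_bootstrap = 8, window_step = 25,
                    metrics = c("smax", "aic_weights"), seed = 9)
  ews <- compute_ews(sc$ts, cfg, truncation_time = 300)
  d <- as.data.frame(ews)
  expect_setequal(unique(d$metric), c("smax", "w_fold", "w_hopf", "w_null"))
  ws <- d[startsWith(d$metric, "w_"), ]
  expect_true(all(ws$point >= 0 & ws$point <= 1))
  expect_true(all(ws$ci_lo <= ws$ci_hi))
  # weights sum to 1 within every window
  sums <- tapply(ws$point, ws$time, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("EWS outputs round-trip through CSV and JSON", {
  sc <- make_scenario("flip_forced", seed = 4)
  cfg <- ews_config(n_bootstrap = 10, metrics = c("variance", "smax"),
                    seed = 6)
  ews <- compute_ews(sc$ts, cfg, sc$truncation_time)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_ews_outputs(ews, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(back$point, as.data.frame(ews)$point, tolerance = 1e-12)
  summ <- jsonlite::read_json(js)
  expect_equal(summ$kendall_tau$variance,
               unname(attr(ews, "kendall_tau")["variance"]),
               tolerance = 1e-12)
  unlink(c(csv, js))
})
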