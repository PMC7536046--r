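# Independent brute-force oracles used to validate the package's fast paths.

# Kendall tau-b by O(n^2) pair counting against time order.
oracle_kendall_tau <- function(x) {
  n <- length(x)
  conc <- disc <- ties_x <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d <- x[j] - x[i]
      if (d > 0) conc <- conc + 1
      else if (d < 0) disc <- disc + 1
      else ties_x <- ties_x + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - ties_x) * n0)  # time index has no ties
}

# AUC as the Mann-Whitney probability by exhaustive pair counting.
oracle_auc <- function(forced, null) {
  s <- 0
  for (f in forced) for (g in null)
    s <- s + (f > g) + 0.5 * (f == g)
  s / (length(forced) * length(null))
}

# Lag-tau autocorrelation as the Pearson correlation of the lag-shifted
# subseries, written out as explicit sums.
oracle_lag_ac <- function(x, tau) {
  n <- length(x)
  a <- x[1:(n - tau)]
  b <- x[(1 + tau):n]
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# 1/n-normalized DFT power by direct O(n^2) summation.
oracle_periodogram <- function(x) {
  n <- length(x)
  sapply(1:n, function(k) {
    z <- sum(x * exp(2i * pi * (seq_len(n) - 1) * (k - 1) / n)) / n
    Mod(z)^2
  })
}

# Build a power_spectrum object from exact analytic values (for fit
# self-consistency tests).
make_exact_spectrum <- function(omegas, powers) {
  dom <- omegas[2] - omegas[1]
  structure(list(omegas = omegas, powers = powers, n_segments = 1L,
                 segment_length = 2L * length(omegas),
                 total_power = 2 * sum(powers) * dom, dt = 1),
            class = "power_spectrum")
}

# Random stable bifurcation specs for property tests.
random_spec <- function() {
  fam <- sample(c("fold", "transcritical", "pitchfork", "hopf",
                  "fold_d", "flip", "neimark_sacker"), 1)
  sigma <- runif(1, 0.2, 2)
  switch(fam,
    fold = bifurcation_spec("fold", "continuous",
                            lam = -runif(1, 0.05, 3), sigma = sigma),
    transcritical = bifurcation_spec("transcritical", "continuous",
                                     lam = -runif(1, 0.05, 3), sigma = sigma),
    pitchfork = bifurcation_spec("pitchfork", "continuous",
                                 lam = -runif(1, 0.05, 3), sigma = sigma),
    hopf = bifurcation_spec("hopf", mu = -runif(1, 0.05, 1),
                            omega0 = runif(1, 0.2, 2), sigma = sigma),
    fold_d = bifurcation_spec("fold", "discrete",
                              lam = runif(1, 0, 0.95), sigma = sigma),
    flip = bifurcation_spec("flip", lam = -runif(1, 0, 0.95), sigma = sigma),
    neimark_sacker = bifurcation_spec("neimark_sacker",
                                      r_mod = runif(1, 0, 0.95),
                                      theta = runif(1, 0.2, 2.9),
                                      sigma = sigma))
}

# Quadrature of the analytic spectrum over its full (two-sided) domain.
spectrum_integral <- function(spec) {
  f <- function(w) analytic_power_spectrum(spec, w)
  if (spec$time_domain == "continuous") {
    stats::integrate(f, -Inf, Inf, rel.tol = 1e-10, abs.tol = 0)$value
  } else {
    stats::integrate(f, -pi, pi, rel.tol = 1e-10, abs.tol = 0)$value
  }
}
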