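# Stochastic simulation of bifurcation normal forms.
#
# Continuous time uses Euler-Maruyama with additive noise; discrete time
# iterates the map with Gaussian innovations. Both reduce exactly to the
# deterministic skeleton at sigma = 0 and are reproducible from `seed`.

drift_continuous <- function(family, x, alpha, omega0) {
  switch(family,
    fold          = alpha - x^2,
    transcritical = alpha * x - x^2,
    pitchfork     = alpha * x - x^3,
    hopf = {
      # supercritical Hopf normal form in (x, y); alpha is the real part mu
      r2 <- x[1L]^2 + x[2L]^2
      c(alpha * x[1L] - omega0 * x[2L] - x[1L] * r2,
        omega0 * x[1L] + alpha * x[2L] - x[2L] * r2)
    },
    stop("unknown continuous family: ", family))
}

map_discrete <- function(family, x, alpha) {
  switch(family,
    fold          = x + alpha - x^2,
    transcritical = x + alpha * x - x^2,
    pitchfork     = x + alpha * x - x^3,
    flip          = -(1 + alpha) * x + x^3,
    stop("unknown discrete family: ", family))
}

blowup_stop <- function(t, bound) {
  stop(structure(
    class = c("ewspec_blowup", "error", "condition"),
    list(message = sprintf(
           "trajectory blow-up: |x| exceeded %g at t = %g", bound, t),
         call = sys.call(-1), time = t)))
}

#' Simulate a continuous-time bifurcation normal form
#'
#' Euler-Maruyama integration of the normal form of a local bifurcation with
#' additive white noise, e.g. \eqn{dx/dt = \alpha - x^2 + \sigma\xi(t)} for
#' the fold. The bifurcation parameter `alpha` may ramp in time. For the Hopf
#' family the state is two-dimensional (`alpha` is the real part \eqn{\mu} of
#' the eigenvalue pair, `omega0` the rotation frequency, isotropic noise on
#' both coordinates) and the first coordinate is returned as the observable.
#'
#' @param family `"fold"`, `"transcritical"`, `"pitchfork"` or `"hopf"`.
#' @param alpha Bifurcation parameter: a number or a [parameter_schedule()].
#' @param sigma Noise amplitude (Gaussian increments of s.d. `sigma*sqrt(dt)`).
#' @param dt Integration time step.
#' @param t_end Final time; the trajectory is returned on `seq(0, t_end, dt)`.
#' @param x0 Initial state (length 2 for `hopf`; a scalar is recycled).
#' @param seed Integer seed fixing the innovation stream.
#' @param omega0 Hopf rotation frequency (ignored otherwise).
#' @param blowup_bound Threshold on `|x|`; exceeding it raises an error of
#'   class `"ewspec_blowup"` carrying the first crossing time.
#' @return An [time_series()] with provenance metadata.
#' @examples
#' simulate_normal_form_continuous("fold", alpha = 1, sigma = 0.05,
#'                                 dt = 0.01, t_end = 10, x0 = 1, seed = 1)
#' @export
simulate_normal_form_continuous <- function(family, alpha, sigma, dt = 0.01,
                                            t_end, x0, seed = NULL,
                                            omega0 = 1, blowup_bound = 1e6) {
  family <- match.arg(family, c("fold", "transcritical", "pitchfork", "hopf"))
  stopifnot(dt > 0, t_end > 0, sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- round(t_end / dt)
  times <- (0:n) * dt
  dim_x <- if (family == "hopf") 2L else 1L
  x <- rep_len(as.numeric(x0), dim_x)
  out <- numeric(n + 1L)
  out[1L] <- x[1L]
  sq <- sigma * sqrt(dt)
  for (i in seq_len(n)) {
    a <- schedule_value(alpha, times[i])
    x <- x + drift_continuous(family, x, a, omega0) * dt +
      if (sq > 0) sq * stats::rnorm(dim_x) else 0
    if (!all(is.finite(x)) || max(abs(x)) > blowup_bound)
      blowup_stop(times[i + 1L], blowup_bound)
    out[i + 1L] <- x[1L]
  }
  time_series(times, out,
              meta = list(model = paste0("normal_form_continuous_", family),
                          sigma = sigma, dt = dt, seed = seed,
                          alpha = alpha, omega0 = omega0))
}

#' Simulate a discrete-time bifurcation normal form
#'
#' Iterates the map form of a local bifurcation with unit time step and
#' Gaussian innovations, e.g. \eqn{x_{t+1} = x_t + \alpha - x_t^2 +
#' \sigma\epsilon_t} for the fold. The flip family iterates
#' \eqn{x_{t+1} = -(1+\alpha)x_t + x_t^3} (multiplier \eqn{-(1+\alpha)} at the
#' origin, period doubling at \eqn{\alpha = 0}).
#'
#' @param family `"fold"`, `"transcritical"`, `"pitchfork"` or `"flip"`.
#' @param alpha Bifurcation parameter: a number or a [parameter_schedule()]
#'   over step index.
#' @param sigma Innovation standard deviation.
#' @param n_steps Number of map iterations.
#' @param x0 Initial state.
#' @param seed Integer seed.
#' @param blowup_bound As in [simulate_normal_form_continuous()].
#' @return An [time_series()] on times `0:n_steps`.
#' @export
simulate_normal_form_discrete <- function(family, alpha, sigma, n_steps, x0,
                                          seed = NULL, blowup_bound = 1e6) {
  family <- match.arg(family, c("fold", "transcritical", "pitchfork", "flip"))
  stopifnot(n_steps >= 1, sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  x <- as.numeric(x0)
  out <- numeric(n_steps + 1L)
  out[1L] <- x
  eps <- if (sigma > 0) stats::rnorm(n_steps, sd = sigma) else numeric(n_steps)
  for (i in seq_len(n_steps)) {
    a <- schedule_value(alpha, i - 1)
    x <- map_discrete(family, x, a) + if (sigma > 0) eps[i] else 0
    if (!is.finite(x) || abs(x) > blowup_bound) blowup_stop(i, blowup_bound)
    out[i + 1L] <- x
  }
  time_series(0:n_steps, out,
              meta = list(model = paste0("normal_form_discrete_", family),
                          sigma = sigma, seed = seed, alpha = alpha))
}

#' Synthetic chemostat-style fixture series
#'
#' Generates short stationary series at a set of fixed control-parameter
#' values approaching a Hopf bifurcation, emulating the structure of
#' predator-prey chemostat experiments (one series per dilution rate, damped
#' oscillations whose decay weakens as the bifurcation nears). Entirely
#' synthetic: intended for pipeline exercises and tests, not as a stand-in for
#' real chemostat measurements.
#'
#' @param mus Vector of (negative) real parts of the dominant eigenvalue pair,
#'   one per series, e.g. `seq(-0.5, -0.05, length.out = 5)`.
#' @param omega0 Oscillation frequency at onset (rad per day).
#' @param n_days Length of each series in days.
#' @param dt Sampling interval in days.
#' @param sigma Noise amplitude.
#' @param seed Integer seed.
#' @return Named list of [time_series()], one per value of `mus`.
#' @export
make_chemostat_fixture <- function(mus = seq(-0.5, -0.05, length.out = 5),
                                   omega0 = 1 / 3, n_days = 60, dt = 1,
                                   sigma = 0.1, seed = 1) {
  stopifnot(all(mus < 0))
  out <- lapply(seq_along(mus), function(i) {
    sim <- simulate_normal_form_continuous(
      "hopf", alpha = mus[i], sigma = sigma, dt = min(dt, 0.1) / 2,
      t_end = n_days, x0 = c(0, 0), seed = seed + i, omega0 = omega0)
    keep <- seq(1L, length(sim$values), by = round(dt / (min(dt, 0.1) / 2)))
    time_series(sim$times[keep], sim$values[keep],
                meta = list(model = "chemostat_fixture", mu = mus[i],
                            omega0 = omega0, seed = seed + i))
  })
  names(out) <- sprintf("mu=%g", mus)
  out
}
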