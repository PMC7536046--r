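# Harvested Ricker population model and its study scenarios.
#
# N_{t+1} = N_t * exp(r (1 - N_t/K) + sigma eps_t) - F N_t^2 / (N_t^2 + h^2)
#
# Increasing harvesting F drives a Fold bifurcation (population collapse);
# increasing growth rate r drives a Flip (period-doubling) bifurcation.

#' Parameters of the harvested Ricker model
#'
#' @param r Intrinsic growth rate.
#' @param K Carrying capacity (`> 0`).
#' @param F Maximum harvesting rate.
#' @param h Half-saturation constant of the harvesting term (`> 0`).
#' @param sigma Environmental noise amplitude (`>= 0`); the noise enters
#'   multiplicatively through the growth exponent.
#' @return Object of class `"ricker_params"`. Defaults are the baseline
#'   parametrization used throughout: `r = 0.75`, `K = 10`, `F = 0`,
#'   `h = 0.75`, `sigma = 0.04`.
#' @examples
#' ricker_params()
#' @export
ricker_params <- function(r = 0.75, K = 10, F = 0, h = 0.75, sigma = 0.04) {
  stopifnot(K > 0, h > 0, sigma >= 0)
  structure(list(r = r, K = K, F = F, h = h, sigma = sigma),
            class = "ricker_params")
}

# Deterministic map and its derivative in N (used for equilibria and
# bifurcation points).
ricker_map <- function(N, r, K, F, h) {
  N * exp(r * (1 - N / K)) - F * N^2 / (N^2 + h^2)
}

ricker_map_deriv <- function(N, r, K, F, h) {
  exp(r * (1 - N / K)) * (1 - r * N / K) - F * 2 * N * h^2 / (N^2 + h^2)^2
}

# Stable equilibrium reached from the carrying capacity under the
# deterministic skeleton (long iteration; scenarios start in the
# steady-state regime r < 2 where this converges).
ricker_equilibrium <- function(params, n_iter = 2000L) {
  N <- params$K
  for (i in seq_len(n_iter))
    N <- max(ricker_map(N, params$r, params$K, params$F, params$h), 0)
  N
}

#' Simulate the harvested Ricker model
#'
#' Iterates the stochastic Ricker map. Either parameter may follow a
#' [parameter_schedule()] (evaluated at the destination step, so a ramp over
#' `[0, n_steps]` attains its end value at the final state). Negative
#' population values arising from noise are reset to zero before the next
#' step.
#'
#' @param params A [ricker_params()].
#' @param r_schedule,F_schedule Optional schedules overriding `params$r` /
#'   `params$F`.
#' @param n_steps Number of iterations; the returned series holds the
#'   `n_steps` post-initial states at times `1:n_steps`.
#' @param N0 Initial population; defaults to the stable equilibrium of the
#'   initial parameter values (solved numerically).
#' @param seed Integer seed.
#' @return An [time_series()] with provenance metadata.
#' @examples
#' simulate_ricker(ricker_params(), n_steps = 100, seed = 1)
#' @export
simulate_ricker <- function(params = ricker_params(), r_schedule = NULL,
                            F_schedule = NULL, n_steps = 500, N0 = NULL,
                            seed = NULL) {
  stopifnot(inherits(params, "ricker_params"), n_steps >= 2)
  r_sched <- if (is.null(r_schedule)) params$r else r_schedule
  F_sched <- if (is.null(F_schedule)) params$F else F_schedule
  if (is.null(N0)) {
    p0 <- params
    p0$r <- schedule_value(r_sched, 0)
    p0$F <- schedule_value(F_sched, 0)
    N0 <- ricker_equilibrium(p0)
  }
  stopifnot(N0 >= 0)
  if (!is.null(seed)) set.seed(seed)
  eps <- if (params$sigma > 0) stats::rnorm(n_steps, sd = params$sigma)
         else numeric(n_steps)
  N <- N0
  out <- numeric(n_steps)
  for (t in seq_len(n_steps)) {
    r_t <- schedule_value(r_sched, t)
    F_t <- schedule_value(F_sched, t)
    N <- N * exp(r_t * (1 - N / params$K) + eps[t]) -
      F_t * N^2 / (N^2 + params$h^2)
    if (N < 0) N <- 0
    out[t] <- N
  }
  time_series(seq_len(n_steps), out,
              meta = list(model = "ricker", params = unclass(params),
                          r_schedule = r_sched, F_schedule = F_sched,
                          N0 = N0, seed = seed))
}

#' Bifurcation points of the deterministic Ricker skeleton
#'
#' Locates, by bracketing root-finding on the noise-free map:
#' * `F_fold`: the harvesting rate at which the upper stable equilibrium is
#'   destroyed in a saddle-node (Fold) bifurcation at the given `r`, found by
#'   solving the simultaneous fixed-point and tangency conditions
#'   \eqn{f(N) = N}, \eqn{f'(N) = 1} (harvesting is eliminated via the
#'   fixed-point condition and the tangency residual is solved in `N`; where
#'   several tangencies exist the one at the largest `F` — the collapse of the
#'   upper branch met as `F` increases — is returned);
#' * `r_flip`: the growth rate at which the positive equilibrium undergoes a
#'   Flip (period-doubling) bifurcation at `F = 0`, i.e. where the map
#'   derivative at the fixed point `N* = K` reaches `-1` (closed form
#'   `1 - r = -1`, solved numerically for consistency).
#'
#' Both roots are located to absolute tolerance 1e-9.
#'
#' @param params A [ricker_params()]; `sigma` is ignored.
#' @return List with `F_fold` and `r_flip`.
#' @examples
#' ricker_bifurcation_points(ricker_params()) # F_fold ~ 2.36, r_flip = 2
#' @export
ricker_bifurcation_points <- function(params = ricker_params()) {
  stopifnot(inherits(params, "ricker_params"))
  r <- params$r; K <- params$K; h <- params$h

  # F that makes N a fixed point, from f(N) = N
  F_of_N <- function(N) (N * exp(r * (1 - N / K)) - N) * (N^2 + h^2) / N^2
  tangency <- function(N) ricker_map_deriv(N, r, K, F_of_N(N), h) - 1
  grid <- seq(K * 1e-3, 1.5 * K, length.out = 4000L)
  tv <- vapply(grid, tangency, numeric(1))
  sign_change <- which(diff(sign(tv)) != 0 & is.finite(tv[-1]) &
                         is.finite(tv[-length(tv)]))
  if (!length(sign_change))
    stop("no fold bifurcation found in the searched range of N")
  folds <- vapply(sign_change, function(i) {
    N <- stats::uniroot(tangency, c(grid[i], grid[i + 1L]), tol = 1e-12)$root
    F_of_N(N)
  }, numeric(1))
  F_fold <- max(folds)

  # flip at F = 0: fixed point is N* = K, multiplier 1 - r
  flip_res <- function(rr) {
    Nstar <- K  # exact fixed point of the unharvested map
    ricker_map_deriv(Nstar, rr, K, 0, h) + 1
  }
  lo <- 0.5; hi <- 4
  if (flip_res(lo) * flip_res(hi) > 0)
    stop("no flip bifurcation found for r in [0.5, 4]")
  r_flip <- stats::uniroot(flip_res, c(lo, hi), tol = 1e-12)$root

  list(F_fold = F_fold, r_flip = r_flip)
}

#' Study scenarios for the Ricker model
#'
#' Builds the four 500-step scenarios used in the simulation experiments, all
#' at baseline parameters ([ricker_params()] defaults):
#' \describe{
#'   \item{`fold_forced`}{harvesting `F` ramps linearly 0 to 2.7 over the 500
#'     steps, crossing the Fold bifurcation at `F = 2.36` (step ~437).}
#'   \item{`fold_null`}{`F` held at 0.}
#'   \item{`flip_forced`}{growth rate `r` ramps linearly 0.5 to 2.3, crossing
#'     the Flip bifurcation at `r = 2.00` (step ~417).}
#'   \item{`flip_null`}{`r` held at 0.5.}
#' }
#' Null scenarios hold the ramped parameter at its initial ramp value. The
#' full series is returned; `truncation_time` marks the step (rounded) at
#' which the ramped parameter crosses the deterministic bifurcation value,
#' i.e. the point up to which early-warning statistics should be computed.
#' Null scenarios carry the truncation time of their forced counterpart so
#' that forced and null indicator series are directly comparable.
#'
#' @param name One of `"fold_forced"`, `"fold_null"`, `"flip_forced"`,
#'   `"flip_null"`.
#' @param seed Integer seed.
#' @param n_steps Scenario length in steps.
#' @return List with `ts` (an [time_series()]) and `truncation_time`.
#' @examples
#' sc <- make_scenario("fold_forced", seed = 1)
#' sc$truncation_time
#' @export
make_scenario <- function(name = c("fold_forced", "fold_null",
                                   "flip_forced", "flip_null"),
                          seed = NULL, n_steps = 500) {
  name <- match.arg(name)
  base <- ricker_params()
  bif <- ricker_bifurcation_points(base)
  if (startsWith(name, "fold")) {
    ramp <- parameter_schedule(0, 2.7, 0, n_steps)
    F_sched <- if (name == "fold_forced") ramp else ramp$start_value
    ts <- simulate_ricker(base, F_schedule = F_sched, n_steps = n_steps,
                          seed = seed)
    trunc <- round(schedule_crossing_time(ramp, bif$F_fold))
  } else {
    ramp <- parameter_schedule(0.5, 2.3, 0, n_steps)
    r_sched <- if (name == "flip_forced") ramp else ramp$start_value
    ts <- simulate_ricker(base, r_schedule = r_sched, n_steps = n_steps,
                          seed = seed)
    trunc <- round(schedule_crossing_time(ramp, bif$r_flip))
  }
  ts$meta$scenario <- name
  ts$meta$truncation_time <- trunc
  list(ts = ts, truncation_time = trunc)
}
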