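#' Describe a local codimension-1 bifurcation for analytic early-warning forms
#'
#' A `bifurcation_spec` parametrizes the linearized (Ornstein-Uhlenbeck)
#' dynamics about an equilibrium approaching a local codimension-1 bifurcation,
#' via its dominant eigenvalue(s) and additive-noise amplitude. It is the input
#' to [analytic_variance()], [analytic_autocorrelation()],
#' [analytic_power_spectrum()] and [analytic_smax()].
#'
#' Families and their eigenvalue parametrization:
#' \describe{
#'   \item{fold / transcritical / pitchfork, continuous time}{single real
#'     eigenvalue `lam` < 0, bifurcation at `lam` = 0.}
#'   \item{hopf (continuous time)}{complex pair `mu` +/- i `omega0`, `mu` < 0,
#'     `omega0` > 0; oscillation frequency at onset is `omega0`.}
#'   \item{fold / transcritical / pitchfork, discrete time}{real multiplier
#'     `lam` in [0, 1), bifurcation at `lam` = 1.}
#'   \item{flip (period doubling, discrete time)}{real multiplier `lam` in
#'     (-1, 0], bifurcation at `lam` = -1.}
#'   \item{neimark_sacker (discrete time)}{complex multiplier of modulus
#'     `r_mod` in [0, 1) and argument `theta`; bifurcation at `r_mod` = 1.}
#' }
#'
#' The three non-oscillatory families (fold, transcritical, pitchfork) share a
#' single analytic form in each time domain; the family is retained as
#' metadata. The Hopf / Neimark-Sacker per-coordinate noise amplitude is
#' identified with the scalar `sigma` (isotropic noise in both coordinates).
#'
#' @param family One of `"fold"`, `"transcritical"`, `"pitchfork"`, `"hopf"`,
#'   `"flip"`, `"neimark_sacker"`.
#' @param time_domain `"continuous"` or `"discrete"`. `hopf` is continuous
#'   only; `flip` and `neimark_sacker` are discrete only.
#' @param lam Dominant real eigenvalue (continuous non-oscillatory families)
#'   or real multiplier (discrete fold/transcritical/pitchfork/flip).
#' @param mu Real part of the complex eigenvalue pair (Hopf), `mu < 0`.
#' @param omega0 Imaginary part of the Hopf pair (rad per time unit), `> 0`.
#' @param r_mod Modulus of the Neimark-Sacker multiplier, in `[0, 1)`.
#' @param theta Argument of the Neimark-Sacker multiplier (rad).
#' @param sigma Additive white-noise amplitude, `> 0`.
#'
#' @return An object of class `"bifurcation_spec"`.
#' @examples
#' bifurcation_spec("fold", "continuous", lam = -0.5, sigma = 1)
#' bifurcation_spec("hopf", mu = -0.1, omega0 = 0.5, sigma = 0.2)
#' @export
bifurcation_spec <- function(family = c("fold", "transcritical", "pitchfork",
                                        "hopf", "flip", "neimark_sacker"),
                             time_domain = NULL,
                             lam = NULL, mu = NULL, omega0 = NULL,
                             r_mod = NULL, theta = NULL, sigma = 1) {
  family <- match.arg(family)
  if (is.null(time_domain)) {
    time_domain <- switch(family,
      hopf = "continuous",
      flip = ,
      neimark_sacker = "discrete",
      "continuous")
  }
  time_domain <- match.arg(time_domain, c("continuous", "discrete"))
  if (family == "hopf" && time_domain != "continuous")
    stop("hopf specs are continuous-time; use neimark_sacker for maps")
  if (family %in% c("flip", "neimark_sacker") && time_domain != "discrete")
    stop(sprintf("%s specs are discrete-time", family))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("sigma must be a positive finite scalar")

  kind <- spec_kind_of(family, time_domain)
  switch(kind,
    cont_real = {
      if (is.null(lam)) stop("lam is required for continuous ", family)
      if (lam >= 0)
        stop("at or beyond the bifurcation: need lam < 0, got ", lam)
    },
    hopf = {
      if (is.null(mu) || is.null(omega0))
        stop("mu and omega0 are required for hopf")
      if (mu >= 0) stop("at or beyond the bifurcation: need mu < 0, got ", mu)
      if (omega0 <= 0) stop("omega0 must be positive")
    },
    disc_real = {
      if (is.null(lam)) stop("lam is required for discrete ", family)
      if (family == "flip") {
        if (lam > 0 || lam <= -1)
          stop("at or beyond the bifurcation: flip needs -1 < lam <= 0, got ", lam)
      } else if (lam < 0 || lam >= 1) {
        stop("at or beyond the bifurcation: discrete ", family,
             " needs 0 <= lam < 1, got ", lam)
      }
    },
    ns = {
      if (is.null(r_mod) || is.null(theta))
        stop("r_mod and theta are required for neimark_sacker")
      if (r_mod < 0 || r_mod >= 1)
        stop("at or beyond the bifurcation: need 0 <= r_mod < 1, got ", r_mod)
    })

  structure(
    list(family = family, time_domain = time_domain, kind = kind,
         lam = lam, mu = mu, omega0 = omega0,
         r_mod = r_mod, theta = theta, sigma = sigma),
    class = "bifurcation_spec")
}

# Collapse family x time_domain to the four distinct analytic code paths.
spec_kind_of <- function(family, time_domain) {
  if (family == "hopf") return("hopf")
  if (family == "neimark_sacker") return("ns")
  if (time_domain == "continuous") return("cont_real")
  "disc_real"
}

#' @export
print.bifurcation_spec <- function(x, ...) {
  ev <- switch(x$kind,
    cont_real = sprintf("lambda = %g", x$lam),
    hopf = sprintf("mu = %g, omega0 = %g", x$mu, x$omega0),
    disc_real = sprintf("lambda = %g", x$lam),
    ns = sprintf("r = %g, theta = %g", x$r_mod, x$theta))
  cat(sprintf("<bifurcation_spec> %s (%s time), %s, sigma = %g\n",
              x$family, x$time_domain, ev, x$sigma))
  invisible(x)
}

#' Stationary variance of the linearized dynamics near a bifurcation
#'
#' Closed-form stationary variance of the Ornstein-Uhlenbeck (continuous time)
#' or linear autoregressive (discrete time) process obtained by linearizing a
#' system about its equilibrium:
#' \deqn{-\sigma^2/(2\lambda)} (continuous non-oscillatory),
#' \deqn{-\sigma^2/(2\mu)} (Hopf, one coordinate),
#' \deqn{\sigma^2/(1-\lambda^2)} (discrete real multiplier),
#' \deqn{\sigma^2/(1-r^2)} (Neimark-Sacker, one coordinate).
#'
#' @param spec A [bifurcation_spec()].
#' @return Positive scalar variance.
#' @examples
#' analytic_variance(bifurcation_spec("fold", lam = -0.5, sigma = 1)) # 1
#' @export
analytic_variance <- function(spec) {
  stopifnot(inherits(spec, "bifurcation_spec"))
  switch(spec$kind,
    cont_real = spec$sigma^2 / (-2 * spec$lam),
    hopf      = spec$sigma^2 / (-2 * spec$mu),
    disc_real = spec$sigma^2 / (1 - spec$lam^2),
    ns        = spec$sigma^2 / (1 - spec$r_mod^2))
}

#' Lag-tau autocorrelation of the linearized dynamics near a bifurcation
#'
#' Closed-form autocorrelation \eqn{\rho(\tau)} of the stationary linearized
#' process: \eqn{e^{\lambda|\tau|}} (continuous non-oscillatory),
#' \eqn{e^{\mu|\tau|}\cos(\omega_0\tau)} (Hopf), \eqn{\lambda^{|\tau|}}
#' (discrete real multiplier), \eqn{r^{|\tau|}\cos(\theta\tau)}
#' (Neimark-Sacker). For oscillatory families the sign of \eqn{\rho(\tau)}
#' depends on how the lag compares with the oscillation period
#' \eqn{T = 2\pi/\omega_0}: lags near \eqn{T/2} correlate peaks with troughs
#' and give negative, decreasing autocorrelation as the bifurcation nears.
#'
#' @param spec A [bifurcation_spec()].
#' @param tau Lag(s) in time units, `>= 0`; integers required in discrete time.
#' @return Autocorrelation value(s) in `[-1, 1]`, vectorized over `tau`.
#' @examples
#' sp <- bifurcation_spec("hopf", mu = -0.1, omega0 = 0.5)
#' analytic_autocorrelation(sp, 2 * pi / 0.5) # exp(-0.4*pi)
#' @export
analytic_autocorrelation <- function(spec, tau) {
  stopifnot(inherits(spec, "bifurcation_spec"), is.numeric(tau), all(tau >= 0))
  if (spec$time_domain == "discrete" && any(abs(tau - round(tau)) > 1e-9))
    stop("tau must be integer for discrete-time specs")
  at <- abs(tau)
  switch(spec$kind,
    cont_real = exp(spec$lam * at),
    hopf      = exp(spec$mu * at) * cos(spec$omega0 * tau),
    disc_real = ifelse(at == 0, 1, spec$lam^at),
    ns        = ifelse(at == 0, 1, spec$r_mod^at) * cos(spec$theta * tau))
}

#' Power spectral density of the linearized dynamics near a bifurcation
#'
#' Closed-form power spectrum \eqn{S(\omega)} of the stationary linearized
#' process, in the angular-frequency density convention: the integral of
#' \eqn{S} over its domain (the real line in continuous time, \eqn{(-\pi,\pi]}
#' in discrete time) equals the stationary variance. Forms:
#' \deqn{S(\omega) = \frac{\sigma^2}{2\pi}\frac{1}{\omega^2+\lambda^2}}
#' (continuous non-oscillatory, a Lorentzian centred at 0),
#' \deqn{S(\omega) = \frac{\sigma^2}{4\pi}\left[\frac{1}{(\omega-\omega_0)^2+\mu^2}
#'   + \frac{1}{(\omega+\omega_0)^2+\mu^2}\right]} (Hopf, Lorentzians at
#' \eqn{\pm\omega_0}),
#' \deqn{S(\omega) = \frac{\sigma^2}{2\pi}\frac{1}{1+\lambda^2-2\lambda\cos\omega}}
#' (discrete real multiplier), and the two-peak analogue at \eqn{\pm\theta} for
#' Neimark-Sacker.
#'
#' @param spec A [bifurcation_spec()].
#' @param omega Angular frequency (rad per time unit); any real value, the
#'   discrete-time forms being 2*pi-periodic. Vectorized.
#' @return Nonnegative spectral density value(s); symmetric in `omega`.
#' @examples
#' sp <- bifurcation_spec("fold", lam = -1, sigma = 1)
#' analytic_power_spectrum(sp, 0) # 1/(2*pi)
#' @export
analytic_power_spectrum <- function(spec, omega) {
  stopifnot(inherits(spec, "bifurcation_spec"), is.numeric(omega))
  s2 <- spec$sigma^2
  switch(spec$kind,
    cont_real = s2 / (2 * pi) / (omega^2 + spec$lam^2),
    hopf = s2 / (4 * pi) * (1 / ((omega - spec$omega0)^2 + spec$mu^2) +
                            1 / ((omega + spec$omega0)^2 + spec$mu^2)),
    disc_real = s2 / (2 * pi) / (1 + spec$lam^2 - 2 * spec$lam * cos(omega)),
    ns = s2 / (4 * pi) *
      (1 / (1 + spec$r_mod^2 - 2 * spec$r_mod * cos(omega - spec$theta)) +
       1 / (1 + spec$r_mod^2 - 2 * spec$r_mod * cos(omega + spec$theta))))
}

#' Peak of the analytic power spectrum (S_max)
#'
#' Location and height of the maximum of the analytic power spectrum over the
#' nonnegative frequency domain. The peak height is the S_max indicator: near
#' the bifurcation it scales like \eqn{\sigma^2/\mu^2}, against
#' \eqn{\sigma^2/\mu} for the variance, so halving the distance to the
#' bifurcation doubles the variance but quadruples S_max.
#'
#' Non-oscillatory families peak at \eqn{\omega = 0} (spectral reddening) and
#' the flip family at \eqn{\omega = \pi}; these are returned exactly. For the
#' Hopf and Neimark-Sacker two-Lorentzian forms, whose maximum has no simple
#' closed form, the peak is located by a dense grid search followed by
#' golden-section refinement.
#'
#' @param spec A [bifurcation_spec()].
#' @param n_grid Number of grid points for the oscillatory-family search.
#' @return List with `omega_peak` and `s_peak`.
#' @examples
#' analytic_smax(bifurcation_spec("fold", lam = -0.5, sigma = 1))
#' @export
analytic_smax <- function(spec, n_grid = 4096) {
  stopifnot(inherits(spec, "bifurcation_spec"))
  S <- function(w) analytic_power_spectrum(spec, w)
  if (spec$kind %in% c("cont_real", "disc_real")) {
    # fold/TC/PF peak at 0; flip (lam < 0) peaks at pi, lam = 0 is flat
    if (spec$kind == "disc_real" && spec$family == "flip" && spec$lam < 0)
      return(list(omega_peak = pi, s_peak = S(pi)))
    return(list(omega_peak = 0, s_peak = S(0)))
  }
  w_max <- if (spec$kind == "hopf") {
    2 * spec$omega0 + 10 * abs(spec$mu) + 1
  } else pi
  grid <- seq(0, w_max, length.out = n_grid)
  i <- which.max(S(grid))
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  if (lo == hi) return(list(omega_peak = grid[i], s_peak = S(grid[i])))
  opt <- stats::optimize(S, c(lo, hi), maximum = TRUE, tol = 1e-12)
  # the boundary omega = 0 can beat the interior refinement
  if (S(0) >= opt$objective) return(list(omega_peak = 0, s_peak = S(0)))
  list(omega_peak = opt$maximum, s_peak = opt$objective)
}

#' Oscillation period implied by an angular frequency
#'
#' Converts the dominant angular frequency read off a power spectrum (e.g. the
#' Hopf `omega0` of a fitted spectral form) into the period of the oscillations
#' expected at the bifurcation, \eqn{T = 2\pi/\omega_0}.
#'
#' @param omega0 Positive angular frequency (rad per time unit).
#' @return Period in the same time units.
#' @examples
#' oscillation_period(1 / 3) # about 19 time units
#' @export
oscillation_period <- function(omega0) {
  stopifnot(is.numeric(omega0), all(omega0 > 0))
  2 * pi / omega0
}
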