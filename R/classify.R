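# Bifurcation-type classification: fit the canonical continuous-time spectral
# forms (fold Lorentzian, Hopf double Lorentzian, flat null) to an estimated
# spectrum and turn the AIC scores into normalized Akaike weights.

spectral_form <- function(form, omega, pars) {
  switch(form,
    fold = pars[["sigma"]]^2 / (2 * pi) / (omega^2 + pars[["lam"]]^2),
    hopf = pars[["sigma"]]^2 / (4 * pi) *
      (1 / ((omega - pars[["omega0"]])^2 + pars[["mu"]]^2) +
       1 / ((omega + pars[["omega0"]])^2 + pars[["mu"]]^2)),
    null = rep(pars[["sigma"]]^2 / (2 * pi), length(omega)),
    stop("unknown spectral form: ", form))
}

n_form_params <- c(fold = 2L, hopf = 3L, null = 1L)

# Half-width (in omega) at half the peak power; crude but serviceable
# initializer for the decay-rate parameters.
half_width <- function(omegas, powers) {
  i <- which.max(powers)
  above <- powers >= powers[i] / 2
  w <- diff(range(omegas[above]))
  max(w / 2, omegas[2L] - omegas[1L])
}

aic_from_rss <- function(rss, n, k, rss_floor, aicc = FALSE) {
  rss_eff <- max(rss, rss_floor, 1e-300)
  aic <- n * log(rss_eff / n) + 2 * k
  if (aicc) {
    if (n - k - 1 <= 0) return(Inf)
    aic <- aic + 2 * k * (k + 1) / (n - k - 1)
  }
  aic
}

#' Fit a canonical spectral form to an estimated power spectrum
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt, on linear power
#' values) of one of the canonical forms to the (omega, power) pairs of a
#' spectrum estimate:
#' \deqn{S_{fold}(\omega;\sigma,\lambda) = \frac{\sigma^2}{2\pi}\frac{1}{\omega^2+\lambda^2}}
#' \deqn{S_{hopf}(\omega;\sigma,\mu,\omega_0) = \frac{\sigma^2}{4\pi}\left[
#'   \frac{1}{(\omega-\omega_0)^2+\mu^2} + \frac{1}{(\omega+\omega_0)^2+\mu^2}\right]}
#' \deqn{S_{null}(\omega;\sigma) = \frac{\sigma^2}{2\pi}}
#' The null fit is the exact flat least-squares solution. The fold and Hopf
#' fits are initialized from the empirical peak (peak frequency for
#' \eqn{\omega_0}, spectral half-width at half maximum for the decay rates)
#' and restarted from perturbed initializations, keeping the best residual
#' sum of squares. The Hopf \eqn{\omega_0} is constrained to at least twice
#' the frequency resolution so the fit cannot degenerate into the fold form.
#'
#' Detrending and per-segment mean removal suppress spectral power within the
#' taper main lobe around zero frequency; beyond the DC bin (which
#' [welch_spectrum()] already drops), the `dc_guard` lowest bins are excluded
#' from the fit so this artifact is not mistaken for an off-zero spectral
#' peak.
#'
#' @param est A `"power_spectrum"` from [welch_spectrum()] with at least 8
#'   bins.
#' @param form `"fold"`, `"hopf"` or `"null"`.
#' @param n_starts Number of multi-start initializations (fold/hopf).
#' @param aicc Apply the small-sample AIC correction (recommended when the
#'   number of bins is small relative to the parameter count).
#' @param dc_guard Number of additional lowest-frequency bins excluded from
#'   the fit as detrending artifacts.
#' @return Object of class `"spectrum_fit"`: list with `form`, the fitted
#'   parameters (`sigma_hat` and, per form, `lam_hat` or
#'   `mu_hat`/`omega0_hat`), `rss`, `n_points`, `aic`, `converged`. A fit in
#'   which no start converges is flagged with `aic = Inf`.
#' @examples
#' est <- welch_spectrum(rnorm(256))
#' fit_form(est, "null")
#' @export
fit_form <- function(est, form = c("fold", "hopf", "null"), n_starts = 3,
                     aicc = FALSE, dc_guard = 1L) {
  form <- match.arg(form)
  stopifnot(inherits(est, "power_spectrum"), dc_guard >= 0)
  keep <- seq_along(est$omegas) > dc_guard
  omega <- est$omegas[keep]
  y <- est$powers[keep]
  n <- length(y)
  if (n < 8L) stop("need at least 8 spectral bins to fit")
  rss_floor <- 1e-12 * est$total_power
  k <- n_form_params[[form]]

  finish <- function(pars, rss, converged) {
    out <- list(form = form,
                sigma_hat = unname(pars[["sigma"]]),
                lam_hat = if (form == "fold") unname(pars[["lam"]]),
                mu_hat = if (form == "hopf") unname(pars[["mu"]]),
                omega0_hat = if (form == "hopf") unname(pars[["omega0"]]),
                rss = rss, n_points = n, k = k, rss_floor = rss_floor,
                aicc = aicc, converged = converged)
    out$aic <- if (converged) aic_from_rss(rss, n, k, rss_floor, aicc) else Inf
    class(out) <- "spectrum_fit"
    out
  }

  if (form == "null") {
    cbar <- mean(y)
    return(finish(c(sigma = sqrt(2 * pi * max(cbar, 0))),
                  sum((y - cbar)^2), TRUE))
  }

  ymax <- max(y)
  if (ymax <= 0) {  # degenerate all-zero spectrum: sigma = 0 fits exactly
    pars <- if (form == "fold") c(sigma = 0, lam = -1)
            else c(sigma = 0, mu = -1, omega0 = omega[which.max(y)])
    return(finish(pars, sum(y^2), TRUE))
  }
  dom <- omega[2L] - omega[1L]
  hw <- half_width(omega, y)
  w_peak <- omega[which.max(y)]
  w_hi <- max(omega)

  if (form == "fold") {
    lower <- c(sigma = 1e-12, lam = -1e6)
    upper <- c(sigma = Inf, lam = -1e-9)
    make_start <- function(f) {
      lam0 <- -hw * f
      c(sigma = sqrt(2 * pi * ymax) * abs(lam0), lam = lam0)
    }
  } else {
    w0_min <- 2 * dom
    lower <- c(sigma = 1e-12, mu = -1e6, omega0 = w0_min)
    upper <- c(sigma = Inf, mu = -1e-9, omega0 = w_hi)
    make_start <- function(f) {
      mu0 <- -hw * f
      w00 <- min(max(w_peak, w0_min), w_hi)
      c(sigma = sqrt(4 * pi * ymax) * abs(mu0), mu = mu0, omega0 = w00)
    }
  }

  resid_fn <- function(p) spectral_form(form, omega, p) - y
  best <- NULL
  factors <- c(1, 1 / 3, 3, 1 / 10, 10)[seq_len(max(1L, n_starts))]
  for (f in factors) {
    st <- pmin(pmax(make_start(f), lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || !all(is.finite(fit$par))) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) {
    pars <- make_start(1)
    return(finish(pars, sum(resid_fn(pars)^2), FALSE))
  }
  finish(best$par, best$rss, TRUE)
}

#' @export
print.spectrum_fit <- function(x, ...) {
  pars <- switch(x$form,
    fold = sprintf("sigma = %.4g, lambda = %.4g", x$sigma_hat, x$lam_hat),
    hopf = sprintf("sigma = %.4g, mu = %.4g, omega0 = %.4g",
                   x$sigma_hat, x$mu_hat, x$omega0_hat),
    null = sprintf("sigma = %.4g", x$sigma_hat))
  cat(sprintf("<spectrum_fit> %s: %s; rss = %.4g, AIC = %.4g\n",
              x$form, pars, x$rss, x$aic))
  invisible(x)
}

#' AIC of a fitted spectral form
#'
#' AIC under a Gaussian residual likelihood on linear power values:
#' \eqn{AIC = n\,\ln(rss/n) + 2k}, with `k` = 2 (fold), 3 (hopf), 1 (null)
#' parameters. A residual floor of `1e-12 * total_power` guards against a
#' perfect fit producing `-Inf`. With `aicc = TRUE` at fit time the
#' small-sample correction `2k(k+1)/(n-k-1)` is added.
#'
#' @param fit A `"spectrum_fit"` from [fit_form()].
#' @return The AIC (`Inf` for a fit flagged as non-converged).
#' @export
aic_of_fit <- function(fit) {
  stopifnot(inherits(fit, "spectrum_fit"))
  if (!fit$converged) return(Inf)
  aic_from_rss(fit$rss, fit$n_points, fit$k, fit$rss_floor, fit$aicc)
}

#' Akaike weights of competing spectral forms
#'
#' Normalized relative support \eqn{w_i = e^{-\Delta_i/2} / \sum_j
#' e^{-\Delta_j/2}} with \eqn{\Delta_i = AIC_i - \min_j AIC_j}. Invariant
#' under adding a constant to all AICs; an infinite AIC receives weight 0.
#'
#' @param aics Numeric vector of three AICs, in the order fold, hopf, null
#'   (or named with those names); at least one must be finite.
#' @return Object of class `"aic_weights"`: list with `w_fold`, `w_hopf`,
#'   `w_null` summing to 1.
#' @examples
#' akaike_weights(c(fold = 10, hopf = 12, null = 12))
#' @export
akaike_weights <- function(aics) {
  stopifnot(is.numeric(aics), length(aics) == 3L)
  if (!is.null(names(aics))) aics <- aics[c("fold", "hopf", "null")]
  if (!any(is.finite(aics))) stop("at least one AIC must be finite")
  delta <- aics - min(aics[is.finite(aics)])
  w <- exp(-delta / 2)
  w[!is.finite(aics)] <- 0
  w <- w / sum(w)
  structure(list(w_fold = w[[1L]], w_hopf = w[[2L]], w_null = w[[3L]]),
            class = "aic_weights")
}

#' @export
print.aic_weights <- function(x, ...) {
  cat(sprintf("<aic_weights> fold %.3f | hopf %.3f | null %.3f\n",
              x$w_fold, x$w_hopf, x$w_null))
  invisible(x)
}

#' Classify the bifurcation type of a stationary window
#'
#' Composition of [welch_spectrum()], [fit_form()] for the three canonical
#' forms, and [akaike_weights()]: estimates the spectrum of a (detrended)
#' window and reports which spectral form — reddened fold Lorentzian,
#' oscillatory Hopf double Lorentzian, or flat white-noise null — most
#' parsimoniously describes it. A dominant `w_hopf` with fitted
#' \eqn{\hat\omega_0 \approx \pi} is the signature of an approaching Flip
#' bifurcation in unit-step data (oscillations of period 2).
#'
#' @param x An [time_series()] or numeric vector (a detrended, approximately
#'   stationary window).
#' @param segment_length,overlap_fraction,window Passed to [welch_spectrum()].
#' @param n_starts,aicc,dc_guard Passed to [fit_form()]; the small-sample AIC
#'   correction is on by default, matching the short spectra (about 19 bins)
#'   of rolling-window use.
#' @return List with `weights` (an `"aic_weights"`), `fits` (named list of
#'   the three `"spectrum_fit"`s) and `spectrum` (the `"power_spectrum"`).
#' @examples
#' classify_window(rnorm(256))
#' @export
classify_window <- function(x, segment_length = NULL, overlap_fraction = 0.5,
                            window = "hamming", n_starts = 3, aicc = TRUE,
                            dc_guard = 1L) {
  est <- welch_spectrum(x, segment_length = segment_length,
                        overlap_fraction = overlap_fraction, window = window)
  fits <- lapply(c(fold = "fold", hopf = "hopf", null = "null"), function(f)
    fit_form(est, f, n_starts = n_starts, aicc = aicc, dc_guard = dc_guard))
  w <- akaike_weights(vapply(fits, aic_of_fit, numeric(1)))
  list(weights = w, fits = fits, spectrum = est)
}

#' Export spectral fits and weights as a JSON record
#'
#' @param cls Result of [classify_window()].
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_classification_json <- function(cls, path) {
  w <- c(fold = cls$weights$w_fold, hopf = cls$weights$w_hopf,
         null = cls$weights$w_null)
  rec <- lapply(names(cls$fits), function(f) {
    ft <- cls$fits[[f]]
    out <- list(form = f, sigma = ft$sigma_hat, rss = ft$rss,
                aic = aic_of_fit(ft), weight = unname(w[[f]]))
    if (f == "fold") out$lam <- ft$lam_hat
    if (f == "hopf") { out$mu <- ft$mu_hat; out$omega0 <- ft$omega0_hat }
    out
  })
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
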