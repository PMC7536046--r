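# Power-spectrum estimation: 1/n-normalized periodogram and Welch averaging,
# rescaled to the angular-frequency density convention of the analytic forms
# (integral of the two-sided spectrum = sample variance).

#' Raw periodogram of a segment
#'
#' Computes \eqn{P(k) = |\tilde x(k)|^2} with the 1/n-normalized discrete
#' Fourier transform \eqn{\tilde x(k) = (1/n)\sum_j x_j e^{2\pi i (j-1)(k-1)/n}}.
#' Under this convention Parseval's identity reads
#' \eqn{\sum_k P(k) = (1/n)\sum_j x_j^2}. The segment is expected to have had
#' its mean removed by the caller.
#'
#' @param x Numeric vector, length `>= 4`.
#' @return Numeric vector of raw powers, one per DFT bin (length `n`).
#' @examples
#' n <- 64
#' periodogram(cos(2 * pi * (0:(n - 1)) * 5 / n)) # 1/4 at bins 6 and 60
#' @export
periodogram <- function(x) {
  n <- length(x)
  if (n < 4L) stop("segment too short for a periodogram (need >= 4 points)")
  if (anyNA(x)) stop("segment contains missing values")
  Mod(stats::fft(x) / n)^2
}

taper_window <- function(window, n) {
  j <- seq_len(n) - 1L
  switch(window,
    hamming = 0.54 - 0.46 * cos(2 * pi * j / (n - 1)),
    hann    = 0.5 - 0.5 * cos(2 * pi * j / (n - 1)),
    none    = rep(1, n),
    stop("unknown taper: ", window))
}

#' Welch estimate of the power spectrum
#'
#' Averages tapered periodograms over overlapping segments, then rescales to
#' a spectral density over angular frequency such that the integral of the
#' symmetric two-sided extension over \eqn{(-\pi/dt, \pi/dt]} equals the
#' sample variance of the input (denominator `n`), matching the normalization
#' of the analytic spectra. The DC bin is excluded (the series is detrended
#' upstream, making it an artifact); frequencies are reported on
#' \eqn{(0, \pi/dt]}.
#'
#' Defaults: Hamming taper, 50% overlap, 40-point segments (the standard
#' choice in rolling-window EWS practice, averaging ~8 periodograms on a
#' 175-point window), capped at half the input and shrunk if needed so that
#' at least 3 segments are averaged.
#'
#' @param x An [time_series()] or a plain numeric vector (unit time step).
#' @param segment_length Segment length in points; `NULL` for the default.
#' @param overlap_fraction Fractional overlap between consecutive segments,
#'   in `[0, 1)`.
#' @param window Taper: `"hamming"`, `"hann"` or `"none"`.
#' @return Object of class `"power_spectrum"`: list with `omegas` (increasing
#'   grid in `(0, pi/dt]`), `powers` (densities), `n_segments`,
#'   `segment_length`, `total_power` (the sample variance) and `dt`.
#' @examples
#' welch_spectrum(rnorm(512))
#' @export
welch_spectrum <- function(x, segment_length = NULL, overlap_fraction = 0.5,
                           window = c("hamming", "hann", "none")) {
  window <- match.arg(window)
  dt <- 1
  if (inherits(x, "ews_ts")) {
    dt <- ts_dt(x)
    x <- x$values
  }
  L <- length(x)
  if (L < 8L) stop("series too short for a Welch estimate (need >= 8 points)")
  if (!(overlap_fraction >= 0 && overlap_fraction < 1))
    stop("overlap_fraction must be in [0, 1)")

  n_segments_for <- function(seg) {
    step <- max(1L, round(seg * (1 - overlap_fraction)))
    1L + (L - seg) %/% step
  }
  if (is.null(segment_length)) {
    seg <- min(40L, ceiling(L / 2))
    while (seg > 8L && n_segments_for(seg) < 3L) seg <- seg - 1L
  } else {
    seg <- as.integer(segment_length)
    if (seg > L) stop("segment_length exceeds series length")
    if (seg < 8L) stop("segment_length too small (need >= 8)")
  }
  step <- max(1L, round(seg * (1 - overlap_fraction)))
  starts <- seq(1L, L - seg + 1L, by = step)
  w <- taper_window(window, seg)
  w2 <- mean(w^2)

  pbar <- numeric(seg)
  for (s in starts) {
    xs <- x[s:(s + seg - 1L)]
    xs <- (xs - mean(xs)) * w
    pbar <- pbar + periodogram(xs) / w2
  }
  pbar <- pbar / length(starts)

  # one-sided bins, DC excluded, up to and including Nyquist
  half <- seg %/% 2L
  ks <- 2:(half + 1L)
  omegas <- 2 * pi * (ks - 1L) / seg
  dens <- pbar[ks] * seg / (2 * pi)

  # exact variance normalization of the two-sided extension
  dom <- 2 * pi / seg
  at_pi <- abs(omegas - pi) < 1e-12
  integral <- dom * (2 * sum(dens[!at_pi]) + sum(dens[at_pi]))
  v <- mean((x - mean(x))^2)
  if (integral > 0 && v > 0) dens <- dens * (v / integral) else dens[] <- 0

  structure(list(omegas = omegas / dt, powers = dens * dt,
                 n_segments = length(starts), segment_length = seg,
                 total_power = v, dt = dt),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(
    "<power_spectrum> %d bins on (0, %.4g], %d segment(s) of %d, variance %.4g\n",
    length(x$omegas), max(x$omegas), x$n_segments, x$segment_length,
    x$total_power))
  invisible(x)
}

#' @export
as.data.frame.power_spectrum <- function(x, ...) {
  data.frame(omega = x$omegas, power = x$powers)
}

#' Spectral peak (S_max) of an estimated spectrum
#'
#' Returns the bin of maximal estimated power, the S_max early-warning
#' indicator. Ties are broken toward the lowest frequency.
#'
#' @param est A `"power_spectrum"` from [welch_spectrum()].
#' @return List with `omega_peak` and `s_peak`.
#' @export
smax <- function(est) {
  stopifnot(inherits(est, "power_spectrum"), length(est$powers) > 0L)
  i <- which.max(est$powers)
  list(omega_peak = est$omegas[i], s_peak = est$powers[i])
}

#' Write a power spectrum estimate to CSV
#'
#' @param est A `"power_spectrum"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(est, path) {
  utils::write.csv(format(as.data.frame(est), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
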