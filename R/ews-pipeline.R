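# Rolling-window early-warning-signal pipeline: Lowess detrending, window
# metrics (variance, lag autocorrelation, S_max, AIC weights), stationary
# block-bootstrap confidence intervals and Kendall tau trend statistics.

#' Configuration of the rolling-window EWS pipeline
#'
#' @param window_fraction Rolling-window length as a fraction of the
#'   (truncated) series, in `(0, 1]`; the classic choice is 0.4.
#' @param window_step Steps between consecutive window ends.
#' @param lowess_span Lowess smoother span as a fraction of the series.
#' @param lowess_span_time Alternative absolute span in time units (e.g. 80
#'   days for daily chemostat-style data); overrides `lowess_span` when set.
#' @param ac_lags Positive integer lags at which autocorrelation is computed.
#' @param n_bootstrap Number of stationary-block-bootstrap resamples per
#'   window (0 disables bootstrap summaries).
#' @param mean_block_length Mean geometric block length; `NULL` selects, per
#'   window, the smallest lag at which the sample ACF drops below 1/e,
#'   bounded to `[5, 40]`, so that significant temporal correlation is
#'   retained in the resamples.
#' @param welch Named list of overrides for [welch_spectrum()]
#'   (`segment_length`, `overlap_fraction`, `window`).
#' @param metrics Which metrics to compute: any of `"variance"`, `"ac"`,
#'   `"smax"`, `"aic_weights"`.
#' @param seed Integer seed for the bootstrap streams.
#' @param n_starts,aicc Passed to [fit_form()] when `"aic_weights"` is on.
#' @return Object of class `"ews_config"`.
#' @export
ews_config <- function(window_fraction = 0.4, window_step = 10,
                       lowess_span = 0.2, lowess_span_time = NULL,
                       ac_lags = c(1L, 2L), n_bootstrap = 100,
                       mean_block_length = NULL, welch = list(),
                       metrics = c("variance", "ac", "smax", "aic_weights"),
                       seed = NULL, n_starts = 3, aicc = TRUE) {
  stopifnot(window_fraction > 0, window_fraction <= 1, window_step >= 1,
            all(ac_lags >= 1), n_bootstrap >= 0)
  metrics <- match.arg(metrics, several.ok = TRUE)
  structure(list(window_fraction = window_fraction,
                 window_step = as.integer(window_step),
                 lowess_span = lowess_span,
                 lowess_span_time = lowess_span_time,
                 ac_lags = as.integer(ac_lags),
                 n_bootstrap = as.integer(n_bootstrap),
                 mean_block_length = mean_block_length,
                 welch = welch, metrics = metrics, seed = seed,
                 n_starts = n_starts, aicc = aicc),
            class = "ews_config")
}

#' Lowess detrending
#'
#' Removes slow drift with a locally weighted linear smoother
#' ([stats::lowess()]), returning both the trend and the residuals on which
#' all EWS are computed.
#'
#' @param ts An [time_series()].
#' @param span Smoother span as a fraction of the series length.
#' @param span_time Absolute span in time units (e.g. 80 for an 80-day span
#'   on daily data); overrides `span` when given.
#' @return List with `trend` and `residuals`, both [time_series()].
#' @examples
#' sc <- make_scenario("fold_forced", seed = 1)
#' d <- lowess_detrend(sc$ts)
#' @export
lowess_detrend <- function(ts, span = 0.2, span_time = NULL) {
  stopifnot(inherits(ts, "ews_ts"))
  if (!is.null(span_time)) {
    total <- diff(range(ts$times))
    span <- span_time / total
  }
  n <- length(ts$values)
  if (span * n < 3) stop("lowess span too small: fewer than 3 points per fit")
  span <- min(span, 1)
  sm <- stats::lowess(ts$times, ts$values, f = span)
  trend <- sm$y
  time_meta <- c(ts$meta, list(lowess_span = span))
  list(trend = time_series(ts$times, trend, time_meta),
       residuals = time_series(ts$times, ts$values - trend, time_meta))
}

#' Stationary block bootstrap
#'
#' Resamples a segment by concatenating blocks whose start positions are
#' uniform on the segment and whose lengths are geometric with the given
#' mean, with circular wrap-around; each resample has the original length.
#' With a mean block length much larger than the segment, every resample is a
#' circular rotation of the input.
#'
#' @param x Numeric vector (a stationary window of residuals).
#' @param mean_block_length Mean geometric block length, `>= 1`.
#' @param n_samples Number of resamples.
#' @param seed Optional integer seed.
#' @return List of numeric vectors, each of `length(x)`.
#' @export
stationary_block_bootstrap <- function(x, mean_block_length, n_samples,
                                       seed = NULL) {
  stopifnot(mean_block_length >= 1, n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  p <- 1 / mean_block_length
  lapply(seq_len(n_samples), function(i) {
    idx <- integer(0)
    while (length(idx) < n) {
      start <- sample.int(n, 1L)
      g <- suppressWarnings(stats::rgeom(1L, p))  # NA on integer overflow
      len <- if (is.na(g)) n - length(idx) else min(g + 1L, n - length(idx))
      idx <- c(idx, ((start - 1L) + 0:(len - 1L)) %% n + 1L)
    }
    x[idx]
  })
}

# Data-driven default block length: first lag where the sample ACF drops
# below 1/e, bounded to [5, 40].
default_block_length <- function(x, lower = 5, upper = 40) {
  n <- length(x)
  if (stats::sd(x) == 0) return(lower)
  ac <- stats::acf(x, lag.max = min(n - 2L, upper + 10L), plot = FALSE,
                   demean = TRUE)$acf[-1L]
  k <- which(ac < exp(-1))[1L]
  if (is.na(k)) k <- upper
  min(max(k, lower), upper)
}

#' Sample variance of a window
#'
#' Sample variance with denominator `n`, the convention under which the
#' two-sided spectral estimate integrates exactly to the variance.
#'
#' @param x Numeric vector.
#' @return Nonnegative scalar.
#' @export
window_variance <- function(x) {
  mean((x - mean(x))^2)
}

#' Lag-tau sample autocorrelation of a window
#'
#' Pearson correlation between the window and its lag-shifted copy,
#' `cor(x[1:(n-tau)], x[(1+tau):n])`. This is the estimator used in common
#' EWS practice; it is exactly -1 for an alternating sequence and bounded in
#' `[-1, 1]`. A constant window has undefined autocorrelation and yields
#' `NA`.
#'
#' @param x Numeric vector, `length(x) > tau + 1`.
#' @param tau Nonnegative integer lag.
#' @return Autocorrelation in `[-1, 1]`, or `NA` for a constant window.
#' @export
lag_autocorrelation <- function(x, tau) {
  stopifnot(tau >= 0, tau == round(tau))
  n <- length(x)
  if (n <= tau + 1) stop("window too short for lag ", tau)
  if (tau == 0) return(1)
  a <- x[1:(n - tau)]
  b <- x[(1 + tau):n]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Kendall tau trend statistic
#'
#' Tie-corrected Kendall rank correlation (tau-b) of a metric series against
#' time order; the standard measure of increasing or decreasing trend in an
#' early-warning indicator. An all-tied series returns 0 by convention.
#'
#' @param x Numeric vector of metric values, ordered by time (`>= 3` values;
#'   `NA`s are dropped).
#' @return Kendall tau in `[-1, 1]`.
#' @export
kendall_tau <- function(x) {
  t_idx <- seq_along(x)
  ok <- !is.na(x)
  x <- x[ok]; t_idx <- t_idx[ok]
  if (length(x) < 3L) stop("need at least 3 points for a trend")
  if (length(unique(x)) == 1L) return(0)
  stats::cor(x, t_idx, method = "kendall")
}

metric_names <- function(config) {
  nm <- character(0)
  if ("variance" %in% config$metrics) nm <- c(nm, "variance")
  if ("ac" %in% config$metrics)
    nm <- c(nm, paste0("ac_", config$ac_lags))
  if ("smax" %in% config$metrics) nm <- c(nm, "smax")
  if ("aic_weights" %in% config$metrics)
    nm <- c(nm, "w_fold", "w_hopf", "w_null")
  nm
}

# All requested point metrics of one detrended window. Returns a named
# numeric vector; `extras` additionally captures the spectral peak frequency.
window_metrics <- function(x, config, extras = FALSE) {
  out <- c()
  if ("variance" %in% config$metrics) out <- c(out, variance = window_variance(x))
  if ("ac" %in% config$metrics)
    for (lag in config$ac_lags)
      out[paste0("ac_", lag)] <- lag_autocorrelation(x, lag)
  need_spec <- any(c("smax", "aic_weights") %in% config$metrics)
  omega_peak <- NA_real_
  if (need_spec) {
    est <- tryCatch(do.call(welch_spectrum, c(list(x), config$welch)),
                    error = function(e) NULL)
    if ("smax" %in% config$metrics) {
      if (!is.null(est)) {
        pk <- smax(est)
        out["smax"] <- pk$s_peak
        omega_peak <- pk$omega_peak
      } else out["smax"] <- NA_real_
    }
    if ("aic_weights" %in% config$metrics) {
      w <- if (!is.null(est) && est$total_power > 0) {
        tryCatch({
          fits <- lapply(c("fold", "hopf", "null"), function(f)
            fit_form(est, f, n_starts = config$n_starts, aicc = config$aicc))
          akaike_weights(vapply(fits, aic_of_fit, numeric(1)))
        }, error = function(e) NULL)
      }
      out["w_fold"] <- if (is.null(w)) NA_real_ else w$w_fold
      out["w_hopf"] <- if (is.null(w)) NA_real_ else w$w_hopf
      out["w_null"] <- if (is.null(w)) NA_real_ else w$w_null
    }
  }
  if (extras) attr(out, "omega_peak") <- omega_peak
  out
}

#' Rolling-window early-warning signals of a time series
#'
#' The full EWS pipeline: the series is truncated at `truncation_time` (the
#' last pre-bifurcation point), detrended with a Lowess smoother, and each
#' rolling window of the residuals is summarized by its variance, lag
#' autocorrelations, spectral peak S_max and (optionally) AIC weights of the
#' canonical spectral forms. With `n_bootstrap > 0`, every window is
#' resampled with the stationary block bootstrap and all metrics are
#' recomputed on each resample, giving bootstrap means and percentile 95%
#' confidence intervals. Each metric's trend over window-end times is
#' summarized by its Kendall tau.
#'
#' @param ts An [time_series()].
#' @param config An [ews_config()].
#' @param truncation_time Truncate the series at this time before windowing
#'   (`NULL` keeps the full series). Scenario objects from [make_scenario()]
#'   carry the appropriate value.
#' @return Object of class `"ews_series"`: a long-format data frame with
#'   columns `time`, `metric`, `point`, `boot_mean`, `ci_lo`, `ci_hi`, plus
#'   attributes `kendall_tau` (named vector of trend statistics),
#'   `omega_peak` (per-window spectral peak frequency), `window_length` and
#'   `config`.
#' @examples
#' sc <- make_scenario("fold_forced", seed = 1)
#' ews <- compute_ews(sc$ts, ews_config(n_bootstrap = 0,
#'                                      metrics = c("variance", "smax")),
#'                    truncation_time = sc$truncation_time)
#' attr(ews, "kendall_tau")
#' @export
compute_ews <- function(ts, config = ews_config(), truncation_time = NULL) {
  stopifnot(inherits(ts, "ews_ts"), inherits(config, "ews_config"))
  if (is.null(truncation_time) && !is.null(ts$meta$truncation_time))
    truncation_time <- ts$meta$truncation_time
  if (!is.null(truncation_time)) ts <- ts_truncate(ts, truncation_time)

  det <- lowess_detrend(ts, span = config$lowess_span,
                        span_time = config$lowess_span_time)
  res <- det$residuals$values
  L <- length(res)
  w <- max(20L, round(config$window_fraction * L))
  if (w > L) stop("series shorter than one rolling window (need >= ",
                  w, " points after truncation)")
  ends <- seq(w, L, by = config$window_step)
  nm <- metric_names(config)
  if (!is.null(config$seed)) set.seed(config$seed)

  rows <- vector("list", length(ends))
  peaks <- numeric(length(ends))
  for (j in seq_along(ends)) {
    e <- ends[j]
    seg <- res[(e - w + 1L):e]
    pt <- window_metrics(seg, config, extras = TRUE)
    peaks[j] <- attr(pt, "omega_peak")
    boot_mean <- ci_lo <- ci_hi <- rep(NA_real_, length(nm))
    if (config$n_bootstrap > 0) {
      mbl <- if (is.null(config$mean_block_length))
        default_block_length(seg) else config$mean_block_length
      samples <- stationary_block_bootstrap(seg, mbl, config$n_bootstrap)
      bm <- vapply(samples, function(s) window_metrics(s, config)[nm],
                   numeric(length(nm)))
      bm <- matrix(bm, nrow = length(nm))
      boot_mean <- rowMeans(bm, na.rm = TRUE)
      ci_lo <- apply(bm, 1L, stats::quantile, probs = 0.025, na.rm = TRUE,
                     names = FALSE)
      ci_hi <- apply(bm, 1L, stats::quantile, probs = 0.975, na.rm = TRUE,
                     names = FALSE)
    }
    rows[[j]] <- data.frame(time = det$residuals$times[e], metric = nm,
                            point = unname(pt[nm]), boot_mean = boot_mean,
                            ci_lo = ci_lo, ci_hi = ci_hi)
  }
  out <- do.call(rbind, rows)
  taus <- vapply(nm, function(m)
    kendall_tau(out$point[out$metric == m]), numeric(1))
  structure(out, kendall_tau = taus, omega_peak = peaks,
            window_length = w, config = config,
            class = c("ews_series", "data.frame"))
}

#' @export
print.ews_series <- function(x, ...) {
  taus <- attr(x, "kendall_tau")
  cat(sprintf("<ews_series> %d windows of %d points, metrics: %s\n",
              length(unique(x$time)), attr(x, "window_length"),
              paste(unique(x$metric), collapse = ", ")))
  cat("Kendall tau:\n")
  print(round(taus, 3))
  invisible(x)
}

#' Write an EWS series and its trend summary to disk
#'
#' Writes the tidy per-window table as CSV (`time, metric, point, boot_mean,
#' ci_lo, ci_hi`) and a JSON summary holding the Kendall taus and the
#' final-window metric values.
#'
#' @param ews An `"ews_series"` from [compute_ews()].
#' @param csv_path,json_path Output file paths (either may be `NULL` to
#'   skip).
#' @return Invisibly, a list of the written paths.
#' @export
write_ews_outputs <- function(ews, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    df <- as.data.frame(ews)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(z)
      format(z, digits = 17, trim = TRUE, scientific = FALSE))
    utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    last_t <- max(ews$time)
    final <- ews[ews$time == last_t, c("metric", "point")]
    summary <- list(
      kendall_tau = as.list(attr(ews, "kendall_tau")),
      window_length = attr(ews, "window_length"),
      final_window = stats::setNames(as.list(final$point), final$metric))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(list(csv = csv_path, json = json_path))
}
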