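#' Uniformly sampled univariate time series
#'
#' Light container used throughout the package: strictly uniformly sampled
#' times, numeric values, and free-form provenance metadata (model, seed,
#' parameter schedules).
#'
#' @param times Numeric vector of time stamps, uniformly spaced (relative
#'   tolerance 1e-9 on the spacing).
#' @param values Numeric vector, same length as `times`, no missing values.
#' @param meta Named list of provenance metadata.
#' @return Object of class `"ews_ts"` with fields `times`, `values`, `meta`
#'   and attribute `dt` (the sampling interval).
#' @examples
#' time_series(0:9, rnorm(10))
#' @export
time_series <- function(times, values, meta = list()) {
  if (length(times) < 2L) stop("time series needs at least 2 points")
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (anyNA(times) || anyNA(values) || !all(is.finite(values)))
    stop("time series must not contain missing or non-finite values")
  d <- diff(times)
  dt <- d[1L]
  if (dt <= 0) stop("times must be strictly increasing")
  if (max(abs(d - dt)) > 1e-9 * max(abs(dt), 1))
    stop("times must be uniformly spaced (rel. tol 1e-9)")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 meta = meta),
            dt = dt, class = "ews_ts")
}

#' @export
print.ews_ts <- function(x, ...) {
  cat(sprintf("<ews_ts> %d points, t in [%g, %g], dt = %g\n",
              length(x$values), x$times[1L], x$times[length(x$times)],
              attr(x, "dt")))
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.ews_ts <- function(x, ...) {
  data.frame(time = x$times, value = x$values)
}

#' @export
length.ews_ts <- function(x) length(x$values)

ts_dt <- function(x) attr(x, "dt")

# Restrict a series to times <= t_max (used for pre-bifurcation truncation).
ts_truncate <- function(x, t_max) {
  keep <- x$times <= t_max + 1e-9 * max(abs(ts_dt(x)), 1)
  if (sum(keep) < 2L) stop("truncation leaves fewer than 2 points")
  time_series(x$times[keep], x$values[keep], x$meta)
}

#' Write a time series to CSV
#'
#' Writes two columns, `time` and `value`, with header; plain UTF-8, period
#' decimal separator. The full numeric precision is kept so that a
#' write/read round trip is lossless to 1e-12.
#'
#' @param x An `ews_ts` (or a data frame with `time`/`value` columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(x, path) {
  df <- if (inherits(x, "ews_ts")) as.data.frame(x) else x
  stopifnot(all(c("time", "value") %in% names(df)))
  utils::write.csv(format(df[c("time", "value")], digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a time series from CSV
#'
#' Expects columns `time` and `value`; the sampling must be uniform.
#'
#' @param path Input file path.
#' @param meta Optional metadata list to attach.
#' @return An `ews_ts`.
#' @export
read_timeseries_csv <- function(path, meta = list()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  if (!all(c("time", "value") %in% names(df)))
    stop("CSV must contain 'time' and 'value' columns")
  time_series(as.numeric(df$time), as.numeric(df$value),
              meta = c(meta, list(source = path)))
}

#' Linear ramp schedule for a bifurcation parameter
#'
#' Describes a parameter that ramps linearly from `start_value` at
#' `start_time` to `end_value` at `end_time` and is held constant outside the
#' ramp. A plain number is accepted anywhere a schedule is expected and means
#' a constant parameter.
#'
#' @param start_value,end_value Parameter values at the ramp ends.
#' @param start_time,end_time Ramp interval; `end_time > start_time`.
#' @return Object of class `"parameter_schedule"`.
#' @examples
#' s <- parameter_schedule(0, 2.7, 0, 500)
#' schedule_value(s, c(0, 250, 500))
#' @export
parameter_schedule <- function(start_value, end_value, start_time, end_time) {
  if (!(end_time > start_time)) stop("end_time must exceed start_time")
  structure(list(start_value = start_value, end_value = end_value,
                 start_time = start_time, end_time = end_time),
            class = "parameter_schedule")
}

#' Evaluate a parameter schedule
#'
#' @param sched A [parameter_schedule()] or a plain number (constant).
#' @param t Time(s) at which to evaluate.
#' @return Parameter value(s), vectorized over `t`.
#' @export
schedule_value <- function(sched, t) {
  if (is.numeric(sched) && length(sched) == 1L) return(rep(sched, length(t)))
  stopifnot(inherits(sched, "parameter_schedule"))
  frac <- (t - sched$start_time) / (sched$end_time - sched$start_time)
  frac <- pmin(pmax(frac, 0), 1)
  sched$start_value + frac * (sched$end_value - sched$start_value)
}

# First time at which a ramp reaches `value` (NA if never).
schedule_crossing_time <- function(sched, value) {
  if (is.numeric(sched)) return(NA_real_)
  dv <- sched$end_value - sched$start_value
  if (dv == 0) return(NA_real_)
  frac <- (value - sched$start_value) / dv
  if (frac < 0 || frac > 1) return(NA_real_)
  sched$start_time + frac * (sched$end_time - sched$start_time)
}
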