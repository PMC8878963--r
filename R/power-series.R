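#' Uniformly sampled power trace for one channel
#'
#' The basic container for metered power: one channel (the household
#' aggregate or a single appliance), a start time, a fixed sample period and
#' a vector of instantaneous power readings in watts.  All timestamps are
#' UTC; day boundaries downstream are taken at UTC midnight.
#'
#' @param channel_id Channel name, e.g. `"aggregate"` or `"kettle"`.
#' @param start_time `POSIXct` time of the first sample (converted to UTC).
#' @param sample_period Sample spacing in seconds (> 0; smart-meter feeds in
#'   this domain typically report every 8 s).
#' @param values Numeric vector of watts; must be finite and `>= 0`.
#' @return An object of class `power_series`.
#' @examples
#' ps <- power_series("kettle", as.POSIXct("2014-09-01", tz = "UTC"), 8,
#'                    c(0, 2000, 2000, 0))
#' length(ps$values)
#' @export
power_series <- function(channel_id, start_time, sample_period = 8, values) {
  stopifnot(is.character(channel_id), length(channel_id) == 1L)
  if (!inherits(start_time, "POSIXct")) {
    stop("`start_time` must be POSIXct")
  }
  if (!is.numeric(sample_period) || length(sample_period) != 1L ||
      sample_period <= 0) {
    stop("`sample_period` must be a single positive number of seconds")
  }
  values <- as.numeric(values)
  if (length(values) == 0L) stop("`values` must have length > 0")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("power values must be finite")
  }
  if (any(values < 0)) {
    stop("negative power at index ", which(values < 0)[1L])
  }
  attr(start_time, "tzone") <- "UTC"
  structure(
    list(channel_id = channel_id, start_time = start_time,
         sample_period = as.numeric(sample_period), values = values),
    class = "power_series"
  )
}

#' @export
print.power_series <- function(x, ...) {
  cat(sprintf("<power_series> channel '%s': %d samples @ %gs from %s\n",
              x$channel_id, length(x$values), x$sample_period,
              format(x$start_time, "%Y-%m-%d %H:%M:%S", tz = "UTC")))
  cat(sprintf("  range %.1f-%.1f W, energy %.2f kWh\n",
              min(x$values), max(x$values),
              sum(x$values) * x$sample_period / 3.6e6))
  invisible(x)
}

#' @export
length.power_series <- function(x) length(x$values)

#' Sample timestamps of a power series
#'
#' @param series A [power_series()].
#' @return `POSIXct` vector, one element per sample.
#' @export
series_times <- function(series) {
  series$start_time + (seq_along(series$values) - 1L) * series$sample_period
}

#' Down-sample a power series by block averaging
#'
#' Averages the input over non-overlapping windows of `period` seconds
#' aligned to the series start.  Each output value is the window sum divided
#' by the window's nominal sample capacity, so a window only partially
#' covered by data reads proportionally lower (an entirely uncovered window
#' reads 0 W): metering gaps show up as missing power rather than silently
#' shortening the day.  A trailing window with no data at all is dropped.
#' Up-sampling is not supported.
#'
#' This convention conserves energy over the covered windows:
#' `sum(out$values) * period == sum(in$values) * in$sample_period`.
#'
#' @param series A [power_series()].
#' @param period Target sample period in seconds; must be `>=` the input
#'   period.
#' @return A [power_series()] with `sample_period = period`.
#' @export
resample <- function(series, period) {
  stopifnot(inherits(series, "power_series"))
  if (!is.numeric(period) || length(period) != 1L || period <= 0) {
    stop("`period` must be a single positive number of seconds")
  }
  if (period < series$sample_period) {
    stop("up-sampling is unsupported: period ", period,
         " s is finer than the input spacing ", series$sample_period, " s")
  }
  ratio <- period / series$sample_period
  n_out <- ceiling(length(series$values) / ratio)
  # index of the output window owning each input sample
  idx <- floor((seq_along(series$values) - 1L) / ratio) + 1L
  out <- numeric(n_out)
  sums <- tapply(series$values, idx, sum)
  out[as.integer(names(sums))] <- as.numeric(sums)
  # average over the window's nominal capacity (0 W where nothing covers it)
  out <- out / ratio
  power_series(series$channel_id, series$start_time, period, out)
}
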