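#' Derive ON/OFF operational states from a power trace
#'
#' A sample is ON exactly when its power is at or above the threshold.  The
#' 500 W default separates high-power hand-operated appliances (kettle,
#' oven, iron) from standby and electronics.
#'
#' @param series A [power_series()].
#' @param threshold Watts (> 0).
#' @return An object of class `state_series`: logical `states` aligned 1:1
#'   with the input samples.
#' @export
derive_states <- function(series, threshold = 500) {
  stopifnot(inherits(series, "power_series"))
  if (threshold <= 0) stop("`threshold` must be > 0")
  structure(list(appliance_id = series$channel_id,
                 start_time = series$start_time,
                 sample_period = series$sample_period,
                 states = series$values >= threshold),
            class = "state_series")
}

empty_activations <- function() {
  data.frame(appliance_id = character(), start = as.POSIXct(character(), tz = "UTC"),
             duration = numeric(), max_power = numeric(),
             date = as.Date(character()), start_hour = numeric(),
             day_of_week = integer(), day_of_month = integer(),
             stringsAsFactors = FALSE)
}

activation_frame <- function(appliance_id, start, duration, max_power) {
  if (length(start) == 0L) return(empty_activations())
  attr(start, "tzone") <- "UTC"
  lt <- as.POSIXlt(start, tz = "UTC")
  df <- data.frame(appliance_id = appliance_id, start = start,
                   duration = duration, max_power = max_power,
                   date = as.Date(start, tz = "UTC"),
                   start_hour = lt$hour + lt$min / 60 + lt$sec / 3600,
                   day_of_week = lt$wday,      # 0 = Sunday
                   day_of_month = lt$mday,
                   stringsAsFactors = FALSE)
  df[order(df$start), , drop = FALSE]
}

#' Extract appliance activations from a state series
#'
#' Finds maximal ON runs, bridges OFF gaps of at most `merge_gap` seconds,
#' discards runs shorter than `min_duration`, and summarises each surviving
#' run with its temporal context (start, duration, day of week, day of
#' month) and operational context (maximum power over the run).
#'
#' The defaults (two 8 s samples each) suppress single-sample switching
#' noise without hiding short kettle boils.
#'
#' @param states A [derive_states()] result.
#' @param power The [power_series()] the states were derived from (must be
#'   aligned: same start, period and length).
#' @param min_duration Seconds; shorter episodes are dropped.
#' @param merge_gap Seconds; OFF gaps up to this long are merged over.
#' @return Activation data frame (possibly empty) with columns
#'   `appliance_id`, `start`, `duration`, `max_power`, `date`, `start_hour`,
#'   `day_of_week`, `day_of_month`.
#' @export
extract_activations <- function(states, power, min_duration = 16,
                                merge_gap = 16) {
  stopifnot(inherits(states, "state_series"), inherits(power, "power_series"))
  if (length(states$states) != length(power$values) ||
      states$sample_period != power$sample_period ||
      states$start_time != power$start_time) {
    stop("contract error: states and power are not aligned")
  }
  period <- states$sample_period
  r <- rle(states$states)
  if (!any(r$values)) return(empty_activations())
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  run_start <- starts[on]
  run_end <- ends[on]
  if (length(on) > 1L) {
    gap <- (run_start[-1L] - run_end[-length(on)] - 1L) * period
    grp <- cumsum(c(0L, as.integer(gap > merge_gap)))
  } else {
    grp <- 0L
  }
  first <- tapply(run_start, grp, min)
  last <- tapply(run_end, grp, max)
  dur <- (last - first + 1L) * period
  keep <- dur >= min_duration
  if (!any(keep)) return(empty_activations())
  first <- first[keep]; last <- last[keep]; dur <- dur[keep]
  maxp <- mapply(function(a, b) max(power$values[a:b]), first, last)
  start_t <- states$start_time + (first - 1L) * period
  activation_frame(states$appliance_id, start_t, as.numeric(dur), maxp)
}

#' Estimate discrete appliance power levels from sub-metered traces
#'
#' A rated model gives each appliance the level set `{0, m}` where `m` is
#' the median of its samples at or above the ON threshold.  Appliances that
#' are never ON are dropped with a warning.
#'
#' @param appliance_traces Named list of [power_series()].
#' @param threshold ON threshold in watts.
#' @return Named list of numeric level vectors (class `rated_model`), each
#'   containing 0.
#' @export
fit_rated_model <- function(appliance_traces, threshold = 500) {
  levels <- lapply(appliance_traces, function(ps) {
    on <- ps$values[ps$values >= threshold]
    if (length(on) == 0L) return(NULL)
    c(0, stats::median(on))
  })
  dropped <- names(levels)[vapply(levels, is.null, TRUE)]
  if (length(dropped)) {
    warning("appliance(s) never ON at ", threshold, " W, excluded: ",
            paste(dropped, collapse = ", "))
  }
  levels <- levels[!vapply(levels, is.null, TRUE)]
  if (length(levels) == 0L) stop("no appliance reaches the ON threshold")
  structure(levels, class = "rated_model")
}

#' Combinatorial-optimisation load disaggregation
#'
#' The classical event-less baseline: at every sample, exhaustively choose
#' the combination of appliance levels whose sum best matches the aggregate
#' reading (minimum absolute deviation).  Ties are broken toward fewer ON
#' appliances, then toward switching off the lexicographically later
#' appliance.  No temporal smoothing is applied.
#'
#' @param aggregate Aggregate [power_series()].
#' @param model A [fit_rated_model()] result (or named list of level
#'   vectors each containing 0).
#' @param max_combinations Guard on the exhaustive search space size.
#' @return A list of class `disaggregation_estimate` with named lists
#'   `power` ([power_series()] of the chosen level) and `states`
#'   (`state_series`, ON where the level is positive).
#' @export
co_disaggregate <- function(aggregate, model, max_combinations = 4096) {
  stopifnot(inherits(aggregate, "power_series"))
  apps <- names(model)
  n_comb <- prod(vapply(model, length, 0L))
  if (n_comb > max_combinations) {
    stop("combination count ", n_comb, " exceeds the cap of ",
         max_combinations, "; reduce appliances or levels")
  }
  grid <- expand.grid(lapply(model, function(x) sort(x)),
                      KEEP.OUT.ATTRS = FALSE)
  sums <- rowSums(grid)
  n_on <- rowSums(grid > 0)
  # tie-break order: fewer ON appliances first, then prefer OFF for the
  # lexicographically last appliance, then the one before it, ...
  ord <- do.call(order, c(list(n_on),
                          rev(lapply(apps[order(apps)], function(a) grid[[a]]))))
  grid <- grid[ord, , drop = FALSE]
  sums <- sums[ord]
  vals <- aggregate$values
  u <- unique(vals)
  best <- integer(length(u))
  chunk <- max(1L, floor(5e6 / length(sums)))
  for (i0 in seq(1L, length(u), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, length(u))
    d <- abs(outer(u[i0:i1], sums, "-"))
    best[i0:i1] <- max.col(-d, ties.method = "first")
  }
  pick <- best[match(vals, u)]
  out_power <- lapply(apps, function(a) {
    power_series(a, aggregate$start_time, aggregate$sample_period,
                 grid[[a]][pick])
  })
  names(out_power) <- apps
  out_states <- lapply(out_power, function(ps) {
    structure(list(appliance_id = ps$channel_id, start_time = ps$start_time,
                   sample_period = ps$sample_period, states = ps$values > 0),
              class = "state_series")
  })
  structure(list(power = out_power, states = out_states),
            class = "disaggregation_estimate")
}
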