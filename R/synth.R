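#' Usage profile of one hand-operated appliance
#'
#' Describes how an occupant habitually uses an appliance: rectangular pulses
#' at the rated power, with per-day activation counts drawn per usage window
#' (Poisson with the window's daily mean), start times uniform within the
#' window, and durations from a truncated normal.
#'
#' @param appliance_id Appliance name, e.g. `"kettle"`.
#' @param rated_power Pulse height in watts (> 0).
#' @param usage_windows Data frame (or list coercible to one) with columns
#'   `start`, `end` (hours of day, `0 <= start < end <= 24`) and `rate`
#'   (mean activations per day in that window, `>= 0`).
#' @param duration_dist List with `mean`, `sd`, `min` in seconds; durations
#'   are normal draws truncated below at `min`.
#' @param night_use Logical; whether the occupant habitually uses the
#'   appliance at night.  Unless `TRUE`, windows intersecting the 0-4 h
#'   night band are rejected, keeping normal and night-anomalous usage
#'   separable.
#' @return An object of class `appliance_profile`.
#' @export
appliance_profile <- function(appliance_id, rated_power, usage_windows,
                              duration_dist = list(mean = 180, sd = 60, min = 60),
                              night_use = FALSE) {
  stopifnot(is.character(appliance_id), length(appliance_id) == 1L)
  if (rated_power <= 0) stop("configuration error: rated_power must be > 0")
  w <- as.data.frame(usage_windows)
  stopifnot(all(c("start", "end", "rate") %in% names(w)))
  if (any(w$start < 0) || any(w$end > 24)) {
    stop("configuration error: window hours must lie in [0, 24]")
  }
  if (any(w$start >= w$end)) {
    stop("configuration error: window start must precede its end")
  }
  if (any(w$rate < 0)) stop("configuration error: activation rates must be >= 0")
  if (!night_use && any(w$start < 4)) {
    stop("configuration error: window enters the night band but night_use is FALSE")
  }
  dd <- duration_dist
  if (dd$mean <= 0 || dd$min <= 0) {
    stop("configuration error: durations must be positive")
  }
  structure(list(appliance_id = appliance_id, rated_power = rated_power,
                 usage_windows = w, duration_dist = dd,
                 night_use = isTRUE(night_use)),
            class = "appliance_profile")
}

#' Case-study appliance presets
#'
#' `house4_profile()` emulates a retired couple with a strictly diurnal,
#' strongly habitual kettle routine: pronounced morning and evening peaks,
#' moderate midday use, and no use at night or outside roughly
#' 5 a.m.-10 p.m.  `house11_profile()` emulates a single retired occupant
#' with moderate daytime use, heavier use between 6 p.m. and 10 p.m., and a
#' habitual night-time usage component.
#'
#' @return A list of [appliance_profile()] objects (a single kettle; the
#'   kettle is the canonical indicator appliance for the cooking activity).
#' @export
house4_profile <- function() {
  list(kettle = appliance_profile(
    "kettle", rated_power = 2000,
    usage_windows = data.frame(
      start = c(7, 11, 17),
      end   = c(9, 16, 20),
      rate  = c(3.0, 1.5, 3.0)),
    duration_dist = list(mean = 180, sd = 60, min = 60),
    night_use = FALSE))
}

#' @rdname house4_profile
#' @export
house11_profile <- function() {
  list(kettle = appliance_profile(
    "kettle", rated_power = 2000,
    usage_windows = data.frame(
      start = c(8, 18, 0),
      end   = c(17, 22, 4),
      rate  = c(1.5, 2.5, 1.5)),
    duration_dist = list(mean = 180, sd = 60, min = 60),
    night_use = TRUE))
}

#' Generate a labelled synthetic household dataset
#'
#' Draws per-day activations for each appliance profile, renders them as
#' rectangular pulses at the rated power, and sums them with a constant base
#' load and non-negative Gaussian noise into an aggregate trace.  All days
#' start labelled `"normal"`; [inject_anomalies()] converts days to anomaly
#' classes.  Identical seeds give bit-identical datasets.
#'
#' Overlapping activations of the same appliance are merged into one.
#'
#' @param specs List of [appliance_profile()] objects.
#' @param n_days Number of days (>= 1).
#' @param base_load Constant always-on load in watts.
#' @param noise_sd Standard deviation of the aggregate measurement noise in
#'   watts; draws are truncated below at 0.
#' @param seed Integer seed.
#' @param start_date First day (a `Date`; days break at UTC midnight).
#' @param sample_period Sample period in seconds (default 8).
#' @return An object of class `labelled_dataset`: per-appliance and
#'   aggregate [power_series()], a `labels` data frame (`date`, `label`),
#'   the ground-truth activation table, and the generation parameters.
#' @export
generate_household <- function(specs, n_days, base_load = 40, noise_sd = 10,
                               seed = 1L,
                               start_date = as.Date("2014-09-01"),
                               sample_period = 8) {
  stopifnot(n_days >= 1)
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, `[[`, "", "appliance_id")
  }
  set.seed(seed)
  acts <- do.call(rbind, lapply(names(specs), function(ap) {
    draw_activations(specs[[ap]], n_days)
  }))
  n_samples <- as.integer(n_days * 86400 / sample_period)
  noise <- pmax(stats::rnorm(n_samples, 0, noise_sd), 0)
  dataset <- structure(list(
    appliances = NULL, aggregate = NULL,
    labels = data.frame(date = start_date + seq_len(n_days) - 1L,
                        label = "normal", stringsAsFactors = FALSE),
    activations = acts, specs = specs, base_load = base_load,
    noise = noise, start_date = start_date, n_days = as.integer(n_days),
    sample_period = sample_period), class = "labelled_dataset")
  rebuild_traces(dataset)
}

# Per-day Poisson counts per window, uniform starts, truncated-normal
# durations; same-appliance overlaps merged.
draw_activations <- function(spec, n_days) {
  w <- spec$usage_windows
  dd <- spec$duration_dist
  rows <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    starts <- numeric(0)
    for (r in seq_len(nrow(w))) {
      k <- stats::rpois(1L, w$rate[r])
      if (k > 0L) starts <- c(starts, stats::runif(k, w$start[r], w$end[r]) * 3600)
    }
    if (length(starts) == 0L) next
    dur <- pmax(stats::rnorm(length(starts), dd$mean, dd$sd), dd$min)
    df <- data.frame(appliance_id = spec$appliance_id, day = d,
                     start_sec = starts, duration = dur,
                     power = spec$rated_power, stringsAsFactors = FALSE)
    rows[[d]] <- merge_overlaps(df[order(df$start_sec), , drop = FALSE])
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(appliance_id = character(), day = integer(),
                      start_sec = numeric(), duration = numeric(),
                      power = numeric(), stringsAsFactors = FALSE)
  }
  out
}

merge_overlaps <- function(df) {
  if (nrow(df) <= 1L) return(df)
  keep <- df[1L, , drop = FALSE]
  for (i in 2L:nrow(df)) {
    last <- nrow(keep)
    if (df$start_sec[i] < keep$start_sec[last] + keep$duration[last]) {
      keep$duration[last] <- max(keep$start_sec[last] + keep$duration[last],
                                 df$start_sec[i] + df$duration[i]) -
        keep$start_sec[last]
    } else {
      keep <- rbind(keep, df[i, , drop = FALSE])
    }
  }
  keep
}

# Re-render all channels and the aggregate from the activation table; the
# stored noise vector is reused so injection edits stay consistent with the
# original measurement noise.
rebuild_traces <- function(dataset) {
  n_samples <- length(dataset$noise)
  period <- dataset$sample_period
  t0 <- as.POSIXct(dataset$start_date, tz = "UTC")
  total <- numeric(n_samples)
  dataset$appliances <- lapply(names(dataset$specs), function(ap) {
    vals <- render_pulses(dataset$activations[
      dataset$activations$appliance_id == ap, , drop = FALSE],
      n_samples, period)
    total <<- total + vals
    power_series(ap, t0, period, vals)
  })
  names(dataset$appliances) <- names(dataset$specs)
  dataset$aggregate <- power_series(
    "aggregate", t0, period, total + dataset$base_load + dataset$noise)
  dataset
}

render_pulses <- function(acts, n_samples, period) {
  vals <- numeric(n_samples)
  if (nrow(acts) == 0L) return(vals)
  abs_start <- (acts$day - 1L) * 86400 + acts$start_sec
  i0 <- pmax(1L, floor(abs_start / period) + 1L)
  i1 <- pmin(n_samples, floor((abs_start + acts$duration - 1e-9) / period) + 1L)
  for (j in seq_along(i0)) {
    if (i0[j] <= i1[j]) {
      idx <- i0[j]:i1[j]
      vals[idx] <- pmax(vals[idx], acts$power[j])
    }
  }
  vals
}

#' Inject labelled anomalous days into a dataset
#'
#' Converts `round(rate * length(days))` distinct currently-normal days,
#' chosen uniformly without replacement from `days`, to the requested
#' anomaly class by editing the target appliance's activations; the
#' appliance channel and the household aggregate are re-rendered so they
#' stay mutually consistent.
#'
#' Classes:
#' \describe{
#'   \item{`divergent_usage`}{every activation's start hour is shifted by a
#'     per-day random offset of 4-8 h, wrapped around midnight; offsets that
#'     would land any activation in the 0-4 h night band are redrawn so the
#'     class stays distinguishable from `night_usage`.}
#'   \item{`night_usage`}{`k` activations are added, `k` uniform on
#'     `{1, 2}`, start hours uniform in `[0, 4)`, durations drawn from the
#'     appliance's duration distribution.}
#'   \item{`absence`}{all of the appliance's activations that day are
#'     removed.}
#' }
#'
#' @param dataset A `labelled_dataset`.
#' @param anomaly_class One of `"divergent_usage"`, `"night_usage"`,
#'   `"absence"`.
#' @param rate Fraction of `days` to convert (`0 < rate <= 1`; `rate = 0`
#'   returns the dataset unchanged).
#' @param target_appliance Appliance id to modify (default `"kettle"`).
#' @param seed Integer seed.
#' @param days Integer day indices eligible for injection (default: all
#'   days).  Restricting this to the monitoring period keeps the
#'   observation phase anomaly-free.
#' @return The modified `labelled_dataset` with updated `labels`.
#' @export
inject_anomalies <- function(dataset, anomaly_class, rate,
                             target_appliance = "kettle", seed = 1L,
                             days = seq_len(dataset$n_days)) {
  stopifnot(inherits(dataset, "labelled_dataset"))
  anomaly_class <- match.arg(anomaly_class,
                             c("divergent_usage", "night_usage", "absence"))
  if (rate < 0 || rate > 1) stop("`rate` must lie in [0, 1]")
  if (!target_appliance %in% names(dataset$specs)) {
    stop("unknown appliance: ", target_appliance)
  }
  n_inject <- round(rate * length(days))
  if (n_inject == 0L) return(dataset)
  eligible <- days[dataset$labels$label[days] == "normal"]
  if (length(eligible) < n_inject) {
    stop("fewer normal days (", length(eligible), ") than required (",
         n_inject, ") for injection")
  }
  set.seed(seed)
  chosen <- sort(sample(eligible, n_inject))
  dd <- dataset$specs[[target_appliance]]$duration_dist
  rated <- dataset$specs[[target_appliance]]$rated_power
  acts <- dataset$activations
  for (d in chosen) {
    sel <- acts$appliance_id == target_appliance & acts$day == d
    if (anomaly_class == "divergent_usage") {
      h <- (acts$start_sec[sel] / 3600)
      repeat {
        off <- stats::runif(1L, 4, 8)
        h_new <- (h + off) %% 24
        if (!any(h_new >= 0 & h_new < 4)) break
      }
      acts$start_sec[sel] <- h_new * 3600
    } else if (anomaly_class == "night_usage") {
      k <- sample(1:2, 1L)
      add <- data.frame(appliance_id = target_appliance, day = d,
                        start_sec = stats::runif(k, 0, 4) * 3600,
                        duration = pmax(stats::rnorm(k, dd$mean, dd$sd), dd$min),
                        power = rated, stringsAsFactors = FALSE)
      acts <- rbind(acts, add)
    } else {
      acts <- acts[!sel, , drop = FALSE]
    }
  }
  dataset$activations <- acts[order(acts$appliance_id, acts$day,
                                    acts$start_sec), , drop = FALSE]
  rownames(dataset$activations) <- NULL
  dataset$labels$label[chosen] <- anomaly_class
  rebuild_traces(dataset)
}

#' @export
print.labelled_dataset <- function(x, ...) {
  tab <- table(x$labels$label)
  cat(sprintf("<labelled_dataset> %d days from %s, %d appliance(s) @ %gs\n",
              x$n_days, format(x$start_date), length(x$appliances),
              x$sample_period))
  cat("  day labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Reconstruct a labelled dataset from metered channels
#'
#' Builds a `labelled_dataset` around externally supplied traces (e.g. read
#' with [load_power_csv()]) so that [inject_anomalies()] can operate on
#' them.  Appliance activations are recovered by threshold extraction and
#' re-rendered as rectangular pulses at each activation's maximum power;
#' whatever the pulse approximation misses (base load, noise, partial
#' samples) is kept as a residual term, so the aggregate trace is
#' reproduced exactly and stays consistent under later injection edits.
#' Each appliance's duration distribution and rated power are estimated
#' from its extracted activations.
#'
#' @param channels Named list of [power_series()] including `"aggregate"`.
#' @param labels Optional data frame (`date`, `label`); defaults to all
#'   `"normal"`.
#' @param threshold ON threshold in watts for activation recovery.
#' @param min_duration,merge_gap Passed to [extract_activations()].
#' @return A `labelled_dataset`.
#' @export
dataset_from_channels <- function(channels, labels = NULL, threshold = 500,
                                  min_duration = 16, merge_gap = 16) {
  stopifnot("aggregate" %in% names(channels))
  agg <- channels$aggregate
  apps <- setdiff(names(channels), "aggregate")
  if (length(apps) == 0L) stop("no appliance channels supplied")
  period <- agg$sample_period
  n_days <- floor(length(agg$values) * period / 86400)
  if (n_days < 1L) stop("trace shorter than one day")
  n_samples <- as.integer(n_days * 86400 / period)
  start_date <- as.Date(agg$start_time, tz = "UTC")
  t0 <- as.numeric(as.POSIXct(start_date, tz = "UTC"))
  acts_list <- lapply(apps, function(ap) {
    ps <- channels[[ap]]
    a <- extract_activations(derive_states(ps, threshold), ps,
                             min_duration, merge_gap)
    if (nrow(a) == 0L) return(NULL)
    rel <- as.numeric(a$start) - t0
    data.frame(appliance_id = ap, day = floor(rel / 86400) + 1L,
               start_sec = rel %% 86400, duration = a$duration,
               power = a$max_power, stringsAsFactors = FALSE)
  })
  acts <- do.call(rbind, acts_list)
  if (is.null(acts)) {
    stop("no activations recovered at ", threshold, " W")
  }
  acts <- acts[acts$day >= 1L & acts$day <= n_days, , drop = FALSE]
  specs <- lapply(apps, function(ap) {
    sel <- acts$appliance_id == ap
    dur <- if (any(sel)) acts$duration[sel] else 180
    rated <- if (any(sel)) max(stats::median(acts$power[sel]), threshold) else
      threshold
    appliance_profile(
      ap, rated_power = rated,
      usage_windows = data.frame(start = 4, end = 24, rate = 0),
      duration_dist = list(mean = mean(dur),
                           sd = max(stats::sd(dur), 1, na.rm = TRUE),
                           min = max(min(dur), min_duration)),
      night_use = TRUE)
  })
  names(specs) <- apps
  if (is.null(labels)) {
    labels <- data.frame(date = start_date + seq_len(n_days) - 1L,
                         label = "normal", stringsAsFactors = FALSE)
  } else {
    labels$date <- as.Date(labels$date)
  }
  rendered <- Reduce(`+`, lapply(apps, function(ap) {
    render_pulses(acts[acts$appliance_id == ap, , drop = FALSE],
                  n_samples, period)
  }))
  dataset <- structure(list(
    appliances = NULL, aggregate = NULL, labels = labels,
    activations = acts, specs = specs, base_load = 0,
    noise = agg$values[seq_len(n_samples)] - rendered,
    start_date = start_date, n_days = as.integer(n_days),
    sample_period = period), class = "labelled_dataset")
  rebuild_traces(dataset)
}

#' Ground-truth activations of a dataset as a monitoring activation table
#'
#' Converts the generator's internal activation table to the same layout
#' [extract_activations()] produces, so ground truth can feed the monitor
#' directly.
#'
#' @param dataset A `labelled_dataset`.
#' @param appliance Optional appliance id filter.
#' @return Activation data frame (`appliance_id`, `start`, `duration`,
#'   `max_power`, `date`, `start_hour`, `day_of_week`, `day_of_month`).
#' @export
true_activations <- function(dataset, appliance = NULL) {
  acts <- dataset$activations
  if (!is.null(appliance)) {
    acts <- acts[acts$appliance_id %in% appliance, , drop = FALSE]
  }
  start <- as.POSIXct(dataset$start_date, tz = "UTC") +
    (acts$day - 1L) * 86400 + acts$start_sec
  activation_frame(acts$appliance_id, start, acts$duration, acts$power)
}
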