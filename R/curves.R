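#' Build the daily activity curve for one activity
#'
#' The activity curve is the probability distribution of the time an
#' occupant spends on an activity across the bins of one day: every
#' activation of an appliance mapped to the activity contributes its
#' duration to the bins it overlaps (activations crossing midnight are
#' clipped to the day, their remainder belonging to the neighbouring day),
#' and the binned durations are normalised to sum to one.  A day with no
#' mapped usage yields an empty curve.
#'
#' @param activations Activation data frame ([extract_activations()] /
#'   [true_activations()] layout); may span many days.
#' @param mapping Activity-to-appliance mapping (see
#'   [default_activity_mapping()]).
#' @param activity Activity name; must be a key of `mapping`.
#' @param date The day (a `Date`, UTC).
#' @param bins_per_day Number of equal bins (default 24).
#' @return An object of class `activity_curve`: `date`, `activity`, `bins`
#'   (probabilities summing to 1, or `NULL` when `empty`),
#'   `total_duration` in seconds, and `empty`.
#' @export
build_activity_curve <- function(activations, mapping, activity, date,
                                 bins_per_day = 24) {
  if (!activity %in% names(mapping)) {
    stop("configuration error: unknown activity '", activity, "'")
  }
  day_start <- as.numeric(as.POSIXct(date, tz = "UTC"))
  bin_w <- 86400 / bins_per_day
  bins <- numeric(bins_per_day)
  total <- 0
  sel <- activations$appliance_id %in% mapping[[activity]]
  if (any(sel)) {
    s <- as.numeric(activations$start[sel]) - day_start
    e <- s + activations$duration[sel]
    # clip to this day
    s <- pmax(s, 0); e <- pmin(e, 86400)
    ok <- which(e > s)
    for (i in ok) {
      b0 <- floor(s[i] / bin_w)
      b1 <- floor((e[i] - 1e-9) / bin_w)
      for (b in b0:b1) {
        ov <- min(e[i], (b + 1) * bin_w) - max(s[i], b * bin_w)
        bins[b + 1L] <- bins[b + 1L] + ov
      }
    }
    total <- sum(bins)
  }
  if (total <= 0) {
    return(structure(list(date = date, activity = activity, bins = NULL,
                          total_duration = 0, empty = TRUE),
                     class = "activity_curve"))
  }
  structure(list(date = date, activity = activity, bins = bins / total,
                 total_duration = total, empty = FALSE),
            class = "activity_curve")
}

#' @export
print.activity_curve <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("<activity_curve> %s %s: empty (no usage)\n",
                format(x$date), x$activity))
  } else {
    top <- order(x$bins, decreasing = TRUE)[1:3]
    cat(sprintf("<activity_curve> %s %s: %.0f s over %d bins; top bins %s\n",
                format(x$date), x$activity, x$total_duration,
                sum(x$bins > 0),
                paste(top - 1L, sprintf("(%.2f)", x$bins[top]),
                      collapse = " ")))
  }
  invisible(x)
}

#' Summarise an occupant's profile for one activity
#'
#' The profile is the unweighted element-wise mean of the non-empty stored
#' curves, renormalised to sum to one.
#'
#' @param store An [observation_store()].
#' @param activity Activity name.
#' @return An `activity_curve` (date `NA`).
#' @export
summarize_profile <- function(store, activity) {
  P <- stored_curve_matrix(store, activity)
  if (nrow(P) == 0L) stop("no observations for activity '", activity, "'")
  m <- colMeans(P)
  m <- m / sum(m)
  structure(list(date = as.Date(NA), activity = activity, bins = m,
                 total_duration = NA_real_, empty = FALSE),
            class = "activity_curve")
}
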