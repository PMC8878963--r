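#' Generalised Jensen-Shannon divergence between activity curves
#'
#' For distributions `P_1..P_n` and weights `pi` summing to one, the
#' divergence is `sum_i pi_i * D(P_i || M)` with mixture `M = sum_i pi_i P_i`
#' and `D(P || M) = sum_x P(x) log(P(x) / M(x))` in natural log, with the
#' convention `0 * log(0 / .) = 0`.  It is non-negative, zero exactly when
#' all positive-weight distributions coincide, and bounded by `log(2)` in
#' the equal-weight two-distribution case.
#'
#' @param curves List of non-empty [build_activity_curve()] results, or a
#'   numeric matrix with one distribution per row.
#' @param weights Numeric weights summing to 1, or a
#'   [compute_weights()] result.
#' @return A single non-negative score (nats).
#' @export
generalized_jsd <- function(curves, weights) {
  if (inherits(weights, "weight_vector")) weights <- weights$pi
  P <- if (is.matrix(curves)) curves else {
    empt <- vapply(curves, function(cv) isTRUE(cv$empty), TRUE)
    if (any(empt)) stop("contract error: empty curve passed to generalized_jsd")
    do.call(rbind, lapply(curves, `[[`, "bins"))
  }
  if (nrow(P) != length(weights)) {
    stop("contract error: ", nrow(P), " curves but ", length(weights),
         " weights")
  }
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  M <- drop(crossprod(P, weights))
  total <- 0
  for (i in seq_len(nrow(P))) {
    p <- P[i, ]
    pos <- p > 0 & weights[i] > 0
    total <- total + weights[i] * sum(p[pos] * log(p[pos] / M[pos]))
  }
  max(total, 0)
}

#' Score one day against the observation store
#'
#' The day's activity curve is compared with the weight-mixed profile of
#' the stored curves, `M = sum_i pi_i P_i` (empty stored curves excluded,
#' weights renormalised), via the equal-weight two-distribution
#' Jensen-Shannon divergence `JSD(P_day, M)`.  The score lies in
#' `[0, log 2]`; an empty day short-circuits to `empty_day = TRUE` (scored
#' downstream as an absence anomaly).
#'
#' @param day_curve The day's `activity_curve`.
#' @param store An [observation_store()] with at least one non-empty curve
#'   for the activity.
#' @param weights Optional [compute_weights()] result over the stored days
#'   (default: computed with `beta`).
#' @param beta Weight ratio used when `weights` is not supplied.
#' @return List of class `day_score`: `date`, `activity`, `jsd`,
#'   `empty_day`.
#' @export
day_score <- function(day_curve, store, weights = NULL, beta = 2) {
  stopifnot(inherits(day_curve, "activity_curve"))
  if (store_size(store) == 0L) stop("empty store")
  if (day_curve$empty) {
    return(structure(list(date = day_curve$date, activity = day_curve$activity,
                          jsd = NA_real_, empty_day = TRUE),
                     class = "day_score"))
  }
  if (is.null(weights)) weights <- compute_weights(store, beta)
  P <- stored_curve_matrix(store, day_curve$activity)
  if (nrow(P) == 0L) stop("no non-empty observations for activity '",
                          day_curve$activity, "'")
  w <- weights$pi[attr(P, "day_idx")]
  w <- w / sum(w)
  M <- drop(crossprod(P, w))
  jsd <- generalized_jsd(rbind(day_curve$bins, M), c(0.5, 0.5))
  structure(list(date = day_curve$date, activity = day_curve$activity,
                 jsd = jsd, empty_day = FALSE), class = "day_score")
}

#' Inter-quantile-range decision interval
#'
#' `[Q1 - factor * IQR, Q3 + factor * IQR]` with `IQR = Q3 - Q1`.
#' Quantiles use linear interpolation between order statistics (the
#' convention of [stats::quantile()] type 7); the interval bounds depend on
#' this choice, so it is fixed here.  Under approximate normality the
#' default `factor = 1.5` interval covers about 99.3% of the data, which is
#' what motivates its use as an outlier fence.
#'
#' @param scores Numeric vector, length `>= 4`.
#' @param factor Non-negative multiplier (default 1.5).
#' @return List of class `iqr_interval`: `q1`, `q3`, `iqr`, `lower`,
#'   `upper`, `factor`.
#' @export
iqr_interval <- function(scores, factor = 1.5) {
  if (length(scores) < 4L) {
    stop("insufficient observation days: need >= 4 scores, got ",
         length(scores))
  }
  q <- stats::quantile(scores, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  structure(list(q1 = q[1L], q3 = q[2L], iqr = iqr,
                 lower = q[1L] - factor * iqr, upper = q[2L] + factor * iqr,
                 factor = factor),
            class = "iqr_interval")
}

# Leave-one-out reference scores: every stored (non-empty) day scored
# against the store minus that day, with the divergence weights
# recomputed over the remaining days.
loo_scores <- function(store, activity, beta = 2) {
  P <- stored_curve_matrix(store, activity)
  idx <- attr(P, "day_idx")
  if (nrow(P) < 2L) {
    stop("insufficient observation days: need >= 2 non-empty curves")
  }
  flags <- store_feedback(store)[idx]
  vapply(seq_len(nrow(P)), function(i) {
    w <- compute_weights(flags[-i], beta)$pi
    M <- drop(crossprod(P[-i, , drop = FALSE], w))
    generalized_jsd(rbind(P[i, ], M), c(0.5, 0.5))
  }, 0)
}

#' Classify one day as normal or anomalous
#'
#' The reference score distribution is obtained by leave-one-out scoring of
#' every stored day against the rest of the store; the decision interval is
#' the IQR fence over those reference scores.  The monitored day is
#' anomalous when its score falls outside the interval, or when it is
#' empty (no usage at all).
#'
#' @param day_curve The day's `activity_curve`.
#' @param store An [observation_store()] with at least 4 scoreable days.
#' @param config A [pipeline_config()].
#' @return List: `decision` (`"normal"`/`"anomalous"`), `score`
#'   (a `day_score`), `interval` (an `iqr_interval`), `ref_scores`.
#' @export
classify_day <- function(day_curve, store, config = pipeline_config()) {
  ref <- loo_scores(store, day_curve$activity, config$beta)
  interval <- iqr_interval(ref, config$iqr_factor)
  sc <- day_score(day_curve, store, beta = config$beta)
  decision <- if (sc$empty_day) {
    "anomalous"
  } else if (sc$jsd < interval$lower || sc$jsd > interval$upper) {
    "anomalous"
  } else {
    "normal"
  }
  list(decision = decision, score = sc, interval = interval,
       ref_scores = ref)
}

#' Classify an activation as a variation or a deviation
#'
#' A variation is a benign shift in the routine; a deviation is a
#' reportable departure.  The decision threshold is derived from the
#' stored self-similarity matrix: the upper IQR fence over the historical
#' nearest-neighbour distances (off-diagonal minimum per stored
#' activation).  The activation is a deviation when its own
#' nearest-neighbour distance to history exceeds that threshold.
#'
#' @param activation One-row activation data frame.
#' @param store An [observation_store()] tracking similarity for the
#'   activation's appliance.
#' @param factor IQR factor (default 1.5).
#' @return `"variation"` or `"deviation"`.
#' @export
classify_activation <- function(activation, store, factor = 1.5) {
  ap <- activation$appliance_id[1L]
  s <- store$sim[[ap]]
  if (is.null(s) || nrow(s$feat) < 2L) {
    stop("no activation history for appliance '", ap, "'")
  }
  m <- s$mat
  diag(m) <- Inf
  nn_hist <- apply(m, 1L, min)
  threshold <- iqr_interval(nn_hist, factor)$upper
  d <- min(cross_distances(activation_features(activation), s$feat))
  if (d > threshold) "deviation" else "variation"
}

#' Assign the anomaly class of an anomalous day
#'
#' Deterministic priority: `absence` when the day has no activations,
#' otherwise `night_usage` when any activation starts inside the night
#' band, otherwise `abnormal_usage_time`.
#'
#' @param date The day.
#' @param activations The day's activation data frame (for the monitored
#'   activity's appliances).
#' @param decision Must be `"anomalous"`.
#' @param night_band Hour interval `[from, to)` counted as night.
#' @return One of `"absence"`, `"night_usage"`, `"abnormal_usage_time"`.
#' @export
classify_anomaly_type <- function(date, activations, decision,
                                  night_band = c(0, 4)) {
  if (!identical(decision, "anomalous")) {
    stop("contract error: classify_anomaly_type() called on a non-anomalous day")
  }
  if (NROW(activations) == 0L) return("absence")
  h <- activations$start_hour
  if (any(h >= night_band[1L] & h < night_band[2L])) return("night_usage")
  "abnormal_usage_time"
}
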