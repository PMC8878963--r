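#' Create an (empty) observation store
#'
#' The observation store is the ordered database of daily observations the
#' occupant's profile is built from: one record per day holding its
#' activity curves, its activations, and a feedback flag, plus one
#' self-similarity matrix per appliance encoding the pairwise distance
#' between all stored activations of that appliance.  Days are kept in
#' chronological order and the store has a fixed capacity (the length of
#' the observation phase): once full, days enter only by replacement (see
#' [replace_day()]).
#'
#' @param capacity Maximum number of stored days.
#' @param mapping Activity-to-appliance mapping.
#' @param activities Activities to track (default: all mapping keys).
#' @param bins_per_day Bins per activity curve.
#' @param track_similarity Maintain per-appliance similarity matrices
#'   (needed for activation-level anomaly analysis).
#' @return An object of class `observation_store`.
#' @export
observation_store <- function(capacity, mapping = default_activity_mapping(),
                              activities = names(mapping), bins_per_day = 24,
                              track_similarity = TRUE) {
  validate_mapping(mapping)
  stopifnot(capacity >= 1)
  structure(list(days = list(), capacity = as.integer(capacity),
                 mapping = mapping, activities = activities,
                 bins_per_day = as.integer(bins_per_day),
                 track_similarity = isTRUE(track_similarity),
                 sim = list(), next_id = 1L),
            class = "observation_store")
}

#' @export
print.observation_store <- function(x, ...) {
  cat(sprintf("<observation_store> %d/%d days, activities: %s\n",
              length(x$days), x$capacity,
              paste(x$activities, collapse = ", ")))
  if (length(x$days)) {
    cat(sprintf("  %s .. %s, %d feedback day(s)\n",
                format(x$days[[1L]]$date),
                format(x$days[[length(x$days)]]$date),
                sum(store_feedback(x))))
  }
  invisible(x)
}

store_size <- function(store) length(store$days)

store_feedback <- function(store) {
  vapply(store$days, `[[`, TRUE, "feedback")
}

store_dates <- function(store) {
  as.Date(vapply(store$days, function(d) as.character(d$date), ""))
}

make_day_record <- function(store, date, activations, feedback = FALSE) {
  curves <- lapply(store$activities, function(a) {
    build_activity_curve(activations, store$mapping, a, date,
                         store$bins_per_day)
  })
  names(curves) <- store$activities
  list(id = NA_integer_, date = date, curves = curves, feedback = feedback,
       activations = activations)
}

#' Append a day to the observation store
#'
#' Used during the observation phase while the store is filling; once at
#' capacity, days enter via [update_after_day()] / [replace_day()].
#'
#' @param store An [observation_store()].
#' @param date Day (`Date`).
#' @param activations That day's activation data frame.
#' @param feedback Feedback flag for the day.
#' @return The updated store.
#' @export
store_add_day <- function(store, date, activations, feedback = FALSE) {
  if (store_size(store) >= store$capacity) {
    stop("store is at capacity (", store$capacity, "); use replace_day()")
  }
  rec <- make_day_record(store, date, activations, feedback)
  rec$id <- store$next_id
  store$next_id <- store$next_id + 1L
  store$days[[store_size(store) + 1L]] <- rec
  if (store$track_similarity) store <- sim_add_day(store, rec)
  store
}

#' Divergence weights over the stored days
#'
#' Days carrying external-agent feedback receive weight
#' `1 / (N1 + beta * N2)` and days without feedback
#' `beta / (N1 + beta * N2)`, where `N1` and `N2` count feedback and
#' non-feedback days; the weights sum to one exactly.
#'
#' @param store An [observation_store()] (or a logical vector of feedback
#'   flags).
#' @param beta Weight ratio, `>= 2`.
#' @return List of class `weight_vector`: `pi`, `N1`, `N2`, `beta`.
#' @export
compute_weights <- function(store, beta = 2) {
  if (beta < 2) stop("configuration error: `beta` must be >= 2")
  flags <- if (inherits(store, "observation_store")) {
    store_feedback(store)
  } else {
    as.logical(store)
  }
  if (length(flags) == 0L) stop("empty store")
  N1 <- sum(flags)
  N2 <- sum(!flags)
  pi <- ifelse(flags, 1, beta) / (N1 + beta * N2)
  structure(list(pi = pi, N1 = N1, N2 = N2, beta = beta),
            class = "weight_vector")
}

# Matrix of the non-empty stored curves for an activity (rows = days), with
# the originating day indices as attribute "day_idx".
stored_curve_matrix <- function(store, activity) {
  keep <- which(vapply(store$days,
                       function(d) !d$curves[[activity]]$empty, TRUE))
  P <- do.call(rbind, lapply(store$days[keep],
                             function(d) d$curves[[activity]]$bins))
  if (is.null(P)) P <- matrix(numeric(), 0L, store$bins_per_day)
  attr(P, "day_idx") <- keep
  P
}

## ---- activation similarity ------------------------------------------------

# Feature space for activation similarity: circular start hour (difference
# folded to [0, 12] hours) and log duration.
activation_features <- function(acts) {
  data.frame(start_hour = acts$start_hour, log_duration = log(acts$duration))
}

cross_distances <- function(fa, fb) {
  dh <- abs(outer(fa$start_hour, fb$start_hour, "-"))
  dh <- pmin(dh, 24 - dh)
  dd <- outer(fa$log_duration, fb$log_duration, "-")
  sqrt(dh^2 + dd^2)
}

#' Self-similarity matrix of a set of activations
#'
#' Entry `(i, j)` is the Euclidean distance between activations `i` and `j`
#' in a feature space of circular start hour (so 23:00 and 01:00 are 2 h
#' apart, never 22) and log duration.  The matrix is symmetric with a zero
#' diagonal.
#'
#' @param activations Activation data frame with at least 2 rows.
#' @return A symmetric numeric matrix.
#' @export
build_similarity_matrix <- function(activations) {
  if (NROW(activations) < 2L) stop("need at least 2 activations")
  f <- activation_features(activations)
  m <- cross_distances(f, f)
  diag(m) <- 0
  m
}

# Incremental similarity bookkeeping: each tracked appliance holds the
# features of all stored activations (tagged with the owning day id) and
# the full distance matrix.
tracked_appliances <- function(store) {
  unique(unlist(store$mapping[store$activities], use.names = FALSE))
}

sim_add_day <- function(store, rec) {
  acts <- rec$activations
  for (ap in intersect(tracked_appliances(store), unique(acts$appliance_id))) {
    sel <- acts$appliance_id == ap
    f_new <- activation_features(acts[sel, , drop = FALSE])
    ids <- rep(rec$id, sum(sel))
    s <- store$sim[[ap]]
    if (is.null(s)) {
      m <- cross_distances(f_new, f_new)
      diag(m) <- 0
      store$sim[[ap]] <- list(feat = f_new, day_id = ids, mat = m)
    } else {
      cross <- cross_distances(s$feat, f_new)
      self <- cross_distances(f_new, f_new)
      diag(self) <- 0
      s$mat <- rbind(cbind(s$mat, cross), cbind(t(cross), self))
      s$feat <- rbind(s$feat, f_new)
      s$day_id <- c(s$day_id, ids)
      store$sim[[ap]] <- s
    }
  }
  store
}

sim_drop_day <- function(store, day_id) {
  for (ap in names(store$sim)) {
    s <- store$sim[[ap]]
    keep <- s$day_id != day_id
    if (all(keep)) next
    if (!any(keep)) {
      store$sim[[ap]] <- NULL
    } else {
      store$sim[[ap]] <- list(feat = s$feat[keep, , drop = FALSE],
                              day_id = s$day_id[keep],
                              mat = s$mat[keep, keep, drop = FALSE])
    }
  }
  store
}

# Oracle-style full rebuild of the similarity matrices from the stored days.
sim_rebuild <- function(store) {
  store$sim <- list()
  for (rec in store$days) store <- sim_add_day(store, rec)
  store
}
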