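#' A feedback record from the external agent
#'
#' @param date Day the feedback refers to (a reported day).
#' @param verdict `"confirm_anomaly"` or `"reject_anomaly"`.
#' @param received_at Timestamp of reception (informational).
#' @return List of class `feedback_record`.
#' @export
feedback_record <- function(date, verdict,
                            received_at = as.POSIXct(Sys.time(), tz = "UTC")) {
  verdict <- match.arg(verdict, c("confirm_anomaly", "reject_anomaly"))
  structure(list(date = as.Date(date), verdict = verdict,
                 received_at = received_at),
            class = "feedback_record")
}

#' Read feedback records from a CSV or JSON file
#'
#' The file holds one record per row/object with fields `date` and
#' `verdict`.
#'
#' @param path `.csv` or `.json` file.
#' @return List of [feedback_record()] objects, named by date.
#' @export
read_feedback <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("date", "verdict") %in% names(df)))
  out <- lapply(seq_len(nrow(df)),
                function(i) feedback_record(df$date[i], df$verdict[i]))
  names(out) <- as.character(as.Date(df$date))
  out
}

#' Pick the stored day to be replaced
#'
#' Implements the forgetting policy favouring old and unlabelled entries:
#' when any day lacks feedback, the oldest such day is replaced (a rolling
#' window over the unlabelled observations, so feedback days are never
#' evicted while an unlabelled one remains).  Only when every stored day
#' carries feedback does divergence enter: the most divergent day --
#' highest leave-one-out divergence score, summed over the tracked
#' activities -- is chosen, ties broken toward the oldest.  Replacing
#' unlabelled days by divergence instead would systematically evict the
#' spread of the reference distribution and collapse the decision interval
#' over a long monitoring period.  Days whose curves are all empty carry
#' no profile information and are treated as maximally divergent.
#'
#' @param store A full [observation_store()].
#' @param beta Weight ratio for the leave-one-out scoring.
#' @return The index of the day to replace.
#' @export
select_replacement <- function(store, beta = 2) {
  n <- store_size(store)
  if (n == 0L) stop("empty store")
  flags <- store_feedback(store)
  if (any(!flags)) {
    # oldest unlabelled day (days are kept in chronological order)
    return(which(!flags)[1L])
  }
  div <- rep(NA_real_, n)
  for (a in store$activities) {
    P <- stored_curve_matrix(store, a)
    idx <- attr(P, "day_idx")
    if (nrow(P) < 2L) next
    sc <- loo_scores(store, a, beta)
    div[idx] <- ifelse(is.na(div[idx]), 0, div[idx]) + sc
  }
  div[is.na(div)] <- Inf   # all-empty days: nothing to lose by evicting
  # most divergent first; ties toward the oldest
  order(-div, seq_len(n))[1L]
}

#' Replace one stored day with a new day
#'
#' The record at `index` is evicted; the new day is appended (the store
#' stays in chronological order) with the given feedback flag.  The
#' per-appliance similarity matrices are updated incrementally: the rows
#' and columns of the evicted day's activations are deleted and rows and
#' columns for the new day's activations are appended with freshly
#' computed distances, which is equivalent to a full rebuild.
#'
#' @param store A non-empty [observation_store()].
#' @param index Index of the day to evict.
#' @param date Date of the new day.
#' @param activations The new day's activation data frame.
#' @param feedback_flag Feedback flag for the new day.
#' @return The updated store (size unchanged).
#' @export
replace_day <- function(store, index, date, activations,
                        feedback_flag = FALSE) {
  n <- store_size(store)
  if (!is.numeric(index) || length(index) != 1L || index < 1L || index > n) {
    stop("invalid index: ", index)
  }
  old_id <- store$days[[index]]$id
  store$days[[index]] <- NULL
  if (store$track_similarity) store <- sim_drop_day(store, old_id)
  rec <- make_day_record(store, date, activations, feedback_flag)
  rec$id <- store$next_id
  store$next_id <- store$next_id + 1L
  store$days[[store_size(store) + 1L]] <- rec
  if (store$track_similarity) store <- sim_add_day(store, rec)
  store
}

#' Fold a monitored day into the store according to its report and feedback
#'
#' The maintenance policy after each monitored day:
#' \itemize{
#'   \item no feedback, decision normal: the framework takes its own report
#'     as correct and inserts the day via [replace_day()] (rolling window,
#'     so the profile tracks seasonal change);
#'   \item no feedback, decision anomalous: the store is left unchanged
#'     (unconfirmed anomalies never contaminate the profile);
#'   \item feedback `reject_anomaly` (misidentified anomaly): the day is a
#'     legitimate new routine, inserted via [replace_day()] and tagged as a
#'     feedback day;
#'   \item feedback `confirm_anomaly`: the store is left unchanged.
#' }
#'
#' @param store The [observation_store()].
#' @param date The monitored day.
#' @param decision `"normal"` or `"anomalous"` from [classify_day()].
#' @param activations The day's activation data frame.
#' @param feedback Optional [feedback_record()] for the day.
#' @param beta Weight ratio used by [select_replacement()].
#' @return The updated store.
#' @export
update_after_day <- function(store, date, decision, activations,
                             feedback = NULL, beta = 2) {
  insert <- FALSE
  flag <- FALSE
  if (is.null(feedback)) {
    insert <- identical(decision, "normal")
  } else {
    stopifnot(inherits(feedback, "feedback_record"))
    if (feedback$verdict == "reject_anomaly") {
      insert <- TRUE
      flag <- TRUE
    }
  }
  if (!insert) return(store)
  if (store_size(store) < store$capacity) {
    return(store_add_day(store, date, activations, feedback = flag))
  }
  idx <- select_replacement(store, beta)
  replace_day(store, idx, date, activations, feedback_flag = flag)
}
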