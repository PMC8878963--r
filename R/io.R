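#' Read a REFIT-style household CSV into power series
#'
#' Reads the cleaned-CSV dialect common to public household electricity
#' datasets: a header row, one timestamp column (ISO-8601 text or epoch
#' seconds, interpreted as UTC) and one numeric watt column per channel
#' (aggregate plus numbered appliances).  Columns not named in
#' `channel_map` are ignored.
#'
#' Timestamps must be strictly increasing.  Spacing is not required to be
#' uniform here; irregular feeds must be made uniform (e.g. with
#' [resample()]) before entering the monitoring pipeline, which assumes a
#' fixed sample period.  When spacing is irregular the modal spacing is
#' recorded as the `sample_period` and a `"times"` attribute carries the raw
#' timestamps.
#'
#' @param path CSV file path.
#' @param channel_map Named character vector mapping channel names to column
#'   names, e.g. `c(aggregate = "Aggregate", kettle = "Appliance1")`.
#' @param timestamp_col Name of the timestamp column (default `"Time"`).
#' @return Named list of [power_series()], one per entry of `channel_map`.
#' @export
load_power_csv <- function(path, channel_map, timestamp_col = "Time") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(c(timestamp_col, unname(channel_map)), names(df))
  if (length(missing_cols)) {
    stop("configuration error: column(s) not present in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  times <- parse_timestamps(df[[timestamp_col]])
  if (length(times) > 1L) {
    dt <- diff(as.numeric(times))
    bad <- which(dt <= 0)
    if (length(bad)) {
      stop("format error: timestamps not strictly increasing at row ",
           bad[1L] + 1L)
    }
    period <- modal_spacing(dt)
  } else {
    period <- 8
  }
  out <- lapply(names(channel_map), function(ch) {
    vals <- df[[channel_map[[ch]]]]
    neg <- which(vals < 0)
    if (length(neg)) {
      stop("value error: negative power in column '", channel_map[[ch]],
           "' at row ", neg[1L])
    }
    ps <- power_series(ch, times[1L], period, vals)
    attr(ps, "times") <- times
    ps
  })
  names(out) <- names(channel_map)
  out
}

parse_timestamps <- function(x) {
  if (is.numeric(x)) {
    return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  }
  t <- as.POSIXct(x, tz = "UTC",
                  tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
                                 "%Y-%m-%d"))
  if (anyNA(t)) stop("format error: unparseable timestamp at row ",
                     which(is.na(t))[1L])
  t
}

modal_spacing <- function(dt) {
  tab <- table(dt)
  as.numeric(names(tab)[which.max(tab)])
}

#' Write a labelled household dataset as REFIT-style CSV files
#'
#' Emits the same dialect [load_power_csv()] reads (`Time`, `Aggregate`, one
#' column per appliance) plus a per-day labels CSV (`date,label`).
#'
#' @param dataset A [generate_household()] result.
#' @param path Output CSV path for the traces.
#' @param labels_path Optional path for the labels CSV (default: `path` with
#'   a `_labels.csv` suffix).
#' @return Invisibly, the two paths written.
#' @export
write_household_csv <- function(dataset, path,
                                labels_path = sub("\\.csv$", "_labels.csv", path)) {
  stopifnot(inherits(dataset, "labelled_dataset"))
  times <- series_times(dataset$aggregate)
  df <- data.frame(Time = format(times, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                   Aggregate = dataset$aggregate$values,
                   check.names = FALSE)
  for (ap in names(dataset$appliances)) {
    df[[ap]] <- dataset$appliances[[ap]]$values
  }
  utils::write.csv(df, path, row.names = FALSE)
  utils::write.csv(dataset$labels, labels_path, row.names = FALSE)
  invisible(c(path, labels_path))
}

#' Write anomaly reports as JSON lines
#'
#' One JSON object per monitored day with the day's score, decision interval,
#' decision, anomaly class (null for normal days) and contributing
#' activations.  The file round-trips losslessly through [read_report()].
#'
#' @param reports A data frame of day reports as produced by
#'   [monitor_household()] (columns `date`, `activity`, `score`, `lower`,
#'   `upper`, `decision`, `anomaly_class`, list-column `activations`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(reports, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (NROW(reports) == 0L) return(invisible(path))
  for (i in seq_len(nrow(reports))) {
    acts <- reports$activations[[i]]
    rec <- list(
      date = as.character(reports$date[i]),
      activity = reports$activity[i],
      score = if (is.na(reports$score[i])) NULL else reports$score[i],
      lower = reports$lower[i],
      upper = reports$upper[i],
      decision = reports$decision[i],
      anomaly_class = if (is.na(reports$anomaly_class[i])) NULL else
        reports$anomaly_class[i],
      activations = if (NROW(acts) == 0L) list() else lapply(
        seq_len(nrow(acts)), function(j) {
          rec <- list(
            start = format(acts$start[j], "%Y-%m-%d %H:%M:%S", tz = "UTC"),
            duration = acts$duration[j],
            max_power = acts$max_power[j],
            day_of_week = acts$day_of_week[j],
            day_of_month = acts$day_of_month[j])
          if (!is.null(acts$verdict)) rec$verdict <- acts$verdict[j]
          rec
        })
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                digits = NA), con)
  }
  invisible(path)
}

#' Read a JSON-lines anomaly report written by [write_report()]
#'
#' @param path File path.
#' @return Data frame in the same layout [write_report()] consumes.
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(data.frame(date = as.Date(character()), activity = character(),
                      score = numeric(), lower = numeric(), upper = numeric(),
                      decision = character(), anomaly_class = character()))
  }
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = FALSE)
  out <- data.frame(
    date = as.Date(vapply(recs, `[[`, "", "date")),
    activity = vapply(recs, `[[`, "", "activity"),
    score = vapply(recs, function(r)
      if (is.null(r$score)) NA_real_ else as.numeric(r$score), 0),
    lower = vapply(recs, function(r) as.numeric(r$lower), 0),
    upper = vapply(recs, function(r) as.numeric(r$upper), 0),
    decision = vapply(recs, `[[`, "", "decision"),
    anomaly_class = vapply(recs, function(r)
      if (is.null(r$anomaly_class)) NA_character_ else r$anomaly_class, ""),
    stringsAsFactors = FALSE)
  out$activations <- lapply(recs, function(r) {
    if (length(r$activations) == 0L) return(empty_activations())
    df <- data.frame(
      start = as.POSIXct(vapply(r$activations, `[[`, "", "start"), tz = "UTC"),
      duration = vapply(r$activations, function(a) as.numeric(a$duration), 0),
      max_power = vapply(r$activations, function(a) as.numeric(a$max_power), 0),
      day_of_week = vapply(r$activations, function(a)
        as.integer(a$day_of_week), 0L),
      day_of_month = vapply(r$activations, function(a)
        as.integer(a$day_of_month), 0L))
    verdicts <- lapply(r$activations, function(a) a$verdict)
    if (!any(vapply(verdicts, is.null, TRUE))) {
      df$verdict <- unlist(verdicts)
    }
    df
  })
  out
}
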