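#' Pipeline configuration
#'
#' Bundles the tunable parameters of the monitoring pipeline with their
#' defaults and validity constraints.
#'
#' @param state_threshold Watts above which an appliance counts as ON
#'   (default 500, appropriate for high-power hand-operated appliances such
#'   as a kettle).
#' @param bins_per_day Number of equal bins an activity curve divides the day
#'   into (default 24, i.e. hourly).
#' @param beta Weighting ratio between days without and with external-agent
#'   feedback in the divergence weights; must be `>= 2`.
#' @param observation_days Length of the passive observation phase in days
#'   (default 51); also the capacity of the observation store.
#' @param anomaly_rate Fraction of days an injection run converts to a given
#'   anomaly class (default 0.10).
#' @param iqr_factor Multiplier on the inter-quantile range in the decision
#'   interval (default 1.5).
#' @param min_duration Shortest ON episode kept as an activation, seconds.
#' @param merge_gap OFF gaps up to this many seconds are bridged when
#'   extracting activations.
#' @param night_band Half-open hour interval `[from, to)` counted as night
#'   (default `c(0, 4)`).
#' @param activation_level Logical; run appliance-level (similarity-matrix)
#'   anomaly analysis on days flagged anomalous.
#' @param sample_period Sample period of the traces, seconds.
#' @param seed Integer seed for every stochastic step.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(state_threshold = 500,
                            bins_per_day = 24,
                            beta = 2,
                            observation_days = 51,
                            anomaly_rate = 0.10,
                            iqr_factor = 1.5,
                            min_duration = 16,
                            merge_gap = 16,
                            night_band = c(0, 4),
                            activation_level = TRUE,
                            sample_period = 8,
                            seed = 1L) {
  if (beta < 2) stop("configuration error: `beta` must be >= 2")
  if (anomaly_rate < 0 || anomaly_rate > 1) {
    stop("configuration error: `anomaly_rate` must lie in [0, 1]")
  }
  if (state_threshold <= 0) stop("configuration error: `state_threshold` must be > 0")
  if (bins_per_day < 1) stop("configuration error: `bins_per_day` must be >= 1")
  samples_per_day <- 24 * 3600 / sample_period
  if (samples_per_day %% bins_per_day != 0) {
    stop("configuration error: `bins_per_day` must divide the ",
         samples_per_day, " samples of a day evenly")
  }
  if (length(night_band) != 2L || night_band[1] < 0 || night_band[2] > 24 ||
      night_band[1] >= night_band[2]) {
    stop("configuration error: `night_band` must be an increasing pair in [0, 24]")
  }
  structure(list(
    state_threshold = state_threshold, bins_per_day = as.integer(bins_per_day),
    beta = beta, observation_days = as.integer(observation_days),
    anomaly_rate = anomaly_rate, iqr_factor = iqr_factor,
    min_duration = min_duration, merge_gap = merge_gap,
    night_band = as.numeric(night_band),
    activation_level = isTRUE(activation_level),
    sample_period = sample_period, seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML or JSON file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys raise an
#' error, absent keys take their defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown)) {
    stop("configuration error: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' Default mapping from daily activities to indicating appliances
#'
#' The activity vocabulary follows the instrumental-activities-of-daily-
#' living literature: each activity is indicated by a set of hand-operated
#' appliances, and one appliance may serve several activities.
#'
#' @return Named list: activity name to character vector of appliance ids.
#' @export
default_activity_mapping <- function() {
  list(
    cooking      = c("kettle", "oven", "coffee_maker", "microwave", "toaster"),
    ironing      = "iron",
    entertaining = c("television", "audio_system"),
    laundry      = c("washing_machine", "washer_dryer"),
    cleaning     = c("dishwasher", "vacuum_cleaner")
  )
}

#' Validate an activity-to-appliance mapping
#'
#' @param mapping Named list of non-empty character vectors.
#' @return The mapping, invisibly, after validation.
#' @export
validate_mapping <- function(mapping) {
  if (!is.list(mapping) || is.null(names(mapping)) ||
      any(!nzchar(names(mapping)))) {
    stop("configuration error: mapping must be a named list")
  }
  empty <- vapply(mapping, function(x) length(x) == 0L, TRUE)
  if (any(empty)) {
    stop("configuration error: activity '", names(mapping)[empty][1L],
         "' maps to no appliances")
  }
  invisible(mapping)
}
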