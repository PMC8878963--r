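# Shared in-code fixtures for the suite.

T0 <- as.POSIXct("2014-09-01", tz = "UTC")

make_ps <- function(values, channel = "kettle", period = 8, start = T0) {
  power_series(channel, start, period, values)
}

# One activation per positive bin, with duration proportional to the bin
# probability, so the resulting activity curve equals `bins` exactly
# (durations stay well inside a single hour bin).
acts_from_bins <- function(date, bins, appliance = "kettle",
                           max_power = 2000) {
  idx <- which(bins > 0)
  start <- as.POSIXct(date, tz = "UTC") + (idx - 1L) * 3600
  adlwatch:::activation_frame(rep(appliance, length(idx)), start,
                              duration = bins[idx] * 1000,
                              max_power = rep(max_power, length(idx)))
}

# Observation store whose successive days carry the given bin vectors.
store_from_bins <- function(bin_rows, feedback = rep(FALSE, length(bin_rows)),
                            start_date = as.Date("2014-09-01"),
                            capacity = length(bin_rows),
                            track_similarity = TRUE) {
  mapping <- list(cooking = "kettle")
  st <- observation_store(capacity, mapping, activities = "cooking",
                          track_similarity = track_similarity)
  for (i in seq_along(bin_rows)) {
    st <- store_add_day(st, start_date + i - 1L,
                        acts_from_bins(start_date + i - 1L, bin_rows[[i]]),
                        feedback = feedback[i])
  }
  st
}

point_mass <- function(bin, n_bins = 24) {
  x <- numeric(n_bins)
  x[bin + 1L] <- 1
  x
}

random_curve <- function(n_bins = 24, sparsity = 0.5) {
  x <- stats::runif(n_bins)
  x[stats::runif(n_bins) < sparsity] <- 0
  if (sum(x) == 0) x[sample.int(n_bins, 1L)] <- 1
  x / sum(x)
}

# Independent brute-force generalised JSD: explicit elementwise loops,
# sharing no code with the package implementation.
jsd_bruteforce <- function(P, w) {
  n_bins <- ncol(P)
  M <- numeric(n_bins)
  for (i in seq_len(nrow(P))) {
    for (x in seq_len(n_bins)) M[x] <- M[x] + w[i] * P[i, x]
  }
  total <- 0
  for (i in seq_len(nrow(P))) {
    d <- 0
    for (x in seq_len(n_bins)) {
      if (P[i, x] > 0 && w[i] > 0) d <- d + P[i, x] * log(P[i, x] / M[x])
    }
    total <- total + w[i] * d
  }
  as.numeric(unname(total))
}
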