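test_that("generation is deterministic under a fixed seed", {
  a <- generate_household(house4_profile(), n_days = 5, seed = 9)
  b <- generate_household(house4_profile(), n_days = 5, seed = 9)
  expect_identical(a$aggregate$values, b$aggregate$values)
  expect_identical(a$activations, b$activations)
  c <- generate_household(house4_profile(), n_days = 5, seed = 10)
  expect_false(identical(a$aggregate$values, c$aggregate$values))
})

test_that("zero activation rates give a silent appliance", {
  spec <- list(kettle = appliance_profile(
    "kettle", 2000, data.frame(start = 7, end = 9, rate = 0)))
  ds <- generate_household(spec, n_days = 3, seed = 1)
  expect_true(all(ds$appliances$kettle$values == 0))
  expect_true(all(ds$labels$label == "normal"))
})

test_that("the diurnal preset never starts an activation at night", {
  ds <- generate_household(house4_profile(), n_days = 100, seed = 123)
  h <- true_activations(ds)$start_hour
  expect_gt(length(h), 100)           # kettle used daily, several times
  expect_false(any(h >= 22 | h < 5))
})

test_that("the night-habit preset does produce night activations", {
  ds <- generate_household(house11_profile(), n_days = 50, seed = 123)
  h <- true_activations(ds)$start_hour
  expect_true(any(h >= 0 & h < 4))
})

test_that("aggregate equals appliances plus base load plus stored noise", {
  specs <- c(house4_profile(), list(
    oven = appliance_profile("oven", 2400,
                             data.frame(start = 17, end = 19, rate = 0.8),
                             duration_dist = list(mean = 1800, sd = 300,
                                                  min = 600))))
  ds <- generate_household(specs, n_days = 4, base_load = 35, noise_sd = 12,
                           seed = 3)
  channel_sum <- Reduce(`+`, lapply(ds$appliances, `[[`, "values"))
  expect_equal(ds$aggregate$values, channel_sum + 35 + ds$noise,
               tolerance = 1e-12)
  expect_true(all(ds$aggregate$values >= channel_sum - 1e-9))
})

test_that("injection converts exactly round(rate * n) eligible days", {
  ds <- generate_household(house4_profile(), n_days = 60, seed = 21)
  ds <- inject_anomalies(ds, "night_usage", 0.10, seed = 22)
  expect_equal(sum(ds$labels$label == "night_usage"), 6L)
  ds <- inject_anomalies(ds, "divergent_usage", 0.10, seed = 23)
  expect_equal(sum(ds$labels$label == "divergent_usage"), 6L)
  # classes land on disjoint day sets
  expect_equal(sum(ds$labels$label != "normal"), 12L)
})

test_that("rate zero leaves the dataset untouched", {
  ds <- generate_household(house4_profile(), n_days = 10, seed = 2)
  ds2 <- inject_anomalies(ds, "absence", 0, seed = 2)
  expect_identical(ds$activations, ds2$activations)
  expect_identical(ds$labels, ds2$labels)
})

test_that("night insertions start strictly inside the 0-4 h band", {
  ds <- generate_household(house4_profile(), n_days = 50, seed = 31)
  before <- true_activations(ds)
  ds <- inject_anomalies(ds, "night_usage", 0.2, seed = 32)
  after <- true_activations(ds)
  added <- after[!paste(after$start, after$duration) %in%
                   paste(before$start, before$duration), ]
  expect_gt(nrow(added), 0)
  expect_true(all(added$start_hour >= 0 & added$start_hour < 4))
  # at most 2 insertions per day, at least 1
  per_day <- table(added$date)
  expect_true(all(per_day >= 1 & per_day <= 2))
})

test_that("divergent shifts never land in the night band", {
  ds <- generate_household(house4_profile(), n_days = 80, seed = 41)
  ds <- inject_anomalies(ds, "divergent_usage", 0.25, seed = 42)
  div_days <- ds$labels$date[ds$labels$label == "divergent_usage"]
  acts <- true_activations(ds)
  h <- acts$start_hour[acts$date %in% div_days]
  expect_gt(length(h), 0)
  expect_false(any(h >= 0 & h < 4))
})

test_that("absence removes the day's pulses from appliance and aggregate", {
  ds <- generate_household(house4_profile(), n_days = 20, seed = 51,
                           noise_sd = 0)
  ds2 <- inject_anomalies(ds, "absence", 0.10, seed = 52)
  gone <- ds2$labels$date[ds2$labels$label == "absence"]
  expect_equal(length(gone), 2L)
  acts2 <- true_activations(ds2)
  expect_false(any(acts2$date %in% gone))
  # brute-force re-summation: aggregate drop equals exactly the removed
  # kettle samples
  drop_agg <- ds$aggregate$values - ds2$aggregate$values
  drop_kettle <- ds$appliances$kettle$values - ds2$appliances$kettle$values
  expect_equal(drop_agg, drop_kettle, tolerance = 1e-12)
  day_idx <- which(ds$labels$date %in% gone)
  samples_per_day <- 86400 / ds$sample_period
  in_day <- rep(FALSE, length(drop_agg))
  for (d in day_idx) {
    in_day[((d - 1) * samples_per_day + 1):(d * samples_per_day)] <- TRUE
  }
  expect_true(all(drop_kettle[!in_day] == 0))
})

test_that("injection refuses when normal days run short", {
  ds <- generate_household(house4_profile(), n_days = 10, seed = 61)
  ds <- inject_anomalies(ds, "absence", 0.9, seed = 62)
  expect_error(inject_anomalies(ds, "night_usage", 0.5, seed = 63),
               "fewer normal days")
})

test_that("profile validation rejects impossible windows", {
  expect_error(appliance_profile("k", 2000,
                                 data.frame(start = 9, end = 7, rate = 1)),
               "precede")
  expect_error(appliance_profile("k", 2000,
                                 data.frame(start = 1, end = 3, rate = 1),
                                 night_use = FALSE),
               "night band")
  expect_error(appliance_profile("k", -5,
                                 data.frame(start = 7, end = 9, rate = 1)),
               "rated_power")
})

test_that("a dataset rebuilt from CSV channels supports injection", {
  ds <- generate_household(house4_profile(), n_days = 12, seed = 91,
                           base_load = 30, noise_sd = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_household_csv(ds, path)
  chans <- load_power_csv(path, c(aggregate = "Aggregate",
                                  kettle = "kettle"))
  ds2 <- dataset_from_channels(chans)
  expect_equal(ds2$aggregate$values, ds$aggregate$values, tolerance = 1e-6)
  expect_equal(ds2$n_days, 12L)
  # injection still keeps channel/aggregate consistency on the rebuilt set
  ds3 <- inject_anomalies(ds2, "absence", 0.25, seed = 92)
  gone <- ds3$labels$date[ds3$labels$label == "absence"]
  expect_equal(length(gone), 3L)
  drop_agg <- ds2$aggregate$values - ds3$aggregate$values
  drop_kettle <- ds2$appliances$kettle$values - ds3$appliances$kettle$values
  expect_equal(drop_agg, drop_kettle, tolerance = 1e-9)
})
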