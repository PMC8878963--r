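test_that("divergence weights follow the feedback partition and sum to 1", {
  w <- compute_weights(rep(FALSE, 5), beta = 2)
  expect_equal(w$pi, rep(0.2, 5))
  expect_equal(w$N1, 0); expect_equal(w$N2, 5)

  w2 <- compute_weights(c(TRUE, FALSE, FALSE), beta = 2)
  expect_equal(w2$pi, c(0.2, 0.4, 0.4))

  w3 <- compute_weights(rep(TRUE, 4), beta = 3)
  expect_equal(w3$pi, rep(0.25, 4))

  expect_error(compute_weights(rep(FALSE, 3), beta = 1.9), "beta")
  expect_error(compute_weights(logical(0)), "empty")

  for (beta in c(2, 3, 5)) {
    for (n1 in c(0, 1, 7)) {
      for (n2 in c(0, 1, 12)) {
        if (n1 + n2 == 0) next
        w <- compute_weights(c(rep(TRUE, n1), rep(FALSE, n2)), beta)
        expect_equal(sum(w$pi), 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("generalised JSD has its closed-form landmarks", {
  p <- random_curve()
  expect_equal(generalized_jsd(rbind(p, p), c(0.5, 0.5)), 0)
  expect_equal(generalized_jsd(rbind(point_mass(3), point_mass(17)),
                               c(0.5, 0.5)), log(2))
  q <- random_curve()
  expect_equal(generalized_jsd(rbind(p, q), c(1, 0)), 0)
})

test_that("generalised JSD equals a brute-force bin summation", {
  set.seed(404)
  for (rep in 1:200) {
    n <- sample(2:5, 1)
    P <- do.call(rbind, replicate(n, random_curve(), simplify = FALSE))
    w <- runif(n); w <- w / sum(w)
    expect_equal(generalized_jsd(P, w), jsd_bruteforce(P, w),
                 tolerance = 1e-12)
  }
})

test_that("JSD is permutation-symmetric, non-negative and bounded", {
  set.seed(405)
  for (rep in 1:50) {
    P <- rbind(random_curve(), random_curve(), random_curve())
    w <- runif(3); w <- w / sum(w)
    perm <- sample(3)
    expect_equal(generalized_jsd(P[perm, ], w[perm]),
                 generalized_jsd(P, w), tolerance = 1e-12)
    v <- generalized_jsd(P[1:2, ], c(0.5, 0.5))
    expect_gte(v, 0)
    expect_lte(v, log(2) + 1e-12)
  }
})

test_that("day_score compares the day with the weighted stored mixture", {
  p <- random_curve()
  st <- store_from_bins(list(p))
  cv <- structure(list(date = as.Date("2014-10-22"), activity = "cooking",
                       bins = p, total_duration = 3600, empty = FALSE),
                  class = "activity_curve")
  expect_equal(day_score(cv, st)$jsd, 0)

  # day-time store versus a night-only day: disjoint support, maximal score
  st2 <- store_from_bins(list(point_mass(8), point_mass(9), point_mass(12)))
  night <- structure(list(date = as.Date("2014-10-22"), activity = "cooking",
                          bins = point_mass(2), total_duration = 600,
                          empty = FALSE), class = "activity_curve")
  expect_equal(day_score(night, st2)$jsd, log(2))

  # scores never exceed the two-distribution bound
  set.seed(7)
  st3 <- store_from_bins(replicate(6, random_curve(), simplify = FALSE))
  for (i in 1:20) {
    cv <- structure(list(date = as.Date("2014-10-22"), activity = "cooking",
                         bins = random_curve(), total_duration = 100,
                         empty = FALSE), class = "activity_curve")
    expect_lte(day_score(cv, st3)$jsd, log(2) + 1e-12)
  }

  empty_cv <- structure(list(date = as.Date("2014-10-22"),
                             activity = "cooking", bins = NULL,
                             total_duration = 0, empty = TRUE),
                        class = "activity_curve")
  sc <- day_score(empty_cv, st2)
  expect_true(sc$empty_day)
})

test_that("day_score matches an independent mixture-and-divergence oracle", {
  set.seed(11)
  curves <- replicate(8, random_curve(), simplify = FALSE)
  flags <- c(TRUE, rep(FALSE, 7))
  st <- store_from_bins(curves, feedback = flags)
  day <- random_curve()
  cv <- structure(list(date = as.Date("2014-10-22"), activity = "cooking",
                       bins = day, total_duration = 100, empty = FALSE),
                  class = "activity_curve")
  got <- day_score(cv, st, beta = 2)$jsd
  # oracle: explicit weights, mixture and equal-weight two-curve JSD
  pi <- ifelse(flags, 1, 2) / (1 + 2 * 7)
  M <- colSums(do.call(rbind, curves) * pi)
  expect_equal(got, jsd_bruteforce(rbind(day, M), c(0.5, 0.5)),
               tolerance = 1e-12)
})

test_that("IQR interval uses interpolated quartiles", {
  iv <- iqr_interval(c(1, 2, 3, 4, 5))
  expect_equal(iv$q1, 2); expect_equal(iv$q3, 4)
  expect_equal(iv$lower, -1); expect_equal(iv$upper, 7)

  cst <- iqr_interval(rep(0.3, 6))
  expect_equal(cst$lower, 0.3); expect_equal(cst$upper, 0.3)

  expect_error(iqr_interval(c(1, 2, 3)), "insufficient observation days")
})

test_that("the IQR fence covers roughly 99.3% of normal data", {
  set.seed(2024)
  x <- rnorm(10000)
  iv <- iqr_interval(x)
  cover <- mean(x >= iv$lower & x <= iv$upper)
  expect_gte(cover, 0.985)
  expect_lte(cover, 0.998)
})

test_that("classify_day flags scores outside the reference fence", {
  p <- point_mass(8)
  st <- store_from_bins(list(p, p, p, p, p))
  cfg <- pipeline_config(observation_days = 5)
  same <- structure(list(date = as.Date("2014-10-22"), activity = "cooking",
                         bins = p, total_duration = 600, empty = FALSE),
                    class = "activity_curve")
  out <- classify_day(same, st, cfg)
  expect_equal(out$decision, "normal")
  expect_equal(out$score$jsd, 0)
  expect_equal(out$interval$lower, 0)
  expect_equal(out$interval$upper, 0)

  night <- structure(list(date = as.Date("2014-10-22"), activity = "cooking",
                          bins = point_mass(2), total_duration = 600,
                          empty = FALSE), class = "activity_curve")
  expect_equal(classify_day(night, st, cfg)$decision, "anomalous")

  empty_cv <- structure(list(date = as.Date("2014-10-22"),
                             activity = "cooking", bins = NULL,
                             total_duration = 0, empty = TRUE),
                        class = "activity_curve")
  expect_equal(classify_day(empty_cv, st, cfg)$decision, "anomalous")
})

test_that("similarity distances use circular hours and log durations", {
  a <- adlwatch:::activation_frame(rep("kettle", 2),
                                   as.POSIXct("2014-09-01", tz = "UTC") +
                                     c(3600, 3600), c(180, 180), 2000)
  m <- build_similarity_matrix(a)
  expect_equal(m, matrix(0, 2, 2))

  b <- adlwatch:::activation_frame(rep("kettle", 2),
                                   as.POSIXct("2014-09-01", tz = "UTC") +
                                     c(1, 23) * 3600, c(180, 180), 2000)
  m2 <- build_similarity_matrix(b)
  expect_equal(m2[1, 2], 2)            # wrap-around, not 22

  set.seed(5)
  c3 <- adlwatch:::activation_frame(rep("kettle", 6),
                                    as.POSIXct("2014-09-01", tz = "UTC") +
                                      runif(6, 0, 86000),
                                    runif(6, 60, 600), 2000)
  m3 <- build_similarity_matrix(c3)
  expect_equal(m3, t(m3))
  expect_equal(diag(m3), rep(0, 6))
  expect_error(build_similarity_matrix(c3[1, ]), "at least 2")
})

test_that("activation verdicts separate variations from deviations", {
  # history: a tight morning cluster over several stored days
  set.seed(6)
  d0 <- as.Date("2014-09-01")
  st <- observation_store(10, list(cooking = "kettle"),
                          activities = "cooking")
  for (i in 1:6) {
    a <- adlwatch:::activation_frame(
      "kettle", as.POSIXct(d0 + i - 1, tz = "UTC") +
        (7 + runif(2, 0, 0.3)) * 3600, c(170, 190), 2000)
    st <- store_add_day(st, d0 + i - 1, a)
  }
  inside <- adlwatch:::activation_frame(
    "kettle", as.POSIXct(d0 + 9, tz = "UTC") + 7.1 * 3600, 180, 2000)
  expect_equal(classify_activation(inside, st), "variation")
  far <- adlwatch:::activation_frame(
    "kettle", as.POSIXct(d0 + 9, tz = "UTC") + 17 * 3600, 180, 2000)
  expect_equal(classify_activation(far, st), "deviation")

  # two well-separated habitual clusters: membership of either is normal
  st2 <- observation_store(10, list(cooking = "kettle"),
                           activities = "cooking")
  for (i in 1:6) {
    a <- adlwatch:::activation_frame(
      "kettle", as.POSIXct(d0 + i - 1, tz = "UTC") +
        c(7 + runif(1, 0, 0.3), 18 + runif(1, 0, 0.3)) * 3600,
      c(180, 180), 2000)
    st2 <- store_add_day(st2, d0 + i - 1, a)
  }
  evening <- adlwatch:::activation_frame(
    "kettle", as.POSIXct(d0 + 9, tz = "UTC") + 18.15 * 3600, 180, 2000)
  expect_equal(classify_activation(evening, st2), "variation")

  lone <- observation_store(5, list(cooking = "kettle"),
                            activities = "cooking")
  expect_error(classify_activation(inside, lone), "no activation history")
})

test_that("anomaly classes follow the absence/night/abnormal priority", {
  d <- as.Date("2014-10-22")
  none <- adlwatch:::empty_activations()
  expect_equal(classify_anomaly_type(d, none, "anomalous"), "absence")

  night <- adlwatch:::activation_frame(
    "kettle", as.POSIXct(d, tz = "UTC") + 2.5 * 3600, 180, 2000)
  expect_equal(classify_anomaly_type(d, night, "anomalous"), "night_usage")

  noon <- adlwatch:::activation_frame(
    "kettle", as.POSIXct(d, tz = "UTC") + 15 * 3600, 180, 2000)
  expect_equal(classify_anomaly_type(d, noon, "anomalous"),
               "abnormal_usage_time")
  # night takes precedence over daytime activations on the same day
  both <- rbind(night, noon)
  expect_equal(classify_anomaly_type(d, both, "anomalous"), "night_usage")

  expect_error(classify_anomaly_type(d, noon, "normal"), "contract error")
})

test_that("moving day mass farther from a unimodal profile never lowers the score", {
  prof <- c(0.05, 0.9, 0.05, rep(0, 21))   # unimodal around bin 2
  st <- store_from_bins(list(prof, prof, prof, prof))
  score_at <- vapply(1:12, function(b) {
    cv <- structure(list(date = as.Date("2014-10-22"), activity = "cooking",
                         bins = point_mass(b), total_duration = 600,
                         empty = FALSE), class = "activity_curve")
    day_score(cv, st)$jsd
  }, 0)
  expect_true(all(diff(score_at) >= -1e-12))
})
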