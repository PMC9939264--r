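test_that("degenerate parameters are rejected", {
  expect_error(society_params(n_units = 0), "n_units")
  expect_error(society_params(unit_size_mean = 1), "unit_size_mean")
  expect_error(society_params(census_detect_prob = 1.4), "probability")
  expect_error(society_params(study_start = "2021-01-01", study_end = "2020-01-01"),
               "precede")
  expect_error(society_params(supergroup_windows = list("2021-01-01")), "start < end")
})

test_that("an event-free society has constant membership and an empty event log", {
  p <- perfect_params(n_units = 3L, unit_size_mean = 5L, seed = 4L)
  truth <- simulate_membership(p)
  expect_equal(nrow(truth$events), 0L)
  per_ind <- split(truth$membership$cluster, truth$membership$individual)
  expect_true(all(vapply(per_ind, function(cl) length(unique(cl)) == 1L, logical(1))))
})

test_that("daily clusters partition the population", {
  p <- society_params(n_units = 4L, unit_size_mean = 6L,
                      study_start = "2020-09-01", study_end = "2020-11-01",
                      fission_rate = 0.1, fission_duration_mean = 4,
                      supergroup_windows = list(c("2020-09-20", "2020-10-10")),
                      supergroup_join_prob = 0.8, seed = 6L)
  truth <- simulate_membership(p)
  n_ind <- nrow(truth$individuals)
  by_day <- split(truth$membership, truth$membership$date)
  for (day in by_day) {
    expect_equal(sort(day$individual), sort(truth$individuals$individual))
    expect_equal(nrow(day), n_ind)  # each individual in exactly one cluster
  }
  # latent unit identity is never destroyed
  expect_true(all(truth$membership$unit ==
                    rep(truth$individuals$unit, length(by_day))))
})

test_that("a permanent full-join supergroup gives one cluster but two latent units", {
  p <- perfect_params(n_units = 2L, unit_size_mean = 5L,
                      study_start = "2020-09-01", study_end = "2020-10-01",
                      supergroup_windows = list(c("2020-09-01", "2020-10-01")),
                      supergroup_join_prob = 1, seed = 2L)
  truth <- simulate_membership(p)
  per_day_clusters <- tapply(truth$membership$cluster, truth$membership$date,
                             function(x) length(unique(x)))
  expect_true(all(per_day_clusters == 1L))
  expect_equal(length(unique(truth$membership$unit)), 2L)
  expect_true("supergroup_form" %in% truth$events$event)
})

test_that("fission events occur at the configured per-unit daily rate", {
  p <- society_params(n_units = 8L, unit_size_mean = 10L,
                      study_start = "2020-09-01", study_end = "2021-02-28",
                      fission_rate = 0.05, fission_duration_mean = 1,
                      seed = 1L)
  truth <- simulate_membership(p)
  n_fissions <- sum(truth$events$event == "fission")
  n_trials <- 8L * as.integer(p$study_end - p$study_start)
  mu <- n_trials * 0.05
  sigma <- sqrt(n_trials * 0.05 * 0.95)
  # the rate is gated by ongoing one-day fissions, so the count sits below
  # the binomial mean but must stay within 3 SD of it
  expect_gt(n_fissions, mu - 3 * sigma)
  expect_lt(n_fissions, mu + 3 * sigma)
})

test_that("perfect observation produces two identical 'single' records per unit per day", {
  p <- perfect_params(n_units = 2L, unit_size_mean = 5L,
                      study_start = "2020-09-01", study_end = "2020-09-11", seed = 3L)
  truth <- simulate_membership(p)
  census <- simulate_census(truth, p)
  expect_true(all(census$cohesion == "single"))
  expect_true(all(census$complete))
  expect_true(all(census$n_unmarked == 0L))
  n_days <- 10L
  expect_equal(nrow(census), 2L * 2L * n_days)
  members <- split(truth$individuals$individual, truth$individuals$unit)
  for (r in seq_len(nrow(census))) {
    ids <- census$individual_ids[[r]]
    unit <- truth$individuals$unit[match(ids[1L], truth$individuals$individual)]
    expect_setequal(ids, members[[unit]])
  }
})

test_that("census simulation is reproducible and seed-sensitive", {
  p <- society_params(n_units = 3L, unit_size_mean = 6L,
                      study_start = "2020-09-01", study_end = "2020-10-01", seed = 9L)
  t1 <- simulate_membership(p)
  expect_identical(simulate_census(t1, p), simulate_census(t1, p))
  p2 <- society_params(n_units = 3L, unit_size_mean = 6L,
                       study_start = "2020-09-01", study_end = "2020-10-01", seed = 10L)
  t2 <- simulate_membership(p2)
  expect_false(identical(simulate_census(t1, p), simulate_census(t2, p2)))
})

test_that("the share of identifiable individuals tracks marked_fraction", {
  p <- society_params(n_units = 10L, unit_size_mean = 25L,
                      study_start = "2020-09-01", study_end = "2020-10-01",
                      marked_fraction = 0.9, census_detect_prob = 1,
                      individual_miss_prob = 0, multiple_encounter_prob = 0,
                      incomplete_prob = 0, fission_rate = 0, seed = 12L)
  truth <- simulate_membership(p)
  census <- simulate_census(truth, p)
  seen <- unique(unlist(census$individual_ids))
  n <- nrow(truth$individuals)
  p_hat <- length(seen) / n
  expect_lt(abs(p_hat - 0.9), 3 * sqrt(0.9 * 0.1 / n))
})

test_that("a supergroup day yields one 'single' record containing both units", {
  p <- perfect_params(n_units = 2L, unit_size_mean = 5L,
                      study_start = "2020-09-01", study_end = "2020-09-03",
                      supergroup_windows = list(c("2020-09-01", "2020-09-03")),
                      supergroup_join_prob = 1, seed = 5L)
  truth <- simulate_membership(p)
  census <- simulate_census(truth, p)
  expect_true(all(census$cohesion == "single"))
  expect_true(all(lengths(census$individual_ids) == nrow(truth$individuals)))
})

test_that("zero spread puts same-cluster males on identical coordinates", {
  p <- perfect_params(n_units = 2L, unit_size_mean = 6L,
                      study_start = "2020-09-01", study_end = "2020-09-04",
                      within_unit_spread = 0, n_gps_males_per_unit = 3L,
                      seed = 7L)
  truth <- simulate_membership(p)
  gps <- simulate_gps(truth, p)
  unit_of <- stats::setNames(truth$individuals$unit, truth$individuals$individual)
  gps$unit <- unit_of[gps$individual]
  spread <- tapply(gps$easting, paste(gps$unit, gps$timestamp),
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))
})

test_that("pinned centroids keep two units exactly unit_spacing apart", {
  p <- perfect_params(n_units = 2L, unit_size_mean = 4L,
                      study_start = "2020-09-01", study_end = "2020-09-03",
                      within_unit_spread = 0, home_range_scale = 0,
                      unit_spacing = 5000, n_gps_males_per_unit = 1L, seed = 8L)
  truth <- simulate_membership(p)
  gps <- simulate_gps(truth, p)
  wide <- merge(gps[gps$individual == gps$individual[1L], ],
                gps[gps$individual != gps$individual[1L], ],
                by = "timestamp")
  d <- sqrt((wide$easting.x - wide$easting.y)^2 +
              (wide$northing.x - wide$northing.y)^2)
  expect_true(all(d == 5000))
})

test_that("within-unit scatter reproduces the closed-form mean dyadic distance", {
  # two independent bivariate-normal positions with sd = 50 m per axis are
  # sqrt(pi) * 50 ~ 88.6 m apart on average
  p <- perfect_params(n_units = 1L, unit_size_mean = 8L,
                      study_start = "2020-09-01", study_end = "2020-09-21",
                      within_unit_spread = 50, home_range_scale = 0,
                      n_gps_males_per_unit = 4L, seed = 13L)
  truth <- simulate_membership(p)
  gps <- simulate_gps(truth, p)
  part <- community_partition("w", stats::setNames(
    truth$individuals$unit, truth$individuals$individual), "t")
  coh <- daily_pairwise_distances(subsample_fixes(gps), part)
  expect_lt(abs(coh$mean_daily_distance - 50 * sqrt(pi)) / (50 * sqrt(pi)), 0.05)
})

test_that("society CSV exports round-trip through the loaders", {
  p <- perfect_params(n_units = 2L, unit_size_mean = 4L,
                      study_start = "2020-09-01", study_end = "2020-09-05",
                      n_gps_males_per_unit = 2L, seed = 14L)
  sim <- simulate_society(p)
  dir <- withr::local_tempdir()
  write_society(sim, dir)
  census_back <- load_census(file.path(dir, "census.csv"))
  expect_equal(census_back$individual_ids, sim$census$individual_ids)
  expect_equal(census_back$date, sim$census$date)
  gps_back <- load_gps(file.path(dir, "gps.csv"))
  expect_equal(gps_back$individual, sim$gps$individual)
  expect_equal(gps_back$timestamp, sim$gps$timestamp)
  expect_equal(gps_back$easting, sim$gps$easting, tolerance = 1e-6)
})
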