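test_that("designs respect the study layout and are seed-reproducible", {
  d <- generate_design(9, seed = 1)
  expect_identical(d$n_sites, 9L)
  expect_length(d$grids_per_site, 9L)
  expect_true(all(d$grids_per_site >= 2 & d$grids_per_site <= 12))
  expect_identical(generate_design(9, seed = 1), d)
  expect_false(identical(generate_design(9, seed = 2)$grids_per_site,
                         d$grids_per_site))
  d1 <- generate_design(1, seed = 0)
  expect_identical(d1$n_sites, 1L)
  expect_error(generate_design(0), "positive")
  expect_error(generate_design(-3), "positive")
})

test_that("trap-night effort stays within 36 traps x 2-6 nights", {
  tn <- small_sim()$tables$captures$trap_nights
  expect_true(all(tn >= 72 & tn <= 216))
  expect_true(all(tn %% 36 == 0))
})

test_that("daily rainfall is mostly dry with the requested mean event size", {
  d <- generate_design(2, seed = 3, n_trips = 30)  # ~10 years of record
  rain <- simulate_daily_rain(d, mean_event = 5, overdispersion = 1,
                              seed = 5)
  expect_true(all(rain$rainfall >= 0))
  expect_gt(mean(rain$rainfall == 0), 0.8)
  events <- rain$rainfall[rain$rainfall > 0]
  # mean event size 5 with sd(event) = sqrt(4 + 16) on ~700 events
  mc3 <- 3 * sqrt(4 + 16) / sqrt(length(events))
  expect_lt(abs(mean(events) - 5), mc3)
  # per-site series are calendar-contiguous
  one <- rain[rain$site == rain$site[1], ]
  expect_identical(as.integer(diff(one$date)), rep(1L, nrow(one) - 1L))
})

test_that("large overdispersion approaches the light-tailed event-size limit", {
  d <- generate_design(2, seed = 3, n_trips = 30)
  rain <- simulate_daily_rain(d, mean_event = 6, overdispersion = 1e6,
                              seed = 9)
  events <- rain$rainfall[rain$rainfall > 0]
  # shifted-Poisson limit: variance -> mean_event - 1 = 5
  expect_lt(abs(stats::var(events) - 5) / 5, 0.25)
})

test_that("degenerate and invalid rainfall arguments are handled", {
  d <- generate_design(1, seed = 1)
  d$sites <- character()
  empty <- simulate_daily_rain(d, mean_event = 5, seed = 1)
  expect_identical(nrow(empty), 0L)
  d2 <- generate_design(1, seed = 1)
  expect_error(simulate_daily_rain(d2, mean_event = 0), "mean_event")
  expect_error(simulate_daily_rain(d2, mean_event = 5, overdispersion = -1),
               "overdispersion")
})

test_that("seeded simulation is byte-identical and reader-valid", {
  d <- generate_design(3, seed = 2, n_trips = 14, camera_months = 12)
  tr <- ground_truth(d)
  s1 <- simulate_dataset(d, tr, seed = 5)
  s2 <- simulate_dataset(d, tr, seed = 5)
  expect_identical(s1$tables, s2$tables)
  s3 <- simulate_dataset(d, tr, seed = 6)
  expect_false(identical(s1$tables$captures, s3$tables$captures))
  for (ty in names(s1$tables)) {
    expect_silent(validate_study_table(s1$tables[[ty]], ty))
  }
  expect_true(all(s1$tables$camera$phase %in% 1:3))
})

test_that("analysis frames rebuilt from written tables match the generator", {
  sim <- small_sim()
  frames2 <- build_node_frames(sim$tables)
  for (fr in names(sim$frames)) {
    expect_equal(as.data.frame(sim$frames[[fr]]),
                 as.data.frame(frames2[[fr]]), tolerance = 1e-12)
  }
})

test_that("ground-truth arity is validated against the canonical graph", {
  d <- small_design()
  tr <- ground_truth(d)
  expect_silent(validate_truth(tr, d))
  bad <- tr
  bad$nodes$rodents$beta <- bad$nodes$rodents$beta[-2]
  expect_error(validate_truth(bad, d), "arity")
  bad2 <- tr
  bad2$nodes$cover$sd <- -1
  expect_error(validate_truth(bad2, d), "non-negative")
  # truth built for another design (different site count) fails
  d9 <- generate_design(9, seed = 1)
  expect_error(validate_truth(ground_truth(d9), d), "arity")
})

test_that("an intercept-only node reproduces the lognormal-mixture mean", {
  d <- generate_design(9, seed = 4, n_trips = 40, camera_months = 12)
  b0 <- -4
  sigma <- 0.3
  tr <- ground_truth(
    d,
    mulgara = list(beta = c(`(Intercept)` = b0, rodent_rate = 0, cover = 0,
                            fire_years = 0), sd = sigma))
  sim <- simulate_dataset(d, tr, seed = 21)
  cap <- sim$tables$captures
  observed <- mean(cap$mulgara / cap$trap_nights)
  expected <- exp(b0 + sigma^2 / 2)
  # the trip intercepts dominate the Monte-Carlo error: 40 trip draws
  mc3 <- 3 * expected * sqrt(exp(sigma^2) - 1) / sqrt(d$n_trips)
  expect_lt(abs(observed - expected), mc3)
})

test_that("a zero-logit cover intercept gives roughly 50% cover", {
  d <- generate_design(4, seed = 8, n_trips = 12, camera_months = 12)
  tr <- ground_truth(
    d, cover = list(beta = c(`(Intercept)` = 0, fire_years = 0, rain8 = 0),
                    sd = 0))
  sim <- simulate_dataset(d, tr, seed = 31)
  expect_lt(abs(mean(sim$tables$vegetation$cover) - 50), 1.5)
})

test_that("trip random intercepts over-disperse the Poisson counts", {
  d <- generate_design(6, seed = 5, n_trips = 30, camera_months = 12)
  tr <- ground_truth(
    d,
    reptiles = list(beta = c(`(Intercept)` = -3.2, fire_years = 0,
                             cover = 0, rain_days = 0), sd = 0.5))
  sim <- simulate_dataset(d, tr, seed = 13)
  cap <- sim$tables$captures
  rate_groups <- split(cap$reptiles, cap$trap_nights)
  big <- rate_groups[[which.max(lengths(rate_groups))]]
  expect_gt(stats::var(big), mean(big))
})

test_that("truth serialization round-trips through the plain-text config", {
  tr <- small_sim()$truth
  lines <- write_truth_config(tr)
  tr2 <- read_truth_config(lines)
  for (nm in names(tr$nodes)) {
    expect_equal(tr2$nodes[[nm]]$beta, tr$nodes[[nm]]$beta)
    expect_equal(tr2$nodes[[nm]]$sd, tr$nodes[[nm]]$sd)
  }
  expect_equal(tr2$baseline_predators, tr$baseline_predators)
})
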