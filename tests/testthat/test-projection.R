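# small scenario draws shared by the projection tests
.proj_draws <- function(n_draws = 400, seed = 21) {
  list(rain = draw_scenario(scenario_spec("rainfall_8mo", 152, 419, 1.57,
                                          n_draws = n_draws, n_steps = 12,
                                          seed = seed)),
       fire = draw_scenario(scenario_spec("years_since_fire", 21, 10, 3.34,
                                          n_draws = n_draws, n_steps = 12,
                                          seed = seed + 1L)))
}

test_that("projection means equal the closed-form composed equations", {
  sem <- small_sem()
  dr <- .proj_draws()
  n_runs <- 300
  n_rod <- 120
  res <- suppressWarnings(
    propagate(sem, dr$rain, dr$fire, predator_scenario("all_predators"),
              n_runs = n_runs, n_runs_rodent = n_rod, seed = 5))

  # independent composition on the same draws
  R <- dr$rain$values[, 1:n_runs]
  FY <- dr$fire$values[, 1:n_runs]
  bc <- sem$fits$cover$beta
  bs <- sem$fits$seed$beta
  br <- sem$fits$rodents$beta
  rates_tbl <- sem$fits$rodents$model_frame[, c("cat_rate", "fox_rate",
                                                "dingo_rate")]
  rates <- withr::with_seed(5, {
    rates_tbl[sample.int(nrow(rates_tbl), n_runs, replace = TRUE), ]
  })
  cover <- 100 * plogis(bc[["(Intercept)"]] + bc[["fire_years"]] * FY +
                          bc[["rain8"]] * R)
  seedv <- 5 * plogis(bs[["(Intercept)"]] + bs[["cover"]] * cover +
                        bs[["rain8"]] * R)
  k <- 1:n_rod
  rod <- 100 * exp(br[["(Intercept)"]] + br[["seed"]] * seedv[, k] +
                     matrix(br[["cat_rate"]] * rates$cat_rate[k] +
                              br[["fox_rate"]] * rates$fox_rate[k] +
                              br[["dingo_rate"]] * rates$dingo_rate[k],
                            12, n_rod, byrow = TRUE))
  s <- res$summary
  expect_equal(s$mean[s$response == "cover"], rowMeans(cover),
               tolerance = 1e-12)
  expect_equal(s$mean[s$response == "seed"], rowMeans(seedv),
               tolerance = 1e-12)
  expect_equal(s$mean[s$response == "rodents"], rowMeans(rod),
               tolerance = 1e-12)
  expect_equal(s$se[s$response == "cover"],
               apply(cover, 1, sd) / sqrt(n_runs), tolerance = 1e-12)
})

test_that("responses respect their natural bounds and the run counts", {
  sem <- small_sem()
  dr <- .proj_draws()
  res <- suppressWarnings(
    propagate(sem, dr$rain, dr$fire, predator_scenario("all_removed"),
              n_runs = 400, n_runs_rodent = 150, seed = 2))
  s <- res$summary
  expect_true(all(s$mean[s$response == "cover"] >= 0 &
                    s$mean[s$response == "cover"] <= 100))
  expect_true(all(s$mean[s$response == "seed"] >= 0 &
                    s$mean[s$response == "seed"] <= 5))
  expect_true(all(s$mean[s$response == "rodents"] >= 0))
  expect_true(all(s$se >= 0))
  expect_identical(unique(s$n_runs[s$response == "rodents"]), 150L)
  expect_identical(unique(s$n_runs[s$response == "cover"]), 400L)
  expect_identical(sum(s$response == "cover"), 12L)
})

test_that("zero-slope equations give flat intercept-only trajectories", {
  sem <- small_sem()
  sem0 <- sem
  for (nm in c("cover", "seed", "rodents")) {
    b <- sem0$fits[[nm]]$beta
    b[setdiff(names(b), "(Intercept)")] <- 0
    sem0$fits[[nm]]$beta <- b
  }
  dr <- .proj_draws()
  res <- suppressWarnings(
    propagate(sem0, dr$rain, dr$fire, predator_scenario("all_predators"),
              n_runs = 200, n_runs_rodent = 100, seed = 3))
  s <- res$summary
  b0c <- sem0$fits$cover$beta[["(Intercept)"]]
  expect_equal(s$mean[s$response == "cover"],
               rep(100 * plogis(b0c), 12), tolerance = 1e-12)
  expect_equal(unique(round(s$se[s$response == "cover"], 12)), 0)
  b0r <- sem0$fits$rodents$beta[["(Intercept)"]]
  expect_equal(s$mean[s$response == "rodents"],
               rep(100 * exp(b0r), 12), tolerance = 1e-12)
})

test_that("removing predators with the fitted sign pattern raises rodents pointwise", {
  sem <- small_sem()
  # impose the fitted-network sign pattern exactly, so the ordering is a
  # deterministic consequence of the monotone log link
  b <- sem$fits$rodents$beta
  b[["cat_rate"]] <- -abs(b[["cat_rate"]])
  b[["fox_rate"]] <- -abs(b[["fox_rate"]])
  b[["dingo_rate"]] <- abs(b[["dingo_rate"]])
  sem$fits$rodents$beta <- b
  dr <- .proj_draws()
  runs <- lapply(c("all_predators", "introduced_removed", "all_removed"),
                 function(sn) {
                   suppressWarnings(propagate(
                     sem, dr$rain, dr$fire, predator_scenario(sn),
                     n_runs = 300, n_runs_rodent = 150, seed = 4))
                 })
  names(runs) <- c("all_predators", "introduced_removed", "all_removed")
  # pointwise over every run and step
  expect_true(all(runs$introduced_removed$runs$rodents >=
                    runs$all_predators$runs$rodents))
  expect_true(all(runs$introduced_removed$runs$rodents >=
                    runs$all_removed$runs$rodents))
  # pooled percentage changes: introduced-only removal beats full removal
  pc_intro <- percent_change(runs$all_predators, runs$introduced_removed)
  pc_all <- percent_change(runs$all_predators, runs$all_removed)
  expect_gt(pc_intro, pc_all)
  expect_gt(pc_all, 0)
  # cover and seed are upstream of the predators: identical across scenarios
  expect_identical(runs$all_predators$runs$cover,
                   runs$all_removed$runs$cover)
})

test_that("cover declines under the rainfall/wildfire drift with the fitted signs", {
  sem <- small_sem()
  dr <- .proj_draws(n_draws = 1000, seed = 31)
  res <- suppressWarnings(
    propagate(sem, dr$rain, dr$fire, predator_scenario("all_predators"),
              n_runs = 1000, n_runs_rodent = 300, seed = 6))
  cov <- res$summary[res$summary$response == "cover", ]
  expect_gt(cov$mean[cov$step == 1], cov$mean[cov$step == 12])
})

test_that("percentage change is pooled-over-steps arithmetic", {
  mk <- function(means) {
    structure(list(summary = tibble::tibble(
      step = seq_along(means), scenario = "s", response = "rodents",
      mean = means, se = 0, n_runs = 10)), class = "projection_result")
  }
  expect_equal(percent_change(mk(rep(2, 12)), mk(rep(2, 12))), 0)
  expect_equal(percent_change(mk(rep(2, 12)), mk(rep(2.2, 12))), 10)
  expect_error(percent_change(mk(rep(0, 12)), mk(rep(1, 12))), "zero")
  expect_error(percent_change(mk(rep(1, 12)), mk(rep(1, 6))), "identical")
})

test_that("the full three-scenario projection is reproducible and complete", {
  sem <- small_sem()
  run1 <- suppressWarnings(run_full_projection(
    sem, n_runs = 300, n_runs_rodent = 120, seed = 9))
  run2 <- suppressWarnings(run_full_projection(
    sem, n_runs = 300, n_runs_rodent = 120, seed = 9))
  expect_identical(run1$summary, run2$summary)
  expect_identical(nrow(run1$summary), 12L * 3L * 3L)
  expect_identical(sort(unique(run1$summary$scenario)),
                   c("all_predators", "all_removed", "introduced_removed"))
  expect_s3_class(run1$plot, "ggplot")
  expect_identical(run1$percent_change$comparison,
                   c("introduced_removed", "all_removed"))
  # scenario endpoints as printed
  expect_equal(run1$rain$mu[c(1, 12)], c(152, 419))
  expect_equal(run1$fire$mu[c(1, 12)], c(21, 10))
})

test_that("scenario construction zeroes exactly the stated predators", {
  expect_identical(predator_scenario("all_predators")$zeroed, character())
  expect_identical(predator_scenario("introduced_removed")$zeroed,
                   c("cat_rate", "fox_rate"))
  expect_identical(predator_scenario("all_removed")$zeroed,
                   c("cat_rate", "fox_rate", "dingo_rate"))
  expect_error(predator_scenario("dingo_only"))
})
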