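test_that("an intercept-only Poisson node reduces to the closed-form MLE", {
  set.seed(4)
  n <- 120
  E <- 144
  y <- rpois(n, 0.03 * E)
  dat <- data.frame(y = y, effort = E,
                    trip = rep(1:12, each = n / 12))
  spec <- node_spec("count", "poisson", "y", predictors = character(),
                    offset = "effort", random = "trip", frame = "f")
  fit <- fit_node(spec, dat, constrain_sd_zero = TRUE)
  expect_equal(unname(fit$beta[["(Intercept)"]]), log(mean(y) / E),
               tolerance = 1e-7)
  expect_identical(fit$random_sd, 0)
})

test_that("with the random-intercept SD constrained to 0 the fit matches IRLS", {
  sim <- small_sim()
  g <- canonical_graph()

  # Poisson node on a <=200-row instance
  fr <- standardize_predictors(g$nodes$reptiles,
                               as.data.frame(sim$frames$captures))
  fr <- fr[stats::complete.cases(fr[c("reptiles", "fire_years", "cover",
                                      "rain_days")]), ][1:200, ]
  mine <- fit_node(g$nodes$reptiles, fr, constrain_sd_zero = TRUE)
  oracle <- stats::glm(reptiles ~ fire_years + cover + rain_days +
                         offset(log(trap_nights)),
                       family = stats::poisson(), data = fr)
  expect_equal(unname(mine$beta), unname(coef(oracle)), tolerance = 1e-7)

  # binomial node (grid-averaged score, prior-weight IRLS)
  veg <- as.data.frame(sim$frames$vegetation)[1:200, ]
  mine_b <- fit_node(g$nodes$cover, veg, constrain_sd_zero = TRUE)
  veg$p <- veg$cover / 100
  oracle_b <- suppressWarnings(
    stats::glm(p ~ fire_years + rain8, family = stats::binomial(),
               weights = rep(100, nrow(veg)), data = veg))
  expect_equal(unname(mine_b$beta), unname(coef(oracle_b)),
               tolerance = 1e-7)
})

test_that("the Laplace fit agrees with an independent mixed-model fitter", {
  skip_if_not_installed("lme4")
  sim <- small_sim()
  g <- canonical_graph()
  fr <- standardize_predictors(g$nodes$reptiles,
                               as.data.frame(sim$frames$captures))
  mine <- suppressMessages(fit_node(g$nodes$reptiles, fr))
  ref <- suppressWarnings(lme4::glmer(
    reptiles ~ fire_years + cover + rain_days + (1 | trip) +
      offset(log(trap_nights)),
    data = fr, family = stats::poisson()))
  expect_equal(unname(mine$beta), unname(lme4::fixef(ref)),
               tolerance = 5e-3)
  expect_equal(mine$random_sd,
               sqrt(unlist(lme4::VarCorr(ref))[[1]]), tolerance = 1e-2)
  expect_equal(mine$coefficients$se, unname(sqrt(diag(as.matrix(
    stats::vcov(ref))))), tolerance = 2e-2)

  veg <- as.data.frame(sim$frames$vegetation)
  mine_b <- fit_node(g$nodes$cover, veg)
  veg$p <- veg$cover / 100
  ref_b <- suppressWarnings(lme4::glmer(
    p ~ fire_years + rain8 + (1 | trip), data = veg,
    family = stats::binomial(), weights = rep(100, nrow(veg))))
  expect_equal(unname(mine_b$beta), unname(lme4::fixef(ref_b)),
               tolerance = 5e-3)
  expect_equal(mine_b$random_sd,
               sqrt(unlist(lme4::VarCorr(ref_b))[[1]]), tolerance = 1e-2)
})

test_that("the penalized log-likelihood never decreases across iterations", {
  fits <- small_fits()
  for (f in fits) {
    expect_true(all(diff(f$pirls_trace) >= -1e-8))
  }
})

test_that("Wald p-values follow the normal tail formula and predictions respect bounds", {
  fits <- small_fits()
  for (f in fits) {
    expect_equal(f$coefficients$p, 2 * stats::pnorm(-abs(f$coefficients$z)))
    expect_true(all(f$coefficients$p >= 0 & f$coefficients$p <= 1))
    eta <- drop(f$design %*% f$beta) + f$offset_log
    if (f$spec$family == "poisson") {
      expect_true(all(exp(pmin(eta, 30)) > 0))
    } else {
      mu <- stats::plogis(eta)
      expect_true(all(mu > 0 & mu < 1))
    }
  }
})

test_that("effort standardization follows the per-100-trap-night convention", {
  expect_equal(effort_rate(6, 216, 100), 6 / 216 * 100)
  expect_equal(effort_rate(6, 216, 100), 2.7778, tolerance = 1e-4)
  expect_error(effort_rate(3, 0, 100), "positive")
  d <- data.frame(mulgara = c(2, 4), trap_nights = c(72, 216),
                  dasyurids = c(1, 1), site = "S1",
                  rain_event_lag2 = c(1, 2), trip = 1:2)
  spec <- canonical_graph()$nodes$dasyurids
  out <- standardize_predictors(spec, d)
  expect_equal(out$mulgara_rate, c(2 / 72, 4 / 216) * 100)
})

test_that("z-transformation gives unit scale and rejects constant columns", {
  cam <- as.data.frame(small_sim()$frames$camera)
  spec <- canonical_graph()$nodes$fox
  out <- standardize_predictors(spec, cam)
  for (v in c("rodent_rate", "dingo_rate", "phase")) {
    expect_equal(mean(out[[v]], na.rm = TRUE), 0, tolerance = 1e-12)
    expect_equal(stats::sd(out[[v]], na.rm = TRUE), 1, tolerance = 1e-12)
  }
  cam$phase <- 2
  expect_error(standardize_predictors(spec, cam), "constant")
})

test_that("deviance explained reproduces the null-versus-fitted formula", {
  expect_equal(deviance_explained(fake_fit(40, 100)), 0.6)
  expect_equal(deviance_explained(fake_fit(100, 100)), 0)
  expect_error(deviance_explained(fake_fit(40, -1)), "not positive")
  for (f in small_fits()) {
    dv <- deviance_explained(f)
    expect_gte(dv, -1e-6)
    expect_lte(dv, 1)
    expect_gte(f$null_deviance, f$deviance - 1e-6)
  }
})

test_that("a dataset with no between-trip variation is flagged singular and refit at SD 0", {
  dat <- data.frame(y = rep(4L, 300), effort = 100,
                    trip = rep(1:10, each = 30))
  spec <- node_spec("flat", "poisson", "y", predictors = character(),
                    offset = "effort", random = "trip", frame = "f")
  expect_warning(fit <- fit_node(spec, dat), "boundary")
  expect_identical(fit$random_sd, 0)
  expect_true(fit$singular)
})

test_that("missing covariates drop listwise with a message, never silently", {
  sim <- small_sim()
  spec <- canonical_graph()$nodes$dasyurids
  expect_message(fit_node(spec, sim$frames$captures), "dropping")
})
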