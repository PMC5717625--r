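test_that("standardized coefficients match a brute-force two-point sweep", {
  fits <- small_fits()
  for (nm in c("rodents", "cover", "seed", "reptiles")) {
    fit <- fits[[nm]]
    X <- fit$design
    for (tm in setdiff(fit$spec$predictors, fit$spec$factors)) {
      col <- colnames(X)[which(colnames(X) %in%
                                 c(tm, paste(rev(strsplit(tm, ":")[[1]]),
                                             collapse = ":")))]
      xbar <- colMeans(X)
      lo <- hi <- xbar
      lo[col] <- min(X[, col])
      hi[col] <- max(X[, col])
      pred <- function(x) {
        eta <- sum(x * fit$beta) + mean(fit$offset_log)
        if (fit$spec$family == "poisson") {
          exp(eta)
        } else {
          fit$spec$denominator * stats::plogis(eta)
        }
      }
      brute <- (pred(hi) - pred(lo)) / diff(fit$response_range)
      expect_equal(standardized_coefficient(fit, tm), brute,
                   tolerance = 1e-12)
    }
  }
})

test_that("standardized coefficients carry the sign of the raw coefficient", {
  sem <- small_sem()
  ok <- !is.na(sem$paths$raw) & sem$paths$raw != 0
  expect_true(all(sign(sem$paths$standardized[ok]) ==
                    sign(sem$paths$raw[ok])))
})

test_that("standardized coefficients are invariant to affine predictor rescaling", {
  sim <- small_sim()
  spec <- canonical_graph()$nodes$seed
  f1 <- fit_node(spec, sim$frames$vegetation)
  resc <- sim$frames$vegetation
  resc$rain8 <- resc$rain8 * 10 + 3
  f2 <- fit_node(spec, resc)
  expect_equal(standardized_coefficient(f1, "rain8"),
               standardized_coefficient(f2, "rain8"), tolerance = 1e-5)
  expect_equal(standardized_coefficient(f1, "cover"),
               standardized_coefficient(f2, "cover"), tolerance = 1e-5)
})

test_that("degenerate sweeps are caught", {
  sim <- small_sim()
  spec <- canonical_graph()$nodes$seed
  dat <- as.data.frame(sim$frames$vegetation)
  dat$rain8 <- 120
  fit <- fit_node(spec, dat)
  expect_warning(s <- standardized_coefficient(fit, "rain8"), "constant")
  expect_identical(s, 0)
  dat2 <- as.data.frame(sim$frames$vegetation)
  dat2$seed <- 2
  fit2 <- suppressWarnings(fit_node(spec, dat2))
  expect_error(standardized_coefficient(fit2, "cover"), "range")
})

test_that("assembly yields one estimate per canonical edge, none invented", {
  sem <- small_sem()
  g <- canonical_graph()
  expect_identical(nrow(sem$paths), 26L)
  expect_identical(
    sort(paste(sem$paths$source, sem$paths$target)),
    sort(paste(g$edges$source, g$edges$target)))
  expect_identical(sem$paths$significant, sem$paths$p < 0.05)
  expect_length(sem$deviance_explained, 9L)
  expect_error(assemble(small_fits()[-4], g), "rodents")
})

test_that("a strongly positive seed-to-rodent path is recovered as such", {
  sem <- small_sem()
  path <- sem$paths[sem$paths$source == "seed" &
                      sem$paths$target == "rodents", ]
  expect_gt(path$standardized, 0)
  expect_true(path$significant)
})

test_that("the z-transformed fox fit maps back to the raw covariate scale", {
  fits <- small_fits()
  raw <- coef_raw_scale(fits$fox)
  # re-fit the fox formula without the z-transform: same column space,
  # so the raw-scale coefficients must agree up to optimizer tolerance
  spec <- canonical_graph()$nodes$fox
  spec$z_transform <- FALSE
  direct <- fit_node(spec, small_sim()$frames$camera)
  expect_equal(unname(raw$beta[names(direct$beta)]), unname(direct$beta),
               tolerance = 1e-4)
  # untransformed fits pass through unchanged
  expect_identical(coef_raw_scale(fits$dingo)$beta, fits$dingo$beta)
})

test_that("the rendered network shows exactly the significant paths", {
  fake <- structure(list(
    paths = tibble::tibble(
      source = c("a", "b"), target = c("x", "x"),
      raw = c(1, -1), standardized = c(0.5, -0.4),
      p = c(0.049, 0.051), significant = c(TRUE, FALSE)),
    deviance_explained = c(x = 12.5), alpha = 0.05), class = "sem_result")
  lines <- render_network(fake)
  expect_true(any(grepl("a -> x", lines)))
  expect_false(any(grepl("b -> x", lines)))
  expect_true(any(grepl("12.5", lines)))
  # zero significant paths: empty main view, full table intact
  fake$paths$significant <- c(FALSE, FALSE)
  lines0 <- render_network(fake)
  expect_false(any(grepl("->", lines0, fixed = TRUE)))
  expect_identical(nrow(fake$paths), 2L)
})

test_that("the path table round-trips through its delimited form", {
  sem <- small_sem()
  tf <- withr::local_tempfile(fileext = ".csv")
  write_sem_paths(sem, tf)
  back <- read_sem_paths(tf)
  expect_equal(as.data.frame(back), as.data.frame(sem$paths),
               tolerance = 1e-12)
})
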