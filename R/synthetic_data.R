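#' Generate a study design shaped like the long-term monitoring program
#'
#' Nine live-trapping sites, each holding 2-12 one-hectare grids of 36
#' pitfall traps, visited several times a year; a two-year camera-trap
#' window at every site. The number of grids per site is drawn uniformly
#' from 2-12; trapping effort per grid and trip is 36 traps times 2-6
#' nights (72-216 trap-nights), drawn at simulation time.
#'
#' @param n_sites number of sites (the study has 9).
#' @param seed integer seed; the same (n_sites, seed) always returns the
#'   identical design.
#' @param n_trips trips per site (all sites share the trip calendar; the
#'   program ran up to 130 trips per site — the default keeps pooled sample
#'   sizes near the study's larger submodels).
#' @param trips_per_year trips per calendar year (2-6 in the field
#'   program; must divide 12).
#' @param nights_range range of trapping nights per trip.
#' @param camera_months months of continuous camera operation (the study
#'   ran cameras for 24 months).
#' @param cameras_per_site cameras operating at each site (25 cameras over
#'   nine sites in the study).
#' @param start_date date of the first trip.
#' @return An object of class `study_design`.
#' @export
generate_design <- function(n_sites = 9, seed = 1, n_trips = 25,
                            trips_per_year = 3, nights_range = c(2, 6),
                            camera_months = 24, cameras_per_site = 3,
                            start_date = as.Date("2000-03-15")) {
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 1) {
    stop("n_sites must be a positive count", call. = FALSE)
  }
  stopifnot(n_trips >= 1, n_trips <= 130, 12 %% trips_per_year == 0,
            nights_range[1] >= 2, nights_range[2] <= 6,
            camera_months >= 1, camera_months <= 24, cameras_per_site >= 1)
  n_sites <- as.integer(n_sites)
  grids <- withr::with_seed(seed, sample(2:12, n_sites, replace = TRUE))
  structure(list(
    n_sites = n_sites,
    sites = sprintf("S%d", seq_len(n_sites)),
    grids_per_site = grids,
    n_trips = as.integer(n_trips),
    trips_per_year = as.integer(trips_per_year),
    nights_range = as.integer(nights_range),
    camera_months = as.integer(camera_months),
    cameras_per_site = as.integer(cameras_per_site),
    start_date = as.Date(start_date),
    seed = as.integer(seed)
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(paste0("study_design: %d sites, %s grids/site, %d trips ",
                     "(%d/yr from %s), %d camera months\n"),
              x$n_sites, paste(range(x$grids_per_site), collapse = "-"),
              x$n_trips, x$trips_per_year, format(x$start_date),
              x$camera_months))
  invisible(x)
}

#' Trip calendar implied by a design
#'
#' Trips are synchronized across sites (trip = shared sampling period, the
#' random factor of every model), spaced `12 / trips_per_year` months
#' apart, on the 15th of the month.
#'
#' @param design a [generate_design()] result.
#' @return Tibble with `site`, `trip`, `date`.
#' @export
make_trip_calendar <- function(design) {
  step <- 12L %/% design$trips_per_year
  m0 <- .month_index(.month_str(design$start_date))
  idx <- m0 + step * (seq_len(design$n_trips) - 1L)
  dates <- .month_first_day(idx) + 14L
  tidyr::expand_grid(site = design$sites,
                     trip = seq_len(design$n_trips)) |>
    dplyr::mutate(date = dates[.data$trip])
}

# rainfall series core (no seed handling): two-part process, Bernoulli
# wet day then a positive integer event size 1 + NB(mu = mean_event - 1,
# size = overdispersion), so the mean event size is exactly mean_event and
# the large-`overdispersion` limit is the light-tailed (shifted-Poisson)
# law with event-size variance mean_event - 1
.sim_rain_core <- function(design, mean_event, overdispersion, p_wet) {
  if (!length(design$sites)) {
    return(tibble::tibble(site = character(), date = as.Date(character()),
                          rainfall = numeric()))
  }
  cal <- make_trip_calendar(design)
  first <- .month_first_day(.month_index(.month_str(min(cal$date))) - 13L)
  last <- max(cal$date) + 16L
  dates <- seq(first, last, by = "day")
  nd <- length(dates)
  dplyr::bind_rows(lapply(design$sites, function(st) {
    wet <- stats::rbinom(nd, 1L, p_wet)
    amt <- ifelse(wet == 1L,
                  1 + stats::rnbinom(nd, mu = mean_event - 1,
                                     size = overdispersion),
                  0)
    tibble::tibble(site = st, date = dates, rainfall = as.numeric(amt))
  }))
}

#' Simulate daily rainfall for every site of a design
#'
#' Two-part arid-zone rainfall model: each day is wet with probability
#' `p_wet`; wet-day totals are integer millimetres drawn as
#' `1 + NB(mu = mean_event - 1, size = overdispersion)`, so most days are
#' dry, the mean event size is exactly `mean_event`, and small
#' `overdispersion` gives the heavy right tail characteristic of desert
#' rainfall. The series covers the trip calendar plus a 13-month lookback
#' so every covariate window is computable.
#'
#' @param design a [generate_design()] result.
#' @param mean_event mean wet-day rainfall (mm, > 1).
#' @param overdispersion negative-binomial size of the event-size law
#'   (> 0); as it grows the event-size variance approaches the
#'   light-tailed limit `mean_event - 1`.
#' @param p_wet probability a day is wet.
#' @param seed optional integer seed.
#' @return Tibble with `site`, `date`, `rainfall` (mm), contiguous per
#'   site.
#' @export
simulate_daily_rain <- function(design, mean_event = 5, overdispersion = 1,
                                p_wet = 0.10, seed = NULL) {
  if (!is.numeric(mean_event) || mean_event <= 1) {
    stop("mean_event must exceed 1 mm (integer-millimetre event model)",
         call. = FALSE)
  }
  if (!is.numeric(overdispersion) || overdispersion <= 0) {
    stop("overdispersion must be positive", call. = FALSE)
  }
  if (p_wet <= 0 || p_wet >= 1) stop("p_wet must lie in (0, 1)", call. = FALSE)
  if (is.null(seed)) {
    .sim_rain_core(design, mean_event, overdispersion, p_wet)
  } else {
    withr::with_seed(seed,
                     .sim_rain_core(design, mean_event, overdispersion, p_wet))
  }
}

.normalize_term <- function(x) {
  vapply(strsplit(x, ":", fixed = TRUE),
         function(p) paste(sort(p), collapse = ":"), "")
}

# model-matrix column names for a node, given the design's site levels
.node_mm_names <- function(spec, sites) {
  vars <- unique(unlist(strsplit(spec$predictors, ":", fixed = TRUE)))
  tmpl <- as.data.frame(stats::setNames(
    lapply(vars, function(v) {
      if (v %in% spec$factors) factor(sites) else rep(0, length(sites))
    }), vars))
  colnames(stats::model.matrix(stats::reformulate(spec$predictors), tmpl))
}

# assign named truth values (keyed by canonical term names, interaction
# order-insensitive) onto model-matrix column names
.match_beta <- function(mm_names, values) {
  out <- stats::setNames(rep(NA_real_, length(mm_names)), mm_names)
  norm_mm <- .normalize_term(mm_names)
  norm_val <- .normalize_term(names(values))
  idx <- match(norm_mm, norm_val)
  out[] <- values[idx]
  if (anyNA(out)) {
    stop("ground truth is missing coefficient(s): ",
         paste(mm_names[is.na(out)], collapse = ", "), call. = FALSE)
  }
  out
}

#' Ground-truth coefficients for the canonical food-web graph
#'
#' Link-scale coefficient vectors for all nine nodes, with trip-level
#' random-intercept standard deviations and baseline predator photo rates
#' (used for capture records predating the camera window). Signs follow
#' the fitted network of the study system: cover rises with years since
#' wildfire and with eight-month rainfall, seed rises with cover, rodents
#' rise with seed and dingo activity but fall with cat and fox activity,
#' dasyurids fall with mulgara activity, reptiles fall with years since
#' wildfire and rise with rain days, and the dingo x phase interaction
#' suppresses both mesopredators. The red fox node's coefficients are
#' expressed on the raw covariate scale; its fit is z-transformed, and
#' [coef_raw_scale()] maps estimates back for comparison. Any entry can be
#' overridden via `...` (e.g. `rodents = list(beta = c(...), sd = 0)`).
#'
#' @param design a [generate_design()] result (site levels fix the
#'   dasyurid site-effect arity).
#' @param ... per-node overrides: named lists with elements `beta` (full
#'   named coefficient vector) and/or `sd`.
#' @return An object of class `ground_truth`: per-node `beta` (named as
#'   the fitted model matrix), `sd`, plus `baseline_predators` and the
#'   binomial denominators.
#' @export
ground_truth <- function(design, ...) {
  graph <- canonical_graph()
  site_fx <- stats::setNames(
    c(0, 0.30, -0.25, 0.15, -0.35, 0.20, -0.10, 0.45,
      -0.20)[seq_len(design$n_sites)],
    paste0("site", design$sites))
  site_fx <- site_fx[-1L]  # first site is the reference level
  vals <- list(
    dasyurids = c(`(Intercept)` = -3.4, site_fx,
                  rain_event_lag2 = 0.03, mulgara_rate = -0.20),
    cover = c(`(Intercept)` = -2.8, fire_years = 0.10, rain8 = 0.0025),
    seed = c(`(Intercept)` = -3.0, cover = 0.04, rain8 = 0.0005),
    rodents = c(`(Intercept)` = -3.6, seed = 0.45, cat_rate = -3.0,
                fox_rate = -1.5, dingo_rate = 1.0),
    mulgara = c(`(Intercept)` = -5.2, rodent_rate = 0.01, cover = 0.03,
                fire_years = -0.004),
    cat = c(`(Intercept)` = -3.5, rodent_rate = 0.06, dingo_rate = 3.0,
            phase = -0.05, `phase:dingo_rate` = -1.5),
    fox = c(`(Intercept)` = -3.0, rodent_rate = 0.03, dingo_rate = 0.4,
            phase = -0.25, `phase:dingo_rate` = -1.0),
    dingo = c(`(Intercept)` = -3.2, rodent_rate = 0.03),
    reptiles = c(`(Intercept)` = -3.2, fire_years = -0.02, cover = 0.002,
                 rain_days = 0.06)
  )
  sds <- c(dasyurids = 0.4, cover = 0.3, seed = 0.3, rodents = 0.3,
           mulgara = 0.4, cat = 0.3, fox = 0.4, dingo = 0.3, reptiles = 0.4)
  nodes <- lapply(names(graph$nodes), function(nm) {
    mm <- .node_mm_names(graph$nodes[[nm]], design$sites)
    list(beta = .match_beta(mm, vals[[nm]]), sd = unname(sds[nm]))
  })
  names(nodes) <- names(graph$nodes)
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% names(nodes)) stop("unknown node '", nm, "'", call. = FALSE)
    for (fld in names(overrides[[nm]])) {
      nodes[[nm]][[fld]] <- overrides[[nm]][[fld]]
    }
  }
  structure(list(nodes = nodes,
                 baseline_predators = c(cat_rate = 0.05, fox_rate = 0.03,
                                        dingo_rate = 0.05),
                 denominators = c(cover = 100, seed = 5)),
            class = "ground_truth")
}

#' Check a ground truth against the canonical graph and a design
#'
#' @param truth a [ground_truth()] (possibly modified).
#' @param design the [generate_design()] it will be simulated under.
#' @return `truth`, invisibly; errors describe arity or naming mismatches.
#' @export
validate_truth <- function(truth, design) {
  graph <- canonical_graph()
  if (!setequal(names(truth$nodes), names(graph$nodes))) {
    stop("ground truth must cover exactly the canonical nodes",
         call. = FALSE)
  }
  for (nm in names(graph$nodes)) {
    mm <- .node_mm_names(graph$nodes[[nm]], design$sites)
    beta <- truth$nodes[[nm]]$beta
    if (length(beta) != length(mm) ||
        !identical(.normalize_term(names(beta)), .normalize_term(mm))) {
      stop("ground truth for node '", nm, "' does not match the model ",
           "arity: expected terms ", paste(mm, collapse = ", "),
           call. = FALSE)
    }
    if (is.null(truth$nodes[[nm]]$sd) || truth$nodes[[nm]]$sd < 0) {
      stop("ground truth for node '", nm,
           "' needs a non-negative random-intercept SD", call. = FALSE)
    }
  }
  invisible(truth)
}

# linear predictor + count/score simulation for one node
.sim_response <- function(family, X, beta, u, off_log, denom = NULL) {
  eta <- drop(X %*% beta) + u + off_log
  eta <- pmin(pmax(eta, -30), 30)
  if (family == "poisson") {
    stats::rpois(length(eta), exp(eta))
  } else {
    stats::rbinom(length(eta), denom, stats::plogis(eta))
  }
}

# 8-month cumulative rainfall ending at each requested month, per site
.site_month_rain8 <- function(rain_daily, month_strs) {
  monthly <- rain_daily |>
    dplyr::mutate(month = .month_str(.data$date)) |>
    dplyr::group_by(.data$site, .data$month) |>
    dplyr::summarise(total = sum(.data$rainfall), .groups = "drop")
  out <- expand.grid(site = unique(rain_daily$site), month_str = month_strs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$rain8m <- mapply(function(st, ms) {
    idx <- .month_index(ms) - 0:7
    want <- sprintf("%04d-%02d", idx %/% 12L, idx %% 12L + 1L)
    sum(monthly$total[monthly$site == st & monthly$month %in% want])
  }, out$site, out$month_str)
  tibble::as_tibble(out)
}

#' Simulate a full study dataset from known ground truth
#'
#' Generates every raw table of the study design — daily rainfall,
#' wildfire ages, vegetation scores, pitfall captures and camera records —
#' by drawing each node's response from its ground-truth equation with a
#' trip-level (or month-level, for camera data) normal random intercept:
#' Poisson counts with a log-effort offset, binomial scores out of 100
#' (cover) and 5 (seed). The prey-predator simultaneity is broken by time
#' order: predator photo counts in a month use the rodent capture rate at
#' the most recent preceding trip, and rodent captures inside the camera
#' window use that month's observed predator photo rates, so every fitted
#' node sees exactly the covariates used in generation. Capture records
#' before the camera window use the baseline predator rates stored in the
#' truth. Population phase codes (1 boom, 2 decline, 3 bust) are assigned
#' from site-level terciles of eight-month rainfall over the camera
#' window, tying phase to rainfall pulses.
#'
#' @param design a [generate_design()] result.
#' @param truth a [ground_truth()] (validated against the design).
#' @param seed integer seed; identical inputs give byte-identical tables.
#' @param mean_event,overdispersion,p_wet rainfall parameters, see
#'   [simulate_daily_rain()].
#' @return List with `tables` (raw study tables, reader-valid), `frames`
#'   (the per-node analysis tables from [build_node_frames()]), `truth`,
#'   `design`, `month_map` (camera month calendar).
#' @export
simulate_dataset <- function(design, truth, seed = 1, mean_event = 5,
                             overdispersion = 1, p_wet = 0.10) {
  validate_truth(truth, design)
  graph <- canonical_graph()
  withr::with_seed(seed, {
    cal <- make_trip_calendar(design)
    rain_daily <- .sim_rain_core(design, mean_event, overdispersion, p_wet)
    rain_cov <- derive_rain_covariates(rain_daily, cal)
    trip_dates <- cal$date[match(seq_len(design$n_trips), cal$trip)]

    # wildfire: fire scars are patchy, so each grid carries its own burn
    # history — an annual burn probability of 1/26 (the regional mean
    # return interval) during the study, with staggered study-start ages
    # drawn from the regional age distribution
    years <- as.integer(seq(min(format(cal$date, "%Y")),
                            max(format(cal$date, "%Y"))))
    grid_tbl <- dplyr::bind_rows(lapply(seq_len(design$n_sites), function(i) {
      tibble::tibble(site = design$sites[i],
                     grid = sprintf("G%02d", seq_len(design$grids_per_site[i])))
    }))
    grid_tbl$age0 <- stats::rnbinom(nrow(grid_tbl), mu = 20, size = 3.34) + 0.5
    grid_fires <- lapply(seq_len(nrow(grid_tbl)), function(i) {
      yrs <- years[stats::runif(length(years)) < 1 / 26]
      as.Date(sprintf("%d-06-30", yrs))
    })

    fire <- tidyr::expand_grid(grid_tbl, trip = seq_len(design$n_trips)) |>
      dplyr::mutate(date = trip_dates[.data$trip])
    gi_fire <- match(paste(fire$site, fire$grid),
                     paste(grid_tbl$site, grid_tbl$grid))
    fire$fire_years <- vapply(seq_len(nrow(fire)), function(i) {
      fires <- grid_fires[[gi_fire[i]]]
      fires <- fires[fires <= fire$date[i]]
      last <- if (length(fires)) {
        max(fires)
      } else {
        trip_dates[1L] - round(fire$age0[i] * 365.25)
      }
      round(as.numeric(fire$date[i] - last) / 365.25, 2)
    }, 0)
    fire_tbl <- fire[, c("site", "grid", "trip", "fire_years")]

    rain_small <- rain_cov[, c("site", "trip", "rain8", "rain_days",
                               "rain_event_lag2", "mean_event")]

    # vegetation: cover then seed, binomial scores with trip intercepts
    veg <- fire_tbl |>
      dplyr::left_join(rain_small[, c("site", "trip", "rain8")],
                       by = c("site", "trip"))
    u <- function(nm, n_lev) stats::rnorm(n_lev, 0, truth$nodes[[nm]]$sd)
    u_cover <- u("cover", design$n_trips)
    Xc <- stats::model.matrix(~fire_years + rain8, veg)
    veg$cover <- .sim_response("binomial", Xc, truth$nodes$cover$beta,
                               u_cover[veg$trip], 0, 100)
    u_seed <- u("seed", design$n_trips)
    Xs <- stats::model.matrix(~cover + rain8, veg)
    veg$seed <- .sim_response("binomial", Xs, truth$nodes$seed$beta,
                              u_seed[veg$trip], 0, 5)
    vegetation_tbl <- veg[, c("site", "grid", "trip", "cover", "seed")]

    # capture skeleton with covariates
    cap <- veg |>
      dplyr::mutate(trap_nights = 36L * sample(
        design$nights_range[1]:design$nights_range[2], dplyr::n(),
        replace = TRUE)) |>
      dplyr::left_join(rain_small[, c("site", "trip", "rain_days",
                                      "rain_event_lag2")],
                       by = c("site", "trip"))

    month_map <- .camera_month_map(cal, design$camera_months)
    cap$cam_month <- .trip_camera_month(trip_dates[cap$trip], month_map)

    # phase codes from site-level terciles of 8-month rainfall
    r8m <- .site_month_rain8(rain_daily, month_map$month_str)
    r8m <- r8m |>
      dplyr::group_by(.data$site) |>
      dplyr::mutate(phase = 4L - as.integer(cut(
        .data$rain8m,
        breaks = stats::quantile(.data$rain8m, c(0, 1 / 3, 2 / 3, 1)),
        include.lowest = TRUE, labels = FALSE))) |>
      dplyr::ungroup()

    cam <- tidyr::expand_grid(site = design$sites,
                              month = month_map$month) |>
      dplyr::left_join(r8m |>
                         dplyr::mutate(month = match(.data$month_str,
                                                     month_map$month_str)) |>
                         dplyr::select("site", "month", "phase"),
                       by = c("site", "month")) |>
      dplyr::mutate(camera_nights = round(design$cameras_per_site * 30 *
                                            stats::runif(dplyr::n(), 0.85, 1)))

    # rodents before the camera window: baseline predator rates
    bp <- truth$baseline_predators
    u_rod <- u("rodents", design$n_trips)
    beta_rod <- truth$nodes$rodents$beta
    pre <- is.na(cap$cam_month)
    cap$rodents <- NA_integer_
    if (any(pre)) {
      Xr <- stats::model.matrix(
        ~seed + cat_rate + fox_rate + dingo_rate,
        dplyr::mutate(cap[pre, ], cat_rate = bp[["cat_rate"]],
                      fox_rate = bp[["fox_rate"]],
                      dingo_rate = bp[["dingo_rate"]]))
      cap$rodents[pre] <- .sim_response("poisson", Xr, beta_rod,
                                        u_rod[cap$trip[pre]],
                                        log(cap$trap_nights[pre]))
    }

    # camera window, month by month: dingo, then the mesopredators, then
    # the rodent captures of trips falling inside the month
    u_dingo <- u("dingo", design$camera_months)
    u_cat <- u("cat", design$camera_months)
    u_fox <- u("fox", design$camera_months)
    cam$dingo <- NA_integer_
    cam$cat <- NA_integer_
    cam$fox <- NA_integer_
    cam$rodent_rate <- NA_real_
    for (m in month_map$month) {
      cutoff <- month_map$month_start[m]
      for (st in design$sites) {
        done <- cap$site == st & !is.na(cap$rodents) &
          trip_dates[cap$trip] < cutoff
        rr <- if (any(done)) {
          sub <- cap[done, ]
          last_trip <- max(sub$trip)
          sum(sub$rodents[sub$trip == last_trip]) /
            sum(sub$trap_nights[sub$trip == last_trip]) * 100
        } else {
          NA_real_
        }
        cam$rodent_rate[cam$site == st & cam$month == m] <- rr
      }
      i <- which(cam$month == m)
      dfm <- cam[i, ]
      Xd <- stats::model.matrix(~rodent_rate, dfm)
      cam$dingo[i] <- .sim_response("poisson", Xd, truth$nodes$dingo$beta,
                                    u_dingo[m], log(dfm$camera_nights))
      dfm$dingo_rate <- cam$dingo[i] / dfm$camera_nights
      Xcat <- stats::model.matrix(
        ~rodent_rate + dingo_rate + phase + phase:dingo_rate, dfm)
      cam$cat[i] <- .sim_response("poisson", Xcat, truth$nodes$cat$beta,
                                  u_cat[m], log(dfm$camera_nights))
      cam$fox[i] <- .sim_response("poisson", Xcat, truth$nodes$fox$beta,
                                  u_fox[m], log(dfm$camera_nights))
      # rodent captures at trips inside this month
      j <- which(!pre & cap$cam_month == m)
      if (length(j)) {
        rates <- cam[i, c("site", "camera_nights", "cat", "fox", "dingo")]
        mi <- match(cap$site[j], rates$site)
        Xr <- stats::model.matrix(
          ~seed + cat_rate + fox_rate + dingo_rate,
          dplyr::mutate(cap[j, ],
                        cat_rate = rates$cat[mi] / rates$camera_nights[mi],
                        fox_rate = rates$fox[mi] / rates$camera_nights[mi],
                        dingo_rate = rates$dingo[mi] /
                          rates$camera_nights[mi]))
        cap$rodents[j] <- .sim_response("poisson", Xr, beta_rod,
                                        u_rod[cap$trip[j]],
                                        log(cap$trap_nights[j]))
      }
    }

    # mulgara, dasyurids, reptiles over the whole record
    u_mul <- u("mulgara", design$n_trips)
    cap$rodent_rate <- cap$rodents / cap$trap_nights * 100
    Xm <- stats::model.matrix(~rodent_rate + cover + fire_years, cap)
    cap$mulgara <- .sim_response("poisson", Xm, truth$nodes$mulgara$beta,
                                 u_mul[cap$trip], log(cap$trap_nights))

    u_das <- u("dasyurids", design$n_trips)
    cap$mulgara_rate <- cap$mulgara / cap$trap_nights * 100
    das_df <- dplyr::mutate(
      cap, site = factor(.data$site, levels = design$sites),
      rain_event_lag2 = ifelse(is.na(.data$rain_event_lag2), mean_event,
                               .data$rain_event_lag2))
    Xd <- stats::model.matrix(~site + rain_event_lag2 + mulgara_rate, das_df)
    cap$dasyurids <- .sim_response("poisson", Xd, truth$nodes$dasyurids$beta,
                                   u_das[cap$trip], log(cap$trap_nights))

    u_rep <- u("reptiles", design$n_trips)
    Xp <- stats::model.matrix(~fire_years + cover + rain_days, cap)
    cap$reptiles <- .sim_response("poisson", Xp, truth$nodes$reptiles$beta,
                                  u_rep[cap$trip], log(cap$trap_nights))

    tables <- list(
      captures = cap[, c("site", "grid", "trip", "trap_nights", "dasyurids",
                         "rodents", "mulgara", "reptiles")],
      camera = cam[, c("site", "month", "camera_nights", "cat", "fox",
                       "dingo", "phase")],
      vegetation = vegetation_tbl,
      rain_daily = rain_daily,
      fire = fire_tbl,
      trip_calendar = cal
    )
    for (ty in names(tables)) validate_study_table(tables[[ty]], ty)
    frames <- build_node_frames(tables, design$camera_months)
    list(tables = tables, frames = frames, truth = truth, design = design,
         month_map = month_map)
  })
}

#' Serialize ground truth to a plain-text config
#'
#' @param truth a [ground_truth()].
#' @param path file to write (`NULL` to just return the lines).
#' @return Config lines, invisibly.
#' @export
write_truth_config <- function(truth, path = NULL) {
  num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  lines <- unlist(lapply(names(truth$nodes), function(nm) {
    nd <- truth$nodes[[nm]]
    c(sprintf("[node %s]", nm),
      sprintf("beta %s: %s", names(nd$beta), num(nd$beta)),
      sprintf("sd: %s", num(nd$sd)), "")
  }))
  lines <- c(lines, "[baseline_predators]",
             sprintf("rate %s: %s", names(truth$baseline_predators),
                     num(truth$baseline_predators)), "")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read ground truth from a plain-text config
#'
#' @param path file (or character vector of lines) written by
#'   [write_truth_config()].
#' @return A `ground_truth` object.
#' @export
read_truth_config <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(lines)]
  starts <- grep("^\\[", lines)
  ends <- c(starts[-1L] - 1L, length(lines))
  nodes <- list()
  baseline <- NULL
  for (b in seq_along(starts)) {
    hdr <- lines[starts[b]]
    body <- lines[(starts[b] + 1L):ends[b]]
    if (hdr == "[baseline_predators]") {
      nmv <- sub("^rate ([^:]+): .*$", "\\1", body)
      baseline <- stats::setNames(as.numeric(sub("^rate [^:]+: ", "", body)),
                                  nmv)
    } else {
      nm <- sub("^\\[node (.*)\\]$", "\\1", hdr)
      beta_lines <- body[startsWith(body, "beta ")]
      # term names may themselves contain ':', so split at the last ': '
      bnames <- sub(": [^ :]*$", "", substring(beta_lines, 6L))
      beta <- stats::setNames(
        as.numeric(sub("^.*: ", "", beta_lines)), bnames)
      sdv <- as.numeric(sub("^sd: ", "", body[startsWith(body, "sd:")]))
      nodes[[nm]] <- list(beta = beta, sd = sdv)
    }
  }
  structure(list(nodes = nodes, baseline_predators = baseline,
                 denominators = c(cover = 100, seed = 5)),
            class = "ground_truth")
}
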