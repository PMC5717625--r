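# shared date/derivation rules used by both the synthetic generator and the
# reader-side frame builder, so fitted models see exactly the covariates the
# generator used

.month_str <- function(d) format(as.Date(d), "%Y-%m")

.month_index <- function(mstr) {
  as.integer(substr(mstr, 1, 4)) * 12L + as.integer(substr(mstr, 6, 7)) - 1L
}

.month_first_day <- function(idx) {
  as.Date(sprintf("%04d-%02d-01", idx %/% 12L, idx %% 12L + 1L))
}

# camera months are the `camera_months` consecutive calendar months ending
# at the month of the last trip; returns month index (1..M), month string
# and first day
.camera_month_map <- function(trip_calendar, camera_months) {
  last_idx <- max(.month_index(.month_str(trip_calendar$date)))
  idx <- (last_idx - camera_months + 1L):last_idx
  tibble::tibble(month = seq_len(camera_months),
                 month_str = sprintf("%04d-%02d", idx %/% 12L,
                                     idx %% 12L + 1L),
                 month_start = .month_first_day(idx))
}

# camera month (1..M) containing each trip date, NA outside the window
.trip_camera_month <- function(trip_dates, month_map) {
  match(.month_str(trip_dates), month_map$month_str)
}

# site-trip rodent capture rate per 100 trap-nights, pooled over grids
.site_trip_rodent_rate <- function(captures, trip_calendar) {
  captures |>
    dplyr::group_by(.data$site, .data$trip) |>
    dplyr::summarise(rodent_rate = sum(.data$rodents) /
                       sum(.data$trap_nights) * 100, .groups = "drop") |>
    dplyr::left_join(trip_calendar, by = c("site", "trip"))
}

# rodent rate at the most recent trip strictly before each camera month
.lagged_rodent_rate <- function(captures, trip_calendar, month_map) {
  rates <- .site_trip_rodent_rate(captures, trip_calendar)
  out <- expand.grid(site = unique(trip_calendar$site),
                     month = month_map$month,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$rodent_rate <- mapply(function(st, mo) {
    cutoff <- month_map$month_start[month_map$month == mo]
    r <- rates[rates$site == st & rates$date < cutoff, , drop = FALSE]
    if (!nrow(r)) return(NA_real_)
    r$rodent_rate[which.max(as.numeric(r$date))]
  }, out$site, out$month)
  tibble::as_tibble(out)
}

#' Build the per-node analysis tables from the raw study tables
#'
#' Joins the raw long-format tables into the four analysis frames the graph
#' nodes are fitted on: `captures` (grid x trip capture records with
#' vegetation, wildfire and rainfall covariates), `vegetation` (grid x trip
#' cover/seed scores with their drivers), `camera` (site x month predator
#' records with the rodent capture rate at the most recent preceding trip),
#' and `captures_camera_period` (the capture records restricted to the
#' camera window, joined with that month's predator photo rates).
#' Effort-standardized rate columns not created here are derived at fit
#' time by [standardize_predictors()].
#'
#' @param tables named list with `captures`, `camera`, `vegetation`,
#'   `rain_daily`, `fire`, `trip_calendar` (as read by
#'   [read_study_tables()]).
#' @param camera_months number of camera months (defaults to the maximum
#'   month index in the camera table).
#' @return Named list of tibbles keyed by frame name.
#' @export
build_node_frames <- function(tables, camera_months = NULL) {
  need <- c("captures", "camera", "vegetation", "rain_daily", "fire",
            "trip_calendar")
  missing <- setdiff(need, names(tables))
  if (length(missing)) {
    stop("tables list is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cal <- tables$trip_calendar
  cal$date <- as.Date(cal$date)
  if (is.null(camera_months)) camera_months <- max(tables$camera$month)
  rain_cov <- derive_rain_covariates(tables$rain_daily, cal)
  rain_small <- rain_cov[, c("site", "trip", "rain8", "rain_days",
                             "rain_event_lag2")]

  cap <- tables$captures |>
    dplyr::left_join(tables$vegetation, by = c("site", "grid", "trip")) |>
    dplyr::left_join(tables$fire, by = c("site", "grid", "trip")) |>
    dplyr::left_join(rain_small, by = c("site", "trip"))

  veg <- tables$vegetation |>
    dplyr::left_join(tables$fire, by = c("site", "grid", "trip")) |>
    dplyr::left_join(rain_small[, c("site", "trip", "rain8")],
                     by = c("site", "trip"))

  month_map <- .camera_month_map(cal, camera_months)
  cam <- tables$camera |>
    dplyr::left_join(.lagged_rodent_rate(tables$captures, cal, month_map),
                     by = c("site", "month"))

  cam_rates <- cam |>
    dplyr::transmute(.data$site, .data$month,
                     cat_rate = effort_rate(.data$cat, .data$camera_nights, 1),
                     fox_rate = effort_rate(.data$fox, .data$camera_nights, 1),
                     dingo_rate = effort_rate(.data$dingo,
                                              .data$camera_nights, 1))
  cap_cam <- cap |>
    dplyr::left_join(cal, by = c("site", "trip")) |>
    dplyr::mutate(month = .trip_camera_month(.data$date, month_map)) |>
    dplyr::filter(!is.na(.data$month)) |>
    dplyr::select(-"date") |>
    dplyr::inner_join(cam_rates, by = c("site", "month"))

  list(captures = cap, vegetation = veg, camera = cam,
       captures_camera_period = cap_cam)
}
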