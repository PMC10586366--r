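# Spray-drift entry route: annual application events per orchard, wind
# sampling from the rose, downwind test, and power-law drift deposition on
# reach water surfaces. Drift is the only substance entry route considered.

#' Spray-drift curve (power law)
#'
#' Areic drift deposition as a percentage of the applied areic rate at
#' downwind distance `z` (m): `pct(z) = A * z^B`. This is the regression
#' family used for orchard drift; the default coefficients are an
#' illustrative pome-fruit-like parameterisation and are configuration, not
#' a calibrated regulatory curve.
#'
#' @param coefficient_A percentage of the applied rate at 1 m
#' @param exponent_B negative decay exponent
#' @param valid_range distances (m) over which the curve applies; inputs
#'   below the range start are clamped to it (with a warning at use time)
#' @return a `drift_curve`
#' @export
drift_curve <- function(coefficient_A = 60, exponent_B = -1.7,
                        valid_range = c(1, 250)) {
  if (exponent_B >= 0) stop("drift curve exponent must be negative")
  if (coefficient_A <= 0) stop("drift curve coefficient must be positive")
  structure(list(coefficient_A = coefficient_A, exponent_B = exponent_B,
                 valid_range = valid_range),
            class = "drift_curve")
}

# curve value as a FRACTION of the applied areic rate
drift_fraction <- function(curve, z) {
  curve$coefficient_A / 100 * z^curve$exponent_B
}

#' Sample annual application dates
#'
#' One application event per orchard per year; the date is uniform over the
#' annual application window (inclusive) and independent across orchards
#' and years. The spray hour is the configured `application_hour` (noon by
#' default).
#'
#' @param orchards list of orchards
#' @param setup an `application_setup`
#' @param year simulation year index (1-based)
#' @return data.frame with `orchard_id`, `year`, `doy`, `hour`, `rate`
#' @export
sample_application_dates <- function(orchards, setup, year) {
  days <- setup$window_start_doy:setup$window_end_doy
  if (length(days) < 1) stop("configuration error: empty application window")
  doy <- if (length(days) == 1) rep(days, length(orchards))
         else days[sample.int(length(days), length(orchards), replace = TRUE)]
  data.frame(
    orchard_id = vapply(orchards, `[[`, "", "id"),
    year = year, doy = doy, hour = setup$application_hour, rate = setup$rate,
    stringsAsFactors = FALSE
  )
}

#' Sample a wind direction from a wind rose
#'
#' The sector is drawn with the rose probabilities; the direction is
#' uniform within the sector. Returned degrees are the direction the wind
#' blows FROM.
#'
#' @param rose a `wind_rose`
#' @param n number of draws
#' @return direction(s) in degrees `[0, 360)`
#' @export
sample_wind_direction <- function(rose, n = 1L) {
  k <- sample.int(nrow(rose), n, replace = TRUE, prob = rose$probability)
  w <- (rose$bin_end[k] - rose$bin_start[k]) %% 360
  w[w == 0] <- 360
  (rose$bin_start[k] + stats::runif(n) * w) %% 360
}

#' Downwind test for an orchard-reach pair
#'
#' A reach is downwind of an orchard when the compass bearing from the
#' orchard centroid to the nearest point of the reach centreline lies
#' within `sector_half_angle` (inclusive) of the downwind direction
#' (`wind_from + 180`).
#'
#' @param orchard an orchard (`list(id, polygon, crop)`)
#' @param reach_line reach centreline (n x 2 matrix)
#' @param wind_from wind direction (deg, blowing from)
#' @param sector_half_angle half-angle of the downwind sector (deg)
#' @return logical
#' @export
is_downwind <- function(orchard, reach_line, wind_from,
                        sector_half_angle = 45) {
  ctr <- polygon_centroid(orchard$polygon)
  np <- nearest_point_on_polyline(ctr, reach_line)
  if (all(abs(np - ctr) < 1e-12)) return(TRUE) # reach through the centroid
  b <- bearing_deg(ctr, np)
  angle_diff_deg(b, (wind_from + 180) %% 360) <= sector_half_angle
}

#' Orchard-to-reach drift distance
#'
#' Minimum Euclidean distance from the orchard polygon edge to the reach
#' centreline minus half the assumed drift surface width, floored at 0.
#'
#' @param orchard orchard
#' @param reach_line centreline matrix
#' @param drift_surface_width exposed water-surface width (m)
#' @return distance in m
#' @export
orchard_reach_distance <- function(orchard, reach_line, drift_surface_width) {
  d <- polygon_polyline_distance(orchard$polygon, reach_line)
  max(0, d - drift_surface_width / 2)
}

#' Drift deposition on a reach from one application event
#'
#' The effective drift distance is `max(distance, buffer_width)` (the
#' buffer acts as a minimum spray-to-water distance). The areic deposition
#' is the applied areic rate times the drift-curve fraction averaged
#' exactly over the water-surface band `[z, z + w]` (analytic integral of
#' the power law), times `(1 - drift_reduction)`. Mass is areic deposition
#' times the exposed surface (`w` times reach length). Unit conversion:
#' g/ha applied = x100 ug/m^2.
#'
#' @param rate application rate (g a.i./ha)
#' @param distance orchard-to-reach drift distance (m), >= 0
#' @param reach one-row reach data.frame (uses `drift_surface_width`,
#'   `length`)
#' @param curve a `drift_curve`
#' @param setup an `application_setup` (buffer, drift reduction)
#' @return list with `areic_mean` (ug/m^2) and `mass` (ug)
#' @export
drift_deposition <- function(rate, distance, reach, curve, setup) {
  if (distance < 0) stop("distance must be >= 0")
  z <- max(distance, setup$buffer_width)
  if (z < curve$valid_range[1]) {
    warning("drift distance ", signif(z, 3),
            " m below curve valid range; clamped to ", curve$valid_range[1], " m")
    z <- curve$valid_range[1]
  }
  w <- reach$drift_surface_width
  z2 <- z + w
  if (z > curve$valid_range[2]) {
    return(list(areic_mean = 0, mass = 0))
  }
  z2 <- min(z2, curve$valid_range[2])
  # band mean of A/100 * x^B over [z, z2] (exact antiderivative)
  Bp1 <- curve$exponent_B + 1
  frac_mean <- if (abs(Bp1) < 1e-12) {
    curve$coefficient_A / 100 * log(z2 / z) / (z2 - z)
  } else {
    curve$coefficient_A / 100 * (z2^Bp1 - z^Bp1) / (Bp1 * (z2 - z))
  }
  areic_applied <- rate * 100 # ug/m^2
  areic <- areic_applied * frac_mean * (1 - setup$drift_reduction)
  list(areic_mean = areic, mass = areic * w * reach$length)
}

#' Generate the full drift deposition series
#'
#' For each simulation year and orchard: sample an application date, then a
#' wind direction for the event day, and deposit drift on every reach that
#' is downwind of the orchard and within the drift curve's range.
#' Deterministic under the bundle seed: application dates and wind draws
#' come from separate named RNG streams.
#'
#' @param bundle a `scenario_bundle`
#' @param seed master seed
#' @param curve a `drift_curve`
#' @param sector_half_angle downwind sector half-angle (deg)
#' @return a `drift_series` data.frame: `reach_id`, `year`, `doy`, `hour`
#'   (0-based simulation hour), `orchard_id`, `areic_ug_per_m2`, `mass_ug`
#' @export
generate_drift_series <- function(bundle, seed, curve = drift_curve(),
                                  sector_half_angle = 45) {
  net <- bundle$network
  r <- net$reaches
  orchards <- bundle$orchards
  years <- seq_len(bundle$period$total_years)
  if (length(orchards) == 0) {
    return(.empty_drift_series())
  }
  if (is.null(net$geometry)) {
    stop("drift simulation requires reach centreline geometry")
  }

  # precompute candidate reaches per orchard (within curve range), their
  # distances and bearings
  cand <- lapply(orchards, function(o) {
    ctr <- polygon_centroid(o$polygon)
    rows <- list()
    for (i in seq_len(nrow(r))) {
      line <- net$geometry[[r$id[i]]]
      d <- orchard_reach_distance(o, line, r$drift_surface_width[i])
      z <- max(d, bundle$application$buffer_width)
      if (z > curve$valid_range[2]) next
      np <- nearest_point_on_polyline(ctr, line)
      brg <- if (all(abs(np - ctr) < 1e-12)) NA_real_ else bearing_deg(ctr, np)
      rows[[length(rows) + 1]] <- list(i = i, distance = d, bearing = brg)
    }
    rows
  })

  dates <- with_stream(seed, "application", {
    do.call(rbind, lapply(years, function(y) {
      sample_application_dates(orchards, bundle$application, y)
    }))
  })
  winds <- with_stream(seed, "wind", {
    sample_wind_direction(bundle$wind_rose, nrow(dates))
  })

  out <- vector("list", nrow(dates))
  for (k in seq_len(nrow(dates))) {
    oi <- match(dates$orchard_id[k], vapply(orchards, `[[`, "", "id"))
    downwind_dir <- (winds[k] + 180) %% 360
    recs <- list()
    for (cc in cand[[oi]]) {
      hit <- is.na(cc$bearing) ||
        angle_diff_deg(cc$bearing, downwind_dir) <= sector_half_angle
      if (!hit) next
      dep <- drift_deposition(dates$rate[k], cc$distance, r[cc$i, ],
                              curve, bundle$application)
      if (dep$mass <= 0) next
      recs[[length(recs) + 1]] <- data.frame(
        reach_id = r$id[cc$i], year = dates$year[k], doy = dates$doy[k],
        hour = (dates$year[k] - 1L) * HOURS_PER_YEAR +
          (dates$doy[k] - 1L) * 24L + dates$hour[k],
        orchard_id = dates$orchard_id[k],
        areic_ug_per_m2 = dep$areic_mean, mass_ug = dep$mass,
        stringsAsFactors = FALSE
      )
    }
    if (length(recs)) out[[k]] <- do.call(rbind, recs)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  res <- if (length(out)) do.call(rbind, out) else .empty_drift_series()
  res <- res[order(res$hour, res$reach_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("drift_series", "data.frame")
  res
}

.empty_drift_series <- function() {
  structure(data.frame(reach_id = character(), year = integer(),
                       doy = integer(), hour = integer(),
                       orchard_id = character(),
                       areic_ug_per_m2 = numeric(), mass_ug = numeric(),
                       stringsAsFactors = FALSE),
            class = c("drift_series", "data.frame"))
}

#' Write a drift series to CSV
#'
#' Columns: `reach_id, timestamp, mass_ug, areic_ug_per_m2`.
#'
#' @param drift a `drift_series`
#' @param path CSV path
#' @param base_year nominal first year
#' @export
write_drift_csv <- function(drift, path, base_year = 2001L) {
  df <- data.frame(reach_id = drift$reach_id,
                   timestamp = format_sim_hour(drift$hour, base_year),
                   mass_ug = drift$mass_ug,
                   areic_ug_per_m2 = drift$areic_ug_per_m2)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
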