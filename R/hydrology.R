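# Hydrology: catchment-area-yield disaggregation of an outlet discharge
# series, Manning normal-depth solution for trapezoidal channels, and
# residence times. Hydrology is externalized with respect to the fate
# module: it can be computed here or ingested from per-reach CSVs.

#' Disaggregate an outlet discharge series over the network
#'
#' Catchment-area-yield approach: every reach carries the outlet discharge
#' scaled by the ratio of its contributing drainage area to the outlet's.
#'
#' @param outlet_series hourly outlet discharge (m^3/h)
#' @param net a `reach_network`
#' @return matrix of discharge (m^3/h), reaches (rows, named by id) x hours
#' @export
disaggregate_discharge <- function(outlet_series, net) {
  r <- net$reaches
  outlet_area <- r$drainage_area[is.na(r$downstream_id)]
  if (outlet_area <= 0) stop("configuration error: outlet drainage area must be > 0")
  ratio <- r$drainage_area / outlet_area
  if (any(ratio > 1 + 1e-9)) {
    stop("reach drainage areas must not exceed the outlet's")
  }
  out <- outer(ratio, outlet_series)
  rownames(out) <- r$id
  out
}

#' Manning normal depth for a trapezoidal reach
#'
#' Solves `Q = (1/n) A(d) R(d)^(2/3) S^(1/2)` for depth `d`, with
#' `A = d (b + s d)`, wetted perimeter `P = b + 2 d sqrt(1 + s^2)` and
#' `R = A / P`. Discharge is monotone in depth, so bisection on
#' `[floor, dmax]` is unconditionally safe. `Q = 0` (or any discharge the
#' channel already carries at the floor depth) returns the configured
#' minimum depth floor.
#'
#' @param discharge discharge (m^3/h), vectorised
#' @param reach one-row data.frame (or list) with `bottom_width`,
#'   `bank_slope`, `manning_n`, `longitudinal_slope`
#' @param floor_depth minimum depth (m), default 0.01
#' @param tol bisection tolerance (m)
#' @param dmax upper bracket (m)
#' @return depth(s) in m
#' @export
solve_depth_manning <- function(discharge, reach, floor_depth = 0.01,
                                tol = 1e-8, dmax = 10) {
  manning_depth_cpp(discharge, reach$bottom_width, reach$bank_slope,
                    reach$manning_n, reach$longitudinal_slope,
                    floor_depth, tol, dmax)
}

#' Manning discharge at a given depth (forward formula)
#'
#' @param depth depth (m), vectorised
#' @inheritParams solve_depth_manning
#' @return discharge (m^3/h)
#' @export
manning_discharge <- function(depth, reach) {
  A <- depth * (reach$bottom_width + reach$bank_slope * depth)
  P <- reach$bottom_width + 2 * depth * sqrt(1 + reach$bank_slope^2)
  R <- ifelse(P > 0, A / P, 0)
  (1 / reach$manning_n) * A * R^(2 / 3) * sqrt(reach$longitudinal_slope) * 3600
}

# trapezoidal cross-section area at depth d
channel_area <- function(depth, bottom_width, bank_slope) {
  depth * (bottom_width + bank_slope * depth)
}

#' Residence time of water in a reach
#'
#' @param volume water volume (m^3)
#' @param discharge discharge (m^3/h)
#' @return residence time in minutes; `Inf` where discharge is zero
#'   (stagnant water has infinite advective residence)
#' @export
residence_time <- function(volume, discharge) {
  out <- ifelse(discharge > 0, 60 * volume / discharge, Inf)
  out[volume == 0] <- 0
  out
}

#' Compute per-reach hourly hydrology
#'
#' Applies [disaggregate_discharge()] and the Manning depth solver to give
#' hourly discharge, depth, velocity and volume per reach. Intended for
#' desk-scale series (the routing kernel recomputes the same quantities
#' internally on long runs without materialising them).
#'
#' @param bundle a `scenario_bundle` (or a `reach_network` plus
#'   `outlet_series`)
#' @param hours optional integer subset of hours (1-based) to compute
#' @param outlet_series override for the bundle's discharge series
#' @param floor_depth minimum depth (m)
#' @return a `hydro_series`: list of reach x hour matrices `discharge`
#'   (m^3/h), `depth` (m), `velocity` (m/h), `volume` (m^3), plus
#'   `reach_ids` and `hours`
#' @export
compute_hydrology <- function(bundle, hours = NULL, outlet_series = NULL,
                              floor_depth = 0.01) {
  net <- if (inherits(bundle, "scenario_bundle")) bundle$network else bundle
  if (is.null(outlet_series)) outlet_series <- bundle$discharge
  if (is.null(hours)) hours <- seq_along(outlet_series)
  q <- disaggregate_discharge(outlet_series[hours], net)
  r <- net$reaches
  depth <- q
  for (i in seq_len(nrow(r))) {
    depth[i, ] <- solve_depth_manning(q[i, ], r[i, ], floor_depth = floor_depth)
  }
  area <- channel_area(depth, r$bottom_width, r$bank_slope)
  volume <- area * r$length
  velocity <- q / area
  structure(list(discharge = q, depth = depth, velocity = velocity,
                 volume = volume, reach_ids = r$id, hours = hours),
            class = "hydro_series")
}

#' Write / read per-reach hydrology as long-format CSV
#'
#' Columns: `reach_id, timestamp, discharge_m3_per_h, depth_m,
#' velocity_m_per_h, volume_m3`.
#'
#' @param hydro a `hydro_series`
#' @param path CSV path
#' @param base_year nominal first year for timestamps
#' @return `path` (write) or a `hydro_series` (read)
#' @export
write_hydro_csv <- function(hydro, path, base_year = 2001L) {
  n <- length(hydro$reach_ids)
  hh <- hydro$hours
  df <- data.frame(
    reach_id = rep(hydro$reach_ids, times = length(hh)),
    timestamp = rep(format_sim_hour(hh - 1L, base_year), each = n),
    discharge_m3_per_h = as.vector(hydro$discharge),
    depth_m = as.vector(hydro$depth),
    velocity_m_per_h = as.vector(hydro$velocity),
    volume_m3 = as.vector(hydro$volume)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hydro_csv
#' @export
read_hydro_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(df$reach_id)
  ts <- unique(df$timestamp)
  shape <- function(col) {
    m <- matrix(df[[col]], nrow = length(ids), ncol = length(ts))
    rownames(m) <- ids
    m
  }
  structure(list(discharge = shape("discharge_m3_per_h"),
                 depth = shape("depth_m"),
                 velocity = shape("velocity_m_per_h"),
                 volume = shape("volume_m3"),
                 reach_ids = ids, hours = seq_along(ts)),
            class = "hydro_series")
}
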