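#' Construct a reach network
#'
#' A reach network is the spatial backbone of the simulator: a directed
#' acyclic river graph oriented towards a single outlet. Each reach is a
#' discrete stream segment with trapezoidal cross-section geometry and a
#' contributing drainage area.
#'
#' @param reaches a data.frame with one row per reach and columns `id`
#'   (character), `length` (m), `bottom_width` (m), `bank_slope`
#'   (horizontal run per unit rise; 0 = rectangular), `manning_n`
#'   (s m^-1/3), `longitudinal_slope` (m/m), `downstream_id` (character,
#'   `NA` for the single outlet), `drainage_area` (m^2),
#'   `drift_surface_width` (m, exposed water-surface width intercepting
#'   drift). Optional `strahler_order`; if absent it is computed.
#' @param geometry optional named list (by reach id) of n x 2 coordinate
#'   matrices (projected metric CRS) giving reach centrelines.
#' @param validate validate invariants (default TRUE)
#' @return an object of class `reach_network`
#' @seealso [compute_strahler()], [generate_synthetic_catchment()]
#' @export
reach_network <- function(reaches, geometry = NULL, validate = TRUE) {
  reaches <- as.data.frame(reaches, stringsAsFactors = FALSE)
  required <- c("id", "length", "bottom_width", "bank_slope", "manning_n",
                "longitudinal_slope", "downstream_id", "drainage_area",
                "drift_surface_width")
  missing_cols <- setdiff(required, names(reaches))
  if (length(missing_cols)) {
    stop("reach table is missing field(s): ", paste(missing_cols, collapse = ", "))
  }
  reaches$id <- as.character(reaches$id)
  reaches$downstream_id <- as.character(reaches$downstream_id)
  if (!"strahler_order" %in% names(reaches)) reaches$strahler_order <- NA_integer_
  net <- structure(list(reaches = reaches, geometry = geometry),
                   class = "reach_network")
  if (validate) validate_network(net)
  if (all(is.na(reaches$strahler_order))) net <- compute_strahler(net)
  net
}

#' Validate reach-network invariants
#'
#' Checks positivity of geometric attributes, uniqueness of ids, that
#' exactly one reach is the outlet, that every `downstream_id` resolves,
#' that the graph is acyclic, and that drainage area is non-decreasing
#' downstream.
#'
#' @param net a `reach_network`
#' @return the network, invisibly; errors on violation
#' @export
validate_network <- function(net) {
  r <- net$reaches
  if (anyDuplicated(r$id)) stop("duplicate reach ids")
  if (any(r$length <= 0)) stop("reach length must be > 0")
  if (any(r$manning_n <= 0)) stop("manning_n must be > 0")
  if (any(r$longitudinal_slope <= 0)) stop("longitudinal_slope must be > 0")
  if (any(r$bank_slope < 0)) stop("bank_slope must be >= 0")
  if (any(r$bottom_width < 0)) stop("bottom_width must be >= 0")
  if (any(r$drainage_area <= 0)) stop("drainage_area must be > 0")
  outlet <- is.na(r$downstream_id)
  if (sum(outlet) != 1) {
    stop("topology error: network must have exactly one outlet, found ", sum(outlet))
  }
  down <- r$downstream_id[!outlet]
  bad <- !down %in% r$id
  if (any(bad)) {
    stop("topology error: dangling downstream_id: ",
         paste(unique(down[bad]), collapse = ", "))
  }
  ord <- topological_order(net) # errors on cycle
  idx <- match(r$downstream_id, r$id)
  da_bad <- which(!is.na(idx) & r$drainage_area > r$drainage_area[idx] + 1e-9)
  if (length(da_bad)) {
    stop("drainage_area decreases downstream at reach ",
         paste(r$id[da_bad], collapse = ", "))
  }
  invisible(net)
}

#' Topological (upstream-to-downstream) order of reach indices
#'
#' @param net a `reach_network`
#' @return integer vector of row indices such that every reach appears
#'   before its downstream neighbour
#' @export
topological_order <- function(net) {
  r <- net$reaches
  n <- nrow(r)
  idx_down <- match(r$downstream_id, r$id)
  n_up <- tabulate(idx_down[!is.na(idx_down)], nbins = n)
  queue <- which(n_up == 0)
  out <- integer(0)
  remaining <- n_up
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    out <- c(out, i)
    d <- idx_down[i]
    if (!is.na(d)) {
      remaining[d] <- remaining[d] - 1L
      if (remaining[d] == 0L) queue <- c(queue, d)
    }
  }
  if (length(out) != n) stop("topology error: cycle detected in reach network")
  out
}

#' Assign Strahler stream orders
#'
#' Classical Strahler rule: headwater reaches are order 1; where two
#' tributaries of equal maximum order join, the downstream order increments
#' by one, otherwise the maximum order propagates.
#'
#' @param net a `reach_network`
#' @return the network with `strahler_order` filled
#' @export
compute_strahler <- function(net) {
  r <- net$reaches
  ord <- topological_order(net)
  idx_down <- match(r$downstream_id, r$id)
  up <- vector("list", nrow(r))
  for (i in seq_len(nrow(r))) {
    d <- idx_down[i]
    if (!is.na(d)) up[[d]] <- c(up[[d]], i)
  }
  so <- integer(nrow(r))
  for (i in ord) {
    u <- up[[i]]
    if (length(u) == 0) {
      so[i] <- 1L
    } else {
      o <- so[u]
      m <- max(o)
      so[i] <- if (sum(o == m) >= 2L) m + 1L else m
    }
  }
  net$reaches$strahler_order <- so
  net
}

#' Set reach geometry attributes from a Strahler-order lookup
#'
#' The hydraulic attributes of a reach (other than length) are set from its
#' Strahler order, mirroring how landscape scenarios parameterise channel
#' geometry when surveyed cross-sections are unavailable.
#'
#' @param net a `reach_network` with orders assigned
#' @param lookup a data.frame with columns `order`, `bottom_width`,
#'   `bank_slope`, `manning_n`, `drift_surface_width` and optionally
#'   `longitudinal_slope`; must cover every order present
#' @return the network with attributes replaced; lengths untouched
#' @export
assign_geometry_by_strahler <- function(net, lookup) {
  so <- net$reaches$strahler_order
  if (any(is.na(so))) stop("strahler_order not assigned; run compute_strahler first")
  miss <- setdiff(unique(so), lookup$order)
  if (length(miss)) {
    stop("configuration error: geometry lookup missing Strahler order(s) ",
         paste(sort(miss), collapse = ", "))
  }
  j <- match(so, lookup$order)
  for (col in c("bottom_width", "bank_slope", "manning_n", "drift_surface_width",
                "longitudinal_slope")) {
    if (col %in% names(lookup)) net$reaches[[col]] <- lookup[[col]][j]
  }
  validate_network(net)
  net
}

#' @export
print.reach_network <- function(x, ...) {
  r <- x$reaches
  cat("<reach_network> ", nrow(r), " reaches, outlet '",
      r$id[is.na(r$downstream_id)], "'\n", sep = "")
  tab <- table(r$strahler_order)
  cat("  Strahler orders:",
      paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = "  "), "\n")
  cat("  total length:", round(sum(r$length) / 1000, 2), "km\n")
  invisible(x)
}

#' Substance physico-chemical properties
#'
#' @param koc organic-carbon sorption coefficient (L/kg)
#' @param dt50_water,dt50_sediment transformation half-lives (d)
#' @param ref_temp reference temperature for the half-lives (degC)
#' @param molar_activation_energy Arrhenius activation energy (kJ/mol);
#'   65.4 is the surface-water modelling convention
#' @param volatilization_rate first-order loss from the dissolved phase (1/d)
#' @param sed_exchange_velocity water-sediment diffusive exchange velocity (m/d)
#' @param foc_suspended,foc_sediment organic-carbon fractions (-)
#' @param suspended_solids suspended-solids concentration (kg/L)
#' @param sediment_depth mixed sediment layer depth (m)
#' @param sediment_porosity pore volume fraction (-)
#' @param sediment_bulk_density dry bulk density (kg/L)
#' @return a `substance_properties` list
#' @export
substance_properties <- function(koc,
                                 dt50_water,
                                 dt50_sediment,
                                 ref_temp = 20,
                                 molar_activation_energy = 65.4,
                                 volatilization_rate = 0,
                                 sed_exchange_velocity = 0.01,
                                 foc_suspended = 0.1,
                                 foc_sediment = 0.05,
                                 suspended_solids = 1.5e-5,
                                 sediment_depth = 0.05,
                                 sediment_porosity = 0.6,
                                 sediment_bulk_density = 0.8) {
  s <- list(koc = koc, dt50_water = dt50_water, dt50_sediment = dt50_sediment,
            ref_temp = ref_temp,
            molar_activation_energy = molar_activation_energy,
            volatilization_rate = volatilization_rate,
            sed_exchange_velocity = sed_exchange_velocity,
            foc_suspended = foc_suspended, foc_sediment = foc_sediment,
            suspended_solids = suspended_solids,
            sediment_depth = sediment_depth,
            sediment_porosity = sediment_porosity,
            sediment_bulk_density = sediment_bulk_density)
  pos <- c("koc", "dt50_water", "dt50_sediment", "sed_exchange_velocity",
           "foc_suspended", "foc_sediment", "sediment_depth",
           "sediment_porosity", "sediment_bulk_density")
  for (f in pos) {
    if (!is.finite(s[[f]]) || s[[f]] <= 0) stop("substance field must be positive: ", f)
  }
  if (s$volatilization_rate < 0) stop("volatilization_rate must be >= 0")
  if (s$suspended_solids < 0) stop("suspended_solids must be >= 0")
  structure(s, class = "substance_properties")
}

#' Annual application setup
#'
#' @param window_start,window_end annual application window, `"MM-DD"`
#' @param rate application rate (g a.i./ha)
#' @param drift_reduction fraction in `[0,1]` (drift-reducing technology)
#' @param buffer_width no-spray buffer along surface water (m); acts as a
#'   minimum effective drift distance
#' @param application_hour hour of day of the spray event (default noon)
#' @return an `application_setup` list
#' @export
application_setup <- function(window_start = "04-20", window_end = "04-30",
                              rate = 12.5, drift_reduction = 0.75,
                              buffer_width = 10, application_hour = 12L) {
  ds <- doy_from_mmdd(window_start)
  de <- doy_from_mmdd(window_end)
  if (ds > de) stop("window_start must be on or before window_end")
  if (rate <= 0) stop("application rate must be > 0")
  if (drift_reduction < 0 || drift_reduction > 1) {
    stop("drift_reduction must be in [0, 1]")
  }
  structure(list(window_start = window_start, window_end = window_end,
                 window_start_doy = ds, window_end_doy = de,
                 rate = rate, drift_reduction = drift_reduction,
                 buffer_width = buffer_width,
                 application_hour = as.integer(application_hour)),
            class = "application_setup")
}

#' Wind rose
#'
#' Directions are compass degrees the wind blows FROM; bins partition
#' `[0, 360)`.
#'
#' @param bin_start,bin_end bin edges (deg)
#' @param probability bin probabilities, must sum to 1 (within 1e-9)
#' @return a `wind_rose` data.frame
#' @export
wind_rose <- function(bin_start, bin_end, probability) {
  if (any(probability < 0)) stop("wind rose probabilities must be >= 0")
  if (abs(sum(probability) - 1) > 1e-9) {
    stop("wind rose probabilities must sum to 1 (got ", sum(probability), ")")
  }
  o <- order(bin_start)
  bin_start <- bin_start[o]; bin_end <- bin_end[o]; probability <- probability[o]
  width <- (bin_end - bin_start) %% 360
  width[width == 0] <- 360
  if (abs(sum(width) - 360) > 1e-9 || bin_start[1] != 0) {
    stop("wind rose bins must partition [0, 360)")
  }
  if (length(bin_start) > 1 &&
      any(abs(bin_end[-length(bin_end)] - bin_start[-1]) > 1e-9)) {
    stop("wind rose bins must be contiguous")
  }
  structure(data.frame(bin_start = bin_start, bin_end = bin_end,
                       probability = probability),
            class = c("wind_rose", "data.frame"))
}

# convenience: n equal sectors with given probabilities (or uniform)
uniform_wind_rose <- function(n_sectors = 8L, probability = NULL) {
  edges <- seq(0, 360, length.out = n_sectors + 1)
  if (is.null(probability)) probability <- rep(1 / n_sectors, n_sectors)
  wind_rose(edges[-(n_sectors + 1)], edges[-1], probability)
}

#' Simulation period
#'
#' @param warmup_years years simulated but excluded from assessment
#' @param assessment_years years entering the risk end points
#' @return a `simulation_period` list
#' @export
simulation_period <- function(warmup_years = 6L, assessment_years = 20L) {
  warmup_years <- as.integer(warmup_years)
  assessment_years <- as.integer(assessment_years)
  if (warmup_years < 0) stop("warmup_years must be >= 0")
  if (assessment_years < 1) stop("assessment_years must be >= 1")
  structure(list(warmup_years = warmup_years,
                 assessment_years = assessment_years,
                 total_years = warmup_years + assessment_years),
            class = "simulation_period")
}

#' Assemble a scenario bundle
#'
#' The scenario bundle collects every landscape input the simulation chain
#' needs: network, orchards, wind rose, substance, application setup,
#' hourly outlet discharge, daily temperature (stored raw; the 3-day
#' trailing mean used by the fate module is computed here), and the
#' simulation period.
#'
#' @param network a `reach_network`
#' @param orchards list of orchards, each `list(id, polygon = n x 2 matrix,
#'   crop)`
#' @param wind_rose a `wind_rose`
#' @param substance a `substance_properties`
#' @param application an `application_setup`
#' @param discharge hourly outlet discharge (m^3/h), length
#'   `total_years * 8760`
#' @param temperature daily temperature (degC), length `total_years * 365`
#' @param period a `simulation_period`
#' @return a `scenario_bundle`
#' @export
scenario_bundle <- function(network, orchards, wind_rose, substance,
                            application, discharge, temperature, period) {
  stopifnot(inherits(network, "reach_network"),
            inherits(wind_rose, "wind_rose"),
            inherits(substance, "substance_properties"),
            inherits(application, "application_setup"),
            inherits(period, "simulation_period"))
  nh <- period$total_years * HOURS_PER_YEAR
  nd <- period$total_years * DAYS_PER_YEAR
  if (length(discharge) != nh) {
    stop("discharge series must have ", nh, " hourly values, got ", length(discharge))
  }
  if (length(temperature) != nd) {
    stop("temperature series must have ", nd, " daily values, got ", length(temperature))
  }
  if (any(discharge < 0)) stop("discharge must be >= 0")
  for (o in orchards) {
    if (is.null(o$polygon) || nrow(o$polygon) < 3 || polygon_area(o$polygon) <= 0) {
      stop("orchard polygon must be a simple polygon with non-empty area")
    }
  }
  structure(list(network = network, orchards = orchards, wind_rose = wind_rose,
                 substance = substance, application = application,
                 discharge = discharge, temperature = temperature,
                 temperature_3day = trailing_3day_mean(temperature),
                 period = period),
            class = "scenario_bundle")
}

#' Trailing 3-day mean of a daily temperature series
#'
#' Value for day t is the mean of days t-3..t-1. The first three days,
#' which have no full preceding window, are padded with the first available
#' mean (any artefact is absorbed by the warm-up period).
#'
#' @param x daily series
#' @return series of the same length
#' @export
trailing_3day_mean <- function(x) {
  n <- length(x)
  if (n < 4) return(rep(mean(x), n))
  prev <- c(0, cumsum(x)) # prev[t] = sum of first t-1 values
  out <- numeric(n)
  out[4:n] <- (prev[4:n] - prev[1:(n - 3)]) / 3
  out[1:3] <- out[4]
  out
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat("<scenario_bundle>\n")
  print(x$network)
  cat("  orchards:", length(x$orchards),
      "| period:", x$period$warmup_years, "warm-up +",
      x$period$assessment_years, "assessment years\n")
  cat("  application:", x$application$rate, "g/ha,",
      x$application$window_start, "to", x$application$window_end,
      "| drift reduction", x$application$drift_reduction,
      "| buffer", x$application$buffer_width, "m\n")
  invisible(x)
}
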