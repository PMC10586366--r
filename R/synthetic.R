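#' Default Strahler-order geometry lookup for synthetic catchments
#'
#' Channel geometry per Strahler order for small lowland streams: widths of
#' a few decimetres in headwaters to a few metres near the outlet, mild
#' slopes decreasing downstream. Used by [generate_synthetic_catchment()];
#' replaceable by the user.
#'
#' @return data.frame with one row per order 1..6
#' @export
default_geometry_lookup <- function() {
  data.frame(
    order = 1:6,
    bottom_width = c(0.4, 0.8, 1.5, 2.5, 4.0, 6.0),
    bank_slope = rep(1, 6),
    manning_n = c(0.04, 0.035, 0.035, 0.03, 0.03, 0.03),
    longitudinal_slope = c(0.004, 0.003, 0.002, 0.0015, 0.001, 0.001),
    drift_surface_width = c(0.6, 1.0, 1.8, 3.0, 4.5, 6.5)
  )
}

#' Generate a synthetic dendritic catchment scenario
#'
#' Builds a random dendritic reach network (Galton-Watson-style upstream
#' growth with at most two tributaries per junction), embeds it in the
#' plane, attaches orchard polygons to a fraction of reaches, and
#' synthesises seasonal hourly outlet discharge, daily temperature and a
#' wind rose. The defaults emulate the composition of a small lowland
#' orchard catchment: reach lengths around 100 m (clamped to 5-110 m),
#' roughly 55 percent order-1 headwater reaches, depths of centimetres to
#' decimetres, and advective residence times of minutes.
#'
#' Fully reproducible: identical `(n_reaches, seed, params)` give an
#' identical bundle.
#'
#' @param n_reaches number of reaches (>= 1)
#' @param seed master integer seed
#' @param branch_prob probability that a new upstream reach starts a new
#'   tributary (creates a junction) rather than extending an existing
#'   headwater chain; controls the share of order-1 reaches
#' @param length_mean,length_sd,length_min,length_max reach length draw (m)
#' @param local_area_meanlog,local_area_sdlog lognormal local drainage area
#'   per reach (log m^2)
#' @param geometry_lookup Strahler-order geometry table
#'   (see [default_geometry_lookup()])
#' @param orchard_fraction fraction of reaches flanked by an orchard
#' @param orchard_distance_range min/max distance (m) from reach centreline
#'   to the near orchard edge
#' @param orchard_length,orchard_depth orchard rectangle dimensions (m)
#' @param specific_yield mean specific discharge (m^3/h per m^2 of
#'   drainage area); default 3.6e-5 (~10 L/s/km^2)
#' @param seasonal_amplitude relative amplitude of the seasonal discharge
#'   sinusoid; `peak_doy` its day-of-year maximum (winter default)
#' @param flow_noise_sdlog day-to-day lognormal discharge noise (log scale)
#' @param temp_mean,temp_amplitude,temp_noise_sd daily temperature model
#'   (degC); peak at mid-July
#' @param n_wind_sectors,wind_probabilities wind rose (uniform by default)
#' @param substance,application,period overrides; defaults are a high-Koc
#'   pyrethroid-like substance (Koc 1.024e6 L/kg, DT50 1000 d water /
#'   43.9 d sediment), 12.5 g/ha applied April 20-30 with 75 percent drift
#'   reduction and a 10 m buffer, and 6 warm-up + 20 assessment years
#' @return a `scenario_bundle`
#' @export
generate_synthetic_catchment <- function(
    n_reaches,
    seed,
    branch_prob = 0.42,
    length_mean = 100, length_sd = 15, length_min = 5, length_max = 110,
    local_area_meanlog = log(8.8e4), local_area_sdlog = 0.5,
    geometry_lookup = default_geometry_lookup(),
    orchard_fraction = 0.35,
    orchard_distance_range = c(3, 40),
    orchard_length = 80, orchard_depth = 120,
    specific_yield = 3.6e-5,
    seasonal_amplitude = 0.6, peak_doy = 15,
    flow_noise_sdlog = 0.25,
    temp_mean = 10.5, temp_amplitude = 7.5, temp_noise_sd = 1.5,
    n_wind_sectors = 8L, wind_probabilities = NULL,
    substance = NULL, application = NULL, period = NULL) {
  n_reaches <- as.integer(n_reaches)
  if (n_reaches < 1) stop("n_reaches must be >= 1")
  if (is.null(substance)) {
    substance <- substance_properties(koc = 1.024e6, dt50_water = 1000,
                                      dt50_sediment = 43.9)
  }
  if (is.null(application)) application <- application_setup()
  if (is.null(period)) period <- simulation_period()

  with_stream(seed, "generator", {
    ## ---- topology: grow the tree upstream from the outlet ----
    parent <- rep(NA_integer_, n_reaches) # downstream neighbour
    n_children <- integer(n_reaches)
    if (n_reaches > 1) {
      for (i in 2:n_reaches) {
        candidates1 <- which(n_children[seq_len(i - 1)] == 1L) # junction targets
        candidates0 <- which(n_children[seq_len(i - 1)] == 0L) # chain tips
        make_junction <- length(candidates1) > 0 &&
          (length(candidates0) == 0 || stats::runif(1) < branch_prob)
        pool <- if (make_junction) candidates1 else candidates0
        p <- pool[sample.int(length(pool), 1L)]
        parent[i] <- p
        n_children[p] <- n_children[p] + 1L
      }
    }

    ## ---- lengths and drainage areas ----
    len <- pmin(length_max,
                pmax(length_min, stats::rnorm(n_reaches, length_mean, length_sd)))
    local_area <- stats::rlnorm(n_reaches, local_area_meanlog, local_area_sdlog)
    drainage <- local_area
    # accumulate upstream-to-downstream (children have larger index than n=1? no:
    # parents always have smaller index, so iterate from highest index down)
    for (i in n_reaches:2) {
      if (i > 1) drainage[parent[i]] <- drainage[parent[i]] + drainage[i]
    }

    ## ---- planar embedding ----
    # downstream end of the outlet at the origin; network grows northward
    dir_deg <- numeric(n_reaches) # direction of flow FROM upstream TO downstream
    dir_deg[1] <- 180 # outlet flows south
    end_x <- numeric(n_reaches); end_y <- numeric(n_reaches)
    start_x <- numeric(n_reaches); start_y <- numeric(n_reaches)
    # process in index order: parents first by construction
    kids <- vector("list", n_reaches)
    if (n_reaches > 1) for (i in 2:n_reaches) kids[[parent[i]]] <- c(kids[[parent[i]]], i)
    # angles: a single upstream child continues with jitter; two children fork
    for (i in seq_len(n_reaches)) {
      k <- kids[[i]]
      if (length(k) == 1) {
        dir_deg[k] <- dir_deg[i] + stats::runif(1, -20, 20)
      } else if (length(k) >= 2) {
        spread <- stats::runif(1, 25, 50)
        dir_deg[k[1]] <- dir_deg[i] - spread + stats::runif(1, -10, 10)
        dir_deg[k[2]] <- dir_deg[i] + spread + stats::runif(1, -10, 10)
      }
    }
    # positions: walk index order (parents first); upstream end = downstream
    # end displaced against the flow direction
    end_x[1] <- 0; end_y[1] <- 0
    for (i in seq_len(n_reaches)) {
      if (i > 1) { end_x[i] <- start_x[parent[i]]; end_y[i] <- start_y[parent[i]] }
      th <- dir_deg[i] * pi / 180 # compass bearing of the flow direction
      start_x[i] <- end_x[i] - sin(th) * len[i]
      start_y[i] <- end_y[i] - cos(th) * len[i]
    }

    ids <- sprintf("r%03d", seq_len(n_reaches))
    geom <- lapply(seq_len(n_reaches), function(i) {
      rbind(c(start_x[i], start_y[i]), c(end_x[i], end_y[i]))
    })
    names(geom) <- ids

    reaches <- data.frame(
      id = ids,
      length = len,
      bottom_width = 1, bank_slope = 1, manning_n = 0.035,
      longitudinal_slope = 0.002,
      downstream_id = ifelse(is.na(parent), NA_character_, ids[parent]),
      drainage_area = drainage,
      drift_surface_width = 1,
      stringsAsFactors = FALSE
    )
    net <- reach_network(reaches, geometry = geom)
    net <- assign_geometry_by_strahler(net, geometry_lookup)

    ## ---- orchards along a random subset of reaches ----
    n_orch <- round(orchard_fraction * n_reaches)
    orchards <- list()
    if (n_orch > 0) {
      near <- sample.int(n_reaches, n_orch)
      for (j in seq_along(near)) {
        i <- near[j]
        d_edge <- stats::runif(1, orchard_distance_range[1], orchard_distance_range[2])
        side <- if (stats::runif(1) < 0.5) 1 else -1
        # unit vectors along and perpendicular to the reach
        ax <- end_x[i] - start_x[i]; ay <- end_y[i] - start_y[i]
        L <- sqrt(ax^2 + ay^2); ax <- ax / L; ay <- ay / L
        px <- -ay * side; py <- ax * side
        mx <- (start_x[i] + end_x[i]) / 2; my <- (start_y[i] + end_y[i]) / 2
        w2 <- net$reaches$drift_surface_width[i] / 2
        o1 <- c(mx, my) + (d_edge + w2) * c(px, py) - orchard_length / 2 * c(ax, ay)
        ring <- rbind(
          o1,
          o1 + orchard_length * c(ax, ay),
          o1 + orchard_length * c(ax, ay) + orchard_depth * c(px, py),
          o1 + orchard_depth * c(px, py)
        )
        orchards[[j]] <- list(id = sprintf("o%03d", j), polygon = unname(ring),
                              crop = "pome_fruit")
      }
    }

    ## ---- wind rose ----
    rose <- uniform_wind_rose(n_wind_sectors, wind_probabilities)

    ## ---- discharge and temperature series ----
    n_days <- period$total_years * DAYS_PER_YEAR
    doy <- rep(seq_len(DAYS_PER_YEAR), period$total_years)
    q_mean <- drainage[1] * specific_yield # outlet mean (m^3/h)
    seasonal <- 1 + seasonal_amplitude * cos(2 * pi * (doy - peak_doy) / DAYS_PER_YEAR)
    noise <- stats::rlnorm(n_days, -flow_noise_sdlog^2 / 2, flow_noise_sdlog)
    q_daily <- q_mean * seasonal * noise
    discharge <- rep(q_daily, each = 24L)

    temp_season <- temp_mean +
      temp_amplitude * cos(2 * pi * (doy - 196) / DAYS_PER_YEAR)
    temperature <- temp_season + stats::rnorm(n_days, 0, temp_noise_sd)

    scenario_bundle(net, orchards, rose, substance, application,
                    discharge, temperature, period)
  })
}
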