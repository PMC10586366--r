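# Fixtures are built in code: tiny networks, random trees with an
# independent Strahler oracle, and a hand-written minimal scenario
# directory.

# straight chain r1 (outlet) <- r2 <- ... <- rn, equal geometry, drainage
# accumulating downstream
make_chain_network <- function(n, length = 100, bottom_width = 1,
                               bank_slope = 1, manning_n = 0.035,
                               slope = 0.002, local_area = 1e5,
                               drift_surface_width = 1) {
  ids <- paste0("r", seq_len(n))
  df <- data.frame(
    id = ids, length = length, bottom_width = bottom_width,
    bank_slope = bank_slope, manning_n = manning_n,
    longitudinal_slope = slope,
    downstream_id = c(NA, ids[-n]),
    drainage_area = local_area * (n:1),
    drift_surface_width = drift_surface_width,
    stringsAsFactors = FALSE
  )
  geom <- lapply(seq_len(n), function(i) {
    rbind(c(0, i * length), c(0, (i - 1) * length))
  })
  names(geom) <- ids
  reach_network(df, geometry = geom)
}

# random tree as a parent vector (parent[i] < i, at most two children);
# independent of the package's catchment generator
random_parent_tree <- function(n) {
  parent <- rep(NA_integer_, n)
  n_child <- integer(n)
  for (i in seq_len(n)[-1]) {
    cand <- which(n_child[seq_len(i - 1)] < 2L)
    p <- cand[sample.int(length(cand), 1)]
    parent[i] <- p
    n_child[p] <- n_child[p] + 1L
  }
  parent
}

# brute-force recursive Strahler oracle on a parent vector
strahler_oracle <- function(parent) {
  n <- length(parent)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(parent[i])) children[[parent[i]]] <- c(children[[parent[i]]], i)
  }
  rec <- function(i) {
    ch <- children[[i]]
    if (length(ch) == 0) return(1L)
    o <- vapply(ch, rec, integer(1))
    m <- max(o)
    if (sum(o == m) >= 2L) m + 1L else m
  }
  vapply(seq_len(n), rec, integer(1))
}

network_from_parents <- function(parent, local_area = 1e5) {
  n <- length(parent)
  ids <- paste0("t", seq_len(n))
  drainage <- rep(local_area, n)
  for (i in n:2) drainage[parent[i]] <- drainage[parent[i]] + drainage[i]
  reach_network(data.frame(
    id = ids, length = 100, bottom_width = 1, bank_slope = 1,
    manning_n = 0.035, longitudinal_slope = 0.002,
    downstream_id = c(NA, ids[parent[-1]]),
    drainage_area = drainage, drift_surface_width = 1,
    stringsAsFactors = FALSE
  ))
}

# substance with (near-)inert behaviour except where switched on; keeps
# advection as the only active process by default
inert_substance <- function(dt50_water = 1e9, dt50_sediment = 1e9,
                            sed_exchange_velocity = 1e-12, koc = 1e-6,
                            suspended_solids = 0, ...) {
  substance_properties(koc = koc, dt50_water = dt50_water,
                       dt50_sediment = dt50_sediment,
                       molar_activation_energy = 1e-9,
                       sed_exchange_velocity = sed_exchange_velocity,
                       suspended_solids = suspended_solids, ...)
}

# bundle around an arbitrary network with constant outlet discharge and
# temperature; no orchards unless supplied
make_bundle <- function(net, q_outlet_m3h = 360, temp = 15,
                        warmup = 0, assess = 1, orchards = list(),
                        substance = inert_substance(),
                        application = application_setup()) {
  period <- simulation_period(warmup, assess)
  nh <- period$total_years * 8760
  nd <- period$total_years * 365
  scenario_bundle(net, orchards, uniform_wind_rose(8), substance,
                  application,
                  discharge = rep(q_outlet_m3h, nh),
                  temperature = rep(temp, nd), period = period)
}

# a drift series with pulses at given hours (bypasses the stochastic sampler)
pulse_drift <- function(reach_id, hour, mass_ug) {
  n <- length(hour)
  structure(data.frame(reach_id = reach_id, year = hour %/% 8760 + 1L,
                       doy = (hour %% 8760) %/% 24 + 1L, hour = hour,
                       orchard_id = rep("pulse", n),
                       areic_ug_per_m2 = rep(NA_real_, n),
                       mass_ug = mass_ug, stringsAsFactors = FALSE),
            class = c("drift_series", "data.frame"))
}

# hand-written minimal scenario directory (2 reaches, 1 orchard)
write_minimal_scenario <- function(dir, drop_field = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  props2 <- paste0(
    '"id":"r2","length":100,"bottom_width":1,"bank_slope":1,',
    '"manning_n":0.035,"longitudinal_slope":0.002,',
    '"downstream_id":"r1","drainage_area":100000,"drift_surface_width":1'
  )
  if (!is.null(drop_field)) {
    props2 <- gsub(sprintf('"%s":[^,]+,?', drop_field), "", props2)
    props2 <- sub(",$", "", props2)
  }
  writeLines(paste0(
    '{"type":"FeatureCollection","features":[',
    '{"type":"Feature","geometry":{"type":"LineString",',
    '"coordinates":[[0,100],[0,0]]},"properties":{',
    '"id":"r1","length":100,"bottom_width":1,"bank_slope":1,',
    '"manning_n":0.035,"longitudinal_slope":0.002,',
    '"drainage_area":200000,"drift_surface_width":1}},',
    '{"type":"Feature","geometry":{"type":"LineString",',
    '"coordinates":[[0,200],[0,100]]},"properties":{', props2, '}}]}'
  ), file.path(dir, "network.geojson"))
  writeLines(paste0(
    '{"type":"FeatureCollection","features":[',
    '{"type":"Feature","geometry":{"type":"Polygon",',
    '"coordinates":[[[20,50],[120,50],[120,150],[20,150],[20,50]]]},',
    '"properties":{"id":"o1","crop":"pome_fruit"}}]}'
  ), file.path(dir, "orchards.geojson"))
  nh <- 8760
  writeLines(c("timestamp,discharge_m3_per_s",
               paste0(aquarisk:::format_sim_hour(0:(nh - 1)), ",0.1")),
             file.path(dir, "discharge.csv"))
  writeLines(c("date,temperature_c",
               paste0(substr(aquarisk:::format_sim_hour((0:364) * 24), 1, 10),
                      ",", rep(12, 365))),
             file.path(dir, "temperature.csv"))
  writeLines(c("bin_start_deg,bin_end_deg,probability",
               "0,180,0.5", "180,360,0.5"),
             file.path(dir, "wind_rose.csv"))
  writeLines(c(
    "substance:", "  koc: 1024000.0", "  dt50_water: 1000.0",
    "  dt50_sediment: 43.9",
    "application:", "  window_start: '04-20'", "  window_end: '04-30'",
    "  rate: 12.5", "  drift_reduction: 0.75", "  buffer_width: 10",
    "  application_hour: 12",
    "period:", "  warmup_years: 0", "  assessment_years: 1"
  ), file.path(dir, "config.yaml"))
  dir
}
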