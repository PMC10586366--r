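# Scenario directory layout (one directory = one landscape scenario):
#   network.geojson   LineString features, reach attributes in properties
#   orchards.geojson  Polygon features
#   discharge.csv     timestamp, discharge_m3_per_s  (hourly, outlet)
#   temperature.csv   date, temperature_c            (daily, raw)
#   wind_rose.csv     bin_start_deg, bin_end_deg, probability
#   config.yaml       substance, application, period blocks
# Coordinates are a projected metric CRS; all distances in metres.

#' Write a scenario bundle to a directory
#'
#' Serialises the bundle to the documented plain-text scenario layout
#' (GeoJSON + CSV + YAML). Deterministic: the same bundle always produces
#' byte-identical files.
#'
#' @param bundle a `scenario_bundle`
#' @param dir output directory (created if needed)
#' @param base_year nominal first calendar year for timestamps
#' @return `dir`, invisibly
#' @export
write_scenario <- function(bundle, dir, base_year = 2001L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  r <- bundle$network$reaches
  geom <- bundle$network$geometry
  feat <- lapply(seq_len(nrow(r)), function(i) {
    coords <- if (!is.null(geom)) geom[[r$id[i]]] else matrix(c(0, 0, 0, 1), 2)
    list(
      type = "Feature",
      geometry = list(type = "LineString",
                      coordinates = lapply(seq_len(nrow(coords)), function(k) {
                        c(round(coords[k, 1], 3), round(coords[k, 2], 3))
                      })),
      properties = Filter(Negate(is.null), list(
        id = r$id[i], length = r$length[i], bottom_width = r$bottom_width[i],
        bank_slope = r$bank_slope[i], manning_n = r$manning_n[i],
        longitudinal_slope = r$longitudinal_slope[i],
        strahler_order = r$strahler_order[i],
        downstream_id = if (is.na(r$downstream_id[i])) NULL else r$downstream_id[i],
        drainage_area = r$drainage_area[i],
        drift_surface_width = r$drift_surface_width[i]
      ))
    )
  })
  .write_json(list(type = "FeatureCollection", features = feat),
              file.path(dir, "network.geojson"))

  ofeat <- lapply(bundle$orchards, function(o) {
    ring <- rbind(o$polygon, o$polygon[1, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)), function(k) {
                           c(round(ring[k, 1], 3), round(ring[k, 2], 3))
                         }))),
         properties = list(id = o$id, crop = o$crop))
  })
  .write_json(list(type = "FeatureCollection", features = ofeat),
              file.path(dir, "orchards.geojson"))

  nh <- length(bundle$discharge)
  utils::write.csv(
    data.frame(timestamp = format_sim_hour(0:(nh - 1), base_year),
               discharge_m3_per_s = sprintf("%.6g", bundle$discharge / 3600)),
    file.path(dir, "discharge.csv"), row.names = FALSE, quote = FALSE)

  nd <- length(bundle$temperature)
  utils::write.csv(
    data.frame(date = substr(format_sim_hour((0:(nd - 1)) * 24L, base_year), 1, 10),
               temperature_c = sprintf("%.4f", bundle$temperature)),
    file.path(dir, "temperature.csv"), row.names = FALSE, quote = FALSE)

  utils::write.csv(
    data.frame(bin_start_deg = bundle$wind_rose$bin_start,
               bin_end_deg = bundle$wind_rose$bin_end,
               probability = sprintf("%.8g", bundle$wind_rose$probability)),
    file.path(dir, "wind_rose.csv"), row.names = FALSE, quote = FALSE)

  cfg <- list(
    substance = unclass(bundle$substance),
    application = unclass(bundle$application)[c("window_start", "window_end",
                                                "rate", "drift_reduction",
                                                "buffer_width", "application_hour")],
    period = list(warmup_years = bundle$period$warmup_years,
                  assessment_years = bundle$period$assessment_years)
  )
  writeLines(yaml::as.yaml(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

.write_json <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  writeLines(txt, path)
}

#' Load a scenario bundle from a directory
#'
#' Reads the documented scenario layout written by [write_scenario()] (or
#' assembled by hand). Validates all cross-references (topology, orchard
#' polygons, wind rose) and checks series lengths against the configured
#' simulation period. The daily temperature series is transformed to the
#' trailing 3-day mean used by the fate module when the bundle is
#' assembled.
#'
#' @param dir scenario directory
#' @return a `scenario_bundle`
#' @export
load_scenario <- function(dir) {
  need <- c("network.geojson", "orchards.geojson", "discharge.csv",
            "temperature.csv", "wind_rose.csv", "config.yaml")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("scenario directory is missing file(s): ", paste(missing, collapse = ", "))
  }
  gj <- jsonlite::fromJSON(file.path(dir, "network.geojson"),
                           simplifyVector = FALSE)
  reaches <- do.call(rbind, lapply(gj$features, function(f) {
    p <- f$properties
    for (field in c("id", "length", "bottom_width", "bank_slope", "manning_n",
                    "longitudinal_slope", "drainage_area", "drift_surface_width")) {
      if (is.null(p[[field]])) {
        stop("schema error: reach feature missing field '", field, "'")
      }
    }
    data.frame(id = p$id, length = p$length, bottom_width = p$bottom_width,
               bank_slope = p$bank_slope, manning_n = p$manning_n,
               longitudinal_slope = p$longitudinal_slope,
               strahler_order = if (is.null(p$strahler_order)) NA_integer_
                                else as.integer(p$strahler_order),
               downstream_id = if (length(p$downstream_id) != 1) NA_character_
                               else p$downstream_id,
               drainage_area = p$drainage_area,
               drift_surface_width = p$drift_surface_width,
               stringsAsFactors = FALSE)
  }))
  geom <- lapply(gj$features, function(f) {
    do.call(rbind, lapply(f$geometry$coordinates, function(c2) unlist(c2)[1:2]))
  })
  names(geom) <- reaches$id
  net <- reach_network(reaches, geometry = geom)

  oj <- jsonlite::fromJSON(file.path(dir, "orchards.geojson"),
                           simplifyVector = FALSE)
  orchards <- lapply(oj$features, function(f) {
    ring <- do.call(rbind,
                    lapply(f$geometry$coordinates[[1]], function(c2) unlist(c2)[1:2]))
    # drop duplicated closing vertex
    if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ])) {
      ring <- ring[-nrow(ring), , drop = FALSE]
    }
    list(id = f$properties$id, polygon = unname(ring),
         crop = if (is.null(f$properties$crop)) "pome_fruit" else f$properties$crop)
  })

  q <- utils::read.csv(file.path(dir, "discharge.csv"), stringsAsFactors = FALSE)
  if (!all(c("timestamp", "discharge_m3_per_s") %in% names(q))) {
    stop("schema error: discharge.csv must have columns timestamp, discharge_m3_per_s")
  }
  te <- utils::read.csv(file.path(dir, "temperature.csv"), stringsAsFactors = FALSE)
  if (!all(c("date", "temperature_c") %in% names(te))) {
    stop("schema error: temperature.csv must have columns date, temperature_c")
  }
  wr <- utils::read.csv(file.path(dir, "wind_rose.csv"), stringsAsFactors = FALSE)
  rose <- wind_rose(wr$bin_start_deg, wr$bin_end_deg, wr$probability)

  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  sub <- do.call(substance_properties, cfg$substance)
  app <- do.call(application_setup, cfg$application)
  per <- do.call(simulation_period, cfg$period)

  scenario_bundle(net, orchards, rose, sub, app,
                  discharge = q$discharge_m3_per_s * 3600,
                  temperature = te$temperature_c, period = per)
}
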