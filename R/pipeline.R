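# End-to-end orchestration: the consecutive component chain
# (application -> drift -> fate -> effects -> risk end points) mediated by
# a plain-file run store, with a provenance manifest. There is no direct
# exchange between stages other than through the store.

#' Run configuration
#'
#' @param seed master seed (mandatory; one seed spawns named per-component
#'   streams)
#' @param scenario_dir path to a scenario directory (see [load_scenario()]),
#'   or `NULL` to generate a synthetic catchment
#' @param generator named list of [generate_synthetic_catchment()] arguments
#'   (used when `scenario_dir` is `NULL`; `n_reaches` required)
#' @param output_dir run directory (created)
#' @param species species GUTS parameter blocks
#' @param curve drift curve
#' @param conc_floor reporting floor for concentrations (ug/L)
#' @param lp50_cutoff LP50 sentinel cutoff
#' @param keep_concentrations write the long-format hourly concentration
#'   CSV (can be large; default TRUE)
#' @return a `run_config`
#' @export
run_config <- function(seed, output_dir, scenario_dir = NULL,
                       generator = list(n_reaches = 100L),
                       species = illustrative_species_params(),
                       curve = drift_curve(),
                       conc_floor = 1e-6, lp50_cutoff = 1e5,
                       keep_concentrations = TRUE) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  structure(list(seed = as.integer(seed), output_dir = output_dir,
                 scenario_dir = scenario_dir, generator = generator,
                 species = species, curve = curve,
                 conc_floor = conc_floor, lp50_cutoff = lp50_cutoff,
                 keep_concentrations = keep_concentrations),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognised keys: `seed`, `output_dir`, `scenario_dir`, `generator`
#' (block of synthetic-generator arguments), `substance`, `application`,
#' `period` (forwarded to the generator), `drift_curve` (`coefficient_A`,
#' `exponent_B`, `valid_range`), `species` (per-species blocks with
#' `variant` fields), `conc_floor`, `lp50_cutoff`.
#'
#' @param path YAML file
#' @param output_dir override for the output directory
#' @param seed override for the seed
#' @return a `run_config`
#' @export
read_run_config <- function(path, output_dir = NULL, seed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  gen <- y$generator %||% list(n_reaches = 100L)
  if (!is.null(y$substance)) gen$substance <- do.call(substance_properties, y$substance)
  if (!is.null(y$application)) gen$application <- do.call(application_setup, y$application)
  if (!is.null(y$period)) gen$period <- do.call(simulation_period, y$period)
  curve <- if (!is.null(y$drift_curve)) do.call(drift_curve, y$drift_curve)
           else drift_curve()
  species <- if (!is.null(y$species)) {
    lapply(y$species, function(sp) {
      list(sd = do.call(guts_params, c(list(variant = "SD"), sp$sd)),
           it = do.call(guts_params, c(list(variant = "IT"), sp$it)))
    })
  } else illustrative_species_params()
  run_config(seed = seed %||% y$seed,
             output_dir = output_dir %||% y$output_dir %||% "aquarisk_run",
             scenario_dir = y$scenario_dir, generator = gen,
             species = species, curve = curve,
             conc_floor = y$conc_floor %||% 1e-6,
             lp50_cutoff = y$lp50_cutoff %||% 1e5,
             keep_concentrations = y$keep_concentrations %||% TRUE)
}

#' Run the full simulation chain
#'
#' Executes the components in consecutive order -- scenario, drift inputs,
#' fate, effects, risk end points -- writing every stage product to the run
#' directory: `scenario/` (the scenario serialization),
#' `drift_deposition.csv`, `concentrations.csv` (optional),
#' `mass_ledger.json`, `pec_max.csv`, `lp50.csv`, `risk_summary.json`,
#' `category_map.csv` and `manifest.json` (seed, configuration digest,
#' stage timings). Identical configuration and seed give identical
#' outputs.
#'
#' @param config a `run_config`
#' @return list with the in-memory stage products (`bundle`, `drift`,
#'   `field`, `ledger`, `lp50`, `pec`, `summary`), invisibly
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - s, 3)
    message(sprintf("[aquarisk] stage %-10s %8.2f s", name, timings[[name]]))
    out
  }

  bundle <- stage("scenario", {
    b <- if (!is.null(config$scenario_dir)) {
      load_scenario(config$scenario_dir)
    } else {
      do.call(generate_synthetic_catchment,
              c(list(seed = config$seed), config$generator))
    }
    write_scenario(b, file.path(config$output_dir, "scenario"))
    b
  })

  drift <- stage("drift", {
    d <- generate_drift_series(bundle, config$seed, curve = config$curve)
    write_drift_csv(d, file.path(config$output_dir, "drift_deposition.csv"))
    d
  })

  fate <- stage("fate", {
    f <- route_network(bundle, drift)
    .write_json(unclass(f$ledger),
                file.path(config$output_dir, "mass_ledger.json"))
    if (config$keep_concentrations) {
      write_concentration_csv(f$field,
                              file.path(config$output_dir, "concentrations.csv"),
                              floor_conc = config$conc_floor)
    }
    f
  })

  lp <- stage("effects", {
    tab <- run_effects(fate$field, species = config$species,
                       cutoff = config$lp50_cutoff)
    write_lp50_csv(tab, file.path(config$output_dir, "lp50.csv"))
    tab
  })

  summary <- stage("risk", {
    pec <- pec_max(fate$field, floor_conc = config$conc_floor)
    utils::write.csv(pec, file.path(config$output_dir, "pec_max.csv"),
                     row.names = FALSE, quote = FALSE)
    sp1 <- names(config$species)[1]
    it1 <- lp[lp$species == sp1 & lp$variant == "IT", ]
    cmap <- categorize_lp50(it1, cutoff = config$lp50_cutoff)
    utils::write.csv(cmap, file.path(config$output_dir, "category_map.csv"),
                     row.names = FALSE, quote = FALSE)
    rm_exp <- build_rank_matrix(pec, "exposure")
    never_exposed <- mean(apply(rm_exp$values, 2, max) < config$conc_floor)
    sm <- list(
      pec_max_overall_p90 = overall_percentile(pec, 90),
      lp50_overall_p10 = lapply(split(lp, paste(lp$species, lp$variant)),
                                function(t2) {
                                  cls <- class(t2); class(t2) <- c("lp50_table", "data.frame")
                                  overall_percentile(t2, 10)
                                }),
      fraction_reaches_never_exposed = never_exposed,
      category_counts = as.list(table(cmap$category))
    )
    .write_json(sm, file.path(config$output_dir, "risk_summary.json"))
    list(pec = pec, summary = sm, category_map = cmap)
  })

  manifest <- list(
    package = "aquarisk",
    version = as.character(utils::packageVersion("aquarisk")),
    seed = config$seed,
    n_reaches = nrow(bundle$network$reaches),
    warmup_years = bundle$period$warmup_years,
    assessment_years = bundle$period$assessment_years,
    ledger_closure_error = ledger_closure_error(fate$ledger),
    stage_timings_s = timings,
    total_s = round(proc.time()[["elapsed"]] - t0, 3)
  )
  .write_json(manifest, file.path(config$output_dir, "manifest.json"))

  invisible(list(bundle = bundle, drift = drift, field = fate$field,
                 ledger = fate$ledger, lp50 = lp, pec = summary$pec,
                 summary = summary$summary, category_map = summary$category_map,
                 manifest = manifest))
}
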