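# End-to-end orchestration: configuration, per-stage runners over persisted
# intermediates, and the full pipeline.

REFERENCE_PARAMS <- c("buffer_radius_miles", "area_fraction_threshold",
                      "min_services", "procedure_code", "per_capita",
                      "tertile_breaks", "distinct_providers",
                      "include_zero_density", "percentile_method",
                      "density_pool")

#' Pipeline configuration
#'
#' Defaults are the reference analysis parameters: a 30-mile buffer, the
#' strict 51% area served rule, the G0297 screening code with the 11-service
#' suppression floor, densities per 1000 beneficiaries, and tertile breaks
#' at the 34th and 67th percentiles. Any departure is labelled
#' "deviates from reference configuration" in the run report.
#'
#' @param seed Integer seed (required for simulation; echoed in reports).
#' @param indir Directory holding the input bundle.
#' @param outdir Directory for stage outputs; default `indir`.
#' @param buffer_radius_miles Buffer radius; default 30.
#' @param area_fraction_threshold Served-rule threshold (strict); default 0.51.
#' @param min_services Provider suppression floor; default 11.
#' @param procedure_code Screening procedure code; default `"G0297"`.
#' @param per_capita Density denominator scale; default 1000.
#' @param tertile_breaks Percentile breaks; default `c(34, 67)`.
#' @param projection `"albers_auto"` (fit an equal-area conic to the tract
#'   layer) is the only built-in; an `albers_proj` object may be supplied.
#' @param buffer_segments Buffer vertices per quarter circle; default 64.
#' @param distinct_providers Alternative county aggregation counting each
#'   provider once per county; default FALSE (sum of tract counts).
#' @param include_zero_density Include no-service counties as zeros in
#'   distribution summaries; default TRUE.
#' @param percentile_method `"midrank"` or `"ecdf"`.
#' @param density_pool `"served"` or `"all"` (see [classify_bivariate()]).
#' @param render_maps Render optional PNG maps; default FALSE.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = NULL, indir = ".", outdir = indir,
                       buffer_radius_miles = 30,
                       area_fraction_threshold = 0.51,
                       min_services = 11L,
                       procedure_code = "G0297",
                       per_capita = 1000,
                       tertile_breaks = c(34, 67),
                       projection = "albers_auto",
                       buffer_segments = 64L,
                       distinct_providers = FALSE,
                       include_zero_density = TRUE,
                       percentile_method = "midrank",
                       density_pool = "served",
                       render_maps = FALSE) {
  stopifnot(buffer_radius_miles > 0,
            area_fraction_threshold >= 0, area_fraction_threshold <= 1,
            min_services >= 0, per_capita > 0,
            length(tertile_breaks) == 2, tertile_breaks[1] < tertile_breaks[2])
  structure(list(
    seed = seed, indir = indir, outdir = outdir,
    buffer_radius_miles = buffer_radius_miles,
    area_fraction_threshold = area_fraction_threshold,
    min_services = as.integer(min_services),
    procedure_code = procedure_code,
    per_capita = per_capita,
    tertile_breaks = tertile_breaks,
    projection = projection,
    buffer_segments = as.integer(buffer_segments),
    distinct_providers = distinct_providers,
    include_zero_density = include_zero_density,
    percentile_method = percentile_method,
    density_pool = density_pool,
    render_maps = render_maps
  ), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file of `run_config()` arguments.
#' @param ... Overrides.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Generate the synthetic input bundle for a configured run
#'
#' @param config A [run_config()]; its `seed` is required.
#' @param scenario Optional [synthetic_scenario()]; default built from the
#'   config seed with the reference scenario parameters.
#' @return Invisibly, the [simulate_bundle()] result.
#' @export
run_simulate <- function(config, scenario = NULL) {
  if (is.null(config$seed)) stop("run_simulate requires a seed in the config")
  if (is.null(scenario)) scenario <- synthetic_scenario(seed = config$seed)
  log_stage("simulate", "seed=%d nx=%d ny=%d counties=%dx%d providers=%d",
            scenario$seed, scenario$nx, scenario$ny,
            ceiling(scenario$nx / scenario$county_block),
            ceiling(scenario$ny / scenario$county_block), scenario$n_providers)
  simulate_bundle(scenario, config$indir)
}

read_table <- function(path, ...) {
  if (!file.exists(path)) stop("required input not found: ", path)
  readr::read_csv(path, col_types = readr::cols(...), progress = FALSE,
                  show_col_types = FALSE)
}

#' Run the provider ingest stage
#'
#' Reads `providers.csv` from the input directory; writes
#' `providers_clean.csv` and `provider_summary.json` to the output
#' directory.
#'
#' @param config A [run_config()].
#' @return The cleaned provider records, invisibly.
#' @export
stage_ingest <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  rows <- load_provider_table(file.path(config$indir, "providers.csv"))
  n_in <- nrow(rows)
  matching <- sum(rows$hcpcs_code == config$procedure_code)
  clean <- filter_and_aggregate(rows, code = config$procedure_code,
                                min_services = config$min_services)
  log_stage("provider_ingest",
            "rows in=%d, matching code %s=%d, providers retained=%d (floor %d)",
            n_in, config$procedure_code, matching, nrow(clean), config$min_services)
  readr::write_csv(clean, file.path(config$outdir, "providers_clean.csv"))
  summ <- provider_summary(clean)
  jsonlite::write_json(summ, file.path(config$outdir, "provider_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(clean)
}

#' Run the coverage stage
#'
#' Reads `providers_clean.csv` plus the tract and county GeoJSON layers;
#' projects everything to planar miles; writes `coverage.csv`,
#' `tract_counts.csv`, `county_counts.csv`.
#'
#' @param config A [run_config()].
#' @return The [count_providers()] result, invisibly.
#' @export
stage_coverage <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  clean <- read_table(file.path(config$outdir, "providers_clean.csv"),
                      provider_id = readr::col_character())
  tracts <- read_geojson(file.path(config$indir, "tracts.geojson"))
  proj <- if (inherits(config$projection, "albers_proj")) config$projection
          else fit_projection(tracts)
  tracts_planar <- project_layer(tracts, proj)
  providers <- clean
  if (nrow(providers) > 0) {
    xy <- project_points(proj, cbind(providers$lon, providers$lat))
    providers$x <- xy[, 1]; providers$y <- xy[, 2]
  } else {
    providers$x <- numeric(0); providers$y <- numeric(0)
  }
  res <- count_providers(providers, tracts_planar,
                         radius_miles = config$buffer_radius_miles,
                         threshold = config$area_fraction_threshold,
                         segments = config$buffer_segments,
                         distinct_providers = config$distinct_providers)
  log_stage("coverage_model",
            "providers=%d tracts=%d served pairs=%d",
            nrow(providers), n_units(tracts), sum(res$coverage$served))
  readr::write_csv(res$coverage, file.path(config$outdir, "coverage.csv"))
  readr::write_csv(res$tract_counts, file.path(config$outdir, "tract_counts.csv"))
  readr::write_csv(res$county_counts, file.path(config$outdir, "county_counts.csv"))
  invisible(res)
}

#' Run the density stage
#'
#' Reads the persisted tract/county counts and population tables; writes
#' `density_tract.csv`, `density_county.csv`, `summary.json`, and
#' `rank_tables.csv`.
#'
#' @param config A [run_config()].
#' @return List of tract and county density records, invisibly.
#' @export
stage_density <- function(config) {
  tract_counts <- read_table(file.path(config$outdir, "tract_counts.csv"),
                             tract_id = readr::col_character(),
                             county_id = readr::col_character())
  county_counts <- read_table(file.path(config$outdir, "county_counts.csv"),
                              county_id = readr::col_character())
  tract_pop <- read_table(file.path(config$indir, "tract_pop.csv"),
                          tract_id = readr::col_character())
  county_pop <- read_table(file.path(config$indir, "county_pop.csv"),
                           county_id = readr::col_character())
  smoking <- read_table(file.path(config$indir, "smoking.csv"),
                        county_id = readr::col_character())

  d_tract <- compute_density(tract_counts[, c("tract_id", "provider_count")],
                             tract_pop, per = config$per_capita)
  d_county <- compute_density(county_counts, county_pop, per = config$per_capita)
  log_stage("density_metrics",
            "tracts excluded (zero population)=%d; counties without service=%d/%d",
            sum(d_tract$excluded), sum(!d_county$has_service), nrow(d_county))

  readr::write_csv(d_tract, file.path(config$outdir, "density_tract.csv"))
  readr::write_csv(d_county, file.path(config$outdir, "density_county.csv"))

  summ <- list(
    tract_uncovered = uncovered_fraction(d_tract),
    county_uncovered = uncovered_fraction(d_county),
    county_density_all = summarize_density(d_county, include_zero_density = TRUE),
    county_density_served = summarize_density(d_county, include_zero_density = FALSE),
    county_density = summarize_density(d_county,
                                       include_zero_density = config$include_zero_density),
    smoking = list(median = stats::median(smoking$smoking_prev_pct),
                   q1 = unname(stats::quantile(smoking$smoking_prev_pct, 0.25, type = 7)),
                   q3 = unname(stats::quantile(smoking$smoking_prev_pct, 0.75, type = 7)))
  )
  jsonlite::write_json(summ, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  tables <- list(
    density_top = rank_table(d_county, smoking, by = "density", direction = "top"),
    density_bottom = rank_table(d_county, smoking, by = "density", direction = "bottom"),
    smoking_top = rank_table(d_county, smoking, by = "smoking", direction = "top"),
    smoking_bottom = rank_table(d_county, smoking, by = "smoking", direction = "bottom")
  )
  ranks <- dplyr::bind_rows(lapply(names(tables), function(nm) {
    dplyr::mutate(tables[[nm]], table = nm, .before = 1)
  }))
  readr::write_csv(ranks, file.path(config$outdir, "rank_tables.csv"))
  invisible(list(tract = d_tract, county = d_county, summary = summ))
}

#' Run the bivariate classification stage
#'
#' Reads `density_county.csv` and the smoking table; writes
#' `bivariate_classes.csv` and `crosstab.csv`.
#'
#' @param config A [run_config()].
#' @return The classes tibble, invisibly.
#' @export
stage_classify <- function(config) {
  d_county <- read_table(file.path(config$outdir, "density_county.csv"),
                         county_id = readr::col_character())
  smoking <- read_table(file.path(config$indir, "smoking.csv"),
                        county_id = readr::col_character())
  classes <- classify_bivariate(d_county, smoking,
                                breaks = config$tertile_breaks,
                                percentile_method = config$percentile_method,
                                density_pool = config$density_pool)
  log_stage("bivariate_classify", "classified=%d no_service=%d",
            nrow(classes), sum(classes$code == "no_service"))
  readr::write_csv(classes, file.path(config$outdir, "bivariate_classes.csv"))
  readr::write_csv(crosstab(classes), file.path(config$outdir, "crosstab.csv"))
  invisible(classes)
}

#' Run the report stage
#'
#' Reads the persisted county layer, densities, and classes; writes
#' `map_layer.geojson`, `scatter.csv`, `report.md`, and (optionally)
#' rendered PNG maps.
#'
#' @param config A [run_config()].
#' @return Path of the report, invisibly.
#' @export
stage_report <- function(config) {
  counties <- read_geojson(file.path(config$indir, "counties.geojson"))
  d_county <- read_table(file.path(config$outdir, "density_county.csv"),
                         county_id = readr::col_character())
  classes <- read_table(file.path(config$outdir, "bivariate_classes.csv"),
                        county_id = readr::col_character())
  layer <- export_map_layer(counties, d_county, classes,
                            file.path(config$outdir, "map_layer.geojson"))
  export_scatter(classes, file.path(config$outdir, "scatter.csv"))
  if (isTRUE(config$render_maps)) {
    render_maps(layer, file.path(config$outdir, "map"))
  }
  inputs <- file.path(config$indir,
                      c("providers.csv", "tracts.geojson", "counties.geojson",
                        "tract_pop.csv", "county_pop.csv", "smoking.csv"))
  inputs <- inputs[file.exists(inputs)]
  digests <- tools::md5sum(inputs)
  names(digests) <- basename(inputs)
  summ <- jsonlite::read_json(file.path(config$outdir, "summary.json"))
  psum <- jsonlite::read_json(file.path(config$outdir, "provider_summary.json"))
  stats <- list(
    providers = psum$n_providers,
    total_services = psum$total_services,
    mean_services = psum$mean,
    median_services = psum$median,
    tracts_without_provider = sprintf("%d/%d (%.1f%%)",
      summ$tract_uncovered$n_without, summ$tract_uncovered$n_total,
      100 * summ$tract_uncovered$proportion),
    counties_without_service = sprintf("%d/%d (%.1f%%)",
      summ$county_uncovered$n_without, summ$county_uncovered$n_total,
      100 * summ$county_uncovered$proportion),
    county_density_median = summ$county_density_all$median,
    served_county_density_median = summ$county_density_served$median,
    smoking_median_pct = summ$smoking$median
  )
  path <- write_run_report(config, digests, stats,
                           file.path(config$outdir, "report.md"))
  log_stage("report_outputs", "report written to %s", basename(path))
  invisible(path)
}

PIPELINE_STAGES <- list(
  ingest = list(label = "provider_ingest", fn = stage_ingest),
  coverage = list(label = "coverage_model", fn = stage_coverage),
  density = list(label = "density_metrics", fn = stage_density),
  classify = list(label = "bivariate_classify", fn = stage_classify),
  report = list(label = "report_outputs", fn = stage_report)
)

#' Run the full pipeline
#'
#' Executes the stages in order (ingest, coverage, density, classify,
#' report). Each stage reads its inputs from persisted files, so any suffix
#' of stages can be re-run from intermediates. A failure raises an error
#' prefixed with the failing stage's name.
#'
#' @param config A [run_config()].
#' @param stages Which stages to run, in order; default all.
#' @return Invisibly, `config`.
#' @export
run_pipeline <- function(config, stages = names(PIPELINE_STAGES)) {
  stopifnot(all(stages %in% names(PIPELINE_STAGES)))
  for (st in stages) {
    entry <- PIPELINE_STAGES[[st]]
    tryCatch(entry$fn(config), error = function(e) {
      stop(sprintf("%s: %s", entry$label, conditionMessage(e)), call. = FALSE)
    })
  }
  invisible(config)
}
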