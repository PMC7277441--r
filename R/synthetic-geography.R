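# Seeded synthetic-geography generator.
#
# Emulates the structural properties of the national inputs the accessibility
# analysis consumes: a tract tessellation nested in counties, right-skewed
# Medicare populations with some zero-population tracts, a spatially
# autocorrelated county smoking surface, and a provider utilization table
# with the public-use file's suppression of low-volume providers. Each
# sub-generator draws from its own RNG stream derived from the scenario seed,
# so adding a generator never perturbs the others.

#' Define a synthetic scenario
#'
#' Default values are the reference study conditions used throughout the
#' package: a 400 x 400 mile region of 10-mile tracts grouped 4 x 4 into 100
#' counties, 60 providers placed with a moderate negative spatial correlation
#' to smoking (the mismatch pattern the method is designed to expose), a
#' county smoking surface with mean 17.5% and SD 3.4%, and provider service
#' counts that are lognormal with median 19, truncated below 11.
#'
#' @param seed Integer seed; drives every random draw through per-generator
#'   streams.
#' @param nx,ny Tract grid dimensions (columns, rows); both >= 1.
#' @param tract_side_miles Side length of the (unjittered) square tracts.
#' @param county_block Tracts per county side; counties are contiguous
#'   `county_block` x `county_block` blocks (edge counties may be smaller).
#' @param n_providers Number of retained (post-suppression) providers.
#' @param provider_clustering Real in \[-1, 1\]: sign and strength of the
#'   spatial correlation between provider placement intensity and the smoking
#'   surface. Negative values emulate the observed mismatch.
#' @param zero_pop_tract_fraction Fraction of tracts with exactly zero
#'   Medicare population, in \[0, 1).
#' @param smoking_mean_pct,smoking_sd_pct Target mean and SD of the county
#'   smoking prevalence surface, in percent.
#' @param jitter Vertex jitter as a fraction of the tract side (interior grid
#'   nodes only, so the tessellation is preserved). 0 gives exact rectangles.
#' @param pop_median,pop_sdlog Median and log-SD of the lognormal tract
#'   Medicare population distribution.
#' @param ffs_fraction County fee-for-service population as a fraction of the
#'   county's summed tract Medicare population.
#' @param smoothing_bandwidth_miles Gaussian kernel bandwidth used to smooth
#'   the smoking noise over county centroids; default 1.5 county sides.
#' @param clustering_strength Log-weight multiplier scaling how strongly
#'   `provider_clustering` concentrates providers; at the default 3 a full
#'   `provider_clustering = -1` is a strong effect (county weights spanning
#'   several orders of magnitude).
#' @param services_median,services_sdlog Median and log-SD of the lognormal
#'   per-provider service-count distribution (truncated below
#'   `min_services`).
#' @param min_services Suppression floor re-applied by ingest; retained
#'   synthetic providers always have at least this many services.
#' @param n_suppressed_rows Sub-threshold rows (counts 1-10) added to the
#'   provider table to exercise the ingest filter.
#' @param n_decoy_rows Rows with non-target procedure codes added to the
#'   provider table.
#' @param origin_lon,origin_lat WGS84 anchor of the region center.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(seed,
                               nx = 40L, ny = 40L,
                               tract_side_miles = 10,
                               county_block = 4L,
                               n_providers = 60L,
                               provider_clustering = -0.6,
                               zero_pop_tract_fraction = 0.008,
                               smoking_mean_pct = 17.5,
                               smoking_sd_pct = 3.4,
                               jitter = 0.3,
                               pop_median = 210,
                               pop_sdlog = 1.0,
                               ffs_fraction = 0.7,
                               smoothing_bandwidth_miles = NULL,
                               clustering_strength = 3,
                               services_median = 19,
                               services_sdlog = 0.84,
                               min_services = 11L,
                               n_suppressed_rows = 8L,
                               n_decoy_rows = 8L,
                               origin_lon = -96,
                               origin_lat = 38.5) {
  if (missing(seed) || is.null(seed) || is.na(seed)) stop("scenario requires a seed")
  if (nx < 1 || ny < 1) stop("nx and ny must be >= 1, got nx=", nx, " ny=", ny)
  if (tract_side_miles <= 0) stop("tract_side_miles must be positive")
  if (county_block < 1) stop("county_block must be >= 1")
  if (n_providers < 0) stop("n_providers must be >= 0")
  if (abs(provider_clustering) > 1) stop("provider_clustering must lie in [-1, 1]")
  if (zero_pop_tract_fraction < 0 || zero_pop_tract_fraction >= 1) {
    stop("zero_pop_tract_fraction must lie in [0, 1)")
  }
  if (is.null(smoothing_bandwidth_miles)) {
    smoothing_bandwidth_miles <- 1.5 * county_block * tract_side_miles
  }
  structure(list(
    seed = as.integer(seed), nx = as.integer(nx), ny = as.integer(ny),
    tract_side_miles = tract_side_miles, county_block = as.integer(county_block),
    n_providers = as.integer(n_providers),
    provider_clustering = provider_clustering,
    zero_pop_tract_fraction = zero_pop_tract_fraction,
    smoking_mean_pct = smoking_mean_pct, smoking_sd_pct = smoking_sd_pct,
    jitter = jitter, pop_median = pop_median, pop_sdlog = pop_sdlog,
    ffs_fraction = ffs_fraction,
    smoothing_bandwidth_miles = smoothing_bandwidth_miles,
    clustering_strength = clustering_strength,
    services_median = services_median, services_sdlog = services_sdlog,
    min_services = as.integer(min_services),
    n_suppressed_rows = as.integer(n_suppressed_rows),
    n_decoy_rows = as.integer(n_decoy_rows),
    origin_lon = origin_lon, origin_lat = origin_lat
  ), class = "synthetic_scenario")
}

# Per-generator RNG stream seed; stays below 2^31.
stream_seed <- function(seed, name) {
  off <- c(grid = 1L, populations = 2L, smoking = 3L, providers = 4L)
  (as.integer(seed) %% 32749L) * 32771L + 7919L * off[[name]]
}

#' Build the tract and county tessellation for a scenario
#'
#' Tracts are (optionally jittered) quadrilaterals on an `nx` x `ny` grid in
#' a planar Albers system anchored at the scenario origin; interior grid
#' nodes are jittered jointly so neighboring tracts share edges exactly and
#' the region is partitioned without gaps or overlaps. Counties are
#' contiguous `county_block` x `county_block` blocks of tracts dissolved
#' along their shared outline.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list with `tracts` and `counties` (WGS84 `geo_layer`s),
#'   `tracts_planar` and `counties_planar` (the same layers in planar miles),
#'   and the `projection` linking the two.
#' @export
make_grid_tracts <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  nx <- scenario$nx; ny <- scenario$ny; side <- scenario$tract_side_miles
  W <- nx * side; H <- ny * side
  lat_span <- max(H / 69, 0.5)
  proj <- albers_projection(
    lon0 = scenario$origin_lon, lat0 = scenario$origin_lat,
    lat1 = scenario$origin_lat - lat_span / 3,
    lat2 = scenario$origin_lat + lat_span / 3
  )

  # node grid, centered on the planar origin
  gx <- matrix(rep(seq(0, nx) * side - W / 2, ny + 1), nx + 1, ny + 1)
  gy <- matrix(rep(seq(0, ny) * side - H / 2, each = nx + 1), nx + 1, ny + 1)
  if (scenario$jitter > 0 && nx > 1 && ny > 1) {
    set.seed(stream_seed(scenario$seed, "grid"))
    amp <- scenario$jitter * side / 2
    ii <- 2:nx; jj <- 2:ny
    gx[ii, jj] <- gx[ii, jj] + matrix(stats::runif((nx - 1) * (ny - 1), -amp, amp), nx - 1)
    gy[ii, jj] <- gy[ii, jj] + matrix(stats::runif((nx - 1) * (ny - 1), -amp, amp), nx - 1)
  }

  cb <- scenario$county_block
  ncx <- ceiling(nx / cb); ncy <- ceiling(ny / cb)
  tract_ids <- character(nx * ny)
  county_of <- character(nx * ny)
  tract_geoms <- vector("list", nx * ny)
  k <- 0L
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      k <- k + 1L
      tract_ids[k] <- sprintf("T%05d", k)
      county_of[k] <- sprintf("C%03d",
                              (ceiling(j / cb) - 1L) * ncx + ceiling(i / cb))
      tract_geoms[[k]] <- cbind(
        c(gx[i, j], gx[i + 1, j], gx[i + 1, j + 1], gx[i, j + 1]),
        c(gy[i, j], gy[i + 1, j], gy[i + 1, j + 1], gy[i, j + 1])
      )
    }
  }
  names(tract_geoms) <- tract_ids
  tracts_planar <- geo_layer(
    tract_geoms,
    tibble::tibble(tract_id = tract_ids, county_id = county_of),
    crs = proj
  )

  # dissolve counties: trace the outline of each block through the node grid
  county_ids <- sort(unique(county_of))
  county_geoms <- lapply(county_ids, function(cid) {
    idx <- as.integer(sub("C", "", cid)) - 1L
    cx <- idx %% ncx; cy <- idx %/% ncx
    i0 <- cx * cb + 1L; i1 <- min((cx + 1L) * cb, nx)
    j0 <- cy * cb + 1L; j1 <- min((cy + 1L) * cb, ny)
    bottom <- cbind(gx[i0:(i1 + 1L), j0], gy[i0:(i1 + 1L), j0])
    right  <- cbind(gx[i1 + 1L, j0:(j1 + 1L)], gy[i1 + 1L, j0:(j1 + 1L)])
    top    <- cbind(gx[(i1 + 1L):i0, j1 + 1L], gy[(i1 + 1L):i0, j1 + 1L])
    left   <- cbind(gx[i0, (j1 + 1L):j0], gy[i0, (j1 + 1L):j0])
    ring <- rbind(bottom, right[-1, , drop = FALSE],
                  top[-1, , drop = FALSE], left[-1, , drop = FALSE])
    ring[-nrow(ring), , drop = FALSE]
  })
  names(county_geoms) <- county_ids
  counties_planar <- geo_layer(
    county_geoms, tibble::tibble(county_id = county_ids), crs = proj
  )

  list(
    tracts = unproject_layer(tracts_planar),
    counties = unproject_layer(counties_planar),
    tracts_planar = tracts_planar,
    counties_planar = counties_planar,
    projection = proj
  )
}

#' Sample tract Medicare populations and county FFS populations
#'
#' Tract populations are lognormal (right-skewed, matching the heavy upper
#' tail of small-area Medicare counts) with an exact number
#' `round(zero_pop_tract_fraction * n)` of tracts set to zero population.
#' County fee-for-service population is a fixed fraction of the county's
#' summed tract population, rounded.
#'
#' @param scenario A [synthetic_scenario()].
#' @param tracts Tract `geo_layer` from [make_grid_tracts()] (needs the
#'   `county_id` attribute).
#' @return List with `tract_pop` (`tract_id`, `medicare_pop`) and
#'   `county_pop` (`county_id`, `ffs_pop`) tibbles.
#' @export
sample_populations <- function(scenario, tracts) {
  stopifnot(inherits(tracts, "geo_layer"), "county_id" %in% names(tracts$data))
  set.seed(stream_seed(scenario$seed, "populations"))
  n <- n_units(tracts)
  pop <- pmax(1, round(stats::rlnorm(n, log(scenario$pop_median), scenario$pop_sdlog)))
  n_zero <- round(scenario$zero_pop_tract_fraction * n)
  if (n_zero > 0) pop[sample.int(n, n_zero)] <- 0L
  tract_pop <- tibble::tibble(tract_id = tracts$data$tract_id, medicare_pop = as.integer(pop))
  county_pop <- tract_pop |>
    dplyr::mutate(county_id = tracts$data$county_id) |>
    dplyr::group_by(.data$county_id) |>
    dplyr::summarise(ffs_pop = as.integer(round(scenario$ffs_fraction * sum(.data$medicare_pop))),
                     .groups = "drop") |>
    dplyr::arrange(.data$county_id)
  list(tract_pop = tract_pop, county_pop = county_pop)
}

#' Sample a spatially autocorrelated county smoking surface
#'
#' Independent Gaussian noise at county centroids is smoothed with a
#' Gaussian kernel over centroid distances, then affinely rescaled to the
#' target mean/SD and clipped to (0.1, 99.9) percent.
#'
#' @param scenario A [synthetic_scenario()].
#' @param counties_planar County `geo_layer` in planar miles.
#' @return Tibble (`county_id`, `smoking_prev_pct`).
#' @export
sample_smoking_surface <- function(scenario, counties_planar) {
  stopifnot(inherits(counties_planar, "geo_layer"))
  set.seed(stream_seed(scenario$seed, "smoking"))
  n <- n_units(counties_planar)
  z <- stats::rnorm(n)
  cent <- t(vapply(counties_planar$geometry, polygon_centroid, numeric(2)))
  h <- scenario$smoothing_bandwidth_miles
  if (n > 1 && h > 0) {
    d2 <- as.matrix(stats::dist(cent))^2
    w <- exp(-d2 / (2 * h^2))
    z <- as.vector(w %*% z) / rowSums(w)
  }
  s <- if (n > 1 && isTRUE(stats::sd(z) > 0) && scenario$smoking_sd_pct > 0) {
    scenario$smoking_mean_pct + scenario$smoking_sd_pct * (z - mean(z)) / stats::sd(z)
  } else {
    rep(scenario$smoking_mean_pct, n)
  }
  tibble::tibble(
    county_id = counties_planar$data$county_id,
    smoking_prev_pct = pmin(99.9, pmax(0.1, s))
  )
}

# service counts: lognormal truncated below the suppression floor
draw_service_counts <- function(n, median, sdlog, floor_at) {
  x <- round(stats::rlnorm(n, log(median), sdlog))
  while (any(x < floor_at)) {
    i <- which(x < floor_at)
    x[i] <- round(stats::rlnorm(length(i), log(median), sdlog))
  }
  as.integer(x)
}

#' Sample a provider utilization table
#'
#' Providers are assigned to counties with weights
#' `exp(clustering_strength * provider_clustering * z)`, where `z` is the
#' standardized smoking surface, so the sign of the county-level correlation
#' between provider counts and smoking follows `provider_clustering`. Each
#' provider is placed uniformly inside a tract of its county (tracts chosen
#' with probability proportional to area). The emitted table contains the
#' retained rows (target procedure code, counts >= `min_services`), decoy
#' rows with non-target codes at the same provider coordinates, and
#' sub-threshold rows (counts 1-10) that the ingest filter must drop.
#'
#' @param scenario A [synthetic_scenario()].
#' @param geography Result of [make_grid_tracts()].
#' @param smoking County smoking tibble from [sample_smoking_surface()].
#' @param code Target procedure code; default `"G0297"`.
#' @return List with `providers` (the raw utilization tibble:
#'   `npi`, `hcpcs_code`, `line_srvc_cnt`, `longitude`, `latitude`),
#'   `assigned_county` (`county_id`, `n_assigned` for every county), and
#'   `truth` (`county_id`, `planted_label`).
#' @export
sample_providers <- function(scenario, geography, smoking, code = "G0297") {
  set.seed(stream_seed(scenario$seed, "providers"))
  counties <- geography$counties_planar
  tracts <- geography$tracts_planar
  proj <- geography$projection
  n_c <- n_units(counties)
  np <- scenario$n_providers

  z <- smoking$smoking_prev_pct
  z <- if (n_c > 1 && isTRUE(stats::sd(z) > 0)) (z - mean(z)) / stats::sd(z) else rep(0, n_c)
  w <- exp(scenario$clustering_strength * scenario$provider_clustering * z)
  w <- w / sum(w)

  tract_area <- layer_areas(tracts)
  county_of_tract <- tracts$data$county_id

  place_in_county <- function(cid) {
    members <- which(county_of_tract == cid)
    t_idx <- members[sample.int(length(members), 1L,
                                prob = tract_area[members])]
    poly <- tracts$geometry[[t_idx]]
    bb <- bbox_of(poly)
    repeat {
      p <- c(stats::runif(1, bb["xmin"], bb["xmax"]),
             stats::runif(1, bb["ymin"], bb["ymax"]))
      if (points_in_polygon(matrix(p, 1), poly)) return(p)
    }
  }

  assigned <- if (np > 0) sample.int(n_c, np, replace = TRUE, prob = w) else integer(0)
  rows <- list()
  if (np > 0) {
    pts <- t(vapply(counties$data$county_id[assigned], place_in_county, numeric(2)))
    lonlat <- unproject_points(proj, pts)
    counts <- draw_service_counts(np, scenario$services_median,
                                  scenario$services_sdlog, scenario$min_services)
    npis <- sprintf("%010d", 1000000000L + seq_len(np))
    rows$retained <- tibble::tibble(
      npi = npis, hcpcs_code = code, line_srvc_cnt = counts,
      longitude = lonlat[, 1], latitude = lonlat[, 2]
    )
    nd <- min(scenario$n_decoy_rows, np)
    if (nd > 0) {
      decoy_codes <- rep(c("71250", "G0296"), length.out = nd)
      rows$decoy <- tibble::tibble(
        npi = npis[seq_len(nd)], hcpcs_code = decoy_codes,
        line_srvc_cnt = sample(11:60, nd, replace = TRUE),
        longitude = lonlat[seq_len(nd), 1], latitude = lonlat[seq_len(nd), 2]
      )
    }
  }
  ns <- scenario$n_suppressed_rows
  if (ns > 0) {
    sup_counties <- sample.int(n_c, ns, replace = TRUE)
    sup_pts <- t(vapply(counties$data$county_id[sup_counties], place_in_county, numeric(2)))
    sup_lonlat <- unproject_points(proj, sup_pts)
    rows$suppressed <- tibble::tibble(
      npi = sprintf("%010d", 1900000000L + seq_len(ns)),
      hcpcs_code = code,
      line_srvc_cnt = sample(1:10, ns, replace = TRUE),
      longitude = sup_lonlat[, 1], latitude = sup_lonlat[, 2]
    )
  }
  providers <- dplyr::bind_rows(rows)
  if (nrow(providers) == 0) {
    providers <- tibble::tibble(npi = character(), hcpcs_code = character(),
                                line_srvc_cnt = integer(),
                                longitude = numeric(), latitude = numeric())
  }

  n_assigned <- tabulate(assigned, nbins = n_c)
  smoking_pct <- percentile_rank(smoking$smoking_prev_pct, smoking$smoking_prev_pct)
  planted <- dplyr::case_when(
    smoking_pct >= 67 & n_assigned == 0 ~ "high-smoking/low-access",
    smoking_pct < 34 & n_assigned > 0 ~ "low-smoking/high-access",
    .default = "background"
  )
  list(
    providers = providers,
    assigned_county = tibble::tibble(county_id = counties$data$county_id,
                                     n_assigned = n_assigned),
    truth = tibble::tibble(county_id = counties$data$county_id,
                           planted_label = planted)
  )
}

#' Generate and write a full synthetic input bundle
#'
#' Writes `tracts.geojson`, `counties.geojson`, `providers.csv`,
#' `tract_pop.csv`, `county_pop.csv`, `smoking.csv`, and `truth.csv` to
#' `outdir`. Identical scenarios produce byte-identical bundles.
#'
#' @param scenario A [synthetic_scenario()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, a list with the in-memory objects and file paths.
#' @export
simulate_bundle <- function(scenario, outdir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  geo <- make_grid_tracts(scenario)
  pops <- sample_populations(scenario, geo$tracts)
  smoking <- sample_smoking_surface(scenario, geo$counties_planar)
  prov <- sample_providers(scenario, geo, smoking)

  paths <- list(
    tracts = file.path(outdir, "tracts.geojson"),
    counties = file.path(outdir, "counties.geojson"),
    providers = file.path(outdir, "providers.csv"),
    tract_pop = file.path(outdir, "tract_pop.csv"),
    county_pop = file.path(outdir, "county_pop.csv"),
    smoking = file.path(outdir, "smoking.csv"),
    truth = file.path(outdir, "truth.csv")
  )
  write_geojson(geo$tracts, paths$tracts)
  write_geojson(geo$counties, paths$counties)
  readr::write_csv(prov$providers, paths$providers)
  readr::write_csv(pops$tract_pop, paths$tract_pop)
  readr::write_csv(pops$county_pop, paths$county_pop)
  readr::write_csv(smoking, paths$smoking)
  readr::write_csv(prov$truth, paths$truth)
  invisible(list(scenario = scenario, geography = geo, populations = pops,
                 smoking = smoking, providers = prov, paths = paths))
}
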