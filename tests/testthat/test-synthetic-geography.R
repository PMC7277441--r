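test_that("grid tessellation has exact block arithmetic and partition areas", {
  sc <- synthetic_scenario(seed = 1, nx = 2, ny = 2, county_block = 2,
                           tract_side_miles = 10, jitter = 0, n_providers = 0)
  geo <- make_grid_tracts(sc)
  expect_equal(n_units(geo$tracts), 4)
  expect_equal(n_units(geo$counties), 1)
  a <- layer_areas(geo$tracts_planar)
  expect_equal(unname(layer_areas(geo$counties_planar)), 4 * unname(a[1]))

  sc2 <- synthetic_scenario(seed = 1, nx = 8, ny = 8, county_block = 4,
                            n_providers = 0)
  geo2 <- make_grid_tracts(sc2)
  expect_equal(n_units(geo2$tracts), 64)
  expect_equal(n_units(geo2$counties), 4)
  expect_equal(as.integer(table(geo2$tracts$data$county_id)), rep(16L, 4))
})

test_that("jittered tracts still partition the region and dissolve into counties", {
  for (seed in c(2, 9)) {
    sc <- synthetic_scenario(seed = seed, nx = 7, ny = 5, county_block = 3,
                             tract_side_miles = 8, jitter = 0.4, n_providers = 0)
    geo <- make_grid_tracts(sc)
    region_area <- 7 * 5 * 8^2
    expect_equal(sum(layer_areas(geo$tracts_planar)), region_area,
                 tolerance = 1e-9)
    # county outlines equal the union of their member tracts, area-wise
    tract_by_county <- tapply(layer_areas(geo$tracts_planar),
                              geo$tracts$data$county_id, sum)
    county_a <- layer_areas(geo$counties_planar)
    expect_equal(unname(county_a[names(tract_by_county)]),
                 as.numeric(tract_by_county), tolerance = 1e-9)
    # edge counties may be smaller blocks: widths (3,3,1) x heights (3,2)
    expect_equal(sort(as.integer(table(geo$tracts$data$county_id))),
                 c(2L, 3L, 6L, 6L, 9L, 9L))
  }
})

test_that("invalid scenario parameters are rejected with the field named", {
  expect_error(synthetic_scenario(seed = 1, nx = 0), "nx")
  expect_error(synthetic_scenario(seed = 1, tract_side_miles = -1), "tract_side_miles")
  expect_error(synthetic_scenario(seed = 1, zero_pop_tract_fraction = 1), "zero_pop")
  expect_error(synthetic_scenario(), "seed")
})

test_that("populations are right-skewed with the exact zero-tract count", {
  sc <- synthetic_scenario(seed = 5, nx = 10, ny = 10, county_block = 5,
                           zero_pop_tract_fraction = 0.1, n_providers = 0)
  geo <- make_grid_tracts(sc)
  pops <- sample_populations(sc, geo$tracts)
  expect_equal(sum(pops$tract_pop$medicare_pop == 0), 10)
  expect_true(all(pops$tract_pop$medicare_pop >= 0))
  expect_gt(mean(pops$tract_pop$medicare_pop), median(pops$tract_pop$medicare_pop))

  sc0 <- synthetic_scenario(seed = 5, nx = 10, ny = 10, county_block = 5,
                            zero_pop_tract_fraction = 0, n_providers = 0)
  pops0 <- sample_populations(sc0, geo$tracts)
  expect_true(all(pops0$tract_pop$medicare_pop > 0))
  # county FFS population is the configured fraction of summed tract population
  sums <- tapply(pops0$tract_pop$medicare_pop, geo$tracts$data$county_id, sum)
  expect_equal(pops0$county_pop$ffs_pop,
               as.integer(round(0.7 * unname(sums[pops0$county_pop$county_id]))))
})

test_that("smoking surface hits target moments and is spatially autocorrelated", {
  sc <- synthetic_scenario(seed = 6, nx = 30, ny = 30, county_block = 3,
                           n_providers = 0)  # 100 counties
  geo <- make_grid_tracts(sc)
  smoking <- sample_smoking_surface(sc, geo$counties_planar)
  expect_true(all(smoking$smoking_prev_pct > 0 & smoking$smoking_prev_pct < 100))
  expect_equal(mean(smoking$smoking_prev_pct), 17.5, tolerance = 1 / 17.5)
  expect_equal(median(smoking$smoking_prev_pct), 17.5, tolerance = 0.1)

  # degenerate SD: flat surface
  sc_flat <- synthetic_scenario(seed = 6, nx = 4, ny = 4, county_block = 2,
                                smoking_sd_pct = 0, n_providers = 0)
  geo_flat <- make_grid_tracts(sc_flat)
  s_flat <- sample_smoking_surface(sc_flat, geo_flat$counties_planar)
  expect_true(all(s_flat$smoking_prev_pct == 17.5))

  # Moran-style neighbor correlation: smoothed surface beats unsmoothed noise
  neighbor_cor <- function(vals, cent, cutoff) {
    d <- as.matrix(dist(cent))
    w <- d > 0 & d < cutoff
    lag <- sapply(seq_len(nrow(w)), function(i) mean(vals[w[i, ]]))
    cor(vals, lag)
  }
  cent <- t(vapply(geo$counties_planar$geometry, polygon_centroid, numeric(2)))
  sc_raw <- synthetic_scenario(seed = 6, nx = 30, ny = 30, county_block = 3,
                               smoothing_bandwidth_miles = 0, n_providers = 0)
  s_raw <- sample_smoking_surface(sc_raw, geo$counties_planar)
  cutoff <- 1.5 * 3 * 10  # adjacent county centroids
  expect_gt(neighbor_cor(smoking$smoking_prev_pct, cent, cutoff),
            neighbor_cor(s_raw$smoking_prev_pct, cent, cutoff))
})

test_that("provider placement follows the clustering sign and suppression floor", {
  inst <- planar_instance(7, nx = 30, ny = 30, county_block = 3,
                          n_providers = 60, provider_clustering = -1)
  counts <- inst$raw$assigned_county$n_assigned
  expect_equal(sum(counts), 60)
  expect_lt(cor(counts, inst$smoking$smoking_prev_pct, method = "spearman"), 0)

  raw <- inst$raw$providers
  retained <- raw[raw$hcpcs_code == "G0297" &
                    !startsWith(raw$npi, "19"), ]
  expect_true(all(retained$line_srvc_cnt >= 11))
  sub <- raw[raw$hcpcs_code == "G0297" & startsWith(raw$npi, "19"), ]
  expect_true(all(sub$line_srvc_cnt >= 1 & sub$line_srvc_cnt <= 10))
  expect_true(any(raw$hcpcs_code != "G0297"))
  # planted truth is emitted for every county
  expect_equal(sort(inst$raw$truth$county_id),
               sort(inst$geography$counties$data$county_id))
})

test_that("an empty provider cohort flows through to 100% counties without service", {
  tmp <- withr::local_tempdir()
  cfg <- run_config(seed = 3, indir = tmp)
  sc <- synthetic_scenario(seed = 3, nx = 6, ny = 6, county_block = 3,
                           n_providers = 0, n_suppressed_rows = 2,
                           n_decoy_rows = 0)
  run_simulate(cfg, sc)
  # few counties: rank tables warn about truncation by design
  suppressWarnings(suppressMessages(run_pipeline(cfg)))
  summ <- jsonlite::read_json(file.path(tmp, "summary.json"))
  expect_equal(summ$county_uncovered$proportion, 1)
  expect_equal(summ$tract_uncovered$proportion, 1)
})

test_that("identical seeds give identical draws; different seeds differ", {
  sc <- synthetic_scenario(seed = 42, nx = 6, ny = 6, county_block = 3,
                           n_providers = 10)
  geo1 <- make_grid_tracts(sc)
  geo2 <- make_grid_tracts(sc)
  expect_identical(geo1$tracts$geometry, geo2$tracts$geometry)
  s1 <- sample_smoking_surface(sc, geo1$counties_planar)
  s2 <- sample_smoking_surface(sc, geo2$counties_planar)
  expect_identical(s1, s2)
  sc_b <- synthetic_scenario(seed = 43, nx = 6, ny = 6, county_block = 3,
                             n_providers = 10)
  s3 <- sample_smoking_surface(sc_b, make_grid_tracts(sc_b)$counties_planar)
  expect_false(identical(s1$smoking_prev_pct, s3$smoking_prev_pct))
})
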