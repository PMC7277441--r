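# a 2x2-tract, 1-county planar layer of unit-free 10-mile squares
square_tracts <- function(side = 10, nx = 2, ny = 2, county = "C001") {
  geoms <- list()
  ids <- character(0)
  k <- 0
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    k <- k + 1
    id <- sprintf("T%05d", k)
    x0 <- (i - 1) * side; y0 <- (j - 1) * side
    geoms[[id]] <- cbind(c(x0, x0 + side, x0 + side, x0),
                         c(y0, y0, y0 + side, y0 + side))
    ids <- c(ids, id)
  }
  geo_layer(geoms, tibble::tibble(tract_id = ids, county_id = county),
            crs = albers_projection(-96, 38.5, 36, 41))
}

providers_at <- function(xy) {
  tibble::tibble(provider_id = sprintf("P%02d", seq_len(nrow(xy))),
                 x = xy[, 1], y = xy[, 2])
}

test_that("served rule is a strict inequality at the threshold", {
  expect_false(served(0.51))
  expect_true(served(0.510001))
  expect_true(served(1.0))
  expect_false(served(0))
  expect_error(served(1.2))
})

test_that("coverage fractions are exact for containment and disjointness", {
  tract <- unit_square() * 10
  expect_equal(tract_coverage_fraction(tract, buffer_provider(c(5, 5), 30)), 1)
  expect_equal(tract_coverage_fraction(tract, buffer_provider(c(100, 100), 30)), 0)
  degenerate <- cbind(c(0, 1, 2), c(0, 0, 0))
  attr(degenerate, "id") <- "T00099"
  expect_error(tract_coverage_fraction(degenerate, buffer_provider(c(0, 0), 30)),
               "T00099")
})

test_that("tract and county counts follow the aggregation rule", {
  tracts <- square_tracts()
  # both providers at the center serve all four tracts
  res <- count_providers(providers_at(rbind(c(10, 10), c(10, 10))), tracts,
                         radius_miles = 30)
  expect_true(all(res$tract_counts$provider_count == 2))
  expect_equal(res$county_counts$provider_count, 8L)  # 2 providers x 4 tracts

  # a provider serving 3 of 4 tracts contributes 3 to the county
  # radius 12 from the lower-left corner covers T1 fully and the two
  # adjacent tracts > 51%, but the diagonal tract only fractionally
  res2 <- count_providers(providers_at(rbind(c(2, 2))), tracts, radius_miles = 16)
  served_tracts <- sum(res2$tract_counts$provider_count)
  expect_equal(served_tracts, 3L)
  expect_equal(res2$county_counts$provider_count, 3L)
  # cross-check against brute-force per-pair enumeration
  brute <- sum(vapply(tracts$geometry, function(g) {
    tract_coverage_fraction(g, buffer_provider(c(2, 2), 16)) > 0.51
  }, logical(1)))
  expect_equal(served_tracts, brute)

  # no providers -> all counts zero
  res0 <- count_providers(providers_at(matrix(numeric(0), 0, 2)), tracts)
  expect_true(all(res0$tract_counts$provider_count == 0))
  expect_true(all(res0$county_counts$provider_count == 0))

  # distinct-provider aggregation counts each provider once per county
  res3 <- count_providers(providers_at(rbind(c(10, 10), c(10, 10))), tracts,
                          radius_miles = 30, distinct_providers = TRUE)
  expect_equal(res3$county_counts$provider_count, 2L)
})

test_that("clip-based fractions agree with the Monte-Carlo oracle on an instance", {
  inst <- planar_instance(21, nx = 5, ny = 5, county_block = 5, n_providers = 3,
                          jitter = 0.4)
  tracts <- inst$geography$tracts_planar
  for (p in seq_len(nrow(inst$providers))) {
    center <- c(inst$providers$x[p], inst$providers$y[p])
    buf <- buffer_provider(center, 30)
    for (id in names(tracts$geometry)[seq(1, 25, by = 3)]) {
      g <- tracts$geometry[[id]]
      frac <- tract_coverage_fraction(g, buf)
      expect_lt(abs(frac - mc_area_fraction(g, center, 30, n = 4e4, seed = 99)),
                0.015)
    }
  }
})

test_that("served sets are nested and counts non-decreasing in radius", {
  inst <- planar_instance(31, nx = 8, ny = 8, county_block = 4, n_providers = 6)
  tracts <- inst$geography$tracts_planar
  prev_pairs <- NULL
  prev_tract <- NULL
  for (r in c(10, 20, 30)) {
    res <- count_providers(inst$providers, tracts, radius_miles = r)
    pairs <- with(dplyr::filter(res$coverage, served),
                  paste(provider_id, tract_id))
    if (!is.null(prev_pairs)) {
      expect_true(all(prev_pairs %in% pairs))
      expect_true(all(res$tract_counts$provider_count >= prev_tract))
    }
    prev_pairs <- pairs
    prev_tract <- res$tract_counts$provider_count
  }
})

test_that("fractions and counts are invariant under translation", {
  inst <- planar_instance(41, nx = 4, ny = 4, county_block = 2, n_providers = 4)
  tracts <- inst$geography$tracts_planar
  res1 <- count_providers(inst$providers, tracts, radius_miles = 25)
  shift <- c(1234.5, -987.5)
  tracts2 <- tracts
  tracts2$geometry <- lapply(tracts$geometry, function(g) sweep(g, 2, -shift))
  prov2 <- inst$providers
  prov2$x <- prov2$x + shift[1]; prov2$y <- prov2$y + shift[2]
  res2 <- count_providers(prov2, tracts2, radius_miles = 25)
  expect_equal(res1$coverage$area_fraction, res2$coverage$area_fraction,
               tolerance = 1e-9)
  expect_equal(res1$tract_counts, res2$tract_counts)
  expect_equal(res1$county_counts, res2$county_counts)
})

test_that("tracts without a parent county are fatal", {
  tracts <- square_tracts()
  tracts$data$county_id[2] <- NA
  expect_error(count_providers(providers_at(rbind(c(5, 5))), tracts),
               "parent county")
})
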