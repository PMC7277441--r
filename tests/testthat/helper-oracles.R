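# Independent oracles used across the suite. These deliberately avoid the
# package's own geometry: point-in-polygon comes from mgcv::in.out, geodesic
# distances and areas from geosphere, and buffer membership from the exact
# circle (distance to center), so the clipping implementation is checked
# against a different computational route.

# Monte-Carlo area fraction of `poly` inside the disc (center, radius).
# Uniform points in the polygon by rejection sampling from its bbox.
mc_area_fraction <- function(poly, center, radius, n = 1e5, seed = 1) {
  withr::with_seed(seed, {
    closed <- rbind(poly, poly[1, ])
    xr <- range(poly[, 1]); yr <- range(poly[, 2])
    pts <- matrix(numeric(0), 0, 2)
    while (nrow(pts) < n) {
      cand <- cbind(stats::runif(n, xr[1], xr[2]), stats::runif(n, yr[1], yr[2]))
      keep <- mgcv::in.out(closed, cand)
      pts <- rbind(pts, cand[keep, , drop = FALSE])
    }
    pts <- pts[seq_len(n), , drop = FALSE]
    d2 <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2
    mean(d2 <= radius^2)
  })
}

# Monte-Carlo fraction of `poly` inside an arbitrary clip polygon.
mc_clip_fraction <- function(poly, clip, n = 1e5, seed = 1) {
  withr::with_seed(seed, {
    closed <- rbind(poly, poly[1, ])
    clip_closed <- rbind(clip, clip[1, ])
    xr <- range(poly[, 1]); yr <- range(poly[, 2])
    pts <- matrix(numeric(0), 0, 2)
    while (nrow(pts) < n) {
      cand <- cbind(stats::runif(n, xr[1], xr[2]), stats::runif(n, yr[1], yr[2]))
      keep <- mgcv::in.out(closed, cand)
      pts <- rbind(pts, cand[keep, , drop = FALSE])
    }
    pts <- pts[seq_len(n), , drop = FALSE]
    mean(mgcv::in.out(clip_closed, pts))
  })
}

SQMETERS_PER_SQMILE <- 1609.344^2
METERS_PER_MILE <- 1609.344

# Geodesic (WGS84 ellipsoid) area of a lon/lat ring, in square miles.
geodesic_area_sqmi <- function(lonlat) {
  abs(geosphere::areaPolygon(lonlat)) / SQMETERS_PER_SQMILE
}

# A small jittered tessellation plus cleaned providers in planar miles.
planar_instance <- function(seed, nx = 10, ny = 10, county_block = 5,
                            n_providers = 6, jitter = 0.3, ...) {
  sc <- synthetic_scenario(seed = seed, nx = nx, ny = ny,
                           county_block = county_block,
                           n_providers = n_providers, jitter = jitter, ...)
  geo <- make_grid_tracts(sc)
  smoking <- sample_smoking_surface(sc, geo$counties_planar)
  prov <- sample_providers(sc, geo, smoking)
  clean <- filter_and_aggregate(prov$providers)
  if (nrow(clean) > 0) {
    xy <- project_points(geo$projection, cbind(clean$lon, clean$lat))
    clean$x <- xy[, 1]; clean$y <- xy[, 2]
  } else {
    clean$x <- numeric(0); clean$y <- numeric(0)
  }
  list(scenario = sc, geography = geo, smoking = smoking, raw = prov,
       providers = clean)
}

# unit square [0,1]^2
unit_square <- function() cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
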