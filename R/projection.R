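# Spherical Albers equal-area conic projection, scaled to miles.
#
# The buffer/served geometry needs a planar system in which Euclidean
# distance is miles and areas are (very nearly) true areas. An Albers-type
# equal-area conic with standard parallels bracketing the study region keeps
# both distance and area distortion small over a region a few hundred miles
# across. The sphere uses the authalic radius, which matches ellipsoidal
# areas closely.

#' Authalic earth radius in miles
#' @keywords internal
R_AUTHALIC_MILES <- 6371.0072 / 1.609344

#' Construct an Albers equal-area conic projection
#'
#' @param lon0 Central meridian (degrees).
#' @param lat0 Latitude of origin (degrees); maps to planar (0, 0) with `lon0`.
#' @param lat1,lat2 Standard parallels (degrees).
#' @param radius_miles Sphere radius; default the authalic radius.
#' @return An object of class `albers_proj`.
#' @export
albers_projection <- function(lon0, lat0, lat1, lat2, radius_miles = R_AUTHALIC_MILES) {
  stopifnot(abs(lat1) < 90, abs(lat2) < 90, abs(lat0) < 90)
  d2r <- pi / 180
  p1 <- lat1 * d2r; p2 <- lat2 * d2r
  n <- (sin(p1) + sin(p2)) / 2
  if (abs(n) < 1e-12) stop("standard parallels may not be symmetric about the equator")
  C <- cos(p1)^2 + 2 * n * sin(p1)
  rho0 <- radius_miles / n * sqrt(C - 2 * n * sin(lat0 * d2r))
  structure(
    list(lon0 = lon0, lat0 = lat0, lat1 = lat1, lat2 = lat2,
         R = radius_miles, n = n, C = C, rho0 = rho0),
    class = "albers_proj"
  )
}

#' @export
print.albers_proj <- function(x, ...) {
  cat(sprintf(
    "Albers equal-area conic (miles): lon0=%.4f lat0=%.4f parallels=%.4f/%.4f\n",
    x$lon0, x$lat0, x$lat1, x$lat2))
  invisible(x)
}

#' Forward-project WGS84 points to planar miles
#'
#' @param proj An `albers_proj` object.
#' @param lonlat Two-column matrix of longitude, latitude in degrees.
#' @return Two-column matrix of x, y in miles.
#' @export
project_points <- function(proj, lonlat) {
  stopifnot(inherits(proj, "albers_proj"), ncol(lonlat) == 2)
  d2r <- pi / 180
  rho <- proj$R / proj$n * sqrt(proj$C - 2 * proj$n * sin(lonlat[, 2] * d2r))
  theta <- proj$n * (lonlat[, 1] - proj$lon0) * d2r
  cbind(rho * sin(theta), proj$rho0 - rho * cos(theta))
}

#' Inverse-project planar miles back to WGS84
#'
#' @param proj An `albers_proj` object.
#' @param xy Two-column matrix of x, y in miles.
#' @return Two-column matrix of longitude, latitude in degrees.
#' @export
unproject_points <- function(proj, xy) {
  stopifnot(inherits(proj, "albers_proj"), ncol(xy) == 2)
  r2d <- 180 / pi
  rho <- sqrt(xy[, 1]^2 + (proj$rho0 - xy[, 2])^2)
  theta <- atan2(xy[, 1], proj$rho0 - xy[, 2])
  lat <- asin((proj$C - (rho * proj$n / proj$R)^2) / (2 * proj$n)) * r2d
  lon <- proj$lon0 + theta * r2d / proj$n
  cbind(lon, lat)
}

#' Fit an Albers projection to a WGS84 layer
#'
#' Centers the projection on the layer's bounding box and places the standard
#' parallels at 1/6 and 5/6 of the latitude span (the usual one-sixth rule),
#' so distortion stays small across the region.
#'
#' @param layer A `geo_layer` in WGS84 (see [geo_layer()]).
#' @return An `albers_proj`.
#' @export
fit_projection <- function(layer) {
  stopifnot(inherits(layer, "geo_layer"), identical(layer$crs, "wgs84"))
  all_xy <- do.call(rbind, layer$geometry)
  lat_min <- min(all_xy[, 2]); lat_max <- max(all_xy[, 2])
  span <- max(lat_max - lat_min, 0.5)
  albers_projection(
    lon0 = mean(range(all_xy[, 1])),
    lat0 = (lat_min + lat_max) / 2,
    lat1 = lat_min + span / 6,
    lat2 = lat_max - span / 6
  )
}

#' Project a WGS84 layer to planar miles
#'
#' Warns (with unit ids) for geometries outside the projection's comfortable
#' validity window, taken as latitudes more than 25 degrees from the latitude
#' of origin.
#'
#' @param layer A `geo_layer` in WGS84.
#' @param proj An `albers_proj`; default fitted from the layer.
#' @return The layer with planar geometry and `crs` set to the projection.
#' @export
project_layer <- function(layer, proj = fit_projection(layer)) {
  stopifnot(inherits(layer, "geo_layer"))
  if (!identical(layer$crs, "wgs84")) stop("layer is not in WGS84")
  bad <- vapply(layer$geometry, function(g) any(abs(g[, 2] - proj$lat0) > 25), logical(1))
  if (any(bad)) {
    warning("geometries outside projection validity window: ",
            paste(names(layer$geometry)[bad], collapse = ", "))
  }
  layer$geometry <- lapply(layer$geometry, function(g) project_points(proj, g))
  layer$crs <- proj
  layer
}

#' Inverse-project a planar layer to WGS84
#'
#' @param layer A `geo_layer` whose `crs` is an `albers_proj`.
#' @return The layer in WGS84.
#' @export
unproject_layer <- function(layer) {
  stopifnot(inherits(layer, "geo_layer"), inherits(layer$crs, "albers_proj"))
  proj <- layer$crs
  layer$geometry <- lapply(layer$geometry, function(g) unproject_points(proj, g))
  layer$crs <- "wgs84"
  layer
}
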