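# Lightweight polygon-layer container and GeoJSON I/O.
#
# A geo_layer holds single-ring polygons (two-column vertex matrices, not
# closed) named by unit id, an attribute tibble whose first column is that
# id, and a crs that is either the string "wgs84" or an albers_proj. This is
# deliberately minimal: the pipeline needs exact planar areas and attribute
# joins, not a full simple-features model.

#' Construct a polygon layer
#'
#' @param geometry Named list of two-column vertex matrices (rings not closed).
#' @param data Data frame of attributes; its first column must contain the
#'   unit ids, matching `names(geometry)` exactly and in order.
#' @param crs `"wgs84"` or an `albers_proj` object.
#' @return A `geo_layer`.
#' @export
geo_layer <- function(geometry, data, crs = "wgs84") {
  stopifnot(is.list(geometry), is.data.frame(data), nrow(data) == length(geometry))
  ids <- as.character(data[[1]])
  if (!identical(names(geometry), ids)) {
    stop("geometry names must equal the first attribute column")
  }
  structure(list(geometry = geometry, data = tibble::as_tibble(data), crs = crs),
            class = "geo_layer")
}

#' @export
print.geo_layer <- function(x, ...) {
  crs <- if (identical(x$crs, "wgs84")) "WGS84" else "planar (miles)"
  cat(sprintf("<geo_layer> %d polygons, %s, attributes: %s\n",
              length(x$geometry), crs, paste(names(x$data), collapse = ", ")))
  invisible(x)
}

#' Number of polygons in a layer
#' @param layer A `geo_layer`.
#' @export
n_units <- function(layer) length(layer$geometry)

#' Areas of all polygons in a layer
#'
#' @param layer A `geo_layer` (planar for areas in square miles).
#' @return Named numeric vector of absolute areas.
#' @export
layer_areas <- function(layer) {
  vapply(layer$geometry, polygon_area, numeric(1))
}

fmt_num <- function(x) {
  # %.17g round-trips doubles exactly; integers print without exponent
  ifelse(is.na(x), "null",
         ifelse(x == floor(x) & abs(x) < 1e15, sprintf("%.0f", x),
                sprintf("%.17g", x)))
}

json_escape <- function(s) {
  s <- gsub("\\\\", "\\\\\\\\", s)
  gsub('"', '\\\\"', s)
}

fmt_prop <- function(v) {
  if (is.numeric(v)) fmt_num(v)
  else if (is.logical(v)) ifelse(is.na(v), "null", ifelse(v, "true", "false"))
  else ifelse(is.na(v), "null", paste0('"', json_escape(as.character(v)), '"'))
}

#' Write a WGS84 layer to GeoJSON
#'
#' Coordinates and numeric attributes are serialized at full double
#' precision (`%.17g`), so a read-back reproduces them exactly and repeated
#' writes of identical inputs are byte-identical.
#'
#' @param layer A `geo_layer` in WGS84.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(layer, path) {
  stopifnot(inherits(layer, "geo_layer"))
  if (!identical(layer$crs, "wgs84")) stop("write_geojson expects a WGS84 layer")
  dat <- layer$data
  feats <- vapply(seq_along(layer$geometry), function(i) {
    ring <- layer$geometry[[i]]
    ring <- rbind(ring, ring[1, ])  # GeoJSON rings are closed
    coords <- paste0("[", fmt_num(ring[, 1]), ",", fmt_num(ring[, 2]), "]",
                     collapse = ",")
    props <- paste0('"', names(dat), '":',
                    vapply(dat, function(col) fmt_prop(col[i]), character(1)),
                    collapse = ",")
    paste0('{"type":"Feature","properties":{', props,
           '},"geometry":{"type":"Polygon","coordinates":[[', coords, ']]}}')
  }, character(1))
  txt <- paste0('{"type":"FeatureCollection","features":[\n',
                paste(feats, collapse = ",\n"), '\n]}\n')
  writeLines(txt, path, sep = "")
  invisible(path)
}

#' Read a GeoJSON polygon layer
#'
#' Accepts FeatureCollections of single-ring Polygons as written by
#' [write_geojson()]. The first property of the first feature is taken as
#' the unit-id column.
#'
#' @param path GeoJSON file path.
#' @param id_field Name of the property holding unit ids; default the first
#'   property encountered.
#' @return A `geo_layer` in WGS84.
#' @export
read_geojson <- function(path, id_field = NULL) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) stop("not a GeoJSON FeatureCollection")
  feats <- gj$features
  if (length(feats) == 0) stop("empty FeatureCollection")
  if (is.null(id_field)) id_field <- names(feats[[1]]$properties)[1]
  geometry <- vector("list", length(feats))
  props <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    if (!identical(f$geometry$type, "Polygon")) stop("only Polygon geometries are supported")
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    geometry[[i]] <- m
    props[[i]] <- lapply(f$properties, function(v) if (is.null(v)) NA else v)
  }
  data <- dplyr::bind_rows(lapply(props, tibble::as_tibble))
  data <- dplyr::relocate(data, dplyr::all_of(id_field))
  names(geometry) <- as.character(data[[id_field]])
  geo_layer(geometry, data, crs = "wgs84")
}
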