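# Class-coded map layer, scatter data, optional rendered figures, and the
# human-readable run report. The acceptance surface is the attribute data;
# figures are convenience output.

#' Export the class-coded county map layer
#'
#' Joins county geometries with densities and bivariate classes and writes a
#' GeoJSON FeatureCollection whose properties are `county_id`,
#' `density_per_1000`, `smoking_prev_pct`, `density_level`, `smoking_level`,
#' `code`. No-service counties carry the explicit `"no_service"` string in
#' the level/code fields (never an absent field). Attribute values are
#' written at full precision, so identical inputs produce bit-identical
#' files. Counties present in the geometry but absent from the attribute
#' tables (or vice versa) are fatal.
#'
#' @param counties County `geo_layer` in WGS84.
#' @param densities County density records from [compute_density()].
#' @param classes Tibble from [classify_bivariate()].
#' @param path Output GeoJSON path.
#' @return The written layer, invisibly.
#' @export
export_map_layer <- function(counties, densities, classes, path) {
  stopifnot(inherits(counties, "geo_layer"))
  ids <- counties$data$county_id
  id_col <- names(densities)[1]
  attrs <- dplyr::full_join(
    stats::setNames(densities[, c(id_col, "density_per_1000")], c("county_id", "density_per_1000")),
    classes[, c("county_id", "smoking_prev_pct", "density_level", "smoking_level", "code")],
    by = "county_id"
  )
  missing_attr <- setdiff(ids, attrs$county_id)
  missing_geom <- setdiff(attrs$county_id, ids)
  if (length(missing_attr) > 0 || length(missing_geom) > 0) {
    stop("county id mismatch between layers; missing attributes: ",
         paste(missing_attr, collapse = ", "), "; missing geometries: ",
         paste(missing_geom, collapse = ", "))
  }
  attrs <- attrs[match(ids, attrs$county_id), ]
  # counties unclassified (no smoking data / zero population) keep an explicit sentinel
  for (col in c("density_level", "smoking_level", "code")) {
    attrs[[col]][is.na(attrs[[col]])] <- "no_data"
  }
  layer <- geo_layer(counties$geometry, attrs, crs = counties$crs)
  write_geojson(layer, path)
  invisible(layer)
}

#' Export scatter data (density vs smoking, class-coded)
#'
#' One row per served county; no-service counties are omitted from the
#' scatter and counted in a `#` header comment.
#'
#' @param classes Tibble from [classify_bivariate()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_scatter <- function(classes, path) {
  served_rows <- dplyr::filter(classes, .data$code != "no_service")
  n_omitted <- nrow(classes) - nrow(served_rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# no_service counties omitted: %d", n_omitted), con)
  writeLines("county_id,density_per_1000,smoking_prev_pct,code", con)
  if (nrow(served_rows) > 0) {
    writeLines(sprintf("%s,%.17g,%.17g,%s", served_rows$county_id,
                       served_rows$density_per_1000, served_rows$smoking_prev_pct,
                       served_rows$code), con)
  }
  invisible(path)
}

# default 3x3 bivariate palette (corner-interpolated), plus white for
# no-service and grey for missing data
bivariate_palette <- function(low_low = "#e8e8e8", high_low = "#c85a5a",
                              low_high = "#64acbe", high_high = "#574249") {
  corner <- grDevices::colorRamp(c(low_low, high_low))
  corner2 <- grDevices::colorRamp(c(low_high, high_high))
  mix <- function(fx, fy) {
    a <- corner(fx); b <- corner2(fx)
    rgb <- a + fy * (b - a)
    grDevices::rgb(rgb[1], rgb[2], rgb[3], maxColorValue = 255)
  }
  lv <- c(0, 0.5, 1)
  cols <- character(9)
  k <- 0
  for (fy in lv) for (fx in lv) {
    k <- k + 1
    cols[k] <- mix(fx, fy)
  }
  # order: density level within smoking level rows low->high
  names(cols) <- as.vector(outer(c("low", "medium", "high"),
                                 c("low", "medium", "high"),
                                 function(d, s) paste(d, s, sep = "-")))
  c(cols, no_service = "#FFFFFF", no_data = "#BBBBBB")
}

#' Render univariate and bivariate county maps (best effort)
#'
#' Convenience rendering of the exported map layer with ggplot2. Rendering
#' never fails the pipeline: if the plotting backend is unavailable the
#' function warns and returns no paths.
#'
#' @param layer Map layer as returned by [export_map_layer()].
#' @param path_prefix Path prefix; writes `<prefix>_density.png`,
#'   `<prefix>_smoking.png`, `<prefix>_bivariate.png`.
#' @return Character vector of written paths (possibly empty), invisibly.
#' @export
render_maps <- function(layer, path_prefix) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    warning("ggplot2 not available; skipping map rendering")
    return(invisible(character(0)))
  }
  out <- tryCatch({
    df <- do.call(rbind, lapply(seq_along(layer$geometry), function(i) {
      g <- layer$geometry[[i]]
      data.frame(county_id = names(layer$geometry)[i], x = g[, 1], y = g[, 2])
    }))
    df <- merge(df, as.data.frame(layer$data), by = "county_id")
    pal <- bivariate_palette()
    paths <- paste0(path_prefix, c("_density.png", "_smoking.png", "_bivariate.png"))
    gg_base <- function(fill) {
      ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$county_id,
                                       fill = {{ fill }})) +
        ggplot2::geom_polygon(color = "grey30", linewidth = 0.1) +
        ggplot2::coord_equal() + ggplot2::theme_void()
    }
    ggplot2::ggsave(paths[1], gg_base(.data$density_per_1000) +
                      ggplot2::scale_fill_viridis_c(na.value = "white"),
                    width = 7, height = 6, dpi = 120)
    ggplot2::ggsave(paths[2], gg_base(.data$smoking_prev_pct) +
                      ggplot2::scale_fill_viridis_c(option = "magma"),
                    width = 7, height = 6, dpi = 120)
    ggplot2::ggsave(paths[3], gg_base(.data$code) +
                      ggplot2::scale_fill_manual(values = pal),
                    width = 7, height = 6, dpi = 120)
    paths
  }, error = function(e) {
    warning("map rendering skipped: ", conditionMessage(e))
    character(0)
  })
  invisible(out)
}

#' Write the human-readable run report
#'
#' Echoes the full analysis configuration (every parameter, defaulted or
#' not), input file digests, per-stage filter counts, and headline
#' statistics. Paths are reported as basenames so reports from identical
#' runs in different directories are byte-identical.
#'
#' @param config A [run_config()].
#' @param digests Named md5 digests of the input files.
#' @param stats Named list of headline statistics.
#' @param path Output markdown path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(config, digests, stats, path) {
  fmt <- function(x) {
    if (is.numeric(x)) paste(format(x, digits = 10), collapse = ", ")
    else paste(as.character(x), collapse = ", ")
  }
  deviates <- !isTRUE(all.equal(config[REFERENCE_PARAMS],
                                run_config(seed = config$seed)[REFERENCE_PARAMS]))
  lines <- c(
    "# Accessibility pipeline run report", "",
    if (deviates) "**Note: deviates from reference configuration.**",
    "## Configuration", "",
    sprintf("- %s: %s", names(config)[!names(config) %in% c("indir", "outdir")],
            vapply(config[!names(config) %in% c("indir", "outdir")], fmt, character(1))),
    "", "## Input digests", "",
    sprintf("- %s: %s", names(digests), unname(digests)),
    "", "## Headline statistics", "",
    sprintf("- %s: %s", names(stats), vapply(stats, fmt, character(1)))
  )
  writeLines(lines, path)
  invisible(path)
}
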