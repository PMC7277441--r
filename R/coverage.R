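# Buffer coverage model: per-(provider, tract) area fractions, the served
# rule, and aggregation of provider counts to tracts and counties.

#' Fraction of a tract's area inside a buffer
#'
#' Exact polygon clipping (Sutherland–Hodgman against the convex buffer)
#' followed by the shoelace area ratio.
#'
#' @param tract_polygon Two-column matrix, planar miles; may carry an `id`
#'   attribute used in error messages.
#' @param buffer_polygon Convex buffer polygon from [buffer_provider()].
#' @return Area fraction in \[0, 1\].
#' @export
tract_coverage_fraction <- function(tract_polygon, buffer_polygon) {
  a <- polygon_area(tract_polygon)
  if (a <= 0) {
    id <- attr(tract_polygon, "id")
    stop("zero-area tract", if (!is.null(id)) paste0(": ", id) else "")
  }
  inter <- clip_polygon_convex(tract_polygon, buffer_polygon)
  if (nrow(inter) < 3) return(0)
  min(polygon_area(inter) / a, 1)
}

#' Served rule
#'
#' A tract is served by a provider when strictly more than `threshold` of its
#' area lies inside the provider's buffer ("more than 51%"): a fraction of
#' exactly 0.51 is NOT served.
#'
#' @param area_fraction Fraction(s) in \[0, 1\].
#' @param threshold Strict lower bound; default 0.51.
#' @return Logical.
#' @export
served <- function(area_fraction, threshold = 0.51) {
  stopifnot(all(area_fraction >= 0 & area_fraction <= 1))
  area_fraction > threshold
}

#' Coverage matrix and provider counts per tract and county
#'
#' For every provider a circular buffer of `radius_miles` is built in the
#' planar system; for every tract the covered area fraction is computed and
#' the served rule applied. The tract provider count is the number of
#' providers serving it; the county count is, by default, the sum of its
#' member tracts' counts, so one provider serving k tracts of a county
#' contributes k (the aggregation consistent with published county densities
#' of order 100+ providers per 1000 beneficiaries). Set
#' `distinct_providers = TRUE` for the alternative that counts each provider
#' at most once per county — a documented deviation from the reference
#' aggregation.
#'
#' Cheap exact screens avoid clipping most pairs: a tract whose bounding box
#' is at least `radius_miles` from the provider is untouched, and a tract
#' whose vertices all lie within the buffer polygon's inscribed radius is
#' fully covered.
#'
#' @param providers Tibble with `provider_id` and planar `x`, `y` (miles).
#' @param tracts Planar tract `geo_layer` with a `county_id` attribute.
#' @param radius_miles Buffer radius; default 30.
#' @param threshold Served-rule threshold; default 0.51.
#' @param segments Buffer vertices per quarter circle; default 64.
#' @param distinct_providers Count providers at most once per county.
#' @return List: `coverage` (tibble `provider_id`, `tract_id`,
#'   `area_fraction`, `served`, one row per pair with positive fraction),
#'   `tract_counts` (`tract_id`, `county_id`, `provider_count`), and
#'   `county_counts` (`county_id`, `provider_count`).
#' @export
count_providers <- function(providers, tracts, radius_miles = 30,
                            threshold = 0.51, segments = 64L,
                            distinct_providers = FALSE) {
  stopifnot(inherits(tracts, "geo_layer"))
  if (!("county_id" %in% names(tracts$data)) ||
      any(is.na(tracts$data$county_id))) {
    stop("every tract must have a parent county id")
  }
  tract_ids <- tracts$data$tract_id
  county_of <- tracts$data$county_id
  geoms <- lapply(seq_along(tracts$geometry), function(i) {
    g <- repair_ring(tracts$geometry[[i]], tract_ids[i])
    attr(g, "id") <- tract_ids[i]
    g
  })
  bboxes <- t(vapply(geoms, bbox_of, numeric(4)))
  inscribed <- radius_miles * cos(pi / (4 * segments))

  cov <- vector("list", nrow(providers))
  for (p in seq_len(nrow(providers))) {
    pt <- c(providers$x[p], providers$y[p])
    # exact screens
    dx <- pmax(bboxes[, 1] - pt[1], 0, pt[1] - bboxes[, 3])
    dy <- pmax(bboxes[, 2] - pt[2], 0, pt[2] - bboxes[, 4])
    near <- sqrt(dx^2 + dy^2) < radius_miles
    if (!any(near)) next
    buf <- buffer_provider(pt, radius_miles, segments)
    idx <- which(near)
    frac <- vapply(idx, function(i) {
      g <- geoms[[i]]
      vd2 <- (g[, 1] - pt[1])^2 + (g[, 2] - pt[2])^2
      if (max(vd2) <= inscribed^2) return(1)  # all vertices inside inscribed circle
      tract_coverage_fraction(g, buf)
    }, numeric(1))
    keep <- frac > 0
    if (!any(keep)) next
    cov[[p]] <- tibble::tibble(
      provider_id = providers$provider_id[p],
      tract_id = tract_ids[idx[keep]],
      area_fraction = frac[keep]
    )
  }
  coverage <- dplyr::bind_rows(cov)
  if (nrow(coverage) == 0) {
    coverage <- tibble::tibble(provider_id = character(), tract_id = character(),
                               area_fraction = numeric())
  }
  coverage$served <- served(coverage$area_fraction, threshold)
  coverage <- dplyr::arrange(coverage, .data$provider_id, .data$tract_id)

  served_pairs <- dplyr::filter(coverage, .data$served)
  tract_counts <- tibble::tibble(tract_id = tract_ids, county_id = county_of) |>
    dplyr::left_join(dplyr::count(served_pairs, .data$tract_id, name = "provider_count"),
                     by = "tract_id") |>
    dplyr::mutate(provider_count = as.integer(dplyr::coalesce(.data$provider_count, 0L)))

  if (distinct_providers) {
    county_counts <- served_pairs |>
      dplyr::left_join(tibble::tibble(tract_id = tract_ids, county_id = county_of),
                       by = "tract_id") |>
      dplyr::distinct(.data$provider_id, .data$county_id) |>
      dplyr::count(.data$county_id, name = "provider_count")
  } else {
    county_counts <- tract_counts |>
      dplyr::group_by(.data$county_id) |>
      dplyr::summarise(provider_count = sum(.data$provider_count), .groups = "drop")
  }
  county_counts <- tibble::tibble(county_id = sort(unique(county_of))) |>
    dplyr::left_join(county_counts, by = "county_id") |>
    dplyr::mutate(provider_count = as.integer(dplyr::coalesce(.data$provider_count, 0L)))

  list(coverage = coverage, tract_counts = tract_counts, county_counts = county_counts)
}

# Drop duplicated consecutive vertices; warn when a ring self-intersects in
# a way the shoelace/clipping pipeline cannot represent. Simple cleaning in
# the spirit of zero-width buffer repair.
repair_ring <- function(ring, id = NULL) {
  n <- nrow(ring)
  if (n >= 2) {
    dup <- c(FALSE, ring[-1, 1] == ring[-n, 1] & ring[-1, 2] == ring[-n, 2])
    if (ring[n, 1] == ring[1, 1] && ring[n, 2] == ring[1, 2]) dup[n] <- TRUE
    if (any(dup)) {
      warning("repaired degenerate vertices in ring",
              if (!is.null(id)) paste0(" ", id) else "")
      ring <- ring[!dup, , drop = FALSE]
    }
  }
  ring
}
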