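# Provider densities per 1000 beneficiaries, distributional summaries,
# uncovered fractions, and ranking tables.

#' Provider density per capita
#'
#' Density is `per * provider_count / population` for units with positive
#' population. Zero-population units get an undefined (NA) density and an
#' `excluded` flag — they are dropped from distributional summaries, the
#' same exclusion semantics applied to zero-beneficiary tracts in the
#' source data.
#'
#' @param counts Tibble with a unit-id column (first) and `provider_count`.
#' @param populations Tibble with the same unit-id column and a population
#'   column (second).
#' @param per Denominator scale; default 1000.
#' @return Tibble: unit id, `provider_count`, `population`,
#'   `density_per_1000`, `has_service`, `excluded`.
#' @export
compute_density <- function(counts, populations, per = 1000) {
  id_col <- names(counts)[1]
  stopifnot(id_col == names(populations)[1])
  pop_col <- names(populations)[2]
  if (any(populations[[pop_col]] < 0)) {
    stop("negative population for unit(s): ",
         paste(populations[[id_col]][populations[[pop_col]] < 0], collapse = ", "))
  }
  missing <- setdiff(counts[[id_col]], populations[[id_col]])
  if (length(missing) > 0) {
    stop("no population entry for unit(s): ", paste(missing, collapse = ", "))
  }
  out <- dplyr::left_join(
    counts[, c(id_col, "provider_count")],
    stats::setNames(populations[, c(id_col, pop_col)], c(id_col, "population")),
    by = id_col
  )
  out |>
    dplyr::mutate(
      density_per_1000 = ifelse(.data$population > 0,
                                per * .data$provider_count / .data$population,
                                NA_real_),
      has_service = .data$provider_count > 0,
      excluded = .data$population == 0
    )
}

#' Median and IQR of densities
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). With `include_zero_density = TRUE` (default)
#' all units with a defined density enter the summary, so no-service units
#' contribute zeros; with `FALSE` only units with service are summarized.
#' Zero-population (excluded) units never enter.
#'
#' @param records Density records from [compute_density()].
#' @param include_zero_density Include no-service units as zeros.
#' @return List: `n`, `median`, `q1`, `q3`, `defined`.
#' @export
summarize_density <- function(records, include_zero_density = TRUE) {
  x <- records$density_per_1000[!records$excluded]
  if (!include_zero_density) {
    x <- records$density_per_1000[!records$excluded & records$has_service]
  }
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    return(list(n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                defined = FALSE))
  }
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  list(n = length(x), median = q[2], q1 = q[1], q3 = q[3], defined = TRUE)
}

#' Fraction of units without service
#'
#' @param records Density records from [compute_density()].
#' @return List: `n_without` (m), `n_total` (n), `proportion` (m/n).
#' @export
uncovered_fraction <- function(records) {
  if (nrow(records) == 0) stop("no records")
  m <- sum(!records$has_service)
  n <- nrow(records)
  list(n_without = m, n_total = n, proportion = m / n)
}

#' Top/bottom-k ranking table
#'
#' Ranks counties by density or by smoking prevalence. Ranking by density
#' considers only units with a defined density, and the bottom-density
#' ranking additionally excludes no-service units (their density is a
#' structural zero, reported on maps as missing, not as a low density).
#' Units without service appearing in smoking-ranked tables carry
#' `"not available"` in the density column. Ties are broken by unit id.
#'
#' @param records County density records from [compute_density()].
#' @param smoking Tibble (`county_id`, `smoking_prev_pct`).
#' @param by `"density"` or `"smoking"`.
#' @param direction `"top"` or `"bottom"`.
#' @param k Number of rows; truncated with a warning when fewer units exist.
#' @param include_no_service Include no-service units in bottom-density
#'   rankings (deviation flag); default FALSE.
#' @return Tibble: unit id, `density_display`, `density_per_1000`,
#'   `smoking_prev_pct`, with attributes `by`, `direction`, `k`.
#' @export
rank_table <- function(records, smoking, by = c("density", "smoking"),
                       direction = c("top", "bottom"), k = 10,
                       include_no_service = FALSE) {
  by <- match.arg(by)
  direction <- match.arg(direction)
  id_col <- names(records)[1]
  joined <- dplyr::inner_join(records, smoking, by = stats::setNames("county_id", id_col))
  if (by == "density") {
    pool <- dplyr::filter(joined, !is.na(.data$density_per_1000))
    if (direction == "bottom" && !include_no_service) {
      pool <- dplyr::filter(pool, .data$has_service)
    }
    key <- pool$density_per_1000
  } else {
    pool <- joined
    key <- pool$smoking_prev_pct
  }
  ord <- order(if (direction == "top") -key else key, pool[[id_col]])
  if (k > nrow(pool)) {
    warning(sprintf("requested k=%d but only %d units available; truncating",
                    k, nrow(pool)))
    k <- nrow(pool)
  }
  out <- pool[ord[seq_len(k)], , drop = FALSE]
  out$density_display <- as.character(ifelse(
    out$has_service & !is.na(out$density_per_1000),
    formatC(out$density_per_1000, format = "fg"), "not available"))
  out <- out[, c(id_col, "density_display", "density_per_1000", "smoking_prev_pct")]
  attr(out, "by") <- by
  attr(out, "direction") <- direction
  attr(out, "k") <- k
  out
}
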