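# Bivariate tertile classification: percentile ranks, low/medium/high
# levels at the (34, 67) breaks, the 9-class combined code, and the
# no-service sentinel.

#' Mid-rank percentile of values
#'
#' `100 * (count(x < v) + 0.5 * count(x == v)) / n`. Symmetric and
#' tie-stable: all members of a tie share one percentile, and n distinct
#' values receive percentiles `(i - 0.5) / n * 100`. The alternative
#' `"ecdf"` convention uses `100 * count(x <= v) / n`.
#'
#' @param values Non-empty numeric vector defining the distribution.
#' @param v Value(s) whose percentile is sought (vectorized).
#' @param method `"midrank"` (default) or `"ecdf"`.
#' @return Percentile(s) in \[0, 100\].
#' @export
percentile_rank <- function(values, v, method = c("midrank", "ecdf")) {
  method <- match.arg(method)
  if (length(values) == 0) stop("percentile_rank requires non-empty values")
  n <- length(values)
  vapply(v, function(vi) {
    if (method == "midrank") {
      100 * (sum(values < vi) + 0.5 * sum(values == vi)) / n
    } else {
      100 * sum(values <= vi) / n
    }
  }, numeric(1))
}

#' Tertile level from a percentile
#'
#' low if p < breaks\[1\]; medium if breaks\[1\] <= p < breaks\[2\]; high if
#' p >= breaks\[2\]. Defaults to the (34, 67) breaks: low (< 34th
#' percentile), medium (>= 34th and < 67th), high (>= 67th).
#'
#' @param percentile Percentile(s) in \[0, 100\].
#' @param breaks Length-2 increasing cutpoints; default `c(34, 67)`.
#' @return Character vector of `"low"`, `"medium"`, `"high"`.
#' @export
tertile_level <- function(percentile, breaks = c(34, 67)) {
  stopifnot(length(breaks) == 2, breaks[1] < breaks[2],
            all(percentile >= 0 & percentile <= 100))
  ifelse(percentile < breaks[1], "low",
         ifelse(percentile < breaks[2], "medium", "high"))
}

#' Bivariate classification of counties
#'
#' Each county with a defined density gets a density level and a smoking
#' level by percentile rank, combined into one of nine codes
#' (`"low-low"` ... `"high-high"`). Counties without service receive the
#' `"no_service"` sentinel: they are excluded from the density percentile
#' pool by default (they are missing on the maps, not "low" — including
#' ~half the counties as zeros would collapse the low and medium density
#' tertiles onto zero) but remain in the smoking pool. Counties missing a
#' smoking value are dropped with a warning. Zero-population counties are
#' dropped (undefined density).
#'
#' @param records County density records from [compute_density()].
#' @param smoking Tibble (`county_id`, `smoking_prev_pct`).
#' @param breaks Tertile breaks; default `c(34, 67)`.
#' @param percentile_method Passed to [percentile_rank()].
#' @param density_pool `"served"` (default: percentile pool is served
#'   counties only) or `"all"` (pool includes no-service zeros).
#' @return Tibble: `county_id`, `density_per_1000`, `smoking_prev_pct`,
#'   `density_level` (low/medium/high/no_service), `smoking_level`, `code`.
#' @export
classify_bivariate <- function(records, smoking, breaks = c(34, 67),
                               percentile_method = c("midrank", "ecdf"),
                               density_pool = c("served", "all")) {
  percentile_method <- match.arg(percentile_method)
  density_pool <- match.arg(density_pool)
  id_col <- names(records)[1]
  no_smoking <- setdiff(records[[id_col]], smoking$county_id)
  if (length(no_smoking) > 0) {
    warning("excluding ", length(no_smoking),
            " county(ies) without smoking data: ",
            paste(utils::head(no_smoking, 5), collapse = ", "))
  }
  joined <- dplyr::inner_join(records, smoking,
                              by = stats::setNames("county_id", id_col))
  joined <- dplyr::filter(joined, !is.na(.data$density_per_1000))

  smoking_pct <- percentile_rank(joined$smoking_prev_pct, joined$smoking_prev_pct,
                                 method = percentile_method)
  smoking_level <- tertile_level(smoking_pct, breaks)

  pool <- if (density_pool == "served") {
    joined$density_per_1000[joined$has_service]
  } else {
    joined$density_per_1000
  }
  density_level <- rep("no_service", nrow(joined))
  classify_idx <- if (density_pool == "served") which(joined$has_service) else seq_len(nrow(joined))
  if (length(pool) > 0 && length(classify_idx) > 0) {
    d_pct <- percentile_rank(pool, joined$density_per_1000[classify_idx],
                             method = percentile_method)
    density_level[classify_idx] <- tertile_level(d_pct, breaks)
  }
  density_level[!joined$has_service] <- "no_service"

  tibble::tibble(
    county_id = joined[[id_col]],
    density_per_1000 = joined$density_per_1000,
    smoking_prev_pct = joined$smoking_prev_pct,
    density_level = density_level,
    smoking_level = smoking_level,
    code = ifelse(density_level == "no_service", "no_service",
                  paste(density_level, smoking_level, sep = "-"))
  )
}

#' All nine bivariate codes
#' @return Character vector `"low-low"` ... `"high-high"`.
#' @export
bivariate_codes <- function() {
  lv <- c("low", "medium", "high")
  as.vector(t(outer(lv, lv, paste, sep = "-")))
}

#' 3x3 (+ no-service) contingency counts of bivariate classes
#'
#' @param classes Tibble from [classify_bivariate()].
#' @return Tibble: `density_level`, `smoking_level`, `n` — the nine
#'   combinations plus one `no_service` row per smoking level; counts sum to
#'   the number of classified counties.
#' @export
crosstab <- function(classes) {
  grid <- expand.grid(
    density_level = c("low", "medium", "high", "no_service"),
    smoking_level = c("low", "medium", "high"),
    stringsAsFactors = FALSE
  )
  counts <- dplyr::count(classes, .data$density_level, .data$smoking_level)
  tibble::as_tibble(grid) |>
    dplyr::left_join(counts, by = c("density_level", "smoking_level")) |>
    dplyr::mutate(n = as.integer(dplyr::coalesce(.data$n, 0L))) |>
    dplyr::arrange(match(.data$density_level, c("low", "medium", "high", "no_service")),
                   match(.data$smoking_level, c("low", "medium", "high")))
}
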