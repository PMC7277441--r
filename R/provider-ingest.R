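# Provider utilization ingest: read, validate, filter to the screening
# procedure code, aggregate services per provider, re-apply the public-use
# file's suppression floor.

PROVIDER_COLS <- c("npi", "hcpcs_code", "line_srvc_cnt", "longitude", "latitude")

#' Load a raw provider utilization table
#'
#' Expects a CSV with columns `npi, hcpcs_code, line_srvc_cnt, longitude,
#' latitude` (one row per provider x procedure code). A missing column is
#' fatal. Malformed rows — non-numeric or negative service counts,
#' non-numeric or out-of-range coordinates — are dropped with a warning that
#' reports their line numbers, and returned in the `row_errors` attribute.
#'
#' @param path CSV file path.
#' @return Tibble of valid rows with a `row_errors` attribute (tibble of
#'   `line`, `problem`).
#' @export
load_provider_table <- function(path) {
  if (!file.exists(path)) stop("provider table not found: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(PROVIDER_COLS, names(raw))
  if (length(missing) > 0) {
    stop("provider table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(raw)
  cnt <- suppressWarnings(as.numeric(raw$line_srvc_cnt))
  lon <- suppressWarnings(as.numeric(raw$longitude))
  lat <- suppressWarnings(as.numeric(raw$latitude))
  problems <- character(n)
  bad <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    problems[cond & problems == ""] <<- msg
  }
  bad(is.na(cnt) | cnt < 0 | cnt != floor(cnt), "service count not a non-negative integer")
  bad(is.na(lon) | lon < -180 | lon > 180, "longitude outside [-180, 180]")
  bad(is.na(lat) | lat < -90 | lat > 90, "latitude outside [-90, 90]")
  ok <- problems == ""
  errors <- tibble::tibble(line = which(!ok) + 1L, problem = problems[!ok])
  if (nrow(errors) > 0) {
    warning(sprintf("dropped %d malformed provider row(s) at line(s) %s",
                    nrow(errors), paste(errors$line, collapse = ", ")))
  }
  out <- tibble::tibble(
    npi = raw$npi[ok], hcpcs_code = raw$hcpcs_code[ok],
    line_srvc_cnt = as.integer(cnt[ok]), longitude = lon[ok], latitude = lat[ok]
  )
  attr(out, "row_errors") <- errors
  out
}

#' Filter to the screening code and aggregate services per provider
#'
#' Keeps rows whose procedure code matches `code`, sums service counts per
#' provider id, and drops providers whose summed count falls below
#' `min_services` — the same floor the source file applies at release, so
#' synthetic or alternative sources are handled identically. A provider id
#' appearing with more than one coordinate is a data-integrity error (a
#' silently averaged location could cross a buffer boundary).
#'
#' @param rows Tibble from [load_provider_table()].
#' @param code Procedure code to keep; default `"G0297"`.
#' @param min_services Minimum summed services to retain; default 11.
#' @return Tibble of provider records (`provider_id`, `lon`, `lat`,
#'   `total_services`), sorted by `provider_id`.
#' @export
filter_and_aggregate <- function(rows, code = "G0297", min_services = 11L) {
  stopifnot(all(PROVIDER_COLS %in% names(rows)))
  kept <- dplyr::filter(rows, .data$hcpcs_code == code)
  if (nrow(kept) == 0) {
    return(tibble::tibble(provider_id = character(), lon = numeric(),
                          lat = numeric(), total_services = integer()))
  }
  coord_check <- kept |>
    dplyr::group_by(.data$npi) |>
    dplyr::summarise(n_loc = dplyr::n_distinct(.data$longitude, .data$latitude),
                     .groups = "drop") |>
    dplyr::filter(.data$n_loc > 1)
  if (nrow(coord_check) > 0) {
    stop("conflicting coordinates for provider id(s): ",
         paste(coord_check$npi, collapse = ", "))
  }
  kept |>
    dplyr::group_by(.data$npi) |>
    dplyr::summarise(lon = .data$longitude[1], lat = .data$latitude[1],
                     total_services = as.integer(sum(.data$line_srvc_cnt)),
                     .groups = "drop") |>
    dplyr::filter(.data$total_services >= min_services) |>
    dplyr::rename(provider_id = "npi") |>
    dplyr::arrange(.data$provider_id)
}

#' Descriptive summary of provider service counts
#'
#' The SD convention is population (divide by n) by default, matching the
#' "mean ± SD" style of descriptive reporting; set `sd_type = "sample"` for
#' the n-1 convention. The median uses the midpoint convention for even n.
#'
#' @param records Provider records from [filter_and_aggregate()].
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return List: `n_providers`, `total_services`, `mean`, `sd`, `median`,
#'   `min`, `max`, and `defined` (FALSE when there are no records, in which
#'   case the statistics are NA).
#' @export
provider_summary <- function(records, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  x <- records$total_services
  n <- length(x)
  if (n == 0) {
    return(list(n_providers = 0L, total_services = 0L, mean = NA_real_,
                sd = NA_real_, median = NA_real_, min = NA_real_,
                max = NA_real_, defined = FALSE))
  }
  sdev <- if (n == 1) 0 else stats::sd(x)
  if (sd_type == "population") sdev <- sdev * sqrt((n - 1) / n)
  list(n_providers = n, total_services = as.integer(sum(x)),
       mean = mean(x), sd = sdev, median = stats::median(x),
       min = min(x), max = max(x), defined = TRUE)
}
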