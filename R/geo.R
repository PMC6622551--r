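#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the IUGG mean
#' Earth radius), the convention used for city-centroid distances
#' throughout the package. Sub-kilometre differences between Earth models
#' are immaterial at city/town resolution.
#'
#' @param a,b Numeric vectors `c(lat, lon)` in decimal degrees, or
#'   two-column matrices (lat, lon) of equal length.
#' @return Distance(s) in kilometres.
#' @export
#' @examples
#' great_circle_km(c(43.5448, -80.2482), c(45.4215, -75.6972)) # Guelph-Ottawa
great_circle_km <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 2)
  b <- matrix(as.numeric(b), ncol = 2)
  bad <- function(m) any(abs(m[, 1]) > 90, na.rm = TRUE) ||
    any(abs(m[, 2]) > 180, na.rm = TRUE)
  if (bad(a) || bad(b))
    stop("coordinates out of range: need lat in [-90,90], lon in [-180,180]")
  # geosphere expects (lon, lat)
  geosphere::distHaversine(a[, 2:1, drop = FALSE], b[, 2:1, drop = FALSE],
                           r = 6371.0088)
}

#' Per-month summaries of distances travelled per movement
#'
#' Computes the great-circle distance between the city/town centroids of
#' each movement's origin and destination and summarises them per calendar
#' month (minimum, quartiles, median, maximum). Each movement contributes
#' one distance — summaries are movement-level, not unique-pair-level.
#' Movements with either endpoint lacking coordinates are skipped and
#' counted in `n_skipped`. A distance of 0 km means both endpoints share a
#' city/town centroid. Quantiles use linear interpolation between order
#' statistics (R type 7).
#'
#' @param records Standardised movement records.
#' @param locations Location register with coordinates.
#' @param by_month Summarise per departure month (default) or pooled.
#' @return A tibble with columns `month` (absent when pooled), `n`,
#'   `n_skipped`, `minimum`, `q1`, `median`, `q3`, `maximum`.
#' @export
movement_distances <- function(records, locations, by_month = TRUE) {
  i_o <- match(records$origin_location, locations$location_id)
  i_d <- match(records$destination_location, locations$location_id)
  o <- cbind(locations$latitude[i_o], locations$longitude[i_o])
  d <- cbind(locations$latitude[i_d], locations$longitude[i_d])
  have <- stats::complete.cases(o) & stats::complete.cases(d)
  km <- rep(NA_real_, nrow(records))
  if (any(have)) km[have] <- great_circle_km(o[have, , drop = FALSE],
                                             d[have, , drop = FALSE])
  tab <- tibble::tibble(month = month_label(records$departure_date), km = km)
  if (!by_month) tab$month <- "all"
  tab |>
    dplyr::summarise(
      n = sum(!is.na(.data$km)),
      n_skipped = sum(is.na(.data$km)),
      minimum = min(.data$km, na.rm = TRUE),
      q1 = stats::quantile(.data$km, 0.25, na.rm = TRUE, names = FALSE),
      median = stats::median(.data$km, na.rm = TRUE),
      q3 = stats::quantile(.data$km, 0.75, na.rm = TRUE, names = FALSE),
      maximum = max(.data$km, na.rm = TRUE),
      .by = "month") |>
    dplyr::filter(.data$n > 0) |>
    dplyr::arrange(.data$month)
}

#' Within/between-region movement flows for one month
#'
#' Cross-tabulates retained movements by the census region of their origin
#' and destination. The within-region fraction is the trace of the flow
#' matrix over its total.
#'
#' @param records Standardised movement records.
#' @param locations Location register with regions.
#' @param month Month label (`"YYYY-MM"`), or `NULL` to pool the whole
#'   period.
#' @return An object of class `region_flow`: a list with `month`, `flows`
#'   (square count matrix over the regions present) and `within_fraction`.
#' @export
region_flows <- function(records, locations, month = NULL) {
  if (!is.null(month))
    records <- records[month_label(records$departure_date) == month, ,
                       drop = FALSE]
  from <- locations$region[match(records$origin_location,
                                 locations$location_id)]
  to <- locations$region[match(records$destination_location,
                               locations$location_id)]
  regions <- sort(unique(c(from, to)))
  flows <- table(factor(from, levels = regions), factor(to, levels = regions))
  flows <- unclass(matrix(as.integer(flows), nrow = length(regions),
                          dimnames = list(regions, regions)))
  total <- sum(flows)
  structure(list(
    month = month %||% "all",
    flows = flows,
    within_fraction = if (total > 0) sum(diag(flows)) / total else NA_real_),
    class = "region_flow")
}

#' @export
print.region_flow <- function(x, ...) {
  cat("Region flows,", x$month, "-", sum(x$flows), "movements,",
      sprintf("%.1f%% within region\n", 100 * x$within_fraction))
  print(x$flows)
  invisible(x)
}

#' Region flow series over all months
#'
#' @param records Standardised movement records.
#' @param locations Location register.
#' @return A list with `flows` (long tibble: `month`, `from_region`,
#'   `to_region`, `n`) and `within` (tibble: `month`, `n_within`, `n_total`,
#'   `within_fraction`).
#' @export
region_flow_series <- function(records, locations) {
  months <- sort(unique(month_label(records$departure_date)))
  per <- lapply(months, function(m) region_flows(records, locations, m))
  long <- dplyr::bind_rows(lapply(per, function(rf) {
    df <- as.data.frame(as.table(rf$flows), stringsAsFactors = FALSE)
    names(df) <- c("from_region", "to_region", "n")
    dplyr::mutate(tibble::as_tibble(df), month = rf$month, .before = 1)
  }))
  within <- tibble::tibble(
    month = months,
    n_within = vapply(per, function(rf) sum(diag(rf$flows)), numeric(1)),
    n_total = vapply(per, function(rf) sum(rf$flows), numeric(1)))
  within$within_fraction <- ifelse(within$n_total > 0,
                                   within$n_within / within$n_total, NA_real_)
  list(flows = long, within = within)
}
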