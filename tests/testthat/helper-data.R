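# Compact movement-record builder for fixtures. Dates given as strings.
mk_records <- function(..., participant = "P1", horse = "H1",
                       discipline = "leisure") {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      participant_id = r$participant %||% participant,
      horse_id = r$horse %||% horse,
      discipline = r$discipline %||% discipline,
      origin_name = r$origin %||% "Home A",
      origin_city = r$origin_city %||% "Alpha",
      destination_name = r$dest %||% NA_character_,
      destination_city = r$dest_city %||% "Beta",
      departure_date = as.Date(r$dep),
      return_date = if (is.null(r$ret)) as.Date(NA) else as.Date(r$ret),
      reason = r$reason %||% "riding",
      sanctioned = NA)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mov <- function(dep, ret = NULL, ...) c(list(dep = dep, ret = ret), list(...))

# four-city gazetteer with two regions; Alpha-Beta ~ 55 km apart
tiny_gazetteer <- function() {
  tibble::tibble(
    city_town = c("Alpha", "Beta", "Gamma", "Delta"),
    latitude = c(43.50, 44.00, 43.60, 45.40),
    longitude = c(-80.25, -80.25, -79.50, -75.70),
    region = c("western", "western", "central", "eastern"))
}

# small, fast synthetic configuration for structural tests
small_config <- function(seed = 1L, ...) {
  synthetic_config(seed = seed, n_participants = 40L,
                   cities_per_region = 12L, ...)
}
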