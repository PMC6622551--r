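#' Default keyword table mapping free-text travel reasons to categories
#'
#' Open-ended questionnaire answers are mapped onto the reason categories
#' used throughout the analysis (`competition`, `riding`, `training`,
#' `healthcare`, `boarding_change`, `other`). Matching is case-insensitive
#' substring matching, first hit wins; anything unmatched becomes `other`.
#' Users can extend the table with their own keywords and pass it to
#' [read_movements()].
#'
#' @return A tibble with columns `keyword` and `reason`.
#' @export
#' @examples
#' default_reason_table()
default_reason_table <- function() {
  tibble::tribble(
    ~keyword,       ~reason,
    "competition",  "competition",
    "show",         "competition",
    "event",        "competition",
    "race",         "competition",
    "ride",         "riding",
    "riding",       "riding",
    "trail",        "riding",
    "hack",         "riding",
    "park",         "riding",
    "training",     "training",
    "lesson",       "training",
    "clinic",       "training",
    "schooling",    "training",
    "vet",          "healthcare",
    "clinic vet",   "healthcare",
    "health",       "healthcare",
    "farrier",      "healthcare",
    "breeding",     "healthcare",
    "hospital",     "healthcare",
    "boarding",     "boarding_change",
    "moved barns",  "boarding_change",
    "new home",     "boarding_change",
    "permanent",    "boarding_change"
  )
}

#' @keywords internal
normalise_reason <- function(x, reason_table = default_reason_table()) {
  out <- rep("other", length(x))
  lx <- tolower(trimws(as.character(x)))
  canon <- c("competition", "riding", "training", "healthcare",
             "boarding_change", "other")
  exact <- lx %in% canon
  out[exact] <- lx[exact]
  todo <- which(!exact & !is.na(lx) & lx != "")
  for (i in todo) {
    hit <- which(vapply(reason_table$keyword,
                        function(k) grepl(k, lx[i], fixed = TRUE), logical(1)))
    if (length(hit)) out[i] <- reason_table$reason[hit[1]]
  }
  out[is.na(lx)] <- "other"
  out
}

#' @keywords internal
normalise_discipline <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[lx %in% c("competition", "comp")] <- "competition"
  out[lx %in% c("leisure", "pleasure", "companion", "companionship")] <- "leisure"
  out[grepl("rac|standardbred|thoroughbred", lx)] <- "racing"
  out
}

# Canonical movement-record columns, in storage order.
movement_columns <- function() {
  c("participant_id", "horse_id", "discipline",
    "origin_name", "origin_city", "destination_name", "destination_city",
    "departure_date", "return_date", "reason", "sanctioned")
}

#' Read a movement diary table
#'
#' Ingests a delimited movement table (one row per horse movement) into the
#' canonical record format. Rows whose mandatory fields cannot be parsed
#' (missing participant or horse identifier, or an unparseable date string)
#' are returned in a `rejects` table with a reason code rather than silently
#' dropped; missing-but-parseable fields (e.g. an absent return date) are
#' retained and handled by [apply_inclusion_criteria()]. Exact duplicate
#' rows are collapsed with a warning (questionnaire re-submissions); rows
#' that duplicate another row's (horse, departure date, destination) are
#' flagged with a warning but kept.
#'
#' @param path Path to a CSV file, or a data frame already in memory.
#' @param schema Optional named character vector mapping canonical field
#'   names (see Details) to the column names used in the file. Fields not
#'   named in the schema are looked up under their canonical name.
#' @param reason_table Keyword table for free-text reasons, see
#'   [default_reason_table()].
#'
#' @details Canonical fields: `participant_id`, `horse_id`, `discipline`
#'   (competition/leisure/racing), `origin_name`, `origin_city`,
#'   `destination_name`, `destination_city`, `departure_date`,
#'   `return_date` (absent means a permanent move), `reason`, `sanctioned`.
#'   Dates must be ISO-8601 (`YYYY-MM-DD`).
#'
#' @return A list with elements `records` (tibble of parsed records) and
#'   `rejects` (tibble of rejected raw rows with a `reject_reason` column).
#' @export
read_movements <- function(path, schema = NULL,
                           reason_table = default_reason_table()) {
  if (is.character(path)) {
    if (!file.exists(path)) stop("movement file not found: ", path)
    raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  } else {
    raw <- tibble::as_tibble(path)
    raw[] <- lapply(raw, as.character)
  }

  fields <- movement_columns()
  colmap <- stats::setNames(fields, fields)
  if (!is.null(schema)) {
    unknown <- setdiff(names(schema), fields)
    if (length(unknown))
      stop("schema names unknown fields: ", paste(unknown, collapse = ", "))
    colmap[names(schema)] <- schema
  }
  mapped_missing <- setdiff(
    colmap[c("participant_id", "horse_id", "departure_date",
             "destination_city", "reason")],
    names(raw))
  if (length(mapped_missing))
    stop("columns absent from input: ", paste(mapped_missing, collapse = ", "))

  get_col <- function(field) {
    cn <- colmap[[field]]
    if (cn %in% names(raw)) raw[[cn]] else rep(NA_character_, nrow(raw))
  }
  parse_date <- function(x) as.Date(x, format = "%Y-%m-%d")
  blank_to_na <- function(x) {
    x <- trimws(x)
    x[!is.na(x) & x == ""] <- NA_character_
    x
  }

  dep_raw <- blank_to_na(get_col("departure_date"))
  ret_raw <- blank_to_na(get_col("return_date"))
  dep <- parse_date(dep_raw)
  ret <- parse_date(ret_raw)

  reject_reason <- rep(NA_character_, nrow(raw))
  pid <- blank_to_na(get_col("participant_id"))
  hid <- blank_to_na(get_col("horse_id"))
  reject_reason[is.na(pid) | is.na(hid)] <- "missing_identifier"
  bad_dep <- !is.na(dep_raw) & is.na(dep)
  bad_ret <- !is.na(ret_raw) & is.na(ret)
  reject_reason[is.na(reject_reason) & (bad_dep | bad_ret)] <- "unparseable_date"
  inverted <- !is.na(dep) & !is.na(ret) & ret < dep
  reject_reason[is.na(reject_reason) & inverted] <- "return_before_departure"

  records <- tibble::tibble(
    participant_id   = pid,
    horse_id         = hid,
    discipline       = normalise_discipline(get_col("discipline")),
    origin_name      = blank_to_na(get_col("origin_name")),
    origin_city      = blank_to_na(get_col("origin_city")),
    destination_name = blank_to_na(get_col("destination_name")),
    destination_city = blank_to_na(get_col("destination_city")),
    departure_date   = dep,
    return_date      = ret,
    reason           = normalise_reason(get_col("reason"), reason_table),
    sanctioned       = as.logical(toupper(blank_to_na(get_col("sanctioned"))))
  )

  ok <- is.na(reject_reason)
  rejects <- raw[!ok, , drop = FALSE]
  rejects$reject_reason <- reject_reason[!ok]
  records <- records[ok, , drop = FALSE]

  dup <- duplicated(records)
  if (any(dup)) {
    warning(sum(dup), " exact duplicate row(s) collapsed")
    records <- records[!dup, , drop = FALSE]
  }
  key <- paste(records$horse_id, records$departure_date,
               records$destination_city, records$destination_name, sep = "\r")
  if (anyDuplicated(key))
    warning(sum(duplicated(key)),
            " row(s) share (horse, departure date, destination) with another row")

  list(records = records, rejects = tibble::as_tibble(rejects))
}

#' Apply the study inclusion criteria to movement records
#'
#' A record is kept when it carries complete dates of movement (a departure
#' date, and a return date unless the movement is a permanent boarding
#' change) and at least the city/town of the destination. Racing-discipline
#' records are excluded from analysis. The filter is exhaustive: every input
#' record lands in exactly one of `kept` or `excluded`, and excluded records
#' carry a reason code (`racehorse`, `incomplete_dates`, `no_destination`).
#'
#' @param records A movement record tibble, as from [read_movements()].
#' @return A list with elements `kept` and `excluded`; `excluded` has an
#'   extra `exclusion_code` column.
#' @export
apply_inclusion_criteria <- function(records) {
  code <- rep(NA_character_, nrow(records))
  racing <- !is.na(records$discipline) & records$discipline == "racing"
  code[racing] <- "racehorse"
  incomplete <- is.na(records$departure_date) |
    (is.na(records$return_date) & records$reason != "boarding_change")
  code[is.na(code) & incomplete] <- "incomplete_dates"
  code[is.na(code) & is.na(records$destination_city)] <- "no_destination"

  excluded <- records[!is.na(code), , drop = FALSE]
  excluded$exclusion_code <- code[!is.na(code)]
  list(kept = records[is.na(code), , drop = FALSE], excluded = excluded)
}

#' Standardise locations against an alias table and gazetteer
#'
#' Resolves participant-reported location names through a table of aliases
#' (e.g. "OVC" for "Ontario Veterinary College") and assigns coordinates and
#' a census region by looking the city/town up in a gazetteer. A location is
#' identified by its (canonical name, city/town) pair, so two participants
#' reporting unresolvable names ("my friend's farm") in the same city remain
#' distinct locations — the double counting that open-ended questionnaires
#' make unavoidable is preserved rather than guessed away. Cities absent
#' from the gazetteer get the fallback region and no coordinates.
#'
#' The operation is idempotent: re-standardising already standardised
#' records yields identical location keys.
#'
#' @param records Movement record tibble (origin/destination name and city).
#' @param aliases Optional tibble with columns `raw_name`, `canonical_name`.
#' @param gazetteer Optional tibble with columns `city_town`, `latitude`,
#'   `longitude`, `region`. A city mapped to two different coordinate pairs
#'   is an error.
#' @param fallback_region Region assigned to cities missing from the
#'   gazetteer (default `"out_of_province"`).
#'
#' @return A list with `records` (input plus `origin_location` and
#'   `destination_location` key columns) and `locations` (tibble with
#'   `location_id`, `name`, `city_town`, `region`, `latitude`, `longitude`).
#' @export
standardise_locations <- function(records, aliases = NULL, gazetteer = NULL,
                                  fallback_region = "out_of_province") {
  resolve <- function(nm) {
    if (is.null(aliases) || !nrow(aliases)) return(nm)
    i <- match(nm, aliases$raw_name)
    ifelse(!is.na(i), aliases$canonical_name[i], nm)
  }
  o_name <- resolve(records$origin_name)
  d_name <- resolve(records$destination_name)
  key <- function(nm, city) paste(ifelse(is.na(nm), "", nm),
                                  ifelse(is.na(city), "", city), sep = "\r")
  o_key <- key(o_name, records$origin_city)
  d_key <- key(d_name, records$destination_city)

  all_keys <- sort(unique(c(o_key, d_key)))
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  loc_name <- vapply(parts, function(p) if (p[1] == "") NA_character_ else p[1],
                     character(1))
  loc_city <- vapply(parts, function(p) if (length(p) < 2 || p[2] == "")
    NA_character_ else p[2], character(1))
  location_id <- sprintf("LOC%04d", seq_along(all_keys))

  lat <- lon <- rep(NA_real_, length(all_keys))
  region <- rep(fallback_region, length(all_keys))
  if (!is.null(gazetteer) && nrow(gazetteer)) {
    gz <- dplyr::distinct(tibble::as_tibble(gazetteer))
    if (anyDuplicated(tolower(gz$city_town))) {
      dupes <- unique(gz$city_town[duplicated(tolower(gz$city_town))])
      stop("gazetteer conflict: city mapped to multiple entries: ",
           paste(dupes, collapse = ", "))
    }
    i <- match(tolower(loc_city), tolower(gz$city_town))
    hit <- !is.na(i)
    lat[hit] <- gz$latitude[i[hit]]
    lon[hit] <- gz$longitude[i[hit]]
    region[hit] <- gz$region[i[hit]]
  }
  locations <- tibble::tibble(
    location_id = location_id, name = loc_name, city_town = loc_city,
    region = region, latitude = lat, longitude = lon)

  out <- records
  out$origin_name <- o_name
  out$destination_name <- d_name
  out$origin_location <- location_id[match(o_key, all_keys)]
  out$destination_location <- location_id[match(d_key, all_keys)]
  list(records = out, locations = locations)
}

#' Classify monthly location types
#'
#' Each location active in a month gets the single purpose observed there
#' that month — `home` (an origin facility where a horse is kept, or the
#' destination of a permanent boarding change), or the travel-reason type of
#' the movements that visited it (`competition`, `riding`, `training`,
#' `healthcare`, `other`) — or `mixed` when more than one distinct purpose
#' was observed that month. A trip spanning a month boundary marks both its
#' endpoints in both months (the horse is at the destination in both).
#'
#' @param records Standardised movement records (with location key columns).
#' @param locations Location register from [standardise_locations()]
#'   (unused except for validation; may be `NULL`).
#' @return A tibble with columns `location_id`, `month`, `type`.
#' @export
classify_location_types <- function(records, locations = NULL) {
  if (!nrow(records))
    return(tibble::tibble(location_id = character(), month = character(),
                          type = character()))
  dest_purpose <- ifelse(records$reason == "boarding_change", "home",
                         records$reason)
  dep_m <- month_label(records$departure_date)
  ret_m <- ifelse(is.na(records$return_date), NA_character_,
                  month_label(records$return_date))
  obs <- tibble::tibble(
    location_id = c(records$origin_location, records$destination_location),
    month = c(dep_m, dep_m),
    purpose = c(rep("home", nrow(records)), dest_purpose))
  span <- !is.na(ret_m) & ret_m != dep_m
  if (any(span)) {
    obs <- dplyr::bind_rows(obs, tibble::tibble(
      location_id = c(records$origin_location[span],
                      records$destination_location[span]),
      month = c(ret_m[span], ret_m[span]),
      purpose = c(rep("home", sum(span)), dest_purpose[span])))
  }
  obs |>
    dplyr::distinct(.data$location_id, .data$month, .data$purpose) |>
    dplyr::summarise(
      type = if (dplyr::n() > 1) "mixed" else .data$purpose[1],
      .by = c("location_id", "month")) |>
    dplyr::arrange(.data$location_id, .data$month)
}

#' Questionnaire completeness scenarios
#'
#' `scenario_spec()` resolves a scenario name to its minimum number of
#' completed monthly questionnaires out of the seven study months:
#' `any` requires at least 1, `most` at least 5, `all` all 7.
#'
#' @param name One of `"any"`, `"most"`, `"all"`.
#' @return A list with elements `name` and `min_questionnaires`.
#' @export
scenario_spec <- function(name = c("any", "most", "all")) {
  name <- match.arg(name)
  list(name = name,
       min_questionnaires = c(any = 1L, most = 5L, all = 7L)[[name]])
}

#' Build a participant-by-month questionnaire response table from records
#'
#' When no explicit response table accompanies the data, a month counts as
#' completed for a participant if any record of theirs exists for it (by
#' departure month). An explicit table, when available, is preferable since
#' it can encode "no movements this month" submissions, which also count as
#' completed questionnaires.
#'
#' @param records Movement record tibble.
#' @param months Character vector of month labels (`"YYYY-MM"`) defining the
#'   study period; defaults to the range spanned by the departure dates.
#' @return A tibble with columns `participant_id`, `month`, `responded`.
#' @export
completeness_table <- function(records, months = NULL) {
  if (is.null(months)) {
    r <- range(records$departure_date, na.rm = TRUE)
    months <- month_label(seq(as.Date(format(r[1], "%Y-%m-01")),
                              as.Date(format(r[2], "%Y-%m-01")), by = "1 month"))
  }
  seen <- tibble::tibble(participant_id = records$participant_id,
                         month = month_label(records$departure_date)) |>
    dplyr::distinct()
  tidyr::expand_grid(participant_id = unique(records$participant_id),
                     month = months) |>
    dplyr::left_join(dplyr::mutate(seen, responded = TRUE),
                     by = c("participant_id", "month")) |>
    dplyr::mutate(responded = !is.na(.data$responded))
}

#' Filter records by questionnaire data-completeness scenario
#'
#' Retains only the records of participants who completed at least the
#' scenario's minimum number of monthly questionnaires. Because the
#' thresholds are nested (1/5/7 of 7), the retained participant sets are
#' nested too: `all` is a subset of `most` is a subset of `any`.
#'
#' @param records Movement record tibble.
#' @param response_table Optional tibble (`participant_id`, `month`,
#'   `responded`); inferred from the records via [completeness_table()]
#'   when `NULL`.
#' @param scenario Scenario name or a [scenario_spec()] list.
#' @param months Study months, passed to [completeness_table()] when the
#'   response table is inferred.
#' @return The subset of `records` belonging to retained participants, with
#'   the retained participant ids in attribute `"participants"`.
#' @export
filter_by_completeness <- function(records, response_table = NULL,
                                   scenario = "most", months = NULL) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  if (is.null(response_table))
    response_table <- completeness_table(records, months)
  n_done <- response_table |>
    dplyr::summarise(n = sum(.data$responded), .by = "participant_id")
  keep_ids <- n_done$participant_id[n_done$n >= scenario$min_questionnaires]
  out <- records[records$participant_id %in% keep_ids, , drop = FALSE]
  attr(out, "participants") <- sort(keep_ids)
  out
}
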