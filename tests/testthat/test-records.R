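test_that("read_movements parses rows and returns malformed rows as rejects", {
  tab <- tibble::tibble(
    participant_id = c("P1", "P1", "P2"),
    horse_id = c("H1", "H2", "H3"),
    discipline = c("competition", "leisure", "Leisure"),
    origin_name = "Home", origin_city = "Alpha",
    destination_name = c("Trails", NA, "Showgrounds"),
    destination_city = c("Beta", "Beta", "Gamma"),
    departure_date = c("2015-05-02", "not-a-date", "2015-06-10"),
    return_date = c("2015-05-03", "2015-05-04", "2015-06-11"),
    reason = c("weekend show", "trail ride", "lesson with coach"),
    sanctioned = c("TRUE", NA, NA))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tab, path)

  out <- read_movements(path)
  expect_equal(nrow(out$records), 2)
  expect_equal(nrow(out$rejects), 1)
  expect_equal(out$rejects$reject_reason, "unparseable_date")
  expect_equal(out$records$reason, c("competition", "training"))
  expect_equal(out$records$discipline, c("competition", "leisure"))
  expect_s3_class(out$records$departure_date, "Date")
  expect_true(out$records$sanctioned[1])
})

test_that("read_movements honours a column-mapping schema and flags duplicates", {
  tab <- tibble::tibble(
    owner = c("P1", "P1", "P1"),
    horse = c("H1", "H1", "H1"),
    dest_town = "Beta", why = "riding",
    left_on = "2015-05-02", back_on = "2015-05-02")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tab, path)
  schema <- c(participant_id = "owner", horse_id = "horse",
              destination_city = "dest_town", reason = "why",
              departure_date = "left_on", return_date = "back_on")
  expect_warning(out <- read_movements(path, schema = schema),
                 "duplicate")
  expect_equal(nrow(out$records), 1)
  expect_error(read_movements(path, schema = c(participant_id = "nope")),
               "absent")
  expect_error(read_movements(path, schema = c(not_a_field = "owner")),
               "unknown fields")
})

test_that("records written out and re-read round-trip all retained fields", {
  rec <- mk_records(
    mov("2015-05-02", "2015-05-03", dest = "Trails", reason = "riding"),
    mov("2015-07-10", NULL, reason = "boarding_change", dest_city = "Gamma"),
    mov("2015-06-01", "2015-06-02", reason = "competition",
        discipline = "competition"))
  rec$sanctioned <- c(NA, NA, TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(rec, path)
  again <- read_movements(path)$records
  expect_equal(as.data.frame(again), as.data.frame(rec))
})

test_that("inclusion criteria partition records with the right reason codes", {
  rec <- mk_records(
    mov("2015-05-02", "2015-05-03"),                             # kept
    mov("2015-05-02", "2015-05-03", dest_city = NULL),           # no city
    mov("2015-05-02", NULL, reason = "competition"),             # no return
    mov("2015-05-02", NULL, reason = "boarding_change"),         # permanent ok
    mov("2015-05-02", "2015-05-03", discipline = "racing"))      # racehorse
  rec$destination_city[2] <- NA
  out <- apply_inclusion_criteria(rec)
  expect_equal(nrow(out$kept) + nrow(out$excluded), nrow(rec))
  expect_equal(nrow(out$kept), 2)
  expect_setequal(out$excluded$exclusion_code,
                  c("no_destination", "incomplete_dates", "racehorse"))
  # permanent move with absent return date is retained
  expect_true("boarding_change" %in% out$kept$reason)
})

test_that("alias resolution merges raw spellings into one location", {
  rec <- mk_records(
    mov("2015-05-02", "2015-05-03", dest = "OVC", dest_city = "Guelph"),
    mov("2015-06-02", "2015-06-03", dest = "Ontario Veterinary College",
        dest_city = "Guelph"))
  aliases <- tibble::tibble(raw_name = "OVC",
                            canonical_name = "Ontario Veterinary College")
  merged <- standardise_locations(rec, aliases = aliases)
  expect_equal(nrow(merged$locations), 2)  # home + clinic
  expect_equal(merged$records$destination_location[1],
               merged$records$destination_location[2])

  unmerged <- standardise_locations(rec)
  expect_equal(nrow(unmerged$locations), 3)
})

test_that("standardisation keys by (name, city), is idempotent, and uses the gazetteer", {
  rec <- mk_records(
    mov("2015-05-02", "2015-05-03", dest = "Trails", dest_city = "Beta"),
    mov("2015-05-09", "2015-05-10", dest = "Trails", dest_city = "Gamma"),
    mov("2015-05-16", "2015-05-17", dest = "Trails", dest_city = "Nowhere"))
  out <- standardise_locations(rec, gazetteer = tiny_gazetteer())
  # same venue name in two cities stays two locations
  expect_equal(nrow(out$locations), 4)
  nw <- out$locations[out$locations$city_town == "Nowhere", ]
  expect_equal(nw$region, "out_of_province")
  expect_true(is.na(nw$latitude))
  expect_equal(out$locations$region[out$locations$city_town == "Beta"],
               "western")

  twice <- standardise_locations(out$records, gazetteer = tiny_gazetteer())
  expect_equal(twice$records$destination_location,
               out$records$destination_location)
  expect_equal(twice$locations, out$locations)

  conflicted <- dplyr::bind_rows(
    tiny_gazetteer(),
    tibble::tibble(city_town = "Beta", latitude = 1, longitude = 1,
                   region = "central"))
  expect_error(standardise_locations(rec, gazetteer = conflicted),
               "conflict")
})

test_that("monthly location types reflect single or mixed purposes", {
  rec <- mk_records(
    mov("2015-06-06", "2015-06-06", dest = "Trails", dest_city = "Beta",
        reason = "riding"),
    mov("2015-07-04", "2015-07-05", participant = "P2", horse = "H2",
        origin = "Home B", origin_city = "Gamma",
        dest = "Home A", dest_city = "Alpha", reason = "competition"),
    mov("2015-07-11", "2015-07-11", dest = "Trails", dest_city = "Beta",
        reason = "riding"),
    mov("2015-05-03", "2015-05-03", dest = "Clinic", dest_city = "Gamma",
        reason = "healthcare"),
    mov("2015-08-08", "2015-08-08", dest = "Clinic", dest_city = "Gamma",
        reason = "riding"))
  std <- standardise_locations(rec)
  ty <- classify_location_types(std$records, std$locations)
  type_of <- function(name, city, month) {
    loc <- std$locations$location_id[
      !is.na(std$locations$name) & std$locations$name == name &
        std$locations$city_town == city]
    ty$type[ty$location_id == loc & ty$month == month]
  }
  expect_equal(type_of("Trails", "Beta", "2015-06"), "riding")
  # a home facility that also hosts a competition that month is mixed use
  expect_equal(type_of("Home A", "Alpha", "2015-07"), "mixed")
  # per-month independence of the same location's type
  expect_equal(type_of("Clinic", "Gamma", "2015-05"), "healthcare")
  expect_equal(type_of("Clinic", "Gamma", "2015-08"), "riding")
})

test_that("completeness scenarios keep participants by questionnaire count", {
  months <- sprintf("2015-%02d", 5:11)
  resp <- tidyr::expand_grid(participant_id = c("P1", "P2"), month = months)
  resp$responded <- c(rep(TRUE, 7), c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE,
                                      FALSE))
  rec <- mk_records(mov("2015-05-02", "2015-05-03"),
                    mov("2015-05-09", "2015-05-10", participant = "P2",
                        horse = "H2"))
  for (sc in c("any", "most", "all")) {
    kept <- filter_by_completeness(rec, resp, sc)
    expect_true("P1" %in% attr(kept, "participants"), label = sc)
  }
  expect_true("P2" %in%
                attr(filter_by_completeness(rec, resp, "any"), "participants"))
  expect_false("P2" %in%
                 attr(filter_by_completeness(rec, resp, "most"),
                      "participants"))
  expect_error(filter_by_completeness(rec, resp, "some"))
})

test_that("scenario participant sets are nested for random response patterns", {
  set.seed(42)
  months <- sprintf("2015-%02d", 5:11)
  rec <- mk_records(mov("2015-05-02", "2015-05-03"))
  for (i in 1:25) {
    ids <- paste0("P", 1:30)
    resp <- tidyr::expand_grid(participant_id = ids, month = months)
    resp$responded <- runif(nrow(resp)) < runif(1)
    rec_i <- dplyr::bind_rows(lapply(ids, function(p) {
      r <- rec
      r$participant_id <- p
      r
    }))
    p_any <- attr(filter_by_completeness(rec_i, resp, "any"), "participants")
    p_most <- attr(filter_by_completeness(rec_i, resp, "most"), "participants")
    p_all <- attr(filter_by_completeness(rec_i, resp, "all"), "participants")
    expect_true(all(p_all %in% p_most))
    expect_true(all(p_most %in% p_any))
  }
})

test_that("completeness is inferred from record presence when no table is given", {
  rec <- mk_records(
    mov("2015-05-02", "2015-05-03"),
    mov("2015-06-02", "2015-06-03"),
    mov("2015-07-02", "2015-07-03"),
    mov("2015-08-02", "2015-08-03"),
    mov("2015-09-02", "2015-09-03"),
    mov("2015-05-09", "2015-05-10", participant = "P2", horse = "H2"))
  months <- sprintf("2015-%02d", 5:11)
  ct <- completeness_table(rec, months)
  expect_equal(sum(ct$responded[ct$participant_id == "P1"]), 5)
  kept <- filter_by_completeness(rec, scenario = "most", months = months)
  expect_equal(attr(kept, "participants"), "P1")
})
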