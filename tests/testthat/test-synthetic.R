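test_that("generation is bit-identical under the same seed and config", {
  a <- generate_movement_data(small_config(seed = 4))
  b <- generate_movement_data(small_config(seed = 4))
  expect_identical(a$movements, b$movements)
  expect_identical(a$movements_full, b$movements_full)
  expect_identical(a$response, b$response)
  expect_identical(a$gazetteer, b$gazetteer)
  c_ <- generate_movement_data(small_config(seed = 5))
  expect_false(identical(a$movements_full, c_$movements_full))
})

test_that("an empty population produces an empty, well-typed data set", {
  d <- generate_movement_data(synthetic_config(seed = 1,
                                               n_participants = 0L))
  expect_equal(nrow(d$movements_full), 0)
  expect_equal(nrow(d$participants), 0)
  expect_named(d$movements_full,
               c("participant_id", "horse_id", "discipline", "origin_name",
                 "origin_city", "destination_name", "destination_city",
                 "departure_date", "return_date", "reason", "sanctioned"))
})

test_that("forcing round trips makes every monthly network fully reciprocal", {
  d <- generate_movement_data(small_config(seed = 2, p_round_trip = 1))
  std <- standardise_locations(d$movements_full, gazetteer = d$gazetteer)
  nets <- build_monthly_networks(std$records, std$locations,
                                 names(d$config$monthly_totals))
  recs <- vapply(nets, net_reciprocity, numeric(1))
  expect_true(all(recs[!is.na(recs)] == 1))
  expect_true(all(!is.na(d$movements_full$return_date)))
})

test_that("a unit weekend multiplier gives a uniform day-of-week profile", {
  d <- generate_movement_data(synthetic_config(seed = 6,
                                               weekend_multiplier = 1))
  share <- prop.table(table(format(d$movements_full$departure_date, "%u")))
  expect_equal(length(share), 7)
  expect_true(all(abs(share - 1 / 7) < 0.035))
  # and the default upweights Saturdays and Sundays
  d2 <- generate_movement_data(synthetic_config(seed = 6))
  share2 <- prop.table(table(format(d2$movements_full$departure_date, "%u")))
  expect_gt(min(share2[c("6", "7")]), max(share2[as.character(1:5)]))
})

test_that("full response makes the three completeness scenarios coincide", {
  d <- generate_movement_data(small_config(
    seed = 3, alias_fraction = 0,
    response_model = list(p_dropout = 0, p_respond = 1,
                          p_respond_dropout = 1)))
  expect_true(all(d$response$responded))
  expect_identical(d$movements, d$movements_full)
  sets <- lapply(c("any", "most", "all"), function(s)
    attr(filter_by_completeness(d$movements, d$response, s), "participants"))
  expect_identical(sets[[1]], sets[[2]])
  expect_identical(sets[[2]], sets[[3]])
})

test_that("raising the response probability never shrinks retained participants", {
  for (seed in 1:3) {
    lo <- generate_movement_data(small_config(
      seed = seed, response_model = list(p_dropout = 0, p_respond = 0.6,
                                         p_respond_dropout = 0.6)))
    hi <- generate_movement_data(small_config(
      seed = seed, response_model = list(p_dropout = 0, p_respond = 0.9,
                                         p_respond_dropout = 0.9)))
    p_lo <- attr(filter_by_completeness(lo$movements_full, lo$response,
                                        "most"), "participants")
    p_hi <- attr(filter_by_completeness(hi$movements_full, hi$response,
                                        "most"), "participants")
    expect_true(all(p_lo %in% p_hi))
  }
})

test_that("the discipline mix tracks its configured proportion", {
  frac <- vapply(1:20, function(s) {
    pop <- generate_population(synthetic_config(seed = s,
                                                n_participants = 141L))
    mean(pop$horses$discipline == "competition")
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.636), 0.05)
})

test_that("horses per owner are right-skewed with median 1 and IQR 1-3", {
  pop <- generate_population(synthetic_config(seed = 10))
  n <- table(pop$horses$participant_id)
  counts <- as.numeric(n[match(pop$participants$participant_id, names(n))])
  expect_equal(median(counts), 1)
  expect_equal(unname(quantile(counts, 0.25)), 1)
  expect_lte(unname(quantile(counts, 0.75)), 3)
  expect_lte(max(counts), 10)
})

test_that("alias spellings resolve back to ground-truth locations", {
  d <- generate_movement_data(small_config(seed = 12, alias_fraction = 0.3))
  expect_gt(nrow(d$aliases), 0)
  expect_true(any(d$movements$destination_name %in% d$aliases$raw_name))
  resolved <- standardise_locations(d$movements, aliases = d$aliases,
                                    gazetteer = d$gazetteer)
  truth_names <- unique(c(d$movements_full$origin_name,
                          d$movements_full$destination_name))
  expect_true(all(resolved$locations$name %in% truth_names))
})

test_that("questionnaire non-response deletes exactly the unanswered months", {
  d <- generate_movement_data(small_config(seed = 8))
  missing_keys <- with(d$response[!d$response$responded, ],
                       paste(participant_id, month))
  view_keys <- paste(d$movements$participant_id,
                     format(d$movements$departure_date, "%Y-%m"))
  expect_false(any(view_keys %in% missing_keys))
  # ground truth is a superset of the questionnaire view
  expect_gte(nrow(d$movements_full), nrow(d$movements))
})

test_that("permanent boarding changes update the home facility", {
  d <- generate_movement_data(synthetic_config(seed = 15))
  perm <- d$movements_full[d$movements_full$reason == "boarding_change", ]
  expect_gt(nrow(perm), 0)
  expect_true(all(is.na(perm$return_date)))
  expect_true(all(format(perm$departure_date, "%m") %in% c("10", "11")))
  once <- names(which(table(perm$participant_id) == 1))
  for (p in once) {
    prow <- perm[perm$participant_id == p, ]
    after <- d$movements_full[
      d$movements_full$participant_id == p &
        d$movements_full$departure_date > prow$departure_date, ]
    if (nrow(after)) expect_true(all(after$origin_name ==
                                       prow$destination_name))
  }
})

test_that("recover_parameters reports targets, tolerances and verdicts", {
  d <- generate_movement_data(synthetic_config(seed = 2))
  rp <- recover_parameters(d)
  expect_setequal(rp$statistic,
                  c("competition_horse_fraction", "within_region_fraction",
                    "median_distance_km", "reciprocity",
                    "sanctioned_fraction", "n_movements"))
  expect_type(rp$ok, "logical")
  expect_true(all(is.finite(rp$recovered)))
})
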