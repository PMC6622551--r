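#' Configuration for the synthetic movement-diary generator
#'
#' Defaults encode the statistical structure of a 7-month (May-November)
#' Ontario equestrian-season cohort: 197 enrolled owners with a right-skewed
#' horses-per-owner distribution (median 1, IQR 1-3, about 2.4 horses per
#' owner), 63.6% of horses kept for competition, monthly movement totals
#' peaking in May and August and declining into November, weekend-peaked
#' departure days, a log-normal distance kernel with median 47 km and 75th
#' percentile near 88 km, 73% of movements staying within their census
#' region, 95% of movements returning to the origin within the month
#' (reciprocity), occasional permanent boarding changes late in the season,
#' per-participant monthly questionnaire non-response, and 34.3% of
#' competition movements being sanctioned events.
#'
#' @param seed Integer seed; the same seed and config give bit-identical
#'   output.
#' @param n_participants Number of enrolled horse owners.
#' @param horses_per_owner Probability vector over 1..10 horses per owner.
#' @param p_competition_horse Probability a horse is a competition horse
#'   (otherwise leisure).
#' @param monthly_totals Named vector of expected movement counts per month
#'   for a reference herd of `reference_horses` horses; per-horse monthly
#'   intensity is `monthly_totals / reference_horses`.
#' @param activity_dispersion Gamma shape of the per-horse-month activity
#'   multiplier (mean 1), making monthly movement counts negative
#'   binomial. Small values mean most horses stay home in a given month
#'   while a few travel weekly, and the heavy travellers change from month
#'   to month; `Inf` gives homogeneous Poisson travel.
#' @param reference_horses Herd size to which `monthly_totals` refers.
#' @param weekend_multiplier Relative departure probability of a Saturday or
#'   Sunday versus a weekday (>= 1).
#' @param reason_mix Probability vector over travel reasons.
#' @param distance_meanlog,distance_sdlog Log-normal parameters of the
#'   target trip distance in km (defaults give median 47, Q3 ~ 88).
#' @param region_probs Probability of a participant's home falling in each
#'   Ontario census region.
#' @param p_within_region Probability a movement stays in the home region.
#' @param p_out_of_province,p_international Probability of a trip leaving
#'   the province / the country (carved out of the between-region share).
#' @param p_round_trip Probability a movement returns to its origin within
#'   the same calendar month; the remainder are trips returning the next
#'   month or, late in the season, permanent boarding changes. Monthly
#'   network reciprocity is approximately this value.
#' @param trip_length_probs Probability vector over round-trip durations of
#'   0-3 days.
#' @param p_boarding_late Probability that an October non-returning
#'   movement is a permanent boarding change rather than a long trip
#'   (November non-returners are always permanent, so no trip returns after
#'   the study window).
#' @param response_model List with `p_dropout` (share of participants who
#'   largely stop responding), `p_respond` (monthly response probability of
#'   an engaged participant) and `p_respond_dropout` (of a drop-out).
#' @param p_sanctioned Probability a competition movement is to a
#'   sanctioned event.
#' @param exploration_weight Urn weight of exploring a new destination.
#'   Each movement either revisits a repertoire destination (with
#'   probability proportional to its accumulated visit weight) or explores
#'   a new one (with probability proportional to this constant). Repeat
#'   visits are what give monthly networks repeated dyads (edge counts
#'   well below movement counts) and non-zero between-month loyalty.
#' @param repertoire_decay Multiplier applied to the repertoire's visit
#'   weights at each month boundary. Values well below 1 make a freshly
#'   decayed repertoire lose out against the exploration weight, so the
#'   set of venues an owner frequents churns between months — as the low
#'   between-month loyalty and similarity of observed equestrian travel
#'   suggest — while within-month visits stay concentrated.
#' @param p_private Named probability per reason that a newly explored
#'   destination is participant-private (an unshareable spot such as a
#'   friend's farm or local trail) rather than a facility shared by all
#'   participants in that city; private locations fragment the network the
#'   way unresolvable questionnaire answers do.
#' @param cities_per_region Number of synthetic gazetteer cities per
#'   Ontario region (spatial resolution of the distance kernel).
#' @param alias_fraction Fraction of venues that also appear in the diary
#'   under an abbreviated raw spelling, to exercise alias resolution.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_participants = 197L,
    horses_per_owner = c(0.52, 0.14, 0.12, 0.08, 0.05, 0.04, 0.02, 0.01,
                         0.01, 0.01),
    p_competition_horse = 0.636,
    monthly_totals = c("2015-05" = 313, "2015-06" = 290, "2015-07" = 280,
                       "2015-08" = 312, "2015-09" = 250, "2015-10" = 200,
                       "2015-11" = 109),
    reference_horses = 330,
    activity_dispersion = 1,
    weekend_multiplier = 2.5,
    reason_mix = c(competition = 0.21, riding = 0.40, training = 0.15,
                   healthcare = 0.12, other = 0.12),
    distance_meanlog = log(47),
    distance_sdlog = 0.93,
    region_probs = c(southern = 0.30, western = 0.27, central = 0.22,
                     eastern = 0.16, northern = 0.05),
    p_within_region = 0.73,
    p_out_of_province = 0.015,
    p_international = 0.005,
    p_round_trip = 0.95,
    trip_length_probs = c(0.55, 0.30, 0.10, 0.05),
    p_boarding_late = 0.5,
    response_model = list(p_dropout = 0.30, p_respond = 0.935,
                          p_respond_dropout = 0.35),
    p_sanctioned = 0.343,
    exploration_weight = 1,
    repertoire_decay = 0.02,
    p_private = c(competition = 0.05, riding = 0.6, training = 0.3,
                  healthcare = 0.1, other = 0.5),
    cities_per_region = 40L,
    alias_fraction = 0.08) {
  probs <- c(p_competition_horse, p_within_region, p_out_of_province,
             p_international, p_round_trip, p_sanctioned, alias_fraction,
             p_private, reason_mix, region_probs,
             horses_per_owner, trip_length_probs, unlist(response_model))
  stopifnot(all(probs >= 0), all(probs <= 1),
            all(monthly_totals >= 0), weekend_multiplier >= 1,
            repertoire_decay > 0, repertoire_decay <= 1,
            exploration_weight > 0,
            n_participants >= 0, seed == as.integer(seed))
  stopifnot(abs(sum(reason_mix) - 1) < 1e-8,
            abs(sum(region_probs) - 1) < 1e-8,
            p_within_region + p_out_of_province + p_international <= 1)
  structure(mget(names(formals(synthetic_config))),
            class = "synthetic_config")
}

# Ontario census-region centres plus fixed out-of-province / international
# destination cities (approximate real coordinates, so distance tails reach
# a few thousand km as observed travel does).
region_geometry <- function() {
  list(
    centres = tibble::tribble(
      ~region,    ~lat,  ~lon, ~spread_lat, ~spread_lon,
      "southern", 42.9, -81.2, 0.45, 0.70,
      "western",  43.6, -80.6, 0.40, 0.55,
      "central",  44.4, -79.3, 0.50, 0.65,
      "eastern",  45.1, -76.2, 0.55, 0.90,
      "northern", 46.8, -81.0, 1.10, 2.20),
    far = tibble::tribble(
      ~city_town,      ~latitude, ~longitude, ~region,
      "Quebec City QC",  46.81,  -71.21, "out_of_province",
      "Winnipeg MB",     49.90,  -97.14, "out_of_province",
      "Calgary AB",      51.05, -114.07, "out_of_province",
      "Halifax NS",      44.65,  -63.57, "out_of_province",
      "Vancouver BC",    49.28, -123.12, "out_of_province",
      "Saint-Lazare QC", 45.40,  -74.13, "out_of_province",
      "New York NY",     40.71,  -74.01, "international",
      "Columbus OH",     39.96,  -83.00, "international",
      "Lexington KY",    38.04,  -84.50, "international",
      "Tryon NC",        35.21,  -82.24, "international",
      "Wellington FL",   26.66,  -80.24, "international"))
}

#' Generate a synthetic study population
#'
#' Draws a gazetteer of cities grouped into census regions, owners with
#' home facilities placed in those cities, and horses with disciplines.
#' Deterministic under `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list with tibbles `participants` (id, home city/facility,
#'   region, latent response class), `horses` (id, owner, discipline) and
#'   `gazetteer` (`city_town`, `latitude`, `longitude`, `region`).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  geo <- region_geometry()
  gaz <- dplyr::bind_rows(lapply(seq_len(nrow(geo$centres)), function(i) {
    ct <- geo$centres[i, ]
    k <- config$cities_per_region
    tibble::tibble(
      city_town = sprintf("%s-%02d", tools::toTitleCase(ct$region), seq_len(k)),
      latitude = stats::rnorm(k, ct$lat, ct$spread_lat),
      longitude = stats::rnorm(k, ct$lon, ct$spread_lon),
      region = ct$region)
  }))
  gaz <- dplyr::bind_rows(gaz, geo$far)

  n <- config$n_participants
  if (n == 0) {
    return(list(
      participants = tibble::tibble(participant_id = character(),
                                    region = character(),
                                    home_city = character(),
                                    home_name = character(),
                                    dropout = logical()),
      horses = tibble::tibble(horse_id = character(),
                              participant_id = character(),
                              discipline = character()),
      gazetteer = gaz))
  }
  region <- sample(names(config$region_probs), n, replace = TRUE,
                   prob = config$region_probs)
  home_city <- vapply(region, function(r)
    sample(gaz$city_town[gaz$region == r], 1), character(1))
  participants <- tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    region = region,
    home_city = unname(home_city),
    home_name = sprintf("Home Farm P%03d", seq_len(n)),
    dropout = stats::runif(n) < config$response_model$p_dropout)

  n_horses <- sample(seq_along(config$horses_per_owner), n, replace = TRUE,
                     prob = config$horses_per_owner)
  horses <- tibble::tibble(
    participant_id = rep(participants$participant_id, n_horses))
  horses$horse_id <- sprintf("H%04d", seq_len(nrow(horses)))
  horses$discipline <- ifelse(
    stats::runif(nrow(horses)) < config$p_competition_horse,
    "competition", "leisure")
  list(participants = participants, horses = horses, gazetteer = gaz)
}

# Sample a departure day within a month, weekends upweighted.
sample_days <- function(n, month, weekend_multiplier) {
  first <- as.Date(paste0(month, "-01"))
  days <- seq(first, month_end(first), by = "1 day")
  w <- ifelse(format(days, "%u") %in% c("6", "7"), weekend_multiplier, 1)
  days[sample.int(length(days), n, replace = TRUE, prob = w)]
}

#' Generate synthetic movement diaries
#'
#' Simulates, month by month, the movements of every horse in the
#' population: seasonal per-horse movement intensity, weekend-peaked
#' departures, reason-typed destinations chosen to honour the configured
#' within-region probability and log-normal distance kernel, same-month
#' round trips (with the complement returning next month or, late in the
#' season, permanently changing home facility), sanctioned-competition
#' flags, and per-participant monthly questionnaire non-response.
#'
#' Two views are returned: `movements_full` is the ground truth, and
#' `movements` is the questionnaire view with the records of non-responded
#' participant-months removed and a fraction of venue names replaced by
#' alias spellings (resolvable through the returned `aliases` table).
#'
#' @param population From [generate_population()].
#' @param config The same [synthetic_config()].
#' @return A list with `movements`, `movements_full`, `response`
#'   (participant x month response table) and `aliases`.
#' @export
generate_movements <- function(population, config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  gaz <- population$gazetteer
  horses <- population$horses
  months <- names(config$monthly_totals)
  intensity <- config$monthly_totals / config$reference_horses

  empty <- tibble::tibble(
    participant_id = character(), horse_id = character(),
    discipline = character(), origin_name = character(),
    origin_city = character(), destination_name = character(),
    destination_city = character(),
    departure_date = as.Date(character()), return_date = as.Date(character()),
    reason = character(), sanctioned = logical())
  if (!nrow(horses)) {
    return(list(movements = empty, movements_full = empty,
                response = tibble::tibble(participant_id = character(),
                                          month = character(),
                                          responded = logical()),
                aliases = tibble::tibble(raw_name = character(),
                                         canonical_name = character())))
  }

  # pairwise city distances, and candidate city indices per (region, bucket)
  cm <- cbind(gaz$latitude, gaz$longitude)
  D <- vapply(seq_len(nrow(cm)), function(i)
    great_circle_km(cm[rep(i, nrow(cm)), , drop = FALSE], cm),
    numeric(nrow(cm)))
  ontario <- !gaz$region %in% c("out_of_province", "international")
  regions <- names(config$region_probs)
  cand_within <- lapply(regions, function(r) which(gaz$region == r))
  names(cand_within) <- regions
  cand_other <- lapply(regions, function(r) which(ontario & gaz$region != r))
  names(cand_other) <- regions
  cand_oop <- which(gaz$region == "out_of_province")
  cand_intl <- which(gaz$region == "international")

  home_city <- stats::setNames(population$participants$home_city,
                               population$participants$participant_id)
  home_name <- stats::setNames(population$participants$home_name,
                               population$participants$participant_id)
  city_idx <- function(city) match(city, gaz$city_town)

  bucket_probs <- c(
    within = config$p_within_region,
    other = 1 - config$p_within_region - config$p_out_of_province -
      config$p_international,
    oop = config$p_out_of_province,
    intl = config$p_international)

  venue_name <- function(reason, city) {
    label <- c(competition = "Showgrounds", riding = "Trails",
               training = "Training Centre", healthcare = "Equine Clinic",
               other = "Sales Barn")[reason]
    paste(label, city)
  }
  private_label <- c(competition = "Farm Show", riding = "Private Trail",
                     training = "Home Schooling Ring",
                     healthcare = "Farm Call", other = "Friend's Farm")
  # per-participant list of previously visited destinations with visit
  # weights; repeats are drawn with probability proportional to weight (a
  # Polya urn with an exploration option), so each owner concentrates on a
  # few favourites. Pooling the repertoire across travel reasons lets the
  # same facility be visited for different purposes, which is what makes
  # mixed-use locations appear in the monthly type classification.
  repertoire <- new.env(parent = emptyenv())
  rep_counts <- new.env(parent = emptyenv())

  out <- vector("list", length(months))
  last_month <- months[length(months)]
  for (mi in seq_along(months)) {
    m <- months[mi]
    if (mi > 1) {
      for (k in ls(rep_counts))
        rep_counts[[k]] <- rep_counts[[k]] * config$repertoire_decay
    }
    # overdispersed monthly travel: the per-horse-month activity multiplier
    # (mean-1 gamma) makes counts negative-binomial, so most horses stay
    # home in a given month while a few travel weekly, and the set of
    # heavy travellers changes from month to month
    activity <- if (is.finite(config$activity_dispersion)) {
      stats::rgamma(nrow(horses), shape = config$activity_dispersion,
                    rate = config$activity_dispersion)
    } else {
      rep(1, nrow(horses))
    }
    n_mov <- stats::rpois(nrow(horses), intensity[[m]] * activity)
    idx <- rep(seq_len(nrow(horses)), n_mov)
    nm <- length(idx)
    if (nm == 0) {
      out[[mi]] <- empty
      next
    }
    pid <- horses$participant_id[idx]
    reason <- sample(names(config$reason_mix), nm, replace = TRUE,
                     prob = config$reason_mix)
    bucket <- sample(names(bucket_probs), nm, replace = TRUE,
                     prob = bucket_probs)
    o_city <- unname(home_city[pid])
    o_idx <- city_idx(o_city)
    o_region <- gaz$region[o_idx]
    # Target trip distances are drawn from the log-normal kernel,
    # stratified by destination bucket: within-region trips take the
    # kernel's shortest p_within quantile band and between-region Ontario
    # trips the band above it, so that pooled distances follow the full
    # kernel while short trips stay local. The destination is then chosen
    # among candidate cities within +/- max(25%, 10 km) of the target,
    # weighted by 1/distance to offset the growth of city count with
    # radius (nearest candidate if the window is empty). Short targets can
    # land on the origin's own city: 0 km, another venue in the same
    # city/town.
    q_within <- config$p_within_region
    q_upper <- q_within +
      (1 - q_within - config$p_out_of_province - config$p_international)
    u <- stats::runif(nm)
    band_lo <- ifelse(bucket == "within", 0, q_within)
    band_hi <- ifelse(bucket == "within", q_within, q_upper)
    target_km <- stats::qlnorm(band_lo + u * (band_hi - band_lo),
                               config$distance_meanlog,
                               config$distance_sdlog)
    dep <- sample_days(nm, m, config$weekend_multiplier)
    round_trip <- stats::runif(nm) < config$p_round_trip
    dur <- sample(0:3, nm, replace = TRUE, prob = config$trip_length_probs)
    ret <- pmin(dep + dur, month_end(dep))
    ret[!round_trip] <- NA

    # non-returning movements: long trips into next month, or permanent
    # boarding changes in October/November
    permanent <- !round_trip &
      (m == last_month |
         (mi == length(months) - 1 & stats::runif(nm) < config$p_boarding_late))
    long_trip <- !round_trip & !permanent
    if (any(long_trip)) {
      nxt <- as.Date(paste0(months[pmin(mi + 1, length(months))], "-01"))
      ret[long_trip] <- nxt + sample.int(10, sum(long_trip), replace = TRUE) - 1
    }
    reason[permanent] <- "boarding_change"

    reuse_u <- stats::runif(nm)
    pp <- config$p_private[reason]
    pp[is.na(pp)] <- 0
    private <- stats::runif(nm) < pp
    d_city <- d_name <- character(nm)
    for (i in seq_len(nm)) {
      rkey <- pid[i]
      seen <- repertoire[[rkey]]
      w <- rep_counts[[rkey]]
      if (!permanent[i] && length(seen) &&
          reuse_u[i] < sum(w) / (sum(w) + config$exploration_weight)) {
        k <- sample.int(length(seen), 1, prob = w)
        pick <- seen[[k]]
        d_city[i] <- pick[2]
        d_name[i] <- pick[1]
        rep_counts[[rkey]][k] <- w[k] + 1
        next
      }
      # permanent boarding changes relocate within the home region; other
      # movements follow the drawn bucket
      cand <- if (permanent[i]) {
        cand_within[[o_region[i]]]
      } else {
        switch(bucket[i],
               within = cand_within[[o_region[i]]],
               other = cand_other[[o_region[i]]],
               oop = cand_oop,
               intl = cand_intl)
      }
      j <- if (!permanent[i] && bucket[i] %in% c("oop", "intl")) {
        cand[sample.int(length(cand), 1)]
      } else {
        dk <- D[o_idx[i], cand]
        gap <- abs(dk - target_km[i])
        hw <- max(0.25 * target_km[i], 10)
        inside <- which(gap <= hw)
        if (length(inside)) {
          w <- 1 / pmax(dk[inside], 5)
          cand[inside[sample.int(length(inside), 1, prob = w)]]
        } else {
          cand[which.min(gap)]
        }
      }
      d_city[i] <- gaz$city_town[j]
      d_name[i] <- if (private[i]) {
        sprintf("%s (%s) %s", private_label[reason[i]], pid[i], d_city[i])
      } else {
        venue_name(reason[i], d_city[i])
      }
      if (!permanent[i]) {
        repertoire[[rkey]] <- c(seen, list(c(d_name[i], d_city[i])))
        rep_counts[[rkey]] <- c(rep_counts[[rkey]], 1)
      }
    }

    rec <- tibble::tibble(
      participant_id = pid,
      horse_id = horses$horse_id[idx],
      discipline = horses$discipline[idx],
      origin_name = unname(home_name[pid]),
      origin_city = o_city,
      destination_name = d_name,
      destination_city = d_city,
      departure_date = dep,
      return_date = ret,
      reason = reason,
      sanctioned = ifelse(reason == "competition",
                          stats::runif(nm) < config$p_sanctioned, NA))

    if (any(permanent)) {
      # one boarding change per participant-month; the new facility becomes
      # the home for subsequent months
      perm_idx <- which(permanent)
      first_perm <- perm_idx[!duplicated(pid[perm_idx])]
      movers <- rep(FALSE, nm)
      movers[first_perm] <- TRUE
      drop_extra <- permanent & !movers
      new_home <- sprintf("%s Winter", home_name[pid[movers]])
      rec$destination_name[movers] <- new_home
      home_city[pid[movers]] <- rec$destination_city[movers]
      home_name[pid[movers]] <- new_home
      rec <- rec[!drop_extra, , drop = FALSE]
      # the new facility is the origin from the change date forward
      for (i in which(rec$reason == "boarding_change")) {
        later <- rec$participant_id == rec$participant_id[i] &
          rec$departure_date > rec$departure_date[i]
        rec$origin_name[later] <- rec$destination_name[i]
        rec$origin_city[later] <- rec$destination_city[i]
      }
    }
    out[[mi]] <- rec
  }
  full <- dplyr::bind_rows(out)
  full <- full[order(full$departure_date, full$participant_id,
                     full$horse_id), , drop = FALSE]

  resp_p <- ifelse(population$participants$dropout,
                   config$response_model$p_respond_dropout,
                   config$response_model$p_respond)
  response <- tidyr::expand_grid(
    participant_id = population$participants$participant_id,
    month = months)
  response$responded <- stats::runif(nrow(response)) <
    rep(resp_p, each = length(months))

  key <- paste(full$participant_id, month_label(full$departure_date))
  responded_key <- paste(response$participant_id,
                         response$month)[response$responded]
  view <- full[key %in% responded_key, , drop = FALSE]

  # alias spellings for a fraction of venues, exercising standardisation
  venues <- sort(unique(full$destination_name))
  venues <- venues[!grepl("^Home Farm", venues)]
  n_alias <- floor(config$alias_fraction * length(venues))
  aliases <- tibble::tibble(raw_name = character(),
                            canonical_name = character())
  if (n_alias > 0) {
    aliased <- sample(venues, n_alias)
    raw <- toupper(abbreviate(aliased, minlength = 10, dot = FALSE))
    keep <- !raw %in% c(venues, full$origin_name) & !duplicated(raw)
    aliases <- tibble::tibble(raw_name = unname(raw[keep]),
                              canonical_name = aliased[keep])
    hit <- which(view$destination_name %in% aliases$canonical_name &
                   stats::runif(nrow(view)) < 0.5)
    view$destination_name[hit] <- aliases$raw_name[
      match(view$destination_name[hit], aliases$canonical_name)]
  }

  list(movements = view, movements_full = full, response = response,
       aliases = aliases)
}

#' Generate a complete synthetic data set
#'
#' Convenience wrapper running [generate_population()] and
#' [generate_movements()] under one configuration.
#'
#' @param config A [synthetic_config()].
#' @return A list with `movements` (questionnaire view), `movements_full`
#'   (ground truth), `response`, `aliases`, `participants`, `horses`,
#'   `gazetteer` and `config`.
#' @export
generate_movement_data <- function(config = synthetic_config()) {
  pop <- generate_population(config)
  mov <- generate_movements(pop, config)
  c(mov, pop, list(config = config))
}

#' Compare statistics recovered by the pipeline to their configured targets
#'
#' Runs the analysis pipeline on the ground-truth view of a synthetic data
#' set and compares the recovered summary statistics to the values the
#' generator was configured to produce: competition-horse fraction,
#' within-region movement fraction, median trip distance, monthly network
#' reciprocity (against the same-month round-trip probability), sanctioned
#' competition fraction, and the total movement count.
#'
#' @param data From [generate_movement_data()].
#' @param config The generating configuration (defaults to `data$config`).
#' @return A tibble with columns `statistic`, `target`, `recovered`,
#'   `tolerance`, `tol_type` (`"abs"`/`"rel"`) and `ok`.
#' @export
recover_parameters <- function(data, config = data$config) {
  std <- standardise_locations(data$movements_full, aliases = data$aliases,
                               gazetteer = data$gazetteer)
  inc <- apply_inclusion_criteria(std$records)
  nets <- suppressWarnings(
    build_monthly_networks(inc$kept, std$locations,
                           months = names(config$monthly_totals)))
  rec <- stats::median(vapply(nets, net_reciprocity, numeric(1)),
                       na.rm = TRUE)
  rf <- region_flows(inc$kept, std$locations)
  dist_med <- movement_distances(inc$kept, std$locations,
                                 by_month = FALSE)$median
  comp <- data$movements_full$reason == "competition"
  expected_total <- sum(config$monthly_totals) * nrow(data$horses) /
    config$reference_horses

  res <- tibble::tribble(
    ~statistic, ~target, ~recovered, ~tolerance, ~tol_type,
    "competition_horse_fraction", config$p_competition_horse,
    mean(data$horses$discipline == "competition"), 0.05, "abs",
    "within_region_fraction", config$p_within_region,
    rf$within_fraction, 0.05, "abs",
    "median_distance_km", exp(config$distance_meanlog),
    dist_med, 0.10, "rel",
    "reciprocity", config$p_round_trip, rec, 0.03, "abs",
    "sanctioned_fraction", config$p_sanctioned,
    mean(data$movements_full$sanctioned[comp]), 0.05, "abs",
    "n_movements", expected_total, nrow(data$movements_full), 0.10, "rel")
  res$ok <- ifelse(res$tol_type == "abs",
                   abs(res$recovered - res$target) <= res$tolerance,
                   abs(res$recovered - res$target) <=
                     res$tolerance * res$target)
  res
}
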