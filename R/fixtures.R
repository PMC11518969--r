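# Synthetic calibration fixtures: microdata, hazard-rate tables, name
# frequency tables, a business-location-name corpus, and an address lexicon.
# These emulate the *shapes* of the public input tables a national
# microsimulation would be calibrated from (household-clustered survey
# microdata with weights, demographic rate tables, administrative name
# frequency files), not their real-world distributions.

# ---------------------------------------------------------------------------
# microdata

microdata_columns <- c(
  "household_key", "person_key", "age_years", "sex", "race_code",
  "hispanic_flag", "relationship_code", "gq_flag", "institutional_flag",
  "weight", "recent_immigrant_flag", "foreign_born_flag"
)

.race_codes <- c("white", "black", "aian", "asian", "nhopi", "other",
                 "two_or_more")

#' Generate synthetic household-clustered microdata
#'
#' Builds a survey-microdata-shaped table of persons clustered into
#' residential households plus individual group-quarters (GQ) records. Each
#' non-GQ household has exactly one reference person; other members carry one
#' of the remaining 12 relationship values. Household sizes follow a
#' truncated geometric distribution. A configurable fraction of households
#' (and of GQ persons) is flagged as recent immigrants; recent immigrants are
#' always foreign-born. When the flagged fraction is positive, at least one
#' multi-member household and one GQ record are guaranteed to be flagged, so
#' every immigration move type has a non-empty sampling subset.
#'
#' @param n_households Number of residential households (>= 0).
#' @param gq_fraction Target fraction of all persons living in group
#'   quarters, in `[0, 1]`.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param config Optional list overriding `mean_household_size` (default 2.5),
#'   `max_household_size` (10), `recent_immigrant_fraction` (0.01),
#'   `foreign_born_fraction` (0.12), `hispanic_fraction` (0.15),
#'   `institutional_fraction` (0.5).
#' @return A data.frame with one row per person (class `microdata_table`).
#' @export
generate_microdata <- function(n_households, gq_fraction = 0.03, seed = 1,
                               config = list()) {
  stopifnot(length(n_households) == 1, n_households >= 0,
            n_households == as.integer(n_households))
  if (!is.numeric(gq_fraction) || length(gq_fraction) != 1 ||
      is.na(gq_fraction) || gq_fraction < 0 || gq_fraction > 1) {
    stop("gq_fraction must be a probability in [0, 1]")
  }
  cfg <- merge_config(list(
    mean_household_size = 2.5,
    max_household_size = 10L,
    recent_immigrant_fraction = 0.01,
    foreign_born_fraction = 0.12,
    hispanic_fraction = 0.15,
    institutional_fraction = 0.5
  ), config)
  set.seed(seed)
  n_households <- as.integer(n_households)

  empty <- data.frame(
    household_key = character(), person_key = character(),
    age_years = integer(), sex = character(), race_code = character(),
    hispanic_flag = logical(), relationship_code = character(),
    gq_flag = logical(), institutional_flag = logical(), weight = numeric(),
    recent_immigrant_flag = logical(), foreign_born_flag = logical(),
    stringsAsFactors = FALSE
  )
  if (n_households == 0 && gq_fraction == 0) {
    class(empty) <- c("microdata_table", "data.frame")
    return(empty)
  }

  hh <- empty
  if (n_households > 0) {
    # household sizes: 1 + truncated geometric, mean ~ mean_household_size
    sizes <- 1L + stats::rgeom(n_households, prob = 1 / cfg$mean_household_size)
    sizes <- pmin(sizes, cfg$max_household_size)

    rp_age <- sample(18:90, n_households, replace = TRUE,
                     prob = stats::dnorm(18:90, mean = 45, sd = 16))
    hh_race <- sample(.race_codes, n_households, replace = TRUE,
                      prob = c(0.58, 0.12, 0.01, 0.06, 0.005, 0.125, 0.10))
    hh_hisp <- stats::runif(n_households) < cfg$hispanic_fraction
    hh_recent <- stats::runif(n_households) < cfg$recent_immigrant_fraction

    hh_idx <- rep.int(seq_len(n_households), sizes)
    n_persons <- length(hh_idx)
    member_rank <- sequence(sizes)
    is_rp <- member_rank == 1L

    rel <- character(n_persons)
    rel[is_rp] <- "Reference person"
    other_rels <- setdiff(relationship_values, "Reference person")
    rel_weights <- c(0.40, 0.02, 0.04, 0.07, 0.06, 0.05, 0.02, 0.02,
                     0.07, 0.12, 0.01, 0.12)
    rel[!is_rp] <- sample(other_rels, sum(!is_rp), replace = TRUE,
                          prob = rel_weights)

    base_age <- rp_age[hh_idx]
    age <- integer(n_persons)
    age[is_rp] <- rp_age
    downward <- rel %in% c(.child_relationships, "Grandchild", "Foster child")
    upward <- rel %in% c("Parent", "Parent-in-law")
    lateral <- !is_rp & !downward & !upward
    age[downward] <- pmax(0L, base_age[downward] -
                            sample(20:40, sum(downward), replace = TRUE))
    age[upward] <- base_age[upward] + sample(20:35, sum(upward), replace = TRUE)
    age[lateral] <- pmax(0L, base_age[lateral] +
                           sample(-15:15, sum(lateral), replace = TRUE))

    foreign <- hh_recent[hh_idx] |
      (stats::runif(n_persons) < cfg$foreign_born_fraction)

    hh <- data.frame(
      household_key = paste0("H", hh_idx),
      person_key = paste0("P", seq_len(n_persons)),
      age_years = age,
      sex = sample(c("male", "female"), n_persons, replace = TRUE),
      race_code = ifelse(stats::runif(n_persons) < 0.8, hh_race[hh_idx],
                         sample(.race_codes, n_persons, replace = TRUE)),
      hispanic_flag = hh_hisp[hh_idx],
      relationship_code = rel,
      gq_flag = FALSE,
      institutional_flag = FALSE,
      weight = stats::runif(n_persons, 50, 150),
      recent_immigrant_flag = hh_recent[hh_idx],
      foreign_born_flag = foreign,
      stringsAsFactors = FALSE
    )
  }

  n_gq <- round(gq_fraction / (1 - min(gq_fraction, 0.999999)) * nrow(hh))
  if (nrow(hh) == 0 && gq_fraction > 0) n_gq <- max(n_gq, 1L)
  gq <- empty
  if (n_gq > 0) {
    recent <- stats::runif(n_gq) < cfg$recent_immigrant_fraction
    gq <- data.frame(
      household_key = paste0("GQ", seq_len(n_gq)),
      person_key = paste0("G", seq_len(n_gq)),
      age_years = sample(16:95, n_gq, replace = TRUE),
      sex = sample(c("male", "female"), n_gq, replace = TRUE),
      race_code = sample(.race_codes, n_gq, replace = TRUE),
      hispanic_flag = stats::runif(n_gq) < cfg$hispanic_fraction,
      relationship_code = NA_character_,
      gq_flag = TRUE,
      institutional_flag = stats::runif(n_gq) < cfg$institutional_fraction,
      weight = stats::runif(n_gq, 50, 150),
      recent_immigrant_flag = recent,
      foreign_born_flag = recent | (stats::runif(n_gq) <
                                      cfg$foreign_born_fraction),
      stringsAsFactors = FALSE
    )
  }

  # guarantee a non-empty recent-immigrant subset for every immigration
  # move type (whole household with a non-reference member; GQ person),
  # so that positive immigration counts always have records to sample
  if (cfg$recent_immigrant_fraction > 0) {
    if (nrow(hh) > 0 &&
        !any(hh$recent_immigrant_flag &
               hh$relationship_code != "Reference person")) {
      sizes_by_key <- table(hh$household_key)
      pick <- names(sizes_by_key)[which.max(sizes_by_key)]
      sel <- hh$household_key == pick
      hh$recent_immigrant_flag[sel] <- TRUE
      hh$foreign_born_flag[sel] <- TRUE
    }
    if (nrow(gq) > 0 && !any(gq$recent_immigrant_flag)) {
      gq$recent_immigrant_flag[1] <- TRUE
      gq$foreign_born_flag[1] <- TRUE
    }
  }

  out <- rbind(hh, gq)
  rownames(out) <- NULL
  class(out) <- c("microdata_table", "data.frame")
  out
}

#' Check microdata invariants
#'
#' Errors unless: every non-GQ household has exactly one reference person, GQ
#' records carry no relationship code, ages are non-negative integers, and
#' weights are positive.
#'
#' @param microdata A `microdata_table`.
#' @return The table, invisibly.
#' @export
validate_microdata <- function(microdata) {
  stopifnot(is.data.frame(microdata),
            all(microdata_columns %in% names(microdata)))
  md <- microdata
  if (nrow(md) == 0) return(invisible(md))
  stopifnot(all(md$age_years >= 0), all(md$age_years == floor(md$age_years)),
            all(md$weight > 0), all(md$sex %in% c("male", "female")))
  if (any(!is.na(md$relationship_code[md$gq_flag]))) {
    stop("GQ records must have no relationship code")
  }
  res <- md[!md$gq_flag, ]
  if (nrow(res) > 0) {
    if (any(is.na(res$relationship_code)) ||
        !all(res$relationship_code %in% relationship_values)) {
      stop("invalid relationship codes in residential records")
    }
    n_rp <- tapply(res$relationship_code == "Reference person",
                   res$household_key, sum)
    if (any(n_rp != 1)) {
      stop("every non-GQ household must have exactly one reference person")
    }
  }
  invisible(md)
}

# ---------------------------------------------------------------------------
# rate tables

#' Default fixture states
#'
#' Synthetic two-letter state codes used by the address lexicon and the
#' emigration rate strata.
#' @export
fixture_states <- c("WA", "OR", "CA", "ID", "NV")

#' Generate the full set of stratified hazard-rate tables
#'
#' Rates are deterministic functions of the configuration (smooth parametric
#' shapes over 5-year age groups); the seed is reserved for optional jitter
#' (`jitter_sd > 0`). Mortality rises with age within each sex
#' (Gompertz-like); fertility is confined to female ages 15-49; domestic
#' migration peaks in young adulthood; emigration is stratified by age group,
#' sex, race/ethnicity, nativity, and state with a strong foreign-born
#' multiplier. Immigration is expressed as expected events per year by move
#' type.
#'
#' @param config Optional list overriding `mortality_base` (hazard at age 0,
#'   default 1e-4/yr), `mortality_slope` (log-hazard slope per year of age,
#'   0.08), `mortality_sex_ratio` (male/female, 1.4), `fertility_rates`
#'   (named per-year rates for the seven reproductive age groups),
#'   `domestic_individual_base` (0.15/person-yr), `domestic_household_base`
#'   (0.10/household-yr), `emigration_base` (0.002/person-yr),
#'   `immigration_counts` (named yearly event counts for move types
#'   `household`, `gq_person`, `non_reference_person`; absolute counts sized
#'   for a desk-scale run of roughly a thousand simulants — scale them with
#'   the target population), `jitter_sd` (0).
#' @param seed Seed for optional jitter.
#' @return List of data.frames (class `rate_table_set`): `mortality`,
#'   `fertility`, `domestic_individual`, `domestic_household`, `emigration`,
#'   `immigration_counts`.
#' @export
generate_rate_tables <- function(config = list(), seed = 1) {
  cfg <- merge_config(list(
    mortality_base = 1e-4,
    mortality_slope = 0.08,
    mortality_sex_ratio = 1.4,
    fertility_rates = c(`15-19` = 0.03, `20-24` = 0.08, `25-29` = 0.10,
                        `30-34` = 0.09, `35-39` = 0.05, `40-44` = 0.012,
                        `45-49` = 0.002),
    domestic_individual_base = 0.15,
    domestic_household_base = 0.10,
    emigration_base = 0.002,
    immigration_counts = c(household = 3, gq_person = 1,
                           non_reference_person = 3),
    jitter_sd = 0
  ), config)
  if (cfg$mortality_base < 0 || cfg$domestic_individual_base < 0 ||
      cfg$domestic_household_base < 0 || cfg$emigration_base < 0 ||
      any(cfg$fertility_rates < 0) || any(cfg$immigration_counts < 0)) {
    stop("base rates must be non-negative")
  }

  ag <- age_group_labels()
  mids <- age_group_midpoints()
  sexes <- c("male", "female")
  races <- race_ethnicity_levels

  mortality <- expand.grid(age_group = ag, sex = sexes,
                           stringsAsFactors = FALSE)
  mortality$rate <- cfg$mortality_base *
    exp(cfg$mortality_slope * mids[match(mortality$age_group, ag)]) *
    ifelse(mortality$sex == "male", cfg$mortality_sex_ratio, 1)

  fertility <- data.frame(age_group = ag, rate = 0)
  idx <- match(names(cfg$fertility_rates), ag)
  if (any(is.na(idx))) stop("fertility_rates names must be age-group labels")
  fertility$rate[idx] <- unname(cfg$fertility_rates)

  # young-adult-peaked multiplier shared by the migration families
  move_mult <- c(0.8, 0.6, 0.5, 1.2, 2.2, 2.0, 1.5, 1.1, 0.9, 0.7, 0.6,
                 0.5, 0.45, 0.4, 0.35, 0.3, 0.3, 0.3)
  race_mult <- stats::setNames(seq(0.9, 1.1, length.out = length(races)),
                               races)

  domestic_individual <- expand.grid(age_group = ag, sex = sexes,
                                     race_ethnicity = races,
                                     stringsAsFactors = FALSE)
  domestic_individual$rate <- cfg$domestic_individual_base *
    move_mult[match(domestic_individual$age_group, ag)] *
    race_mult[domestic_individual$race_ethnicity]

  hh_mult <- c(rep(1, 3), 1.2, 1.8, 1.6, 1.3, 1.0, 0.8, 0.6, 0.5, 0.4,
               0.35, 0.3, 0.25, 0.2, 0.2, 0.2)
  domestic_household <- expand.grid(age_group = ag, sex = sexes,
                                    race_ethnicity = races,
                                    stringsAsFactors = FALSE)
  domestic_household$rate <- cfg$domestic_household_base *
    hh_mult[match(domestic_household$age_group, ag)] *
    race_mult[domestic_household$race_ethnicity]

  type_mult <- c(household = 0.5, gq_person = 0.2, non_reference_person = 1)
  nativity_mult <- c(`US-born` = 0.2, `foreign-born` = 8)
  state_mult <- stats::setNames(seq(0.9, 1.1,
                                    length.out = length(fixture_states)),
                                fixture_states)
  emigration <- expand.grid(age_group = ag, sex = sexes,
                            race_ethnicity = races,
                            nativity = names(nativity_mult),
                            state = fixture_states,
                            move_type = names(type_mult),
                            stringsAsFactors = FALSE)
  emigration$rate <- cfg$emigration_base *
    move_mult[match(emigration$age_group, ag)] *
    race_mult[emigration$race_ethnicity] *
    nativity_mult[emigration$nativity] *
    state_mult[emigration$state] *
    type_mult[emigration$move_type]

  immigration_counts <- data.frame(
    move_type = names(type_mult),
    events_per_year = as.numeric(
      cfg$immigration_counts[names(type_mult)]),
    stringsAsFactors = FALSE
  )
  if (any(is.na(immigration_counts$events_per_year))) {
    stop("immigration_counts must name household, gq_person, ",
         "non_reference_person")
  }

  out <- list(mortality = mortality, fertility = fertility,
              domestic_individual = domestic_individual,
              domestic_household = domestic_household,
              emigration = emigration,
              immigration_counts = immigration_counts)
  if (cfg$jitter_sd > 0) {
    set.seed(seed)
    for (nm in setdiff(names(out), "immigration_counts")) {
      out[[nm]]$rate <- pmax(0, out[[nm]]$rate *
                               exp(stats::rnorm(nrow(out[[nm]]), 0,
                                                cfg$jitter_sd)))
    }
  }
  class(out) <- "rate_table_set"
  out
}

# ---------------------------------------------------------------------------
# name tables

# deterministic synthetic name pools built from syllables; clearly synthetic,
# not drawn from any real administrative file
.make_name_pool <- function(n, onsets, codas, seed) {
  set.seed(seed)
  pool <- character(0)
  while (length(pool) < n) {
    cand <- paste0(sample(onsets, n, replace = TRUE),
                   sample(codas, n, replace = TRUE))
    pool <- unique(c(pool, cand))
  }
  pool[seq_len(n)]
}

#' Generate synthetic name-frequency tables
#'
#' First- and middle-name frequencies are stratified by sex and birth-decade
#' cohort; last-name frequencies by race/ethnicity. Frequencies follow a
#' Zipf-like decay with a minimum-frequency floor, emulating administrative
#' name files that suppress rare names.
#'
#' @param config Optional list overriding `n_first` (names per sex, default
#'   60), `n_last` (120), `min_frequency` (floor, default 5), `zipf_scale`
#'   (10000), `cohorts` (birth-decade start years, default 1920-2040).
#' @param seed Integer seed.
#' @return List of data.frames (class `name_tables`): `first_names`
#'   (sex, cohort, name, frequency), `middle_names` (same), `last_names`
#'   (race_ethnicity, name, frequency).
#' @export
generate_name_tables <- function(config = list(), seed = 1) {
  cfg <- merge_config(list(
    n_first = 60L, n_last = 120L, min_frequency = 5,
    zipf_scale = 10000, cohorts = seq(1920, 2040, by = 10)
  ), config)
  stopifnot(cfg$n_first >= 1, cfg$n_last >= 1, cfg$min_frequency >= 0)

  onsets <- c("Al", "Bren", "Car", "Dor", "El", "Fa", "Gar", "Hal", "Is",
              "Jor", "Kel", "Lor", "Mar", "Nel", "Or", "Per", "Quin", "Ros",
              "Sam", "Tam", "Ur", "Vel", "Wil", "Xan", "Yol", "Zel")
  f_codas <- c("a", "ia", "ine", "elle", "issa", "ora", "ette", "yn", "ara")
  m_codas <- c("o", "an", "on", "er", "ius", "ard", "in", "os", "ton")
  l_codas <- c("son", "ez", "field", "worth", "man", "ley", "ford", "berg",
               "well", "ton")

  female <- .make_name_pool(cfg$n_first, onsets, f_codas, seed)
  male <- .make_name_pool(cfg$n_first, onsets, m_codas, seed + 1)
  last <- .make_name_pool(cfg$n_last, onsets, l_codas, seed + 2)

  zipf <- function(n, rot) {
    ranks <- ((seq_len(n) + rot - 1) %% n) + 1
    pmax(cfg$min_frequency, round(cfg$zipf_scale / ranks))
  }
  first_stratum <- function(sex, pool) {
    do.call(rbind, lapply(seq_along(cfg$cohorts), function(i) {
      data.frame(sex = sex, cohort = cfg$cohorts[i], name = pool,
                 frequency = zipf(length(pool), rot = 3L * i),
                 stringsAsFactors = FALSE)
    }))
  }
  first_names <- rbind(first_stratum("female", female),
                       first_stratum("male", male))
  middle_names <- rbind(first_stratum("female", rev(female)),
                        first_stratum("male", rev(male)))
  last_names <- do.call(rbind, lapply(seq_along(race_ethnicity_levels),
    function(i) {
      data.frame(race_ethnicity = race_ethnicity_levels[i], name = last,
                 frequency = zipf(length(last), rot = 7L * i),
                 stringsAsFactors = FALSE)
    }))
  rownames(first_names) <- rownames(middle_names) <- rownames(last_names) <-
    NULL
  out <- list(first_names = first_names, middle_names = middle_names,
              last_names = last_names)
  class(out) <- "name_tables"
  out
}

# ---------------------------------------------------------------------------
# location-name corpus and address lexicon

#' Generate a synthetic business-location-name corpus
#'
#' Word sequences shaped like the business "location names" a points-of-
#' interest database would supply, used to train the bigram name generator.
#'
#' @param n_names Number of names (>= 0).
#' @param seed Integer seed.
#' @return Character vector of names (class `location_corpus`).
#' @export
generate_location_corpus <- function(n_names, seed = 1) {
  stopifnot(length(n_names) == 1, n_names >= 0)
  set.seed(seed)
  n_names <- as.integer(n_names)
  openers <- c("Golden", "Red", "Blue", "Silver", "Royal", "Happy", "Lucky",
               "Grand", "Little", "Big", "Sunny", "North", "South", "East",
               "West", "Old", "New", "Tony's", "Maria's", "Red's", "Pikes")
  middles <- c("Oak", "River", "Creek", "Valley", "Hill", "Star", "Crown",
               "Eagle", "Fox", "Hen", "Bear", "Pine", "Maple", "Harbor",
               "Garden", "Bridge", "Family", "City", "Country")
  closers <- c("Cafe", "Diner", "Market", "Supply", "Hardware", "Bakery",
               "Garage", "Salon", "Clinic", "Pharmacy", "Books",
               "Landscaping", "Campground", "Dairy", "Shoes", "Auto",
               "Electric", "Plumbing", "Practice", "Properties")
  suffixes <- c("Inc", "LLC", "Co", "Group")
  if (n_names == 0) {
    out <- character(0)
    class(out) <- c("location_corpus", "character")
    return(out)
  }
  n_words <- sample(1:3, n_names, replace = TRUE, prob = c(0.2, 0.45, 0.35))
  with_suffix <- stats::runif(n_names) < 0.25
  names_out <- vapply(seq_len(n_names), function(i) {
    w <- switch(n_words[i],
                sample(middles, 1),
                c(sample(openers, 1), sample(closers, 1)),
                c(sample(openers, 1), sample(middles, 1), sample(closers, 1)))
    if (with_suffix[i]) w <- c(w, sample(suffixes, 1))
    paste(w, collapse = " ")
  }, character(1))
  class(names_out) <- c("location_corpus", "character")
  names_out
}

#' Generate a synthetic address lexicon
#'
#' Component lists (street names and suffixes, cities with states and zip
#' codes, unit designators) from which unique addresses are composed.
#'
#' @param config Optional list overriding `n_streets` (default 80) and
#'   `n_cities` (20).
#' @param seed Integer seed.
#' @return Named list of component vectors (class `address_lexicon`):
#'   `street_names`, `street_suffixes`, `cities`, `states` (state per city),
#'   `zips` (zip per city), `unit_designators`.
#' @export
generate_address_lexicon <- function(config = list(), seed = 1) {
  cfg <- merge_config(list(n_streets = 80L, n_cities = 20L), config)
  stopifnot(cfg$n_streets >= 1, cfg$n_cities >= 1)
  set.seed(seed)
  stems <- c("Cedar", "Birch", "Walnut", "Spruce", "Aspen", "Willow",
             "Juniper", "Sycamore", "Magnolia", "Cypress", "Summit",
             "Prairie", "Canyon", "Meadow", "Ridge", "Brook", "Lake",
             "Sunset", "Highland", "Union", "Franklin", "Jefferson",
             "Madison", "Monroe", "Jackson", "Lincoln", "Grant", "Harrison")
  ord_suffix <- function(n) {
    ifelse(n %% 100 %in% 11:13, "th",
           c("th", "st", "nd", "rd", rep("th", 6))[n %% 10 + 1])
  }
  ordinals <- paste0(4:40, ord_suffix(4:40))
  street_pool <- unique(c(stems, paste(sample(stems), "Park"), ordinals))
  street_names <- sample(street_pool, min(cfg$n_streets,
                                          length(street_pool)))
  city_stems <- c("Fair", "Spring", "Green", "Oak", "River", "Lake", "Hill",
                  "Clear", "Bright", "Stone", "Mill", "Glen", "Ash", "Elm")
  city_ends <- c("view", "field", "town", "ville", "port", "wood", "dale",
                 "burg")
  cities <- unique(paste0(sample(city_stems, cfg$n_cities, replace = TRUE),
                          sample(city_ends, cfg$n_cities, replace = TRUE)))
  states <- sample(fixture_states, length(cities), replace = TRUE)
  zips <- sprintf("%05d", sample(10000:99999, length(cities)))
  out <- list(
    street_names = street_names,
    street_suffixes = c("St", "Ave", "Blvd", "Rd", "Ln", "Dr", "Way", "Ct"),
    cities = cities,
    states = states,
    zips = zips,
    unit_designators = c("Apt", "Unit", "#")
  )
  class(out) <- "address_lexicon"
  out
}

# ---------------------------------------------------------------------------
# bundle + serialization

#' Generate the full fixture bundle
#'
#' Convenience wrapper producing every calibration input the simulator needs,
#' each from a sub-seed derived from `seed`.
#'
#' @param seed Master fixture seed.
#' @param n_households Residential households in the microdata.
#' @param n_corpus_names Business names in the location corpus.
#' @param microdata_config,rate_config,name_config,lexicon_config Optional
#'   per-table configuration lists.
#' @param gq_fraction Target GQ person fraction in the microdata.
#' @return List (class `fixture_set`) with elements `microdata`, `rates`,
#'   `names`, `corpus`, `lexicon`, and attribute `seed`.
#' @export
generate_fixtures <- function(seed = 1, n_households = 2000,
                              gq_fraction = 0.03, n_corpus_names = 500,
                              microdata_config = list(),
                              rate_config = list(), name_config = list(),
                              lexicon_config = list()) {
  out <- list(
    microdata = generate_microdata(n_households, gq_fraction,
                                   seed = substream_seed(seed, 101, 0),
                                   config = microdata_config),
    rates = generate_rate_tables(rate_config,
                                 seed = substream_seed(seed, 102, 0)),
    names = generate_name_tables(name_config,
                                 seed = substream_seed(seed, 103, 0)),
    corpus = generate_location_corpus(n_corpus_names,
                                      seed = substream_seed(seed, 104, 0)),
    lexicon = generate_address_lexicon(lexicon_config,
                                       seed = substream_seed(seed, 105, 0))
  )
  attr(out, "seed") <- seed
  class(out) <- "fixture_set"
  out
}

#' Write fixtures to delimited text files
#'
#' One UTF-8 comma-separated file per table plus a `manifest.json` recording
#' paths, the seed, and a content hash.
#'
#' @param fixtures A `fixture_set`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_fixtures <- function(fixtures, dir) {
  stopifnot(inherits(fixtures, "fixture_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  wr <- function(df, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, fileEncoding = "UTF-8")
    paths[[name]] <<- basename(p)
  }
  wr(fixtures$microdata, "microdata")
  for (nm in names(fixtures$rates)) {
    wr(fixtures$rates[[nm]], paste0("rates_", nm))
  }
  for (nm in names(fixtures$names)) wr(fixtures$names[[nm]], nm)
  wr(data.frame(name = as.character(fixtures$corpus)), "location_corpus")
  lex <- fixtures$lexicon
  wr(data.frame(component = rep(names(lex), lengths(lex)),
                value = unlist(lex, use.names = FALSE)), "address_lexicon")
  manifest <- list(paths = paths, seed = attr(fixtures, "seed"),
                   config_hash = rlang::hash(unclass(fixtures)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read fixtures written by [write_fixtures()]
#'
#' @param dir Directory containing the fixture files and manifest.
#' @return A `fixture_set`.
#' @export
read_fixtures <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  rd <- function(name) {
    utils::read.csv(file.path(dir, paste0(name, ".csv")),
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
  rates <- lapply(c("mortality", "fertility", "domestic_individual",
                    "domestic_household", "emigration",
                    "immigration_counts"),
                  function(nm) rd(paste0("rates_", nm)))
  names(rates) <- c("mortality", "fertility", "domestic_individual",
                    "domestic_household", "emigration", "immigration_counts")
  class(rates) <- "rate_table_set"
  nm_tables <- list(first_names = rd("first_names"),
                    middle_names = rd("middle_names"),
                    last_names = rd("last_names"))
  class(nm_tables) <- "name_tables"
  md <- rd("microdata")
  class(md) <- c("microdata_table", "data.frame")
  corpus <- rd("location_corpus")$name
  class(corpus) <- c("location_corpus", "character")
  lex_df <- rd("address_lexicon")
  lexicon <- split(lex_df$value, lex_df$component)
  lexicon <- lexicon[c("street_names", "street_suffixes", "cities", "states",
                       "zips", "unit_designators")]
  class(lexicon) <- "address_lexicon"
  out <- list(microdata = md, rates = rates, names = nm_tables,
              corpus = corpus, lexicon = lexicon)
  attr(out, "seed") <- manifest$seed
  class(out) <- "fixture_set"
  out
}
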