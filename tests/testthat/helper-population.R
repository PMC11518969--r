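# Helpers building small, fully controlled population states in code.

# A population of n simulants with identical controlled attributes, parked
# in the College GQ unit (no households, so no succession side effects).
flat_population <- function(n, age = 30,
                            sex = rep(c("male", "female"), length.out = n),
                            race = "White",
                            start_date = as.Date("2019-01-01")) {
  lex <- generate_address_lexicon(seed = 99)
  reg <- new_address_registry(lex)
  all_kinds <- unlist(gq_kinds, use.names = FALSE)
  hh <- data.frame(
    household_id = seq_along(all_kinds), kind = all_kinds,
    physical_address_id = new_address(reg, length(all_kinds)),
    mailing_address_id = NA_integer_, reference_person_id = NA_integer_,
    active = TRUE, stringsAsFactors = FALSE
  )
  hh$mailing_address_id <- hh$physical_address_id
  s <- empty_simulants(n)
  s$simulant_id <- seq_len(n)
  s$sex <- rep_len(sex, n)
  s$precise_age <- rep_len(age, n)
  s$dob <- derive_dob(s$precise_age, start_date)
  s$race_ethnicity <- rep_len(race, n)
  s$nativity <- "US-born"
  s$has_ssn <- TRUE
  s$household_id <- hh$household_id[match("College", hh$kind)]
  pop <- list(simulants = s, households = hh, employers = NULL,
              income_model = income_model(), address_registry = reg,
              ssn_registry = new_id_registry(),
              itin_registry = new_id_registry(), stints = list(),
              births = list(), start_date = start_date,
              current_date = start_date, next_simulant_id = n + 1L,
              next_household_id = max(hh$household_id) + 1L)
  class(pop) <- "sim_population"
  pop
}

# A population of small residential households built in code: each household
# has one reference person plus `extra` members with the given relationships.
household_population <- function(member_ages, member_rels,
                                 start_date = as.Date("2019-01-01")) {
  # member_ages / member_rels: lists, one element per household; element 1
  # of each must be the reference person
  lex <- generate_address_lexicon(seed = 99)
  reg <- new_address_registry(lex)
  all_kinds <- unlist(gq_kinds, use.names = FALSE)
  gq <- data.frame(
    household_id = seq_along(all_kinds), kind = all_kinds,
    physical_address_id = new_address(reg, length(all_kinds)),
    mailing_address_id = NA_integer_, reference_person_id = NA_integer_,
    active = TRUE, stringsAsFactors = FALSE
  )
  gq$mailing_address_id <- gq$physical_address_id
  k <- length(member_ages)
  sizes <- lengths(member_ages)
  n <- sum(sizes)
  hh_ids <- max(gq$household_id) + seq_len(k)
  s <- empty_simulants(n)
  s$simulant_id <- seq_len(n)
  s$sex <- rep(c("female", "male"), length.out = n)
  s$precise_age <- unlist(member_ages)
  s$dob <- derive_dob(s$precise_age, start_date)
  s$race_ethnicity <- "White"
  s$nativity <- "US-born"
  s$has_ssn <- TRUE
  s$household_id <- rep(hh_ids, sizes)
  s$relationship <- unlist(member_rels)
  first_member <- cumsum(c(1, utils::head(sizes, -1)))
  res <- data.frame(
    household_id = hh_ids, kind = "Residential",
    physical_address_id = new_address(reg, k),
    mailing_address_id = NA_integer_,
    reference_person_id = s$simulant_id[first_member], active = TRUE,
    stringsAsFactors = FALSE
  )
  res$mailing_address_id <- res$physical_address_id
  pop <- list(simulants = s, households = rbind(gq, res), employers = NULL,
              income_model = income_model(), address_registry = reg,
              ssn_registry = new_id_registry(),
              itin_registry = new_id_registry(), stints = list(),
              births = list(), start_date = start_date,
              current_date = start_date, next_simulant_id = n + 1L,
              next_household_id = max(res$household_id) + 1L)
  class(pop) <- "sim_population"
  pop
}

# constant-rate tables covering all strata
constant_mortality_table <- function(rate) {
  tab <- expand.grid(age_group = age_group_labels(),
                     sex = c("male", "female"), stringsAsFactors = FALSE)
  tab$rate <- rate
  tab
}

constant_fertility_table <- function(rate, groups = "25-29") {
  tab <- data.frame(age_group = age_group_labels(), rate = 0)
  tab$rate[tab$age_group %in% groups] <- rate
  tab
}

constant_asr_table <- function(rate) {
  tab <- expand.grid(age_group = age_group_labels(),
                     sex = c("male", "female"),
                     race_ethnicity = race_ethnicity_levels,
                     stringsAsFactors = FALSE)
  tab$rate <- rate
  tab
}

constant_emigration_table <- function(rate) {
  tab <- expand.grid(age_group = age_group_labels(),
                     sex = c("male", "female"),
                     race_ethnicity = race_ethnicity_levels,
                     nativity = c("US-born", "foreign-born"),
                     state = fixture_states,
                     move_type = c("household", "gq_person",
                                   "non_reference_person"),
                     stringsAsFactors = FALSE)
  tab$rate <- rate
  tab
}

# rate-table set with everything switched off (for isolating one component)
zero_rate_config <- function() {
  list(mortality_base = 0,
       fertility_rates = stats::setNames(
         rep(0, 7), c("15-19", "20-24", "25-29", "30-34", "35-39",
                      "40-44", "45-49")),
       domestic_individual_base = 0, domestic_household_base = 0,
       emigration_base = 0,
       immigration_counts = c(household = 0, gq_person = 0,
                              non_reference_person = 0))
}

# chi-square goodness of fit, iteratively pooling the smallest expected
# cells until every cell has expectation >= min_expected
chisq_pooled <- function(obs, w, min_expected = 5) {
  obs <- as.numeric(obs)
  w <- w / sum(w)
  repeat {
    exp_c <- sum(obs) * w
    if (all(exp_c >= min_expected) || length(obs) <= 2) break
    i <- order(exp_c)[1:2]
    obs <- c(obs[-i], sum(obs[i]))
    w <- c(w[-i], sum(w[i]))
  }
  stats::chisq.test(obs, p = w)$p.value
}
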