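# Domestic individual and household migration, international immigration and
# emigration, and the address lifecycle they drive.

# state of residence per simulant row, via household physical address
simulant_states <- function(pop, rows) {
  addr <- addresses(pop$address_registry)
  hh <- pop$households
  aid <- hh$physical_address_id[match(pop$simulants$household_id[rows],
                                      hh$household_id)]
  addr$state[match(aid, addr$address_id)]
}

rate_array_emigration <- function(tab, states) {
  ag <- age_group_labels()
  types <- c("household", "gq_person", "non_reference_person")
  a <- array(NA_real_,
             dim = c(.n_age_groups, 2, 7, 2, length(states), 3),
             dimnames = list(ag, c("male", "female"), race_ethnicity_levels,
                             c("US-born", "foreign-born"), states, types))
  a[cbind(match(tab$age_group, ag), match(tab$sex, c("male", "female")),
          match(tab$race_ethnicity, race_ethnicity_levels),
          match(tab$nativity, c("US-born", "foreign-born")),
          match(tab$state, states), match(tab$move_type, types))] <- tab$rate
  if (any(is.na(a))) stop("emigration table is missing strata")
  a
}

# remove a simulant from their household, running succession / close-out;
# the mover has already been reassigned (or will be) by the caller
depart_household <- function(pop, row, old_household) {
  hh <- pop$households
  hrow <- which(hh$household_id == old_household)
  if (length(hrow) == 0 || hh$kind[hrow] != "Residential") return(pop)
  was_rp <- identical(hh$reference_person_id[hrow],
                      pop$simulants$simulant_id[row])
  if (was_rp) {
    pop$households$reference_person_id[hrow] <- NA_integer_
    pop <- succeed_reference_person(pop, old_household)
  } else {
    pop <- close_empty_households(pop, old_household)
  }
  pop
}

#' Apply one step of domestic individual migration
#'
#' Present simulants move with the per-step probability of their (age group,
#' sex, race/ethnicity) rate, at most once per step. Destination kind is
#' drawn from `destination_split`: establish a new one-person household (the
#' mover becomes its reference person), join an existing residential
#' household (uniformly chosen; relationship "Other nonrelative"), or join a
#' GQ unit of a uniformly chosen kind. Movers of working age change
#' employment. A household that loses its reference person runs succession;
#' an emptied household is closed.
#'
#' @param pop A `sim_population`.
#' @param rates Rate table (age_group, sex, race_ethnicity, rate per
#'   person-year).
#' @param destination_split Probability vector over `new_household`,
#'   `join_household`, `gq` (default 0.5/0.4/0.1).
#' @param step_days Step length in days.
#' @param date Step date.
#' @param p_po_box Probability the new household's mail goes to a PO box.
#' @return List with `pop`, `moved` (simulant ids), and
#'   `employment_changes` (count of move-triggered employment changes).
#' @export
apply_domestic_individual <- function(pop, rates,
                                      destination_split = c(
                                        new_household = 0.5,
                                        join_household = 0.4, gq = 0.1),
                                      step_days = 28,
                                      date = pop$current_date,
                                      p_po_box = 0.1) {
  stopifnot(length(destination_split) == 3,
            abs(sum(destination_split) - 1) < 1e-8,
            all(destination_split >= 0))
  a <- rate_array_asr(rates)
  s <- pop$simulants
  at_risk <- which(s$status == "present")
  if (length(at_risk) == 0) {
    return(list(pop = pop, moved = integer(0), employment_changes = 0L))
  }
  idx <- cbind(age_group_index(s$precise_age[at_risk]),
               match(s$sex[at_risk], c("male", "female")),
               match(s$race_ethnicity[at_risk], race_ethnicity_levels))
  p <- rate_to_step_probability(a[idx], step_days)
  movers <- at_risk[stats::runif(length(at_risk)) < p]
  if (length(movers) == 0) {
    return(list(pop = pop, moved = integer(0), employment_changes = 0L))
  }
  dest <- sample(c("new_household", "join_household", "gq"), length(movers),
                 replace = TRUE, prob = destination_split)
  emp_changes <- 0L
  for (i in seq_along(movers)) {
    row <- movers[i]
    old_hh <- pop$simulants$household_id[row]
    if (dest[i] == "new_household") {
      hid <- pop$next_household_id
      pop$next_household_id <- hid + 1L
      phys <- new_address(pop$address_registry, 1)
      mail <- if (stats::runif(1) < p_po_box) {
        new_address(pop$address_registry, 1, po_box = TRUE)
      } else phys
      pop$households <- rbind(pop$households, data.frame(
        household_id = hid, kind = "Residential",
        physical_address_id = phys, mailing_address_id = mail,
        reference_person_id = pop$simulants$simulant_id[row], active = TRUE,
        stringsAsFactors = FALSE))
      pop$simulants$household_id[row] <- hid
      pop$simulants$relationship[row] <- "Reference person"
    } else if (dest[i] == "join_household") {
      hh <- pop$households
      cand <- hh$household_id[hh$kind == "Residential" & hh$active &
                                hh$household_id != old_hh]
      if (length(cand) == 0) next  # nowhere to go; move fizzles
      target <- cand[sample.int(length(cand), 1)]
      pop$simulants$household_id[row] <- target
      pop$simulants$relationship[row] <- "Other nonrelative"
    } else {
      kind <- sample(unlist(gq_kinds, use.names = FALSE), 1)
      gid <- pop$households$household_id[pop$households$kind == kind][1]
      pop$simulants$household_id[row] <- gid
      pop$simulants$relationship[row] <- NA_character_
    }
    pop <- depart_household(pop, row, old_hh)
    if (pop$simulants$precise_age[row] >= 18 && !is.null(pop$employers)) {
      pop <- resample_employment(pop, row, date)
      emp_changes <- emp_changes + 1L
    }
  }
  moved <- pop$simulants$simulant_id[movers]
  list(pop = pop, moved = moved, employment_changes = emp_changes)
}

#' Apply one step of domestic household migration
#'
#' Active residential households with more than one present member move as a
#' unit with the per-step probability of the reference person's (age group,
#' sex, race/ethnicity) household-migration rate. The household receives a
#' fresh physical (and mailing) address — the old address is vacated and
#' never reused — relationships are unchanged, and working-age members
#' change employment.
#'
#' @inheritParams apply_domestic_individual
#' @param rates Rate table stratified by reference-person demographics
#'   (age_group, sex, race_ethnicity, rate per household-year).
#' @return List with `pop`, `moved_households` (ids), and
#'   `employment_changes` (count).
#' @export
apply_domestic_household <- function(pop, rates, step_days = 28,
                                     date = pop$current_date,
                                     p_po_box = 0.1) {
  a <- rate_array_asr(rates)
  s <- pop$simulants
  pres <- s[s$status == "present", ]
  hh <- pop$households
  sizes <- table(pres$household_id)
  eligible <- hh$kind == "Residential" & hh$active &
    hh$household_id %in% as.integer(names(sizes)[sizes > 1])
  rows <- which(eligible)
  if (length(rows) == 0) {
    return(list(pop = pop, moved_households = integer(0),
                employment_changes = 0L))
  }
  rp <- match(hh$reference_person_id[rows], s$simulant_id)
  idx <- cbind(age_group_index(s$precise_age[rp]),
               match(s$sex[rp], c("male", "female")),
               match(s$race_ethnicity[rp], race_ethnicity_levels))
  p <- rate_to_step_probability(a[idx], step_days)
  moving <- rows[stats::runif(length(rows)) < p]
  emp_changes <- 0L
  for (hrow in moving) {
    old_phys <- pop$households$physical_address_id[hrow]
    old_mail <- pop$households$mailing_address_id[hrow]
    vacate_address(pop$address_registry, unique(c(old_phys, old_mail)))
    phys <- new_address(pop$address_registry, 1)
    mail <- if (stats::runif(1) < p_po_box) {
      new_address(pop$address_registry, 1, po_box = TRUE)
    } else phys
    pop$households$physical_address_id[hrow] <- phys
    pop$households$mailing_address_id[hrow] <- mail
    hid <- pop$households$household_id[hrow]
    members <- which(pop$simulants$household_id == hid &
                       pop$simulants$status == "present")
    adults <- members[pop$simulants$precise_age[members] >= 18]
    if (length(adults) > 0 && !is.null(pop$employers)) {
      pop <- resample_employment(pop, adults, date)
      emp_changes <- emp_changes + length(adults)
    }
  }
  list(pop = pop, moved_households = pop$households$household_id[moving],
       employment_changes = emp_changes)
}

#' Apply one step of international emigration
#'
#' Per-person hazards stratified by (age group, sex, race/ethnicity,
#' nativity, state of residence) and move type: `household` hazards apply to
#' residential reference persons and remove the whole household; `gq_person`
#' hazards apply to GQ residents; `non_reference_person` hazards apply to
#' residential non-reference members (so a reference person never leaves via
#' this type and no succession is triggered by it). Emigrants get status
#' `"emigrated"` permanently and never reappear in observer output.
#'
#' @param pop A `sim_population`.
#' @param rates Emigration rate table (age_group, sex, race_ethnicity,
#'   nativity, state, move_type, rate per person-year).
#' @param step_days Step length in days.
#' @param date Step date.
#' @return List with `pop` and `emigrated` (simulant ids).
#' @export
apply_emigration <- function(pop, rates, step_days = 28,
                             date = pop$current_date) {
  states <- sort(unique(rates$state))
  a <- rate_array_emigration(rates, states)
  s <- pop$simulants
  pres <- which(s$status == "present")
  if (length(pres) == 0) return(list(pop = pop, emigrated = integer(0)))
  hh <- pop$households
  gq_ids <- hh$household_id[hh$kind != "Residential"]
  in_gq <- s$household_id[pres] %in% gq_ids
  rp_ids <- hh$reference_person_id[hh$kind == "Residential" & hh$active]
  is_rp <- s$simulant_id[pres] %in% rp_ids
  type <- ifelse(in_gq, "gq_person",
                 ifelse(is_rp, "household", "non_reference_person"))
  st <- simulant_states(pop, pres)
  st[is.na(st) | !(st %in% states)] <- states[1]
  idx <- cbind(age_group_index(s$precise_age[pres]),
               match(s$sex[pres], c("male", "female")),
               match(s$race_ethnicity[pres], race_ethnicity_levels),
               match(s$nativity[pres], c("US-born", "foreign-born")),
               match(st, states),
               match(type, c("household", "gq_person",
                             "non_reference_person")))
  p <- rate_to_step_probability(a[idx], step_days)
  hit <- stats::runif(length(pres)) < p

  emigrated_rows <- integer(0)
  # household-type events take the whole household
  hh_events <- pres[hit & type == "household"]
  if (length(hh_events) > 0) {
    hids <- unique(s$household_id[hh_events])
    members <- which(pop$simulants$household_id %in% hids &
                       pop$simulants$status == "present")
    emigrated_rows <- c(emigrated_rows, members)
  }
  # GQ-person and non-reference-person events take the individual, unless
  # their household already left above
  ind_events <- pres[hit & type != "household"]
  ind_events <- setdiff(ind_events, emigrated_rows)
  emigrated_rows <- unique(c(emigrated_rows, ind_events))
  if (length(emigrated_rows) == 0) {
    return(list(pop = pop, emigrated = integer(0)))
  }
  ids <- pop$simulants$simulant_id[emigrated_rows]
  pop <- close_stints(pop, ids, date)
  pop$simulants$status[emigrated_rows] <- "emigrated"
  pop$simulants$status_date[emigrated_rows] <- as_date(date)
  pop$simulants$employer_id[emigrated_rows] <- NA_integer_
  pop$simulants$income[emigrated_rows] <- 0
  pop$simulants$employer_since[emigrated_rows] <- as.Date(NA)
  pop <- close_empty_households(
    pop, unique(pop$simulants$household_id[emigrated_rows]))
  list(pop = pop, emigrated = ids)
}

#' Apply one step of international immigration
#'
#' Event counts per move type are Poisson-distributed with per-step mean
#' `events_per_year * step_days / 365.25` (rates constant over time, no
#' seasonality). Entities are sampled weight-proportionally from the
#' recent-immigrant subset of the microdata; ages are made precise (integer
#' plus uniform fraction) but NOT shifted. `household` events instantiate a
#' whole household with relationships preserved; `gq_person` events add one
#' GQ resident (GQ kind drawn by institutional status); and
#' `non_reference_person` events add one simulant to a uniformly chosen
#' existing residential household with their (non-reference) relationship
#' code.
#'
#' @param pop A `sim_population`.
#' @param microdata The `microdata_table` with `recent_immigrant_flag`.
#' @param immigration_counts data.frame (move_type, events_per_year).
#' @param step_days Step length in days.
#' @param date Step date (immigrants' reference date for date of birth).
#' @param step Engine step index recorded on new simulants.
#' @param p_po_box,p_ssn_foreign_born Configuration probabilities.
#' @return List with `pop` and `immigrant_ids`.
#' @export
apply_immigration <- function(pop, microdata, immigration_counts,
                              step_days = 28, date = pop$current_date,
                              step = 0L, p_po_box = 0.1,
                              p_ssn_foreign_born = 0.6) {
  counts <- stats::setNames(immigration_counts$events_per_year,
                            immigration_counts$move_type)
  mean_events <- counts * step_days / days_per_year
  n_events <- stats::setNames(
    stats::rpois(length(mean_events), mean_events), names(mean_events))
  if (sum(n_events) == 0) return(list(pop = pop, immigrant_ids = integer(0)))

  md <- microdata
  recent <- md[md$recent_immigrant_flag, , drop = FALSE]
  if (nrow(recent) == 0) {
    stop("positive immigration counts but no recent-immigrant records")
  }
  new_ids <- integer(0)

  add_simulants <- function(pop, rows_md, household_id, relationship) {
    n <- nrow(rows_md)
    precise <- rows_md$age_years + stats::runif(n)
    nb <- empty_simulants(n)
    nb$simulant_id <- pop$next_simulant_id + seq_len(n) - 1L
    nb$sex <- rows_md$sex
    nb$precise_age <- precise
    nb$dob <- derive_dob(precise, date)
    nb$race_ethnicity <- map_race_ethnicity(rows_md$race_code,
                                            rows_md$hispanic_flag)
    nb$nativity <- "foreign-born"
    nb$has_ssn <- stats::runif(n) < p_ssn_foreign_born
    nb$household_id <- household_id
    nb$relationship <- relationship
    nb$entered_step <- as.integer(step)
    pop$simulants <- rbind(pop$simulants, nb)
    pop$next_simulant_id <- pop$next_simulant_id + n
    new_ids <<- c(new_ids, nb$simulant_id)
    pop
  }

  # household moves: whole recent-immigrant households, relationships kept
  if (n_events[["household"]] > 0) {
    hh_md <- recent[!recent$gq_flag, , drop = FALSE]
    keys <- unique(hh_md$household_key)
    if (length(keys) == 0) {
      stop("household immigration requires recent-immigrant households")
    }
    rp_w <- vapply(split(hh_md$weight, hh_md$household_key), max, 0)[keys]
    picks <- sample(seq_along(keys), n_events[["household"]],
                    replace = TRUE, prob = rp_w)
    for (k in picks) {
      rows_md <- hh_md[hh_md$household_key == keys[k], , drop = FALSE]
      hid <- pop$next_household_id
      pop$next_household_id <- hid + 1L
      phys <- new_address(pop$address_registry, 1)
      mail <- if (stats::runif(1) < p_po_box) {
        new_address(pop$address_registry, 1, po_box = TRUE)
      } else phys
      first_id <- pop$next_simulant_id
      pop <- add_simulants(pop, rows_md, hid, rows_md$relationship_code)
      rp_off <- which(rows_md$relationship_code == "Reference person") - 1L
      pop$households <- rbind(pop$households, data.frame(
        household_id = hid, kind = "Residential",
        physical_address_id = phys, mailing_address_id = mail,
        reference_person_id = first_id + rp_off[1], active = TRUE,
        stringsAsFactors = FALSE))
    }
  }

  # GQ person moves
  if (n_events[["gq_person"]] > 0) {
    gq_md <- recent[recent$gq_flag, , drop = FALSE]
    if (nrow(gq_md) == 0) {
      stop("gq_person immigration requires recent-immigrant GQ records")
    }
    picks <- sample.int(nrow(gq_md), n_events[["gq_person"]],
                        replace = TRUE, prob = gq_md$weight)
    rows_md <- gq_md[picks, , drop = FALSE]
    kinds <- assign_gq_type(rows_md$institutional_flag)
    gids <- pop$households$household_id[match(kinds, pop$households$kind)]
    pop <- add_simulants(pop, rows_md, gids, NA_character_)
  }

  # non-reference-person moves into existing residential households
  if (n_events[["non_reference_person"]] > 0) {
    nr_md <- recent[!recent$gq_flag &
                      recent$relationship_code != "Reference person", ,
                    drop = FALSE]
    if (nrow(nr_md) == 0) {
      stop("non_reference_person immigration requires recent-immigrant ",
           "non-reference records")
    }
    hh <- pop$households
    cand <- hh$household_id[hh$kind == "Residential" & hh$active]
    if (length(cand) > 0) {
      picks <- sample.int(nrow(nr_md), n_events[["non_reference_person"]],
                          replace = TRUE, prob = nr_md$weight)
      rows_md <- nr_md[picks, , drop = FALSE]
      targets <- cand[sample.int(length(cand), nrow(rows_md),
                                 replace = TRUE)]
      pop <- add_simulants(pop, rows_md, targets,
                           rows_md$relationship_code)
    }
  }
  list(pop = pop, immigrant_ids = new_ids)
}
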