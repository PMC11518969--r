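# Mortality, fertility (with twinning and attribute inheritance), and the
# household relationship maintenance that death and departure trigger.

# ---------------------------------------------------------------------------
# rate lookup helpers (arrays indexed by age group / sex / race / ...)

rate_matrix_mortality <- function(mortality) {
  ag <- age_group_labels()
  m <- matrix(NA_real_, nrow = .n_age_groups, ncol = 2,
              dimnames = list(ag, c("male", "female")))
  m[cbind(match(mortality$age_group, ag),
          match(mortality$sex, c("male", "female")))] <- mortality$rate
  if (any(is.na(m))) stop("mortality table is missing strata")
  m
}

rate_vector_fertility <- function(fertility) {
  ag <- age_group_labels()
  v <- rep(NA_real_, .n_age_groups)
  v[match(fertility$age_group, ag)] <- fertility$rate
  if (any(is.na(v))) stop("fertility table is missing age groups")
  v
}

rate_array_asr <- function(tab) {
  ag <- age_group_labels()
  a <- array(NA_real_, dim = c(.n_age_groups, 2, 7),
             dimnames = list(ag, c("male", "female"), race_ethnicity_levels))
  a[cbind(match(tab$age_group, ag), match(tab$sex, c("male", "female")),
          match(tab$race_ethnicity, race_ethnicity_levels))] <- tab$rate
  if (any(is.na(a))) stop("rate table is missing strata")
  a
}

# ---------------------------------------------------------------------------
# mortality

#' Apply one step of mortality
#'
#' Each present simulant dies during the step with probability
#' `rate_to_step_probability(rate, step_days)` for their (age group, sex)
#' all-cause mortality rate. Dead simulants get status `"dead"`, their open
#' employment stint is closed, and if a dead simulant was a residential
#' reference person, reference-person succession runs in that household.
#' Households left empty are closed and their addresses vacated (never
#' reused).
#'
#' @param pop A `sim_population`.
#' @param mortality Mortality rate table (age_group, sex, rate per
#'   person-year) covering all strata.
#' @param step_days Step length in days.
#' @param date Date of the step (used to close employment stints).
#' @return List with `pop` (updated) and `deaths` (integer simulant ids).
#' @export
apply_mortality <- function(pop, mortality, step_days = 28,
                            date = pop$current_date) {
  m <- rate_matrix_mortality(mortality)
  s <- pop$simulants
  at_risk <- which(s$status == "present")
  if (length(at_risk) == 0) return(list(pop = pop, deaths = integer(0)))
  idx <- cbind(age_group_index(s$precise_age[at_risk]),
               match(s$sex[at_risk], c("male", "female")))
  p <- rate_to_step_probability(m[idx], step_days)
  dead <- at_risk[stats::runif(length(at_risk)) < p]
  if (length(dead) == 0) return(list(pop = pop, deaths = integer(0)))

  dead_ids <- s$simulant_id[dead]
  pop <- close_stints(pop, dead_ids, date)
  pop$simulants$status[dead] <- "dead"
  pop$simulants$status_date[dead] <- as_date(date)
  pop$simulants$employer_id[dead] <- NA_integer_
  pop$simulants$income[dead] <- 0
  pop$simulants$employer_since[dead] <- as.Date(NA)

  # succession in residential households that lost their reference person
  hh <- pop$households
  lost_rp <- hh$household_id[hh$kind == "Residential" & hh$active &
                               hh$reference_person_id %in% dead_ids]
  for (h in lost_rp) pop <- succeed_reference_person(pop, h)
  pop <- close_empty_households(
    pop, unique(pop$simulants$household_id[dead]))
  list(pop = pop, deaths = dead_ids)
}

# close residential households with no present members; vacate addresses
close_empty_households <- function(pop, household_ids) {
  hh <- pop$households
  cand <- hh$household_id %in% household_ids & hh$kind == "Residential" &
    hh$active
  if (!any(cand)) return(pop)
  pres <- pop$simulants$household_id[pop$simulants$status == "present"]
  empty <- hh$household_id[cand & !(hh$household_id %in% pres)]
  if (length(empty) == 0) return(pop)
  sel <- hh$household_id %in% empty
  vacate_address(pop$address_registry,
                 c(hh$physical_address_id[sel], hh$mailing_address_id[sel]))
  pop$households$active[sel] <- FALSE
  pop$households$reference_person_id[sel] <- NA_integer_
  pop
}

#' Relationship remapping when a new reference person takes over
#'
#' Deterministic business rules mapping a member's relationship to the old
#' reference person into a relationship to the new reference person, given
#' the new reference person's former relationship `new_rp_rel`. Non-kin
#' relationships (roommate, other nonrelative, foster child) stay non-kin;
#' child types of the same generation become siblings; a parent of the old
#' reference person becomes the grandparent-side "Other relative" unless the
#' new reference person was a parent (then members who were children of the
#' old reference person become grandchildren); everything not directly
#' derivable collapses to "Other relative".
#'
#' @param relationship Character vector: members' former relationships.
#' @param new_rp_rel Former relationship of the new reference person.
#' @return Character vector of remapped relationships.
#' @export
remap_relationship <- function(relationship, new_rp_rel) {
  out <- rep("Other relative", length(relationship))
  nonkin <- relationship %in% .nonkin_relationships
  out[nonkin] <- "Other nonrelative"
  if (new_rp_rel %in% .child_relationships) {
    out[!nonkin & relationship %in% .child_relationships] <- "Sibling"
  } else if (new_rp_rel == "Parent") {
    out[!nonkin & relationship %in% .child_relationships] <- "Grandchild"
    # the old reference person's other parent
    out[!nonkin & relationship == "Parent"] <- "Other relative"
  } else if (new_rp_rel == "Sibling") {
    out[!nonkin & relationship == "Sibling"] <- "Sibling"
    out[!nonkin & relationship == "Parent"] <- "Parent"
  } else if (new_rp_rel == "Grandchild") {
    out[!nonkin & relationship == "Grandchild"] <- "Other relative"
  }
  out
}

#' Reference-person succession
#'
#' After a residential household's reference person dies or moves away, the
#' oldest remaining present member becomes the reference person and all other
#' members' relationships are remapped with [remap_relationship()]. A
#' household left with no present members is closed and its addresses are
#' vacated.
#'
#' @param pop A `sim_population`.
#' @param household_id Residential household to update.
#' @return Updated `sim_population`.
#' @export
succeed_reference_person <- function(pop, household_id) {
  s <- pop$simulants
  members <- which(s$household_id == household_id & s$status == "present")
  hrow <- which(pop$households$household_id == household_id)
  if (length(members) == 0) {
    return(close_empty_households(pop, household_id))
  }
  new_rp <- members[which.max(s$precise_age[members])]
  old_rel <- s$relationship[new_rp]
  others <- setdiff(members, new_rp)
  if (length(others) > 0 && !is.na(old_rel) &&
      old_rel != "Reference person") {
    pop$simulants$relationship[others] <-
      remap_relationship(s$relationship[others], old_rel)
  }
  pop$simulants$relationship[new_rp] <- "Reference person"
  pop$households$reference_person_id[hrow] <- s$simulant_id[new_rp]
  pop
}

# ---------------------------------------------------------------------------
# fertility

#' Relationship of a newborn to the household reference person
#'
#' Deterministic table keyed by the parent's relationship: the reference
#' person's newborn is a biological child; a child's newborn is a grandchild;
#' a grandchild's newborn and newborns of lateral kin are "Other relative";
#' newborns of non-kin members are "Other nonrelative".
#'
#' @param parent_relationship Character vector of parents' relationships.
#' @return Character vector of newborn relationships.
#' @export
newborn_relationship <- function(parent_relationship) {
  table <- c(
    "Reference person" = "Biological child",
    "Biological child" = "Grandchild",
    "Adopted child" = "Grandchild",
    "Stepchild" = "Grandchild",
    "Grandchild" = "Other relative",
    "Sibling" = "Other relative",
    "Parent" = "Other relative",
    "Parent-in-law" = "Other relative",
    "Child-in-law" = "Other relative",
    "Other relative" = "Other relative",
    "Roommate" = "Other nonrelative",
    "Other nonrelative" = "Other nonrelative",
    "Foster child" = "Other nonrelative"
  )
  if (any(!parent_relationship %in% names(table))) {
    stop("parent relationship not in the 13-value set")
  }
  unname(table[parent_relationship])
}

#' Apply one step of fertility
#'
#' Present female simulants have a per-step birth probability from the
#' age-specific fertility rate for their age group. Each birth event occurs
#' at a uniformly random time within the step; a configurable fraction
#' (default 4%) of birth events are twins. Newborns inherit household,
#' race/ethnicity, and (at identity assignment) last name from the single
#' identified parent, are US-born with an SSN, and get a relationship to the
#' reference person from [newborn_relationship()]. A newborn of a GQ-resident
#' parent is placed in the parent's GQ unit with no relationship.
#'
#' @param pop A `sim_population`.
#' @param fertility Fertility rate table (age_group, rate per person-year).
#' @param step_days Step length in days.
#' @param date Start date of the step.
#' @param twin_probability Probability a birth event is twins, in `[0, 1]`.
#' @param step Engine step index recorded on the newborns.
#' @return List with `pop` (updated), `births` (data.frame: mother_id,
#'   date, is_twin), and `newborn_ids`.
#' @export
apply_fertility <- function(pop, fertility, step_days = 28,
                            date = pop$current_date, twin_probability = 0.04,
                            step = 0L) {
  stopifnot(twin_probability >= 0, twin_probability <= 1)
  v <- rate_vector_fertility(fertility)
  s <- pop$simulants
  at_risk <- which(s$status == "present" & s$sex == "female")
  empty <- data.frame(mother_id = integer(0), date = as.Date(character(0)),
                      is_twin = logical(0))
  if (length(at_risk) == 0) {
    return(list(pop = pop, births = empty, newborn_ids = integer(0)))
  }
  rates <- v[age_group_index(s$precise_age[at_risk])]
  p <- rate_to_step_probability(rates, step_days)
  mothers <- at_risk[stats::runif(length(at_risk)) < p]
  if (length(mothers) == 0) {
    return(list(pop = pop, births = empty, newborn_ids = integer(0)))
  }
  n_events <- length(mothers)
  event_date <- as_date(date) + floor(stats::runif(n_events) * step_days)
  is_twin <- stats::runif(n_events) < twin_probability
  n_babies <- ifelse(is_twin, 2L, 1L)

  ev <- rep.int(seq_len(n_events), n_babies)
  n_new <- length(ev)
  mother_row <- mothers[ev]
  gq_ids <- pop$households$household_id[pop$households$kind != "Residential"]
  mother_in_gq <- s$household_id[mother_row] %in% gq_ids

  nb <- empty_simulants(n_new)
  nb$simulant_id <- pop$next_simulant_id + seq_len(n_new) - 1L
  nb$sex <- sample(c("male", "female"), n_new, replace = TRUE)
  nb$dob <- event_date[ev]
  nb$precise_age <- 0
  nb$race_ethnicity <- s$race_ethnicity[mother_row]
  nb$nativity <- "US-born"
  nb$has_ssn <- TRUE
  nb$household_id <- s$household_id[mother_row]
  nb$relationship[!mother_in_gq] <-
    newborn_relationship(s$relationship[mother_row[!mother_in_gq]])
  nb$mother_id <- s$simulant_id[mother_row]
  nb$entered_step <- as.integer(step)

  pop$simulants <- rbind(pop$simulants, nb)
  pop$next_simulant_id <- pop$next_simulant_id + n_new
  births <- data.frame(mother_id = s$simulant_id[mothers],
                       date = event_date, is_twin = is_twin)
  pop$births <- c(pop$births, list(births))
  list(pop = pop, births = births, newborn_ids = nb$simulant_id)
}
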