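test_that("zero mortality rates produce no deaths", {
  pop <- flat_population(200)
  set.seed(1)
  res <- apply_mortality(pop, constant_mortality_table(0))
  expect_length(res$deaths, 0)
  expect_true(all(simulants(res$pop)$status == "present"))
})

test_that("a constant hazard reproduces its analytic death probability", {
  # 0.02/yr on 10,000 simulants over 13 28-day steps (~one year)
  n <- 10000
  pop <- flat_population(n)
  tab <- constant_mortality_table(0.02)
  set.seed(2)
  for (i in 1:13) {
    res <- apply_mortality(pop, tab, step_days = 28)
    pop <- res$pop
  }
  deaths <- sum(simulants(pop)$status == "dead")
  p_expected <- 1 - exp(-0.02)
  se <- sqrt(n * p_expected * (1 - p_expected))
  expect_lt(abs(deaths - n * p_expected), 3 * se)
})

test_that("simulated crude death rate converges to the input rate at large n", {
  n <- 50000
  pop <- flat_population(n, age = 50)
  rate <- 0.01
  set.seed(3)
  res <- apply_mortality(pop, constant_mortality_table(rate), step_days = 28)
  p <- rate_to_step_probability(rate, 28)
  se <- sqrt(n * p * (1 - p))
  expect_lt(abs(length(res$deaths) - n * p), 3 * se)
})

test_that("missing mortality strata abort", {
  pop <- flat_population(10)
  tab <- constant_mortality_table(0.01)[-5, ]
  expect_error(apply_mortality(pop, tab), "missing strata")
})

test_that("succession promotes the oldest remaining member", {
  pop <- household_population(
    member_ages = list(c(70, 44, 17)),
    member_rels = list(c("Reference person", "Biological child",
                         "Grandchild")))
  # reference person (70) dies: the 44-year-old becomes reference person
  rp_id <- households(pop)$reference_person_id[
    households(pop)$kind == "Residential"]
  pop$simulants$status[pop$simulants$simulant_id == rp_id] <- "dead"
  pop$households$reference_person_id[
    households(pop)$kind == "Residential"] <- NA_integer_
  hh_id <- households(pop)$household_id[
    households(pop)$kind == "Residential"]
  pop <- succeed_reference_person(pop, hh_id)
  s <- simulants(pop)
  new_rp <- s[s$relationship %in% "Reference person" &
                s$status == "present", ]
  expect_equal(nrow(new_rp), 1)
  expect_equal(new_rp$precise_age, 44)
  # the grandchild (child of the new reference person's generation) remaps
  other <- s[s$status == "present" & s$simulant_id != new_rp$simulant_id, ]
  expect_true(all(other$relationship %in% relationship_values))
})

test_that("a lone remaining member becomes reference person, however young", {
  pop <- household_population(
    member_ages = list(c(40, 17)),
    member_rels = list(c("Reference person", "Biological child")))
  rp_id <- households(pop)$reference_person_id[
    households(pop)$kind == "Residential"]
  pop$simulants$status[pop$simulants$simulant_id == rp_id] <- "dead"
  hh_id <- households(pop)$household_id[
    households(pop)$kind == "Residential"]
  pop$households$reference_person_id[
    pop$households$household_id == hh_id] <- NA_integer_
  pop <- succeed_reference_person(pop, hh_id)
  s <- simulants(pop)
  minor <- s[s$status == "present", ]
  expect_equal(minor$precise_age, 17)
  expect_equal(minor$relationship, "Reference person")
})

test_that("relationship remapping follows the documented business rules", {
  expect_equal(remap_relationship("Biological child", "Biological child"),
               "Sibling")
  expect_equal(remap_relationship("Stepchild", "Biological child"),
               "Sibling")
  expect_equal(remap_relationship("Biological child", "Parent"),
               "Grandchild")
  expect_equal(remap_relationship("Parent", "Sibling"), "Parent")
  expect_equal(remap_relationship("Roommate", "Biological child"),
               "Other nonrelative")
  expect_equal(remap_relationship("Foster child", "Sibling"),
               "Other nonrelative")
  expect_equal(remap_relationship("Parent-in-law", "Grandchild"),
               "Other relative")
  # closure: everything maps into the 13-value set
  for (r0 in setdiff(relationship_values, "Reference person")) {
    out <- remap_relationship(
      setdiff(relationship_values, "Reference person"), r0)
    expect_true(all(out %in% relationship_values))
  }
})

test_that("newborn relationships follow the kinship table", {
  expect_equal(newborn_relationship("Reference person"), "Biological child")
  expect_equal(newborn_relationship("Biological child"), "Grandchild")
  expect_equal(newborn_relationship("Adopted child"), "Grandchild")
  expect_equal(newborn_relationship("Grandchild"), "Other relative")
  expect_equal(newborn_relationship("Roommate"), "Other nonrelative")
  expect_equal(newborn_relationship("Sibling"), "Other relative")
  out <- newborn_relationship(setdiff(relationship_values, character(0)))
  expect_true(all(out %in% relationship_values))
  expect_error(newborn_relationship("Cousin"), "13-value")
})

test_that("zero twin probability yields only singleton births", {
  pop <- flat_population(2000, age = 27, sex = "female")
  set.seed(4)
  res <- apply_fertility(pop, constant_fertility_table(1), step_days = 28,
                         twin_probability = 0)
  expect_gt(nrow(res$births), 0)
  expect_true(all(!res$births$is_twin))
  expect_equal(length(res$newborn_ids), nrow(res$births))
})

test_that("twin events occur at the configured 4% of birth events", {
  pop <- flat_population(4000, age = 27, sex = "female")
  tab <- constant_fertility_table(2)
  set.seed(5)
  events <- 0L
  twins <- 0L
  while (events < 10000) {
    res <- apply_fertility(pop, tab, step_days = 28,
                           twin_probability = 0.04)
    events <- events + nrow(res$births)
    twins <- twins + sum(res$births$is_twin)
    # keep the at-risk set fixed: do not accumulate newborns
  }
  se <- sqrt(0.04 * 0.96 / events)
  expect_lt(abs(twins / events - 0.04), 3 * se)
})

test_that("newborns inherit household, race/ethnicity and are US-born with SSN", {
  pop <- household_population(
    member_ages = list(c(30, 28)),
    member_rels = list(c("Reference person", "Sibling")))
  pop$simulants$race_ethnicity <- "Latino"
  pop$simulants$sex <- "female"
  set.seed(6)
  res <- apply_fertility(pop, constant_fertility_table(60, c("25-29",
                                                             "30-34")),
                         step_days = 28)
  expect_gt(length(res$newborn_ids), 0)
  s <- simulants(res$pop)
  nb <- s[s$simulant_id %in% res$newborn_ids, ]
  mothers <- s[match(nb$mother_id, s$simulant_id), ]
  expect_equal(nb$household_id, mothers$household_id)
  expect_equal(nb$race_ethnicity, mothers$race_ethnicity)
  expect_true(all(nb$nativity == "US-born"))
  expect_true(all(nb$has_ssn))
  expect_true(all(nb$relationship %in%
                    newborn_relationship(mothers$relationship)))
})

test_that("twins share household and date of birth", {
  pop <- flat_population(3000, age = 27, sex = "female")
  set.seed(7)
  res <- apply_fertility(pop, constant_fertility_table(2), step_days = 28,
                         twin_probability = 1)
  expect_true(all(res$births$is_twin))
  s <- simulants(res$pop)
  nb <- s[s$simulant_id %in% res$newborn_ids, ]
  by_mother <- split(nb, nb$mother_id)
  for (tw in by_mother) {
    expect_equal(nrow(tw), 2)
    expect_equal(tw$dob[1], tw$dob[2])
    expect_equal(tw$household_id[1], tw$household_id[2])
  }
})

test_that("mortality before fertility prevents same-step death and birth", {
  fx <- generate_fixtures(seed = 41, n_households = 150,
                          rate_config = list(mortality_base = 0.02))
  cfg <- sim_config(target_population = 500, master_seed = 12, steps = 13,
                    components = list(domestic_migration = FALSE,
                                      emigration = FALSE,
                                      immigration = FALSE,
                                      employment = FALSE),
                    observers = list(survey = FALSE))
  r <- run_simulation(cfg, fx)
  s <- simulants(r$population)
  births <- do.call(rbind, r$population$births)
  if (!is.null(births)) {
    dead <- s[s$status == "dead", "simulant_id"]
    dead_mothers <- births$mother_id %in% dead
    # a dead simulant can have given birth in an earlier step, but never in
    # the step they died: event dates of their births precede death
    expect_true(all(births$date[dead_mothers] < r$population$current_date))
  }
  # one reference person per occupied residential household, every run end
  expect_silent(validate_population(r$population))
})
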