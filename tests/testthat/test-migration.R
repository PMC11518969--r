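test_that("zero migration rates produce no moves of any kind", {
  pop <- household_population(
    member_ages = list(c(40, 12), c(35, 33)),
    member_rels = list(c("Reference person", "Biological child"),
                       c("Reference person", "Roommate")))
  set.seed(1)
  ind <- apply_domestic_individual(pop, constant_asr_table(0))
  expect_length(ind$moved, 0)
  hh <- apply_domestic_household(pop, constant_asr_table(0))
  expect_length(hh$moved_households, 0)
  em <- apply_emigration(pop, constant_emigration_table(0))
  expect_length(em$emigrated, 0)
  im <- apply_immigration(pop, generate_microdata(50, seed = 1),
                          data.frame(move_type = c("household", "gq_person",
                                                   "non_reference_person"),
                                     events_per_year = 0))
  expect_length(im$immigrant_ids, 0)
})

test_that("individual movers joining a household become Other nonrelative", {
  pop <- household_population(
    member_ages = rep(list(c(40, 35)), 30),
    member_rels = rep(list(c("Reference person", "Sibling")), 30))
  set.seed(2)
  res <- apply_domestic_individual(
    pop, constant_asr_table(3),
    destination_split = c(new_household = 0, join_household = 1, gq = 0))
  expect_gt(length(res$moved), 0)
  s <- simulants(res$pop)
  moved <- s[s$simulant_id %in% res$moved, ]
  expect_true(all(moved$relationship == "Other nonrelative" |
                    moved$relationship == "Reference person"))
  # movers who were not promoted by succession are exactly Other nonrelative
  joined <- moved[moved$relationship == "Other nonrelative", ]
  expect_gt(nrow(joined), 0)
})

test_that("new-household movers become the reference person of a fresh unit", {
  pop <- household_population(
    member_ages = rep(list(c(40, 35)), 10),
    member_rels = rep(list(c("Reference person", "Sibling")), 10))
  set.seed(3)
  res <- apply_domestic_individual(
    pop, constant_asr_table(3),
    destination_split = c(new_household = 1, join_household = 0, gq = 0))
  expect_gt(length(res$moved), 0)
  s <- simulants(res$pop)
  moved <- s[s$simulant_id %in% res$moved, ]
  expect_true(all(moved$relationship == "Reference person"))
  hh <- households(res$pop)
  new_hh <- hh[hh$household_id %in% moved$household_id, ]
  expect_true(all(new_hh$reference_person_id %in% moved$simulant_id))
  expect_silent(validate_population(res$pop))
})

test_that("at most one individual migration per simulant per step", {
  pop <- household_population(
    member_ages = rep(list(c(40, 35)), 25),
    member_rels = rep(list(c("Reference person", "Roommate")), 25))
  set.seed(4)
  res <- apply_domestic_individual(pop, constant_asr_table(50))
  expect_false(any(duplicated(res$moved)))
})

test_that("working-age individual movers change employment", {
  pop <- household_population(
    member_ages = rep(list(c(40, 16)), 20),
    member_rels = rep(list(c("Reference person", "Biological child")), 20))
  pop$employers <- initialize_employers(10, seed = 5)
  set.seed(5)
  adults <- which(pop$simulants$precise_age >= 18)
  pop <- linksim:::resample_employment(pop, adults, pop$current_date)
  res <- apply_domestic_individual(pop, constant_asr_table(5))
  s <- simulants(res$pop)
  moved <- s[s$simulant_id %in% res$moved, ]
  expect_gt(nrow(moved), 0)
  # every moved adult has an employment stint boundary at the move date
  moved_adults <- moved[moved$precise_age >= 18, ]
  expect_equal(res$employment_changes, nrow(moved_adults))
  expect_true(all(moved_adults$employer_since == pop$current_date))
  # minors never hold employment
  expect_true(all(is.na(s$employer_id[s$precise_age < 18])))
})

test_that("one-person households are never selected for household moves", {
  pop <- household_population(
    member_ages = c(rep(list(40), 15), rep(list(c(40, 38)), 15)),
    member_rels = c(rep(list("Reference person"), 15),
                    rep(list(c("Reference person", "Sibling")), 15)))
  set.seed(6)
  res <- apply_domestic_household(pop, constant_asr_table(100))
  hh <- households(pop)
  sizes <- table(pop$simulants$household_id)
  moved_sizes <- sizes[as.character(res$moved_households)]
  expect_gt(length(res$moved_households), 0)
  expect_true(all(moved_sizes > 1))
})

test_that("household moves change addresses but preserve relationships", {
  pop <- household_population(
    member_ages = rep(list(c(40, 38, 10)), 12),
    member_rels = rep(list(c("Reference person", "Sibling",
                             "Biological child")), 12))
  before <- simulants(pop)[, c("simulant_id", "relationship",
                               "household_id")]
  addr_before <- households(pop)[, c("household_id",
                                     "physical_address_id")]
  set.seed(7)
  res <- apply_domestic_household(pop, constant_asr_table(100))
  expect_gt(length(res$moved_households), 0)
  after <- simulants(res$pop)[, c("simulant_id", "relationship",
                                  "household_id")]
  expect_identical(before, after)
  addr_after <- households(res$pop)
  moved <- res$moved_households
  old <- addr_before$physical_address_id[
    match(moved, addr_before$household_id)]
  new <- addr_after$physical_address_id[
    match(moved, addr_after$household_id)]
  expect_true(all(old != new))
  # vacated addresses are recorded and never reissued
  reg <- res$pop$address_registry
  expect_true(all(old %in% reg$vacated))
  later <- new_address(reg, 50)
  expect_false(any(later %in% old))
})

test_that("emigrants leave permanently and whole-household moves empty the unit", {
  pop <- household_population(
    member_ages = rep(list(c(40, 38)), 40),
    member_rels = rep(list(c("Reference person", "Sibling")), 40))
  tab <- constant_emigration_table(0)
  tab$rate[tab$move_type == "household"] <- 30
  set.seed(8)
  res <- apply_emigration(pop, tab)
  expect_gt(length(res$emigrated), 0)
  s <- simulants(res$pop)
  gone <- s[s$simulant_id %in% res$emigrated, ]
  expect_true(all(gone$status == "emigrated"))
  # household-type events removed entire households
  left_hh <- unique(gone$household_id)
  remaining <- s[s$household_id %in% left_hh & s$status == "present", ]
  expect_equal(nrow(remaining), 0)
  hh <- households(res$pop)
  expect_true(all(!hh$active[hh$household_id %in% left_hh]))
})

test_that("non-reference-person emigration never removes a reference person", {
  pop <- household_population(
    member_ages = rep(list(c(40, 38, 35)), 30),
    member_rels = rep(list(c("Reference person", "Sibling", "Roommate")),
                      30))
  tab <- constant_emigration_table(0)
  tab$rate[tab$move_type == "non_reference_person"] <- 20
  set.seed(9)
  res <- apply_emigration(pop, tab)
  expect_gt(length(res$emigrated), 0)
  s <- simulants(res$pop)
  hh <- households(res$pop)
  res_hh <- hh[hh$kind == "Residential", ]
  # every remaining active household still has its original reference person
  expect_true(all(res_hh$reference_person_id %in%
                    s$simulant_id[s$status == "present"]))
  gone <- s[s$simulant_id %in% res$emigrated, ]
  expect_false(any(gone$relationship %in% "Reference person"))
})

test_that("immigration volume follows the Poisson expectation over a year", {
  pop <- household_population(
    member_ages = rep(list(c(40, 38)), 5),
    member_rels = rep(list(c("Reference person", "Sibling")), 5))
  md <- generate_microdata(400, seed = 10,
                           config = list(recent_immigrant_fraction = 0.3))
  counts <- data.frame(
    move_type = c("household", "gq_person", "non_reference_person"),
    events_per_year = c(0, 1000, 0))
  set.seed(11)
  total <- 0L
  for (i in 1:13) {
    res <- apply_immigration(pop, md, counts, step_days = 28)
    total <- total + length(res$immigrant_ids)
  }
  lambda <- 1000 * 13 * 28 / 365.25
  expect_lt(abs(total - lambda), 3 * sqrt(lambda))
})

test_that("immigrant ages are not perturbed and households keep structure", {
  pop <- household_population(
    member_ages = rep(list(c(40, 38)), 5),
    member_rels = rep(list(c("Reference person", "Sibling")), 5))
  md <- generate_microdata(300, seed = 12,
                           config = list(recent_immigrant_fraction = 0.25))
  counts <- data.frame(
    move_type = c("household", "gq_person", "non_reference_person"),
    events_per_year = c(200, 50, 100))
  set.seed(13)
  res <- apply_immigration(pop, md, counts, step_days = 28)
  expect_gt(length(res$immigrant_ids), 0)
  s <- simulants(res$pop)
  im <- s[s$simulant_id %in% res$immigrant_ids, ]
  # integer age equals a source-record age: no normal shift applied
  expect_true(all(floor(im$precise_age) %in% md$age_years))
  expect_true(all(im$nativity == "foreign-born"))
  expect_silent(validate_population(res$pop))
  # non-reference joiners never arrive as reference person
  hh <- households(res$pop)
  gq_ids <- hh$household_id[hh$kind != "Residential"]
  joiners <- im[!(im$household_id %in% gq_ids) &
                  im$household_id %in% pop$households$household_id, ]
  expect_false(any(joiners$relationship %in% "Reference person"))
})

test_that("positive immigration with no recent-immigrant records aborts", {
  pop <- flat_population(10)
  md <- generate_microdata(20, seed = 14,
                           config = list(recent_immigrant_fraction = 0))
  counts <- data.frame(
    move_type = c("household", "gq_person", "non_reference_person"),
    events_per_year = c(5000, 0, 0))
  set.seed(15)
  expect_error(apply_immigration(pop, md, counts),
               "recent-immigrant")
})

test_that("issued addresses are unique and vacated ids never return", {
  reg <- new_address_registry(generate_address_lexicon(seed = 1))
  set.seed(16)
  a <- new_address(reg, 2)
  expect_length(unique(a), 2)
  ids <- new_address(reg, 10000)
  expect_length(unique(ids), 10000)
  expect_false(any(ids %in% a))
  vacate_address(reg, ids[1:5])
  more <- new_address(reg, 100)
  expect_false(any(more %in% ids[1:5]))
  df <- addresses(reg)
  expect_equal(nrow(df), 10102)
  expect_false(any(duplicated(df$address_id)))
  key <- paste(df$street_number, df$street_name, df$street_suffix, df$unit,
               df$city, df$po_box)
  expect_false(any(duplicated(key)))
})

test_that("other-nonrelative share drifts upward under individual migration", {
  fx <- generate_fixtures(seed = 51, n_households = 150,
                          rate_config = list(mortality_base = 0,
                                             emigration_base = 0))
  cfg <- sim_config(target_population = 400, master_seed = 17, steps = 39,
                    components = list(mortality = FALSE, fertility = FALSE,
                                      emigration = FALSE,
                                      immigration = FALSE,
                                      employment = FALSE),
                    observers = list(survey = FALSE, tax = FALSE,
                                     wic = FALSE, census = FALSE))
  r <- run_simulation(cfg, fx)
  s0 <- simulants(r$population)
  frac_end <- mean(s0$relationship %in% "Other nonrelative", na.rm = TRUE)
  frac_start <- mean(
    fx$microdata$relationship_code %in% "Other nonrelative")
  expect_gt(frac_end, frac_start)
})
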