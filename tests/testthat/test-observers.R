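# a small fully-run simulation shared across observer tests
obs_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- generate_fixtures(seed = 61, n_households = 150)
      cfg <- sim_config(target_population = 400, master_seed = 21,
                        start_date = "2019-06-01",
                        end_threshold_date = "2021-01-15",
                        observers = list(survey = TRUE, survey_rate = 0.05))
      cache <<- list(result = run_simulation(cfg, fx), fixtures = fx)
    }
    cache
  }
})

test_that("census rows carry the full schema with floored ages", {
  r <- obs_fixture()$result
  cens <- r$observations[["decennial_census_2020"]]
  expect_s3_class(cens, "observation_table")
  expect_true(all(c("simulant_id", "first_name", "middle_initial",
                    "last_name", "age", "date_of_birth", "sex",
                    "race_ethnicity", "relationship_to_reference_person",
                    "housing_kind") %in% names(cens)))
  expect_gt(nrow(cens), 0)
  s <- simulants(r$population)
  dob <- s$dob[match(cens$simulant_id, s$simulant_id)]
  expect_equal(cens$age,
               floor(as.numeric(as.Date("2020-04-01") - dob) / 365.25))
  expect_true(all(cens$sex %in% c("F", "M")))
})

test_that("a known date of birth yields the floored census age", {
  # DOB 1993-08-05 observed 2020-04-01 reads age 26
  pop <- flat_population(1, age = 26)
  pop$simulants$dob <- as.Date("1993-08-05")
  pop <- assign_names(pop, generate_name_tables(seed = 1))
  tab <- observe_decennial_census(pop, as.Date("2020-04-01"))
  expect_equal(tab$age, 26)
  expect_equal(tab$date_of_birth, "08/05/1993")
})

test_that("dead and emigrated simulants never appear in later observations", {
  r <- obs_fixture()$result
  s <- simulants(r$population)
  gone <- s[s$status != "present", ]
  expect_gt(nrow(gone), 0)
  for (tbl in r$observations) {
    d <- attr(tbl, "date")
    banned <- gone$simulant_id[gone$status_date < d]
    expect_false(any(tbl$simulant_id %in% banned))
  }
  # direct check: construct a death mid-run and observe afterwards
  pop <- household_population(
    member_ages = list(c(40, 35)),
    member_rels = list(c("Reference person", "Sibling")))
  pop <- assign_names(pop, generate_name_tables(seed = 2))
  victim <- simulants(pop)$simulant_id[2]
  pop$simulants$status[2] <- "dead"
  cens <- observe_decennial_census(pop, as.Date("2020-04-01"))
  expect_false(victim %in% cens$simulant_id)
  srv <- observe_household_survey(pop, as.Date("2020-04-01"), 1)
  expect_false(victim %in% srv$simulant_id)
})

test_that("every observation row carries a ground-truth simulant id", {
  r <- obs_fixture()$result
  s <- simulants(r$population)
  for (tbl in r$observations) {
    if (nrow(tbl) > 0) {
      expect_true(all(tbl$simulant_id %in% s$simulant_id))
    }
  }
})

test_that("tax rows cover stints with one row per employer and a 1040 per filer", {
  r <- obs_fixture()$result
  tax <- r$observations[["tax_2020"]]
  expect_s3_class(tax, "observation_table")
  expect_true(all(c("simulant_id", "first_name", "last_name", "ssn",
                    "employer_name", "wages", "tax_form") %in% names(tax)))
  wage_rows <- tax[tax$tax_form %in% c("W2", "1099"), ]
  expect_gt(nrow(wage_rows), 0)
  # a mid-year employer change yields multiple wage rows, same identity,
  # different employers (a change can also re-draw the same employer)
  n_emp <- tapply(wage_rows$employer_name, wage_rows$simulant_id,
                  function(x) length(unique(x)))
  expect_gt(max(n_emp), 1)
  switcher <- as.integer(names(which.max(n_emp)))
  rows <- wage_rows[wage_rows$simulant_id == switcher, ]
  expect_equal(length(unique(rows$ssn)), 1)
  expect_equal(length(unique(rows$last_name)), 1)
  # every filer has exactly one 1040 with their total wages
  f1040 <- tax[tax$tax_form == "1040", ]
  expect_false(any(duplicated(f1040$simulant_id)))
  totals <- tapply(wage_rows$wages, wage_rows$simulant_id, sum)
  expect_equal(as.numeric(totals[as.character(f1040$simulant_id)]),
               f1040$wages)
  # identifiers: SSN where held, ITIN (leading 9) otherwise; never blank
  expect_true(all(!is.na(tax$ssn)))
  s <- simulants(r$population)
  no_ssn <- !s$has_ssn[match(f1040$simulant_id, s$simulant_id)]
  expect_true(all(substr(f1040$ssn[no_ssn], 1, 1) == "9"))
})

test_that("ITINs are issued only to SSN-less filers", {
  r <- obs_fixture()$result
  s <- simulants(r$population)
  expect_true(all(is.na(s$itin[s$has_ssn])))
})

test_that("unemployed simulants with no wages file no wage rows", {
  pop <- flat_population(30, age = 40)
  pop$employers <- initialize_employers(
    3, config = list(p_unemployed = 1 - 1e-9, p_military = 0), seed = 3)
  set.seed(3)
  pop <- apply_employment_change(pop, change_rate = 0)$pop
  pop <- assign_names(pop, generate_name_tables(seed = 3))
  pop$current_date <- as.Date("2019-12-31")
  tax <- observe_tax(pop, 2019)
  expect_equal(nrow(tax[tax$tax_form %in% c("W2", "1099"), ]), 0)
})

test_that("WIC respects the household income threshold and categories", {
  r <- obs_fixture()$result
  pop <- r$population
  # threshold 0: empty
  wic0 <- observe_wic(pop, 2020, config = list(multiplier = 0))
  expect_equal(nrow(wic0), 0)
  # infinite threshold: exactly the eligible categories
  wic_inf <- observe_wic(pop, 2020, config = list(multiplier = 1e12))
  s <- simulants(pop)
  births <- do.call(rbind, pop$births)
  mothers_2020 <- unique(births$mother_id[format(births$date, "%Y") ==
                                            "2020"])
  date <- as.Date("2020-12-31")
  age_at <- floor(as.numeric(date - s$dob) / 365.25)
  eligible <- s$simulant_id[s$status == "present" &
                              (s$simulant_id %in% mothers_2020 |
                                 age_at < 5)]
  expect_setequal(wic_inf$simulant_id, eligible)
  # default threshold: a subset of the eligible categories, and every
  # member's household is below its threshold
  wic <- observe_wic(pop, 2020)
  expect_true(all(wic$simulant_id %in% eligible))
})

test_that("household survey sampling rates 0 and 1 bracket the population", {
  r <- obs_fixture()$result
  pop <- r$population
  set.seed(4)
  none <- observe_household_survey(pop, pop$current_date, 0)
  expect_equal(nrow(none), 0)
  all_rows <- observe_household_survey(pop, pop$current_date, 1)
  s <- simulants(pop)
  hh <- households(pop)
  res_ids <- hh$household_id[hh$kind == "Residential" & hh$active]
  expected <- s$simulant_id[s$status == "present" &
                              s$household_id %in% res_ids]
  expect_setequal(all_rows$simulant_id, expected)
  # fixed seed reproduces the sample
  set.seed(99)
  a <- observe_household_survey(pop, pop$current_date, 0.3)
  set.seed(99)
  b <- observe_household_survey(pop, pop$current_date, 0.3)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("observation tables serialize with a run manifest", {
  r <- obs_fixture()$result
  dir <- withr::local_tempdir()
  man <- write_observations(r$observations, dir, config_hash = "abc")
  files <- list.files(dir)
  expect_true("run_manifest.json" %in% files)
  expect_true(any(grepl("^decennial_census_2020\\.csv$", files)))
  expect_true(any(grepl("^tax_", files)))
  expect_equal(length(man$outputs), length(r$observations))
  back <- utils::read.csv(file.path(dir, "decennial_census_2020.csv"))
  expect_equal(nrow(back),
               nrow(r$observations[["decennial_census_2020"]]))
})
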