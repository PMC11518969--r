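# Dataset observers: decennial census, tax forms, WIC, and a household
# survey, each emitting rows that carry ground-truth simulant ids.

observation_table <- function(rows, dataset, date = NULL, year = NULL) {
  attr(rows, "dataset") <- dataset
  attr(rows, "date") <- date
  attr(rows, "year") <- year
  class(rows) <- c("observation_table", "data.frame")
  rows
}

#' @export
print.observation_table <- function(x, ...) {
  cat(sprintf("<observation_table: %s%s, %d rows>\n",
              attr(x, "dataset"),
              if (!is.null(attr(x, "year"))) {
                paste0(" ", attr(x, "year"))
              } else paste0(" ", format(attr(x, "date"))),
              nrow(x)))
  NextMethod()
}

# floored age in whole years at an observation date
observed_age <- function(dob, date) {
  floor(as.numeric(as_date(date) - dob) / days_per_year)
}

# census-like row block for the given simulant rows
census_rows <- function(pop, rows, date) {
  s <- pop$simulants[rows, , drop = FALSE]
  hh <- pop$households
  hmatch <- match(s$household_id, hh$household_id)
  addr <- addresses(pop$address_registry)
  amatch <- match(hh$physical_address_id[hmatch], addr$address_id)
  kind <- hh$kind[hmatch]
  data.frame(
    simulant_id = s$simulant_id,
    first_name = s$first_name,
    middle_initial = substr(s$middle_name, 1, 1),
    last_name = s$last_name,
    age = observed_age(s$dob, date),
    date_of_birth = format(s$dob, "%m/%d/%Y"),
    sex = ifelse(s$sex == "female", "F", "M"),
    race_ethnicity = s$race_ethnicity,
    relationship_to_reference_person = s$relationship,
    street_number = addr$street_number[amatch],
    street_name = addr$street_name[amatch],
    street_suffix = addr$street_suffix[amatch],
    unit = addr$unit[amatch],
    city = addr$city[amatch],
    state = addr$state[amatch],
    zipcode = addr$zip[amatch],
    housing_kind = kind,
    stringsAsFactors = FALSE
  )
}

#' Observe a decennial census
#'
#' One row per present simulant (full enumeration; coverage noise is out of
#' scope), with floored age at the census date, date of birth, sex,
#' race/ethnicity, relationship to reference person (NA for GQ residents),
#' household address components, and GQ kind. Simulants dead or emigrated
#' before the census date are absent.
#'
#' @param pop A `sim_population`.
#' @param census_date Observation date (default schedule: April 1 of years
#'   divisible by 10).
#' @return An `observation_table`.
#' @export
observe_decennial_census <- function(pop, census_date) {
  rows <- which(pop$simulants$status == "present")
  observation_table(census_rows(pop, rows, census_date), "decennial_census",
                    date = as_date(census_date),
                    year = as.integer(format(as_date(census_date), "%Y")))
}

#' Observe tax forms for a calendar year
#'
#' One W2/1099 row per employment stint overlapping the tax year (form kind
#' is the employer's), with wages prorated linearly by the stint's fraction
#' of the year; a simulant employed by two employers in sequence yields two
#' rows. Each filer (a simulant with at least one wage row) additionally
#' files a 1040 with total wages; filers without an SSN are issued an ITIN,
#' which appears in place of the SSN. Simulants whose status changed before
#' the start of the tax year are absent.
#'
#' @param pop A `sim_population` (with names assigned).
#' @param tax_year Calendar year.
#' @return An `observation_table` dated January 1 of the tax year.
#' @export
observe_tax <- function(pop, tax_year) {
  st <- stints_for_year(pop, tax_year)
  s <- pop$simulants
  empty <- data.frame(simulant_id = integer(0), first_name = character(0),
                      last_name = character(0), ssn = character(0),
                      employer_name = character(0), wages = numeric(0),
                      tax_form = character(0), stringsAsFactors = FALSE)
  obs_date <- as.Date(sprintf("%d-01-01", tax_year))
  if (is.null(st) || nrow(st) == 0) {
    return(observation_table(empty, "tax", date = obs_date,
                             year = tax_year))
  }
  st <- st[st$employer_id != UNEMPLOYED_ID & st$income > 0, , drop = FALSE]
  year_days <- as.numeric(as.Date(sprintf("%d-12-31", tax_year)) -
                            as.Date(sprintf("%d-01-01", tax_year))) + 1
  smatch <- match(st$simulant_id, s$simulant_id)
  # exclude simulants already dead/emigrated before the year started
  keep <- s$status[smatch] == "present" | is.na(st$end) |
    st$end >= obs_date
  st <- st[keep, , drop = FALSE]
  smatch <- smatch[keep]
  if (nrow(st) == 0) {
    return(observation_table(empty, "tax", date = obs_date,
                             year = tax_year))
  }
  wages <- round(st$income * st$overlap_days / year_days)

  # issue ITINs to SSN-less filers
  filers <- unique(st$simulant_id)
  frow <- match(filers, s$simulant_id)
  need_itin <- frow[!s$has_ssn[frow] & is.na(s$itin[frow])]
  if (length(need_itin) > 0) {
    pop$simulants$itin[need_itin] <-
      generate_itin(pop$itin_registry, length(need_itin))
    s <- pop$simulants
  }
  tax_id <- ifelse(s$has_ssn[smatch], s$ssn[smatch], s$itin[smatch])

  emp <- pop$employers
  wage_rows <- data.frame(
    simulant_id = st$simulant_id,
    first_name = s$first_name[smatch],
    last_name = s$last_name[smatch],
    ssn = tax_id,
    employer_name = emp$name[match(st$employer_id, emp$employer_id)],
    wages = wages,
    tax_form = emp$tax_form[match(st$employer_id, emp$employer_id)],
    stringsAsFactors = FALSE
  )
  total <- tapply(wage_rows$wages, wage_rows$simulant_id, sum)
  frow2 <- match(as.integer(names(total)), s$simulant_id)
  f1040 <- data.frame(
    simulant_id = as.integer(names(total)),
    first_name = s$first_name[frow2],
    last_name = s$last_name[frow2],
    ssn = ifelse(s$has_ssn[frow2], s$ssn[frow2], s$itin[frow2]),
    employer_name = NA_character_,
    wages = as.numeric(total),
    tax_form = "1040",
    stringsAsFactors = FALSE
  )
  out <- rbind(wage_rows, f1040)
  rownames(out) <- NULL
  tbl <- observation_table(out, "tax", date = obs_date, year = tax_year)
  attr(tbl, "population") <- NULL
  # ITIN issuance mutated the population; return it alongside via attribute
  structure(tbl, updated_population = pop)
}

#' Observe WIC enrollment for a calendar year
#'
#' Rows only for members of households whose summed member income is below
#' the configured threshold, restricted to the eligible categories: women
#' with a birth event during the year, and children under five at year end.
#' Observed at December 31 of the year; simulants not present then are
#' absent.
#'
#' @param pop A `sim_population`.
#' @param year Calendar year.
#' @param config Optional list overriding `income_base` (threshold for a
#'   one-person household, default 14580), `income_per_member` (5140), and
#'   `multiplier` (1.85): the threshold is
#'   `multiplier * (income_base + income_per_member * (size - 1))`.
#' @return An `observation_table` dated December 31.
#' @export
observe_wic <- function(pop, year, config = list()) {
  cfg <- merge_config(list(income_base = 14580, income_per_member = 5140,
                           multiplier = 1.85), config)
  date <- as.Date(sprintf("%d-12-31", year))
  s <- pop$simulants
  pres <- which(s$status == "present")
  births <- if (length(pop$births) > 0) do.call(rbind, pop$births) else NULL
  birth_mothers <- if (!is.null(births)) {
    unique(births$mother_id[format(births$date, "%Y") == as.character(year)])
  } else integer(0)
  eligible <- pres[(s$simulant_id[pres] %in% birth_mothers) |
                     observed_age(s$dob[pres], date) < 5]
  if (length(eligible) == 0) {
    return(observation_table(census_rows(pop, integer(0), date), "wic",
                             date = date, year = year))
  }
  # household income and size over present members
  hh_income <- tapply(s$income[pres], s$household_id[pres], sum)
  hh_size <- tapply(rep(1L, length(pres)), s$household_id[pres], sum)
  thresh <- cfg$multiplier *
    (cfg$income_base + cfg$income_per_member * (hh_size - 1))
  ok_hh <- as.integer(names(hh_income))[hh_income < thresh]
  eligible <- eligible[s$household_id[eligible] %in% ok_hh]
  observation_table(census_rows(pop, eligible, date), "wic", date = date,
                    year = year)
}

#' Observe a household survey
#'
#' Active residential households are sampled independently at
#' `sampling_rate`; one census-like row per present member of each sampled
#' household.
#'
#' @param pop A `sim_population`.
#' @param date Survey date.
#' @param sampling_rate Probability each household is sampled, in `[0, 1]`.
#' @return An `observation_table`.
#' @export
observe_household_survey <- function(pop, date, sampling_rate) {
  stopifnot(sampling_rate >= 0, sampling_rate <= 1)
  hh <- pop$households
  res <- hh$household_id[hh$kind == "Residential" & hh$active]
  sampled <- res[stats::runif(length(res)) < sampling_rate]
  s <- pop$simulants
  rows <- which(s$status == "present" & s$household_id %in% sampled)
  observation_table(census_rows(pop, rows, date), "household_survey",
                    date = as_date(date),
                    year = as.integer(format(as_date(date), "%Y")))
}

#' Write observation tables and a run manifest
#'
#' Each table goes to `<dataset>_<year>.csv` (UTF-8, comma-separated,
#' header row); `run_manifest.json` lists files, row counts, and the
#' configuration hash.
#'
#' @param observations List of `observation_table`s (e.g.
#'   `sim_result$observations`).
#' @param dir Output directory.
#' @param config_hash Optional hash string recorded in the manifest.
#' @return Invisibly, the manifest list.
#' @export
write_observations <- function(observations, dir, config_hash = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(observations, function(tbl) {
    stamp <- if (identical(attr(tbl, "dataset"), "household_survey")) {
      format(attr(tbl, "date"), "%Y%m%d")
    } else {
      attr(tbl, "year")
    }
    fname <- sprintf("%s_%s.csv", attr(tbl, "dataset"), stamp)
    utils::write.csv(as.data.frame(tbl), file.path(dir, fname),
                     row.names = FALSE, fileEncoding = "UTF-8")
    list(file = fname, dataset = attr(tbl, "dataset"),
         year = attr(tbl, "year"), rows = nrow(tbl))
  })
  manifest <- list(outputs = unname(entries), config_hash = config_hash)
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
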