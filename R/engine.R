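# Simulation engine: clock, configuration, per-component seeded substreams,
# fixed component ordering, and the run loop with its event accounting.

#' Number of simulation steps
#'
#' The clock starts at `start_date` and advances in `step_days` increments
#' until it strictly exceeds `end_threshold_date`; the step count is the
#' smallest k with `start_date + k * step_days > end_threshold_date`.
#'
#' @param start_date,end_threshold_date Dates (start <= threshold).
#' @param step_days Positive integer step length in days.
#' @return Integer number of steps (>= 1).
#' @export
num_steps <- function(start_date, end_threshold_date, step_days = 28) {
  if (step_days < 1) stop("step_days must be a positive integer")
  start_date <- as_date(start_date)
  end_threshold_date <- as_date(end_threshold_date)
  if (start_date > end_threshold_date) {
    stop("start_date must not be after end_threshold_date")
  }
  diff <- as.numeric(end_threshold_date - start_date)
  as.integer(diff %/% step_days) + 1L
}

#' Convert a yearly hazard rate to a per-step probability
#'
#' Standard discrete-time hazard conversion
#' `1 - exp(-rate * step_days / 365.25)`: monotone in the rate, in `[0, 1)`.
#'
#' @param rate_per_year Non-negative rate(s) per person-year.
#' @param step_days Step length in days.
#' @return Probability of at least one event during the step.
#' @export
rate_to_step_probability <- function(rate_per_year, step_days = 28) {
  if (any(rate_per_year < 0)) stop("rates must be non-negative")
  # clamp to the largest double below 1 so the result stays in [0, 1)
  pmin(1 - exp(-rate_per_year * step_days / days_per_year),
       1 - .Machine$double.eps / 2)
}

#' Simulation configuration
#'
#' Collects every tunable parameter of a run with its default. Component
#' toggles allow switching off any event family; observer settings control
#' the emission schedule (census decennially on April 1, tax and WIC per
#' completed calendar year, survey every step at `survey_rate`).
#'
#' @param start_date Start of the clock (default 2019-01-01).
#' @param end_threshold_date Run until the clock exceeds this date (default
#'   2041-05-01).
#' @param step_days Step length in days (default 28).
#' @param target_population Minimum initial present-person count.
#' @param master_seed Integer master seed; all component substreams derive
#'   from it.
#' @param steps Optional explicit step count overriding the date-derived
#'   one.
#' @param components Named logical list toggling `mortality`, `fertility`,
#'   `domestic_migration`, `emigration`, `immigration`, `employment`.
#' @param observers Named list: logical `census`, `tax`, `wic`, `survey`,
#'   plus `survey_rate`.
#' @param n_employers Regular employers in the registry.
#' @param twin_probability Probability a birth event is twins.
#' @param employment_change_rate Employment changes per person-year.
#' @param destination_split Probabilities for individual-move destinations
#'   (new household / join household / GQ).
#' @param p_po_box Probability a residential household's mail is a PO box.
#' @param p_ssn_foreign_born Probability a foreign-born simulant has an SSN.
#' @param max_path_length Word cap for bigram employer names.
#' @param employer_config,income_config,hyphenation,wic_config Optional
#'   lists passed to the respective modules.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(start_date = "2019-01-01",
                       end_threshold_date = "2041-05-01",
                       step_days = 28L, target_population = 1000,
                       master_seed = 42L, steps = NULL,
                       components = list(), observers = list(),
                       n_employers = 100L, twin_probability = 0.04,
                       employment_change_rate = 0.5,
                       destination_split = c(new_household = 0.5,
                                             join_household = 0.4,
                                             gq = 0.1),
                       p_po_box = 0.1, p_ssn_foreign_born = 0.6,
                       max_path_length = 10L, employer_config = list(),
                       income_config = list(), hyphenation = list(),
                       wic_config = list()) {
  comp <- merge_config(list(mortality = TRUE, fertility = TRUE,
                            domestic_migration = TRUE, emigration = TRUE,
                            immigration = TRUE, employment = TRUE),
                       components)
  obs <- merge_config(list(census = TRUE, tax = TRUE, wic = TRUE,
                           survey = TRUE, survey_rate = 0.005), observers)
  cfg <- list(start_date = as_date(start_date),
              end_threshold_date = as_date(end_threshold_date),
              step_days = as.integer(step_days),
              target_population = target_population,
              master_seed = as.integer(master_seed), steps = steps,
              components = comp, observers = obs,
              n_employers = as.integer(n_employers),
              twin_probability = twin_probability,
              employment_change_rate = employment_change_rate,
              destination_split = destination_split,
              p_po_box = p_po_box,
              p_ssn_foreign_born = p_ssn_foreign_born,
              max_path_length = as.integer(max_path_length),
              employer_config = employer_config,
              income_config = income_config, hyphenation = hyphenation,
              wic_config = wic_config)
  if (cfg$step_days < 1) stop("step_days must be >= 1")
  if (cfg$start_date > cfg$end_threshold_date) {
    stop("start_date must not be after end_threshold_date")
  }
  stopifnot(cfg$target_population >= 1, cfg$twin_probability >= 0,
            cfg$twin_probability <= 1, cfg$employment_change_rate >= 0)
  class(cfg) <- "sim_config"
  cfg
}

# component ids for substream derivation
.component_ids <- c(init = 0, mortality = 1, fertility = 2,
                    domestic_individual = 3, domestic_household = 4,
                    emigration = 5, immigration = 6, employment = 7,
                    observers = 8, identity = 9)

seed_component <- function(master_seed, component, step) {
  set.seed(substream_seed(master_seed, .component_ids[[component]], step))
}

# assign names and SSNs to simulants that do not have them yet
assign_identities <- function(pop, fixtures, cfg) {
  pop <- assign_names(pop, fixtures$names, hyphenation = cfg$hyphenation)
  s <- pop$simulants
  need_ssn <- which(s$has_ssn & is.na(s$ssn))
  if (length(need_ssn) > 0) {
    pop$simulants$ssn[need_ssn] <- generate_ssn(pop$ssn_registry,
                                                length(need_ssn))
  }
  pop
}

run_component <- function(step, name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("step %d, component %s: %s", step, name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the microsimulation
#'
#' Initializes the population from the fixtures, then executes the fixed
#' per-step component order — mortality, fertility, domestic migration
#' (individual then household), emigration, immigration, employment change,
#' then observers due this step — advancing a 28-day (configurable) clock
#' until it exceeds the end threshold. Every component draws from its own
#' per-(component, step) RNG substream derived from the master seed, so a
#' run is fully reproducible. Per-step event counts satisfy the accounting
#' identity present(t+1) = present(t) + births + immigrants - deaths -
#' emigrants.
#'
#' @param config A `sim_config`.
#' @param fixtures A `fixture_set`.
#' @param verbose Print one line per step (step index, date, event counts).
#' @return Object of class `sim_result`: list with `population`
#'   (final `sim_population`), `event_log` (class `event_log` data.frame,
#'   one row per step), `observations` (named list of `observation_table`s),
#'   and `config`.
#' @export
run_simulation <- function(config, fixtures, verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"), inherits(fixtures, "fixture_set"))
  cfg <- config
  step_days <- cfg$step_days
  n_steps <- cfg$steps %||%
    num_steps(cfg$start_date, cfg$end_threshold_date, step_days)

  seed_component(cfg$master_seed, "init", 0)
  pop <- initialize_population(
    fixtures$microdata, cfg$target_population, cfg$start_date,
    fixtures$lexicon,
    config = list(p_po_box = cfg$p_po_box,
                  p_ssn_foreign_born = cfg$p_ssn_foreign_born))
  pop$income_model <- income_model(cfg$income_config)
  pop$employers <- initialize_employers(cfg$n_employers,
                                        cfg$employer_config,
                                        registry = pop$address_registry)
  seed_component(cfg$master_seed, "identity", 0)
  graph <- build_bigram_graph(fixtures$corpus)
  pop$employers <- assign_employer_names(pop$employers, graph,
                                         cfg$max_path_length)
  if (cfg$components$employment) {
    adults <- which(pop$simulants$status == "present" &
                      pop$simulants$precise_age >= 18)
    pop <- resample_employment(pop, adults, cfg$start_date)
  }
  pop <- assign_identities(pop, fixtures, cfg)

  log_rows <- vector("list", n_steps)
  observations <- list()
  obs_add <- function(tbl) {
    key <- sprintf("%s_%s", attr(tbl, "dataset"), attr(tbl, "year"))
    while (!is.null(observations[[key]])) key <- paste0(key, "+")
    observations[[key]] <<- tbl
  }

  for (i in seq_len(n_steps)) {
    step_start <- cfg$start_date + (i - 1L) * step_days
    step_end <- step_start + step_days
    pop$current_date <- step_start
    present_start <- n_present(pop)
    deaths <- emigrants <- immigrants <- 0L
    birth_events <- twin_births <- births <- 0L
    ind_moves <- hh_moves <- emp_changes <- 0L

    if (cfg$components$mortality) {
      seed_component(cfg$master_seed, "mortality", i)
      res <- run_component(i, "mortality",
        apply_mortality(pop, fixtures$rates$mortality, step_days,
                        step_start))
      pop <- res$pop
      deaths <- length(res$deaths)
    }
    if (cfg$components$fertility) {
      seed_component(cfg$master_seed, "fertility", i)
      res <- run_component(i, "fertility",
        apply_fertility(pop, fixtures$rates$fertility, step_days,
                        step_start, cfg$twin_probability, step = i))
      pop <- res$pop
      birth_events <- nrow(res$births)
      twin_births <- sum(res$births$is_twin)
      births <- length(res$newborn_ids)
    }
    if (cfg$components$domestic_migration) {
      seed_component(cfg$master_seed, "domestic_individual", i)
      res <- run_component(i, "domestic_individual",
        apply_domestic_individual(pop, fixtures$rates$domestic_individual,
                                  cfg$destination_split, step_days,
                                  step_start, cfg$p_po_box))
      pop <- res$pop
      ind_moves <- length(res$moved)
      emp_changes <- emp_changes + res$employment_changes
      seed_component(cfg$master_seed, "domestic_household", i)
      res <- run_component(i, "domestic_household",
        apply_domestic_household(pop, fixtures$rates$domestic_household,
                                 step_days, step_start, cfg$p_po_box))
      pop <- res$pop
      hh_moves <- length(res$moved_households)
      emp_changes <- emp_changes + res$employment_changes
    }
    if (cfg$components$emigration) {
      seed_component(cfg$master_seed, "emigration", i)
      res <- run_component(i, "emigration",
        apply_emigration(pop, fixtures$rates$emigration, step_days,
                         step_start))
      pop <- res$pop
      emigrants <- length(res$emigrated)
    }
    if (cfg$components$immigration) {
      seed_component(cfg$master_seed, "immigration", i)
      res <- run_component(i, "immigration",
        apply_immigration(pop, fixtures$microdata,
                          fixtures$rates$immigration_counts, step_days,
                          step_start, step = i, p_po_box = cfg$p_po_box,
                          p_ssn_foreign_born = cfg$p_ssn_foreign_born))
      pop <- res$pop
      immigrants <- length(res$immigrant_ids)
    }
    if (cfg$components$employment) {
      seed_component(cfg$master_seed, "employment", i)
      res <- run_component(i, "employment",
        apply_employment_change(pop, cfg$employment_change_rate, step_days,
                                step_start))
      pop <- res$pop
      emp_changes <- emp_changes + length(res$changed)
    }

    # identity for this step's entrants, before observation
    seed_component(cfg$master_seed, "identity", i)
    pop <- assign_identities(pop, fixtures, cfg)

    # observers due this step
    seed_component(cfg$master_seed, "observers", i)
    step_dates <- seq(step_start, by = 1, length.out = step_days)
    if (cfg$observers$census) {
      cens <- step_dates[format(step_dates, "%m-%d") == "04-01" &
                           as.integer(format(step_dates, "%Y")) %% 10 == 0]
      for (d in as.list(cens)) {
        obs_add(run_component(i, "census_observer",
                              observe_decennial_census(pop, d)))
      }
    }
    year_start <- step_dates[format(step_dates, "%m-%d") == "01-01"]
    completed <- as.integer(format(year_start, "%Y")) - 1L
    completed <- completed[completed >=
                             as.integer(format(cfg$start_date, "%Y"))]
    for (y in completed) {
      if (cfg$observers$tax) {
        tbl <- run_component(i, "tax_observer", observe_tax(pop, y))
        upd <- attr(tbl, "updated_population")
        if (!is.null(upd)) pop <- upd
        attr(tbl, "updated_population") <- NULL
        obs_add(tbl)
      }
      if (cfg$observers$wic) {
        obs_add(run_component(i, "wic_observer",
                              observe_wic(pop, y, cfg$wic_config)))
      }
    }
    if (cfg$observers$survey && cfg$observers$survey_rate > 0) {
      obs_add(run_component(i, "survey_observer",
        observe_household_survey(pop, step_start,
                                 cfg$observers$survey_rate)))
    }

    # aging: simulants present since the start of the step age by one step;
    # this step's newborns get their exact age at step end
    s <- pop$simulants
    aging <- s$status == "present" & s$entered_step < i
    pop$simulants$precise_age[aging] <-
      s$precise_age[aging] + step_days / days_per_year
    newborn <- s$status == "present" & s$entered_step == i &
      !is.na(s$mother_id)
    if (any(newborn)) {
      pop$simulants$precise_age[newborn] <-
        pmax(0, as.numeric(step_end - s$dob[newborn]) / days_per_year)
    }
    pop$current_date <- step_end

    log_rows[[i]] <- data.frame(
      step = i, date = step_start, present_start = present_start,
      birth_events = birth_events, twin_births = twin_births,
      births = births, deaths = deaths,
      domestic_individual_moves = ind_moves,
      domestic_household_moves = hh_moves, immigrants = immigrants,
      emigrants = emigrants, employment_changes = emp_changes,
      present_end = n_present(pop))
    if (verbose) {
      message(sprintf(
        paste0("step %3d %s: present %d, births %d, deaths %d, ",
               "moves %d/%d, immig %d, emig %d, job changes %d"),
        i, format(step_start), n_present(pop), births, deaths, ind_moves,
        hh_moves, immigrants, emigrants, emp_changes))
    }
  }

  event_log <- do.call(rbind, log_rows)
  class(event_log) <- c("event_log", "data.frame")
  out <- list(population = pop, event_log = event_log,
              observations = observations, config = cfg)
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  el <- x$event_log
  cat("<sim_result>\n")
  cat(sprintf("  %d steps: %s .. %s\n", nrow(el), format(el$date[1]),
              format(el$date[nrow(el)] + x$config$step_days)))
  cat(sprintf("  population: %d -> %d present\n", el$present_start[1],
              el$present_end[nrow(el)]))
  cat(sprintf(
    "  totals: %d births, %d deaths, %d immigrants, %d emigrants\n",
    sum(el$births), sum(el$deaths), sum(el$immigrants),
    sum(el$emigrants)))
  cat(sprintf("  %d observation tables\n", length(x$observations)))
  invisible(x)
}

#' Check the per-step population accounting identity
#'
#' Asserts present(t+1) = present(t) + births + immigrants - deaths -
#' emigrants exactly for every step of an event log.
#'
#' @param event_log An `event_log`.
#' @return TRUE invisibly; errors if the identity fails anywhere.
#' @export
check_accounting_identity <- function(event_log) {
  el <- event_log
  lhs <- el$present_end
  rhs <- el$present_start + el$births + el$immigrants - el$deaths -
    el$emigrants
  if (!all(lhs == rhs)) {
    bad <- which(lhs != rhs)
    stop("accounting identity violated at step(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(TRUE)
}
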