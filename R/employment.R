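# Employer registry, size-proportional assignment, employment-change
# dynamics, and log-normal wage income.

UNEMPLOYED_ID <- 0L
MILITARY_ID <- 1L

#' Initialize the employer registry
#'
#' Employers receive an initial size drawn from a heavy-tailed (log-normal)
#' distribution, so a few employers are large and many are small. The
#' registry also contains the two distinguished states — unemployment and the
#' single military employer — whose assignment weights are configuration
#' constants rather than sizes. Regular employers share the remaining
#' assignment weight in proportion to initial size.
#'
#' @param n_employers Number of regular (non-military) employers (>= 1).
#' @param config Optional list overriding `size_meanlog` (default 1),
#'   `size_sdlog` (1.5), `p_unemployed` (assignment weight of unemployment,
#'   0.05), `p_military` (0.01), `p_w2` (probability an employer issues W2s
#'   rather than 1099s, 0.85).
#' @param registry Optional `address_registry` used to give each employer a
#'   business address.
#' @param seed Optional integer seed.
#' @return data.frame (class `employer_registry`) with employer_id, name
#'   (NA until employer names are generated), initial_size, weight,
#'   tax_form, address_id. Row 1 is unemployment (id 0), row 2 the military
#'   (id 1).
#' @export
initialize_employers <- function(n_employers, config = list(),
                                 registry = NULL, seed = NULL) {
  stopifnot(n_employers >= 1)
  cfg <- merge_config(list(size_meanlog = 1, size_sdlog = 1.5,
                           p_unemployed = 0.05, p_military = 0.01,
                           p_w2 = 0.85), config)
  if (!is.null(seed)) set.seed(seed)
  sizes <- stats::rlnorm(n_employers, cfg$size_meanlog, cfg$size_sdlog)
  p_reg <- 1 - cfg$p_unemployed - cfg$p_military
  stopifnot(p_reg > 0)
  emp <- data.frame(
    employer_id = c(UNEMPLOYED_ID, MILITARY_ID,
                    seq_len(n_employers) + MILITARY_ID),
    name = c(NA_character_, "Military", rep(NA_character_, n_employers)),
    initial_size = c(NA_real_, NA_real_, sizes),
    weight = c(cfg$p_unemployed, cfg$p_military, p_reg * sizes / sum(sizes)),
    tax_form = c(NA_character_, "W2",
                 ifelse(stats::runif(n_employers) < cfg$p_w2, "W2", "1099")),
    address_id = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (!is.null(registry)) {
    emp$address_id[-1] <- new_address(registry, n_employers + 1L)
  }
  class(emp) <- c("employer_registry", "data.frame")
  emp
}

#' Draw employers size-proportionally
#'
#' Categorical draw where each regular employer's probability is
#' proportional to its initial size, with unemployment and the military
#' included at their configured weights. The identical procedure is used at
#' initialization and at every employment-change event.
#'
#' @param employers An `employer_registry`.
#' @param n Number of draws.
#' @return Integer vector of employer ids (0 = unemployed, 1 = military).
#' @export
assign_employer <- function(employers, n = 1) {
  stopifnot(is.data.frame(employers), nrow(employers) >= 1, n >= 0)
  if (n == 0) return(integer(0))
  employers$employer_id[sample.int(nrow(employers), n, replace = TRUE,
                                   prob = employers$weight)]
}

#' Build the synthetic income model
#'
#' Log-normal wage parameters per (age group, sex, race/ethnicity) stratum.
#' These are synthetic, non-calibrated defaults: a common location with a
#' concave age profile peaking in mid-career, a male/female offset, and small
#' race/ethnicity offsets; constant log-scale.
#'
#' @param config Optional list overriding `base_median` (annual wage median
#'   at the reference stratum, default 32000), `sdlog` (0.7), `sex_gap`
#'   (male minus female log-location, 0.1).
#' @return List (class `income_model`) with arrays `meanlog` and `sdlog`
#'   indexed [age group, sex, race/ethnicity].
#' @export
income_model <- function(config = list()) {
  cfg <- merge_config(list(base_median = 32000, sdlog = 0.7,
                           sex_gap = 0.1), config)
  ag <- age_group_labels()
  mids <- age_group_midpoints()
  # concave age profile: rises to ~50, flat-ish after
  age_eff <- 0.9 * log(pmax(mids, 18) / 18) -
    0.25 * (log(pmax(mids, 18) / 18))^2
  race_eff <- stats::setNames(seq(-0.1, 0.1, length.out = 7),
                              race_ethnicity_levels)
  meanlog <- array(0, dim = c(.n_age_groups, 2, 7),
                   dimnames = list(ag, c("male", "female"),
                                   race_ethnicity_levels))
  for (si in 1:2) for (ri in 1:7) {
    meanlog[, si, ri] <- log(cfg$base_median) + age_eff +
      ifelse(si == 1, cfg$sex_gap / 2, -cfg$sex_gap / 2) + race_eff[ri]
  }
  out <- list(meanlog = meanlog,
              sdlog = array(cfg$sdlog, dim = dim(meanlog),
                            dimnames = dimnames(meanlog)))
  class(out) <- "income_model"
  out
}

#' Sample annual wage income
#'
#' Unemployed simulants earn 0; employed simulants draw from the log-normal
#' distribution of their (age group, sex, race/ethnicity) stratum,
#' independently of which employer they hold.
#'
#' @param age Numeric ages.
#' @param sex Character sexes.
#' @param race_ethnicity Character composite categories.
#' @param model An `income_model`.
#' @param employer_id Integer employer ids (0 = unemployed).
#' @return Numeric annual wages (>= 0).
#' @export
sample_income <- function(age, sex, race_ethnicity, model, employer_id) {
  n <- length(age)
  stopifnot(length(sex) == n, length(race_ethnicity) == n,
            length(employer_id) == n, inherits(model, "income_model"))
  if (n == 0) return(numeric(0))
  idx <- cbind(age_group_index(age), match(sex, c("male", "female")),
               match(race_ethnicity, race_ethnicity_levels))
  if (any(is.na(idx))) stop("income model stratum not found")
  out <- stats::rlnorm(n, model$meanlog[idx], model$sdlog[idx])
  out[employer_id == UNEMPLOYED_ID] <- 0
  out
}

# close the open employment stint of the given simulants as of `date`
close_stints <- function(pop, simulant_ids, date) {
  s <- pop$simulants
  rows <- which(s$simulant_id %in% simulant_ids & !is.na(s$employer_id))
  if (length(rows) == 0) return(pop)
  stint <- data.frame(
    simulant_id = s$simulant_id[rows], employer_id = s$employer_id[rows],
    income = s$income[rows], start = s$employer_since[rows],
    end = as_date(date), stringsAsFactors = FALSE
  )
  pop$stints <- c(pop$stints, list(stint))
  pop
}

# assign (or reassign) employer and income for the given simulant rows;
# closes any open stint first when `count_change` callers pass movers etc.
resample_employment <- function(pop, rows, date) {
  if (length(rows) == 0) return(pop)
  s <- pop$simulants
  had <- rows[!is.na(s$employer_id[rows])]
  pop <- close_stints(pop, s$simulant_id[had], date)
  new_emp <- assign_employer(pop$employers, length(rows))
  pop$simulants$employer_id[rows] <- new_emp
  pop$simulants$employer_since[rows] <- as_date(date)
  pop$simulants$income[rows] <- sample_income(
    s$precise_age[rows], s$sex[rows], s$race_ethnicity[rows],
    pop$income_model, new_emp)
  pop
}

#' Apply one step of employment dynamics
#'
#' Working-age present simulants (age >= 18, including the unemployed) change
#' employment with the per-step probability implied by `change_rate` per
#' person-year. A change re-draws the employer with [assign_employer()] —
#' possibly re-drawing the same employer; the event still counts — and
#' resamples income. Present simulants who have reached working age without
#' an employer state are initialized first (not counted as changes).
#'
#' @param pop A `sim_population` with `employers` and `income_model` set.
#' @param change_rate Employment changes per person-year (default 0.5, i.e.
#'   50 per 100 person-years).
#' @param step_days Step length in days.
#' @param date Date of the step.
#' @return List with `pop` and `changed` (integer simulant ids that had a
#'   change event).
#' @export
apply_employment_change <- function(pop, change_rate = 0.5, step_days = 28,
                                    date = pop$current_date) {
  stopifnot(change_rate >= 0)
  s <- pop$simulants
  working <- which(s$status == "present" & s$precise_age >= 18)
  # initial assignment for simulants newly of working age
  newly <- working[is.na(s$employer_id[working])]
  pop <- resample_employment(pop, newly, date)
  p <- rate_to_step_probability(change_rate, step_days)
  changed <- working[stats::runif(length(working)) < p]
  pop <- resample_employment(pop, changed, date)
  list(pop = pop, changed = pop$simulants$simulant_id[changed])
}

# stints overlapping a calendar year: closed ones plus open ones, for tax
stints_for_year <- function(pop, year) {
  y0 <- as.Date(sprintf("%d-01-01", year))
  y1 <- as.Date(sprintf("%d-12-31", year))
  closed <- if (length(pop$stints) > 0) do.call(rbind, pop$stints) else NULL
  s <- pop$simulants
  open_rows <- which(!is.na(s$employer_id))
  open <- data.frame(
    simulant_id = s$simulant_id[open_rows],
    employer_id = s$employer_id[open_rows], income = s$income[open_rows],
    start = s$employer_since[open_rows],
    end = as.Date(rep(NA, length(open_rows))), stringsAsFactors = FALSE
  )
  all <- rbind(closed, open)
  if (is.null(all) || nrow(all) == 0) return(all)
  end_eff <- all$end
  end_eff[is.na(end_eff)] <- max(y1, pop$current_date)
  keep <- all$start <= y1 & end_eff >= y0
  all <- all[keep, , drop = FALSE]
  end_eff <- end_eff[keep]
  all$overlap_days <- as.numeric(pmin(end_eff, y1) -
                                   pmax(all$start, y0)) + 1
  all
}
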