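# Population state: simulants, households/GQ units, addresses, and the
# initialization-by-weighted-sampling of the starting population.

#' @title Population state object
#' @description A `sim_population` is a list holding the full mutable state
#'   of one simulation: a `simulants` data.frame (one row per person-agent,
#'   with demographics, household membership, relationship, employment and
#'   identity fields, and a `status` of present/dead/emigrated), a
#'   `households` data.frame (residential units and pooled group-quarters
#'   units with address ids and reference person), an address registry, ID
#'   registries for SSNs and ITINs, closed employment stints, and birth
#'   records. Use the accessors rather than reaching into the list.
#' @name sim_population
NULL

simulant_columns <- c(
  "simulant_id", "sex", "dob", "precise_age", "race_ethnicity", "nativity",
  "has_ssn", "household_id", "relationship", "employer_id", "income",
  "employer_since", "status", "status_date", "mother_id", "entered_step",
  "first_name", "middle_name", "last_name", "ssn", "itin"
)

empty_simulants <- function(n = 0) {
  data.frame(
    simulant_id = integer(n), sex = character(n),
    dob = as.Date(rep(NA, n)), precise_age = numeric(n),
    race_ethnicity = character(n), nativity = character(n),
    has_ssn = logical(n), household_id = integer(n),
    relationship = rep(NA_character_, n), employer_id = rep(NA_integer_, n),
    income = numeric(n), employer_since = as.Date(rep(NA, n)),
    status = rep("present", n), status_date = as.Date(rep(NA, n)),
    mother_id = rep(NA_integer_, n),
    entered_step = integer(n), first_name = rep(NA_character_, n),
    middle_name = rep(NA_character_, n), last_name = rep(NA_character_, n),
    ssn = rep(NA_character_, n), itin = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# address registry

#' Create an address registry
#'
#' Issues globally unique addresses composed from a lexicon. Address ids are
#' strictly increasing and never reused; a vacated address id is recorded and
#' never reissued, and no two issued addresses share the same component
#' combination.
#'
#' @param lexicon An `address_lexicon`.
#' @return An environment of class `address_registry`.
#' @export
new_address_registry <- function(lexicon) {
  stopifnot(inherits(lexicon, "address_lexicon"),
            length(lexicon$street_names) > 0, length(lexicon$cities) > 0)
  reg <- new.env(parent = emptyenv())
  reg$lexicon <- lexicon
  reg$next_id <- 1L
  reg$used <- new.env(parent = emptyenv())
  reg$vacated <- integer(0)
  reg$rows <- list()
  class(reg) <- "address_registry"
  reg
}

#' Issue new unique addresses
#'
#' @param registry An `address_registry`.
#' @param n Number of addresses to issue.
#' @param po_box Logical (recycled): issue PO-box mailing addresses instead
#'   of street addresses.
#' @return Integer vector of the new address ids.
#' @export
new_address <- function(registry, n = 1, po_box = FALSE) {
  stopifnot(inherits(registry, "address_registry"), n >= 0)
  if (n == 0) return(integer(0))
  lex <- registry$lexicon
  po_box <- rep_len(po_box, n)
  ids <- registry$next_id + seq_len(n) - 1L
  registry$next_id <- registry$next_id + as.integer(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    for (attempt in 1:100) {
      ci <- sample.int(length(lex$cities), 1)
      if (po_box[i]) {
        num <- sample.int(99999, 1)
        row <- list(address_id = ids[i], street_number = num,
                    street_name = "PO Box", street_suffix = "",
                    unit = "", city = lex$cities[ci],
                    state = lex$states[ci], zip = lex$zips[ci],
                    po_box = TRUE)
        key <- paste("POB", num, ci)
      } else {
        num <- sample(100:9999, 1)
        st <- sample(lex$street_names, 1)
        sf <- sample(lex$street_suffixes, 1)
        unit <- if (stats::runif(1) < 0.2) {
          paste(sample(lex$unit_designators, 1), sample.int(99, 1))
        } else ""
        row <- list(address_id = ids[i], street_number = num,
                    street_name = st, street_suffix = sf, unit = unit,
                    city = lex$cities[ci], state = lex$states[ci],
                    zip = lex$zips[ci], po_box = FALSE)
        key <- paste(num, st, sf, unit, ci)
      }
      if (is.null(registry$used[[key]])) {
        registry$used[[key]] <- TRUE
        rows[[i]] <- row
        break
      }
      if (attempt == 100) {
        stop("synthetic address space exhausted; enlarge the lexicon")
      }
    }
  }
  registry$rows <- c(registry$rows, rows)
  ids
}

#' Mark an address as vacated
#'
#' Vacated addresses are never reissued (ids are never reused by
#' construction; this records the vacancy for auditing).
#'
#' @param registry An `address_registry`.
#' @param address_ids Integer ids to vacate.
#' @return The registry, invisibly.
#' @export
vacate_address <- function(registry, address_ids) {
  registry$vacated <- unique(c(registry$vacated, address_ids))
  invisible(registry)
}

#' Materialize the address table
#'
#' @param registry An `address_registry`.
#' @return data.frame of all issued addresses.
#' @export
addresses <- function(registry) {
  if (length(registry$rows) == 0) {
    return(data.frame(address_id = integer(0), street_number = integer(0),
                      street_name = character(0), street_suffix = character(0),
                      unit = character(0), city = character(0),
                      state = character(0), zip = character(0),
                      po_box = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(registry$rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
}

new_id_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$used <- new.env(parent = emptyenv())
  reg$count <- 0L
  reg
}

# ---------------------------------------------------------------------------
# elemental rules

#' Perturb a vector of precise ages by one shared shift
#'
#' All members of a sampled entity receive the same normal age shift; any
#' resulting negative age has its sign flipped.
#'
#' @param precise_ages Numeric vector of precise (fractional) ages.
#' @param shift Single numeric shift in years.
#' @return Numeric vector of non-negative perturbed ages.
#' @export
perturb_ages <- function(precise_ages, shift) {
  stopifnot(length(shift) == 1, is.finite(shift))
  out <- precise_ages + shift
  neg <- out < 0
  out[neg] <- -out[neg]
  out
}

#' Map race code and Hispanic indicator to the composite category
#'
#' A true Hispanic indicator maps to "Latino" regardless of race code;
#' otherwise the race code maps to its composite category.
#'
#' @param race_code Character vector of codes (`white`, `black`, `aian`,
#'   `asian`, `nhopi`, `other`, `two_or_more`).
#' @param hispanic_flag Logical vector.
#' @return Character vector over [race_ethnicity_levels].
#' @export
map_race_ethnicity <- function(race_code, hispanic_flag) {
  mapping <- c(white = "White", black = "Black",
               aian = "American Indian and Alaskan Native",
               asian = "Asian",
               nhopi = "Native Hawaiian and Other Pacific Islander",
               other = "Multiracial or Some Other Race",
               two_or_more = "Multiracial or Some Other Race")
  if (any(!race_code %in% names(mapping))) {
    stop("unknown race code: ",
         paste(unique(setdiff(race_code, names(mapping))), collapse = ", "))
  }
  out <- unname(mapping[race_code])
  out[hispanic_flag] <- "Latino"
  out
}

#' Choose group-quarters kinds
#'
#' Institutional residents get a uniform draw over carceral / nursing home /
#' other institutional; non-institutional over college / military / other
#' non-institutional.
#'
#' @param institutional_flag Logical vector.
#' @return Character vector of GQ kinds.
#' @export
assign_gq_type <- function(institutional_flag) {
  n <- length(institutional_flag)
  out <- character(n)
  out[institutional_flag] <-
    gq_kinds$institutional[sample.int(3, sum(institutional_flag),
                                      replace = TRUE)]
  out[!institutional_flag] <-
    gq_kinds$noninstitutional[sample.int(3, sum(!institutional_flag),
                                         replace = TRUE)]
  out
}

#' Derive a date of birth consistent with a precise age
#'
#' @param precise_age Numeric vector of ages in years (>= 0).
#' @param reference_date Date at which the ages hold.
#' @return Date vector, never after `reference_date`.
#' @export
derive_dob <- function(precise_age, reference_date) {
  stopifnot(all(precise_age >= 0))
  as_date(reference_date) - round(precise_age * days_per_year)
}

# ---------------------------------------------------------------------------
# initialization

#' Initialize the simulated population
#'
#' Samples entities — whole non-GQ households and individual GQ persons —
#' from the microdata with replacement, with probability proportional to
#' weight (the reference person's weight for households), until the present
#' population reaches `target_size`. Household internal structure is
#' preserved; every sampled entity receives one shared standard-normal age
#' shift applied to precise ages (nominal integer age plus a uniform
#' fraction), with negative results sign-flipped. GQ residents are pooled
#' into one unit per GQ kind, chosen uniformly within their
#' institutional/non-institutional status.
#'
#' @param microdata A `microdata_table` (non-empty).
#' @param target_size Minimum number of present simulants (>= 1).
#' @param start_date Simulation start date.
#' @param lexicon An `address_lexicon` for issuing addresses.
#' @param config Optional list overriding `p_po_box` (probability a
#'   residential household receives mail at a PO box, default 0.1) and
#'   `p_ssn_foreign_born` (probability a foreign-born simulant holds an SSN,
#'   default 0.6).
#' @param seed Optional integer seed.
#' @return A `sim_population`.
#' @export
initialize_population <- function(microdata, target_size,
                                  start_date = as.Date("2019-01-01"),
                                  lexicon = generate_address_lexicon(),
                                  config = list(), seed = NULL) {
  if (!is.data.frame(microdata) || nrow(microdata) == 0) {
    stop("microdata must be a non-empty microdata table")
  }
  stopifnot(target_size >= 1)
  cfg <- merge_config(list(p_po_box = 0.1, p_ssn_foreign_born = 0.6), config)
  if (!is.null(seed)) set.seed(seed)
  start_date <- as_date(start_date)
  md <- microdata

  registry <- new_address_registry(lexicon)
  ssn_registry <- new_id_registry()
  itin_registry <- new_id_registry()

  # pooled GQ units, one per kind, ids 1..6
  all_gq_kinds <- unlist(gq_kinds, use.names = FALSE)
  gq_units <- data.frame(
    household_id = seq_along(all_gq_kinds), kind = all_gq_kinds,
    physical_address_id = new_address(registry, length(all_gq_kinds)),
    mailing_address_id = NA_integer_, reference_person_id = NA_integer_,
    active = TRUE, stringsAsFactors = FALSE
  )
  gq_units$mailing_address_id <- gq_units$physical_address_id

  # entity table: residential households + individual GQ persons
  res <- md[!md$gq_flag, , drop = FALSE]
  gq <- md[md$gq_flag, , drop = FALSE]
  res_rows <- split(seq_len(nrow(res)), res$household_key)
  res_keys <- names(res_rows)
  rp_weight <- vapply(res_rows, function(ix) {
    res$weight[ix][res$relationship_code[ix] == "Reference person"][1]
  }, numeric(1))
  ent_size <- c(vapply(res_rows, length, integer(1)),
                rep(1L, nrow(gq)))
  ent_weight <- c(rp_weight, gq$weight)
  ent_is_res <- c(rep(TRUE, length(res_rows)), rep(FALSE, nrow(gq)))
  n_ent <- length(ent_size)

  # sample entities with replacement until the person count reaches target
  draws <- integer(0)
  while (sum(ent_size[draws]) < target_size) {
    need <- target_size - sum(ent_size[draws])
    m <- max(16L, ceiling(1.3 * need / mean(ent_size)))
    draws <- c(draws, sample.int(n_ent, m, replace = TRUE,
                                 prob = ent_weight))
    if (sum(ent_size[draws]) >= target_size) {
      cum <- cumsum(ent_size[draws])
      draws <- draws[seq_len(which(cum >= target_size)[1])]
    }
  }
  k <- length(draws)
  draw_is_res <- ent_is_res[draws]

  # expand to person rows in draw order
  src_rows <- lapply(draws, function(e) {
    if (ent_is_res[e]) res_rows[[e]] else -(e - length(res_rows))
  })
  ent_of_person <- rep.int(seq_len(k), ent_size[draws])
  flat <- unlist(src_rows)
  person_md <- rbind(res, gq)[ifelse(flat > 0, flat, nrow(res) - flat), ]
  # note: negative flat encodes GQ row index
  n_persons <- nrow(person_md)

  # ages: precise = integer + uniform fraction, then one shared shift per
  # sampled entity, then sign flip of negatives
  shift <- stats::rnorm(k)
  precise0 <- person_md$age_years + stats::runif(n_persons)
  precise <- precise0 + shift[ent_of_person]
  precise[precise < 0] <- -precise[precise < 0]

  sim <- empty_simulants(n_persons)
  sim$simulant_id <- seq_len(n_persons)
  sim$sex <- person_md$sex
  sim$precise_age <- precise
  sim$dob <- derive_dob(precise, start_date)
  sim$race_ethnicity <- map_race_ethnicity(person_md$race_code,
                                           person_md$hispanic_flag)
  sim$nativity <- ifelse(person_md$foreign_born_flag, "foreign-born",
                         "US-born")
  sim$has_ssn <- sim$nativity == "US-born" |
    stats::runif(n_persons) < cfg$p_ssn_foreign_born
  sim$entered_step <- 0L

  # households for residential draws
  n_res_draws <- sum(draw_is_res)
  hh_id_of_draw <- rep(NA_integer_, k)
  hh_id_of_draw[draw_is_res] <- nrow(gq_units) + seq_len(n_res_draws)
  is_gq_person <- person_md$gq_flag

  sim$relationship <- ifelse(is_gq_person, NA_character_,
                             person_md$relationship_code)
  sim$household_id <- hh_id_of_draw[ent_of_person]
  if (any(is_gq_person)) {
    kinds <- assign_gq_type(person_md$institutional_flag[is_gq_person])
    sim$household_id[is_gq_person] <-
      gq_units$household_id[match(kinds, gq_units$kind)]
  }

  households <- gq_units
  if (n_res_draws > 0) {
    phys <- new_address(registry, n_res_draws)
    pob <- stats::runif(n_res_draws) < cfg$p_po_box
    mail <- phys
    if (any(pob)) mail[pob] <- new_address(registry, sum(pob), po_box = TRUE)
    rp_id <- sim$simulant_id[!is.na(sim$relationship) &
                               sim$relationship == "Reference person"]
    rp_hh <- sim$household_id[match(rp_id, sim$simulant_id)]
    res_hh <- data.frame(
      household_id = hh_id_of_draw[draw_is_res], kind = "Residential",
      physical_address_id = phys, mailing_address_id = mail,
      reference_person_id = rp_id[match(hh_id_of_draw[draw_is_res], rp_hh)],
      active = TRUE, stringsAsFactors = FALSE
    )
    households <- rbind(gq_units, res_hh)
  }

  pop <- list(
    simulants = sim,
    households = households,
    employers = NULL,
    income_model = NULL,
    address_registry = registry,
    ssn_registry = ssn_registry,
    itin_registry = itin_registry,
    stints = list(),
    births = list(),
    start_date = start_date,
    current_date = start_date,
    next_simulant_id = n_persons + 1L,
    next_household_id = max(households$household_id) + 1L
  )
  class(pop) <- "sim_population"
  pop
}

# ---------------------------------------------------------------------------
# accessors & methods

#' Simulant table accessor
#' @param pop A `sim_population`.
#' @return data.frame of simulants.
#' @export
simulants <- function(pop) pop$simulants

#' Household table accessor
#' @param pop A `sim_population`.
#' @return data.frame of households and GQ units.
#' @export
households <- function(pop) pop$households

#' Employer registry accessor
#' @param pop A `sim_population`.
#' @return data.frame of employers, or NULL before employment initialization.
#' @export
employers <- function(pop) pop$employers

#' Number of present simulants
#' @param pop A `sim_population`.
#' @return Integer count of simulants with status `"present"`.
#' @export
n_present <- function(pop) sum(pop$simulants$status == "present")

#' @export
print.sim_population <- function(x, ...) {
  s <- x$simulants
  cat("<sim_population>\n")
  cat(sprintf("  %d simulants (%d present, %d dead, %d emigrated)\n",
              nrow(s), sum(s$status == "present"), sum(s$status == "dead"),
              sum(s$status == "emigrated")))
  res <- x$households$kind == "Residential" & x$households$active
  cat(sprintf("  %d active residential households, %d GQ units\n",
              sum(res), sum(x$households$kind != "Residential")))
  cat(sprintf("  dates: start %s, current %s\n",
              format(x$start_date), format(x$current_date)))
  invisible(x)
}

#' Validate population-state invariants
#'
#' Checks: non-negative precise ages; GQ residents have no relationship;
#' every active residential household with a present member has exactly one
#' present reference person (who is a member); DOB consistent with precise
#' age at the current date to within `tol_days`.
#'
#' @param pop A `sim_population`.
#' @param tol_days Allowed DOB/age inconsistency in days (default 2).
#' @return The population, invisibly; errors on violation.
#' @export
validate_population <- function(pop, tol_days = 2) {
  s <- pop$simulants
  stopifnot(all(s$precise_age >= 0))
  gq_ids <- pop$households$household_id[pop$households$kind != "Residential"]
  in_gq <- s$household_id %in% gq_ids
  if (any(!is.na(s$relationship[in_gq]))) {
    stop("GQ residents must have no relationship")
  }
  pres <- s[s$status == "present", ]
  res_hh <- pop$households[pop$households$kind == "Residential" &
                             pop$households$active, ]
  occupied <- res_hh[res_hh$household_id %in% pres$household_id, ]
  if (nrow(occupied) > 0) {
    n_rp <- tapply(pres$relationship == "Reference person",
                   factor(pres$household_id, levels = occupied$household_id),
                   sum, default = 0L)
    if (any(n_rp != 1)) {
      stop("residential households must have exactly one reference person")
    }
    rp_ok <- occupied$reference_person_id %in%
      pres$simulant_id[pres$relationship == "Reference person"]
    if (!all(rp_ok)) stop("reference_person_id must be a present member")
  }
  age_from_dob <- as.numeric(pop$current_date - pres$dob) / days_per_year
  elapsed_slack <- tol_days / days_per_year +
    as.numeric(pop$current_date - pop$start_date) / days_per_year * 0
  if (any(abs(age_from_dob - pres$precise_age) * days_per_year >
            tol_days + 28)) {
    stop("precise_age inconsistent with date of birth")
  }
  invisible(pop)
}

# ---------------------------------------------------------------------------
# serialization

#' Write population state to delimited text
#'
#' Writes simulants, households, addresses, employers (if initialized) as
#' CSV plus a small JSON of scalars. IDs are stable across save/load.
#'
#' @param pop A `sim_population`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  wr(pop$simulants, "simulants")
  wr(pop$households, "households")
  wr(addresses(pop$address_registry), "addresses")
  lex <- pop$address_registry$lexicon
  wr(data.frame(component = rep(names(lex), lengths(lex)),
                value = unlist(lex, use.names = FALSE)), "lexicon")
  if (!is.null(pop$employers)) wr(pop$employers, "employers")
  if (length(pop$stints) > 0) {
    wr(do.call(rbind, pop$stints), "stints")
  }
  if (length(pop$births) > 0) {
    wr(do.call(rbind, pop$births), "births")
  }
  issued <- function(reg) ls(reg$used)
  jsonlite::write_json(
    list(start_date = format(pop$start_date),
         current_date = format(pop$current_date),
         next_simulant_id = pop$next_simulant_id,
         next_household_id = pop$next_household_id,
         next_address_id = pop$address_registry$next_id,
         vacated_addresses = pop$address_registry$vacated,
         issued_ssns = issued(pop$ssn_registry),
         issued_itins = issued(pop$itin_registry)),
    file.path(dir, "population_meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read population state written by [write_population()]
#'
#' Restores simulants, households, the address registry (including issued
#' component combinations and vacated ids), employer registry, stints,
#' births, and the SSN/ITIN registries. All ids are identical to the saved
#' state.
#'
#' @param dir Directory written by [write_population()].
#' @return A `sim_population`.
#' @export
read_population <- function(dir) {
  rd <- function(name) {
    p <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(p)) return(NULL)
    utils::read.csv(p, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
  meta <- jsonlite::read_json(file.path(dir, "population_meta.json"))
  s <- rd("simulants")
  for (col in c("dob", "employer_since", "status_date")) {
    s[[col]] <- as.Date(s[[col]])
  }
  lex_df <- rd("lexicon")
  lexicon <- split(lex_df$value, lex_df$component)
  lexicon <- lexicon[c("street_names", "street_suffixes", "cities",
                       "states", "zips", "unit_designators")]
  class(lexicon) <- "address_lexicon"
  reg <- new_address_registry(lexicon)
  addr <- rd("addresses")
  if (!is.null(addr) && nrow(addr) > 0) {
    reg$rows <- lapply(seq_len(nrow(addr)), function(i) as.list(addr[i, ]))
    ci <- match(addr$city, lexicon$cities)
    key <- ifelse(addr$po_box, paste("POB", addr$street_number, ci),
                  paste(addr$street_number, addr$street_name,
                        addr$street_suffix, addr$unit, ci))
    for (k in key) reg$used[[k]] <- TRUE
  }
  reg$next_id <- as.integer(meta$next_address_id)
  reg$vacated <- as.integer(unlist(meta$vacated_addresses))
  restore_ids <- function(ids) {
    r <- new_id_registry()
    for (k in unlist(ids)) r$used[[k]] <- TRUE
    r$count <- length(unlist(ids))
    r
  }
  emp <- rd("employers")
  if (!is.null(emp)) class(emp) <- c("employer_registry", "data.frame")
  stints <- rd("stints")
  if (!is.null(stints)) {
    stints$start <- as.Date(stints$start)
    stints$end <- as.Date(stints$end)
  }
  births <- rd("births")
  if (!is.null(births)) births$date <- as.Date(births$date)
  pop <- list(
    simulants = s, households = rd("households"), employers = emp,
    income_model = NULL, address_registry = reg,
    ssn_registry = restore_ids(meta$issued_ssns),
    itin_registry = restore_ids(meta$issued_itins),
    stints = if (is.null(stints)) list() else list(stints),
    births = if (is.null(births)) list() else list(births),
    start_date = as.Date(meta$start_date),
    current_date = as.Date(meta$current_date),
    next_simulant_id = as.integer(meta$next_simulant_id),
    next_household_id = as.integer(meta$next_household_id)
  )
  class(pop) <- "sim_population"
  pop
}
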