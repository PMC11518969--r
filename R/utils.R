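# Shared vocabularies and small helpers used across the simulation modules.

#' Relationship-to-reference-person values
#'
#' The 13 relationship values recorded for members of residential households.
#' Group-quarters residents have no relationship (NA).
#'
#' @format Character vector of length 13.
#' @export
relationship_values <- c(
  "Reference person", "Biological child", "Adopted child", "Stepchild",
  "Sibling", "Parent", "Grandchild", "Parent-in-law", "Child-in-law",
  "Other relative", "Roommate", "Foster child", "Other nonrelative"
)

# relationship subsets used by succession / newborn business rules
.child_relationships <- c("Biological child", "Adopted child", "Stepchild")
.nonkin_relationships <- c("Roommate", "Other nonrelative", "Foster child")

#' Composite race/ethnicity categories
#'
#' Seven exhaustive, mutually exclusive categories; a Hispanic/Latino
#' ethnicity indicator takes precedence over any race code.
#'
#' @format Character vector of length 7.
#' @export
race_ethnicity_levels <- c(
  "White", "Black", "Latino", "American Indian and Alaskan Native",
  "Asian", "Native Hawaiian and Other Pacific Islander",
  "Multiracial or Some Other Race"
)

#' Group-quarters kinds
#'
#' Institutional GQ kinds (carceral, nursing home, other institutional) and
#' non-institutional kinds (college, military, other non-institutional).
#' Residential households have kind `"Residential"`.
#'
#' @format Named list with elements `institutional` and `noninstitutional`.
#' @export
gq_kinds <- list(
  institutional = c("Carceral", "Nursing home", "Other institutional"),
  noninstitutional = c("College", "Military", "Other non-institutional")
)

# 5-year age groups 0-4 ... 80-84, 85+
.n_age_groups <- 18L

age_group_labels <- function() {
  c(paste(seq(0, 80, 5), seq(4, 84, 5), sep = "-"), "85+")
}

# midpoint used when rates are generated as smooth functions of age
age_group_midpoints <- function() c(seq(2.5, 82.5, 5), 90)

#' Map ages to 5-year age-group indices
#'
#' @param age Numeric vector of ages in years.
#' @return Integer vector of indices into `age_group_labels()` (1 = 0-4,
#'   18 = 85+).
#' @export
age_group_index <- function(age) {
  stopifnot(all(age >= 0))
  pmin(as.integer(age %/% 5), .n_age_groups - 1L) + 1L
}

days_per_year <- 365.25

# Deterministic per-(component, step) substream seed derived from the master
# seed by a Lehmer-style mix mod 2^31 - 1. Products stay below 2^53 so the
# arithmetic is exact in doubles.
substream_seed <- function(master_seed, component, step) {
  m <- 2147483647
  x <- (abs(as.numeric(master_seed)) %% m) + 1
  x <- (x * 48271 + as.numeric(component) * 7919) %% m
  x <- (x * 48271 + as.numeric(step)) %% m
  as.integer(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# merge user options into defaults (shallow)
merge_config <- function(defaults, config) {
  if (is.null(config)) return(defaults)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  }
  defaults[names(config)] <- config
  defaults
}

as_date <- function(x) {
  if (inherits(x, "Date")) x else as.Date(x)
}
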