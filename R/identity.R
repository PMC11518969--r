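# Identity post-processing: simulant names, SSNs and ITINs, and employer
# names generated by random walks on a bigram multigraph of business names.

# ---------------------------------------------------------------------------
# simulant names

#' Assign simulant names
#'
#' First and middle names are drawn frequency-weighted from the (sex,
#' birth-decade cohort) stratum; last names frequency-weighted by
#' race/ethnicity, drawn independently of the first name. With a configured
#' probability a drawn last name becomes a two-part compound joined by a
#' hyphen or a space. Simulants with a recorded mother inherit the mother's
#' last name instead of drawing one (twins therefore share it); mothers are
#' named before their children regardless of row order.
#'
#' @param pop A `sim_population`.
#' @param name_tables A `name_tables` fixture.
#' @param hyphenation Optional list overriding `p_compound` (default 0.05)
#'   and `p_hyphen` (probability a compound uses a hyphen rather than a
#'   space, 0.5).
#' @param ids Simulant ids to name (default: all without a first name).
#' @return Updated `sim_population`.
#' @export
assign_names <- function(pop, name_tables, hyphenation = list(),
                         ids = NULL) {
  cfg <- merge_config(list(p_compound = 0.05, p_hyphen = 0.5), hyphenation)
  s <- pop$simulants
  if (is.null(ids)) ids <- s$simulant_id[is.na(s$first_name)]
  rows <- match(ids, s$simulant_id)
  if (length(rows) == 0) return(pop)

  cohorts <- sort(unique(name_tables$first_names$cohort))
  dob_year <- as.integer(format(s$dob[rows], "%Y"))
  cohort <- pmax(min(cohorts), pmin(max(cohorts), (dob_year %/% 10) * 10))

  draw_from <- function(tab, stratum_keys, keys) {
    # one frequency-weighted draw per element of keys, grouped by stratum
    out <- character(length(keys))
    for (k in unique(keys)) {
      sel <- which(keys == k)
      sub <- tab[stratum_keys == k, , drop = FALSE]
      if (nrow(sub) == 0) stop("name table is missing stratum: ", k)
      out[sel] <- sub$name[sample.int(nrow(sub), length(sel),
                                      replace = TRUE,
                                      prob = sub$frequency)]
    }
    out
  }

  fkey <- paste(s$sex[rows], cohort)
  ftab_key <- paste(name_tables$first_names$sex,
                    name_tables$first_names$cohort)
  mtab_key <- paste(name_tables$middle_names$sex,
                    name_tables$middle_names$cohort)
  pop$simulants$first_name[rows] <-
    draw_from(name_tables$first_names, ftab_key, fkey)
  pop$simulants$middle_name[rows] <-
    draw_from(name_tables$middle_names, mtab_key, fkey)

  # last names: inherit from mother where recorded, else draw by race
  need_draw <- rows[is.na(s$mother_id[rows])]
  if (length(need_draw) > 0) {
    ltab <- name_tables$last_names
    ln <- draw_from(ltab, ltab$race_ethnicity,
                    s$race_ethnicity[need_draw])
    compound <- stats::runif(length(ln)) < cfg$p_compound
    if (any(compound)) {
      second <- draw_from(ltab, ltab$race_ethnicity,
                          s$race_ethnicity[need_draw][compound])
      joiner <- ifelse(stats::runif(sum(compound)) < cfg$p_hyphen, "-", " ")
      ln[compound] <- paste0(ln[compound], joiner, second)
    }
    pop$simulants$last_name[need_draw] <- ln
  }
  inherit <- rows[!is.na(s$mother_id[rows])]
  if (length(inherit) > 0) {
    # resolve in dob order so a mother named in this same pass comes first
    inherit <- inherit[order(pop$simulants$dob[inherit])]
    for (r in inherit) {
      mrow <- match(pop$simulants$mother_id[r],
                    pop$simulants$simulant_id)
      pop$simulants$last_name[r] <- pop$simulants$last_name[mrow]
    }
  }
  pop
}

# ---------------------------------------------------------------------------
# SSN / ITIN

.ssn_areas <- setdiff(1:899, 666)

#' Generate unique Social Security Numbers
#'
#' Area uniformly from 001-899 excluding 666, group from 01-99, serial from
#' 0001-9999, rendered `AAA-GG-SSSS`; uniform over the valid space minus
#' already-issued numbers, globally unique within the registry.
#'
#' @param registry Registry from `new_id_registry()` (the population carries
#'   one as `pop$ssn_registry`).
#' @param n Number of SSNs to issue.
#' @return Character vector of formatted SSNs.
#' @export
generate_ssn <- function(registry, n = 1) {
  if (n == 0) return(character(0))
  space <- length(.ssn_areas) * 99 * 9999
  if (registry$count + n > space) stop("SSN space exhausted")
  out <- character(n)
  i <- 1L
  while (i <= n) {
    cand <- sprintf("%03d-%02d-%04d",
                    .ssn_areas[sample.int(length(.ssn_areas), 1)],
                    sample.int(99, 1), sample.int(9999, 1))
    if (is.null(registry$used[[cand]])) {
      registry$used[[cand]] <- TRUE
      out[i] <- cand
      i <- i + 1L
    }
  }
  registry$count <- registry$count + n
  out
}

#' Generate unique Individual Taxpayer Identification Numbers
#'
#' Nine digits rendered like an SSN, with the first digit always 9 and the
#' two group digits restricted to the configured allowed ranges. Issued only
#' to tax filers without an SSN.
#'
#' @param registry Registry from `new_id_registry()` (the population carries
#'   one as `pop$itin_registry`).
#' @param n Number of ITINs.
#' @param config Optional list overriding `allowed_groups` (default the
#'   conventional 50-65, 70-88, 90-92, 94-99).
#' @return Character vector of formatted ITINs.
#' @export
generate_itin <- function(registry, n = 1, config = list()) {
  cfg <- merge_config(list(
    allowed_groups = c(50:65, 70:88, 90:92, 94:99)), config)
  if (n == 0) return(character(0))
  groups <- cfg$allowed_groups
  space <- 100 * length(groups) * 9999
  if (registry$count + n > space) stop("ITIN space exhausted")
  out <- character(n)
  i <- 1L
  while (i <= n) {
    cand <- sprintf("9%02d-%02d-%04d", sample.int(100, 1) - 1L,
                    groups[sample.int(length(groups), 1)],
                    sample.int(9999, 1))
    if (is.null(registry$used[[cand]])) {
      registry$used[[cand]] <- TRUE
      out[i] <- cand
      i <- i + 1L
    }
  }
  registry$count <- registry$count + n
  out
}

# ---------------------------------------------------------------------------
# bigram multigraph employer names

#' Build a bigram multigraph from a location-name corpus
#'
#' Words are nodes (plus `<start>` and `<end>` sentinels); each adjacent
#' word pair in each corpus name contributes one directed multi-edge, so the
#' edge count between two words equals the number of adjacent occurrences
#' across the corpus, including `<start>` to each first word and each last
#' word to `<end>`.
#'
#' @param corpus Character vector of whitespace-separated business names
#'   (non-empty, no empty strings).
#' @return Object of class `bigram_graph`: list with `edges` (data.frame
#'   from, to, count) and `adjacency` (per-node data.frames of to/count).
#' @export
build_bigram_graph <- function(corpus) {
  corpus <- as.character(corpus)
  if (length(corpus) == 0) stop("corpus must be non-empty")
  if (any(!nzchar(trimws(corpus)))) stop("corpus contains empty names")
  tokens <- strsplit(trimws(corpus), "\\s+")
  from <- unlist(lapply(tokens, function(w) c("<start>", w)))
  to <- unlist(lapply(tokens, function(w) c(w, "<end>")))
  counts <- table(paste(from, to, sep = "\r"))
  pair <- strsplit(names(counts), "\r", fixed = TRUE)
  edges <- data.frame(from = vapply(pair, `[`, "", 1),
                      to = vapply(pair, `[`, "", 2),
                      count = as.integer(counts),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  adjacency <- split(edges[c("to", "count")], edges$from)
  out <- list(edges = edges, adjacency = adjacency)
  class(out) <- "bigram_graph"
  out
}

#' Generate one employer name by random walk
#'
#' Walks from `<start>`, at each node choosing uniformly among the outgoing
#' multi-edges (i.e. with probability proportional to edge counts), until
#' `<end>` is reached or `max_path_length` words have been emitted (the
#' partial name is then returned).
#'
#' @param graph A `bigram_graph`.
#' @param max_path_length Maximum words in the name (>= 1).
#' @return A single name string.
#' @export
generate_employer_name <- function(graph, max_path_length = 10) {
  stopifnot(inherits(graph, "bigram_graph"), max_path_length >= 1)
  node <- "<start>"
  words <- character(0)
  while (length(words) < max_path_length) {
    adj <- graph$adjacency[[node]]
    if (is.null(adj)) break
    nxt <- adj$to[sample.int(nrow(adj), 1, prob = adj$count)]
    if (nxt == "<end>") break
    words <- c(words, nxt)
    node <- nxt
  }
  paste(words, collapse = " ")
}

#' Name all regular employers in a registry
#'
#' @param employers An `employer_registry`.
#' @param graph A `bigram_graph`.
#' @param max_path_length Maximum words per name.
#' @return The registry with `name` filled for regular employers.
#' @export
assign_employer_names <- function(employers, graph, max_path_length = 10) {
  need <- which(is.na(employers$name) &
                  employers$employer_id != UNEMPLOYED_ID)
  employers$name[need] <- vapply(
    need, function(i) generate_employer_name(graph, max_path_length), "")
  # a degenerate walk can emit an empty name; retry a few times
  for (i in which(!nzchar(employers$name) &
                    employers$employer_id != UNEMPLOYED_ID)) {
    for (try in 1:20) {
      nm <- generate_employer_name(graph, max_path_length)
      if (nzchar(nm)) break
    }
    employers$name[i] <- if (nzchar(nm)) nm else "Unnamed"
  }
  employers
}
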