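#' Rule-based disease ascertainment
#'
#' Classifies every cohort member as affected/unaffected for one disease and
#' derives the onset date (the earliest qualifying diagnosis or prescription
#' event). A person is affected when all of the following hold:
#' \itemize{
#'   \item the number of inclusion-code events reaches
#'     `min_inclusion_count`;
#'   \item the exclusion rule does not fire. Exclusion codes mark a
#'     non-autoimmune etiology; with two or more inclusion events, two or more
#'     exclusion events are required to overturn the diagnosis, while a single
#'     inclusion event is overturned by a single exclusion event;
#'   \item the drug requirement, if the definition has one, is met: persons
#'     alive after the stated date need the stated minimum number of
#'     drug-register dispensations with the ATC prefix; persons who died
#'     before that date are exempt.
#' }
#' Ascertainment is independent of the ordering of rows in the events table.
#'
#' @param cohort A [twin_cohort()].
#' @param definition A [disease_definition()].
#' @return data.frame with one row per person: `person_id`, `disease`,
#'   `affected`, `onset_date` (`NA` when unaffected).
#' @export
ascertain <- function(cohort, definition) {
  stopifnot(inherits(cohort, "twin_cohort"), inherits(definition, "disease_definition"))
  ind <- cohort$individuals
  ev <- cohort$events
  pid <- factor(ev$person_id, levels = ind$person_id)

  match_prefixes <- function(codemap) {
    if (!length(codemap) || !nrow(ev)) return(rep(FALSE, nrow(ev)))
    m <- rep(FALSE, nrow(ev))
    for (sys in names(codemap)) {
      in_sys <- ev$system == sys
      if (!any(in_sys)) next
      for (pfx in codemap[[sys]])
        m[in_sys] <- m[in_sys] | startsWith(ev$code[in_sys], pfx)
    }
    m
  }

  incl <- match_prefixes(definition$inclusion)
  if (definition$use_diabetes_register && nrow(ev))
    incl <- incl | ev$register == "diabetes_register"
  excl <- match_prefixes(definition$exclusion)

  count_by_person <- function(mask) {
    out <- integer(nrow(ind))
    if (any(mask)) {
      tb <- table(pid[mask])
      out <- as.integer(tb)
    }
    out
  }
  n_incl <- count_by_person(incl)
  n_excl <- count_by_person(excl)

  excluded <- ifelse(n_incl >= 2L, n_excl >= 2L, n_excl >= 1L)

  drug_ok <- rep(TRUE, nrow(ind))
  atc_first <- rep(as.Date(NA), nrow(ind))
  ra <- definition$required_atc
  if (!is.null(ra)) {
    atc_mask <- if (nrow(ev)) ev$system == "ATC" & ev$register == "drug_register" &
      startsWith(ev$code, ra$atc_prefix) else logical(0)
    n_atc <- count_by_person(atc_mask)
    applies <- is.na(ind$death_date) | ind$death_date > ra$applies_if_alive_after
    drug_ok <- !applies | n_atc >= ra$min_dispensations
    if (any(atc_mask)) {
      mn <- tapply(ev$date[atc_mask], droplevels(pid[atc_mask]), min)
      atc_first[match(names(mn), ind$person_id)] <- as.Date(mn, origin = "1970-01-01")
    }
  }

  affected <- n_incl >= definition$min_inclusion_count & !excluded & drug_ok

  onset <- rep(as.Date(NA), nrow(ind))
  if (any(incl)) {
    mn <- tapply(ev$date[incl], droplevels(pid[incl]), min)
    onset[match(names(mn), ind$person_id)] <- as.Date(mn, origin = "1970-01-01")
  }
  # a qualifying prescription can precede the first coded diagnosis
  use_atc <- !is.na(atc_first) & (is.na(onset) | atc_first < onset)
  onset[use_atc] <- atc_first[use_atc]
  onset[!affected] <- NA

  data.frame(person_id = ind$person_id, disease = definition$name,
             affected = affected, onset_date = onset,
             stringsAsFactors = FALSE)
}

#' Ascertain several diseases at once
#'
#' @param cohort A [twin_cohort()].
#' @param definitions Named list of [disease_definition()]s.
#' @return Named list of phenotype data.frames, one per disease.
#' @export
ascertain_all <- function(cohort, definitions = default_disease_definitions()) {
  setNames(lapply(definitions, function(d) ascertain(cohort, d)),
           vapply(definitions, `[[`, "", "name"))
}

#' Aggregate per-disease phenotypes into an "any disease" phenotype
#'
#' A person is affected by the aggregate trait when affected by at least one
#' of the component diseases; the aggregate onset is the earliest component
#' onset.
#'
#' @param phenotypes List of phenotype data.frames from [ascertain()], all on
#'   the same persons.
#' @param name Name for the aggregate trait.
#' @return Phenotype data.frame.
#' @export
aggregate_any <- function(phenotypes, name = "any_disease") {
  stopifnot(length(phenotypes) >= 1L)
  ids <- phenotypes[[1L]]$person_id
  for (p in phenotypes)
    if (!identical(p$person_id, ids))
      stop("phenotype tables must cover identical persons in identical order",
           call. = FALSE)
  aff_mat <- vapply(phenotypes, `[[`, logical(length(ids)), "affected")
  onset_mat <- vapply(phenotypes, function(p) as.numeric(p$onset_date),
                      numeric(length(ids)))
  if (is.null(dim(aff_mat))) { # single person
    aff_mat <- matrix(aff_mat, nrow = 1L)
    onset_mat <- matrix(onset_mat, nrow = 1L)
  }
  affected <- rowSums(aff_mat) > 0
  onset <- suppressWarnings(apply(onset_mat, 1L, min, na.rm = TRUE))
  onset[!is.finite(onset)] <- NA
  data.frame(person_id = ids, disease = name, affected = affected,
             onset_date = as.Date(onset, origin = "1970-01-01"),
             stringsAsFactors = FALSE)
}
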