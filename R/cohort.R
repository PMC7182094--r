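#' Twin cohort container
#'
#' A `twin_cohort` bundles an individuals table (one row per twin) with a
#' register event stream (one row per coded diagnosis or dispensation).
#' Individuals carry `person_id`, `pair_id`, `zygosity` (`"MZ"`, `"DZ"`, or
#' `"UN"` for unknown prior to exclusion), `sex` (`"female"`/`"male"`),
#' `birth_date` and optional `death_date`. Events carry `person_id`,
#' `system` (`ICD7`, `ICD8`, `ICD9`, `ICD10`, `ATC`), `code`, `date` and
#' `register` (`patient_register`, `drug_register`, `diabetes_register`).
#'
#' @param individuals data.frame of individuals.
#' @param events data.frame of code events (may have zero rows).
#' @param require_complete_pairs Require exactly two members per `pair_id`.
#' @return An object of class `twin_cohort` with elements `individuals` and
#'   `events`.
#' @export
twin_cohort <- function(individuals, events = NULL, require_complete_pairs = TRUE) {
  ind_cols <- c("person_id", "pair_id", "zygosity", "sex", "birth_date", "death_date")
  missing_cols <- setdiff(ind_cols, names(individuals))
  if (length(missing_cols))
    stop("individuals table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  individuals <- as.data.frame(individuals)[ind_cols]
  individuals$person_id <- as.character(individuals$person_id)
  individuals$pair_id <- as.character(individuals$pair_id)
  individuals$zygosity <- as.character(individuals$zygosity)
  individuals$sex <- as.character(individuals$sex)
  individuals$birth_date <- as_iso_date(individuals$birth_date, "birth_date", allow_na = FALSE)
  individuals$death_date <- as_iso_date(individuals$death_date, "death_date")

  if (anyDuplicated(individuals$person_id))
    stop("duplicated person_id in individuals table", call. = FALSE)
  if (!all(individuals$zygosity %in% c("MZ", "DZ", "UN")))
    stop("zygosity must be one of MZ, DZ, UN", call. = FALSE)
  if (!all(individuals$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'", call. = FALSE)
  bad_death <- !is.na(individuals$death_date) &
    individuals$death_date < individuals$birth_date
  if (any(bad_death))
    stop("death_date precedes birth_date for person(s): ",
         paste(head(individuals$person_id[bad_death], 5L), collapse = ", "),
         call. = FALSE)
  if (require_complete_pairs) {
    sz <- table(individuals$pair_id)
    if (any(sz != 2L))
      stop("incomplete pair(s): ",
           paste(head(names(sz)[sz != 2L], 5L), collapse = ", "), call. = FALSE)
    zyg_per_pair <- tapply(individuals$zygosity, individuals$pair_id,
                           function(z) length(unique(z)))
    if (any(zyg_per_pair != 1L))
      stop("co-twins with conflicting zygosity in pair(s): ",
           paste(head(names(zyg_per_pair)[zyg_per_pair != 1L], 5L), collapse = ", "),
           call. = FALSE)
  }

  if (is.null(events) || nrow(as.data.frame(events)) == 0L) {
    events <- data.frame(person_id = character(), system = character(),
                         code = character(), date = as.Date(character()),
                         register = character(), stringsAsFactors = FALSE)
  } else {
    ev_cols <- c("person_id", "system", "code", "date", "register")
    missing_cols <- setdiff(ev_cols, names(events))
    if (length(missing_cols))
      stop("events table lacks column(s): ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    events <- as.data.frame(events)[ev_cols]
    events$person_id <- as.character(events$person_id)
    events$system <- as.character(events$system)
    events$code <- as.character(events$code)
    events$date <- as_iso_date(events$date, "event date", allow_na = FALSE)
    events$register <- as.character(events$register)
    if (!all(events$system %in% c("ICD7", "ICD8", "ICD9", "ICD10", "ATC")))
      stop("event system must be one of ICD7, ICD8, ICD9, ICD10, ATC", call. = FALSE)
    if (!all(events$register %in% c("patient_register", "drug_register", "diabetes_register")))
      stop("event register must be patient_register, drug_register or diabetes_register",
           call. = FALSE)
    orphan <- setdiff(events$person_id, individuals$person_id)
    if (length(orphan))
      stop("events reference unknown person_id(s): ",
           paste(head(orphan, 5L), collapse = ", "), call. = FALSE)
  }
  structure(list(individuals = individuals, events = events), class = "twin_cohort")
}

#' Read a twin cohort from delimited text files
#'
#' @param individuals_path Path to the individuals file (columns `person_id`,
#'   `pair_id`, `zygosity`, `sex`, `birth_date`, `death_date`; ISO-8601 dates,
#'   empty `death_date` for living individuals).
#' @param events_path Path to the events file (columns `person_id`, `system`,
#'   `code`, `date`, `register`). May be `NULL` for a cohort without events.
#' @param sep Field separator; `","` (default) or `"\t"`.
#' @param require_complete_pairs Passed to [twin_cohort()].
#' @return A validated [twin_cohort()].
#' @export
read_cohort <- function(individuals_path, events_path = NULL, sep = ",",
                        require_complete_pairs = TRUE) {
  if (!file.exists(individuals_path))
    stop("individuals file not found: ", individuals_path, call. = FALSE)
  ind <- read.csv(individuals_path, sep = sep, colClasses = "character")
  ev <- NULL
  if (!is.null(events_path)) {
    if (!file.exists(events_path))
      stop("events file not found: ", events_path, call. = FALSE)
    ev <- read.csv(events_path, sep = sep, colClasses = "character")
  }
  twin_cohort(ind, ev, require_complete_pairs = require_complete_pairs)
}

#' Write a twin cohort to delimited text files
#'
#' Inverse of [read_cohort()]; a write/read round trip preserves all fields.
#'
#' @param cohort A [twin_cohort()].
#' @param individuals_path,events_path Output paths.
#' @param sep Field separator.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, individuals_path, events_path, sep = ",") {
  stopifnot(inherits(cohort, "twin_cohort"))
  ind <- cohort$individuals
  ind$birth_date <- format(ind$birth_date, "%Y-%m-%d")
  ind$death_date <- ifelse(is.na(ind$death_date), "",
                           format(ind$death_date, "%Y-%m-%d"))
  ev <- cohort$events
  ev$date <- format(ev$date, "%Y-%m-%d")
  write.table(ind, individuals_path, sep = sep, row.names = FALSE, quote = FALSE)
  write.table(ev, events_path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(c(individuals_path, events_path))
}

#' @export
print.twin_cohort <- function(x, ...) {
  n <- nrow(x$individuals)
  cat("Twin cohort:", n, "individuals in", length(unique(x$individuals$pair_id)),
      "pairs;", nrow(x$events), "register events\n")
  zt <- table(x$individuals$zygosity)
  cat("  zygosity:", paste(sprintf("%s=%d", names(zt), zt), collapse = ", "), "\n")
  invisible(x)
}

n_pairs <- function(cohort) length(unique(cohort$individuals$pair_id))
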