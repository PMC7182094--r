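# Small in-code cohort builders.

# n_pairs complete pairs, everyone alive, no events by default.
toy_cohort <- function(n_pairs = 3L, zygosity = "MZ", birth = "1950-06-15",
                       events = NULL, sexes = NULL, deaths = NULL) {
  n <- 2L * n_pairs
  zyg <- rep_len(zygosity, n_pairs)
  sexes <- sexes %||% rep(c("female", "male"), n_pairs)
  ind <- data.frame(
    person_id = sprintf("p%03d", seq_len(n)),
    pair_id = rep(sprintf("q%03d", seq_len(n_pairs)), each = 2L),
    zygosity = rep(zyg, each = 2L),
    sex = rep_len(sexes, n),
    birth_date = as.Date(rep_len(birth, n)),
    death_date = if (is.null(deaths)) as.Date(rep(NA, n)) else as.Date(deaths),
    stringsAsFactors = FALSE)
  twin_cohort(ind, events)
}

event_row <- function(person_id, code, date, system = "ICD10",
                      register = "patient_register") {
  data.frame(person_id = person_id, system = system, code = code,
             date = date, register = register, stringsAsFactors = FALSE)
}

# phenotype table built directly (bypassing ascertainment) for descriptive
# and survival tests
toy_phenotype <- function(cohort, affected, onset = NULL, disease = "toy") {
  ids <- cohort$individuals$person_id
  onset_date <- rep(as.Date(NA), length(ids))
  if (!is.null(onset)) onset_date[!is.na(onset)] <- as.Date(onset[!is.na(onset)])
  data.frame(person_id = ids, disease = disease,
             affected = rep_len(affected, length(ids)),
             onset_date = onset_date, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
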