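#' Reference pair-classification tables
#'
#' Published pair counts (concordant unaffected / discordant / concordant
#' affected, by zygosity) for seven organ-specific autoimmune diseases and
#' their "any disease" aggregate in a nationwide twin cohort of 110 814
#' twins. Bundled as validation fixtures and for the examples: the
#' tetrachoric and biometric fitters can be run directly on these counts.
#'
#' @return data.frame with columns `disease`, `zygosity`,
#'   `n_concordant_unaffected`, `n_discordant`, `n_concordant_affected`.
#' @examples
#' tabs <- aid_pair_tables()
#' ht_mz <- subset(tabs, disease == "hashimoto" & zygosity == "MZ")
#' fit_tetrachoric(as.numeric(ht_mz[1, 3:5]))
#' @export
aid_pair_tables <- function() {
  read.csv(system.file("extdata", "pair_tables.csv", package = "twinherit",
                       mustWork = TRUE), stringsAsFactors = FALSE)
}

#' Extract one reference pair table
#'
#' @param disease Disease name as in [aid_pair_tables()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A [pair_table()].
#' @export
aid_pair_table <- function(disease, zygosity) {
  tabs <- aid_pair_tables()
  row <- tabs[tabs$disease == disease & tabs$zygosity == zygosity, ]
  if (nrow(row) != 1L) stop("no such reference table", call. = FALSE)
  pair_table(row$n_concordant_unaffected, row$n_discordant,
             row$n_concordant_affected, disease = disease, zygosity = zygosity)
}

#' Reference sex-stratified case counts
#'
#' Published case counts and denominators (all / female / male) for the same
#' cohort as [aid_pair_tables()]; prevalence per 100 000 is
#' `1e5 * n_cases / n_denominator`.
#'
#' @return data.frame with columns `disease`, `stratum`, `n_cases`,
#'   `n_denominator`.
#' @export
aid_prevalence_counts <- function() {
  read.csv(system.file("extdata", "prevalence_counts.csv",
                       package = "twinherit", mustWork = TRUE),
           stringsAsFactors = FALSE)
}

#' Reference inclusion-cascade tallies
#'
#' The exclusion cascade of the reference cohort: 120 286 individuals from
#' complete pairs at entry; removed in order for unknown zygosity, death
#' before 1976, being the co-twin of someone who died before 1976, and
#' ambiguous birth data; 110 814 remain.
#'
#' @return Named list: `initial_n`, `unknown_zygosity`, `dead_before_cutoff`,
#'   `cotwin_of_dead`, `ambiguous_birth`, `final_n`.
#' @export
aid_exclusion_tallies <- function() {
  list(initial_n = 120286L, unknown_zygosity = 3966L,
       dead_before_cutoff = 3453L, cotwin_of_dead = 2049L,
       ambiguous_birth = 4L, final_n = 110814L)
}

#' Synthetic cohort realising a set of exclusion-cascade tallies
#'
#' Builds a minimal in-memory cohort whose [apply_exclusions()] report
#' reproduces the given tallies: pairs of unknown zygosity, pairs with both
#' members dead before the cutoff, pairs with exactly one member dead before
#' the cutoff (whose co-twin falls to the co-twin rule), pairs with
#' ambiguous birth years, and unremarkable pairs making up the total. The
#' individuals are synthetic; only the tally structure is meaningful.
#'
#' @param tallies As returned by [aid_exclusion_tallies()].
#' @return A [twin_cohort()].
#' @export
exclusion_fixture_cohort <- function(tallies = aid_exclusion_tallies()) {
  t <- tallies
  n_pairs_unknown <- t$unknown_zygosity / 2L
  n_pairs_one_dead <- t$cotwin_of_dead
  n_pairs_both_dead <- (t$dead_before_cutoff - t$cotwin_of_dead) / 2L
  n_pairs_amb <- t$ambiguous_birth / 2L
  stopifnot(n_pairs_unknown == round(n_pairs_unknown),
            n_pairs_both_dead == round(n_pairs_both_dead),
            n_pairs_both_dead >= 0)
  n_clean <- (t$initial_n - t$unknown_zygosity - t$dead_before_cutoff -
                t$cotwin_of_dead - t$ambiguous_birth) / 2L
  np <- n_pairs_unknown + n_pairs_one_dead + n_pairs_both_dead +
    n_pairs_amb + n_clean
  zyg <- rep(c("UN", "DZ", "DZ", "DZ", "MZ"),
             c(n_pairs_unknown, n_pairs_one_dead, n_pairs_both_dead,
               n_pairs_amb, n_clean))
  birth1 <- rep(as.Date("1940-06-01"), np)
  birth2 <- birth1
  amb_rows <- n_pairs_unknown + n_pairs_one_dead + n_pairs_both_dead +
    seq_len(n_pairs_amb)
  birth2[amb_rows] <- as.Date("1941-06-01")
  death1 <- death2 <- rep(as.Date(NA), np)
  one_dead <- n_pairs_unknown + seq_len(n_pairs_one_dead)
  both_dead <- n_pairs_unknown + n_pairs_one_dead + seq_len(n_pairs_both_dead)
  death1[c(one_dead, both_dead)] <- as.Date("1970-01-15")
  death2[both_dead] <- as.Date("1971-03-02")
  ind <- data.frame(
    person_id = sprintf("X%07d", seq_len(2L * np)),
    pair_id = rep(sprintf("XP%06d", seq_len(np)), each = 2L),
    zygosity = rep(zyg, each = 2L),
    sex = rep(c("female", "male"), np),
    birth_date = as.vector(rbind(birth1, birth2)),
    death_date = as.vector(rbind(death1, death2)),
    stringsAsFactors = FALSE)
  ind$birth_date <- as.Date(ind$birth_date, origin = "1970-01-01")
  ind$death_date <- as.Date(ind$death_date, origin = "1970-01-01")
  twin_cohort(ind)
}
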