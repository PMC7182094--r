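#' Cohort exclusion cascade
#'
#' Applies, in order, the registry-style inclusion rules for a complete-pair
#' twin cohort: (1) drop pairs of unknown zygosity; (2) drop individuals who
#' died before the cutoff year (both twins must be alive, or not yet born, in
#' that year); (3) drop the surviving co-twins of those individuals; (4) drop
#' pairs with ambiguous birth data (co-twins whose recorded birth years
#' differ); (5) drop pairs with any member born outside the admissible birth
#' year range. Pairs are always removed as whole pairs; events belonging to
#' removed individuals are dropped too. The cascade is idempotent.
#'
#' @param cohort A [twin_cohort()].
#' @param cutoff_year Both twins must be alive (or unborn) on Jan 1 of this
#'   year; default 1976.
#' @param birth_year_range Admissible birth years, default `c(1886, 2006)`.
#' @return List with elements `cohort` (the reduced cohort) and `report`
#'   (class `exclusion_report`: ordered rule tallies of individuals removed,
#'   plus `initial_n` and `final_n`).
#' @export
apply_exclusions <- function(cohort, cutoff_year = 1976,
                             birth_year_range = c(1886, 2006)) {
  stopifnot(inherits(cohort, "twin_cohort"))
  ind <- cohort$individuals
  initial_n <- nrow(ind)
  removed <- c(unknown_zygosity = 0L, dead_before_cutoff = 0L,
               cotwin_of_dead = 0L, ambiguous_birth = 0L,
               birth_year_out_of_range = 0L)

  # 1. unknown zygosity (pair-level attribute; whole pairs go)
  drop <- ind$zygosity == "UN"
  removed["unknown_zygosity"] <- sum(drop)
  ind <- ind[!drop, , drop = FALSE]

  # 2. dead before cutoff, and 3. their co-twins
  cutoff <- as.Date(sprintf("%d-01-01", cutoff_year))
  dead <- !is.na(ind$death_date) & ind$death_date < cutoff
  touched_pairs <- unique(ind$pair_id[dead])
  cotwin <- !dead & ind$pair_id %in% touched_pairs
  removed["dead_before_cutoff"] <- sum(dead)
  removed["cotwin_of_dead"] <- sum(cotwin)
  ind <- ind[!(dead | cotwin), , drop = FALSE]

  # 4. ambiguous birth data: co-twins with differing birth years
  if (nrow(ind)) {
    by <- birth_year_of(ind$birth_date)
    nby <- tapply(by, ind$pair_id, function(y) length(unique(y)))
    amb <- ind$pair_id %in% names(nby)[nby > 1L]
    removed["ambiguous_birth"] <- sum(amb)
    ind <- ind[!amb, , drop = FALSE]
  }

  # 5. birth year range (whole pairs)
  if (nrow(ind)) {
    by <- birth_year_of(ind$birth_date)
    bad <- by < birth_year_range[1] | by > birth_year_range[2]
    out <- ind$pair_id %in% unique(ind$pair_id[bad])
    removed["birth_year_out_of_range"] <- sum(out)
    ind <- ind[!out, , drop = FALSE]
  }

  ev <- cohort$events
  ev <- ev[ev$person_id %in% ind$person_id, , drop = FALSE]
  report <- structure(list(removed = removed, initial_n = initial_n,
                           final_n = nrow(ind)), class = "exclusion_report")
  list(cohort = twin_cohort(ind, ev), report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion cascade:", x$initial_n, "individuals at entry\n")
  for (nm in names(x$removed))
    cat(sprintf("  - %-24s %6d removed\n", nm, x$removed[[nm]]))
  cat("  final sample:", x$final_n, "individuals\n")
  invisible(x)
}
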