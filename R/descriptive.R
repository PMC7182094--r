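#' Prevalence by sex
#'
#' Observed register prevalence per 100 000 individuals, overall and by sex.
#'
#' @param cohort A [twin_cohort()].
#' @param phenotype Phenotype data.frame from [ascertain()].
#' @return data.frame with rows `all`, `female`, `male`: `disease`, `stratum`,
#'   `n_cases`, `n_denominator`, `prevalence_per_100k` (full precision; round
#'   for display).
#' @export
prevalence_by_sex <- function(cohort, phenotype) {
  ind <- cohort$individuals
  stopifnot(identical(ind$person_id, phenotype$person_id))
  one <- function(stratum) {
    keep <- if (stratum == "all") rep(TRUE, nrow(ind)) else ind$sex == stratum
    n_den <- sum(keep)
    if (n_den == 0L) stop("zero denominator in stratum '", stratum, "'", call. = FALSE)
    n_cases <- sum(phenotype$affected[keep])
    data.frame(disease = phenotype$disease[1L], stratum = stratum,
               n_cases = n_cases, n_denominator = n_den,
               prevalence_per_100k = 1e5 * n_cases / n_den,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(c("all", "female", "male"), one))
}

#' Sex-difference test for prevalence
#'
#' Two-sided Wald test of the sex coefficient in a marginal logit model of
#' affected status on sex, with variance clustered on twin pair (sandwich
#' estimator). This is the population-averaged (GEE, independence working
#' correlation) analogue accounting for the dependence of co-twins.
#'
#' @param cohort A [twin_cohort()].
#' @param phenotype Phenotype data.frame from [ascertain()].
#' @return List with `p_value`, `estimate` (log odds ratio female vs male),
#'   `robust_se`, `z`. `p_value` is `NA` (flagged via `defined = FALSE`) when
#'   the disease is absent from the cohort.
#' @export
sex_difference_test <- function(cohort, phenotype) {
  ind <- cohort$individuals
  stopifnot(identical(ind$person_id, phenotype$person_id))
  if (length(unique(ind$sex)) < 2L)
    stop("both sexes must be present", call. = FALSE)
  # no cases, or complete separation (all cases in one sex): a Wald test
  # on the logit scale is undefined
  cases_by_sex <- tapply(phenotype$affected, ind$sex, sum)
  if (!any(phenotype$affected) || any(cases_by_sex == 0))
    return(list(p_value = NA_real_, estimate = NA_real_, robust_se = NA_real_,
                z = NA_real_, defined = FALSE))
  d <- data.frame(y = phenotype$affected,
                  female = as.integer(ind$sex == "female"),
                  pair_id = ind$pair_id)
  fit <- glm(y ~ female, family = binomial(), data = d)
  V <- sandwich::vcovCL(fit, cluster = d$pair_id)
  est <- coef(fit)[["female"]]
  se <- sqrt(V["female", "female"])
  z <- est / se
  list(p_value = 2 * pnorm(-abs(z)), estimate = est, robust_se = se, z = z,
       defined = TRUE)
}

#' Twin pair classification table
#'
#' Classifies complete same-zygosity pairs by the number of affected members:
#' concordant unaffected (0), discordant (1), concordant affected (2).
#'
#' @param cohort A [twin_cohort()] of complete pairs.
#' @param phenotype Phenotype data.frame from [ascertain()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A [pair_table()].
#' @export
build_pair_table <- function(cohort, phenotype, zygosity) {
  ind <- cohort$individuals
  stopifnot(identical(ind$person_id, phenotype$person_id),
            zygosity %in% c("MZ", "DZ"))
  keep <- ind$zygosity == zygosity
  n_aff <- tapply(phenotype$affected[keep], ind$pair_id[keep], sum)
  pair_table(n_concordant_unaffected = sum(n_aff == 0L),
             n_discordant = sum(n_aff == 1L),
             n_concordant_affected = sum(n_aff == 2L),
             disease = phenotype$disease[1L], zygosity = zygosity)
}

#' Construct a pair table directly from counts
#'
#' @param n_concordant_unaffected,n_discordant,n_concordant_affected
#'   Non-negative pair counts.
#' @param disease,zygosity Optional labels.
#' @return Object of class `pair_table`.
#' @export
pair_table <- function(n_concordant_unaffected, n_discordant,
                       n_concordant_affected, disease = NA_character_,
                       zygosity = NA_character_) {
  counts <- c(n_concordant_unaffected, n_discordant, n_concordant_affected)
  stopifnot(length(counts) == 3L, all(counts >= 0), all(counts == round(counts)))
  structure(list(disease = disease, zygosity = zygosity,
                 n_concordant_unaffected = as.integer(n_concordant_unaffected),
                 n_discordant = as.integer(n_discordant),
                 n_concordant_affected = as.integer(n_concordant_affected)),
            class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf("Pair table%s%s: %d / %d / %d (conc. unaffected / discordant / conc. affected)\n",
              if (is.na(x$disease)) "" else paste0(" ", x$disease),
              if (is.na(x$zygosity)) "" else paste0(" ", x$zygosity),
              x$n_concordant_unaffected, x$n_discordant, x$n_concordant_affected))
  invisible(x)
}

total_pairs <- function(pt)
  pt$n_concordant_unaffected + pt$n_discordant + pt$n_concordant_affected

#' Probandwise concordance rate
#'
#' The probability that a twin is affected given an affected co-twin,
#' `2C / (2C + D)` from `C` concordant-affected and `D` discordant pairs
#' (each affected member of a concordant pair counts as a proband). The
#' confidence interval is a Wilson score interval on the proband-level
#' proportion; note that the two probands of a concordant pair are not
#' independent observations, so the interval is approximate.
#'
#' @param pt A [pair_table()].
#' @param level Confidence level.
#' @return List: `rate`, `ci_low`, `ci_high`, `n_probands`, `defined`
#'   (`FALSE` when there are no affected pairs at all), `applicable`
#'   (`FALSE` when there are no concordant-affected pairs, mirroring the
#'   convention of printing NA for such strata).
#' @export
probandwise <- function(pt, level = 0.95) {
  stopifnot(inherits(pt, "pair_table"))
  C <- pt$n_concordant_affected
  D <- pt$n_discordant
  n_probands <- 2L * C + D
  if (n_probands == 0L)
    return(list(rate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n_probands = 0L, defined = FALSE, applicable = FALSE))
  rate <- 2 * C / (2 * C + D)
  ci <- wilson_interval(2 * C, n_probands, level)
  list(rate = rate, ci_low = ci[1L], ci_high = ci[2L],
       n_probands = n_probands, defined = TRUE, applicable = C > 0L)
}

#' Descriptive summary table across diseases and zygosities
#'
#' Produces a long table with pair counts, probandwise concordance and
#' tetrachoric correlation per disease and zygosity, in the column order of a
#' classical twin-study concordance table.
#'
#' @param cohort A [twin_cohort()].
#' @param phenotypes Named list of phenotype data.frames.
#' @return data.frame, one row per disease x zygosity.
#' @export
concordance_table <- function(cohort, phenotypes) {
  rows <- list()
  for (nm in names(phenotypes)) {
    for (z in c("MZ", "DZ")) {
      pt <- build_pair_table(cohort, phenotypes[[nm]], z)
      pb <- probandwise(pt)
      tet <- tryCatch(fit_tetrachoric(pt), error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        disease = nm, zygosity = z,
        n_concordant_unaffected = pt$n_concordant_unaffected,
        n_discordant = pt$n_discordant,
        n_concordant_affected = pt$n_concordant_affected,
        probandwise = if (pb$applicable) pb$rate else NA_real_,
        probandwise_low = if (pb$applicable) pb$ci_low else NA_real_,
        probandwise_high = if (pb$applicable) pb$ci_high else NA_real_,
        tetrachoric = if (!is.null(tet) && pb$applicable) unname(coef(tet)["rho"]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
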