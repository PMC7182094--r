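#' Risk episodes with time-varying co-twin exposure
#'
#' Builds, for each twin, delayed-entry risk episodes on the age scale in
#' which the exposure is the co-twin's diagnosis of the index disease: a twin
#' is unexposed while the co-twin is undiagnosed and exposed strictly after
#' the co-twin's diagnosis date. The outcome event depends on `outcome_mode`:
#' \describe{
#'   \item{`same_disease`}{own diagnosis of the index disease;}
#'   \item{`different_disease`}{own diagnosis of any studied disease other
#'     than the index disease;}
#'   \item{`any_disease`}{own diagnosis of any studied disease.}
#' }
#' Follow-up runs from the later of birth and the start of registry coverage
#' to the earliest of the own event, death, and the end of coverage. When the
#' co-twin's diagnosis and the own event fall on the same day, the exposed
#' episode would have zero length and is dropped: the event is counted at the
#' end of the unexposed episode (exposure begins strictly after the co-twin's
#' diagnosis, avoiding immortal person-time).
#'
#' @param cohort A [twin_cohort()].
#' @param phenotypes Named list of phenotype data.frames for all studied
#'   diseases.
#' @param index_disease Name of the exposure-defining disease (must be in
#'   `phenotypes`).
#' @param outcome_mode `"same_disease"`, `"different_disease"` or
#'   `"any_disease"`.
#' @param registry_start_year,end_year Observation window for the outcome.
#' @return data.frame of episodes: `person_id`, `pair_id`, `entry_age`,
#'   `exit_age`, `event`, `exposed`, `sex`, `birth_year`. Persons already
#'   past their own event at entry contribute no episodes; their number is
#'   in `attr(, "n_prevalent")`.
#' @export
build_episodes <- function(cohort, phenotypes, index_disease,
                           outcome_mode = c("same_disease", "different_disease",
                                            "any_disease"),
                           registry_start_year = 1964, end_year = 2015) {
  outcome_mode <- match.arg(outcome_mode)
  stopifnot(index_disease %in% names(phenotypes))
  ind <- cohort$individuals
  index_ph <- phenotypes[[index_disease]]
  stopifnot(identical(ind$person_id, index_ph$person_id))

  outcome_ph <- switch(outcome_mode,
    same_disease = index_ph,
    different_disease = {
      others <- phenotypes[setdiff(names(phenotypes), index_disease)]
      if (!length(others)) NULL else aggregate_any(others, "different")
    },
    any_disease = aggregate_any(phenotypes, "any"))
  if (is.null(outcome_ph)) {
    out <- data.frame(person_id = character(), pair_id = character(),
                      entry_age = numeric(), exit_age = numeric(),
                      event = logical(), exposed = logical(),
                      sex = character(), birth_year = integer())
    attr(out, "n_prevalent") <- 0L
    return(out)
  }

  reg_start <- as.Date(sprintf("%d-01-01", registry_start_year))
  reg_end <- as.Date(sprintf("%d-12-31", end_year))
  # co-twin lookup: within each pair the other member
  ord <- order(ind$pair_id)
  pos <- integer(nrow(ind))
  pos[ord] <- seq_along(ord)
  co_row <- ord[ifelse(pos %% 2L == 1L, pos + 1L, pos - 1L)]

  entry_date <- pmax(ind$birth_date, reg_start)
  own_event_date <- as.Date(ifelse(outcome_ph$affected,
                                   outcome_ph$onset_date, NA),
                            origin = "1970-01-01")
  end_date <- reg_end
  has_death <- !is.na(ind$death_date)
  end_date <- as.Date(ifelse(has_death, pmin(reg_end, ind$death_date), reg_end),
                      origin = "1970-01-01")
  exit_date <- as.Date(ifelse(!is.na(own_event_date),
                              pmin(own_event_date, end_date), end_date),
                       origin = "1970-01-01")
  event <- !is.na(own_event_date) & own_event_date <= end_date
  co_onset <- as.Date(ifelse(index_ph$affected[co_row],
                             index_ph$onset_date[co_row], NA),
                      origin = "1970-01-01")

  prevalent <- exit_date <= entry_date
  birth_year <- birth_year_of(ind$birth_date)
  idx <- which(!prevalent)
  e0 <- entry_date[idx]; e1 <- exit_date[idx]; sw <- co_onset[idx]
  split <- !is.na(sw) & sw > e0 & sw < e1

  s <- idx[split]; u <- idx[!split]
  sw_s <- sw[split]
  # unsplit: a single episode, exposed throughout iff co-twin diagnosed
  # at or before entry
  exposed_u <- !is.na(sw[!split]) & sw[!split] <= e0[!split]
  take <- c(s, s, u)
  seg_start <- c(e0[split], sw_s, e0[!split])
  seg_end <- c(sw_s, e1[split], e1[!split])
  out <- data.frame(
    person_id = ind$person_id[take], pair_id = ind$pair_id[take],
    entry_age = age_at(ind$birth_date[take], seg_start),
    exit_age = age_at(ind$birth_date[take], seg_end),
    event = c(rep(FALSE, sum(split)), event[s], event[u]),
    exposed = c(rep(FALSE, sum(split)), rep(TRUE, sum(split)), exposed_u),
    sex = ind$sex[take], birth_year = birth_year[take],
    stringsAsFactors = FALSE)
  out <- out[order(out$person_id, out$entry_age), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_prevalent") <- sum(prevalent)
  out
}

#' Age-scale Cox regression with pair-clustered robust variance
#'
#' Proportional-hazards fit of the episode data from [build_episodes()]:
#' partial likelihood on the age scale with delayed entry, Efron handling of
#' tied event ages (Breslow available), co-twin exposure plus optional sex
#' and birth-cohort adjustment, and both model-based and cluster-robust
#' (sandwich, clustered on twin pair) standard errors.
#'
#' @param episodes data.frame from [build_episodes()].
#' @param adjust Character vector among `"sex"`, `"birth_year"` to include as
#'   covariates (birth year as 10-year categories).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `coagg_fit`: coefficient table with `log_hr`,
#'   `se`, `robust_se`, `hr`, `ci_low`, `ci_high` (robust, Wald), plus
#'   `n_events`, `n_episodes`, and the underlying `coxph` fit. The exposure
#'   coefficient is flagged undefined when there is no exposed person-time.
#' @export
fit_cox <- function(episodes, adjust = c("sex", "birth_year"),
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (!nrow(episodes) || !any(episodes$event))
    stop("need at least one event", call. = FALSE)
  if (!any(episodes$exposed))
    return(structure(list(coefficients = NULL, defined = FALSE,
                          n_events = sum(episodes$event),
                          n_episodes = nrow(episodes)), class = "coagg_fit"))
  d <- episodes
  d$exposed <- as.integer(d$exposed)
  terms <- "exposed"
  if ("sex" %in% adjust && length(unique(d$sex)) > 1L) {
    d$female <- as.integer(d$sex == "female")
    terms <- c(terms, "female")
  }
  if ("birth_year" %in% adjust) {
    d$byc <- birth_year_category(d$birth_year)
    if (nlevels(droplevels(d$byc)) > 1L) terms <- c(terms, "byc")
  }
  fml <- as.formula(paste("survival::Surv(entry_age, exit_age, event) ~",
                          paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = d, ties = ties, cluster = pair_id,
                         control = survival::coxph.control(eps = 1e-11,
                                                           iter.max = 50L),
                         x = FALSE, y = FALSE)
  est <- coef(fit)
  rse <- sqrt(diag(fit$var))          # robust (clustered) variance
  mse <- sqrt(diag(fit$naive.var %||% fit$var))
  z <- qnorm(0.975)
  tab <- data.frame(term = names(est), log_hr = unname(est),
                    se = unname(mse), robust_se = unname(rse),
                    hr = exp(unname(est)),
                    ci_low = exp(unname(est) - z * rse),
                    ci_high = exp(unname(est) + z * rse),
                    stringsAsFactors = FALSE)
  monotone <- !any(d$event & !d$exposed)
  structure(list(coefficients = tab, defined = TRUE,
                 boundary_flag = monotone,
                 n_events = sum(d$event), n_episodes = nrow(d),
                 ties = ties, coxph = fit), class = "coagg_fit")
}

#' @export
print.coagg_fit <- function(x, digits = 3L, ...) {
  if (!x$defined) {
    cat("Co-aggregation Cox fit: exposure effect undefined (no exposed person-time)\n")
    return(invisible(x))
  }
  cat(sprintf("Co-aggregation Cox fit (%s ties): %d events over %d episodes\n",
              x$ties, x$n_events, x$n_episodes))
  tt <- x$coefficients[x$coefficients$term == "exposed", ]
  cat(sprintf("  co-twin exposure HR: %.*f (95%% CI %.*f to %.*f; robust SE %.3f)\n",
              digits, tt$hr, digits, tt$ci_low, digits, tt$ci_high, tt$robust_se))
  if (isTRUE(x$boundary_flag))
    cat("  note: no unexposed events (monotone likelihood); estimate unstable\n")
  invisible(x)
}

#' @export
coef.coagg_fit <- function(object, ...) {
  if (!object$defined) return(NULL)
  setNames(object$coefficients$log_hr, object$coefficients$term)
}

#' Familial aggregation and co-aggregation report
#'
#' For each index disease, outcome mode and zygosity stratum, fits the
#' age-scale Cox model with co-twin exposure and reports the hazard ratio
#' with cluster-robust confidence interval and event counts — the long-table
#' form of a forest plot of familial (co-)aggregation.
#'
#' @param cohort A [twin_cohort()].
#' @param phenotypes Named list of phenotype data.frames.
#' @param diseases Index diseases to report (default all in `phenotypes`).
#' @param outcome_modes Subset of the three outcome definitions.
#' @param adjust Covariates, as in [fit_cox()].
#' @return data.frame with one row per disease x outcome mode x zygosity:
#'   `hr`, `ci_low`, `ci_high`, `n_events`, `n_episodes`, `estimable`.
#' @export
aggregation_report <- function(cohort, phenotypes,
                               diseases = names(phenotypes),
                               outcome_modes = c("same_disease",
                                                 "different_disease",
                                                 "any_disease"),
                               adjust = c("sex", "birth_year")) {
  ind <- cohort$individuals
  rows <- list()
  for (dis in diseases) for (mode in outcome_modes) {
    ep <- build_episodes(cohort, phenotypes, dis, mode)
    for (z in c("MZ", "DZ")) {
      keep <- ep$pair_id %in% ind$pair_id[ind$zygosity == z]
      epz <- ep[keep, , drop = FALSE]
      # sparse strata routinely produce monotone-likelihood warnings for
      # nuisance covariate levels; the scan carries flags instead
      fit <- tryCatch(suppressWarnings(fit_cox(epz, adjust = adjust)),
                      error = function(e) NULL)
      est <- !is.null(fit) && isTRUE(fit$defined)
      tt <- if (est) fit$coefficients[fit$coefficients$term == "exposed", ] else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        disease = dis, outcome_mode = mode, zygosity = z,
        hr = if (est) tt$hr else NA_real_,
        ci_low = if (est) tt$ci_low else NA_real_,
        ci_high = if (est) tt$ci_high else NA_real_,
        n_events = if (!is.null(fit)) fit$n_events else sum(epz$event),
        n_episodes = nrow(epz), estimable = est,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("aggregation_report", class(out))
  out
}

#' Forest-style plot of an aggregation report
#'
#' @param x An [aggregation_report()] result.
#' @param log_scale Plot hazard ratios on a log axis.
#' @param ... Passed to plotting primitives.
#' @export
plot.aggregation_report <- function(x, log_scale = TRUE, ...) {
  d <- x[x$estimable, , drop = FALSE]
  if (!nrow(d)) { warning("nothing estimable to plot"); return(invisible(x)) }
  lab <- paste(d$disease, d$outcome_mode, d$zygosity)
  yy <- rev(seq_len(nrow(d)))
  op <- par(mar = c(4, 12, 1, 1)); on.exit(par(op))
  plot(d$hr, yy, log = if (log_scale) "x" else "", pch = 19,
       xlim = range(c(d$ci_low, d$ci_high, 1), finite = TRUE),
       xlab = "hazard ratio (co-twin exposed vs unexposed)", ylab = "",
       yaxt = "n", ...)
  segments(d$ci_low, yy, d$ci_high, yy)
  abline(v = 1, lty = 2)
  axis(2, at = yy, labels = lab, las = 1, cex.axis = 0.7)
  invisible(x)
}
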