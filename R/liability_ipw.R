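#' Observation windows on the age scale
#'
#' For each cohort member, derives the delayed-entry observation window for
#' one disease: entry age is the age at the later of birth and the start of
#' registry coverage; exit age is the age at the earliest of disease onset,
#' death, and the end of registry coverage. Persons whose onset precedes
#' entry (diagnosis recorded at the start of coverage) retain affected status
#' and are flagged `prevalent_at_entry`.
#'
#' @param cohort A [twin_cohort()] (exclusion cascade applied).
#' @param phenotype Phenotype data.frame from [ascertain()].
#' @param registry_start_year First year of registry coverage for this
#'   disease (default 1964).
#' @param end_year Last year of coverage (default 2015; exit is Dec 31).
#' @return data.frame with `person_id`, `entry_age`, `exit_age`, `affected`,
#'   `prevalent_at_entry`; windows with `exit_age <= entry_age` are dropped
#'   and counted in `attr(, "n_dropped")` with a warning.
#' @export
build_windows <- function(cohort, phenotype, registry_start_year = 1964,
                          end_year = 2015) {
  ind <- cohort$individuals
  stopifnot(identical(ind$person_id, phenotype$person_id))
  reg_start <- as.Date(sprintf("%d-01-01", registry_start_year))
  reg_end <- as.Date(sprintf("%d-12-31", end_year))
  entry_date <- pmax(ind$birth_date, reg_start)
  exit_date <- rep(reg_end, nrow(ind))
  has_death <- !is.na(ind$death_date)
  exit_date[has_death] <- pmin(exit_date[has_death], ind$death_date[has_death])
  has_onset <- phenotype$affected & !is.na(phenotype$onset_date)
  exit_date[has_onset] <- pmin(exit_date[has_onset], phenotype$onset_date[has_onset])
  # prevalent at entry: onset recorded at or before start of coverage
  prevalent <- has_onset & phenotype$onset_date <= entry_date
  exit_date[prevalent] <- entry_date[prevalent]

  w <- data.frame(person_id = ind$person_id,
                  entry_age = age_at(ind$birth_date, entry_date),
                  exit_age = age_at(ind$birth_date, exit_date),
                  affected = phenotype$affected,
                  prevalent_at_entry = prevalent,
                  stringsAsFactors = FALSE)
  # prevalent cases keep status but have no risk time; give them a token
  # window ending at entry so weighting can treat them (flagged above)
  drop <- w$exit_age <= w$entry_age & !prevalent
  if (any(drop))
    warning(sum(drop), " window(s) dropped (exit before entry)", call. = FALSE)
  w <- w[!drop, , drop = FALSE]
  attr(w, "n_dropped") <- sum(drop)
  w
}

#' Product-limit model of the censoring process on the age scale
#'
#' Estimates the probability `S_c(age)` of still being under observation
#' (neither dead nor past the end of registry coverage) at a given age, by a
#' Kaplan-Meier fit with delayed entry in which a non-disease exit is the
#' event and disease onset censors. `1 / S_c(onset age)` is the
#' inverse-probability-of-censoring weight of an observed case.
#'
#' @param windows Output of [build_windows()].
#' @return Object of class `censoring_model`: a step function `S_c` plus the
#'   underlying `survival::survfit`.
#' @export
estimate_censoring <- function(windows) {
  w <- windows[windows$exit_age > windows$entry_age, , drop = FALSE]
  cens_event <- as.integer(!w$affected)   # non-disease exit = event
  if (!any(cens_event == 1L)) {
    sf <- NULL
    S <- function(age) rep(1, length(age))
  } else {
    fit <- survival::survfit(
      survival::Surv(w$entry_age, w$exit_age, cens_event) ~ 1)
    sf <- fit
    # left-continuous evaluation: weight at onset age uses S_c(age-)
    S <- stepfun(fit$time, c(1, fit$surv), right = TRUE)
  }
  structure(list(S_c = S, fit = sf), class = "censoring_model")
}

#' @export
print.censoring_model <- function(x, ...) {
  cat("Censoring model: product-limit estimate on the age scale\n")
  if (!is.null(x$fit))
    cat(sprintf("  %d subjects, %d censoring events\n", x$fit$n,
                sum(x$fit$n.event)))
  invisible(x)
}

# IPC weights: 1/S_c(exit-) for affected members, 1 otherwise; truncated at
# the given quantile of the affected weights for stability.
ipw_weights <- function(windows, censoring_model, truncate_at = 0.99) {
  w <- rep(1, nrow(windows))
  aff <- windows$affected
  if (any(aff)) {
    s <- censoring_model$S_c(windows$exit_age[aff])
    s[s <= 0] <- min(s[s > 0], 1e-3)
    wi <- 1 / s
    if (is.finite(truncate_at) && truncate_at < 1) {
      cap <- quantile(wi, truncate_at, names = FALSE)
      wi <- pmin(wi, cap)
    }
    w[aff] <- wi
  }
  w
}

#' Covariate specification for threshold adjustment
#'
#' @param sex Include a female indicator on the probit threshold.
#' @param birth_year_bin_width Width (years) of the birth-cohort categories;
#'   `NULL` omits birth-year adjustment.
#' @return Object of class `covariate_spec`.
#' @export
covariate_spec <- function(sex = TRUE, birth_year_bin_width = 10L) {
  structure(list(sex = isTRUE(sex),
                 birth_year_bin_width = birth_year_bin_width),
            class = "covariate_spec")
}

covariate_matrix <- function(spec, individuals) {
  X <- NULL
  if (is.null(spec)) return(NULL)
  if (spec$sex)
    X <- cbind(female = as.numeric(individuals$sex == "female"))
  if (!is.null(spec$birth_year_bin_width)) {
    byc <- birth_year_category(birth_year_of(individuals$birth_date),
                               spec$birth_year_bin_width)
    if (nlevels(byc) > 1L) {
      M <- stats::model.matrix(~ byc)[, -1L, drop = FALSE]
      colnames(M) <- paste0("by", levels(byc)[-1L])
      X <- cbind(X, M)
    }
  }
  X
}

#' Individual-level liability model with censoring weights
#'
#' Fits the liability-threshold variance-component model on individual pairs
#' rather than collapsed tables, which allows (i) person-specific thresholds
#' `tau_i = tau0 + x_i' beta` (sex, birth-cohort category) and (ii) an
#' inverse-probability-of-censoring adjustment for left truncation and right
#' censoring. Each pair contributes its bivariate-probit cell probability
#' (affected/unaffected status of both members), and each term is weighted by
#' the product of member weights: `1 / S_c(onset age)` for affected members
#' (up-weighting cases that were at risk of being censored before diagnosis)
#' and 1 for unaffected members. The weighted pairwise composite
#' log-likelihood is maximised over the threshold, covariate coefficients and
#' variance components; zygosity correlations are structured by
#' [implied_correlations()].
#'
#' With all weights equal to 1 and no covariates the objective collapses to
#' the pair-table likelihood and the fit reproduces [fit_biometric()].
#'
#' @param cohort A [twin_cohort()].
#' @param windows Output of [build_windows()].
#' @param censoring_model From [estimate_censoring()], or `NULL` for
#'   unweighted fitting.
#' @param model Variance decomposition (`"AE"`, `"ACE"`, `"ADE"`, `"CE"`,
#'   `"E"`).
#' @param covariates A [covariate_spec()], or `NULL` for an unadjusted fit.
#' @param truncate_weights Quantile at which case weights are capped
#'   (default 0.99).
#' @param nboot Number of pair-level bootstrap resamples for confidence
#'   intervals on `a2` (0 = no interval).
#' @return Object of class `c("liability_fit", "biometric_fit")` with
#'   `components`, `tau`, `beta`, `loglik` (weighted composite), `aic`
#'   (composite-likelihood analogue, comparable across models on the same
#'   data), and `ci` when bootstrapped.
#' @export
fit_liability_ipw <- function(cohort, windows, censoring_model = NULL,
                              model = "AE", covariates = NULL,
                              truncate_weights = 0.99, nboot = 0L) {
  model <- match.arg(model, biometric_models)
  ind <- cohort$individuals
  m <- match(windows$person_id, ind$person_id)
  stopifnot(!anyNA(m))
  dat <- data.frame(person_id = windows$person_id,
                    pair_id = ind$pair_id[m],
                    zygosity = ind$zygosity[m],
                    affected = windows$affected,
                    exit_age = windows$exit_age,
                    stringsAsFactors = FALSE)
  X <- covariate_matrix(covariates, ind[m, , drop = FALSE])
  dat$w <- if (is.null(censoring_model)) 1
           else ipw_weights(windows, censoring_model, truncate_weights)

  # keep pairs with both members windowed
  cnt <- table(dat$pair_id)
  keep <- dat$pair_id %in% names(cnt)[cnt == 2L]
  dat <- dat[keep, , drop = FALSE]
  if (!is.null(X)) X <- X[keep, , drop = FALSE]
  ord <- order(dat$pair_id)
  dat <- dat[ord, , drop = FALSE]
  if (!is.null(X)) X <- X[ord, , drop = FALSE]
  i1 <- seq(1L, nrow(dat), by = 2L)
  i2 <- i1 + 1L
  zyg <- dat$zygosity[i1]
  y1 <- dat$affected[i1]; y2 <- dat$affected[i2]
  wpair <- dat$w[i1] * dat$w[i2]
  if (!any(c(y1, y2))) stop("no affected individuals", call. = FALSE)

  p <- if (is.null(X)) 0L else ncol(X)
  k <- n_free_components(model)

  nll <- function(par) {
    tau0 <- par[1L]
    beta <- if (p) par[1L + seq_len(p)] else numeric()
    comps <- components_from_theta(model, if (k) par[1L + p + seq_len(k)] else numeric())
    r <- implied_correlations(comps["a2"], comps["c2"], comps["d2"])
    tau_i <- tau0 + if (p) as.vector(X %*% beta) else 0
    t1 <- if (p) tau_i[i1] else rep(tau0, length(i1))
    t2 <- if (p) tau_i[i2] else rep(tau0, length(i1))
    ll <- 0
    for (z in c("MZ", "DZ")) {
      sel <- zyg == z
      if (!any(sel)) next
      rho <- min(if (z == "MZ") r[1L] else r[2L], 0.9999)
      p11 <- bvn_upper_orthant(t1[sel], t2[sel], rho, nodes = 32L)
      s1 <- pnorm(t1[sel], lower.tail = FALSE)
      s2 <- pnorm(t2[sel], lower.tail = FALSE)
      cell <- ifelse(y1[sel] & y2[sel], p11,
              ifelse(y1[sel] & !y2[sel], s1 - p11,
              ifelse(!y1[sel] & y2[sel], s2 - p11, 1 - s1 - s2 + p11)))
      if (any(cell <= 1e-300)) return(1e12)
      ll <- ll + sum(wpair[sel] * log(cell))
    }
    if (!is.finite(ll)) 1e12 else -ll
  }

  prev <- sum(dat$w * dat$affected) / sum(dat$w)
  start <- c(qnorm(1 - prev), rep(0, p),
             switch(model, E = numeric(), AE = 0.5, CE = 0,
                    ACE = c(0, 0), ADE = c(0, 0)))
  fits <- list()
  for (st in list(start, start + c(0, rep(0, p), rep(0.8, k)))) {
    o <- tryCatch(optim(st, nll, method = "BFGS",
                        control = list(reltol = 1e-10, maxit = 1000L)),
                  error = function(e) NULL)
    if (!is.null(o)) fits[[length(fits) + 1L]] <- o
  }
  if (!length(fits)) stop("liability fit failed to converge from all starts",
                          call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  tau0 <- best$par[1L]
  beta <- if (p) setNames(best$par[1L + seq_len(p)], colnames(X)) else NULL
  comps <- components_from_theta(model, if (k) best$par[1L + p + seq_len(k)] else numeric())
  comps[comps < 1e-6] <- 0
  comps["e2"] <- 1 - comps["a2"] - comps["c2"] - comps["d2"]
  loglik <- -best$value
  aic <- 2 * (1 + p + k) - 2 * loglik

  ci_tab <- NULL
  if (nboot > 0L) {
    a2s <- replicate(nboot, {
      rs <- sample(length(i1), replace = TRUE)
      idx <- as.vector(rbind(i1[rs], i2[rs]))
      sub_w <- windows[match(dat$person_id[idx], windows$person_id), , drop = FALSE]
      sub_w$person_id <- sprintf("b%06d", seq_len(nrow(sub_w)))
      sub_ind <- ind[match(dat$person_id[idx], ind$person_id), , drop = FALSE]
      sub_ind$person_id <- sub_w$person_id
      sub_ind$pair_id <- rep(sprintf("bp%06d", seq_along(rs)), each = 2L)
      bc <- twin_cohort(sub_ind, NULL)
      bf <- tryCatch(fit_liability_ipw(bc, sub_w, censoring_model, model,
                                       covariates, truncate_weights, nboot = 0L),
                     error = function(e) NULL)
      if (is.null(bf)) NA_real_ else bf$components[["a2"]]
    })
    qs <- quantile(a2s, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    ci_tab <- rbind(a2 = c(low = qs[1L], high = qs[2L]))
  }

  structure(list(components = comps, tau = tau0, beta = beta, loglik = loglik,
                 aic = aic, ci = ci_tab, model = model, degenerate = FALSE,
                 weighted = !is.null(censoring_model),
                 n_pairs = length(i1),
                 mz = pair_table(0, 0, 0), dz = pair_table(0, 0, 0)),
            class = c("liability_fit", "biometric_fit"))
}

#' @export
print.liability_fit <- function(x, digits = 3L, ...) {
  cat(sprintf("Individual-level liability %s model (%s), %d pairs\n",
              x$model, if (x$weighted) "IPC-weighted" else "unweighted",
              x$n_pairs))
  comps <- x$components[x$components > 0 | names(x$components) == "e2"]
  cat("  variance shares:",
      paste(sprintf("%s = %.*f", names(comps), digits, comps), collapse = ", "), "\n")
  cat(sprintf("  baseline threshold: %.*f\n", digits, x$tau))
  if (!is.null(x$beta)) {
    cat("  threshold shifts:\n")
    for (nm in names(x$beta))
      cat(sprintf("    %-12s %+.*f\n", nm, digits, x$beta[[nm]]))
  }
  if (!is.null(x$ci))
    cat(sprintf("  a2 bootstrap 95%% CI: %.*f to %.*f\n",
                digits, x$ci["a2", "low"], digits, x$ci["a2", "high"]))
  invisible(x)
}

#' Adjustment-by-censoring grid of liability fits
#'
#' Convenience wrapper producing the four-cell grid
#' \{unadjusted, covariate-adjusted\} x \{unweighted, censoring-weighted\}
#' for one disease, as used in sensitivity reporting.
#'
#' @param cohort A [twin_cohort()].
#' @param phenotype Phenotype data.frame.
#' @param model Variance decomposition.
#' @param registry_start_year,end_year Passed to [build_windows()].
#' @return data.frame with one row per grid cell: a2, e2 (and c2/d2), tau.
#' @export
liability_grid <- function(cohort, phenotype, model = "AE",
                           registry_start_year = 1964, end_year = 2015) {
  w <- build_windows(cohort, phenotype, registry_start_year, end_year)
  cm <- estimate_censoring(w)
  cells <- expand.grid(adjusted = c(FALSE, TRUE), weighted = c(FALSE, TRUE))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    f <- fit_liability_ipw(cohort, w,
                           censoring_model = if (cells$weighted[i]) cm else NULL,
                           model = model,
                           covariates = if (cells$adjusted[i]) covariate_spec() else NULL)
    data.frame(adjusted = cells$adjusted[i], censoring_weighted = cells$weighted[i],
               a2 = f$components[["a2"]], c2 = f$components[["c2"]],
               d2 = f$components[["d2"]], e2 = f$components[["e2"]],
               tau = f$tau, loglik = f$loglik)
  })
  do.call(rbind, rows)
}
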