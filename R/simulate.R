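#' Trait specification for the synthetic twin cohort
#'
#' Declares one simulated binary trait under the liability-threshold model:
#' variance shares `a2` (additive genetic), `c2` (shared environment), `d2`
#' (dominance) and the remainder `e2`; a lifetime prevalence that fixes the
#' liability threshold `tau = qnorm(1 - prevalence)`; an optional
#' female-excess threshold shift (females get threshold `tau - fe/2`, males
#' `tau + fe/2`, keeping the overall prevalence near the target); a lognormal
#' onset-age distribution truncated to ages 0-100; and the register codes
#' emitted for diagnosed cases.
#'
#' @param name Trait name.
#' @param a2,c2,d2 Variance shares; `e2` is the remainder and must be
#'   non-negative.
#' @param prevalence Lifetime prevalence in (0, 0.5).
#' @param female_excess Threshold shift (probit scale) between the sexes.
#' @param onset_meanlog,onset_sdlog Lognormal onset-age parameters (years).
#' @param icd10_code Inclusion code emitted to the patient register.
#' @param atc_code Optional ATC class; diagnosed cases alive after 2005 also
#'   receive two dispensation events.
#' @param use_diabetes_register Emit a diabetes-register event per case.
#' @return Object of class `trait_spec`.
#' @export
trait_spec <- function(name, a2, c2 = 0, d2 = 0, prevalence,
                       female_excess = 0, onset_meanlog = log(45),
                       onset_sdlog = 0.45, icd10_code = "X99",
                       atc_code = NULL, use_diabetes_register = FALSE) {
  e2 <- 1 - a2 - c2 - d2
  stopifnot(a2 >= 0, c2 >= 0, d2 >= 0, e2 >= -1e-9,
            prevalence > 0, prevalence < 0.5)
  structure(list(name = name, a2 = a2, c2 = c2, d2 = d2, e2 = max(e2, 0),
                 prevalence = prevalence, female_excess = female_excess,
                 onset_meanlog = onset_meanlog, onset_sdlog = onset_sdlog,
                 icd10_code = icd10_code, atc_code = atc_code,
                 use_diabetes_register = isTRUE(use_diabetes_register)),
            class = "trait_spec")
}

#' Default per-decade death model
#'
#' Coarse conditional probabilities of dying within each decade of age given
#' survival to its start — enough to exercise death-based censoring and the
#' alive-in-1976 truncation rule, with no claim of demographic calibration.
#'
#' @return Numeric vector of 11 decade probabilities (ages 0-9 ... 100+).
#' @export
default_death_model <- function() {
  c(0.03, 0.005, 0.01, 0.01, 0.02, 0.05, 0.10, 0.25, 0.50, 0.85, 1.0)
}

#' Simulation configuration
#'
#' @param n_pairs Number of twin pairs.
#' @param traits List of [trait_spec()]s.
#' @param mz_fraction Fraction of pairs that are monozygotic (default 1/3).
#' @param birth_year_range Birth years, default `c(1886, 2006)`.
#' @param death_model Per-decade death probabilities
#'   ([default_death_model()]) or `NULL` to disable death.
#' @param registry List with `patient_start`, `patient_end` (calendar years of
#'   patient-register coverage) and `drug_start` (ISO date the drug register
#'   opens).
#' @param r_g Cross-trait additive-genetic correlation matrix (unit diagonal,
#'   positive semidefinite); default identity.
#' @param seed Root seed; every component derives its own substream.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_pairs, traits, mz_fraction = 1 / 3,
                       birth_year_range = c(1886, 2006),
                       death_model = default_death_model(),
                       registry = list(patient_start = 1964,
                                       patient_end = 2015,
                                       drug_start = "2005-07-01"),
                       r_g = NULL, seed = 1L) {
  stopifnot(n_pairs >= 1, length(traits) >= 1)
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  nm <- vapply(traits, `[[`, "", "name")
  names(traits) <- nm
  Tn <- length(traits)
  if (is.null(r_g)) r_g <- diag(Tn)
  r_g <- as.matrix(r_g)
  if (!all(dim(r_g) == Tn) || any(abs(diag(r_g) - 1) > 1e-8))
    stop("r_g must be a square correlation matrix matching the traits",
         call. = FALSE)
  if (min(eigen(r_g, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("r_g is not positive semidefinite", call. = FALSE)
  structure(list(n_pairs = as.integer(n_pairs), traits = traits,
                 mz_fraction = mz_fraction,
                 birth_year_range = birth_year_range,
                 death_model = death_model, registry = registry,
                 r_g = r_g, seed = as.integer(seed)),
            class = "sim_config")
}

# draw n x T standard-normal matrix whose columns follow correlation R,
# mixed through the lower-triangular Cholesky factor so that trait t only
# consumes the base streams of traits 1..t (appending traits later leaves
# earlier traits' draws untouched)
mix_corr <- function(Z, R) {
  L <- t(chol(R + diag(1e-10, nrow(R))))
  Z %*% t(L)
}

#' Simulate a twin cohort with known ground truth
#'
#' Generates a complete-pair twin cohort under the classical twin model:
#' per-pair additive genetic scores correlated 1 (MZ) or 0.5 (DZ) across
#' twins and `r_g` across traits; shared-environment scores correlated 1
#' within pairs; dominance scores correlated 1 (MZ) / 0.25 (DZ); independent
#' unique-environment scores. A person is (latently) affected when the
#' weighted liability exceeds the sex-shifted trait threshold; affected
#' persons get a lognormal onset age, drawn independently of liability
#' magnitude. Diagnoses reach the register only when the person is alive at
#' onset and the date falls inside the patient-register window; cases alive
#' after 2005 additionally receive drug-register dispensations when the
#' trait carries an ATC code. The result is schema-identical to
#' [read_cohort()] input and runs through the whole analysis pipeline.
#'
#' @param config A [sim_config()].
#' @return A [twin_cohort()] with attribute `ground_truth`: the config, the
#'   per-trait thresholds, and the latent affected status matrix.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  np <- config$n_pairs
  n <- 2L * np
  traits <- config$traits
  Tn <- length(traits)
  reg <- config$registry
  pat_start <- as.Date(sprintf("%d-01-01", reg$patient_start))
  pat_end <- as.Date(sprintf("%d-12-31", reg$patient_end))
  drug_start <- as.Date(reg$drug_start)

  set.seed(derive_seed(config$seed, "structure"))
  zyg_pair <- ifelse(runif(np) < config$mz_fraction, "MZ", "DZ")
  sex1 <- ifelse(runif(np) < 0.5, "female", "male")
  sex2 <- ifelse(zyg_pair == "MZ", sex1,
                 ifelse(runif(np) < 0.5, "female", "male"))
  by <- config$birth_year_range
  bdate_pair <- as.Date(sprintf("%d-01-01", by[1])) +
    floor(runif(np) * (365.25 * (by[2] - by[1] + 1) - 1))

  ind <- data.frame(
    person_id = sprintf("P%07d", seq_len(n)),
    pair_id = rep(sprintf("T%06d", seq_len(np)), each = 2L),
    zygosity = rep(zyg_pair, each = 2L),
    sex = as.vector(rbind(sex1, sex2)),
    birth_date = rep(bdate_pair, each = 2L),
    stringsAsFactors = FALSE)

  # death ages from the per-decade model
  death_date <- rep(as.Date(NA), n)
  if (!is.null(config$death_model)) {
    set.seed(derive_seed(config$seed, "death"))
    q <- config$death_model
    cum_surv <- cumprod(1 - q)
    u <- runif(n)
    # decade in which death occurs: first decade where the survival path
    # drops below u
    dec <- max.col(outer(u, cum_surv, ">"), ties.method = "first")
    dec[u <= cum_surv[length(q)]] <- length(q)  # safety; last decade has q=1
    death_age <- (dec - 1L) * 10 + runif(n) * 10
    death_date <- ind$birth_date + round(death_age * 365.25)
  }

  # liability components; one base stream per trait and component
  draw_T <- function(label, rows) {
    set.seed(derive_seed(config$seed, label))
    matrix(rnorm(rows * Tn), rows, Tn)
  }
  S <- mix_corr(draw_T("additive_shared", np), config$r_g)
  U1 <- mix_corr(draw_T("additive_unique1", np), config$r_g)
  U2 <- mix_corr(draw_T("additive_unique2", np), config$r_g)
  mz <- ind$zygosity[seq(1L, n, 2L)] == "MZ"
  A1 <- ifelse(mz, 1, 0) * S + ifelse(mz, 0, 1) * (sqrt(0.5) * S + sqrt(0.5) * U1)
  A2 <- ifelse(mz, 1, 0) * S + ifelse(mz, 0, 1) * (sqrt(0.5) * S + sqrt(0.5) * U2)
  Csh <- draw_T("common_env", np)
  # the cross-trait genetic correlation applies to dominance scores too
  D_s <- mix_corr(draw_T("dominance_shared", np), config$r_g)
  D_u1 <- mix_corr(draw_T("dominance_unique1", np), config$r_g)
  D_u2 <- mix_corr(draw_T("dominance_unique2", np), config$r_g)
  D1 <- ifelse(mz, 1, 0) * D_s + ifelse(mz, 0, 1) * (0.5 * D_s + sqrt(0.75) * D_u1)
  D2 <- ifelse(mz, 1, 0) * D_s + ifelse(mz, 0, 1) * (0.5 * D_s + sqrt(0.75) * D_u2)
  E1 <- draw_T("unique_env1", np)
  E2 <- draw_T("unique_env2", np)

  interleave <- function(M1, M2) {
    M <- matrix(0, n, Tn)
    M[seq(1L, n, 2L), ] <- M1
    M[seq(2L, n, 2L), ] <- M2
    M
  }
  a <- sqrt(vapply(traits, `[[`, 0, "a2"))
  cc <- sqrt(vapply(traits, `[[`, 0, "c2"))
  dd <- sqrt(vapply(traits, `[[`, 0, "d2"))
  ee <- sqrt(vapply(traits, `[[`, 0, "e2"))
  liab <- sweep(interleave(A1, A2), 2L, a, `*`) +
    sweep(interleave(Csh, Csh), 2L, cc, `*`) +
    sweep(interleave(D1, D2), 2L, dd, `*`) +
    sweep(interleave(E1, E2), 2L, ee, `*`)
  colnames(liab) <- names(traits)

  tau <- vapply(traits, function(t) qnorm(1 - t$prevalence), 0)
  fe <- vapply(traits, `[[`, 0, "female_excess")
  female <- ind$sex == "female"
  thr <- outer(rep(1, n), tau) + outer(ifelse(female, -0.5, 0.5), fe)
  latent <- liab > thr

  # onset ages and register events
  ev <- list()
  onset_ages <- matrix(NA_real_, n, Tn, dimnames = list(NULL, names(traits)))
  for (t in seq_len(Tn)) {
    tr <- traits[[t]]
    aff <- which(latent[, t])
    if (!length(aff)) next
    set.seed(derive_seed(config$seed, paste0("onset_", tr$name)))
    lo <- plnorm(0, tr$onset_meanlog, tr$onset_sdlog)
    hi <- plnorm(100, tr$onset_meanlog, tr$onset_sdlog)
    onset_age <- qlnorm(runif(length(aff), lo, hi),
                        tr$onset_meanlog, tr$onset_sdlog)
    onset_ages[aff, t] <- onset_age
    onset_date <- ind$birth_date[aff] + round(onset_age * 365.25)
    alive_at_onset <- is.na(death_date[aff]) | death_date[aff] >= onset_date
    first_obs <- pmax(onset_date, pat_start)
    recordable <- alive_at_onset & first_obs <= pat_end &
      (is.na(death_date[aff]) | death_date[aff] >= first_obs)
    rec <- aff[recordable]
    if (!length(rec)) next
    d1 <- first_obs[recordable]
    lim <- pmin(pat_end,
                as.Date(ifelse(is.na(death_date[rec]), pat_end, death_date[rec]),
                        origin = "1970-01-01"))
    d2 <- pmin(d1 + 365L, lim)
    ev[[length(ev) + 1L]] <- data.frame(
      person_id = rep(ind$person_id[rec], 2L),
      system = "ICD10", code = tr$icd10_code,
      date = c(d1, d2), register = "patient_register",
      stringsAsFactors = FALSE)
    if (tr$use_diabetes_register)
      ev[[length(ev) + 1L]] <- data.frame(
        person_id = ind$person_id[rec], system = "ICD10",
        code = tr$icd10_code, date = d1, register = "diabetes_register",
        stringsAsFactors = FALSE)
    if (!is.null(tr$atc_code)) {
      alive_2006 <- is.na(death_date[rec]) | death_date[rec] > as.Date("2005-12-31")
      ra <- rec[alive_2006]
      if (length(ra)) {
        da <- pmax(d1[alive_2006], drug_start)
        da <- pmin(da, pmin(pat_end,
                            as.Date(ifelse(is.na(death_date[ra]), pat_end,
                                           death_date[ra]),
                                    origin = "1970-01-01")))
        ev[[length(ev) + 1L]] <- data.frame(
          person_id = rep(ind$person_id[ra], 2L),
          system = "ATC", code = tr$atc_code,
          date = c(da, da), register = "drug_register",
          stringsAsFactors = FALSE)
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else NULL

  ind$death_date <- as.Date(ifelse(!is.na(death_date) & death_date <= pat_end,
                                   death_date, NA), origin = "1970-01-01")
  cohort <- twin_cohort(ind, events)
  attr(cohort, "ground_truth") <- list(
    config = config, thresholds = tau, latent = latent, liability = liab,
    onset_age = onset_ages)
  cohort
}

#' Disease definitions matching a set of simulated traits
#'
#' @param traits List of [trait_spec()]s (or a [sim_config()]).
#' @return Named list of [disease_definition()]s whose rules ascertain
#'   exactly the events [simulate_cohort()] emits.
#' @export
definitions_for_traits <- function(traits) {
  if (inherits(traits, "sim_config")) traits <- traits$traits
  defs <- lapply(traits, function(tr)
    disease_definition(
      name = tr$name,
      inclusion = list(ICD10 = tr$icd10_code),
      required_atc = if (is.null(tr$atc_code)) NULL else
        list(atc_prefix = tr$atc_code, min_dispensations = 2L,
             applies_if_alive_after = "2005-12-31"),
      use_diabetes_register = tr$use_diabetes_register))
  names(defs) <- vapply(traits, `[[`, "", "name")
  defs
}

#' Default traits mirroring a seven-disease autoimmune twin cohort
#'
#' Seven organ-specific autoimmune traits at the scale of the bundled
#' reference cohort: lifetime prevalences and female excesses derived from
#' the bundled sex-stratified case counts, AE heritabilities at the bundled
#' best-fit values, and typical onset-age medians.
#'
#' @return Named list of [trait_spec()]s.
#' @export
default_traits <- function() {
  prev <- aid_prevalence_counts()
  herit <- c(hashimoto = 0.64, atrophic_gastritis = 0.38, celiac = 0.91,
             graves = 0.60, type1_diabetes = 0.81, vitiligo = 0.65,
             addison = 0.97)
  onset_median <- c(hashimoto = 50, atrophic_gastritis = 62, celiac = 35,
                    graves = 45, type1_diabetes = 18, vitiligo = 28,
                    addison = 38)
  codes <- c(hashimoto = "E063", atrophic_gastritis = "K294", celiac = "K900",
             graves = "E050", type1_diabetes = "E10", vitiligo = "L80",
             addison = "E271")
  atc <- c(hashimoto = "H03AA", atrophic_gastritis = "B03BA")
  out <- lapply(names(herit), function(nm) {
    pr <- prev[prev$disease == nm, ]
    p_f <- pr$n_cases[pr$stratum == "female"] / pr$n_denominator[pr$stratum == "female"]
    p_m <- pr$n_cases[pr$stratum == "male"] / pr$n_denominator[pr$stratum == "male"]
    p_all <- pr$n_cases[pr$stratum == "all"] / pr$n_denominator[pr$stratum == "all"]
    trait_spec(name = nm, a2 = herit[[nm]], prevalence = p_all,
               female_excess = qnorm(1 - p_m) - qnorm(1 - p_f),
               onset_meanlog = log(onset_median[[nm]]), onset_sdlog = 0.45,
               icd10_code = codes[[nm]],
               atc_code = if (nm %in% names(atc)) atc[[nm]] else NULL,
               use_diabetes_register = nm == "type1_diabetes")
  })
  names(out) <- names(herit)
  out
}

#' Write deterministic miniature fixtures
#'
#' Writes, under `dir`: a miniature simulated cohort (`individuals.csv`,
#' `events.csv`; at most `n_pairs` pairs), its ground truth
#' (`ground_truth.json`), and the bundled reference pair-classification
#' tables (`pair_tables.csv`). Identical seeds give byte-identical files.
#'
#' @param seed Root seed.
#' @param dir Output directory (created if needed).
#' @param n_pairs Pairs in the miniature cohort (default 200).
#' @return Invisibly, the paths written.
#' @export
fixture_suite <- function(seed, dir, n_pairs = 200L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traits <- default_traits()[c("hashimoto", "celiac")]
  cfg <- sim_config(n_pairs = n_pairs, traits = traits, seed = seed)
  cohort <- simulate_cohort(cfg)
  p_ind <- file.path(dir, "individuals.csv")
  p_ev <- file.path(dir, "events.csv")
  write_cohort(cohort, p_ind, p_ev)
  gt <- attr(cohort, "ground_truth")
  p_gt <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(seed = seed, n_pairs = n_pairs,
         traits = lapply(cfg$traits, function(t)
           t[c("name", "a2", "c2", "d2", "e2", "prevalence", "female_excess")]),
         thresholds = as.list(gt$thresholds)),
    p_gt, auto_unbox = TRUE, digits = 10)
  p_pt <- file.path(dir, "pair_tables.csv")
  file.copy(system.file("extdata", "pair_tables.csv", package = "twinherit",
                        mustWork = TRUE), p_pt, overwrite = TRUE)
  invisible(c(p_ind, p_ev, p_gt, p_pt))
}
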