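coagg_toy <- function() {
  # pair q001: co-twin (p002) diagnosed 1994 (age 40); p001 diagnosed 1999
  # pair q002: nobody diagnosed
  coh <- toy_cohort(2, birth = "1954-01-01")
  ph <- toy_phenotype(coh, c(TRUE, TRUE, FALSE, FALSE),
                      onset = c("1999-01-01", "1994-01-01", NA, NA),
                      disease = "idx")
  list(coh = coh, ph = list(idx = ph))
}

test_that("episodes split at the co-twin diagnosis and carry the event", {
  tc <- coagg_toy()
  ep <- build_episodes(tc$coh, tc$ph, "idx", "same_disease")
  e1 <- ep[ep$person_id == "p001", ]
  expect_equal(nrow(e1), 2L)
  expect_equal(e1$entry_age[1], 10, tolerance = 0.01)
  expect_equal(e1$exit_age[1], 40, tolerance = 0.01)
  expect_false(e1$exposed[1]); expect_false(e1$event[1])
  expect_equal(e1$entry_age[2], 40, tolerance = 0.01)
  expect_equal(e1$exit_age[2], 45, tolerance = 0.01)
  expect_true(e1$exposed[2]); expect_true(e1$event[2])
  # undiagnosed co-twin: one unexposed censored episode to end of coverage
  e3 <- ep[ep$person_id == "p003", ]
  expect_equal(nrow(e3), 1L)
  expect_false(e3$exposed); expect_false(e3$event)
  expect_equal(e3$exit_age, 62, tolerance = 0.01)
})

test_that("same-day mutual diagnosis keeps the event in the unexposed state", {
  coh <- toy_cohort(1, birth = "1954-01-01")
  ph <- toy_phenotype(coh, c(TRUE, TRUE),
                      onset = c("1994-05-01", "1994-05-01"), disease = "idx")
  ep <- build_episodes(coh, list(idx = ph), "idx", "same_disease")
  e1 <- ep[ep$person_id == "p001", ]
  expect_equal(nrow(e1), 1L)      # no zero-length exposed episode
  expect_false(e1$exposed)
  expect_true(e1$event)
})

test_that("person-time is conserved by the episode split", {
  cfg <- sim_config(1500, default_traits()[c("hashimoto", "celiac")], seed = 61)
  coh <- simulate_cohort(cfg)
  phs <- ascertain_all(coh, definitions_for_traits(cfg))
  ep <- build_episodes(coh, phs, "hashimoto", "any_disease")
  by_person <- tapply(ep$exit_age - ep$entry_age, ep$person_id, sum)
  # reconstruct each person's total follow-up independently
  ind <- coh$individuals
  anyph <- aggregate_any(phs)
  entry <- pmax(ind$birth_date, as.Date("1964-01-01"))
  exitd <- rep(as.Date("2015-12-31"), nrow(ind))
  hd <- !is.na(ind$death_date)
  exitd[hd] <- pmin(exitd[hd], ind$death_date[hd])
  ho <- anyph$affected
  exitd[ho] <- pmin(exitd[ho], anyph$onset_date[ho])
  tot <- as.numeric(exitd - entry) / 365.25
  names(tot) <- ind$person_id
  tot <- tot[tot > 0]
  expect_equal(sort(names(by_person)), sort(names(tot)))
  expect_equal(as.numeric(by_person[names(tot)]), unname(tot), tolerance = 1e-8)
})

test_that("partial-likelihood estimate matches a brute-force grid", {
  set.seed(62)
  n <- 40L
  x <- rep(0:1, each = n / 2)
  t_ev <- rexp(n, rate = 0.1 * exp(0.8 * x))
  ep <- data.frame(person_id = sprintf("i%02d", 1:n),
                   pair_id = sprintf("i%02d", 1:n),  # no clustering
                   entry_age = 0, exit_age = t_ev,
                   event = t_ev < quantile(t_ev, 0.8),  # some censoring
                   exposed = as.logical(x),
                   sex = "female", birth_year = 1950L)
  fit <- fit_cox(ep, adjust = character(0))
  ep$x <- x
  beta_grid <- oracle_cox_grid(ep)
  expect_lt(abs(coef(fit)[["exposed"]] - beta_grid), 1e-3)
})

test_that("exposure-independent outcomes give a hazard ratio near one", {
  set.seed(63)
  # births inside the registry window: no left truncation, so risk sets are
  # free of never-diagnosable (pre-entry latent onset) individuals whose
  # presence is shared within pairs and would distort even a null cohort
  cfg <- sim_config(10000, trait_spec("t1", a2 = 0, c2 = 0, prevalence = 0.05,
                                      onset_meanlog = log(30),
                                      onset_sdlog = 0.3),
                    birth_year_range = c(1964, 1990),
                    death_model = NULL, seed = 63)
  coh <- simulate_cohort(cfg)
  phs <- ascertain_all(coh, definitions_for_traits(cfg))
  ep <- build_episodes(coh, phs, "t1", "same_disease")
  fit <- suppressWarnings(fit_cox(ep, adjust = c("sex", "birth_year")))
  tt <- fit$coefficients[fit$coefficients$term == "exposed", ]
  expect_lt(abs(tt$log_hr), 2.5 * tt$robust_se)
})

test_that("cross-twin dependence yields a clearly elevated same-disease HR", {
  cfg <- sim_config(15000, trait_spec("t1", a2 = 0.7, prevalence = 0.02,
                                      onset_meanlog = log(45)),
                    mz_fraction = 1, death_model = NULL, seed = 64)
  coh <- simulate_cohort(cfg)
  phs <- ascertain_all(coh, definitions_for_traits(cfg))
  ep <- build_episodes(coh, phs, "t1", "same_disease")
  fit <- fit_cox(ep, adjust = "sex")
  tt <- fit$coefficients[fit$coefficients$term == "exposed", ]
  expect_gt(tt$hr, 2)
  expect_gt(tt$ci_low, 1)
})

test_that("the robust SE exceeds the model SE under within-pair correlation", {
  cfg <- sim_config(15000, trait_spec("t1", a2 = 0.5, c2 = 0.3,
                                      prevalence = 0.05),
                    death_model = NULL, seed = 65)
  coh <- simulate_cohort(cfg)
  phs <- ascertain_all(coh, definitions_for_traits(cfg))
  ep <- build_episodes(coh, phs, "t1", "any_disease")
  fit <- fit_cox(ep, adjust = "sex")
  tt <- fit$coefficients[fit$coefficients$term == "exposed", ]
  expect_gte(tt$robust_se, tt$se * 0.98)
})

test_that("the partial-likelihood score vanishes at the reported optimum", {
  tcfg <- sim_config(3000, trait_spec("t1", a2 = 0.6, prevalence = 0.05),
                     death_model = NULL, seed = 66)
  coh <- simulate_cohort(tcfg)
  phs <- ascertain_all(coh, definitions_for_traits(tcfg))
  ep <- build_episodes(coh, phs, "t1", "same_disease")
  fit <- fit_cox(ep, adjust = "sex")
  b <- coef(fit)
  d <- ep; d$exposed <- as.integer(d$exposed)
  d$female <- as.integer(d$sex == "female")
  pll <- function(bb) survival::coxph(
    survival::Surv(entry_age, exit_age, event) ~ exposed + female,
    data = d, ties = "efron", init = bb,
    control = survival::coxph.control(iter.max = 0))$loglik[2]
  h <- 1e-5
  for (j in seq_along(b)) {
    e <- rep(0, length(b)); e[j] <- h
    expect_lt(abs((pll(b + e) - pll(b - e)) / (2 * h)), 1e-4)
  }
})

test_that("no exposed person-time flags the exposure effect undefined", {
  # the only case's co-twin dies before the diagnosis: an event exists but
  # nobody ever accrues exposed person-time
  coh <- toy_cohort(2, birth = "1954-01-01",
                    deaths = c(NA, "1998-01-01", NA, NA))
  ph <- toy_phenotype(coh, c(TRUE, FALSE, FALSE, FALSE),
                      onset = c("1999-01-01", NA, NA, NA), disease = "idx")
  ep <- build_episodes(coh, list(idx = ph), "idx", "same_disease")
  fit <- fit_cox(ep, adjust = character(0))
  expect_false(fit$defined)
  expect_error(fit_cox(ep[!ep$event, , drop = FALSE]), "event")
})

test_that("aggregation report covers strata and single-disease degeneracies", {
  cfg <- sim_config(4000, default_traits()[c("hashimoto", "celiac")], seed = 67)
  coh <- simulate_cohort(cfg)
  phs <- ascertain_all(coh, definitions_for_traits(cfg))
  rep_ <- aggregation_report(coh, phs, adjust = "sex")
  expect_equal(nrow(rep_), 2 * 3 * 2)
  expect_true(all(rep_$hr[rep_$estimable] > 0))
  # single-disease cohort: different-disease outcomes cannot exist,
  # any-disease coincides with same-disease
  one <- phs["hashimoto"]
  ep_diff <- build_episodes(coh, one, "hashimoto", "different_disease")
  expect_equal(nrow(ep_diff), 0L)
  ep_same <- build_episodes(coh, one, "hashimoto", "same_disease")
  ep_any <- build_episodes(coh, one, "hashimoto", "any_disease")
  expect_equal(ep_any$event, ep_same$event)
  expect_equal(ep_any$exit_age, ep_same$exit_age)
})
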