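test_that("observation windows follow registry arithmetic", {
  coh <- toy_cohort(3, birth = c("1950-01-01", "1950-01-01",
                                 "1980-01-01", "1980-01-01",
                                 "1940-01-01", "1940-01-01"),
                    deaths = c(NA, NA, NA, NA, "1970-01-01", NA))
  ph <- toy_phenotype(coh, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
                      onset = c("1990-01-01", NA, NA, NA, NA, NA))
  w <- build_windows(coh, ph, registry_start_year = 1964, end_year = 2015)
  g <- function(id) w[w$person_id == id, ]
  # born 1950, onset 1990: entry at 14, exit at 40, affected
  expect_equal(g("p001")$entry_age, 14, tolerance = 0.01)
  expect_equal(g("p001")$exit_age, 40, tolerance = 0.01)
  expect_true(g("p001")$affected)
  # born 1980, no onset: entry 0, exit 35 censored
  expect_equal(g("p003")$entry_age, 0, tolerance = 0.01)
  expect_equal(g("p003")$exit_age, 36, tolerance = 0.01)
  expect_false(g("p003")$affected)
  # born 1940, died 1970 without onset: exit 30 censored
  expect_equal(g("p005")$exit_age, 30, tolerance = 0.01)
  expect_false(g("p005")$affected)
})

test_that("onset before registry entry flags a prevalent case", {
  coh <- toy_cohort(1, birth = "1940-01-01")
  ph <- toy_phenotype(coh, c(TRUE, FALSE), onset = c("1950-01-01", NA))
  w <- build_windows(coh, ph)
  expect_true(w$prevalent_at_entry[w$person_id == "p001"])
  expect_true(w$affected[w$person_id == "p001"])
})

test_that("censoring survival matches hand-computed product-limit steps", {
  w <- data.frame(person_id = c("a", "b", "c", "d"),
                  entry_age = c(0, 10, 0, 20),
                  exit_age = c(50, 60, 70, 80),
                  affected = c(FALSE, TRUE, FALSE, FALSE),
                  prevalent_at_entry = FALSE)
  cm <- estimate_censoring(w)
  # events (non-disease exits) at 50 (4 at risk), 70 (2 at risk), 80 (1)
  expect_equal(cm$S_c(c(49, 50, 51, 70, 71, 80, 81)),
               c(1, 1, 0.75, 0.75, 0.375, 0.375, 0))
})

test_that("no censoring before the maximum age gives a flat survival of 1", {
  w <- data.frame(person_id = c("a", "b"), entry_age = 0,
                  exit_age = c(40, 55), affected = TRUE,
                  prevalent_at_entry = FALSE)
  cm <- estimate_censoring(w)
  expect_equal(cm$S_c(c(0, 30, 54)), c(1, 1, 1))
})

test_that("estimated censoring survival tracks the simulated truth", {
  set.seed(51)
  n <- 10000L
  onset <- rlnorm(n, log(45), 0.45)
  C <- runif(n, 0, 150)
  affected <- onset <= C
  exit <- ifelse(affected, onset, C)
  w <- data.frame(person_id = sprintf("s%05d", 1:n), entry_age = 0,
                  exit_age = exit, affected = affected,
                  prevalent_at_entry = FALSE)
  cm <- estimate_censoring(w)
  # deciles of the observed exit ages (risk sets are thin beyond them)
  ages <- quantile(exit, seq(0.1, 0.9, by = 0.1), names = FALSE)
  expect_true(all(abs(cm$S_c(ages) - (1 - ages / 150)) < 0.02))
})

test_that("weights are at least 1 and unit weights reproduce the unweighted fit", {
  set.seed(52)
  cfg <- sim_config(2000, trait_spec("t1", a2 = 0.6, prevalence = 0.05),
                    death_model = NULL, seed = 52)
  coh <- simulate_cohort(cfg)
  w <- censored_windows(coh)
  cm <- estimate_censoring(w)
  wt <- twinherit:::ipw_weights(w, cm)
  expect_true(all(wt >= 1))
  # a censoring model that never censors leaves the fit exactly unweighted
  flat <- structure(list(S_c = function(a) rep(1, length(a)), fit = NULL),
                    class = "censoring_model")
  f0 <- fit_liability_ipw(coh, w, NULL, "AE")
  f1 <- fit_liability_ipw(coh, w, flat, "AE")
  expect_equal(f1$components, f0$components, tolerance = 1e-8)
  expect_equal(f1$loglik, f0$loglik, tolerance = 1e-8)
})

test_that("with full observation the pairwise fit collapses to the table fit", {
  set.seed(53)
  cfg <- sim_config(3000, trait_spec("t1", a2 = 0.7, prevalence = 0.05),
                    death_model = NULL, seed = 53)
  coh <- simulate_cohort(cfg)
  w <- full_windows(coh)
  lf <- fit_liability_ipw(coh, w, NULL, "AE")
  gt <- attr(coh, "ground_truth")
  ph <- toy_phenotype(coh, gt$latent[, 1])
  bf <- fit_biometric(build_pair_table(coh, ph, "MZ"),
                      build_pair_table(coh, ph, "DZ"), "AE", ci = FALSE)
  expect_equal(lf$components[["a2"]], bf$components[["a2"]], tolerance = 1e-4)
  expect_equal(lf$tau, bf$tau, tolerance = 1e-4)
})

test_that("censoring weights recover heritability under 30% case censoring", {
  set.seed(54)
  truth <- 0.65
  err <- replicate(3, {
    cfg <- sim_config(20000, trait_spec("t1", a2 = truth, prevalence = 0.02),
                      mz_fraction = 0.5, death_model = NULL,
                      seed = sample.int(1e6, 1))
    coh <- simulate_cohort(cfg)
    w <- censored_windows(coh)
    cm <- estimate_censoring(w)
    fit_liability_ipw(coh, w, cm, "AE")$components[["a2"]] - truth
  })
  expect_lt(abs(mean(err)), 0.07)
})

test_that("the adjustment-by-censoring grid produces four coherent fits", {
  cfg <- sim_config(1500, trait_spec("t1", a2 = 0.6, prevalence = 0.05,
                                     onset_meanlog = log(40)),
                    birth_year_range = c(1950, 1980), seed = 57)
  coh <- simulate_cohort(cfg)
  ph <- ascertain(coh, definitions_for_traits(cfg)$t1)
  # childhood deaths before registry start legitimately drop windows
  grid <- suppressWarnings(liability_grid(coh, ph, "AE"))
  expect_equal(nrow(grid), 4L)
  expect_setequal(paste(grid$adjusted, grid$censoring_weighted),
                  c("FALSE FALSE", "TRUE FALSE", "FALSE TRUE", "TRUE TRUE"))
  expect_true(all(grid$a2 >= 0 & grid$a2 <= 1))
  expect_true(all(abs(grid$a2 + grid$c2 + grid$d2 + grid$e2 - 1) < 1e-8))
})

test_that("a simulated female threshold shift is recovered by the sex adjustment", {
  cfg <- sim_config(25000, trait_spec("t1", a2 = 0.6, prevalence = 0.03,
                                      female_excess = 0.3),
                    death_model = NULL, seed = 55)
  coh <- simulate_cohort(cfg)
  w <- full_windows(coh)
  fit <- fit_liability_ipw(coh, w, NULL, "AE",
                           covariates = covariate_spec(sex = TRUE,
                                                       birth_year_bin_width = NULL))
  # the estimator should nail the realised per-sex threshold difference ...
  gt <- attr(coh, "ground_truth")
  f <- coh$individuals$sex == "female"
  realised <- qnorm(1 - mean(gt$latent[f, 1])) - qnorm(1 - mean(gt$latent[!f, 1]))
  expect_equal(unname(fit$beta[["female"]]), realised, tolerance = 0.02)
  # ... and the population value up to sampling error (clustered binomial
  # SE of the threshold contrast is about 0.027 at this size)
  expect_lt(abs(unname(fit$beta[["female"]]) - (-0.3)), 0.08)
  # and with no sex effect the coefficient stays near zero
  cfg0 <- sim_config(25000, trait_spec("t1", a2 = 0.6, prevalence = 0.03),
                     death_model = NULL, seed = 56)
  coh0 <- simulate_cohort(cfg0)
  fit0 <- fit_liability_ipw(coh0, full_windows(coh0), NULL, "AE",
                            covariates = covariate_spec(sex = TRUE,
                                                        birth_year_bin_width = NULL))
  expect_lt(abs(fit0$beta[["female"]]), 0.05)
})
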