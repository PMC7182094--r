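test_that("additive scores are identical in MZ pairs and half-shared in DZ pairs", {
  cfg <- sim_config(50000, trait_spec("t1", a2 = 1, c2 = 0, prevalence = 0.05,
                                      # e2 = 0: liability is the additive score
                                      onset_meanlog = log(40)),
                    death_model = NULL, seed = 71)
  coh <- simulate_cohort(cfg)
  gt <- attr(coh, "ground_truth")
  liab <- gt$liability[, 1]
  t1 <- liab[seq(1, length(liab), 2)]
  t2 <- liab[seq(2, length(liab), 2)]
  mz <- coh$individuals$zygosity[seq(1, length(liab), 2)] == "MZ"
  expect_equal(t1[mz], t2[mz], tolerance = 1e-12)
  expect_equal(cor(t1[!mz], t2[!mz]), 0.5, tolerance = 0.02)
})

test_that("observed latent prevalence matches the target", {
  cfg <- sim_config(50000, trait_spec("t1", a2 = 0.5, prevalence = 0.02),
                    seed = 72)
  coh <- simulate_cohort(cfg)
  gt <- attr(coh, "ground_truth")
  expect_equal(mean(gt$latent[, 1]), 0.02, tolerance = 0.1)
  expect_lt(abs(mean(gt$latent[, 1]) - 0.02), 0.002)
})

test_that("zygosity fractions and sex sharing follow the configuration", {
  cfg <- sim_config(20000, trait_spec("t1", a2 = 0.5, prevalence = 0.05),
                    seed = 73)
  coh <- simulate_cohort(cfg)
  ind <- coh$individuals
  expect_equal(mean(ind$zygosity == "MZ"), 1 / 3, tolerance = 0.05)
  s1 <- ind$sex[seq(1, nrow(ind), 2)]; s2 <- ind$sex[seq(2, nrow(ind), 2)]
  zy <- ind$zygosity[seq(1, nrow(ind), 2)]
  expect_true(all(s1[zy == "MZ"] == s2[zy == "MZ"]))
  expect_equal(mean(s1[zy == "DZ"] == s2[zy == "DZ"]), 0.5, tolerance = 0.05)
  yrs <- as.integer(format(ind$birth_date, "%Y"))
  expect_gte(min(yrs), 1886); expect_lte(max(yrs), 2006)
})

test_that("end-to-end tetrachorics recover the generating correlations", {
  # averaged over replicates: the DZ tetrachoric has a sampling SE close to
  # 0.05 at this prevalence and size
  est <- vapply(74:76, function(s) {
    cfg <- sim_config(40000, trait_spec("t1", a2 = 0.64, prevalence = 0.015),
                      mz_fraction = 0.5, death_model = NULL, seed = s)
    coh <- simulate_cohort(cfg)
    gt <- attr(coh, "ground_truth")
    ph <- toy_phenotype(coh, gt$latent[, 1])
    c(fit_tetrachoric(build_pair_table(coh, ph, "MZ"), ci = FALSE)$rho,
      fit_tetrachoric(build_pair_table(coh, ph, "DZ"), ci = FALSE)$rho)
  }, c(0, 0))
  expect_lt(abs(mean(est[1, ]) - 0.64), 0.05)
  expect_lt(abs(mean(est[2, ]) - 0.32), 0.05)
})

test_that("cross-twin cross-trait correlation equals r_g scaled by the paths", {
  r_g <- matrix(c(1, 0.6, 0.6, 1), 2)
  cfg <- sim_config(50000,
                    list(trait_spec("x", a2 = 0.64, prevalence = 0.02),
                         trait_spec("y", a2 = 0.36, prevalence = 0.02)),
                    r_g = r_g, mz_fraction = 1, death_model = NULL, seed = 75)
  coh <- simulate_cohort(cfg)
  gt <- attr(coh, "ground_truth")
  lx <- gt$liability[seq(1, nrow(gt$liability), 2), "x"]
  ly <- gt$liability[seq(2, nrow(gt$liability), 2), "y"]
  # MZ cross-twin cross-trait: r_g * a_x * a_y = 0.6 * 0.8 * 0.6
  expect_equal(cor(lx, ly), 0.6 * sqrt(0.64) * sqrt(0.36), tolerance = 0.03)
})

test_that("infeasible cross-trait correlation matrices are rejected", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(sim_config(10, list(trait_spec("a", 0.5, prevalence = 0.1),
                                   trait_spec("b", 0.5, prevalence = 0.1),
                                   trait_spec("c", 0.5, prevalence = 0.1)),
                          r_g = bad), "positive semidefinite")
  expect_error(trait_spec("bad", a2 = 0.8, c2 = 0.5, prevalence = 0.1))
})

test_that("without death or window truncation every latent case is ascertained", {
  cfg <- sim_config(3000, trait_spec("t1", a2 = 0.6, prevalence = 0.05,
                                     onset_meanlog = log(30),
                                     onset_sdlog = 0.3),
                    birth_year_range = c(1964, 1975),
                    registry = list(patient_start = 1964, patient_end = 2120,
                                    drug_start = "2005-07-01"),
                    death_model = NULL, seed = 76)
  coh <- simulate_cohort(cfg)
  gt <- attr(coh, "ground_truth")
  ph <- ascertain(coh, definitions_for_traits(cfg)$t1)
  expect_equal(ph$affected, unname(gt$latent[, 1]))
})

test_that("the generator is deterministic and fixtures are byte-identical", {
  cfg <- function() sim_config(300, default_traits()[c("hashimoto", "celiac")],
                               seed = 77)
  c1 <- simulate_cohort(cfg()); c2 <- simulate_cohort(cfg())
  expect_identical(c1$individuals, c2$individuals)
  expect_identical(c1$events, c2$events)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  fixture_suite(7, d1, n_pairs = 50)
  fixture_suite(7, d2, n_pairs = 50)
  for (f in c("individuals.csv", "events.csv", "ground_truth.json",
              "pair_tables.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("fixture outputs parse and validate cleanly", {
  d <- file.path(tempdir(), "fx3")
  fixture_suite(3, d, n_pairs = 60)
  expect_warning(coh <- read_cohort(file.path(d, "individuals.csv"),
                                    file.path(d, "events.csv")), NA)
  expect_s3_class(coh, "twin_cohort")
  pt <- read.csv(file.path(d, "pair_tables.csv"))
  addison_mz <- pt[pt$disease == "addison" & pt$zygosity == "MZ", ]
  expect_equal(as.numeric(addison_mz[, 3:5]), c(17986, 4, 5))
})

test_that("adding a trait leaves earlier traits' draws untouched", {
  t1 <- trait_spec("alpha", a2 = 0.6, prevalence = 0.03)
  t2 <- trait_spec("beta", a2 = 0.4, prevalence = 0.05)
  c1 <- simulate_cohort(sim_config(500, list(t1), seed = 78))
  c2 <- simulate_cohort(sim_config(500, list(t1, t2), seed = 78))
  g1 <- attr(c1, "ground_truth"); g2 <- attr(c2, "ground_truth")
  expect_identical(g1$liability[, "alpha"], g2$liability[, "alpha"])
})
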