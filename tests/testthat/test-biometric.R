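test_that("implied correlations follow the classical twin constraints", {
  expect_equal(implied_correlations(a2 = 0.8),
               c(rho_mz = 0.8, rho_dz = 0.4))
  expect_equal(implied_correlations(),
               c(rho_mz = 0, rho_dz = 0))
  expect_equal(implied_correlations(a2 = 0.5, d2 = 0.3),
               c(rho_mz = 0.8, rho_dz = 0.325))
  expect_equal(implied_correlations(a2 = 0.3, c2 = 0.2),
               c(rho_mz = 0.5, rho_dz = 0.35))
})

test_that("AE fit recovers the generating a2 from large simulated tables", {
  set.seed(41)
  truth <- 0.7; prev <- 0.02
  tau <- qnorm(1 - prev)
  draw <- function(N, rho) {
    p <- twinherit:::pair_cell_probs(tau, rho)
    cnt <- as.vector(rmultinom(1, N, p))
    pair_table(cnt[1], cnt[2], cnt[3])
  }
  fit <- fit_biometric(draw(20000, truth), draw(20000, truth / 2), "AE",
                       ci = FALSE)
  expect_equal(unname(fit$components["a2"]), truth, tolerance = 0.05)
  expect_equal(pnorm(fit$tau, lower.tail = FALSE), prev, tolerance = 0.005)
})

test_that("ACE fit finds c2 near zero when rho_mz is twice rho_dz", {
  set.seed(42)
  tau <- qnorm(1 - 0.05)
  p_mz <- twinherit:::pair_cell_probs(tau, 0.6)
  p_dz <- twinherit:::pair_cell_probs(tau, 0.3)
  mz <- pair_table(round(3e5 * p_mz[1]), round(3e5 * p_mz[2]), round(3e5 * p_mz[3]))
  dz <- pair_table(round(3e5 * p_dz[1]), round(3e5 * p_dz[2]), round(3e5 * p_dz[3]))
  fit <- fit_biometric(mz, dz, "ACE", ci = FALSE)
  expect_lt(unname(fit$components["c2"]), 0.02)
  expect_equal(unname(fit$components["a2"]), 0.6, tolerance = 0.03)
})

test_that("joint MLE matches the exhaustive AE grid oracle on small tables", {
  skip_if_not_installed("mvtnorm")
  fit <- fit_biometric(c(96, 8, 4), c(194, 10, 1), "AE", ci = FALSE)
  g <- oracle_grid_ae(c(96, 8, 4), c(194, 10, 1))
  expect_equal(fit$tau, g[["tau"]], tolerance = 2e-3)
  expect_equal(unname(fit$components["a2"]), g[["a2"]], tolerance = 2e-3)
  expect_gte(fit$loglik, g[["ll"]] - 1e-6)
})

test_that("nested models cannot beat richer ones in likelihood", {
  mz <- pair_table(5000, 80, 20); dz <- pair_table(5000, 95, 6)
  fit_e <- fit_biometric(mz, dz, "E", ci = FALSE)
  fit_ae <- fit_biometric(mz, dz, "AE", ci = FALSE)
  fit_ace <- fit_biometric(mz, dz, "ACE", ci = FALSE)
  expect_lte(fit_e$loglik, fit_ae$loglik + 1e-6)
  expect_lte(fit_ae$loglik, fit_ace$loglik + 1e-6)
  # AIC accounting: threshold + free components
  expect_equal(fit_ae$aic, 2 * 2 - 2 * fit_ae$loglik)
  expect_equal(fit_ace$aic, 2 * 3 - 2 * fit_ace$loglik)
})

test_that("implied rho_mz never falls below rho_dz across fitted models", {
  mz <- pair_table(2000, 50, 12); dz <- pair_table(2000, 60, 3)
  for (m in c("ACE", "ADE", "AE", "CE", "E")) {
    fit <- fit_biometric(mz, dz, m, ci = FALSE)
    r <- implied_correlations(fit$components["a2"], fit$components["c2"],
                              fit$components["d2"])
    expect_gte(r[["rho_mz"]], r[["rho_dz"]] - 1e-12)
  }
})

test_that("model selection minimises AIC with a parsimony tie-break", {
  mz <- pair_table(3000, 60, 15); dz <- pair_table(3000, 70, 4)
  fits <- lapply(c("ACE", "ADE", "AE", "E"), function(m)
    fit_biometric(mz, dz, m, ci = FALSE))
  best <- select_model(fits)
  aics <- vapply(fits, `[[`, 0, "aic")
  expect_equal(best$aic, min(aics))
  # forced tie: feed two copies where the simpler must win
  f_ae <- fits[[3]]; f_ace <- fits[[1]]
  f_ace$aic <- f_ae$aic
  expect_equal(select_model(list(f_ace, f_ae))$model, "AE")
})

test_that("broad-sense heritability is reported when ADE rivals AE", {
  mz <- pair_table(3000, 40, 20); dz <- pair_table(3000, 80, 2)
  fits <- list(fit_biometric(mz, dz, "AE", ci = FALSE),
               fit_biometric(mz, dz, "ADE", ci = FALSE))
  if (abs(fits[[1]]$aic - fits[[2]]$aic) <= 2) {
    best <- select_model(fits)
    expect_false(is.null(best$broad_sense))
    ade <- fits[[2]]
    expect_equal(best$broad_sense,
                 unname(ade$components["a2"] + ade$components["d2"]))
  } else skip("tables did not produce rival fits")
})

test_that("ACE model selection recovers a true shared-environment component", {
  # simulated ACE truth with substantial c2: ACE should usually win on AIC
  set.seed(43)
  tau <- qnorm(1 - 0.05)
  r <- implied_correlations(a2 = 0.4, c2 = 0.3)
  wins <- 0L
  n_rep <- 20L
  for (i in seq_len(n_rep)) {
    draw <- function(N, rho) {
      p <- twinherit:::pair_cell_probs(tau, rho)
      cnt <- as.vector(rmultinom(1, N, p))
      pair_table(cnt[1], cnt[2], cnt[3])
    }
    mz <- draw(20000, r[["rho_mz"]]); dz <- draw(20000, r[["rho_dz"]])
    fits <- list(fit_biometric(mz, dz, "ACE", ci = FALSE),
                 fit_biometric(mz, dz, "AE", ci = FALSE))
    if (select_model(fits)$model == "ACE") wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.8)
})

test_that("the file-based heritability report mirrors direct fits", {
  rep_ <- biometric_report(system.file("extdata", "pair_tables.csv",
                                       package = "twinherit"))
  expect_true(all(c("hashimoto", "addison") %in% rep_$disease))
  direct <- fit_biometric(aid_pair_table("celiac", "MZ"),
                          aid_pair_table("celiac", "DZ"), "AE", ci = FALSE)
  expect_equal(rep_$A[rep_$disease == "celiac"],
               direct$components[["a2"]], tolerance = 1e-6)
  expect_true(all(rep_$A >= 0 & rep_$A <= 1))
  expect_equal(rep_$A + rep_$E, rep(1, nrow(rep_)), tolerance = 1e-8)
})

test_that("degenerate tables are flagged rather than fitted", {
  fit <- fit_biometric(pair_table(100, 0, 0), pair_table(100, 0, 0), "AE")
  expect_true(fit$degenerate)
  expect_error(fit_biometric(pair_table(0, 0, 0), pair_table(10, 1, 0), "AE"),
               "nonempty")
  expect_error(fit_biometric(pair_table(9, 1, 0), pair_table(9, 1, 0), "XYZ"))
})
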