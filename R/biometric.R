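#' Twin correlations implied by a variance decomposition
#'
#' Under the classical twin model the liability correlations are
#' `rho_MZ = a2 + c2 + d2` and `rho_DZ = a2/2 + c2 + d2/4`: monozygotic
#' twins share all additive and dominance genetic variance and the common
#' environment; dizygotic twins share half the additive and a quarter of the
#' dominance variance.
#'
#' @param a2,c2,d2 Variance proportions (additive genetic, shared
#'   environment, dominance). The non-shared environment `e2` is the
#'   remainder and does not enter the correlations.
#' @return Named vector `c(rho_mz, rho_dz)`.
#' @examples
#' implied_correlations(a2 = 0.8)                 # AE: (0.8, 0.4)
#' implied_correlations(a2 = 0.5, d2 = 0.3)       # ADE: (0.8, 0.325)
#' @export
implied_correlations <- function(a2 = 0, c2 = 0, d2 = 0) {
  a2 <- unname(a2); c2 <- unname(c2); d2 <- unname(d2)
  c(rho_mz = a2 + c2 + d2, rho_dz = 0.5 * a2 + c2 + 0.25 * d2)
}

biometric_models <- c("ACE", "ADE", "AE", "CE", "E")

# component vector (a2, c2, d2, e2) from unconstrained parameters
components_from_theta <- function(model, theta) {
  a2 <- c2 <- d2 <- 0
  if (model == "AE") a2 <- plogis(theta[1L])
  else if (model == "CE") c2 <- plogis(theta[1L])
  else if (model == "ACE") {
    z <- exp(c(theta[1L], theta[2L], 0)); z <- z / sum(z)
    a2 <- z[1L]; c2 <- z[2L]
  } else if (model == "ADE") {
    z <- exp(c(theta[1L], theta[2L], 0)); z <- z / sum(z)
    a2 <- z[1L]; d2 <- z[2L]
  }
  c(a2 = a2, c2 = c2, d2 = d2, e2 = 1 - a2 - c2 - d2)
}

n_free_components <- function(model)
  switch(model, E = 0L, AE = 1L, CE = 1L, ACE = 2L, ADE = 2L)

joint_loglik <- function(mz, dz, tau, comps) {
  r <- implied_correlations(comps["a2"], comps["c2"], comps["d2"])
  pair_table_loglik(mz$n_concordant_unaffected, mz$n_discordant,
                    mz$n_concordant_affected, tau, min(r[1L], 0.9999)) +
    pair_table_loglik(dz$n_concordant_unaffected, dz$n_discordant,
                      dz$n_concordant_affected, tau, min(r[2L], 0.9999))
}

#' Fit a liability-threshold variance-component model to MZ and DZ pair tables
#'
#' Jointly maximises the trinomial log-likelihoods of the monozygotic and
#' dizygotic pair tables under a shared liability threshold, with the
#' zygosity-specific liability correlations structured by
#' [implied_correlations()] for the chosen decomposition (`"ACE"`, `"ADE"`,
#' `"AE"`, `"CE"`, `"E"`). Components live on the unit simplex through a
#' softmax-style transform; estimates within `1e-6` of a boundary are
#' reported exactly at 0. Initialisation uses the Falconer start
#' `a2 = 2(r_MZ - r_DZ)` from the zygosity-specific tetrachoric point
#' estimates, clipped to the simplex, plus neutral fallback starts.
#'
#' @param mz,dz [pair_table()]s for MZ and DZ pairs.
#' @param model One of `"ACE"`, `"ADE"`, `"AE"`, `"CE"`, `"E"`.
#' @param conf_level Level for the profile-likelihood interval.
#' @param ci Compute profile intervals for `a2` (and `a2 + d2` under ADE).
#'   Intervals use the chi-squared(1) cutoff and respect the [0, 1]
#'   boundaries.
#' @return Object of class `biometric_fit`: `components` (a2, c2, d2, e2),
#'   `tau`, `loglik`, `aic` (`2k - 2 loglik`, `k` = threshold + free
#'   components), `ci` (rows `a2` and, for ADE, `broad_sense`), `model`,
#'   `degenerate` flag.
#' @export
fit_biometric <- function(mz, dz, model = "AE", conf_level = 0.95, ci = TRUE) {
  if (is.numeric(mz)) mz <- pair_table(mz[1], mz[2], mz[3], zygosity = "MZ")
  if (is.numeric(dz)) dz <- pair_table(dz[1], dz[2], dz[3], zygosity = "DZ")
  stopifnot(inherits(mz, "pair_table"), inherits(dz, "pair_table"))
  model <- match.arg(model, biometric_models)
  if (total_pairs(mz) == 0L || total_pairs(dz) == 0L)
    stop("both pair tables must be nonempty", call. = FALSE)
  n_aff <- 2L * (mz$n_concordant_affected + dz$n_concordant_affected) +
    mz$n_discordant + dz$n_discordant
  degenerate <- n_aff == 0L
  if (degenerate)
    return(structure(list(components = c(a2 = NA, c2 = NA, d2 = NA, e2 = NA),
                          tau = NA_real_, loglik = NA_real_, aic = NA_real_,
                          ci = NULL, model = model, degenerate = TRUE,
                          mz = mz, dz = dz), class = "biometric_fit"))

  prev <- n_aff / (2 * (total_pairs(mz) + total_pairs(dz)))
  tau0 <- qnorm(1 - prev)
  k <- n_free_components(model)

  nll <- function(p) {
    ll <- joint_loglik(mz, dz, p[1L],
                       components_from_theta(model, if (k) p[-1L] else numeric()))
    if (!is.finite(ll)) 1e12 else -ll
  }

  # Falconer-style start from tetrachoric point estimates
  r_mz <- tryCatch(fit_tetrachoric(mz, ci = FALSE)$rho, error = function(e) NA)
  r_dz <- tryCatch(fit_tetrachoric(dz, ci = FALSE)$rho, error = function(e) NA)
  a2_0 <- if (is.finite(r_mz) && is.finite(r_dz))
    min(0.95, max(0.05, 2 * (r_mz - r_dz))) else 0.5
  c2_0 <- if (is.finite(r_mz) && is.finite(r_dz))
    min(0.9, max(0.02, 2 * r_dz - r_mz)) else 0.2
  starts <- switch(model,
    E = list(tau0),
    AE = list(c(tau0, qlogis(a2_0)), c(tau0, 0)),
    CE = list(c(tau0, qlogis(c2_0)), c(tau0, 0)),
    ACE = list(c(tau0, log(pmax(c(a2_0, c2_0), 1e-3) / max(1 - a2_0 - c2_0, 1e-3))),
               c(tau0, 0, 0)),
    ADE = list(c(tau0, log(pmax(c(a2_0, 0.1), 1e-3) / max(1 - a2_0 - 0.1, 1e-3))),
               c(tau0, 0, 0)))
  best <- NULL
  for (st in starts) {
    o <- tryCatch(
      if (length(st) == 1L)
        optimise(function(t) nll(t), lower = -6, upper = 6, tol = 1e-10)
      else optim(st, nll, method = "BFGS",
                 control = list(reltol = 1e-12, maxit = 1000L)),
      error = function(e) NULL)
    if (is.null(o)) next
    val <- o$objective %||% o$value
    par <- o$minimum %||% o$par
    if (is.null(best) || val < best$val) best <- list(val = val, par = par)
  }
  tau <- best$par[1L]
  comps <- components_from_theta(model, if (k) best$par[-1L] else numeric())
  comps[comps < 1e-6] <- 0
  comps[comps > 1 - 1e-6] <- 1
  comps["e2"] <- 1 - comps["a2"] - comps["c2"] - comps["d2"]
  loglik <- -best$val
  aic <- 2 * (1 + k) - 2 * loglik

  ci_tab <- NULL
  if (ci && model %in% c("AE", "ACE", "ADE")) {
    ci_tab <- rbind(a2 = profile_ci_component(mz, dz, model, "a2",
                                              comps[["a2"]], loglik, conf_level))
    if (model == "ADE")
      ci_tab <- rbind(ci_tab,
                      broad_sense = profile_ci_component(
                        mz, dz, model, "broad_sense",
                        comps[["a2"]] + comps[["d2"]], loglik, conf_level))
  }
  structure(list(components = comps, tau = tau, loglik = loglik, aic = aic,
                 ci = ci_tab, model = model, conf_level = conf_level,
                 degenerate = FALSE, mz = mz, dz = dz),
            class = "biometric_fit")
}

# Profile log-likelihood for one variance share, nuisance parameters
# re-optimised at each fixed value.
profile_loglik_component <- function(mz, dz, model, which, value) {
  nll <- switch(model,
    AE = function(p) { # nuisance: tau
      comps <- c(a2 = value, c2 = 0, d2 = 0, e2 = 1 - value)
      -joint_loglik(mz, dz, p[1L], comps)
    },
    ACE = function(p) { # nuisance: tau, split of (1 - a2) between c2 and e2
      c2 <- (1 - value) * plogis(p[2L])
      comps <- c(a2 = value, c2 = c2, d2 = 0, e2 = 1 - value - c2)
      -joint_loglik(mz, dz, p[1L], comps)
    },
    ADE = if (which == "a2") function(p) {
      d2 <- (1 - value) * plogis(p[2L])
      comps <- c(a2 = value, c2 = 0, d2 = d2, e2 = 1 - value - d2)
      -joint_loglik(mz, dz, p[1L], comps)
    } else function(p) { # broad_sense: a2 + d2 fixed, split profiled
      a2 <- value * plogis(p[2L])
      comps <- c(a2 = a2, c2 = 0, d2 = value - a2, e2 = 1 - value)
      -joint_loglik(mz, dz, p[1L], comps)
    })
  safe <- function(p) { v <- nll(p); if (is.finite(v)) v else 1e12 }
  if (model == "AE") -optimise(function(t) safe(t), c(-6, 6), tol = 1e-9)$objective
  else -optim(c(2, 0), safe, method = "BFGS",
              control = list(reltol = 1e-11, maxit = 500L))$value
}

profile_ci_component <- function(mz, dz, model, which, est, ll_hat, conf_level) {
  cut <- ll_hat - qchisq(conf_level, 1L) / 2
  g <- function(v) profile_loglik_component(mz, dz, model, which, v) - cut
  eps <- 1e-6
  lo <- if (est > eps && g(eps) < 0)
    tryCatch(uniroot(g, c(eps, est), tol = 1e-5)$root, error = function(e) 0)
  else 0
  hi <- if (est < 1 - eps && g(1 - eps) < 0)
    tryCatch(uniroot(g, c(est, 1 - eps), tol = 1e-5)$root, error = function(e) 1)
  else 1
  c(low = lo, high = hi)
}

#' AIC-based selection among fitted variance-component models
#'
#' Picks the minimum-AIC fit; ties go to the model with fewer free
#' parameters. When both AE and ADE fits are supplied and their AICs differ
#' by at most `delta`, the broad-sense heritability `a2 + d2` of the ADE fit
#' is attached to the selection for reporting alongside the narrow-sense
#' estimate.
#'
#' @param fits List of `biometric_fit` objects on identical data.
#' @param delta AIC closeness window for the broad-sense report (default 2).
#' @return The selected `biometric_fit`, with extra fields `aic_table` and,
#'   when applicable, `broad_sense`.
#' @export
select_model <- function(fits, delta = 2) {
  stopifnot(length(fits) >= 2L)
  nobs <- vapply(fits, function(f) total_pairs(f$mz) + total_pairs(f$dz), 0)
  if (length(unique(nobs)) != 1L)
    stop("fits must be on identical data", call. = FALSE)
  models <- vapply(fits, `[[`, "", "model")
  aics <- vapply(fits, `[[`, 0, "aic")
  ks <- vapply(models, n_free_components, 0L) + 1L
  ord <- order(aics, ks)
  best <- fits[[ord[1L]]]
  best$aic_table <- data.frame(model = models, aic = aics, k = ks)[ord, ]
  if (all(c("AE", "ADE") %in% models)) {
    d <- abs(aics[models == "ADE"][1L] - aics[models == "AE"][1L])
    if (d <= delta) {
      ade <- fits[[which(models == "ADE")[1L]]]
      best$broad_sense <- unname(ade$components["a2"] + ade$components["d2"])
    }
  }
  best
}

#' Heritability report from a pair-table file
#'
#' Consumes a delimited table of pair counts (columns `disease`, `zygosity`,
#' then the three counts: concordant unaffected, discordant, concordant
#' affected) and emits one row per disease with the AE estimates and
#' profile-likelihood intervals — the layout of a classical twin-study
#' heritability table (A, 95% CI, E, 95% CI).
#'
#' @param tables Path to a CSV like the one behind [aid_pair_tables()], or
#'   an equivalent data.frame.
#' @param model Variance decomposition to report (default `"AE"`).
#' @return data.frame with `disease`, `A`, `A_low`, `A_high`, `E`, `E_low`,
#'   `E_high`, `aic`.
#' @export
biometric_report <- function(tables, model = "AE") {
  if (is.character(tables)) tables <- read.csv(tables, stringsAsFactors = FALSE)
  stopifnot(all(c("disease", "zygosity") %in% names(tables)))
  cnt <- setdiff(names(tables), c("disease", "zygosity"))[1:3]
  rows <- lapply(unique(tables$disease), function(d) {
    get_z <- function(z) {
      r <- tables[tables$disease == d & tables$zygosity == z, cnt]
      if (nrow(r) != 1L) return(NULL)
      pair_table(r[[1]], r[[2]], r[[3]], disease = d, zygosity = z)
    }
    mz <- get_z("MZ"); dz <- get_z("DZ")
    if (is.null(mz) || is.null(dz)) return(NULL)
    fit <- tryCatch(fit_biometric(mz, dz, model), error = function(e) NULL)
    if (is.null(fit) || fit$degenerate) return(NULL)
    ci <- if (!is.null(fit$ci)) fit$ci["a2", ] else c(low = NA, high = NA)
    data.frame(disease = d, A = fit$components[["a2"]],
               A_low = ci[["low"]], A_high = ci[["high"]],
               E = fit$components[["e2"]],
               E_low = 1 - ci[["high"]], E_high = 1 - ci[["low"]],
               aic = fit$aic, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.biometric_fit <- function(x, digits = 3L, ...) {
  if (x$degenerate) {
    cat("Biometric", x$model, "fit: degenerate (no affected individuals)\n")
    return(invisible(x))
  }
  cat(sprintf("Liability-threshold %s model (threshold %.*f, logLik %.2f, AIC %.2f)\n",
              x$model, digits, x$tau, x$loglik, x$aic))
  comps <- x$components[x$components > 0 | names(x$components) == "e2"]
  cat("  variance shares:",
      paste(sprintf("%s = %.*f", names(comps), digits, comps), collapse = ", "), "\n")
  if (!is.null(x$ci))
    for (nm in rownames(x$ci))
      cat(sprintf("  %s %d%% CI: %.*f to %.*f\n", nm,
                  round(100 * (x$conf_level %||% 0.95)),
                  digits, x$ci[nm, "low"], digits, x$ci[nm, "high"]))
  if (!is.null(x$broad_sense))
    cat(sprintf("  broad-sense heritability (A+D): %.*f\n", digits, x$broad_sense))
  invisible(x)
}

#' @export
coef.biometric_fit <- function(object, ...) c(object$components, tau = object$tau)

#' @export
logLik.biometric_fit <- function(object, ...) {
  structure(object$loglik, df = 1L + n_free_components(object$model),
            nobs = total_pairs(object$mz) + total_pairs(object$dz),
            class = "logLik")
}

#' @export
confint.biometric_fit <- function(object, parm, level = 0.95, ...) object$ci

#' @export
summary.biometric_fit <- function(object, ...) {
  print(object)
  r <- implied_correlations(object$components["a2"], object$components["c2"],
                            object$components["d2"])
  cat(sprintf("  implied correlations: rho_MZ = %.3f, rho_DZ = %.3f\n",
              r[1L], r[2L]))
  invisible(object)
}

#' @export
plot.biometric_fit <- function(x, ...) {
  comps <- x$components
  graphics::barplot(comps, ylim = c(0, 1),
                    ylab = "share of liability variance",
                    main = paste("Variance decomposition:", x$model), ...)
  invisible(x)
}

#' Simulate MZ/DZ pair tables from a fitted biometric model
#'
#' @param object A `biometric_fit`.
#' @param nsim Number of replicate table pairs.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return List of `list(mz =, dz =)` pair tables matching the fitted sizes.
#' @export
simulate.biometric_fit <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  r <- implied_correlations(object$components["a2"], object$components["c2"],
                            object$components["d2"])
  draw <- function(N, rho) {
    p <- pair_cell_probs(object$tau, min(rho, 0.9999))
    cnt <- as.vector(stats::rmultinom(1L, N, p))
    pair_table(cnt[1L], cnt[2L], cnt[3L])
  }
  lapply(seq_len(nsim), function(i)
    list(mz = draw(total_pairs(object$mz), r[1L]),
         dz = draw(total_pairs(object$dz), r[2L])))
}
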