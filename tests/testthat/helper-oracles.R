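# Independent oracles used across tests. These deliberately avoid the
# package's own numerical routines: orthant probabilities come from
# mvtnorm's Genz algorithm, likelihood maxima from exhaustive grid scans.

oracle_orthant <- function(tau1, tau2, rho) {
  mvtnorm::pmvnorm(lower = c(tau1, tau2), upper = Inf,
                   corr = matrix(c(1, rho, rho, 1), 2))[1]
}

oracle_pair_ll <- function(n0, n1, n2, tau, rho) {
  p2 <- oracle_orthant(tau, tau, rho)
  pm <- pnorm(tau, lower.tail = FALSE)
  p1 <- 2 * (pm - p2)
  p0 <- 1 - 2 * pm + p2
  if (p0 <= 0 || p1 <= 0 || p2 <= 0) return(-Inf)
  n0 * log(p0) + n1 * log(p1) + n2 * log(p2)
}

# Exhaustive scan at 1e-3 final resolution (coarse pass, then full-resolution
# local refinement) over tau in [-4, 4], rho in [-0.999, 0.999].
oracle_grid_tetrachoric <- function(n0, n1, n2) {
  scan <- function(taus, rhos) {
    best <- c(tau = NA_real_, rho = NA_real_, ll = -Inf)
    for (tau in taus) for (rho in rhos) {
      v <- oracle_pair_ll(n0, n1, n2, tau, rho)
      if (v > best[["ll"]]) best <- c(tau = tau, rho = rho, ll = v)
    }
    best
  }
  c1 <- scan(seq(-4, 4, by = 0.05), seq(-0.999, 0.999, by = 0.05))
  scan(seq(c1[["tau"]] - 0.06, c1[["tau"]] + 0.06, by = 0.001),
       seq(max(-0.999, c1[["rho"]] - 0.06),
           min(0.999, c1[["rho"]] + 0.06), by = 0.001))
}

# AE-model grid over (tau, a2); MZ/DZ correlations a2 and a2/2.
oracle_grid_ae <- function(mz, dz) {
  jll <- function(tau, a2) {
    oracle_pair_ll(mz[1], mz[2], mz[3], tau, a2) +
      oracle_pair_ll(dz[1], dz[2], dz[3], tau, a2 / 2)
  }
  scan <- function(taus, a2s) {
    best <- c(tau = NA_real_, a2 = NA_real_, ll = -Inf)
    for (tau in taus) for (a2 in a2s) {
      v <- jll(tau, a2)
      if (v > best[["ll"]]) best <- c(tau = tau, a2 = a2, ll = v)
    }
    best
  }
  c1 <- scan(seq(-4, 4, by = 0.05), seq(0.001, 0.999, by = 0.05))
  scan(seq(c1[["tau"]] - 0.06, c1[["tau"]] + 0.06, by = 0.001),
       seq(max(0.001, c1[["a2"]] - 0.06), min(0.999, c1[["a2"]] + 0.06),
           by = 0.001))
}

# Cox partial log-likelihood for single-covariate episode data (Breslow
# ties), written independently of survival::coxph.
oracle_cox_pll <- function(ep, beta) {
  et <- sort(unique(ep$exit_age[ep$event]))
  ll <- 0
  for (t in et) {
    dead <- ep$event & ep$exit_age == t
    risk <- ep$entry_age < t & ep$exit_age >= t
    ll <- ll + sum(beta * ep$x[dead]) -
      sum(dead) * log(sum(exp(beta * ep$x[risk])))
  }
  ll
}

oracle_cox_grid <- function(ep, lo = -3, hi = 3, by = 1e-4) {
  betas <- seq(lo, hi, by = by)
  lls <- vapply(betas, function(b) oracle_cox_pll(ep, b), 0)
  betas[which.max(lls)]
}
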