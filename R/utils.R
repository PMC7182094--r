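# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch), cached by order.
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  ev <- eigen(J, symmetric = TRUE)
  out <- list(x = ev$values, w = 2 * ev$vectors[1L, ]^2)
  .gl_cache[[key]] <- out
  out
}

# Deterministic per-component seed streams: one root seed, independent
# substreams per named component, so adding a component does not perturb
# draws made by earlier ones. Kept below 2^31 - 1.
derive_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

as_iso_date <- function(x, what = "date", allow_na = TRUE) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  blank <- is.na(x) | x == "" | x == "NA"
  d <- rep(as.Date(NA), length(x))
  if (any(!blank)) {
    parsed <- as.Date(x[!blank], format = "%Y-%m-%d")
    if (anyNA(parsed)) {
      bad <- which(!blank)[which(is.na(parsed))]
      stop(sprintf("malformed %s at row(s) %s: '%s'", what,
                   paste(head(bad, 5L), collapse = ", "),
                   x[!blank][which(is.na(parsed))][1L]), call. = FALSE)
    }
    d[!blank] <- parsed
  }
  if (!allow_na && anyNA(d)) stop(sprintf("missing %s not allowed", what), call. = FALSE)
  d
}

# Age in (fractional) years at `when`, from birth date.
age_at <- function(birth_date, when) {
  as.numeric(when - birth_date) / 365.25
}

birth_year_of <- function(birth_date) as.integer(format(birth_date, "%Y"))

# 10-year birth-cohort categories used as adjustment covariates.
birth_year_category <- function(birth_year, width = 10L) {
  lo <- (birth_year %/% width) * width
  factor(sprintf("%d-%d", lo, lo + width - 1L))
}

wilson_interval <- function(x, n, level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}
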