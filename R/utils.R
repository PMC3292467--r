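# Internal numeric helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_petkin <- function(msg, class) {
  stop(structure(
    class = c(class, "petkin_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_petkin(sprintf("`%s` must be a finite numeric scalar", name),
                "petkin_invalid_input")
  if (x < lower || x > upper || (strict_lower && x <= lower))
    stop_petkin(sprintf("`%s` = %g is outside its admissible range", name, x),
                "petkin_invalid_input")
  invisible(x)
}

#' Integral of exp(-mu * s) over [s1, s2]
#'
#' Stable for mu -> 0 via expm1(); vectorised over frames (s1, s2) for a
#' scalar rate.
#' @noRd
int_exp0 <- function(mu, s1, s2) {
  d <- s2 - s1
  out <- numeric(length(d))
  pos <- d > 0
  if (!any(pos)) return(out)
  if (abs(mu) * max(d[pos]) < 1e-12) {
    out[pos] <- d[pos] * exp(-mu * s1[pos])
  } else {
    out[pos] <- exp(-mu * s1[pos]) * (-expm1(-mu * d[pos])) / mu
  }
  out
}

#' Integral of s * exp(-mu * s) over [s1, s2]
#'
#' Used only for the confluent (equal-rate) convolution terms. Splits as
#' e^{-mu s1} * (s1 * J0 + J1) with J0, J1 integrals over [0, d]; J1 uses a
#' series expansion when mu * d is tiny to avoid cancellation.
#' @noRd
int_exp1 <- function(mu, s1, s2) {
  d <- s2 - s1
  out <- numeric(length(d))
  pos <- d > 0
  if (!any(pos)) return(out)
  dp <- d[pos]; s1p <- s1[pos]
  if (mu == 0) {
    out[pos] <- s1p * dp + dp^2 / 2
    return(out)
  }
  j0 <- (-expm1(-mu * dp)) / mu
  md <- mu * dp
  j1 <- ifelse(
    md < 1e-4,
    dp^2 / 2 - mu * dp^3 / 3 + mu^2 * dp^4 / 8,
    (1 - (1 + md) * exp(-md)) / mu^2
  )
  out[pos] <- exp(-mu * s1p) * (s1p * j0 + j1)
  out
}

# Rolling polynomial hash of a raw vector (two runs with different
# multipliers, modulo the Mersenne prime 2^31 - 1), returned as a hex
# string. Used for provenance fingerprints of reports; not cryptographic.
content_hash32 <- function(raw_bytes) {
  b <- as.numeric(raw_bytes)
  p <- 2147483647
  h1 <- 17; h2 <- 19
  for (i in seq_along(b)) {
    h1 <- (h1 * 31 + b[i] + 1) %% p
    h2 <- (h2 * 131 + b[i] + 1) %% p
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

#' Low-discrepancy Halton sequence
#'
#' Deterministic quasi-random points in the unit hypercube, used for
#' multi-start initialisation of nonlinear fits.
#' @noRd
halton <- function(n, dim, skip = 20L) {
  primes <- c(2L, 3L, 5L, 7L, 11L, 13L, 17L)
  stopifnot(dim <= length(primes))
  out <- matrix(0, n, dim)
  for (j in seq_len(dim)) {
    base <- primes[j]
    for (i in seq_len(n)) {
      k <- i + skip
      f <- 1; x <- 0
      while (k > 0) {
        f <- f / base
        x <- x + f * (k %% base)
        k <- k %/% base
      }
      out[i, j] <- x
    }
  }
  out
}
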