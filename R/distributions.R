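#' Zero-truncated count distributions
#'
#' Density and random generation for the two count families used throughout
#' the read-count signal model: the zero-truncated geometric (support 1, 2,
#' ...; mass concentrated near 1) and the zero-truncated negative binomial
#' (overdispersed, used for the high read-count mode). Both are parameterised
#' so that read counts of detected calls are always >= 1 — a call record only
#' exists if at least one read supported it; dropouts are represented by
#' absence, not by zeros.
#'
#' The zero-truncated geometric with success probability `prob` has
#' `P(X = k) = prob * (1 - prob)^(k - 1)` for `k >= 1` and mean `1 / prob`.
#' The zero-truncated negative binomial is the ordinary NB(mu, size)
#' conditioned on being positive.
#'
#' @param x vector of positive integer quantiles.
#' @param n number of draws.
#' @param prob geometric success probability in (0, 1].
#' @param mu,size negative binomial mean and dispersion (size) parameters.
#' @param log logical; return log density.
#' @return `dztgeom()`/`dztnbinom()` return densities; `rztgeom()`/
#'   `rztnbinom()` return integer vectors of draws (all >= 1).
#' @name zt-distributions
NULL

#' @rdname zt-distributions
#' @export
dztgeom <- function(x, prob, log = FALSE) {
  .assert(all(prob > 0 & prob <= 1), "`prob` must lie in (0, 1]")
  out <- ifelse(x >= 1 & x == floor(x), dgeom(x - 1, prob = prob), 0)
  if (log) base::log(out) else out
}

#' @rdname zt-distributions
#' @export
rztgeom <- function(n, prob) {
  .assert(all(prob > 0 & prob <= 1), "`prob` must lie in (0, 1]")
  rgeom(n, prob = prob) + 1L
}

#' @rdname zt-distributions
#' @export
dztnbinom <- function(x, mu, size, log = FALSE) {
  .assert(all(mu > 0) && all(size > 0), "`mu` and `size` must be positive")
  p0 <- dnbinom(0, mu = mu, size = size)
  out <- ifelse(x >= 1 & x == floor(x),
                dnbinom(x, mu = mu, size = size) / (1 - p0), 0)
  if (log) base::log(out) else out
}

#' @rdname zt-distributions
#' @export
rztnbinom <- function(n, mu, size) {
  .assert(all(mu > 0) && all(size > 0), "`mu` and `size` must be positive")
  if (n == 0) return(integer(0))
  # rejection from the untruncated NB; P(0) is modest for the high mode used
  # here, so a couple of rounds suffice
  out <- rnbinom(n, mu = mu, size = size)
  bad <- which(out == 0L)
  while (length(bad) > 0) {
    out[bad] <- rnbinom(length(bad), mu = mu, size = size)
    bad <- bad[out[bad] == 0L]
  }
  out
}

# mean of the zero-truncated NB: mu / (1 - P0)
ztnbinom_mean <- function(mu, size) {
  mu / (1 - dnbinom(0, mu = mu, size = size))
}
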