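#' Hurwitz zeta function for real exponent and integer shift
#'
#' Computes \eqn{\zeta(\alpha, q) = \sum_{k=q}^{\infty} k^{-\alpha}}, the
#' normalizing constant of the discrete power law with lower cutoff `q`.
#' The sum is evaluated by adding the first terms explicitly and closing the
#' tail with an Euler--Maclaurin expansion, which is accurate to near machine
#' precision for `alpha > 1`.
#'
#' @param alpha scaling exponent, a single number greater than 1.
#' @param q integer lower cutoff(s), each at least 1. Vectorized.
#' @return numeric vector of the same length as `q`.
#' @export
#' @examples
#' hurwitz_zeta(2, 1) # pi^2 / 6
hurwitz_zeta <- function(alpha, q) {
  stopifnot(length(alpha) == 1L, is.finite(alpha), alpha > 1)
  q <- as.numeric(q)
  stopifnot(all(q >= 1))
  .hz(alpha, q)
}

# validation-free workhorse (alpha scalar > 1, q numeric >= 1)
.hz <- function(alpha, q) {
  if (length(q) == 1L) {
    if (q >= .zeta_qcut) return(.zeta_em(alpha, q))
    return(sum((q:(.zeta_qcut - 1))^(-alpha)) + .zeta_em(alpha, .zeta_qcut))
  }
  res <- numeric(length(q))
  big <- q >= .zeta_qcut
  if (any(big)) res[big] <- .zeta_em(alpha, q[big])
  if (any(!big)) {
    pow <- (1:(.zeta_qcut - 1))^(-alpha)
    csum <- rev(cumsum(rev(pow))) # csum[j] = sum_{k=j}^{qcut-1} k^-alpha
    res[!big] <- csum[q[!big]] + .zeta_em(alpha, .zeta_qcut)
  }
  res
}

.zeta_qcut <- 32L

# Euler-Maclaurin tail sum_{k=Q}^Inf k^-alpha, valid for Q moderately large.
# Vectorized over Q (alpha scalar) or over alpha (Q scalar).
.zeta_em <- function(alpha, Q) {
  Q^(1 - alpha) / (alpha - 1) + 0.5 * Q^(-alpha) +
    alpha / 12 * Q^(-alpha - 1) -
    alpha * (alpha + 1) * (alpha + 2) / 720 * Q^(-alpha - 3) +
    alpha * (alpha + 1) * (alpha + 2) * (alpha + 3) * (alpha + 4) / 30240 *
      Q^(-alpha - 5)
}

# Discrete power-law pmf and cdf on {xmin, xmin+1, ...}
.pl_pmf <- function(x, alpha, xmin) {
  x^(-alpha) / hurwitz_zeta(alpha, xmin)
}

# P(X <= x) for the zeta-normalized discrete power law
.pl_cdf <- function(x, alpha, xmin) {
  1 - hurwitz_zeta(alpha, x + 1) / hurwitz_zeta(alpha, xmin)
}

#' Sample from the discrete power law
#'
#' Draws i.i.d. values from the zeta-normalized discrete power law
#' \eqn{p(x) = x^{-\alpha} / \zeta(\alpha, x_{min})} on
#' \eqn{\{x_{min}, x_{min}+1, \dots\}} by exact inversion: a cumulative table
#' covers the bulk of the mass and rare draws beyond it are resolved by
#' bisection on the survival function.
#'
#' @param alpha scaling exponent, greater than 1.
#' @param xmin positive integer lower cutoff.
#' @param n number of draws.
#' @param seed optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return integer-valued numeric vector of length `n`, all `>= xmin`.
#' @export
#' @examples
#' x <- sample_discrete_powerlaw(2.5, 1, 100, seed = 1)
#' min(x) >= 1
sample_discrete_powerlaw <- function(alpha, xmin = 1L, n, seed = NULL) {
  if (!is.finite(alpha) || alpha <= 1) {
    stop("`alpha` must be finite and greater than 1")
  }
  stopifnot(n >= 1, xmin >= 1, xmin == round(xmin))
  xmin <- as.integer(xmin)
  sampler <- .pl_sampler(alpha, xmin)
  if (is.null(seed)) sampler(n) else withr::with_seed(seed, sampler(n))
}

# Returns a closure drawing n values; the cdf table is built once so repeated
# bootstrap draws at fixed (alpha, xmin) are cheap.
.pl_sampler <- function(alpha, xmin, table_len = 8192L) {
  Z <- hurwitz_zeta(alpha, xmin)
  ks <- xmin:(xmin + table_len - 1)
  cdf <- cumsum(ks^(-alpha)) / Z
  function(n) {
    u <- stats::runif(n)
    idx <- findInterval(u, cdf)
    out <- xmin + idx
    over <- which(idx == table_len)
    for (i in over) {
      # survival S(x) = P(X > x) = zeta(alpha, x+1)/Z; the draw is the
      # smallest x with S(x) <= 1 - u, found by doubling then bisection
      targ <- 1 - u[i]
      surv <- function(x) hurwitz_zeta(alpha, x + 1) / Z
      lo <- xmin + table_len
      if (surv(lo) <= targ) {
        out[i] <- lo
        next
      }
      hi <- 2 * lo
      while (surv(hi) > targ) {
        lo <- hi
        hi <- 2 * hi
      }
      while (hi - lo > 1) {
        mid <- floor((lo + hi) / 2)
        if (surv(mid) > targ) lo <- mid else hi <- mid
      }
      out[i] <- hi
    }
    out
  }
}
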