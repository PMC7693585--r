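## Analytic convolutions of causal exponentials with a Gaussian instrument
## response. These are the numerical core of every kinetic model in the
## package, so they are written against overflow: for arguments where
## exp(a)*erfc(b) would overflow, the scaled complement erfcx is used via the
## identity a - b^2 = -u^2/(2 sigma^2).

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

## Scaled complementary error function, stable for large positive arguments
## (pracma's erfcx computes exp(x^2)*erfc(x) literally and overflows past
## x ~ 26.6; beyond x = 20 the asymptotic series is accurate to < 1e-10).
erfcxStable <- function(x) {
  out <- numeric(length(x))
  small <- x <= 20
  if (any(small)) out[small] <- pracma::erfcx(x[small])
  if (any(!small)) {
    z <- x[!small]
    iz2 <- 1 / (2 * z^2)
    out[!small] <- (1 - iz2 * (1 - 3 * iz2 * (1 - 5 * iz2))) / (z * sqrt(pi))
  }
  out
}

#' Gaussian-IRF convolution of a causal exponential decay
#'
#' Computes \eqn{(g \otimes f)(t)} where \eqn{f(s) = e^{-k s}} for
#' \eqn{s \ge 0} (zero before time zero) and \eqn{g} is a unit-area Gaussian
#' of standard deviation \code{sigma} centred at \code{t0}. With
#' \code{sigma = 0} the unconvolved causal exponential is returned.
#'
#' @param t numeric vector of times (ps).
#' @param k decay rate (1/ps), \code{k >= 0}; \code{k = 0} gives the
#'   convolved unit step.
#' @param t0 centre of the IRF (ps).
#' @param sigma IRF standard deviation (ps); FWHM = 2.3548 sigma.
#' @return numeric vector, same length as \code{t}.
#' @keywords internal
#' @noRd
gaussExpConv <- function(t, k, t0 = 0, sigma = 0) {
  stopifnot(k >= 0, sigma >= 0)
  u <- t - t0
  if (sigma == 0) {
    return(ifelse(u >= 0, exp(-k * u), 0))
  }
  b <- (sigma^2 * k - u) / (sigma * sqrt(2))
  out <- numeric(length(u))
  pos <- b >= 0
  ## b >= 0: exp(a) may overflow; use exp(-u^2/2s^2) * erfcx(b)
  if (any(pos)) {
    out[pos] <- 0.5 * exp(-u[pos]^2 / (2 * sigma^2)) * erfcxStable(b[pos])
  }
  if (any(!pos)) {
    a <- k * (sigma^2 * k / 2 - u[!pos])  # < 0 whenever b < 0
    out[!pos] <- 0.5 * exp(a) * pracma::erfc(b[!pos])
  }
  out
}

#' Gaussian-IRF convolution of t * exp(-k t) (causal)
#'
#' Needed for the equal-rate limit of the sequential two-state scheme, where
#' the intermediate population is \eqn{k^2 t e^{-k t}}. Obtained as
#' \eqn{-\partial/\partial k} of \code{gaussExpConv}.
#'
#' @inheritParams gaussExpConv
#' @keywords internal
#' @noRd
gaussLinExpConv <- function(t, k, t0 = 0, sigma = 0) {
  stopifnot(k > 0, sigma >= 0)
  u <- t - t0
  if (sigma == 0) {
    return(ifelse(u >= 0, u * exp(-k * u), 0))
  }
  b <- (sigma^2 * k - u) / (sigma * sqrt(2))
  gauss <- exp(-u^2 / (2 * sigma^2))
  out <- numeric(length(u))
  pos <- b >= 0
  if (any(pos)) {
    out[pos] <- 0.5 * gauss[pos] *
      ((u[pos] - sigma^2 * k) * erfcxStable(b[pos]) + sigma * sqrt(2 / pi))
  }
  if (any(!pos)) {
    a <- k * (sigma^2 * k / 2 - u[!pos])
    out[!pos] <- 0.5 * ((u[!pos] - sigma^2 * k) * exp(a) * pracma::erfc(b[!pos]) +
                          sigma * sqrt(2 / pi) * gauss[!pos])
  }
  out
}

## Strictly-increasing check used by several validity methods
isStrictlyIncreasing <- function(x) {
  length(x) >= 2L && all(diff(x) > 0)
}
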