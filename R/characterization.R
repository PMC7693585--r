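#' @include AllClasses.R synthetic-characterization.R
NULL

#' Guinier fit: radius of gyration from low-q scattering
#'
#' Weighted linear fit of \eqn{\ln I} versus \eqn{q^2} in the Guinier regime,
#' with the window chosen iteratively so that \eqn{q_{max} R_g \le 1.3}:
#' starting from an initial estimate on the lowest points, the window is
#' shrunk/grown and the fit repeated until the window is stable. Returns
#' \eqn{R_g = \sqrt{-3\,\mathrm{slope}}} and \eqn{I_0 = e^{\mathrm{intercept}}}.
#' A low-q upturn flag implements the elongation diagnostic: systematically
#' positive residuals of the lowest-q points above the fitted line indicate
#' increased slopes at low q (elongated particles).
#'
#' @param profile a \linkS4class{ScatteringProfile}.
#' @param qMaxRg Guinier window rule, default 1.3.
#' @param minPoints minimum points in the window, default 8.
#' @return a \linkS4class{GuinierResult}.
#' @export
#' @examples
#' pr <- simulateGuinierProfile(rg = 14, noiseRel = 0)
#' guinierFit(pr)  # Rg = 14.000
guinierFit <- function(profile, qMaxRg = 1.3, minPoints = 8L) {
  stopifnot(is(profile, "ScatteringProfile"))
  validObject(profile)
  q <- profile@q
  I <- profile@intensity

  fitWindow <- function(keep) {
    if (any(I[keep] <= 0))
      keep <- keep & I > 0
    x <- q[keep]^2
    y <- log(I[keep])
    w <- if (length(profile@sigma))
      (I[keep] / profile@sigma[keep])^2 else rep(1, sum(keep))
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    list(slope = fit$coefficients[2], intercept = fit$coefficients[1],
         resid = fit$residuals, keep = keep)
  }

  ## initial window: lowest max(minPoints, 1/4 of points)
  nInit <- max(minPoints, ceiling(length(q) / 4))
  keep <- seq_along(q) <= nInit
  rg <- NA_real_
  for (it in 1:20) {
    f <- fitWindow(keep)
    if (!is.finite(f$slope) || f$slope >= 0)
      stop("Guinier fit failed: non-negative slope (no decaying low-q regime)")
    rg <- sqrt(-3 * f$slope)
    newKeep <- q * rg <= qMaxRg
    if (sum(newKeep) < minPoints)
      stop("Guinier window collapse: fewer than ", minPoints,
           " points satisfy q*Rg <= ", qMaxRg)
    if (identical(newKeep, keep)) break
    keep <- newKeep
  }
  f <- fitWindow(keep)
  rg <- sqrt(-3 * f$slope)
  ## upturn: mean standardized residual of the lowest 10% of window points
  nLow <- max(3L, ceiling(sum(keep) * 0.1))
  rs <- f$resid
  sdRes <- stats::sd(rs)
  up <- FALSE
  if (is.finite(sdRes) && sdRes > 0) {
    zLow <- mean(rs[seq_len(nLow)]) / (sdRes / sqrt(nLow))
    up <- zLow > 3
  }
  new("GuinierResult", rg = as.numeric(rg),
      i0 = exp(as.numeric(f$intercept)),
      qWindow = range(q[keep]),
      linearityResidual = if (is.finite(sdRes)) sdRes else 0,
      upturn = up, nPointsUsed = as.integer(sum(keep)))
}

#' Multi-heme Nernst titration fit
#'
#' Least-squares fit of the equal-weight sum of \code{nHemes} one-electron
#' Nernst terms at 298.15 K to a titration curve. The apparent midpoint is
#' the potential where the fitted fraction reduced equals 0.5 (found by root
#' bracketing on the fitted curve); per-heme midpoints are reported sorted
#' ascending (label-exchange convention — individual labels are not
#' identifiable).
#'
#' @param curve a \linkS4class{TitrationCurve} spanning at least 80% of the
#'   reduction transition.
#' @param nHemes number of hemes, default 3 (PpcA).
#' @return list with \code{apparentEm} (mV), \code{emValues} (sorted, mV),
#'   \code{rss}, \code{fitted} (function of potential).
#' @export
#' @examples
#' tc <- simulateTitration(c(-180, -150, -120))
#' nernstFit(tc)$apparentEm  # -150 by symmetry
nernstFit <- function(curve, nHemes = 3L) {
  stopifnot(is(curve, "TitrationCurve"))
  validObject(curve)
  e <- curve@potential
  f <- curve@fractionReduced
  if (min(f) > 0.15 || max(f) < 0.85)
    stop("titration does not bracket the transition (needs ~80% span)")

  ## initial per-heme Ems from quantiles of the transition
  qs <- (seq_len(nHemes) - 0.5) / nHemes
  init <- sapply(qs, function(p) {
    stats::approx(f, e, xout = 1 - p, ties = "ordered")$y
  })
  init[!is.finite(init)] <- stats::median(e)

  residFun <- function(par) f - nernstFraction(e, par)
  fit <- minpack.lm::nls.lm(par = init, fn = residFun,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  em <- sort(fit$par)
  fitted <- function(E) nernstFraction(E, em)
  ## apparent midpoint: fitted fraction = 0.5
  lo <- min(e) - 100; hi <- max(e) + 100
  apparent <- stats::uniroot(function(E) fitted(E) - 0.5, c(lo, hi))$root
  list(apparentEm = apparent, emValues = em, rss = sum(fit$fvec^2),
       fitted = fitted)
}
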