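#' @include AllClasses.R synthetic-ta.R
NULL

## Wavelength window excluded from chirp estimation and reference scaling:
## the sharp heme-reduction band, which rises with the charge-separation
## kinetics (not the IRF) and must not leak into either estimate.
HEME_BAND_NM <- c(545, 560)

#' Estimate the probe chirp t0(lambda) from signal onsets
#'
#' For each wavelength column with sufficient signal-to-noise, locates the
#' half-rise delay of |dA| (linear interpolation between grid delays) inside
#' \code{window}, then least-squares fits a polynomial of degree <=
#' \code{degree} in (lambda - 625) nm through the per-column onsets. Columns
#' within the sharp heme band (545-560 nm) are excluded: that band rises with
#' the charge-separation time constant, not the instrument response, so its
#' half-rise is systematically late. Outside it, the onset is IRF-limited and
#' the half-rise sits at t0(lambda) to within a few fs.
#'
#' @param ds a \linkS4class{TADataset}.
#' @param window numeric length 2: delay range (ps) bracketing time zero.
#' @param degree polynomial degree (<= 2), default 2.
#' @param snrMin minimal peak/noise ratio for a column to contribute,
#'   default 8.
#' @return list with \code{coeffs} (polynomial in (lambda - 625) nm),
#'   \code{residualSD} (ps), \code{nColumns} used, and \code{t0} evaluated on
#'   the dataset's wavelength grid.
#' @export
estimateChirp <- function(ds, window = c(-2, 2), degree = 2, snrMin = 8) {
  stopifnot(is(ds, "TADataset"), length(window) == 2, degree <= 2)
  t <- ds@delays; wl <- ds@wavelengths; m <- ds@deltaA
  inWin <- t >= window[1] & t <= window[2]
  if (sum(inWin) < 5)
    stop("delay window too narrow: fewer than 5 points bracket time zero")
  pre <- t <= -1
  noise <- if (sum(pre) >= 3) stats::median(apply(m[pre, , drop = FALSE], 2,
                                                  stats::sd))
           else stats::mad(m[inWin, ])
  noise <- max(noise, .Machine$double.eps)

  tW <- t[inWin]
  keepWl <- wl < HEME_BAND_NM[1] | wl > HEME_BAND_NM[2]
  onset <- rep(NA_real_, length(wl))
  for (j in which(keepWl)) {
    y <- abs(m[inWin, j])
    pk <- max(y)
    if (pk < snrMin * noise) next
    half <- pk / 2
    ix <- which(y >= half)[1]
    if (is.na(ix) || ix == 1L) next
    ## linear interpolation of the crossing
    y0 <- y[ix - 1]; y1 <- y[ix]
    onset[j] <- tW[ix - 1] + (half - y0) / (y1 - y0) * (tW[ix] - tW[ix - 1])
  }
  ok <- is.finite(onset)
  if (sum(ok) < degree + 2)
    stop("no onset detectable: too few columns with signal above noise (",
         sum(ok), " found); cannot estimate chirp")
  x <- wl[ok] - CHIRP_REF_NM
  X <- outer(x, 0:degree, `^`)
  fit <- stats::lm.fit(X, onset[ok])
  coeffs <- fit$coefficients
  rsd <- stats::sd(fit$residuals)
  list(coeffs = as.numeric(coeffs), residualSD = rsd, nColumns = sum(ok),
       t0 = chirpT0(wl, as.numeric(coeffs)))
}

#' Remove the probe chirp from a TA dataset
#'
#' Re-interpolates every wavelength column onto the common delay grid shifted
#' by -t0(lambda) (linear interpolation), so that time zero is
#' wavelength-independent afterwards. Edge points needing extrapolation are
#' held at the boundary value and their delay indices recorded in the
#' provenance; fitting windows exclude them by construction (they sit before
#' the pulse or at the very end of the sweep).
#'
#' @param ds a \linkS4class{TADataset}.
#' @param coeffs chirp polynomial in (lambda - 625) nm (e.g. from
#'   \code{\link{estimateChirp}}, or the generator ground truth).
#' @return a dechirped \linkS4class{TADataset} with \code{chirpCoeffs}
#'   cleared to the residual (zero) polynomial and provenance appended.
#' @export
dechirp <- function(ds, coeffs) {
  stopifnot(is(ds, "TADataset"), all(is.finite(coeffs)))
  t <- ds@delays
  t0 <- chirpT0(ds@wavelengths, coeffs)
  if (max(abs(t0)) > (max(t) - min(t)) / 2)
    stop("chirp shift exceeds half the delay range; refusing to dechirp")
  m <- ds@deltaA
  out <- m
  for (j in seq_along(ds@wavelengths)) {
    if (t0[j] == 0) next
    out[, j] <- stats::approx(t - t0[j], m[, j], xout = t, rule = 2)$y
  }
  nEdge <- sum(t < min(t) + max(abs(t0)) | t > max(t) - max(abs(t0)))
  TADataset(t, ds@wavelengths, out, chirpCoeffs = numeric(0),
            provenance = c(ds@provenance,
                           sprintf("dechirp(coeffs=[%s]; %d edge points held)",
                                   paste(signif(coeffs, 6), collapse = ","),
                                   nEdge)))
}

#' Subtract a scaled reference dataset
#'
#' Removes a spectrally known contaminant — here the heme excited-state
#' dynamics measured on an unlabeled (wild-type-like) sample — by subtracting
#' \code{scale * ref}. With \code{scale = "fit"} the scale is chosen by least
#' squares over a wavelength window that excludes the 545-560 nm
#' heme-reduction band, so the correction cannot eat the signal of interest.
#'
#' @param ds a \linkS4class{TADataset} (signal + contaminant).
#' @param ref a \linkS4class{TADataset} on identical grids.
#' @param scale a number, or \code{"fit"}.
#' @param fitWindow wavelength range (nm) used when \code{scale = "fit"};
#'   default the full grid minus the protected heme band.
#' @return the corrected \linkS4class{TADataset}; the fitted scale is
#'   recorded in provenance and returned as attribute \code{"scale"}.
#' @export
subtractReference <- function(ds, ref, scale = "fit", fitWindow = NULL) {
  stopifnot(is(ds, "TADataset"), is(ref, "TADataset"))
  if (!isTRUE(all.equal(ds@delays, ref@delays)) ||
      !isTRUE(all.equal(ds@wavelengths, ref@wavelengths)))
    stop("dataset and reference grids differ")
  wl <- ds@wavelengths
  if (identical(scale, "fit")) {
    keep <- wl < HEME_BAND_NM[1] | wl > HEME_BAND_NM[2]
    if (!is.null(fitWindow))
      keep <- keep & wl >= fitWindow[1] & wl <= fitWindow[2]
    if (any(wl[keep] >= HEME_BAND_NM[1] & wl[keep] <= HEME_BAND_NM[2]))
      stop("fit window must exclude the 545-560 nm heme band")
    x <- as.vector(ref@deltaA[, keep])
    y <- as.vector(ds@deltaA[, keep])
    denom <- sum(x^2)
    if (denom <= .Machine$double.eps * length(x))
      stop("singular reference: zero variance in the fit window")
    scale <- sum(x * y) / denom
  }
  out <- ds@deltaA - scale * ref@deltaA
  res <- TADataset(ds@delays, wl, out, chirpCoeffs = ds@chirpCoeffs,
                   provenance = c(ds@provenance,
                                  sprintf("subtractReference(scale=%.6g)",
                                          scale)))
  attr(res, "scale") <- scale
  res
}

#' Extract the 553-541 nm heme-reduction kinetic trace
#'
#' Per delay, dA at 553 and 541 nm are obtained by linear interpolation
#' between neighbouring grid wavelengths; the trace is their difference,
#' which nulls any spectrally flat component. The per-point uncertainty is
#' propagated from \code{noiseSigma} when supplied, otherwise from the SD of
#' the pre-pulse rows (delay <= -1 ps) of the two interpolated columns.
#'
#' @param ds a \linkS4class{TADataset} whose wavelength grid covers 541 and
#'   553 nm.
#' @param noiseSigma optional per-element noise SD (mOD).
#' @return a \linkS4class{KineticTrace}.
#' @export
extractTrace <- function(ds, noiseSigma = NULL) {
  stopifnot(is(ds, "TADataset"))
  wl <- ds@wavelengths
  if (min(wl) > 541 || max(wl) < 553)
    stop("wavelength grid must cover 541 and 553 nm")
  interpCol <- function(target) {
    j <- findInterval(target, wl)
    if (wl[j] == target) return(list(col = ds@deltaA[, j], w = c(1, 0)))
    w1 <- (wl[j + 1] - target) / (wl[j + 1] - wl[j])
    list(col = w1 * ds@deltaA[, j] + (1 - w1) * ds@deltaA[, j + 1],
         w = c(w1, 1 - w1))
  }
  a553 <- interpCol(553)
  a541 <- interpCol(541)
  tr <- a553$col - a541$col
  if (is.null(noiseSigma)) {
    pre <- ds@delays <= -1
    noiseSigma <- if (sum(pre) >= 3) stats::sd(tr[pre]) else NA_real_
    sig <- if (is.finite(noiseSigma) && noiseSigma > 0)
      rep(noiseSigma, length(tr)) else numeric(0)
  } else {
    ## independent noise at the interpolation nodes
    s <- noiseSigma * sqrt(sum(a553$w^2) + sum(a541$w^2))
    sig <- rep(s, length(tr))
  }
  kineticTrace(ds@delays, tr, sigma = sig,
               correctionsApplied = ds@provenance)
}

#' Check the pre-pulse region for residual long-lived signal
#'
#' Spectra collected >= 1 ps before the pump must show no features; a failing
#' check signals populations persisting from the previous pump pulse (or a
#' baseline problem). The mean pre-pulse amplitude is compared, per the whole
#' pre-pulse block, against z * SD/sqrt(n).
#'
#' @param ds a \linkS4class{TADataset} with at least 3 pre-pulse rows
#'   (delay <= -1 ps).
#' @param z z-score threshold, default 3.
#' @return list with \code{mean}, \code{sd}, \code{n}, \code{z}, \code{pass}.
#' @export
prepulseCheck <- function(ds, z = 3) {
  stopifnot(is(ds, "TADataset"))
  pre <- ds@delays <= -1
  if (sum(pre) < 3) stop("need at least 3 pre-pulse rows (delay <= -1 ps)")
  block <- ds@deltaA[pre, , drop = FALSE]
  mu <- mean(block)
  s <- stats::sd(as.vector(block))
  n <- length(block)
  zObs <- abs(mu) / (s / sqrt(n) + .Machine$double.eps)
  list(mean = mu, sd = s, n = n, z = zObs, pass = zObs < z)
}
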