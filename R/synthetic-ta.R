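#' @include AllClasses.R kinetics.R
NULL

#' TAGeneratorConfig: ground-truth parameters for synthetic TA matrices
#'
#' Everything needed to emulate a chirped, artifact-laden pump-probe
#' difference-absorbance matrix of a Ru(bpy)3-cytochrome biohybrid: the
#' sequential-scheme time constants, the band amplitudes, the IRF width, a
#' polynomial probe chirp, a coherent solvent artifact, a fast heme
#' excited-state component and i.i.d. Gaussian noise.
#'
#' @slot delayGrid delays (ps), strictly increasing, with at least one point
#'   at or before -1 ps (pre-pulse region).
#' @slot wavelengthGrid wavelengths (nm), strictly increasing, spanning both
#'   541 and 553 nm.
#' @slot tauCS,tauCR charge-separation / recombination constants (ps), > 0.
#' @slot ampHeme peak amplitude of the 553 nm heme-reduction band (mOD).
#' @slot ampRu peak amplitude of the broad 650 nm Ru excited-state band (mOD).
#' @slot irfFWHM IRF FWHM (ps), > 0.
#' @slot chirpCoeffs polynomial coefficients of t0(lambda): intercept (ps),
#'   linear (ps/nm), quadratic (ps/nm^2), evaluated in (lambda - 625) nm.
#' @slot solventAmp coherent-artifact amplitude (mOD).
#' @slot hemeESTau heme excited-state decay constant (ps).
#' @slot hemeESAmp heme excited-state amplitude (mOD).
#' @slot noiseSigma Gaussian noise SD (mOD), >= 0.
#' @slot seed integer RNG seed.
#' @exportClass TAGeneratorConfig
setClass("TAGeneratorConfig",
  representation(
    delayGrid = "numeric", wavelengthGrid = "numeric",
    tauCS = "numeric", tauCR = "numeric",
    ampHeme = "numeric", ampRu = "numeric",
    irfFWHM = "numeric", chirpCoeffs = "numeric",
    solventAmp = "numeric", hemeESTau = "numeric", hemeESAmp = "numeric",
    noiseSigma = "numeric", seed = "integer"
  )
)

setValidity("TAGeneratorConfig", function(object) {
  msg <- NULL
  if (object@tauCS <= 0 || object@tauCR <= 0)
    msg <- c(msg, "tauCS and tauCR must be positive")
  if (object@irfFWHM <= 0) msg <- c(msg, "irfFWHM must be positive")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@hemeESTau <= 0) msg <- c(msg, "hemeESTau must be positive")
  if (!isStrictlyIncreasing(object@delayGrid))
    msg <- c(msg, "delayGrid must be strictly increasing")
  if (!any(object@delayGrid <= -1))
    msg <- c(msg, "delayGrid must include at least one pre-pulse point <= -1 ps")
  if (!isStrictlyIncreasing(object@wavelengthGrid))
    msg <- c(msg, "wavelengthGrid must be strictly increasing")
  if (min(object@wavelengthGrid) > 541 || max(object@wavelengthGrid) < 553)
    msg <- c(msg, "wavelengthGrid must span both 541 and 553 nm")
  if (length(object@chirpCoeffs) < 1 || length(object@chirpCoeffs) > 3)
    msg <- c(msg, "chirpCoeffs must have 1-3 coefficients (degree <= 2)")
  if (is.null(msg)) TRUE else msg
})

#' Default delay grid: linear through the pulse, log-spaced afterwards
#'
#' -5 to +1 ps on a fine linear grid (resolving the IRF and coherent
#' artifact), then log-spaced to \code{tMax}.
#'
#' @param tMax last delay (ps), default 3000.
#' @param nLog number of log-spaced points after 1 ps.
#' @param dtLin linear step before 1 ps (ps).
#' @return numeric delay grid (ps).
#' @export
defaultDelayGrid <- function(tMax = 3000, nLog = 60, dtLin = 0.05) {
  lin <- seq(-5, 1, by = dtLin)
  lg <- exp(seq(log(1 + dtLin), log(tMax), length.out = nLog))
  c(lin, lg)
}

#' Construct a TAGeneratorConfig
#'
#' Defaults are the study conditions of the ultrafast constructs: K52C-like
#' time constants (2.3 / 5.9 ps), a 0.17 ps IRF (cross-correlation of two
#' 120 fs pulses), a quadratic chirp sweeping ~0.3 ps across the 500-750 nm
#' probe window, a coherent solvent artifact at time zero and a 1 ps heme
#' excited-state component.
#'
#' @param delayGrid delays (ps); default \code{defaultDelayGrid()}.
#' @param wavelengthGrid wavelengths (nm); default 500-750 nm in 2 nm steps.
#' @param tauCS,tauCR kinetic constants (ps); defaults 2.3 and 5.9.
#' @param ampHeme heme band amplitude (mOD), default 1.
#' @param ampRu Ru excited-state band amplitude (mOD), default 1.
#' @param irfFWHM IRF FWHM (ps), default 0.17.
#' @param chirpCoeffs t0(lambda) polynomial in (lambda - 625) nm; default
#'   \code{c(0, 1.2e-3, 4e-6)} (~0.3 ps total sweep).
#' @param solventAmp coherent-artifact amplitude (mOD), default 0.3.
#' @param hemeESTau heme excited-state decay (ps), default 1.
#' @param hemeESAmp heme excited-state amplitude (mOD), default 0.5.
#' @param noiseSigma noise SD (mOD), default 0.02 (2% of the heme band).
#' @param seed integer seed, default 1.
#' @return a \linkS4class{TAGeneratorConfig}.
#' @export
taGeneratorConfig <- function(delayGrid = defaultDelayGrid(),
                              wavelengthGrid = seq(500, 750, by = 2),
                              tauCS = 2.3, tauCR = 5.9,
                              ampHeme = 1, ampRu = 1,
                              irfFWHM = 0.17,
                              chirpCoeffs = c(0, 1.2e-3, 4e-6),
                              solventAmp = 0.3,
                              hemeESTau = 1, hemeESAmp = 0.5,
                              noiseSigma = 0.02, seed = 1L) {
  new("TAGeneratorConfig",
      delayGrid = as.numeric(delayGrid),
      wavelengthGrid = as.numeric(wavelengthGrid),
      tauCS = tauCS, tauCR = tauCR, ampHeme = ampHeme, ampRu = ampRu,
      irfFWHM = irfFWHM, chirpCoeffs = as.numeric(chirpCoeffs),
      solventAmp = solventAmp, hemeESTau = hemeESTau, hemeESAmp = hemeESAmp,
      noiseSigma = noiseSigma, seed = as.integer(seed))
}

## Reference wavelength for the chirp polynomial; using the window centre
## keeps the coefficients well-scaled.
CHIRP_REF_NM <- 625

#' Evaluate the time-zero polynomial t0(lambda)
#'
#' @param wavelengths nm.
#' @param coeffs polynomial coefficients (intercept first) in powers of
#'   (lambda - 625) nm.
#' @return t0 values (ps).
#' @export
chirpT0 <- function(wavelengths, coeffs) {
  x <- wavelengths - CHIRP_REF_NM
  drop(outer(x, seq_along(coeffs) - 1, `^`) %*% coeffs)
}

## Spectral band shapes (unit peak). The heme reduced-minus-oxidized alpha
## band is sharp (sigma 3 nm at 553 nm; effectively zero at 541 nm); the Ru
## excited-state/Ru(III) band is much broader (sigma 40 nm at 650 nm); the
## heme excited state gets its own intermediate band overlapping 541-553 so
## that the reference subtraction is genuinely exercised.
.bandHeme <- function(wl) exp(-(wl - 553)^2 / (2 * 3^2))
.bandRu   <- function(wl) exp(-(wl - 650)^2 / (2 * 40^2))
.bandES   <- function(wl) exp(-(wl - 548)^2 / (2 * 8^2))

#' Generate a synthetic transient-absorbance dataset
#'
#' Builds \eqn{\Delta A(t,\lambda)} as the IRF-convolved sum of (i) the
#' two-state charge-separated intermediate population carrying the sharp
#' 553 nm heme-reduction band, (ii) the donor excited-state population
#' carrying the broad 650 nm band, and (iii) a single-exponential heme
#' excited-state component with its own spectrum, all evaluated at the
#' chirped local time \eqn{t' = t - t_0(\lambda)}, plus a coherent solvent
#' artifact (Gaussian + first derivative at \eqn{t_0(\lambda)}, zero outside
#' 3 IRF widths) and i.i.d. Gaussian noise. Pre-pulse rows contain only
#' noise by construction.
#'
#' @param config a \linkS4class{TAGeneratorConfig}.
#' @return a \linkS4class{TADataset} whose \code{chirpCoeffs} hold the
#'   ground-truth chirp.
#' @export
#' @examples
#' ds <- simulateTADataset(taGeneratorConfig(noiseSigma = 0))
simulateTADataset <- function(config) {
  stopifnot(is(config, "TAGeneratorConfig"))
  validObject(config)
  t <- config@delayGrid
  wl <- config@wavelengthGrid
  t0 <- chirpT0(wl, config@chirpCoeffs)
  sigmaIRF <- config@irfFWHM * FWHM_TO_SIGMA

  p <- schemeParams(tauCS = config@tauCS, tauCR = config@tauCR,
                    irfFWHM = config@irfFWHM, t0 = 0)

  sHeme <- .bandHeme(wl); sRu <- .bandRu(wl); sES <- .bandES(wl)

  m <- matrix(0, length(t), length(wl))
  for (j in seq_along(wl)) {
    tp <- t - t0[j]
    col <- 0
    if (config@ampHeme != 0)
      col <- col + config@ampHeme * sHeme[j] * twoStateSignal(tp, p)
    if (config@ampRu != 0)
      col <- col + config@ampRu * sRu[j] * donorExcitedSignal(tp, p)
    if (config@hemeESAmp != 0)
      col <- col + config@hemeESAmp * sES[j] *
        gaussExpConv(tp, 1 / config@hemeESTau, 0, sigmaIRF)
    if (config@solventAmp != 0)
      col <- col + solventArtifact(tp, config@solventAmp, sigmaIRF)
    m[, j] <- col
  }
  if (config@noiseSigma > 0) {
    set.seed(config@seed)
    m <- m + matrix(stats::rnorm(length(m), 0, config@noiseSigma),
                    nrow(m), ncol(m))
  }
  TADataset(t, wl, m, chirpCoeffs = config@chirpCoeffs,
            provenance = sprintf("simulated (seed %d)", config@seed))
}

#' Coherent solvent artifact: Gaussian plus first derivative at time zero
#'
#' Hard-zeroed outside |t'| < 3 IRF widths (cross-phase modulation is
#' confined to pulse overlap).
#'
#' @param tp local time t - t0(lambda) (ps).
#' @param amp amplitude (mOD).
#' @param sigmaIRF IRF standard deviation (ps).
#' @return numeric vector.
#' @export
solventArtifact <- function(tp, amp, sigmaIRF) {
  g <- exp(-tp^2 / (2 * sigmaIRF^2))
  out <- amp * (g - 0.8 * (tp / sigmaIRF) * g)
  out[abs(tp) >= 3 * sigmaIRF / FWHM_TO_SIGMA] <- 0  # 3 FWHM
  out
}

#' Generate a reference dataset carrying only the heme excited-state component
#'
#' A wild-type-PpcA-like measurement: no charge separation (no covalently
#' linked photosensitizer transfer path), only the heme excited-state
#' dynamics, solvent artifact, chirp and noise. Used as the subtraction
#' reference for \code{\link{subtractReference}}.
#'
#' @param config a \linkS4class{TAGeneratorConfig}; its ampHeme/ampRu are
#'   ignored (set to zero).
#' @param seed optional seed overriding \code{config@seed} (a reference is an
#'   independent measurement with independent noise).
#' @return a \linkS4class{TADataset}.
#' @export
simulateReferenceDataset <- function(config, seed = config@seed + 1000L) {
  cfg <- config
  cfg@ampHeme <- 0
  cfg@ampRu <- 0
  cfg@seed <- as.integer(seed)
  simulateTADataset(cfg)
}
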