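#' @import methods
NULL

## ---------------------------------------------------------------------------
## Transient-absorbance containers
## ---------------------------------------------------------------------------

#' TADataset: a delays x wavelengths difference-absorbance matrix
#'
#' The raw observable of a pump-probe transient-absorbance experiment:
#' \eqn{\Delta A(t, \lambda)} in mOD on a strictly increasing delay grid (ps)
#' and wavelength grid (nm). \code{chirpCoeffs} holds polynomial coefficients
#' (intercept first, powers of nm) of the wavelength-dependent time zero
#' \eqn{t_0(\lambda)}; they are either the generator's ground truth or an
#' estimate, and \code{numeric(0)} when unknown. \code{provenance} records the
#' ordered corrections applied so a corrected matrix is reproducible from the
#' raw file and configuration.
#'
#' @slot delays numeric, pump-probe delays (ps), strictly increasing.
#' @slot wavelengths numeric, probe wavelengths (nm), strictly increasing.
#' @slot deltaA numeric matrix (mOD), one row per delay.
#' @slot chirpCoeffs numeric, polynomial coefficients of t0(lambda).
#' @slot provenance character, ordered processing history.
#' @exportClass TADataset
setClass("TADataset",
  representation(
    delays      = "numeric",
    wavelengths = "numeric",
    deltaA      = "matrix",
    chirpCoeffs = "numeric",
    provenance  = "character"
  ),
  prototype(chirpCoeffs = numeric(0), provenance = character(0))
)

setValidity("TADataset", function(object) {
  msg <- NULL
  if (!isStrictlyIncreasing(object@delays))
    msg <- c(msg, "delays must be strictly increasing (length >= 2)")
  if (!isStrictlyIncreasing(object@wavelengths))
    msg <- c(msg, "wavelengths must be strictly increasing (length >= 2)")
  if (!identical(dim(object@deltaA),
                 c(length(object@delays), length(object@wavelengths))))
    msg <- c(msg, "deltaA must be length(delays) x length(wavelengths)")
  if (!all(is.finite(object@deltaA)))
    msg <- c(msg, "deltaA must be finite")
  if (is.null(msg)) TRUE else msg
})

#' Construct a TADataset
#'
#' @param delays numeric delay grid (ps), strictly increasing.
#' @param wavelengths numeric wavelength grid (nm), strictly increasing.
#' @param deltaA matrix of differential absorbance (mOD), rows follow
#'   \code{delays}.
#' @param chirpCoeffs optional polynomial coefficients of t0(lambda).
#' @param provenance optional character history.
#' @return a \linkS4class{TADataset}.
#' @export
#' @examples
#' ds <- TADataset(delays = c(-1, 0, 1, 2), wavelengths = c(540, 550, 560),
#'                 deltaA = matrix(0, 4, 3))
TADataset <- function(delays, wavelengths, deltaA,
                      chirpCoeffs = numeric(0), provenance = character(0)) {
  new("TADataset", delays = as.numeric(delays),
      wavelengths = as.numeric(wavelengths),
      deltaA = deltaA, chirpCoeffs = as.numeric(chirpCoeffs),
      provenance = provenance)
}

#' KineticTrace: the 553-541 nm heme-reduction time course
#'
#' A single kinetic observable \eqn{\Delta\Delta A(t) = \Delta A(553\,nm) -
#' \Delta A(541\,nm)}, isolating reduction of the c-type heme alpha band from
#' broad overlapping features, plus a per-point uncertainty.
#'
#' @slot delays numeric (ps), strictly increasing.
#' @slot ddA numeric (mOD).
#' @slot sigma numeric (mOD), per-point 1-sigma uncertainty (> 0), possibly
#'   length 0 when unknown.
#' @slot correctionsApplied character, ordered correction names inherited from
#'   the source dataset.
#' @exportClass KineticTrace
setClass("KineticTrace",
  representation(
    delays = "numeric",
    ddA = "numeric",
    sigma = "numeric",
    correctionsApplied = "character"
  ),
  prototype(sigma = numeric(0), correctionsApplied = character(0))
)

setValidity("KineticTrace", function(object) {
  msg <- NULL
  if (!isStrictlyIncreasing(object@delays))
    msg <- c(msg, "delays must be strictly increasing")
  if (length(object@ddA) != length(object@delays))
    msg <- c(msg, "ddA and delays must have equal length")
  if (!all(is.finite(object@ddA)))
    msg <- c(msg, "ddA must be finite")
  if (length(object@sigma) &&
      (length(object@sigma) != length(object@delays) ||
       !all(is.finite(object@sigma)) || any(object@sigma <= 0)))
    msg <- c(msg, "sigma, when given, must be positive, finite, one per delay")
  if (is.null(msg)) TRUE else msg
})

#' Construct a KineticTrace
#'
#' @param delays numeric delay grid (ps).
#' @param ddA numeric, A(553) - A(541) signal (mOD).
#' @param sigma optional per-point uncertainty (mOD).
#' @param correctionsApplied optional character history.
#' @return a \linkS4class{KineticTrace}.
#' @export
kineticTrace <- function(delays, ddA, sigma = numeric(0),
                         correctionsApplied = character(0)) {
  if (length(sigma) == 1L) sigma <- rep(sigma, length(delays))
  new("KineticTrace", delays = as.numeric(delays), ddA = as.numeric(ddA),
      sigma = as.numeric(sigma), correctionsApplied = correctionsApplied)
}

## ---------------------------------------------------------------------------
## Kinetic scheme parameters and fit results
## ---------------------------------------------------------------------------

#' SchemeParams: rate constants of the sequential kinetic scheme
#'
#' Parameters of the photo-induced electron-transfer chain
#' Ru* -(kCS)-> [Ru(III)/heme(red)] -(kCR)-> ground, with an optional
#' heme-to-heme branch kHH from the proximal reduced heme to a long-lived
#' distal reduced heme, plus the Gaussian IRF width and time zero.
#'
#' @slot kCS charge-separation rate (1/ps), > 0.
#' @slot kCR charge-recombination rate (1/ps), > 0.
#' @slot kHH optional heme-to-heme forward rate (1/ps), >= 0.
#' @slot irfFWHM instrument-response FWHM (ps), >= 0 (0 = delta IRF).
#' @slot t0 time zero (ps).
#' @exportClass SchemeParams
setClass("SchemeParams",
  representation(kCS = "numeric", kCR = "numeric", kHH = "numeric",
                 irfFWHM = "numeric", t0 = "numeric"),
  prototype(kHH = 0, irfFWHM = 0, t0 = 0)
)

setValidity("SchemeParams", function(object) {
  msg <- NULL
  if (length(object@kCS) != 1L || !is.finite(object@kCS) || object@kCS <= 0)
    msg <- c(msg, "kCS must be a single positive rate")
  if (length(object@kCR) != 1L || !is.finite(object@kCR) || object@kCR <= 0)
    msg <- c(msg, "kCR must be a single positive rate")
  if (length(object@kHH) != 1L || !is.finite(object@kHH) || object@kHH < 0)
    msg <- c(msg, "kHH must be a single non-negative rate")
  if (length(object@irfFWHM) != 1L || !is.finite(object@irfFWHM) ||
      object@irfFWHM < 0)
    msg <- c(msg, "irfFWHM must be a single non-negative width")
  if (is.null(msg)) TRUE else msg
})

#' Construct SchemeParams
#'
#' @param tauCS charge-separation time constant (ps); alternative to
#'   \code{kCS}.
#' @param tauCR charge-recombination time constant (ps); alternative to
#'   \code{kCR}.
#' @param kCS,kCR rates (1/ps); used if the taus are missing.
#' @param kHH optional heme-to-heme rate (1/ps), default 0.
#' @param irfFWHM Gaussian IRF full width at half maximum (ps), default 0.
#' @param t0 time zero (ps), default 0.
#' @return a \linkS4class{SchemeParams}.
#' @export
#' @examples
#' p <- schemeParams(tauCS = 2.3, tauCR = 5.9, irfFWHM = 0.17)
schemeParams <- function(tauCS = NULL, tauCR = NULL, kCS = NULL, kCR = NULL,
                         kHH = 0, irfFWHM = 0, t0 = 0) {
  if (!is.null(tauCS)) kCS <- 1 / tauCS
  if (!is.null(tauCR)) kCR <- 1 / tauCR
  if (is.null(kCS) || is.null(kCR))
    stop("supply either tauCS/tauCR or kCS/kCR")
  new("SchemeParams", kCS = kCS, kCR = kCR, kHH = kHH,
      irfFWHM = irfFWHM, t0 = t0)
}

#' KineticFit: fitted charge-separation/recombination constants
#'
#' Result of weighted least-squares fitting of a sequential kinetic scheme to
#' a \linkS4class{KineticTrace}. Under the two-state reading the faster
#' fitted constant is reported as tauCS (assignment rule); because swapped
#' rate constants give shape-identical signals up to an amplitude factor,
#' \code{degenerate} is TRUE whenever the swap cannot be excluded from shape
#' alone.
#'
#' @slot tauCS charge-separation time constant (ps).
#' @slot tauCR charge-recombination time constant (ps).
#' @slot amplitude fitted amplitude (mOD).
#' @slot t0 fitted time zero (ps).
#' @slot tauCSErr,tauCRErr 1-sigma errors (ps).
#' @slot scheme "two_state" or "multi_state".
#' @slot kHH fitted heme-to-heme branch rate (1/ps; 0 when absent).
#' @slot rss residual sum of squares (weighted).
#' @slot nPoints number of fitted points.
#' @slot degenerate logical, swap-degeneracy flag.
#' @slot atBounds logical, fit touched a parameter bound.
#' @exportClass KineticFit
setClass("KineticFit",
  representation(
    tauCS = "numeric", tauCR = "numeric", amplitude = "numeric",
    t0 = "numeric", tauCSErr = "numeric", tauCRErr = "numeric",
    scheme = "character", kHH = "numeric", rss = "numeric",
    nPoints = "integer", degenerate = "logical", atBounds = "logical"
  ),
  prototype(kHH = 0, degenerate = FALSE, atBounds = FALSE)
)

setValidity("KineticFit", function(object) {
  msg <- NULL
  if (object@tauCS <= 0 || object@tauCR <= 0)
    msg <- c(msg, "time constants must be positive")
  if (!object@scheme %in% c("two_state", "multi_state"))
    msg <- c(msg, "scheme must be 'two_state' or 'multi_state'")
  if (object@scheme == "two_state" && object@tauCS > object@tauCR * (1 + 1e-12))
    msg <- c(msg, "under two_state, tauCS must be the faster constant")
  if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## Marcus parameters
## ---------------------------------------------------------------------------

#' MarcusParams: inputs of the nonadiabatic Marcus rate expression
#'
#' @slot deltaG driving force (eV); negative = downhill. The activationless
#'   "apex" of the Marcus parabola is deltaG = -lambda.
#' @slot lambda reorganization energy (eV), > 0.
#' @slot temperature absolute temperature (K), > 0.
#' @slot prefactor electronic prefactor (1/ps); arbitrary but fixed within a
#'   comparison — all quantities of interest here are rate ratios.
#' @exportClass MarcusParams
setClass("MarcusParams",
  representation(deltaG = "numeric", lambda = "numeric",
                 temperature = "numeric", prefactor = "numeric"),
  prototype(temperature = 298.15, prefactor = 1)
)

setValidity("MarcusParams", function(object) {
  msg <- NULL
  if (object@lambda <= 0) msg <- c(msg, "lambda must be positive")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Construct MarcusParams
#'
#' @param deltaG driving force (eV); the string \code{"apex"} sets
#'   \code{deltaG = -lambda} (activationless).
#' @param lambda reorganization energy (eV), default 0.85 (the value reported
#'   for Ru-labeled PpcA biohybrids).
#' @param temperature K, default 298.15.
#' @param prefactor 1/ps, default 1 (ratios are prefactor-free).
#' @return a \linkS4class{MarcusParams}.
#' @export
#' @examples
#' marcusParams("apex", lambda = 0.85)
marcusParams <- function(deltaG = "apex", lambda = 0.85,
                         temperature = 298.15, prefactor = 1) {
  if (identical(deltaG, "apex")) deltaG <- -lambda
  new("MarcusParams", deltaG = deltaG, lambda = lambda,
      temperature = temperature, prefactor = prefactor)
}

## ---------------------------------------------------------------------------
## Trajectory containers
## ---------------------------------------------------------------------------

#' Trajectory: labeled multi-frame coordinate set
#'
#' Coordinates (Angstrom) of a photosensitizer-protein construct over MD-like
#' frames, with per-atom group labels and aromatic flags. Only two groups are
#' required for donor-acceptor analysis: \code{"photosensitizer"} (Ru-bpy
#' ring atoms) and \code{"heme"} (porphyrin macrocycle atoms).
#'
#' @slot coords numeric array, nAtoms x 3 x nFrames.
#' @slot atoms data.frame with columns \code{id}, \code{name}, \code{element},
#'   \code{group}, \code{aromatic}, \code{chain}.
#' @slot frameSpacing time between frames (ps); metadata only.
#' @slot metadata list; generator ground truth and provenance.
#' @exportClass Trajectory
setClass("Trajectory",
  representation(coords = "array", atoms = "data.frame",
                 frameSpacing = "numeric", metadata = "list"),
  prototype(frameSpacing = 10, metadata = list())
)

setValidity("Trajectory", function(object) {
  msg <- NULL
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "coords must be an nAtoms x 3 x nFrames array")
  if (!is.null(d) && nrow(object@atoms) != d[1])
    msg <- c(msg, "atoms table must have one row per atom")
  need <- c("id", "name", "element", "group", "aromatic", "chain")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms table needs columns:",
                        paste(need, collapse = ", ")))
  else {
    arom <- object@atoms$aromatic
    grp <- object@atoms$group
    if (!any(arom & grp == "photosensitizer") || !any(arom & grp == "heme"))
      msg <- c(msg,
        "need >= 1 aromatic atom in each of groups 'photosensitizer' and 'heme'")
  }
  if (!all(is.finite(object@coords)))
    msg <- c(msg, "coordinates must be finite")
  if (is.null(msg)) TRUE else msg
})

#' DistanceDistribution: binned minimal donor-acceptor distances
#'
#' Histogram of per-frame minimal aromatic-atom donor-acceptor distances on
#' fixed 0.2 Angstrom bins aligned at 0, with frequencies in percent of
#' frames and the recovered mode bin centers.
#'
#' @slot binEdges numeric (Angstrom), width exactly 0.2, aligned at 0.
#' @slot frequencies numeric, percent of frames per bin; sums to 100.
#' @slot nFrames integer, frames counted (after equilibration exclusion).
#' @slot modes numeric, peak bin centers (Angstrom).
#' @exportClass DistanceDistribution
setClass("DistanceDistribution",
  representation(binEdges = "numeric", frequencies = "numeric",
                 nFrames = "integer", modes = "numeric")
)

setValidity("DistanceDistribution", function(object) {
  msg <- NULL
  w <- diff(object@binEdges)
  if (any(abs(w - 0.2) > 1e-9))
    msg <- c(msg, "bin width must be exactly 0.2 Angstrom")
  if (abs(min(object@binEdges) %% 0.2) > 1e-9 &&
      abs(min(object@binEdges) %% 0.2 - 0.2) > 1e-9)
    msg <- c(msg, "bin edges must be aligned to 0.0")
  if (length(object@frequencies) != length(object@binEdges) - 1L)
    msg <- c(msg, "need one frequency per bin")
  if (abs(sum(object@frequencies) - 100) > 1e-6)
    msg <- c(msg, "frequencies must sum to 100% within 1e-6")
  if (is.null(msg)) TRUE else msg
})

#' PerAtomDistanceMap: per-photosensitizer-atom shortest distances
#'
#' For each aromatic photosensitizer atom (row) and frame (column), the
#' shortest distance to any aromatic heme atom. The column-wise minimum
#' reproduces the global per-frame minimal donor-acceptor distance.
#'
#' @slot distances numeric matrix, atoms x frames (Angstrom).
#' @slot atomIds identifiers of the photosensitizer atoms (rows).
#' @exportClass PerAtomDistanceMap
setClass("PerAtomDistanceMap",
  representation(distances = "matrix", atomIds = "character")
)

## ---------------------------------------------------------------------------
## Characterization containers
## ---------------------------------------------------------------------------

#' ScatteringProfile: 1-D small-angle scattering curve
#'
#' @slot q momentum transfer (1/Angstrom), positive increasing.
#' @slot intensity scattered intensity (a.u.).
#' @slot sigma optional per-point uncertainty (a.u.).
#' @exportClass ScatteringProfile
setClass("ScatteringProfile",
  representation(q = "numeric", intensity = "numeric", sigma = "numeric"),
  prototype(sigma = numeric(0))
)

setValidity("ScatteringProfile", function(object) {
  msg <- NULL
  if (any(object@q <= 0) || !isStrictlyIncreasing(object@q))
    msg <- c(msg, "q must be positive and strictly increasing")
  if (length(object@intensity) != length(object@q))
    msg <- c(msg, "intensity and q must have equal length")
  if (is.null(msg)) TRUE else msg
})

#' Construct a ScatteringProfile
#' @param q momentum transfer grid (1/Angstrom).
#' @param intensity intensities (a.u.).
#' @param sigma optional uncertainties.
#' @return a \linkS4class{ScatteringProfile}.
#' @export
scatteringProfile <- function(q, intensity, sigma = numeric(0)) {
  new("ScatteringProfile", q = as.numeric(q), intensity = as.numeric(intensity),
      sigma = as.numeric(sigma))
}

#' GuinierResult: radius of gyration from the low-q Guinier regime
#'
#' @slot rg radius of gyration (Angstrom).
#' @slot i0 forward scattering I(0) (a.u.).
#' @slot qWindow numeric length 2, fitted q range (1/Angstrom) satisfying
#'   q_max * rg <= 1.3.
#' @slot linearityResidual dimensionless residual SD of ln I vs q^2.
#' @slot upturn logical; TRUE when low-q points rise above the Guinier line
#'   (the elongation diagnostic).
#' @slot nPointsUsed integer.
#' @exportClass GuinierResult
setClass("GuinierResult",
  representation(rg = "numeric", i0 = "numeric", qWindow = "numeric",
                 linearityResidual = "numeric", upturn = "logical",
                 nPointsUsed = "integer")
)

setValidity("GuinierResult", function(object) {
  msg <- NULL
  if (object@rg <= 0) msg <- c(msg, "rg must be positive")
  if (max(object@qWindow) * object@rg > 1.3 + 1e-6)
    msg <- c(msg, "Guinier window must satisfy q_max * rg <= 1.3")
  if (is.null(msg)) TRUE else msg
})

#' TitrationCurve: equilibrium redox titration
#'
#' Fraction of hemes reduced versus solution potential, the observable of a
#' mediated potentiometric titration followed optically.
#'
#' @slot potential mV versus a stated reference, increasing.
#' @slot fractionReduced fraction in [-0.05, 1.05] (noise tolerance).
#' @slot sigma optional uncertainties.
#' @exportClass TitrationCurve
setClass("TitrationCurve",
  representation(potential = "numeric", fractionReduced = "numeric",
                 sigma = "numeric"),
  prototype(sigma = numeric(0))
)

setValidity("TitrationCurve", function(object) {
  msg <- NULL
  if (!isStrictlyIncreasing(object@potential))
    msg <- c(msg, "potential must be strictly increasing")
  if (length(object@fractionReduced) != length(object@potential))
    msg <- c(msg, "fractionReduced and potential must have equal length")
  if (any(object@fractionReduced < -0.05) || any(object@fractionReduced > 1.05))
    msg <- c(msg, "fractionReduced must lie in [-0.05, 1.05]")
  if (is.null(msg)) TRUE else msg
})

#' Construct a TitrationCurve
#' @param potential mV grid (increasing).
#' @param fractionReduced fraction reduced at each potential.
#' @param sigma optional uncertainties.
#' @return a \linkS4class{TitrationCurve}.
#' @export
titrationCurve <- function(potential, fractionReduced, sigma = numeric(0)) {
  new("TitrationCurve", potential = as.numeric(potential),
      fractionReduced = as.numeric(fractionReduced), sigma = as.numeric(sigma))
}
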