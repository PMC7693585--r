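#' @include AllClasses.R
NULL

## Thermal voltage RT/F at 298.15 K, in mV; and kB T in eV
THERMAL_MV <- 25.693
KB_EV <- 8.617333262e-5

#' Generate a synthetic Guinier scattering profile
#'
#' \eqn{I(q) = I_0 \exp(-q^2 R_g^2 / 3)\,(1 + \epsilon)},
#' \eqn{\epsilon \sim N(0, \mathrm{noiseRel}^2)} — the ideal low-q behaviour
#' of a compact globular scatterer. The generator is agnostic about shape:
#' for a homogeneous sphere of radius R the caller sets
#' \eqn{R_g = \sqrt{3/5}\,R}.
#'
#' @param rg radius of gyration (Angstrom), > 0.
#' @param i0 forward scattering (a.u.), default 1.
#' @param qGrid positive increasing momentum-transfer grid (1/Angstrom).
#' @param noiseRel relative noise SD, default 0.
#' @param seed integer seed.
#' @return a \linkS4class{ScatteringProfile} with sigma = i0 * noiseRel *
#'   exp(-q^2 rg^2/3).
#' @export
simulateGuinierProfile <- function(rg, i0 = 1,
                                   qGrid = seq(0.005, 0.25, by = 0.0025),
                                   noiseRel = 0, seed = 1L) {
  if (rg <= 0) stop("rg must be positive")
  if (any(qGrid <= 0) || !isStrictlyIncreasing(qGrid))
    stop("qGrid must be positive and strictly increasing")
  ideal <- i0 * exp(-qGrid^2 * rg^2 / 3)
  if (noiseRel > 0) {
    set.seed(as.integer(seed))
    intensity <- ideal * (1 + stats::rnorm(length(qGrid), 0, noiseRel))
  } else intensity <- ideal
  scatteringProfile(qGrid, intensity,
                    sigma = if (noiseRel > 0) ideal * noiseRel else numeric(0))
}

#' Generate a synthetic multi-heme redox titration
#'
#' Equilibrium fraction of hemes reduced versus solution potential for
#' independent one-electron centres:
#' \deqn{f(E) = \frac{1}{n}\sum_i \frac{1}{1 + e^{(E - E_{m,i})/(RT/F)}}}
#' at 298.15 K, plus Gaussian noise. The potential grid spans
#' [min(Em) - 200, max(Em) + 200] mV, comfortably bracketing the transition.
#'
#' @param emList per-heme midpoint potentials (mV); 3 entries for the triheme
#'   PpcA.
#' @param nPoints number of potentials, default 81.
#' @param noiseSigma absolute noise SD on the fraction, default 0.
#' @param seed integer seed.
#' @return a \linkS4class{TitrationCurve}.
#' @export
#' @examples
#' tc <- simulateTitration(c(-180, -150, -120))
simulateTitration <- function(emList, nPoints = 81L, noiseSigma = 0,
                              seed = 1L) {
  if (!length(emList)) stop("emList must be non-empty")
  e <- seq(min(emList) - 200, max(emList) + 200, length.out = nPoints)
  f <- nernstFraction(e, emList)
  if (noiseSigma > 0) {
    set.seed(as.integer(seed))
    f <- f + stats::rnorm(length(f), 0, noiseSigma)
    f <- pmin(pmax(f, -0.05), 1.05)
  }
  titrationCurve(e, f)
}

#' Equal-weight multi-heme Nernst fraction reduced
#'
#' @param e potentials (mV).
#' @param em per-heme midpoint potentials (mV).
#' @return fraction reduced at each potential.
#' @export
nernstFraction <- function(e, em) {
  mat <- vapply(em, function(m) 1 / (1 + exp((e - m) / THERMAL_MV)),
                numeric(length(e)))
  if (is.null(dim(mat))) mean(mat) else rowMeans(mat)
}
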