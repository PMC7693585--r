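#' @include AllClasses.R synthetic-characterization.R
NULL

#' Nonadiabatic Marcus electron-transfer rate
#'
#' \deqn{k = A \exp\left(-\frac{(\Delta G + \lambda)^2}{4 \lambda k_B T}\right)}
#' with the electronic prefactor \eqn{A} taken as a free scale (all the
#' energetic arguments of interest are rate ratios, in which it cancels).
#' At the apex of the Marcus parabola (\eqn{\Delta G = -\lambda}) the rate is
#' activationless and equals the prefactor. \eqn{k_B T} = 0.025693 eV at
#' 298.15 K.
#'
#' @param p a \linkS4class{MarcusParams}.
#' @return rate (1/ps).
#' @export
#' @examples
#' marcusRate(marcusParams("apex"))  # = prefactor = 1
marcusRate <- function(p) {
  stopifnot(is(p, "MarcusParams"))
  validObject(p)
  kbt <- KB_EV * p@temperature
  p@prefactor * exp(-(p@deltaG + p@lambda)^2 / (4 * p@lambda * kbt))
}

#' Rate fold-change induced by a driving-force shift
#'
#' Ratio \eqn{k(\Delta G + \delta) / k(\Delta G)} — the factor by which a
#' perturbation of the acceptor midpoint potential (e.g. the ~40 mV induced
#' by mutation and covalent labeling) changes the ET rate. Positive
#' \code{shift} moves the driving force uphill (less negative), i.e. toward
#' slow-down when at or uphill of the apex.
#'
#' @param shift driving-force shift (eV); 1 mV of midpoint-potential change
#'   corresponds to 0.001 eV for a one-electron transfer.
#' @param p a \linkS4class{MarcusParams}.
#' @return dimensionless fold-change (exact ratio; prefactor cancels).
#' @export
#' @examples
#' foldChangeForShift(0.04, marcusParams("apex", lambda = 0.85))  # 0.98185
foldChangeForShift <- function(shift, p) {
  stopifnot(is(p, "MarcusParams"))
  p2 <- p
  p2@deltaG <- p@deltaG + shift
  marcusRate(p2) / marcusRate(p)
}

#' Driving-force shift needed for a given rate slow-down
#'
#' Smallest positive \eqn{\delta} (uphill) solving
#' \eqn{(\Delta G + \delta + \lambda)^2 - (\Delta G + \lambda)^2 =
#' 4 \lambda k_B T \ln(\mathrm{fold})}; closed-form quadratic root
#' \eqn{\delta = -x + \sqrt{x^2 + 4\lambda k_B T \ln \mathrm{fold}}} with
#' \eqn{x = \Delta G + \lambda}. At the apex (\eqn{x = 0}) this reduces to
#' \eqn{\delta = \sqrt{4 \lambda k_B T \ln \mathrm{fold}}}.
#'
#' @param fold desired slow-down factor, > 1.
#' @param p a \linkS4class{MarcusParams}.
#' @return shift (eV).
#' @export
#' @examples
#' shiftForFoldChange(1000, marcusParams("apex", lambda = 0.85))  # 0.7768 eV
shiftForFoldChange <- function(fold, p) {
  stopifnot(is(p, "MarcusParams"))
  if (fold < 1) stop("fold must be >= 1")
  if (fold == 1) return(0)
  validObject(p)
  x <- p@deltaG + p@lambda
  q <- 4 * p@lambda * KB_EV * p@temperature * log(fold)
  -x + sqrt(x^2 + q)
}
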