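#' @include AllClasses.R
NULL

#' TrajectoryGeneratorConfig: ground truth for synthetic labeled trajectories
#'
#' Parameters of a mixture-of-Gaussians minimal donor-acceptor distance
#' distribution realized geometrically: per frame a target distance is drawn
#' from the mixture and the rigid photosensitizer group is translated so that
#' the geometric minimal aromatic-atom distance equals the target exactly.
#'
#' @slot nFrames number of frames, >= 1.
#' @slot frameSpacing ps between frames (metadata; snapshots each 10 ps).
#' @slot modeDistances target minimal-distance modes (Angstrom), all > 2.0
#'   (hard-sphere floor).
#' @slot modeWeights mixture weights, summing to 1 within 1e-9.
#' @slot jitterSigma Gaussian jitter around each mode (Angstrom).
#' @slot equilibrationFrames count of initial frames placed at a displaced
#'   distance (equilibration artifact).
#' @slot equilibrationDistance the displaced distance (Angstrom).
#' @slot seed integer RNG seed.
#' @exportClass TrajectoryGeneratorConfig
setClass("TrajectoryGeneratorConfig",
  representation(
    nFrames = "integer", frameSpacing = "numeric",
    modeDistances = "numeric", modeWeights = "numeric",
    jitterSigma = "numeric", equilibrationFrames = "integer",
    equilibrationDistance = "numeric", seed = "integer"
  )
)

setValidity("TrajectoryGeneratorConfig", function(object) {
  msg <- NULL
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (length(object@modeDistances) != length(object@modeWeights))
    msg <- c(msg, "modeDistances and modeWeights must have equal length")
  if (abs(sum(object@modeWeights) - 1) > 1e-9)
    msg <- c(msg, "modeWeights must sum to 1 within 1e-9")
  if (any(object@modeDistances <= 2.0))
    msg <- c(msg, "all modeDistances must exceed the 2.0 Angstrom hard-sphere floor")
  if (object@jitterSigma < 0) msg <- c(msg, "jitterSigma must be >= 0")
  if (object@equilibrationFrames < 0L ||
      object@equilibrationFrames >= object@nFrames)
    msg <- c(msg, "equilibrationFrames must be in [0, nFrames)")
  if (object@equilibrationDistance <= 2.0)
    msg <- c(msg, "equilibrationDistance must exceed 2.0 Angstrom")
  if (is.null(msg)) TRUE else msg
})

#' Construct a TrajectoryGeneratorConfig
#'
#' Defaults emulate the sterically restricted ultrafast constructs: a single
#' narrow subpopulation at 6.6 Angstrom with 0.15 Angstrom jitter, frames
#' recorded each 10 ps.
#'
#' @param nFrames frame count, default 30000 (a ~300 ns run at 10 ps).
#' @param frameSpacing ps, default 10.
#' @param modeDistances modes (Angstrom), default 6.6.
#' @param modeWeights weights, default equal.
#' @param jitterSigma Angstrom, default 0.15.
#' @param equilibrationFrames initial displaced frames, default 0.
#' @param equilibrationDistance Angstrom; default max(2.5, min(mode) - 1).
#' @param seed integer, default 1.
#' @return a \linkS4class{TrajectoryGeneratorConfig}.
#' @export
trajectoryGeneratorConfig <- function(nFrames = 30000L, frameSpacing = 10,
                                      modeDistances = 6.6,
                                      modeWeights = rep(1, length(modeDistances)) /
                                        length(modeDistances),
                                      jitterSigma = 0.15,
                                      equilibrationFrames = 0L,
                                      equilibrationDistance =
                                        max(2.5, min(modeDistances) - 1),
                                      seed = 1L) {
  new("TrajectoryGeneratorConfig",
      nFrames = as.integer(nFrames), frameSpacing = frameSpacing,
      modeDistances = as.numeric(modeDistances),
      modeWeights = as.numeric(modeWeights),
      jitterSigma = jitterSigma,
      equilibrationFrames = as.integer(equilibrationFrames),
      equilibrationDistance = equilibrationDistance,
      seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Template geometry
##
## Heme group: an idealized porphyrin-like macrocycle, 20 aromatic C + 4
## aromatic N in the y-z plane, all atoms at x <= 0, with the closest atom at
## the origin; plus a non-aromatic Fe (element FE) and two methyl carbons
## (names starting CM) to exercise the aromatic filter.
##
## Photosensitizer group: two bipyridine-like 6-rings (10 aromatic C + 2
## aromatic N), all atoms at x >= 0 with the closest atom at the origin, plus
## a non-aromatic Ru. Translating this group by (d, 0, 0) therefore makes the
## exact minimal aromatic-atom distance equal d (closest pair along x; every
## other pair is farther by construction), and rotations about the x axis
## preserve it.
## ---------------------------------------------------------------------------

.hemeTemplate <- function() {
  ## macrocycle ring: 24 atoms on a circle of radius 3.4 A in the y-z plane,
  ## shifted so the nearest atom to the interface sits at the origin
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  y <- 3.4 * cos(ang); z <- 3.4 * sin(ang)
  x <- rep(0, 24)
  ## push the plane back so only one atom touches x = 0: tilt the ring
  ## around z so atoms trail off to negative x with distance from atom 1
  x <- -0.35 * (1 - cos(ang)) * 3.4   # atom 1 (ang = 0) at x = 0, rest x < 0
  y <- y - y[1]; z <- z - z[1]        # atom 1 at origin
  el <- rep("C", 24); el[c(4, 10, 16, 22)] <- "N"
  nm <- sprintf("%s%02d", el, seq_len(24))
  ## decorations: Fe centre and two methyl carbons, clearly non-aromatic
  xtra <- data.frame(
    name = c("FE", "CMA", "CMB"),
    element = c("FE", "C", "C"),
    x = c(-1.19, -2.0, -2.4), y = c(0.4, 3.2, -3.0), z = c(0, 1.0, -1.2),
    aromatic = FALSE)
  ring <- data.frame(name = nm, element = el, x = x, y = y, z = z,
                     aromatic = TRUE)
  out <- rbind(ring, xtra)
  out$group <- "heme"
  out$chain <- "H"
  out
}

.photosensitizerTemplate <- function() {
  ## two fused six-membered rings (bipyridine-like) in the y-z plane at x >= 0
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  r <- 1.39
  ring1 <- cbind(y = r * cos(ang), z = r * sin(ang))
  ring2 <- cbind(y = r * cos(ang) + 2.4, z = r * sin(ang) + 0.4)
  yz <- rbind(ring1, ring2)
  x <- 0.25 * ((yz[, 1] - yz[1, 1])^2 + (yz[, 2] - yz[1, 2])^2)^0.5
  x[1] <- 0                                   # closest atom exactly at origin
  yz[, 1] <- yz[, 1] - yz[1, 1]; yz[, 2] <- yz[, 2] - yz[1, 2]
  el <- rep("C", 12); el[c(3, 9)] <- "N"
  nm <- sprintf("%s%02d", el, seq_len(12))
  ring <- data.frame(name = nm, element = el, x = x, y = yz[, 1], z = yz[, 2],
                     aromatic = TRUE)
  ru <- data.frame(name = "RU", element = "RU", x = 2.0, y = 1.2, z = 0.2,
                   aromatic = FALSE)
  out <- rbind(ring, ru)
  out$group <- "photosensitizer"
  out$chain <- "R"
  out
}

#' Generate a synthetic labeled trajectory
#'
#' Per frame, a target minimal donor-acceptor aromatic-atom distance is drawn
#' from the configured Gaussian mixture (truncated at the 2.0 Angstrom
#' hard-sphere floor) and realized exactly by rigid translation of the
#' photosensitizer group along the interface axis, followed by a random rigid
#' rotation of the photosensitizer about that axis (which preserves the
#' minimal distance). The first \code{equilibrationFrames} frames are placed
#' at \code{equilibrationDistance} instead, emulating conformations present
#' only at equilibration.
#'
#' The sampled ground-truth distances are stored in
#' \code{metadata(trajectory)$targetDistance} for recovery tests.
#'
#' @param config a \linkS4class{TrajectoryGeneratorConfig}.
#' @return a \linkS4class{Trajectory}.
#' @export
#' @examples
#' tr <- simulateTrajectory(trajectoryGeneratorConfig(nFrames = 100L))
simulateTrajectory <- function(config) {
  stopifnot(is(config, "TrajectoryGeneratorConfig"))
  validObject(config)
  set.seed(config@seed)

  heme <- .hemeTemplate()
  ps <- .photosensitizerTemplate()
  atomsTab <- rbind(
    data.frame(id = sprintf("H%02d", seq_len(nrow(heme))),
               heme[, c("name", "element", "group", "aromatic", "chain")]),
    data.frame(id = sprintf("R%02d", seq_len(nrow(ps))),
               ps[, c("name", "element", "group", "aromatic", "chain")])
  )
  rownames(atomsTab) <- NULL

  n <- config@nFrames
  nEq <- config@equilibrationFrames
  nProd <- n - nEq
  comp <- sample.int(length(config@modeDistances), nProd, replace = TRUE,
                     prob = config@modeWeights)
  d <- config@modeDistances[comp] + stats::rnorm(nProd, 0, config@jitterSigma)
  d <- pmax(d, 2.0 + 1e-6)                       # hard-sphere floor
  d <- c(rep(config@equilibrationDistance, nEq), d)
  theta <- stats::runif(n, 0, 2 * pi)

  hemeXYZ <- as.matrix(heme[, c("x", "y", "z")])
  psXYZ <- as.matrix(ps[, c("x", "y", "z")])
  nA <- nrow(hemeXYZ) + nrow(psXYZ)
  coords <- array(NA_real_, c(nA, 3L, n))
  for (i in seq_len(n)) {
    ct <- cos(theta[i]); st <- sin(theta[i])
    rot <- cbind(psXYZ[, 1],
                 ct * psXYZ[, 2] - st * psXYZ[, 3],
                 st * psXYZ[, 2] + ct * psXYZ[, 3])
    rot[, 1] <- rot[, 1] + d[i]
    coords[, , i] <- rbind(hemeXYZ, rot)
  }
  new("Trajectory", coords = coords, atoms = atomsTab,
      frameSpacing = config@frameSpacing,
      metadata = list(targetDistance = d,
                      equilibrationFrames = nEq,
                      seed = config@seed))
}

#' Trajectory metadata
#'
#' @param object a \linkS4class{Trajectory}.
#' @return the metadata list (generator ground truth, provenance).
#' @export
setGeneric("metadata", function(object) standardGeneric("metadata"))

#' @rdname metadata
setMethod("metadata", "Trajectory", function(object) object@metadata)
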