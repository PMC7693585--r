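#' @include AllClasses.R
NULL

#' Accessors for hemeET data classes
#'
#' Standard slot accessors. \code{delays} and \code{wavelengths} return the
#' grids of a \linkS4class{TADataset} or \linkS4class{KineticTrace};
#' \code{deltaA} the mOD matrix; \code{ddA} the 553-541 nm signal;
#' \code{chirpCoeffs} the time-zero polynomial; \code{provenance} the
#' correction history; \code{atoms} and \code{nFrames} the atom table and
#' frame count of a \linkS4class{Trajectory}; \code{frameCoords} one frame's
#' coordinate matrix; \code{binCenters}, \code{frequencies} and \code{modes}
#' the histogram content of a \linkS4class{DistanceDistribution};
#' \code{tauCS}/\code{tauCR} the fitted time constants of a
#' \linkS4class{KineticFit}.
#'
#' @param object an object of the documented classes.
#' @param ... unused.
#' @return the slot value (see details above).
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setGeneric("delays", function(object) standardGeneric("delays"))
#' @rdname accessors
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setGeneric("deltaA", function(object) standardGeneric("deltaA"))
#' @rdname accessors
#' @export
setGeneric("chirpCoeffs", function(object) standardGeneric("chirpCoeffs"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("ddA", function(object) standardGeneric("ddA"))
#' @rdname accessors
#' @export
setGeneric("uncertainty", function(object) standardGeneric("uncertainty"))
#' @rdname accessors
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameCoords", function(object, ...) standardGeneric("frameCoords"))
#' @rdname accessors
#' @export
setGeneric("binCenters", function(object) standardGeneric("binCenters"))
#' @rdname accessors
#' @export
setGeneric("frequencies", function(object) standardGeneric("frequencies"))
#' @rdname accessors
#' @export
setGeneric("modes", function(object) standardGeneric("modes"))
#' @rdname accessors
#' @export
setGeneric("tauCS", function(object) standardGeneric("tauCS"))
#' @rdname accessors
#' @export
setGeneric("tauCR", function(object) standardGeneric("tauCR"))

#' @rdname accessors
setMethod("delays", "TADataset", function(object) object@delays)
#' @rdname accessors
setMethod("wavelengths", "TADataset", function(object) object@wavelengths)
#' @rdname accessors
setMethod("deltaA", "TADataset", function(object) object@deltaA)
#' @rdname accessors
setMethod("chirpCoeffs", "TADataset", function(object) object@chirpCoeffs)
#' @rdname accessors
setMethod("provenance", "TADataset", function(object) object@provenance)

#' @rdname accessors
setMethod("delays", "KineticTrace", function(object) object@delays)
#' @rdname accessors
setMethod("ddA", "KineticTrace", function(object) object@ddA)
#' @rdname accessors
setMethod("uncertainty", "KineticTrace", function(object) object@sigma)
#' @rdname accessors
setMethod("provenance", "KineticTrace",
          function(object) object@correctionsApplied)

#' @rdname accessors
setMethod("atoms", "Trajectory", function(object) object@atoms)
#' @rdname accessors
setMethod("nFrames", "Trajectory", function(object) dim(object@coords)[3])
#' @param frame frame index (1-based).
#' @rdname accessors
setMethod("frameCoords", "Trajectory", function(object, frame = 1L) {
  object@coords[, , frame, drop = TRUE]
})

#' @rdname accessors
setMethod("binCenters", "DistanceDistribution", function(object) {
  e <- object@binEdges
  (e[-length(e)] + e[-1]) / 2
})
#' @rdname accessors
setMethod("frequencies", "DistanceDistribution",
          function(object) object@frequencies)
#' @rdname accessors
setMethod("modes", "DistanceDistribution", function(object) object@modes)
#' @rdname accessors
setMethod("nFrames", "DistanceDistribution", function(object) object@nFrames)

#' @rdname accessors
setMethod("tauCS", "KineticFit", function(object) object@tauCS)
#' @rdname accessors
setMethod("tauCR", "KineticFit", function(object) object@tauCR)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "TADataset", function(object) {
  cat(sprintf("TADataset: %d delays (%.3g .. %.3g ps) x %d wavelengths (%g .. %g nm)\n",
              length(object@delays), min(object@delays), max(object@delays),
              length(object@wavelengths), min(object@wavelengths),
              max(object@wavelengths)))
  if (length(object@chirpCoeffs))
    cat("  chirp coefficients:", signif(object@chirpCoeffs, 4), "\n")
  if (length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = " -> "), "\n")
})

setMethod("show", "KineticTrace", function(object) {
  cat(sprintf("KineticTrace (553-541 nm): %d points, %.3g .. %.3g ps\n",
              length(object@delays), min(object@delays), max(object@delays)))
  if (length(object@correctionsApplied))
    cat("  corrections:", paste(object@correctionsApplied, collapse = " -> "),
        "\n")
})

setMethod("show", "KineticFit", function(object) {
  cat(sprintf("KineticFit [%s]: tauCS = %.3g +/- %.2g ps, tauCR = %.3g +/- %.2g ps\n",
              object@scheme, object@tauCS, object@tauCSErr, object@tauCR,
              object@tauCRErr))
  cat(sprintf("  amplitude = %.3g mOD, t0 = %.3g ps, RSS = %.4g (n = %d)\n",
              object@amplitude, object@t0, object@rss, object@nPoints))
  if (object@kHH > 0)
    cat(sprintf("  heme-to-heme branch kHH = %.3g 1/ps\n", object@kHH))
  if (object@degenerate)
    cat("  note: rate-swap degeneracy — assignment follows the two-state convention\n")
})

setMethod("show", "MarcusParams", function(object) {
  cat(sprintf("MarcusParams: deltaG = %.4g eV, lambda = %.4g eV, T = %.5g K\n",
              object@deltaG, object@lambda, object@temperature))
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat(sprintf("Trajectory: %d frames x %d atoms (%d ps spacing)\n",
              d[3], d[1], object@frameSpacing))
  tab <- table(object@atoms$group, object@atoms$aromatic)
  cat("  groups (aromatic counts):\n")
  print(tab)
})

setMethod("show", "DistanceDistribution", function(object) {
  cat(sprintf("DistanceDistribution: %d frames, %d bins of 0.2 A\n",
              object@nFrames, length(object@frequencies)))
  cat("  modes (A):", paste(signif(object@modes, 3), collapse = ", "), "\n")
})

setMethod("show", "GuinierResult", function(object) {
  cat(sprintf("GuinierResult: Rg = %.3f A, I0 = %.4g, window q = [%.4g, %.4g] 1/A (n = %d)\n",
              object@rg, object@i0, object@qWindow[1], object@qWindow[2],
              object@nPointsUsed))
  if (object@upturn)
    cat("  low-q upturn detected (possible elongated form)\n")
})
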