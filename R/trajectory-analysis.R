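#' @include AllClasses.R synthetic-trajectory.R
NULL

## selections: logical index of aromatic atoms of each group
.aromaticSel <- function(traj, group) {
  a <- traj@atoms
  which(a$aromatic & a$group == group)
}

#' Minimal donor-acceptor distance in one frame
#'
#' Minimum Euclidean distance over all cross pairs between two atom
#' selections. \code{method = "brute"} is the O(n m) reference;
#' \code{method = "grid"} uses an exact spatial-hash acceleration (cell size
#' equal to a cheap upper bound on the minimum, so every candidate within
#' that bound is examined) and returns identical results.
#'
#' @param coords numeric nAtoms x 3 matrix of one frame (Angstrom).
#' @param selA,selB integer or logical atom indices; non-empty, disjoint
#'   use intended but not required.
#' @param method "brute" or "grid".
#' @return minimal distance (Angstrom).
#' @export
#' @examples
#' xyz <- rbind(c(0, 0, 0), c(3, 4, 0))
#' minDaDistance(xyz, 1, 2)  # 5
minDaDistance <- function(coords, selA, selB, method = c("brute", "grid")) {
  method <- match.arg(method)
  A <- coords[selA, , drop = FALSE]
  B <- coords[selB, , drop = FALSE]
  if (!nrow(A) || !nrow(B)) stop("empty atom selection")
  if (method == "brute") {
    d2min <- Inf
    for (i in seq_len(nrow(A))) {
      d2 <- (B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 + (B[, 3] - A[i, 3])^2
      d2min <- min(d2min, min(d2))
    }
    return(sqrt(d2min))
  }
  ## grid: upper bound from one A atom against all B, then hash B into cells
  ## of that size; the true nearest B of any A lies within the 27 neighbour
  ## cells, so the search is exact.
  d2ub <- min((B[, 1] - A[1, 1])^2 + (B[, 2] - A[1, 2])^2 +
                (B[, 3] - A[1, 3])^2)
  s <- sqrt(d2ub)
  if (s == 0) return(0)
  cellOf <- function(M) floor(M / s)
  cb <- cellOf(B)
  keyB <- paste(cb[, 1], cb[, 2], cb[, 3])
  idx <- split(seq_len(nrow(B)), keyB)
  d2min <- d2ub
  ca <- cellOf(A)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(nrow(A))) {
    keys <- paste(ca[i, 1] + offs[, 1], ca[i, 2] + offs[, 2],
                  ca[i, 3] + offs[, 3])
    cand <- unlist(idx[keys], use.names = FALSE)
    if (!length(cand)) next
    d2 <- (B[cand, 1] - A[i, 1])^2 + (B[cand, 2] - A[i, 2])^2 +
      (B[cand, 3] - A[i, 3])^2
    d2min <- min(d2min, min(d2))
  }
  sqrt(d2min)
}

#' Per-frame minimal aromatic donor-acceptor distance series
#'
#' Computes, for every frame, the minimal distance between the aromatic
#' photosensitizer atoms and the aromatic heme atoms. Vectorized over frames
#' pair-by-pair, which is algebraically identical to the per-frame brute
#' force.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @return numeric vector, one minimal distance (Angstrom) per frame.
#' @export
minDistanceSeries <- function(traj) {
  stopifnot(is(traj, "Trajectory"))
  selA <- .aromaticSel(traj, "photosensitizer")
  selB <- .aromaticSel(traj, "heme")
  if (!length(selA) || !length(selB)) stop("empty aromatic selection")
  co <- traj@coords
  n <- dim(co)[3]
  d2min <- rep(Inf, n)
  for (i in selA) {
    ai <- co[i, , , drop = TRUE]          # 3 x n
    for (j in selB) {
      bj <- co[j, , , drop = TRUE]
      d2 <- (ai[1, ] - bj[1, ])^2 + (ai[2, ] - bj[2, ])^2 +
        (ai[3, ] - bj[3, ])^2
      d2min <- pmin(d2min, d2)
    }
  }
  sqrt(d2min)
}

#' Binned minimal donor-acceptor distance distribution
#'
#' Histogram of per-frame minimal aromatic-atom distances on fixed
#' 0.2 Angstrom bins aligned at 0.0, with frequencies in percent of the
#' counted frames. Modes are local maxima of the binned frequencies whose
#' prominence (height above the higher flanking minimum) exceeds
#' \code{prominence} percentage points; each is reported as its bin center.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param excludeEquilibration number of initial frames to drop before
#'   binning; \code{NULL} (default) drops the generator-recorded
#'   equilibration frames if present, else the first 10% of frames.
#' @param prominence mode prominence threshold in percentage points,
#'   default 2.
#' @return a \linkS4class{DistanceDistribution}.
#' @export
distanceDistribution <- function(traj, excludeEquilibration = NULL,
                                 prominence = 2) {
  stopifnot(is(traj, "Trajectory"))
  n <- nFrames(traj)
  if (is.null(excludeEquilibration)) {
    excludeEquilibration <- traj@metadata$equilibrationFrames
    if (is.null(excludeEquilibration))
      excludeEquilibration <- floor(0.1 * n)
  }
  if (n - excludeEquilibration < 100)
    stop("fewer than 100 frames remain after equilibration exclusion")
  d <- minDistanceSeries(traj)
  d <- d[(excludeEquilibration + 1):n]
  edges <- seq(0, (floor(max(d) / 0.2) + 1) * 0.2, by = 0.2)
  counts <- graphics::hist(d, breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  freq <- 100 * counts / sum(counts)
  ## renormalize exactly (guards the sum-to-100 invariant against rounding)
  freq <- freq * (100 / sum(freq))
  centers <- (edges[-length(edges)] + edges[-1]) / 2
  modes <- .findModes(freq, centers, prominence)
  new("DistanceDistribution", binEdges = edges, frequencies = freq,
      nFrames = as.integer(length(d)), modes = modes)
}

## local maxima with a simple prominence rule
.findModes <- function(freq, centers, prominence) {
  nb <- length(freq)
  if (nb == 1L) return(centers)
  modes <- numeric(0)
  for (i in seq_len(nb)) {
    left <- if (i > 1) freq[i - 1] else -Inf
    right <- if (i < nb) freq[i + 1] else -Inf
    if (freq[i] > left && freq[i] >= right && freq[i] > 0) {
      ## prominence: drop to the higher of the two flanking valleys
      jl <- i; while (jl > 1 && freq[jl - 1] <= freq[jl]) jl <- jl - 1
      jr <- i; while (jr < nb && freq[jr + 1] <= freq[jr]) jr <- jr + 1
      base <- max(min(freq[jl:i]), min(freq[i:jr]))
      if (freq[i] - base >= prominence || (jl == 1 && jr == nb))
        modes <- c(modes, centers[i])
    }
  }
  if (!length(modes)) modes <- centers[which.max(freq)]
  modes
}

#' Per-atom shortest-distance map
#'
#' For each aromatic photosensitizer atom (row) and frame (column), the
#' shortest distance to any aromatic heme atom. Column-wise minima reproduce
#' \code{\link{minDistanceSeries}} exactly; the map localizes which
#' bipyridine atoms maintain contact, and conformational jumps show as steps
#' along the frame axis.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @return a \linkS4class{PerAtomDistanceMap}.
#' @export
perAtomMap <- function(traj) {
  stopifnot(is(traj, "Trajectory"))
  selA <- .aromaticSel(traj, "photosensitizer")
  selB <- .aromaticSel(traj, "heme")
  if (!length(selA) || !length(selB)) stop("empty aromatic selection")
  co <- traj@coords
  n <- dim(co)[3]
  m <- matrix(Inf, length(selA), n)
  for (r in seq_along(selA)) {
    ai <- co[selA[r], , , drop = TRUE]
    for (j in selB) {
      bj <- co[j, , , drop = TRUE]
      d2 <- (ai[1, ] - bj[1, ])^2 + (ai[2, ] - bj[2, ])^2 +
        (ai[3, ] - bj[3, ])^2
      m[r, ] <- pmin(m[r, ], d2)
    }
  }
  new("PerAtomDistanceMap", distances = sqrt(m),
      atomIds = traj@atoms$id[selA])
}

#' Fraction of frames in van der Waals contact
#'
#' Fraction of post-equilibration frames whose minimal aromatic
#' donor-acceptor distance is at or below \code{cutoff} — the geometric
#' condition associated with sub-nanosecond electron transfer.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param cutoff contact cutoff (Angstrom), default 4.0 (typical
#'   aromatic-carbon van der Waals contact).
#' @param excludeEquilibration as in \code{\link{distanceDistribution}}.
#' @return fraction in [0, 1].
#' @export
vdwContactFraction <- function(traj, cutoff = 4.0,
                               excludeEquilibration = NULL) {
  stopifnot(cutoff > 0)
  n <- nFrames(traj)
  if (is.null(excludeEquilibration)) {
    excludeEquilibration <- traj@metadata$equilibrationFrames
    if (is.null(excludeEquilibration))
      excludeEquilibration <- floor(0.1 * n)
  }
  d <- minDistanceSeries(traj)
  d <- d[(excludeEquilibration + 1):n]
  mean(d <= cutoff)
}

#' Summary statistics of a distance distribution
#'
#' Mean, SD, interquartile range and mode list of the binned minimal-distance
#' distribution — the quantities used to argue photosensitizer mobility
#' versus steric restriction (broad and long-distance distributions indicate
#' a mobile, weakly coupled photosensitizer).
#'
#' @param dist a \linkS4class{DistanceDistribution}.
#' @return list with \code{mean}, \code{sd}, \code{iqr} (all Angstrom),
#'   \code{modes}.
#' @export
distributionWidthReport <- function(dist) {
  stopifnot(is(dist, "DistanceDistribution"))
  p <- dist@frequencies / 100
  x <- binCenters(dist)
  mu <- sum(p * x)
  sdv <- sqrt(sum(p * (x - mu)^2))
  cdf <- cumsum(p)
  qf <- function(q) {
    i <- which(cdf >= q)[1]
    x[i]
  }
  list(mean = mu, sd = sdv, iqr = qf(0.75) - qf(0.25), modes = dist@modes)
}
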