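#' @include AllClasses.R synthetic-trajectory.R
NULL

## Group/aromatic conventions for PDB trajectories (documented in README):
##  - chain R = photosensitizer, chain H = heme;
##  - ring (aromatic) atoms are carbons/nitrogens whose names do NOT start
##    with "CM" (methyl/substituent); FE, RU, S are never aromatic.
.defaultGroupMap <- function(chain, name, element) {
  group <- ifelse(chain == "R", "photosensitizer",
                  ifelse(chain == "H", "heme", NA_character_))
  aromatic <- element %in% c("C", "N") & !startsWith(name, "CM")
  data.frame(group = group, aromatic = aromatic)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, written through bio3d. Group labels go
#' in the chain ID (R = photosensitizer, H = heme) and aromatic flags follow
#' the atom-name convention: C*/N* names are ring (aromatic) atoms unless the
#' name starts with "CM"; FE/RU are not aromatic. PDB coordinate precision is
#' 1e-3 Angstrom, which bounds the round-trip error.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  a <- traj@atoms
  n <- nFrames(traj)
  xyz <- t(apply(traj@coords, 3, function(fr) as.vector(t(fr))))
  if (n == 1L) xyz <- matrix(xyz, nrow = 1)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    tmp <- tempfile(fileext = ".pdb")
    bio3d::write.pdb(file = tmp,
                     xyz = xyz[f, ],
                     type = rep("HETATM", nrow(a)),
                     resno = as.integer(factor(a$group)),
                     resid = ifelse(a$group == "heme", "HEM", "RUB"),
                     eleno = seq_len(nrow(a)),
                     elety = a$name,
                     chain = a$chain,
                     elesy = a$element,
                     end = FALSE)
    writeLines(readLines(tmp), con)
    unlink(tmp)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a labeled trajectory from multi-model PDB or XYZ
#'
#' PDB files are parsed with bio3d (\code{read.pdb(multi = TRUE)}) after a
#' structural sanity check that every MODEL record has a matching ENDMDL.
#' XYZ files (frame blocks of "n / comment / element x y z") require a
#' sidecar JSON group map (array of \{name, group, aromatic\} or per-atom
#' entries). Every atom must be assigned a group and aromatic flag; unmapped
#' atoms are an explicit error listing their identifiers.
#'
#' @param path input file.
#' @param format "pdb" or "xyz".
#' @param groupMap for "pdb": optional data.frame with columns \code{group},
#'   \code{aromatic} (one row per atom) overriding the chain/name convention;
#'   for "xyz": path to the sidecar JSON (default \code{paste0(path,
#'   ".json")}).
#' @param frameSpacing ps between frames (metadata), default 10.
#' @return a \linkS4class{Trajectory}.
#' @export
readTrajectory <- function(path, format = c("pdb", "xyz"), groupMap = NULL,
                           frameSpacing = 10) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") .readTrajectoryPDB(path, groupMap, frameSpacing)
  else .readTrajectoryXYZ(path, groupMap, frameSpacing)
}

.readTrajectoryPDB <- function(path, groupMap, frameSpacing) {
  lines <- readLines(path)
  nModel <- sum(startsWith(lines, "MODEL"))
  nEnd <- sum(startsWith(lines, "ENDMDL"))
  if (nModel != nEnd)
    stop("malformed multi-model PDB: ", nModel, " MODEL vs ", nEnd,
         " ENDMDL records")
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  nA <- nrow(at)
  xyz <- pdb$xyz                       # nFrames x 3 nA
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n <- nrow(xyz)
  if (ncol(xyz) != 3 * nA)
    stop("inconsistent atom counts across models")
  coords <- array(NA_real_, c(nA, 3L, n))
  for (f in seq_len(n))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(at$elety), 1, 1)
  elem <- trimws(elem)
  if (is.null(groupMap))
    groupMap <- .defaultGroupMap(trimws(at$chain), trimws(at$elety), elem)
  if (nrow(groupMap) != nA)
    stop("group map must have one row per atom")
  if (any(is.na(groupMap$group))) {
    bad <- which(is.na(groupMap$group))
    stop("unmapped atoms (no group): indices ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  }
  atomsTab <- data.frame(
    id = sprintf("%s%02d", trimws(at$chain), stats::ave(
      seq_len(nA), trimws(at$chain), FUN = seq_along)),
    name = trimws(at$elety), element = elem,
    group = groupMap$group, aromatic = groupMap$aromatic,
    chain = trimws(at$chain))
  new("Trajectory", coords = coords, atoms = atomsTab,
      frameSpacing = frameSpacing,
      metadata = list(source = path, format = "pdb"))
}

.readTrajectoryXYZ <- function(path, groupMap, frameSpacing) {
  if (is.null(groupMap)) groupMap <- paste0(path, ".json")
  if (!file.exists(groupMap))
    stop("XYZ trajectories need a sidecar JSON group map; not found: ",
         groupMap)
  gm <- jsonlite::fromJSON(groupMap)
  lines <- readLines(path)
  nA <- as.integer(lines[1])
  if (is.na(nA) || nA < 1) stop("malformed XYZ: bad atom count header")
  blk <- nA + 2L
  if (length(lines) %% blk != 0)
    stop("malformed XYZ: file length is not a multiple of the frame block")
  n <- length(lines) %/% blk
  if (nrow(gm) != nA) stop("group map must have one row per atom")
  if (any(is.na(gm$group)))
    stop("unmapped atoms (no group): indices ",
         paste(which(is.na(gm$group)), collapse = ", "))
  coords <- array(NA_real_, c(nA, 3L, n))
  elem <- character(nA)
  for (f in seq_len(n)) {
    rows <- lines[((f - 1) * blk + 3):((f - 1) * blk + 2 + nA)]
    parts <- do.call(rbind, strsplit(trimws(rows), "\\s+"))
    if (f == 1L) elem <- parts[, 1]
    coords[, , f] <- apply(parts[, 2:4, drop = FALSE], 2, as.numeric)
  }
  atomsTab <- data.frame(
    id = if (!is.null(gm$id)) gm$id else sprintf("A%03d", seq_len(nA)),
    name = if (!is.null(gm$name)) gm$name else elem,
    element = elem, group = gm$group, aromatic = gm$aromatic,
    chain = ifelse(gm$group == "photosensitizer", "R", "H"))
  new("Trajectory", coords = coords, atoms = atomsTab,
      frameSpacing = frameSpacing,
      metadata = list(source = path, format = "xyz"))
}

#' Write a trajectory as XYZ plus a JSON group map
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param path output .xyz file; the sidecar map goes to
#'   \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
writeTrajectoryXYZ <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  a <- traj@atoms
  n <- nFrames(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n)) {
    writeLines(c(as.character(nrow(a)), sprintf("frame %d", f)), con)
    fr <- traj@coords[, , f]
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", a$element,
                       fr[, 1], fr[, 2], fr[, 3]), con)
  }
  jsonlite::write_json(
    a[, c("id", "name", "group", "aromatic")],
    paste0(path, ".json"))
  invisible(path)
}

#' Write a distance distribution as TSV
#'
#' Long format: \code{bin_center} (Angstrom), \code{frequency_percent}.
#'
#' @param dist a \linkS4class{DistanceDistribution}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDistanceDistribution <- function(dist, path) {
  utils::write.table(
    data.frame(bin_center = binCenters(dist),
               frequency_percent = dist@frequencies),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
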