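#' @include AllClasses.R
NULL

#' Write a TA dataset as TSV
#'
#' First row: "delay_ps" followed by the wavelengths (nm); first column:
#' delays (ps). Values are written at full double precision (17 significant
#' digits), so the round trip is lossless.
#'
#' @param ds a \linkS4class{TADataset}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTADataset <- function(ds, path) {
  stopifnot(is(ds, "TADataset"))
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  writeLines(paste(c("delay_ps", fmt(ds@wavelengths)), collapse = "\t"), con)
  for (i in seq_along(ds@delays))
    writeLines(paste(c(fmt(ds@delays[i]), fmt(ds@deltaA[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a TA dataset from TSV
#'
#' @param path file written by \code{\link{writeTADataset}} (first row
#'   wavelengths, first column delays).
#' @return a \linkS4class{TADataset}.
#' @export
readTADataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t",
                                   skip = 1))
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  wl <- as.numeric(hdr[-1])
  TADataset(delays = m[, 1], wavelengths = wl,
            deltaA = unname(m[, -1, drop = FALSE]),
            provenance = sprintf("read from %s", basename(path)))
}

#' Write a kinetic trace as TSV
#'
#' Columns: delay_ps, ddA_mOD, sigma_mOD (sigma omitted when absent).
#'
#' @param trace a \linkS4class{KineticTrace}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeKineticTrace <- function(trace, path) {
  stopifnot(is(trace, "KineticTrace"))
  df <- data.frame(delay_ps = trace@delays, ddA_mOD = trace@ddA)
  if (length(trace@sigma)) df$sigma_mOD <- trace@sigma
  utils::write.table(format(df, digits = 17), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a kinetic trace from TSV
#'
#' @param path file with columns delay_ps, ddA_mOD and optional sigma_mOD.
#' @return a \linkS4class{KineticTrace}.
#' @export
readKineticTrace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  kineticTrace(df$delay_ps, df$ddA_mOD,
               sigma = if ("sigma_mOD" %in% names(df)) df$sigma_mOD
                       else numeric(0))
}
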