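#' @include AllClasses.R synthetic-ta.R ta-processing.R kinetics.R marcus.R
#' @include synthetic-trajectory.R trajectory-analysis.R trajectory-io.R
#' @include characterization.R io-ta.R
NULL

#' Run the full simulate-correct-fit-analyze pipeline
#'
#' Executes the toggled stages of a reproducible end-to-end run:
#' \enumerate{
#'   \item \strong{ta}: simulate a chirped, artifact-laden TA matrix and a
#'     heme-excited-state reference; estimate and remove the chirp; subtract
#'     the scaled reference; extract the 553-541 nm trace; fit the two-state
#'     scheme.
#'   \item \strong{marcus}: evaluate the fold-change for a stated
#'     midpoint-potential shift and the shift needed for a stated fold.
#'   \item \strong{trajectory}: simulate a labeled trajectory and compute the
#'     0.2 Angstrom binned minimal-distance distribution.
#'   \item \strong{guinier}: simulate and refit a Guinier profile.
#'   \item \strong{titration}: simulate and refit a three-heme titration.
#' }
#' All stage outputs are written under \code{outDir} and hashed into a
#' manifest (JSON) carrying the package version, seeds, per-stage parameters
#' and MD5 sums; rerunning with the same config reproduces the outputs
#' bit-for-bit because every stochastic stage is seed-pinned.
#'
#' @param config a named list, or path to a JSON file with the same
#'   structure. Recognized top-level entries: \code{outDir} (required),
#'   \code{seed} (default 1), \code{stages} (character subset of
#'   \code{c("ta", "marcus", "trajectory", "guinier", "titration")}), and
#'   per-stage parameter blocks \code{ta} (fields of
#'   \code{\link{taGeneratorConfig}} plus \code{chirp}: "auto", "none" or
#'   coefficients), \code{marcus} (\code{lambda}, \code{deltaG},
#'   \code{shift}, \code{fold}), \code{trajectory} (fields of
#'   \code{\link{trajectoryGeneratorConfig}}), \code{guinier} (\code{rg},
#'   \code{noiseRel}), \code{titration} (\code{emList}, \code{shift},
#'   \code{noiseSigma}).
#' @return the manifest, invisibly (also written to
#'   \code{outDir/manifest.json}).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (is.null(config$outDir)) stop("config$outDir is required")
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- if (is.null(config$stages))
    c("ta", "marcus", "trajectory", "guinier", "titration")
  else config$stages

  manifest <- list(package = "hemeET",
                   version = as.character(utils::packageVersion("hemeET")),
                   seed = seed, stages = stages, outputs = list())
  addOut <- function(stage, name, path) {
    manifest$outputs[[stage]][[name]] <<- list(
      path = path, md5 = unname(tools::md5sum(path)))
  }
  t0 <- Sys.time()
  logStage <- function(stage)
    message(sprintf("[%s] seed=%d elapsed=%.1fs", stage, seed,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))

  if ("ta" %in% stages) {
    pars <- config$ta
    cfgArgs <- pars[names(pars) %in% names(formals(taGeneratorConfig))]
    cfg <- do.call(taGeneratorConfig, c(cfgArgs, list(seed = seed)))
    ds <- simulateTADataset(cfg)
    ref <- simulateReferenceDataset(cfg)
    writeTADataset(ds, file.path(outDir, "ta_raw.tsv"))
    chirpMode <- if (is.null(pars$chirp)) "auto" else pars$chirp
    if (identical(chirpMode, "auto")) {
      est <- estimateChirp(ds)
      ds <- dechirp(ds, est$coeffs)
      ref <- dechirp(ref, est$coeffs)
    } else if (!identical(chirpMode, "none")) {
      ds <- dechirp(ds, as.numeric(chirpMode))
      ref <- dechirp(ref, as.numeric(chirpMode))
    }
    if (cfg@hemeESAmp != 0)
      ds <- subtractReference(ds, ref, scale = "fit",
                              fitWindow = c(500, 540))
    writeTADataset(ds, file.path(outDir, "ta_corrected.tsv"))
    trace <- extractTrace(ds)
    writeKineticTrace(trace, file.path(outDir, "trace.tsv"))
    fit <- fitBiexponential(trace, "two_state", irfFWHM = cfg@irfFWHM)
    fitJSON <- list(tau_cs = fit@tauCS, tau_cr = fit@tauCR,
                    tau_cs_err = fit@tauCSErr, tau_cr_err = fit@tauCRErr,
                    amplitude = fit@amplitude, t0 = fit@t0,
                    scheme = fit@scheme, rss = fit@rss,
                    n_points = fit@nPoints, degenerate = fit@degenerate,
                    cs_cr_ratio = as.numeric(csCrRatio(fit)))
    jsonlite::write_json(fitJSON, file.path(outDir, "fit.json"),
                         auto_unbox = TRUE, digits = NA)
    addOut("ta", "raw", file.path(outDir, "ta_raw.tsv"))
    addOut("ta", "corrected", file.path(outDir, "ta_corrected.tsv"))
    addOut("ta", "trace", file.path(outDir, "trace.tsv"))
    addOut("ta", "fit", file.path(outDir, "fit.json"))
    logStage("ta")
  }

  if ("marcus" %in% stages) {
    pars <- config$marcus
    lambda <- if (is.null(pars$lambda)) 0.85 else pars$lambda
    dg <- if (is.null(pars$deltaG)) "apex" else pars$deltaG
    shift <- if (is.null(pars$shift)) 0.04 else pars$shift
    fold <- if (is.null(pars$fold)) 1000 else pars$fold
    mp <- marcusParams(dg, lambda = lambda)
    rep <- list(lambda_eV = lambda, deltaG_eV = mp@deltaG,
                shift_eV = shift,
                fold_change_for_shift = foldChangeForShift(shift, mp),
                fold = fold,
                shift_for_fold_eV = shiftForFoldChange(fold, mp))
    jsonlite::write_json(rep, file.path(outDir, "marcus.json"),
                         auto_unbox = TRUE, digits = NA)
    addOut("marcus", "report", file.path(outDir, "marcus.json"))
    logStage("marcus")
  }

  if ("trajectory" %in% stages) {
    pars <- config$trajectory
    cfgArgs <- pars[names(pars) %in% names(formals(trajectoryGeneratorConfig))]
    cfg <- do.call(trajectoryGeneratorConfig, c(cfgArgs, list(seed = seed)))
    tr <- simulateTrajectory(cfg)
    dd <- distanceDistribution(tr)
    writeDistanceDistribution(dd, file.path(outDir, "distance_distribution.tsv"))
    addOut("trajectory", "distribution",
           file.path(outDir, "distance_distribution.tsv"))
    logStage("trajectory")
  }

  if ("guinier" %in% stages) {
    pars <- config$guinier
    rg <- if (is.null(pars$rg)) 14 else pars$rg
    noiseRel <- if (is.null(pars$noiseRel)) 0.01 else pars$noiseRel
    pr <- simulateGuinierProfile(rg, noiseRel = noiseRel, seed = seed)
    gf <- guinierFit(pr)
    rep <- list(rg_true = rg, rg_fit = gf@rg, i0 = gf@i0,
                q_window = gf@qWindow, upturn = gf@upturn)
    jsonlite::write_json(rep, file.path(outDir, "guinier.json"),
                         auto_unbox = TRUE, digits = NA)
    addOut("guinier", "report", file.path(outDir, "guinier.json"))
    logStage("guinier")
  }

  if ("titration" %in% stages) {
    pars <- config$titration
    em <- if (is.null(pars$emList)) c(-180, -150, -120) else pars$emList
    noise <- if (is.null(pars$noiseSigma)) 0.02 else pars$noiseSigma
    tc <- simulateTitration(em, noiseSigma = noise, seed = seed)
    nf <- nernstFit(tc, nHemes = length(em))
    rep <- list(em_true = em, apparent_em = nf$apparentEm,
                em_fit = nf$emValues, rss = nf$rss)
    jsonlite::write_json(rep, file.path(outDir, "titration.json"),
                         auto_unbox = TRUE, digits = NA)
    addOut("titration", "report", file.path(outDir, "titration.json"))
    logStage("titration")
  }

  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
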