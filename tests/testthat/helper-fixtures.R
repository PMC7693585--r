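# Shared fixtures: small, fast configurations used across test files.

# artifact-free picosecond-scale generator config
cleanTAConfig <- function(..., seed = 1L) {
  taGeneratorConfig(noiseSigma = 0, solventAmp = 0, hemeESAmp = 0,
                    ampRu = 0, chirpCoeffs = 0, seed = seed, ...)
}

# nanosecond-scale delay grid for slow-construct datasets (pre-pulse block,
# then log-spaced 0.5 ps .. 500 ns)
nsDelayGrid <- function() {
  c(seq(-1000, -100, by = 100), -50, -10, -2,
    exp(seq(log(0.5), log(5e5), length.out = 150)))
}

# full simulate -> correct -> fit protocol for picosecond-scale constructs
recoverTauCS_ps <- function(seed, tauCS, tauCR) {
  cfg <- taGeneratorConfig(tauCS = tauCS, tauCR = tauCR, seed = seed)
  ds <- simulateTADataset(cfg)
  ref <- simulateReferenceDataset(cfg)
  est <- estimateChirp(ds)
  ds <- dechirp(ds, est$coeffs)
  ref <- dechirp(ref, est$coeffs)
  ds <- subtractReference(ds, ref, scale = "fit", fitWindow = c(500, 540))
  fit <- fitBiexponential(extractTrace(ds), "two_state", irfFWHM = cfg@irfFWHM)
  tauCS(fit)
}

# same protocol on the nanosecond grid (no chirp correction needed: the
# ~0.3 ps sweep is far below the grid resolution)
recoverTauCS_ns <- function(seed, tauCS, tauCR) {
  cfg <- taGeneratorConfig(delayGrid = nsDelayGrid(), tauCS = tauCS,
                           tauCR = tauCR, seed = seed)
  ds <- simulateTADataset(cfg)
  ref <- simulateReferenceDataset(cfg)
  ds <- subtractReference(ds, ref, scale = "fit", fitWindow = c(500, 540))
  fit <- fitBiexponential(extractTrace(ds), "two_state", irfFWHM = cfg@irfFWHM)
  tauCS(fit)
}

aromaticSelections <- function(traj) {
  a <- atoms(traj)
  list(ps = which(a$aromatic & a$group == "photosensitizer"),
       heme = which(a$aromatic & a$group == "heme"))
}
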