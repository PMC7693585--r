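test_that("chirp is recovered from generator ground truth", {
  # artifact-free config: onsets are IRF-limited at every usable wavelength
  cfg <- taGeneratorConfig(seed = 2L, noiseSigma = 0.01, solventAmp = 0)
  ds <- simulateTADataset(cfg)
  est <- estimateChirp(ds)
  truth <- chirpT0(wavelengths(ds), cfg@chirpCoeffs)
  expect_lt(sqrt(mean((est$t0 - truth)^2)), 0.02)
})

test_that("zero-chirp data yield a flat time-zero estimate", {
  cfg <- taGeneratorConfig(seed = 1L, noiseSigma = 0.01, solventAmp = 0,
                           chirpCoeffs = 0)
  est <- estimateChirp(simulateTADataset(cfg))
  expect_lt(diff(range(est$t0)), 0.02)
})

test_that("chirp estimation fails loudly on featureless data", {
  cfg <- taGeneratorConfig(seed = 1L, ampHeme = 0, ampRu = 0, hemeESAmp = 0,
                           solventAmp = 0, noiseSigma = 0.02)
  expect_error(estimateChirp(simulateTADataset(cfg)), "no onset detectable")
})

test_that("dechirp round-trips against a zero-chirp generation", {
  cc <- c(0.05, 1.2e-3, 4e-6)
  cfgC <- cleanTAConfig(seed = 1L)
  cfgC@chirpCoeffs <- cc
  cfg0 <- cleanTAConfig(seed = 1L)
  trC <- extractTrace(dechirp(simulateTADataset(cfgC), cc), noiseSigma = 1e-9)
  tr0 <- extractTrace(simulateTADataset(cfg0), noiseSigma = 1e-9)
  # interpolation tolerance relative to the 1 mOD generator band amplitude
  expect_lt(max(abs(ddA(trC) - ddA(tr0))), 1e-3 * cfg0@ampHeme)
})

test_that("dechirp with zero coefficients is the identity", {
  ds <- simulateTADataset(taGeneratorConfig(seed = 4L))
  out <- dechirp(ds, 0)
  expect_identical(deltaA(out), deltaA(ds))
  expect_match(tail(provenance(out), 1), "dechirp")
})

test_that("dechirp with c then -c is the identity within interpolation error", {
  cc <- c(0, 1.2e-3, 4e-6)
  # dense uniform grid so the double-interpolation error stays at the
  # round-off level of linear interpolation
  # 0.01 ps steps: fine enough that linear interpolation resolves the
  # 0.17 ps FWHM instrument-response rise
  ds <- simulateTADataset(taGeneratorConfig(
    delayGrid = seq(-3, 15, by = 0.01), noiseSigma = 0, solventAmp = 0,
    hemeESAmp = 0, chirpCoeffs = 0, seed = 1L))
  back <- dechirp(dechirp(ds, cc), -cc)
  amp <- max(abs(deltaA(ds)))
  # compare away from grid edges where shifted points were held
  inner <- delays(ds) > -2 & delays(ds) < 14
  expect_lt(max(abs(deltaA(back)[inner, ] - deltaA(ds)[inner, ])), 2e-3 * amp)
})

test_that("dechirp refuses shifts beyond half the delay range", {
  ds <- simulateTADataset(taGeneratorConfig(seed = 1L))
  expect_error(dechirp(ds, 1e4), "half the delay range")
})

test_that("reference subtraction recovers a constructed mixing scale", {
  cfg <- taGeneratorConfig(seed = 6L, noiseSigma = 0.005)
  # signal: heme band only; contaminant: scaled reference with its own noise
  sigCfg <- cfg; sigCfg@ampRu <- 0; sigCfg@hemeESAmp <- 0; sigCfg@solventAmp <- 0
  sig <- simulateTADataset(sigCfg)
  ref <- simulateReferenceDataset(cfg)
  mixed <- TADataset(delays(sig), wavelengths(sig),
                     deltaA(sig) + 0.7 * deltaA(ref))
  refMeas <- simulateReferenceDataset(cfg, seed = 77L)
  out <- subtractReference(mixed, refMeas, scale = "fit")
  expect_equal(attr(out, "scale"), 0.70, tolerance = 0.02)
  # residual no longer carries the reference signature
  resScale <- attr(subtractReference(out, refMeas, scale = "fit"), "scale")
  expect_lt(abs(resScale), 0.02)
})

test_that("reference subtraction degenerate cases behave", {
  ds <- simulateTADataset(taGeneratorConfig(seed = 1L))
  zero <- TADataset(delays(ds), wavelengths(ds),
                    matrix(0, length(delays(ds)), length(wavelengths(ds))))
  expect_error(subtractReference(ds, zero, scale = "fit"), "singular")
  out <- subtractReference(ds, zero, scale = 0)
  expect_identical(deltaA(out), deltaA(ds))
  other <- simulateTADataset(taGeneratorConfig(
    seed = 1L, wavelengthGrid = seq(500, 752, by = 2)))
  expect_error(subtractReference(ds, other, scale = 1), "grids differ")
})

test_that("trace extraction nulls spectrally flat datasets", {
  t <- seq(-2, 10, by = 0.5)
  wl <- seq(500, 700, by = 5)
  flat <- TADataset(t, wl, matrix(rep(exp(-pmax(t, 0)), length(wl)),
                                  ncol = length(wl)))
  tr <- extractTrace(flat, noiseSigma = 1e-9)
  expect_true(all(abs(ddA(tr)) < 1e-12))
})

test_that("pre-pulse trace points are consistent with noise statistics", {
  frac <- sapply(1:20, function(s) {
    ds <- simulateTADataset(taGeneratorConfig(seed = s))
    tr <- extractTrace(ds, noiseSigma = 0.02)
    pre <- delays(tr) <= -1
    mean(abs(ddA(tr)[pre]) < 3 * uncertainty(tr)[pre])
  })
  expect_gte(mean(frac), 0.99)
})

test_that("prepulse check passes clean data and flags persistent offsets", {
  ds <- simulateTADataset(taGeneratorConfig(seed = 8L))
  expect_true(prepulseCheck(ds)$pass)

  # inject a persistent offset well above noise
  m <- deltaA(ds) + 5 * 0.02 / sqrt(length(wavelengths(ds)))
  bad <- TADataset(delays(ds), wavelengths(ds), m)
  expect_false(prepulseCheck(bad)$pass)

  noiseOnly <- simulateTADataset(taGeneratorConfig(
    seed = 9L, ampHeme = 0, ampRu = 0, hemeESAmp = 0, solventAmp = 0))
  expect_true(prepulseCheck(noiseOnly)$pass)

  short <- TADataset(seq(0, 5), seq(500, 760, by = 20),
                     matrix(0, 6, 14))
  expect_error(prepulseCheck(short), "pre-pulse")
})

test_that("corrections append provenance entries", {
  cfg <- taGeneratorConfig(seed = 2L)
  ds <- simulateTADataset(cfg)
  ref <- simulateReferenceDataset(cfg)
  out <- subtractReference(dechirp(ds, cfg@chirpCoeffs),
                           dechirp(ref, cfg@chirpCoeffs), scale = "fit")
  pv <- provenance(out)
  expect_match(pv[length(pv) - 1], "dechirp")
  expect_match(pv[length(pv)], "subtractReference")
  tr <- extractTrace(out)
  expect_identical(provenance(tr), pv)
})

test_that("TA TSV round trip is lossless", {
  ds <- simulateTADataset(taGeneratorConfig(seed = 5L))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTADataset(ds, path)
  back <- readTADataset(path)
  expect_equal(delays(back), delays(ds), tolerance = 1e-15)
  expect_equal(wavelengths(back), wavelengths(ds), tolerance = 1e-15)
  expect_equal(deltaA(back), deltaA(ds), tolerance = 1e-15)
})
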