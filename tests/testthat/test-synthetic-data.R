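test_that("null configuration produces an all-zero matrix", {
  cfg <- taGeneratorConfig(noiseSigma = 0, ampHeme = 0, ampRu = 0,
                           solventAmp = 0, hemeESAmp = 0)
  ds <- simulateTADataset(cfg)
  expect_true(all(deltaA(ds) == 0))
})

test_that("noiseless artifact-free trace equals the closed-form two-state curve", {
  cfg <- cleanTAConfig(tauCS = 2.3, tauCR = 5.9)
  ds <- simulateTADataset(cfg)
  tr <- extractTrace(ds, noiseSigma = 1e-12)
  p <- schemeParams(tauCS = 2.3, tauCR = 5.9, irfFWHM = cfg@irfFWHM)
  model <- twoStateSignal(delays(tr), p)
  # the trace is proportional to B(t): amplitude reflects the interpolated
  # band shape at the 553/541 grid neighbours
  scale <- sum(model * ddA(tr)) / sum(model^2)
  expect_lt(max(abs(ddA(tr) - scale * model)), 1e-12)
})

test_that("pre-pulse rows carry noise only", {
  for (s in 1:5) {
    cfg <- taGeneratorConfig(seed = s)
    ds <- simulateTADataset(cfg)
    pre <- delays(ds) <= -1
    m <- deltaA(ds)[pre, ]
    expect_lt(mean(abs(colMeans(m))),
              3 * cfg@noiseSigma / sqrt(sum(pre)) * 3)
    expect_lt(abs(mean(m)), 3 * cfg@noiseSigma / sqrt(length(m)))
  }
})

test_that("TA generation is deterministic given the seed", {
  a <- simulateTADataset(taGeneratorConfig(seed = 42L))
  b <- simulateTADataset(taGeneratorConfig(seed = 42L))
  expect_identical(deltaA(a), deltaA(b))
  c <- simulateTADataset(taGeneratorConfig(seed = 43L))
  expect_false(identical(deltaA(a), deltaA(c)))
})

test_that("generator config invariants are enforced", {
  expect_error(taGeneratorConfig(tauCS = -1), "positive")
  expect_error(taGeneratorConfig(delayGrid = seq(0, 10)), "pre-pulse")
  expect_error(taGeneratorConfig(wavelengthGrid = seq(560, 700, 2)),
               "span")
  expect_error(taGeneratorConfig(delayGrid = c(-2, 1, 0.5)), "increasing")
})

test_that("trajectory frames realize the sampled target distances exactly", {
  cfg <- trajectoryGeneratorConfig(nFrames = 500L, jitterSigma = 0.2,
                                   seed = 3L)
  tr <- simulateTrajectory(cfg)
  d <- minDistanceSeries(tr)
  expect_lt(max(abs(d - metadata(tr)$targetDistance)), 1e-6)
})

test_that("zero-jitter single-mode trajectories are degenerate at the mode", {
  tr <- simulateTrajectory(trajectoryGeneratorConfig(
    nFrames = 150L, modeDistances = 6.6, jitterSigma = 0))
  expect_lt(max(abs(minDistanceSeries(tr) - 6.6)), 1e-6)
})

test_that("trajectory generator validates weights and the hard-sphere floor", {
  expect_error(trajectoryGeneratorConfig(modeDistances = c(3.8, 4.9),
                                         modeWeights = c(0.6, 0.6)),
               "sum to 1")
  expect_error(trajectoryGeneratorConfig(modeDistances = 1.5), "hard-sphere")
})

test_that("equilibration frames sit at the displaced distance", {
  cfg <- trajectoryGeneratorConfig(nFrames = 300L, modeDistances = 4.9,
                                   jitterSigma = 0.05,
                                   equilibrationFrames = 50L,
                                   equilibrationDistance = 3.8, seed = 2L)
  tr <- simulateTrajectory(cfg)
  d <- minDistanceSeries(tr)
  expect_true(all(abs(d[1:50] - 3.8) < 1e-6))
  expect_true(all(d[51:300] > 4.5))
})

test_that("Guinier generator follows the closed form and sphere identity", {
  pr <- simulateGuinierProfile(rg = 14, i0 = 2, noiseRel = 0)
  lnI <- log(pr@intensity)
  fit <- lm(lnI ~ I(pr@q^2))
  expect_equal(unname(coef(fit)[2]), -14^2 / 3, tolerance = 1e-10)
  expect_equal(exp(unname(coef(fit)[1])), 2, tolerance = 1e-10)
  # sphere identity: caller supplies rg = sqrt(3/5) R
  r <- 18.07
  expect_equal(sqrt(3 / 5) * r, 14.0, tolerance = 1e-3)
  expect_error(simulateGuinierProfile(rg = -3), "positive")
})

test_that("titration generator obeys the Nernst midpoint and degeneracies", {
  tc <- simulateTitration(0, noiseSigma = 0)
  at0 <- approx(tc@potential, tc@fractionReduced, xout = 0)$y
  expect_equal(at0, 0.5, tolerance = 1e-9)
  # three equal midpoints collapse to the single-heme curve
  t3 <- simulateTitration(c(-150, -150, -150), noiseSigma = 0)
  t1 <- simulateTitration(-150, noiseSigma = 0)
  expect_equal(t3@fractionReduced, t1@fractionReduced, tolerance = 1e-12)
  expect_error(simulateTitration(numeric(0)), "non-empty")
})
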