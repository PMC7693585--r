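test_that("Guinier fit is exact on noiseless profiles", {
  g <- guinierFit(simulateGuinierProfile(rg = 14, i0 = 3, noiseRel = 0))
  expect_equal(g@rg, 14, tolerance = 1e-6)
  expect_equal(g@i0, 3, tolerance = 1e-6)
  expect_lte(max(g@qWindow) * g@rg, 1.3 + 1e-6)
  expect_false(g@upturn)
})

test_that("Guinier recovery is within 2% at 1% noise across the Rg range", {
  errs <- sapply(c(10, 14, 20, 30), function(rg) {
    fits <- sapply(1:25, function(s) {
      qmax <- min(0.25, 1.3 / rg * 2)   # keep some points beyond the window
      pr <- simulateGuinierProfile(rg, qGrid = seq(0.004, qmax, length.out = 80),
                                   noiseRel = 0.01, seed = s)
      guinierFit(pr)@rg
    })
    median(abs(fits - rg) / rg)
  })
  expect_true(all(errs < 0.02))
})

test_that("sphere-derived profiles give the expected Rg in the Guinier window", {
  # independent oracle: exact sphere form factor, radius R = 18.07 A
  R <- 18.07
  q <- seq(0.004, 1.3 / (sqrt(3 / 5) * R), length.out = 60)
  x <- q * R
  F2 <- (3 * (sin(x) - x * cos(x)) / x^3)^2
  g <- guinierFit(scatteringProfile(q, F2))
  expect_equal(g@rg, sqrt(3 / 5) * R, tolerance = 0.3 / 14)
})

test_that("low-q excess sets the elongation upturn flag", {
  pr <- simulateGuinierProfile(rg = 14, noiseRel = 0.005, seed = 3L)
  up <- pr@intensity * (1 + 0.25 * exp(-(pr@q / 0.02)^2))
  g <- guinierFit(scatteringProfile(pr@q, up, pr@sigma))
  expect_true(g@upturn)
  expect_error(guinierFit(scatteringProfile(seq(0.01, 0.2, 0.01),
                                            rep(1, 20))), "slope")
})

test_that("Nernst fit recovers single and symmetric multi-heme midpoints", {
  f1 <- nernstFit(simulateTitration(-150, noiseSigma = 0), nHemes = 1L)
  expect_equal(f1$apparentEm, -150, tolerance = 0.1)
  f3 <- nernstFit(simulateTitration(c(-180, -150, -120), noiseSigma = 0))
  expect_equal(f3$apparentEm, -150, tolerance = 0.1)
  expect_equal(f3$emValues, c(-180, -150, -120), tolerance = 1)
})

test_that("Nernst shift equivariance is exact in the noiseless limit", {
  em <- c(-180, -150, -120)
  base <- nernstFit(simulateTitration(em, noiseSigma = 0))
  for (dlt in c(-25, 10, 39)) {
    shifted <- nernstFit(simulateTitration(em + dlt, noiseSigma = 0))
    expect_equal(shifted$apparentEm - base$apparentEm, dlt,
                 tolerance = 1e-6)
  }
})

test_that("a +39 mV uniform shift moves the apparent midpoint by +39 mV", {
  em <- c(-180, -150, -120)
  deltas <- sapply(1:50, function(s) {
    b <- nernstFit(simulateTitration(em, noiseSigma = 0.02, seed = s))
    p <- nernstFit(simulateTitration(em + 39, noiseSigma = 0.02,
                                     seed = s + 500))
    p$apparentEm - b$apparentEm
  })
  expect_equal(median(deltas), 39, tolerance = 2 / 39)
})

test_that("titrations that do not bracket the transition are rejected", {
  tc <- simulateTitration(c(-180, -150, -120), noiseSigma = 0)
  keep <- tc@potential < -140
  trunc <- titrationCurve(tc@potential[keep], tc@fractionReduced[keep])
  expect_error(nernstFit(trunc), "bracket")
})
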