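test_that("two-state signal matches its closed form and peak position", {
  # independent oracle: dense numeric maximization of the closed form
  t <- seq(0, 200, by = 0.001)
  p <- schemeParams(tauCS = 6.4, tauCR = 38)
  s <- twoStateSignal(t, p)
  # analytic stationarity: t* = ln(kCS/kCR)/(kCS - kCR) = 13.70 ps
  kcs <- 1 / 6.4; kcr <- 1 / 38
  tStar <- log(kcs / kcr) / (kcs - kcr)
  expect_equal(tStar, 13.70, tolerance = 1e-3)
  expect_equal(t[which.max(s)], tStar, tolerance = 1e-3)

  # causality without IRF
  expect_identical(twoStateSignal(c(-5, -0.001), p), c(0, 0))

  # equal-rate limit: k t e^{-kt}, maximum at t = 1/k
  k <- 0.5
  s2 <- twoStateSignal(t, schemeParams(kCS = k, kCR = k))
  expect_equal(t[which.max(s2)], 1 / k, tolerance = 1e-3)
  expect_equal(max(s2), exp(-1), tolerance = 1e-6)
  # and it is the continuous limit of the generic form
  s2b <- twoStateSignal(t, schemeParams(kCS = k, kCR = k * (1 + 1e-7)))
  expect_equal(s2, s2b, tolerance = 1e-5)
})

test_that("analytic IRF convolution agrees with numeric convolution", {
  dt <- 5e-4
  tg <- seq(-3, 40, by = dt)
  p0 <- schemeParams(tauCS = 2.3, tauCR = 5.9)
  pI <- schemeParams(tauCS = 2.3, tauCR = 5.9, irfFWHM = 0.17)
  sigma <- 0.17 / (2 * sqrt(2 * log(2)))
  kern <- dnorm(seq(-6 * sigma, 6 * sigma, by = dt), 0, sigma)
  kern <- kern / sum(kern)
  raw <- twoStateSignal(tg, p0)
  num <- stats::filter(raw, kern, sides = 2)
  inner <- !is.na(num)
  # the numeric oracle itself carries O(dt^2) discretization error at the
  # t = 0 kink; 1e-4 is far below any kinetic effect of interest
  expect_lt(max(abs(twoStateSignal(tg, pI)[inner] - num[inner])), 1e-4)
})

test_that("rate-swap amplitude degeneracy holds to 1e-12 relative", {
  t <- seq(-1, 60, by = 0.01)
  for (pair in list(c(0.3, 0.1), c(1 / 2.3, 1 / 5.9), c(2, 0.05))) {
    k1 <- pair[1]; k2 <- pair[2]
    s12 <- twoStateSignal(t, schemeParams(kCS = k1, kCR = k2, irfFWHM = 0.17))
    s21 <- twoStateSignal(t, schemeParams(kCS = k2, kCR = k1, irfFWHM = 0.17))
    # S(t; k1, k2) * k2 = S(t; k2, k1) * k1
    expect_lt(max(abs(s12 * k2 - s21 * k1)) / max(abs(s12 * k2)), 1e-12)
  }
})

test_that("multi-state scheme reduces, branches and plateaus correctly", {
  t <- seq(-1, 500, by = 0.05)
  p <- schemeParams(tauCS = 2.3, tauCR = 5.9, irfFWHM = 0.17)
  expect_lt(max(abs(multiStateSignal(t, p) - twoStateSignal(t, p))), 1e-10)

  # branching fraction plateau kHH/(kHH + kCR)
  pb <- schemeParams(tauCS = 2, kCR = 0.1, kHH = 10)
  expect_equal(multiStateSignal(500, pb), 10 / 10.1, tolerance = 1e-9)

  # independent oracle: numeric ODE solution of the branched chain
  pz <- schemeParams(tauCS = 3, kCR = 0.2, kHH = 0.05)
  ode <- deSolve::ode(
    y = c(ru = 1, a = 0, d = 0),
    times = seq(0, 100, by = 0.5),
    func = function(t, y, parms) {
      list(c(-pz@kCS * y[1],
             pz@kCS * y[1] - (pz@kCR + pz@kHH) * y[2],
             pz@kHH * y[2]))
    }, parms = NULL)
  num <- ode[, "a"] + ode[, "d"]
  ana <- multiStateSignal(seq(0, 100, by = 0.5), pz)
  expect_equal(ana, unname(num), tolerance = 1e-5)
})

test_that("biexponential fitting recovers truth exactly on noiseless traces", {
  t <- defaultDelayGrid()
  p <- schemeParams(tauCS = 2.3, tauCR = 5.9, irfFWHM = 0.17)
  tr <- kineticTrace(t, 0.8 * twoStateSignal(t, p), sigma = 1e-6)
  f <- fitBiexponential(tr, "two_state", irfFWHM = 0.17)
  expect_lt(abs(tauCS(f) - 2.3) / 2.3, 1e-4)
  expect_lt(abs(tauCR(f) - 5.9) / 5.9, 1e-4)
  expect_equal(f@amplitude, 0.8, tolerance = 1e-3)
  expect_true(f@degenerate)
})

test_that("fits of swap-generated traces land on the canonical assignment", {
  t <- defaultDelayGrid()
  swapped <- twoStateSignal(t, schemeParams(tauCS = 5.9, tauCR = 2.3,
                                            irfFWHM = 0.17))
  f <- fitBiexponential(kineticTrace(t, swapped, sigma = 1e-6),
                        irfFWHM = 0.17)
  # assignment rule: tauCS is the faster constant regardless of generation
  expect_lt(abs(tauCS(f) - 2.3) / 2.3, 1e-3)
  expect_lt(abs(tauCR(f) - 5.9) / 5.9, 1e-3)
  expect_true(f@degenerate)
})

test_that("fitting refuses flat or noise-only traces", {
  t <- defaultDelayGrid()
  set.seed(9)
  tr <- kineticTrace(t, rnorm(length(t), 0, 0.01), sigma = 0.01)
  expect_error(fitBiexponential(tr), "no detectable kinetic signal")
})

test_that("CS/CR fold ratios reproduce the published per-construct values", {
  mk <- function(tcs, tcr) new("KineticFit", tauCS = tcs, tauCR = tcr,
                               amplitude = 1, t0 = 0, tauCSErr = 0,
                               tauCRErr = 0, scheme = "two_state", rss = 0,
                               nPoints = 0L)
  expect_equal(attr(csCrRatio(mk(6.4, 38)), "reported"), 5.9)
  expect_equal(attr(csCrRatio(mk(2.3, 5.9)), "reported"), 2.6)
  expect_equal(attr(csCrRatio(mk(9.4, 49)), "reported"), 5.2)
  expect_equal(as.numeric(csCrRatio(mk(3, 3))), 1.0)
})

test_that("scheme comparison reports the identifiability verdict", {
  t <- defaultDelayGrid()
  p <- schemeParams(tauCS = 2.3, tauCR = 5.9, irfFWHM = 0.17)
  clean <- kineticTrace(t, twoStateSignal(t, p), sigma = 0.001)
  cs <- compareSchemes(clean)
  expect_identical(cs$verdict, "indistinguishable")
  expect_equal(cs$impliedCRMultiState, 2.3, tolerance = 1e-3)
  expect_false(cs$subIRF)

  # a plateau (heme-to-heme branch) discriminates the schemes
  pb <- schemeParams(tauCS = 2.3, kCR = 1 / 5.9, kHH = 0.08, irfFWHM = 0.17)
  set.seed(5)
  trp <- kineticTrace(t, multiStateSignal(t, pb) + rnorm(length(t), 0, 0.005),
                      sigma = 0.005)
  expect_identical(compareSchemes(trp)$verdict, "multi_state_preferred")

  set.seed(6)
  noise <- kineticTrace(t, rnorm(length(t), 0, 0.01), sigma = 0.01)
  expect_error(compareSchemes(noise))
})

test_that("IRF-convolved signal integrates to the closed-form area", {
  # area of B(t) is kCS/(kCR-kCS) * (1/kCS - 1/kCR) = 1/kCR; Gaussian IRF
  # preserves the integral
  p <- schemeParams(tauCS = 2.3, tauCR = 5.9, irfFWHM = 0.17)
  t <- seq(-3, 20 * 5.9, by = 0.005)
  area <- sum(twoStateSignal(t, p)) * 0.005
  expect_equal(area, 5.9, tolerance = 1e-4)
})
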