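test_that("minimal distance solves simple geometric cases", {
  xyz <- rbind(c(0, 0, 0), c(3, 4, 0), c(10, 0, 0))
  expect_equal(minDaDistance(xyz, 1, 2), 5)
  expect_equal(minDaDistance(xyz, c(1, 3), 2), 5)
  shared <- rbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(minDaDistance(shared, 1, 2), 0)
  expect_error(minDaDistance(xyz, integer(0), 2), "empty")
})

test_that("grid-accelerated minimal distance equals brute force exactly", {
  set.seed(11)
  for (i in 1:50) {
    A <- matrix(runif(300, 0, 30), ncol = 3)
    B <- matrix(runif(300, 0, 30), ncol = 3)
    co <- rbind(A, B)
    expect_identical(minDaDistance(co, 1:100, 101:200, method = "grid"),
                     minDaDistance(co, 1:100, 101:200, method = "brute"))
  }
})

test_that("per-frame series equals the brute-force frame loop", {
  tr <- simulateTrajectory(trajectoryGeneratorConfig(nFrames = 200L,
                                                     seed = 5L))
  sel <- aromaticSelections(tr)
  series <- minDistanceSeries(tr)
  brute <- sapply(seq_len(nFrames(tr)), function(f)
    minDaDistance(frameCoords(tr, f), sel$ps, sel$heme))
  expect_equal(series, brute, tolerance = 1e-12)
})

test_that("distance distributions recover generator modes", {
  tr <- simulateTrajectory(trajectoryGeneratorConfig(
    nFrames = 20000L, modeDistances = 6.6, jitterSigma = 0.15, seed = 7L))
  dd <- distanceDistribution(tr)
  expect_equal(sum(frequencies(dd)), 100, tolerance = 1e-6)
  expect_length(modes(dd), 1L)
  expect_lt(abs(modes(dd) - 6.6), 0.2 + 1e-9)

  tr2 <- simulateTrajectory(trajectoryGeneratorConfig(
    nFrames = 20000L, modeDistances = c(3.8, 4.9), modeWeights = c(0.5, 0.5),
    jitterSigma = 0.1, seed = 11L))
  dd2 <- distanceDistribution(tr2)
  m <- sort(modes(dd2))
  expect_length(m, 2L)
  expect_lt(abs(m[1] - 3.8), 0.2 + 1e-9)
  expect_lt(abs(m[2] - 4.9), 0.2 + 1e-9)
})

test_that("degenerate distributions collapse to one bin", {
  tr <- simulateTrajectory(trajectoryGeneratorConfig(
    nFrames = 150L, modeDistances = 5.3, jitterSigma = 0))
  dd <- distanceDistribution(tr, excludeEquilibration = 0)
  expect_equal(max(frequencies(dd)), 100)
  expect_equal(modes(dd), 5.3, tolerance = 0.1 + 1e-9)
  expect_error(distanceDistribution(tr, excludeEquilibration = 100L),
               "fewer than 100")
})

test_that("per-atom map dominates and reproduces the global minimum", {
  tr <- simulateTrajectory(trajectoryGeneratorConfig(nFrames = 300L,
                                                     seed = 9L))
  pm <- perAtomMap(tr)
  series <- minDistanceSeries(tr)
  expect_equal(apply(pm@distances, 2, min), series, tolerance = 1e-12)
  expect_true(all(t(pm@distances) >= series - 1e-12))
})

test_that("a conformational jump shows as a recoverable change point", {
  cfgA <- trajectoryGeneratorConfig(nFrames = 250L, modeDistances = 4.9,
                                    jitterSigma = 0.05, seed = 13L)
  cfgB <- trajectoryGeneratorConfig(nFrames = 250L, modeDistances = 10,
                                    jitterSigma = 0.05, seed = 14L)
  a <- simulateTrajectory(cfgA); b <- simulateTrajectory(cfgB)
  co <- array(c(a@coords, b@coords), c(dim(a@coords)[1], 3, 500))
  jump <- new("Trajectory", coords = co, atoms = atoms(a),
              frameSpacing = 10, metadata = list())
  pm <- perAtomMap(jump)
  frameMin <- apply(pm@distances, 2, min)
  cp <- which.max(abs(diff(frameMin)))
  expect_lt(abs(cp - 250), 2 + 1e-9)
})

test_that("van der Waals contact fractions follow the mixture weights", {
  allIn <- simulateTrajectory(trajectoryGeneratorConfig(
    nFrames = 150L, modeDistances = 3.5, jitterSigma = 0))
  expect_equal(vdwContactFraction(allIn, excludeEquilibration = 0L), 1)
  allOut <- simulateTrajectory(trajectoryGeneratorConfig(
    nFrames = 150L, modeDistances = 9.5, jitterSigma = 0))
  expect_equal(vdwContactFraction(allOut, excludeEquilibration = 0L), 0)
  mix <- simulateTrajectory(trajectoryGeneratorConfig(
    nFrames = 10000L, modeDistances = c(3.8, 6.6), modeWeights = c(0.5, 0.5),
    jitterSigma = 0.05, seed = 21L))
  expect_equal(vdwContactFraction(mix, excludeEquilibration = 0L), 0.5,
               tolerance = 0.04)
})

test_that("width report separates narrow and broad distributions", {
  narrow <- distanceDistribution(simulateTrajectory(trajectoryGeneratorConfig(
    nFrames = 20000L, modeDistances = 6.6, jitterSigma = 0.15, seed = 2L)))
  broad <- distanceDistribution(simulateTrajectory(trajectoryGeneratorConfig(
    nFrames = 20000L, modeDistances = 9.5, jitterSigma = 1.0, seed = 3L)))
  rN <- distributionWidthReport(narrow)
  rB <- distributionWidthReport(broad)
  expect_equal(rN$mean, 6.6, tolerance = 0.05)
  expect_equal(rB$mean, 9.5, tolerance = 0.1)
  expect_equal(rB$sd / rN$sd, 6.7, tolerance = 1)

  # delta-like distribution: SD below one bin width
  delta <- distanceDistribution(simulateTrajectory(trajectoryGeneratorConfig(
    nFrames = 150L, modeDistances = 5.3, jitterSigma = 0)),
    excludeEquilibration = 0L)
  expect_lt(distributionWidthReport(delta)$sd, 0.2)

  # bimodal mean lies between the modes
  bi <- distanceDistribution(simulateTrajectory(trajectoryGeneratorConfig(
    nFrames = 10000L, modeDistances = c(3.8, 4.9), modeWeights = c(.5, .5),
    jitterSigma = 0.1, seed = 4L)))
  rBi <- distributionWidthReport(bi)
  expect_gt(rBi$mean, 3.8); expect_lt(rBi$mean, 4.9)
})

test_that("PDB round trip preserves coordinates, groups and aromatic flags", {
  tr <- simulateTrajectory(trajectoryGeneratorConfig(nFrames = 4L, seed = 6L))
  path <- withr::local_tempfile(fileext = ".pdb")
  writeTrajectory(tr, path)
  back <- readTrajectory(path, "pdb")
  expect_equal(nFrames(back), 4L)
  expect_equal(back@coords, tr@coords, tolerance = 1e-3)
  expect_identical(atoms(back)$group, atoms(tr)$group)
  expect_identical(atoms(back)$aromatic, atoms(tr)$aromatic)
  # analysis results survive the round trip to PDB precision
  expect_equal(minDistanceSeries(back), minDistanceSeries(tr),
               tolerance = 2e-3)
})

test_that("malformed multi-model PDB files are rejected", {
  tr <- simulateTrajectory(trajectoryGeneratorConfig(nFrames = 2L))
  path <- withr::local_tempfile(fileext = ".pdb")
  writeTrajectory(tr, path)
  txt <- readLines(path)
  writeLines(txt[!startsWith(txt, "ENDMDL")][1:(length(txt) - 2)], path)
  expect_error(readTrajectory(path, "pdb"), "malformed")
})

test_that("XYZ + JSON sidecar round trips", {
  tr <- simulateTrajectory(trajectoryGeneratorConfig(nFrames = 3L, seed = 8L))
  path <- withr::local_tempfile(fileext = ".xyz")
  writeTrajectoryXYZ(tr, path)
  back <- readTrajectory(path, "xyz")
  expect_equal(back@coords, tr@coords, tolerance = 1e-5)
  expect_identical(atoms(back)$group, atoms(tr)$group)
})
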