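# Kabsch superposition, mean structure, RMSF and RMSD series.

test_that("identical point sets superpose with zero rmsd and identity rotation", {
  set.seed(1)
  P <- matrix(rnorm(30), 10)
  k <- kabsch(P, P)
  expect_equal(k@rmsd, 0, tolerance = 1e-12)
  expect_equal(k@rotation, diag(3), tolerance = 1e-9)
  expect_equal(det(k@rotation), 1, tolerance = 1e-12)
})

test_that("a known rigid transform is recovered exactly", {
  set.seed(2)
  P <- matrix(rnorm(30), 10)
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Q <- sweep(P %*% t(R), 2, c(1, 1, 1), `+`)
  k <- kabsch(P, Q)
  expect_equal(k@rmsd, 0, tolerance = 1e-9)
  expect_equal(k@rotation, R, tolerance = 1e-9)
  expect_equal(k@translation, c(1, 1, 1), tolerance = 1e-9)
})

test_that("kabsch matches the brute-force quaternion minimum on noisy clouds", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    P <- matrix(rnorm(3 * n), n)
    Q <- P + matrix(rnorm(3 * n, sd = 0.3), n)
    expect_equal(kabsch(P, Q)@rmsd, bruteForceMinRmsd(P, Q), tolerance = 1e-6)
  }
})

test_that("kabsch rmsd is never beaten by random rigid transforms", {
  set.seed(4)
  P <- matrix(rnorm(45), 15)
  Q <- matrix(rnorm(45), 15)
  best <- kabsch(P, Q)@rmsd
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  mc <- replicate(2000, rmsdUnderRotation(Pc, Qc,
                                          rotationFromQuaternion(randomQuaternion())))
  expect_true(all(best <= mc + 1e-12))
})

test_that("degenerate and ill-conditioned inputs are handled per contract", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "degenerate")
  line <- cbind(1:5, 0, 0) * 1.0
  k <- kabsch(line, line)
  expect_true(k@illConditioned)
  expect_equal(k@rmsd, 0, tolerance = 1e-9)
})

test_that("kabsch agrees with an independent superposition implementation", {
  skip_if_not_installed("bio3d")
  set.seed(5)
  P <- matrix(rnorm(60), 20)
  Q <- P + matrix(rnorm(60, sd = 0.5), 20)
  ours <- kabsch(P, Q)@rmsd
  xyz <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(Q)), mobile = as.numeric(t(P))))
  theirs <- sqrt(mean(rowSums((matrix(xyz, ncol = 3, byrow = TRUE) - Q)^2)))
  expect_equal(ours, theirs, tolerance = 1e-6)
})

test_that("a static trajectory has itself as mean after one iteration", {
  set.seed(6)
  m <- tinyStructure(10)
  tr <- trajectory(m, list(coords(m), coords(m), coords(m)), 100)
  ms <- meanStructure(tr, seq_len(10))
  expect_true(ms@converged)
  expect_equal(ms@iterations, 1L)
  expect_equal(ms@nFramesUsed, 3L)
  expect_equal(coords(ms@model), coords(m), tolerance = 1e-9)
})

test_that("rigid motions are removed: transformed copies average to the original", {
  set.seed(7)
  m <- tinyStructure(12)
  th <- 0.7
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  f2 <- sweep(coords(m) %*% t(R), 2, c(3, -2, 1), `+`)
  tr <- trajectory(m, list(coords(m), f2), 100)
  ms <- meanStructure(tr, seq_len(12))
  expect_equal(kabsch(coords(ms@model), coords(m))@rmsd, 0, tolerance = 1e-6)
})

test_that("the mean of an OU trajectory converges to the scaffold", {
  spec <- scaffoldSpec(nResidues = 30, firstResidue = 740,
                       ploopRange = c(741, 744))
  sc <- makeScaffold(spec, seed = 8)
  ## short correlation time so frames are nearly independent
  dyn <- dynamicsSpec(nFrames = 10000, coreAmplitude = 0.5,
                      ploopAmplitude = 0.5, helixAmplitude = 0.5,
                      ouCorrelationTime = 20, kCleave = 0, kReform = 0,
                      bridgeStart = "bonded", helixToInactive = 0,
                      helixToActive = 0, helixStart = "inactive")
  sim <- simulateTrajectory(sc, dyn, spec, seed = 9)
  ca <- selectAtoms(sc, atomName = "CA")
  ms <- meanStructure(sim$trajectory, ca)
  fit <- kabsch(coords(ms@model)[ca@indices, ], coords(sc)[ca@indices, ])
  ## rms coordinate deviation bounded by 3 x the standard error of the mean
  expect_lt(fit@rmsd, 3 * 0.5 / sqrt(10000))
})

test_that("RMSF is zero for a static trajectory and recovers sqrt(3)*s for OU", {
  set.seed(10)
  m <- tinyStructure(8)
  static <- trajectory(m, list(coords(m), coords(m)), 100)
  prof <- rmsf(static, alignOn = NULL, measureOn = seq_len(8))
  expect_equal(prof@values, rep(0, 8), tolerance = 1e-12)

  spec <- scaffoldSpec(nResidues = 50, firstResidue = 718)
  sc <- makeScaffold(spec, seed = 11)
  dyn <- dynamicsSpec(nFrames = 10000, kCleave = 0, kReform = 0,
                      bridgeStart = "bonded", helixToInactive = 0,
                      helixToActive = 0, helixStart = "inactive")
  sim <- simulateTrajectory(sc, dyn, spec, seed = 12)
  ca <- selectAtoms(sc, atomName = "CA")
  prof <- rmsf(sim$trajectory, alignOn = NULL, measureOn = ca,
               regions = scaffoldRegions(spec))
  gt <- sim$groundTruth$rmsfPerRegion
  expect_equal(regionRmsf(prof, "ploop"), gt[["ploop"]], tolerance = 0.05)
  expect_equal(regionRmsf(prof, "alphaC"), gt[["alphaC"]], tolerance = 0.05)
})

test_that("RMSF profile peaks inside the P-loop when its amplitude is doubled", {
  spec <- scaffoldSpec(nResidues = 50, firstResidue = 718)
  sc <- makeScaffold(spec, seed = 13)
  dyn <- dynamicsSpec(nFrames = 3000, ploopAmplitude = 0.8,
                      coreAmplitude = 0.4, helixAmplitude = 0.4,
                      kCleave = 0, kReform = 0, bridgeStart = "bonded",
                      helixToInactive = 0, helixToActive = 0,
                      helixStart = "inactive")
  sim <- simulateTrajectory(sc, dyn, spec, seed = 14)
  ca <- selectAtoms(sc, atomName = "CA")
  ms <- meanStructure(sim$trajectory, ca)
  prof <- rmsf(sim$trajectory, alignOn = ca, measureOn = ca, mean = ms,
               regions = scaffoldRegions(spec))
  peak <- prof@residueNumbers[which.max(prof@values)]
  expect_true(peak >= 718 && peak <= 726)
})

test_that("measuring two atoms of one residue is an ambiguity error", {
  spec <- scaffoldSpec()
  sc <- makeScaffold(spec, seed = 15)
  tr <- trajectory(sc, list(coords(sc)), 100)
  lys <- selectAtoms(sc, residueNumber = 745)  # CA + NZ
  expect_error(rmsf(tr, alignOn = NULL, measureOn = lys),
               "more than one atom")
})

test_that("rmsd series: reference = frame 1 gives 0; align==measure equals kabsch", {
  spec <- scaffoldSpec(nResidues = 40, firstResidue = 730,
                       ploopRange = c(731, 735), helixRange = c(752, 767))
  sc <- makeScaffold(spec, seed = 16)
  dyn <- dynamicsSpec(nFrames = 50, kCleave = 0, kReform = 0,
                      bridgeStart = "bonded", helixToInactive = 0,
                      helixToActive = 0, helixStart = "inactive")
  sim <- simulateTrajectory(sc, dyn, spec, seed = 17)
  tr <- sim$trajectory
  ca <- selectAtoms(sc, atomName = "CA")
  ref <- structureModel(atomData(tr), coords(tr)[1, , ], "frame1")
  rs <- rmsdSeries(tr, ref, ca, ca)
  expect_equal(rs@values[1], 0, tolerance = 1e-9)
  direct <- vapply(seq_len(nFrames(tr)), function(k)
    kabsch(coords(tr)[k, ca@indices, ], coords(ref)[ca@indices, ])@rmsd, 1.0)
  expect_equal(rs@values, direct, tolerance = 1e-12)
})

test_that("a residue missing from the reference raises a mapping error", {
  spec <- scaffoldSpec()
  sc <- makeScaffold(spec, seed = 18)
  tr <- trajectory(sc, list(coords(sc)), 100)
  ca <- selectAtoms(sc, atomName = "CA")
  refAtoms <- atomData(sc)[atomData(sc)$residue_number != 750, ]
  ref <- structureModel(refAtoms,
                        coords(sc)[atomData(sc)$residue_number != 750, ],
                        "partial")
  expect_error(rmsdSeries(tr, ref, ca, ca), "750")
})

test_that("analyses are invariant under a global rigid transform of all frames", {
  spec <- scaffoldSpec(nResidues = 40, firstResidue = 730,
                       ploopRange = c(731, 735))
  sc <- makeScaffold(spec, seed = 19)
  dyn <- dynamicsSpec(nFrames = 80, kCleave = 0.05, kReform = 0.05)
  sim <- simulateTrajectory(sc, dyn, spec, seed = 20)
  tr <- sim$trajectory
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- coords(tr)
  for (k in seq_len(nFrames(tr)))
    moved[k, , ] <- sweep(moved[k, , ] %*% t(R), 2, c(5, -3, 8), `+`)
  tr2 <- trajectory(sc, moved, 100)
  ca <- selectAtoms(sc, atomName = "CA")
  ref <- structureModel(atomData(sc), coords(sc), "ref")
  expect_equal(rmsdSeries(tr2, ref, ca, ca)@values,
               rmsdSeries(tr, ref, ca, ca)@values, tolerance = 1e-9)
  ms1 <- meanStructure(tr, ca); ms2 <- meanStructure(tr2, ca)
  expect_equal(kabsch(coords(ms2@model), coords(ms1@model))@rmsd, 0,
               tolerance = 1e-6)
  p1 <- rmsf(tr, ca, ca, ms1); p2 <- rmsf(tr2, ca, ca, ms2)
  expect_equal(p2@values, p1@values, tolerance = 1e-9)
  ## and the pair distance is rigid-motion invariant too
  don <- selectAtoms(sc, atomName = "NZ", residueNumber = 745)
  acc <- selectAtoms(sc, atomName = "CD", residueNumber = 762)
  expect_equal(pairDistanceSeries(tr2, don, acc)@values,
               pairDistanceSeries(tr, don, acc)@values, tolerance = 1e-9)
})

test_that("pooling trajectories equals RMSF of their concatenation", {
  spec <- scaffoldSpec(nResidues = 30, firstResidue = 740,
                       ploopRange = c(741, 744))
  sc <- makeScaffold(spec, seed = 21)
  dyn <- dynamicsSpec(nFrames = 200, kCleave = 0, kReform = 0,
                      bridgeStart = "bonded", helixToInactive = 0,
                      helixToActive = 0, helixStart = "inactive")
  t1 <- simulateTrajectory(sc, dyn, spec, seed = 22)$trajectory
  t2 <- simulateTrajectory(sc, dyn, spec, seed = 23)$trajectory
  ca <- selectAtoms(sc, atomName = "CA")
  arr <- array(NA_real_, c(400, nrow(atomData(sc)), 3))
  arr[1:200, , ] <- coords(t1)
  arr[201:400, , ] <- coords(t2)
  catTr <- trajectory(sc, arr, 100)
  pooled <- rmsf(list(t1, t2), alignOn = NULL, measureOn = ca)
  concat <- rmsf(catTr, alignOn = NULL, measureOn = ca)
  expect_equal(pooled@values, concat@values, tolerance = 1e-12)
})
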