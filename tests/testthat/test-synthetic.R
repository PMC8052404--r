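# Generator properties: construction constraints, determinism, closed-form
# ground truth, presets and the Crooks sampler identities.

test_that("the default scaffold has 100 CA plus the two side-chain atoms", {
  spec <- scaffoldSpec()
  sc <- makeScaffold(spec, seed = 1)
  a <- atomData(sc)
  expect_equal(nrow(a), 102L)
  expect_equal(sum(a$atom_name == "CA"), 100L)
  expect_setequal(a$atom_name[a$atom_name != "CA"], c("NZ", "CD"))
  ## consecutive CA spacing is the construction constant
  ca <- coords(sc)[a$atom_name == "CA", ]
  expect_equal(sqrt(rowSums(diff(ca)^2)), rep(3.8, 99), tolerance = 1e-9)
  ## NZ sits at bonded geometry from CD
  d <- sqrt(sum((coords(sc)[a$atom_name == "NZ", ] -
                 coords(sc)[a$atom_name == "CD", ])^2))
  expect_equal(d, 3.0, tolerance = 1e-9)
})

test_that("scaffold and trajectory generation are deterministic per seed", {
  spec <- scaffoldSpec(nResidues = 30, firstResidue = 740,
                       ploopRange = c(741, 744))
  expect_identical(coords(makeScaffold(spec, seed = 7)),
                   coords(makeScaffold(spec, seed = 7)))
  expect_false(identical(coords(makeScaffold(spec, seed = 7)),
                         coords(makeScaffold(spec, seed = 8))))
  sc <- makeScaffold(spec, seed = 7)
  dyn <- dynamicsSpec(nFrames = 50)
  expect_identical(coords(simulateTrajectory(sc, dyn, spec, seed = 3)$trajectory),
                   coords(simulateTrajectory(sc, dyn, spec, seed = 3)$trajectory))
})

test_that("zero amplitudes and rates freeze every frame at the scaffold", {
  spec <- scaffoldSpec(nResidues = 30, firstResidue = 740,
                       ploopRange = c(741, 744))
  sc <- makeScaffold(spec, seed = 2)
  dyn <- dynamicsSpec(nFrames = 10, coreAmplitude = 0, ploopAmplitude = 0,
                      helixAmplitude = 0, kCleave = 0, kReform = 0,
                      bridgeNoiseSd = 0, bridgeStart = "bonded",
                      helixToInactive = 0, helixToActive = 0,
                      helixStart = "inactive")
  tr <- simulateTrajectory(sc, dyn, spec, seed = 3)$trajectory
  for (k in 1:10)
    expect_equal(coords(tr)[k, , ], unname(coords(sc)), tolerance = 1e-9)
})

test_that("ground truth fields follow the stated closed forms", {
  spec <- scaffoldSpec(nResidues = 30, firstResidue = 740,
                       ploopRange = c(741, 744))
  sc <- makeScaffold(spec, seed = 4)
  dyn <- dynamicsSpec(nFrames = 5, kCleave = 0.02, kReform = 0.06,
                      coreAmplitude = 0.4, ploopAmplitude = 1.0,
                      helixToActive = 0.07, helixToInactive = 0.03)
  gt <- simulateTrajectory(sc, dyn, spec, seed = 5)$groundTruth
  expect_equal(gt$expectedFormedFraction, 0.06 / 0.08)
  expect_equal(gt$expectedEventRatePerNs, 0.75 * 0.02)
  expect_equal(gt$rmsfPerRegion[["ploop"]], sqrt(3) * 1.0)
  expect_equal(gt$rmsfPerRegion[["core"]], sqrt(3) * 0.4)
  expect_equal(gt$poseOccupancy[["active"]], 0.7)
  ## symmetric rates -> occupancy one half
  dyn2 <- dynamicsSpec(kCleave = 0.01, kReform = 0.01, nFrames = 5)
  expect_equal(simulateTrajectory(sc, dyn2, spec, seed = 6)$groundTruth$
                 expectedFormedFraction, 0.5)
})

test_that("the P-loop/core RMSF ratio is recovered within 10% at 10k frames", {
  spec <- scaffoldSpec(nResidues = 50, firstResidue = 718)
  sc <- makeScaffold(spec, seed = 7)
  dyn <- dynamicsSpec(nFrames = 10000, ploopAmplitude = 1.0,
                      coreAmplitude = 0.4, kCleave = 0, kReform = 0,
                      bridgeStart = "bonded", helixToInactive = 0,
                      helixToActive = 0, helixStart = "inactive")
  sim <- simulateTrajectory(sc, dyn, spec, seed = 8)
  ca <- selectAtoms(sc, atomName = "CA")
  prof <- rmsf(sim$trajectory, alignOn = NULL, measureOn = ca,
               regions = scaffoldRegions(spec))
  coreRes <- setdiff(prof@residueNumbers, c(718:726, 752:767))
  coreVal <- mean(prof@values[prof@residueNumbers %in% coreRes])
  expect_equal(regionRmsf(prof, "ploop") / coreVal, 2.5, tolerance = 0.1)
})

test_that("presets have their defining properties", {
  expect_equal(dynamicsPreset("L747P-like")$kCleave, 0)
  wt <- dynamicsPreset("WT-like")
  frWT <- wt$kReform / (wt$kCleave + wt$kReform)
  expect_gt(frWT, 0); expect_lt(frWT, 1)
  expect_gt(wt$ploopAmplitude, dynamicsPreset("L747P-like")$ploopAmplitude)
  expect_error(dynamicsPreset("nope"), "WT-like")
})

test_that("generated trajectories survive the multi-model PDB round trip", {
  spec <- scaffoldSpec(nResidues = 30, firstResidue = 740,
                       ploopRange = c(741, 744))
  sc <- makeScaffold(spec, seed = 9)
  tr <- simulateTrajectory(sc, dynamicsSpec(nFrames = 20), spec,
                           seed = 10)$trajectory
  f <- withr::local_tempfile(fileext = ".pdb")
  writeTrajectory(tr, f)
  tr2 <- readTrajectory(f, 100)
  expect_equal(coords(tr2), coords(tr), tolerance = 5e-4)  # 3-decimal columns
  expect_identical(atomData(tr2)$atom_name, atomData(tr)$atom_name)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeTrajectory(tr2, f2)
  expect_identical(readLines(f), readLines(f2))            # idempotent
})

test_that("the Crooks sampler satisfies the Gaussian dissipation identity", {
  kB <- 0.0019872041
  beta <- 1 / (kB * 300)
  tab <- sampleCrooksWindows(
    data.frame(lambda_from = 0, lambda_to = 1, dG_true = -1.7),
    sigma = 1, n = 10000, seed = 11)
  fw <- tab$work_kcal_mol[tab$direction == "forward"]
  rv <- tab$work_kcal_mol[tab$direction == "reverse"]
  ## mean(W_f) + mean(W_r) -> beta sigma^2 (both directions dissipate alike)
  se <- sqrt(2) * 1 / sqrt(10000)
  expect_lt(abs(mean(fw) + mean(rv) - beta), 3 * se)
  ## sigma -> 0 limit: forward works collapse onto dG_true
  tab0 <- sampleCrooksWindows(
    data.frame(lambda_from = 0, lambda_to = 1, dG_true = -1.7),
    sigma = 1e-9, n = 10, seed = 12)
  expect_equal(mean(tab0$work_kcal_mol[tab0$direction == "forward"]), -1.7,
               tolerance = 1e-6)
})

test_that("preset pipelines reproduce the qualitative orderings", {
  ## three replicas per preset at a reduced problem size; the repeated-run
  ## statistics live in the acceptance suite
  spec <- scaffoldSpec(nResidues = 50, firstResidue = 718)
  sc <- makeScaffold(spec, seed = 13)
  don <- selectAtoms(sc, atomName = "NZ", residueNumber = 745)
  acc <- selectAtoms(sc, atomName = "CD", residueNumber = 762)
  ca <- selectAtoms(sc, atomName = "CA")
  run <- function(preset, seedBase) {
    dyn <- dynamicsPreset(preset); dyn$nFrames <- 2000L
    trs <- lapply(1:3, function(r)
      simulateTrajectory(sc, dyn, spec, seed = seedBase + r)$trajectory)
    sb <- saltBridgeAnalysis(trs, don, acc, analysisStartNs = 50)
    prof <- rmsf(trs, alignOn = NULL, measureOn = ca,
                 regions = scaffoldRegions(spec))
    list(sb = sb, ploop = regionRmsf(prof, "ploop"))
  }
  wt <- run("WT-like", 100)
  lp <- run("L747P-like", 200)
  expect_gt(mean(lp$sb@formedFraction), mean(wt$sb@formedFraction))
  expect_lt(lp$ploop, wt$ploop)
  expect_equal(classifyConformation(lp$sb)$ensemble, "active-stabilized")
})
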