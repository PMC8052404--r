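# Distance series, window smoothing, occupancy/event statistics and
# conformation classification.

makeStaticPair <- function(dA, n = 20) {
  atoms <- data.frame(serial = 1:5, atom_name = c("CA", "CA", "NZ", "CA", "CD"),
                      residue_name = c("ALA", "LYS", "LYS", "GLU", "GLU"),
                      residue_number = c(1L, 2L, 2L, 3L, 3L), chain_id = "A")
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0), c(2, 0, 0), c(dA, 0, 0))
  m <- structureModel(atoms, xyz)
  trajectory(m, replicate(n, xyz, simplify = FALSE), 100)
}

test_that("pair distances follow Euclidean geometry", {
  atoms <- data.frame(serial = 1:3, atom_name = c("NZ", "CD", "CA"),
                      residue_name = "ALA", residue_number = 1:3,
                      chain_id = "A")
  xyz <- rbind(c(0, 0, 0), c(3, 4, 0), c(0, 0, 0))
  tr <- trajectory(structureModel(atoms, xyz), list(xyz, xyz), 100)
  s <- pairDistanceSeries(tr, 1L, 2L)
  expect_equal(s@values, c(5, 5))              # 3-4-5 triangle
  expect_equal(pairDistanceSeries(tr, 1L, 3L)@values, c(0, 0))
  expect_error(pairDistanceSeries(tr, c(1L, 2L), 3L), "exactly one atom")
})

test_that("the telegraph bridge reproduces its occupancy-weighted mean distance", {
  spec <- scaffoldSpec(nResidues = 30, firstResidue = 740,
                       ploopRange = c(741, 744))
  sc <- makeScaffold(spec, seed = 1)
  dyn <- dynamicsSpec(nFrames = 10000, kCleave = 0.01, kReform = 0.01)
  sim <- simulateTrajectory(sc, dyn, spec, seed = 2)
  don <- selectAtoms(sc, atomName = "NZ", residueNumber = 745)
  acc <- selectAtoms(sc, atomName = "CD", residueNumber = 762)
  s <- pairDistanceSeries(sim$trajectory, don, acc)
  gt <- sim$groundTruth
  ## SE of the mean of a correlated two-state mixture
  sdMix <- sqrt(0.25 * (8 - 3)^2 + 0.3^2)
  se <- sdMix * sqrt(2 * gt$bridgeCorrelationTimeNs / 1000)
  expect_lt(abs(mean(s@values) - gt$expectedMeanDistance), 3 * se)
})

test_that("window averaging matches the brute-force smoother exactly", {
  set.seed(3)
  for (i in 1:5) {
    n <- sample(50:200, 1)
    ts <- new("TimeSeries", times = (seq_len(n) - 1) * 100,
              values = rnorm(n), unit = "A", label = "x")
    w <- sample(c(0.3, 1, 2.5, 7), 1)
    sm <- windowAverage(ts, w)
    expect_equal(sm@values, bruteWindowAverage(ts@times, ts@values, w),
                 tolerance = 1e-12)
  }
})

test_that("smoothing preserves constants, linear ramps, and the alternating pattern", {
  n <- 101
  t <- (seq_len(n) - 1) * 100
  const <- new("TimeSeries", times = t, values = rep(2.5, n), unit = "A",
               label = "c")
  expect_equal(windowAverage(const, 1)@values, rep(2.5, n))
  ramp <- new("TimeSeries", times = t, values = seq(0, 10, length.out = n),
              unit = "A", label = "r")
  sm <- windowAverage(ramp, 1)       # 1 ns window = 11 samples
  expect_equal(sm@values[6:(n - 5)], ramp@values[6:(n - 5)], tolerance = 1e-12)
  alt <- new("TimeSeries", times = t, values = rep_len(c(1, -1), n),
             unit = "A", label = "a")
  sm <- windowAverage(alt, 0.4)      # 2k+1 = 5 samples
  expect_equal(sm@values[3:(n - 2)], rep_len(c(1, -1), n)[3:(n - 2)] / 5,
               tolerance = 1e-12)
  expect_error(windowAverage(const, 0.05), "degenerate window")
})

test_that("smoothing commutes with additive constants", {
  set.seed(4)
  ts <- new("TimeSeries", times = (0:99) * 100, values = rnorm(100),
            unit = "A", label = "x")
  ts2 <- new("TimeSeries", times = ts@times, values = ts@values + 7,
             unit = "A", label = "x+7")
  expect_equal(windowAverage(ts2, 2)@values, windowAverage(ts, 2)@values + 7,
               tolerance = 1e-12)
})

test_that("constant-distance trajectories give trivial occupancy and no events", {
  trNear <- makeStaticPair(3.0)
  trFar <- makeStaticPair(8.0)
  don <- selectAtoms(trNear@topology, atomName = "NZ")
  acc <- selectAtoms(trNear@topology, atomName = "CD")
  near <- saltBridgeAnalysis(trNear, don, acc, windowNs = 0.5,
                             minEventNs = 0.5, analysisStartNs = 0)
  expect_equal(near@formedFraction, 1.0)
  expect_equal(near@nCleavageEvents, 0L)
  far <- saltBridgeAnalysis(trFar, don, acc, windowNs = 0.5,
                            minEventNs = 0.5, analysisStartNs = 0)
  expect_equal(far@formedFraction, 0.0)
  expect_equal(far@nCleavageEvents, 0L)
  expect_equal(far@ensembleMean, 8.0)
})

test_that("analysis start beyond the trajectory end is an error", {
  tr <- makeStaticPair(3.0)
  don <- selectAtoms(tr@topology, atomName = "NZ")
  acc <- selectAtoms(tr@topology, atomName = "CD")
  expect_error(saltBridgeAnalysis(tr, don, acc, analysisStartNs = 100),
               "beyond the trajectory end")
})

test_that("stable vs dynamic regimes match telegraph expectations", {
  spec <- scaffoldSpec(nResidues = 30, firstResidue = 740,
                       ploopRange = c(741, 744))
  sc <- makeScaffold(spec, seed = 5)
  don <- selectAtoms(sc, atomName = "NZ", residueNumber = 745)
  acc <- selectAtoms(sc, atomName = "CD", residueNumber = 762)
  mk <- function(dyn, seed) simulateTrajectory(sc, dyn, spec, seed = seed)
  stableDyn <- dynamicsSpec(nFrames = 5000, kCleave = 0, kReform = 0.05,
                            bridgeStart = "bonded")
  dynDyn <- dynamicsSpec(nFrames = 5000, kCleave = 0.02, kReform = 0.02)
  sStable <- saltBridgeAnalysis(mk(stableDyn, 6)$trajectory, don, acc,
                                analysisStartNs = 50)
  expect_equal(sStable@formedFraction, 1.0)
  simD <- mk(dynDyn, 7)
  sDyn <- saltBridgeAnalysis(simD$trajectory, don, acc, analysisStartNs = 50)
  se <- telegraphFractionSe(0.5, simD$groundTruth$bridgeCorrelationTimeNs, 450)
  expect_lt(abs(sDyn@formedFraction - 0.5), 3 * se)
})

test_that("event counts are non-increasing in the dwell filter", {
  spec <- scaffoldSpec(nResidues = 30, firstResidue = 740,
                       ploopRange = c(741, 744))
  sc <- makeScaffold(spec, seed = 8)
  dyn <- dynamicsSpec(nFrames = 8000, kCleave = 0.02, kReform = 0.02)
  tr <- simulateTrajectory(sc, dyn, spec, seed = 9)$trajectory
  don <- selectAtoms(sc, atomName = "NZ", residueNumber = 745)
  acc <- selectAtoms(sc, atomName = "CD", residueNumber = 762)
  counts <- vapply(c(1, 5, 10, 25, 60), function(minEv)
    sum(saltBridgeAnalysis(tr, don, acc, minEventNs = minEv, windowNs = 5,
                           analysisStartNs = 50)@nCleavageEvents), 1L)
  expect_true(all(diff(counts) <= 0L))
})

test_that("formed fraction is invariant under rigid-body motion of frames", {
  spec <- scaffoldSpec(nResidues = 30, firstResidue = 740,
                       ploopRange = c(741, 744))
  sc <- makeScaffold(spec, seed = 10)
  dyn <- dynamicsSpec(nFrames = 500, kCleave = 0.05, kReform = 0.05)
  tr <- simulateTrajectory(sc, dyn, spec, seed = 11)$trajectory
  moved <- coords(tr)
  th <- 0.9
  R <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
  for (k in seq_len(nFrames(tr)))
    moved[k, , ] <- sweep(moved[k, , ] %*% t(R), 2, c(-4, 2, 6), `+`)
  tr2 <- trajectory(tr@topology, moved, 100)
  don <- selectAtoms(sc, atomName = "NZ", residueNumber = 745)
  acc <- selectAtoms(sc, atomName = "CD", residueNumber = 762)
  a <- saltBridgeAnalysis(tr, don, acc, analysisStartNs = 10)
  b <- saltBridgeAnalysis(tr2, don, acc, analysisStartNs = 10)
  expect_equal(a@formedFraction, b@formedFraction, tolerance = 1e-12)
  expect_equal(a@nCleavageEvents, b@nCleavageEvents)
})

test_that("classification follows the stable-fraction rule with majority voting", {
  fake <- function(fr) new("SaltBridgeResult",
    rawSeries = rep(list(new("TimeSeries", times = c(0, 100),
                             values = c(3, 3), unit = "A", label = "")),
                    length(fr)),
    smoothedSeries = rep(list(new("TimeSeries", times = c(0, 100),
                                  values = c(3, 3), unit = "A", label = "")),
                         length(fr)),
    windowNs = 10, formedFraction = fr,
    nCleavageEvents = integer(length(fr)), ensembleMean = 3,
    ensembleSd = 0, analysisStart = 0, parameters = list())
  expect_equal(classifyConformation(fake(c(1, 1, 0.99)), 0.9)$ensemble,
               "active-stabilized")
  expect_equal(classifyConformation(fake(c(0.5, 0.4, 0.6)), 0.9)$ensemble,
               "dynamic")
  ## ties go to dynamic
  expect_equal(classifyConformation(fake(c(1, 0.2)), 0.9)$ensemble, "dynamic")
  expect_error(classifyConformation(fake(0.5), 1.5), "stableFraction")
})
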