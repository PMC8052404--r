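# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: superposition via direct minimisation over
# quaternion-parameterised rotations, smoothing via a double loop.

rotationFromQuaternion <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

randomQuaternion <- function() {
  q <- rnorm(4)
  q / sqrt(sum(q^2))
}

# RMSD of centred mobile onto centred reference under a given rotation
# (translation optimal by construction).
rmsdUnderRotation <- function(Pc, Qc, R) {
  sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
}

# Brute-force minimal RMSD over rotations: Nelder-Mead restarts on the
# 4-parameter quaternion (normalised inside the objective).
bruteForceMinRmsd <- function(P, Q, restarts = 12) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  obj <- function(q) rmsdUnderRotation(Pc, Qc, rotationFromQuaternion(q))
  best <- Inf
  for (r in seq_len(restarts)) {
    q0 <- if (r == 1) c(1, 0, 0, 0) else randomQuaternion()
    o <- optim(q0, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
    o <- optim(o$par, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  best
}

# Brute-force best-fit transform of P onto Q (rotation by quaternion search,
# translation by centroid matching); returns the transformed copy of `apply`.
bruteForceAlign <- function(P, Q, apply = P, restarts = 12) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  obj <- function(q) rmsdUnderRotation(Pc, Qc, rotationFromQuaternion(q))
  best <- NULL; bestVal <- Inf
  for (r in seq_len(restarts)) {
    q0 <- if (r == 1) c(1, 0, 0, 0) else randomQuaternion()
    o <- optim(q0, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
    o <- optim(o$par, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    if (o$value < bestVal) { bestVal <- o$value; best <- o$par }
  }
  R <- rotationFromQuaternion(best)
  sweep(sweep(apply, 2, colMeans(P)) %*% t(R), 2, colMeans(Q), `+`)
}

# Per-pose helix RMSD oracle: pose the helix block of a scaffold, align the
# full C-alpha set onto the reference by brute force, measure over the helix.
purePoseHelixRmsd <- function(scaffoldCoords, caIdx, helixIdx, angleDeg) {
  ctr <- colMeans(scaffoldCoords[helixIdx, , drop = FALSE])
  a <- angleDeg * pi / 180
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  posed <- scaffoldCoords
  posed[helixIdx, ] <- sweep(sweep(scaffoldCoords[helixIdx, , drop = FALSE],
                                   2, ctr) %*% t(Rz), 2, ctr, `+`)
  aligned <- bruteForceAlign(posed[caIdx, , drop = FALSE],
                             scaffoldCoords[caIdx, , drop = FALSE],
                             apply = posed[helixIdx, , drop = FALSE])
  sqrt(mean(rowSums((aligned - scaffoldCoords[helixIdx, , drop = FALSE])^2)))
}

# O(n*w) brute-force centered window average with truncated edges.
bruteWindowAverage <- function(times, values, windowNs) {
  half <- windowNs * 1000 / 2
  vapply(seq_along(times), function(i) {
    keep <- abs(times - times[i]) <= half * (1 + 1e-12)
    mean(values[keep])
  }, 1.0)
}

# Standard error of the time average of a two-state telegraph indicator
# observed for T_ns with correlation time tau_ns (stationary start).
telegraphFractionSe <- function(p, tauNs, tNs) {
  sqrt(p * (1 - p) * 2 * tauNs / tNs)
}

# Build a tiny structure quickly for I/O tests.
tinyStructure <- function(n = 5, label = "tiny") {
  atoms <- data.frame(serial = seq_len(n), atom_name = "CA",
                      residue_name = "ALA", residue_number = seq_len(n),
                      chain_id = "A", stringsAsFactors = FALSE)
  structureModel(atoms, matrix(round(rnorm(3 * n), 3), n, 3), label)
}
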