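## Rigid-body superposition and the fluctuation machinery built on it:
## Kabsch least-squares alignment, iterative mean structure, per-residue RMSF
## and per-frame RMSD series. Superposition is unweighted and, by default,
## C-alpha-only (one atom per residue).

## Core Kabsch on plain n x 3 matrices; returns a plain list (hot path).
.kabschCore <- function(P, Q) {
  n <- nrow(P)
  pbar <- colMeans(P); qbar <- colMeans(Q)
  Pc <- sweep(P, 2, pbar); Qc <- sweep(Q, 2, qbar)
  C <- crossprod(Pc, Qc)                      # 3x3 cross-covariance
  s <- La.svd(C)                              # C = u d vt
  d <- sign(det(crossprod(s$vt, t(s$u))))     # reflection correction
  if (d == 0) d <- 1
  D <- c(1, 1, d)
  R <- crossprod(s$vt, D * t(s$u))            # rotation: maps P onto Q
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * sum(s$d * D)) / n
  list(rotation = R,
       translation = as.numeric(qbar - R %*% pbar),
       rmsd = sqrt(max(msd, 0)),
       illConditioned = s$d[2] < 1e-8 * max(s$d[1], 1e-300))
}

.applyTransform <- function(P, fit) {
  sweep(P %*% t(fit$rotation), 2, fit$translation, `+`)
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation (det +1, reflections corrected via the sign of
#' the smallest singular value) and translation minimising the RMSD of the
#' mobile point set onto the reference. Unweighted.
#'
#' @param mobile,reference numeric n x 3 matrices with equal n >= 3.
#' @return a \linkS4class{SuperpositionResult}; collinear point sets are
#'   flagged \code{illConditioned} with the optimum still returned.
#' @export
kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    .stopf("point sets must have equal size")
  if (nrow(mobile) < 3L)
    .stopf("degenerate alignment: need at least 3 points")
  fit <- .kabschCore(mobile, reference)
  new("SuperpositionResult", rotation = fit$rotation,
      translation = fit$translation, rmsd = fit$rmsd,
      illConditioned = fit$illConditioned)
}

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd %.4f A%s\n", object@rmsd,
              if (object@illConditioned) " (ill-conditioned)" else ""))
})

## Pool frames of several trajectories (shared topology) into one array.
.pooledFrames <- function(trajectories) {
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  if (!length(trajectories)) .stopf("need at least one trajectory")
  na <- nrow(trajectories[[1]]@topology@atoms)
  key0 <- with(trajectories[[1]]@topology@atoms,
               paste(atom_name, residue_number, chain_id))
  for (tr in trajectories) {
    keyk <- with(tr@topology@atoms, paste(atom_name, residue_number, chain_id))
    if (length(keyk) != na || any(keyk != key0))
      .stopf("trajectories must share one topology")
  }
  ntot <- sum(vapply(trajectories, nFrames, 1L))
  arr <- array(NA_real_, c(ntot, na, 3))
  at <- 0L
  for (tr in trajectories) {
    n <- nFrames(tr)
    arr[at + seq_len(n), , ] <- tr@frames
    at <- at + n
  }
  arr
}

#' Iterative mean structure of pooled trajectories
#'
#' Initialises the reference as frame 1 of the first trajectory, then repeats:
#' align every pooled frame to the current reference on \code{alignOn},
#' average coordinates over all pooled frames (equal weight), and take the
#' average as the new reference — until the mean moves less than
#' \code{tolerance} (RMSD between successive means) or \code{maxIter} is
#' reached. Non-convergence is reported via \code{converged=FALSE}, never an
#' error. The arithmetic mean may be stereochemically unphysical; it is used
#' only as an alignment/fluctuation reference.
#'
#' @param trajectories a Trajectory or list of Trajectories sharing a topology.
#' @param alignOn \linkS4class{AtomSelection} (or indices) to superpose on.
#' @param tolerance convergence threshold, Angstrom (default 1e-6).
#' @param maxIter maximum iterations (default 100).
#' @return a \linkS4class{MeanStructure}
#' @export
meanStructure <- function(trajectories, alignOn, tolerance = 1e-6,
                          maxIter = 100L) {
  if (tolerance <= 0) .stopf("tolerance must be > 0")
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  frames <- .pooledFrames(trajectories)
  topo <- trajectories[[1]]@topology
  idx <- .resolveSelection(alignOn, dim(frames)[2], "alignOn")
  if (length(idx) < 3L) .stopf("alignment selection needs >= 3 atoms")
  n <- dim(frames)[1]
  ref <- frames[1, , , drop = TRUE]
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    acc <- matrix(0, dim(frames)[2], 3)
    for (k in seq_len(n)) {
      fr <- frames[k, , , drop = TRUE]
      fit <- .kabschCore(fr[idx, , drop = FALSE], ref[idx, , drop = FALSE])
      acc <- acc + .applyTransform(fr, fit)
    }
    newMean <- acc / n
    shift <- sqrt(mean(rowSums((newMean - ref)^2)))
    ref <- newMean
    if (shift < tolerance) { converged <- TRUE; break }
  }
  model <- structureModel(topo@atoms, ref,
                          paste0("mean(", trajectories[[1]]@label, ")"))
  new("MeanStructure", model = model, nFramesUsed = as.integer(n),
      converged = converged, iterations = iter)
}

setMethod("show", "MeanStructure", function(object) {
  cat(sprintf("MeanStructure: %d pooled frames, %d iterations, %s\n",
              object@nFramesUsed, object@iterations,
              if (object@converged) "converged" else "NOT converged"))
})

#' Per-residue RMSF of pooled, aligned trajectories
#'
#' For each measured atom i, \code{RMSF_i = sqrt(mean(|r_i(t) - <r_i>|^2))}
#' with the average over all pooled frames after aligning each frame to the
#' mean structure on \code{alignOn}. \code{measureOn} must contain one atom
#' per residue (C-alpha). Setting \code{alignOn = NULL} disables alignment
#' (frames are used as-is), in which case the Ornstein-Uhlenbeck closed form
#' sqrt(3) * s applies exactly to synthetic trajectories.
#'
#' @param trajectories Trajectory or list of Trajectories (pooled, equal weight).
#' @param alignOn AtomSelection (or indices) for the fit, or NULL to disable.
#' @param measureOn AtomSelection of one atom per residue.
#' @param mean a \linkS4class{MeanStructure} computed on the same topology;
#'   required when \code{alignOn} is given.
#' @param regions named list of length-2 residue ranges to annotate
#'   (e.g. \code{list(ploop = c(718, 726), alphaC = c(752, 767))}).
#' @return an \linkS4class{RMSFProfile}
#' @export
rmsf <- function(trajectories, alignOn, measureOn, mean = NULL,
                 regions = list()) {
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  frames <- .pooledFrames(trajectories)
  na <- dim(frames)[2]; n <- dim(frames)[1]
  midx <- .resolveSelection(measureOn, na, "measureOn")
  atoms <- trajectories[[1]]@topology@atoms
  resno <- atoms$residue_number[midx]
  if (anyDuplicated(resno))
    .stopf("measureOn contains more than one atom for residue %d",
           resno[which(duplicated(resno))[1]])
  aidx <- .resolveSelection(alignOn, na, "alignOn")
  if (!is.null(aidx)) {
    if (is.null(mean)) .stopf("a MeanStructure is required when aligning")
    refsel <- mean@model@coords[aidx, , drop = FALSE]
    aligned <- array(NA_real_, c(n, length(midx), 3))
    for (k in seq_len(n)) {
      fr <- frames[k, , , drop = TRUE]
      fit <- .kabschCore(fr[aidx, , drop = FALSE], refsel)
      aligned[k, , ] <- .applyTransform(fr[midx, , drop = FALSE], fit)
    }
  } else {
    aligned <- frames[, midx, , drop = FALSE]
  }
  vals <- numeric(length(midx))
  for (j in seq_along(midx)) {
    xyz <- aligned[, j, ]
    mu <- colMeans(xyz)
    vals[j] <- sqrt(mean(rowSums(sweep(xyz, 2, mu)^2)))
  }
  new("RMSFProfile", residueNumbers = as.integer(resno), values = vals,
      regions = regions)
}

#' @describeIn rmsf mean RMSF over an annotated region
#' @param profile an RMSFProfile
#' @param region region name in \code{profile}'s annotations
#' @export
regionRmsf <- function(profile, region) {
  r <- profile@regions[[region]]
  if (is.null(r)) .stopf("unknown region '%s'", region)
  sel <- profile@residueNumbers >= r[1] & profile@residueNumbers <= r[2]
  mean(profile@values[sel])
}

setMethod("show", "RMSFProfile", function(object) {
  cat(sprintf("RMSFProfile: %d residues, mean %.3f A, max %.3f A\n",
              length(object@values), mean(object@values), max(object@values)))
  for (nm in names(object@regions)) {
    cat(sprintf("  region %s (%d-%d): mean %.3f A\n", nm,
                object@regions[[nm]][1], object@regions[[nm]][2],
                regionRmsf(object, nm)))
  }
})

## Map selection indices on a trajectory topology to reference-atom rows by
## (residue_number, atom_name); errors list missing residues.
.mapToReference <- function(atoms, idx, refAtoms) {
  key <- paste(atoms$residue_number[idx], atoms$atom_name[idx])
  refKey <- paste(refAtoms$residue_number, refAtoms$atom_name)
  pos <- match(key, refKey)
  if (anyNA(pos)) {
    missing <- unique(atoms$residue_number[idx][is.na(pos)])
    .stopf("reference is missing residues: %s",
           paste(missing, collapse = ", "))
  }
  pos
}

#' Per-frame RMSD of a trajectory against a reference structure
#'
#' Each frame is superposed onto the reference using \code{alignOn} (matched
#' between trajectory and reference by residue number + atom name), then the
#' RMSD is measured over \code{measureOn} without re-fitting.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param reference a \linkS4class{StructureModel}.
#' @param alignOn,measureOn AtomSelections resolved on the trajectory topology.
#' @return a \linkS4class{TimeSeries} (Angstrom) on the trajectory clock
#' @export
rmsdSeries <- function(traj, reference, alignOn, measureOn) {
  na <- nrow(traj@topology@atoms)
  aidx <- .resolveSelection(alignOn, na, "alignOn")
  midx <- .resolveSelection(measureOn, na, "measureOn")
  if (length(aidx) < 3L) .stopf("alignment selection needs >= 3 atoms")
  atoms <- traj@topology@atoms
  aref <- reference@coords[.mapToReference(atoms, aidx, reference@atoms), ,
                           drop = FALSE]
  mref <- reference@coords[.mapToReference(atoms, midx, reference@atoms), ,
                           drop = FALSE]
  n <- nFrames(traj)
  out <- numeric(n)
  for (k in seq_len(n)) {
    fr <- traj@frames[k, , , drop = TRUE]
    fit <- .kabschCore(fr[aidx, , drop = FALSE], aref)
    moved <- .applyTransform(fr[midx, , drop = FALSE], fit)
    out[k] <- sqrt(mean(rowSums((moved - mref)^2)))
  }
  new("TimeSeries", times = frameTimes(traj), values = out, unit = "A",
      label = sprintf("rmsd(%s vs %s)", traj@label, reference@label))
}
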