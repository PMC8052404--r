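## Synthetic-data generator: every input the pipeline needs, with closed-form
## ground truth. A kinase-like C-alpha scaffold carries the two salt-bridge
## side-chain atoms (Lys NZ, Glu CD); trajectories superimpose (i) per-atom
## Ornstein-Uhlenbeck fluctuations with region-dependent amplitude (exact
## discretisation, so the stationary per-coordinate SD is exact at any frame
## interval), (ii) a two-state telegraph process for the salt-bridge distance
## (imposed kinematically by placing NZ radially from CD), and (iii) telegraph
## switching of the helix block between an active-like and an inactive-like
## rigid pose. Work samples for the free-energy module satisfy the Crooks
## fluctuation relation exactly, so BAR is a consistent estimator of the
## built-in ground truth.

#' Scaffold specification
#'
#' Defaults place residues 700-799 so the familiar kinase numbering can be
#' reused: salt bridge donor 745 (atom NZ) / acceptor 762 (atom CD), helix
#' 752-767, P-loop 718-726 (annotation only).
#'
#' @param nResidues chain length (default 100).
#' @param firstResidue first author residue number (default 700).
#' @param donorResidue,acceptorResidue salt-bridge residue numbers.
#' @param helixRange,ploopRange length-2 inclusive residue ranges.
#' @return validated list of class "ScaffoldSpec"
#' @export
scaffoldSpec <- function(nResidues = 100L, firstResidue = 700L,
                         donorResidue = 745L, acceptorResidue = 762L,
                         helixRange = c(752L, 767L),
                         ploopRange = c(718L, 726L)) {
  last <- firstResidue + nResidues - 1L
  inChain <- function(r) all(r >= firstResidue & r <= last)
  if (!inChain(donorResidue) || !inChain(acceptorResidue))
    .stopf("salt-bridge residues must lie within the chain")
  if (donorResidue == acceptorResidue)
    .stopf("salt-bridge residues must be distinct")
  if (!inChain(helixRange) || !inChain(ploopRange))
    .stopf("region ranges must lie within the chain")
  structure(list(nResidues = as.integer(nResidues),
                 firstResidue = as.integer(firstResidue),
                 donorResidue = as.integer(donorResidue),
                 acceptorResidue = as.integer(acceptorResidue),
                 helixRange = as.integer(helixRange),
                 ploopRange = as.integer(ploopRange)),
            class = "ScaffoldSpec")
}

#' @describeIn scaffoldSpec region annotations (for RMSF profiles)
#' @param spec a ScaffoldSpec
#' @export
scaffoldRegions <- function(spec) {
  list(ploop = spec$ploopRange, alphaC = spec$helixRange)
}

#' Generate a self-avoiding kinase-like C-alpha scaffold
#'
#' A self-avoiding random walk with 3.8 A consecutive C-alpha spacing and a
#' 3.5 A clash cutoff for non-adjacent residues, plus the two named
#' side-chain atoms: the acceptor's carboxyl carbon (CD) offset from its
#' C-alpha, and the donor's terminal nitrogen (NZ) placed at bonded geometry
#' (3.0 A) from CD. Deterministic per seed.
#'
#' @param spec a \code{\link{scaffoldSpec}}.
#' @param seed integer seed.
#' @return a \linkS4class{StructureModel} (nResidues C-alpha + NZ + CD atoms)
#' @export
makeScaffold <- function(spec = scaffoldSpec(), seed = 1L) {
  withSeed(seed, {
    step <- 3.8; clash <- 3.5
    for (attempt in seq_len(50L)) {
      xyz <- matrix(NA_real_, spec$nResidues, 3)
      xyz[1, ] <- c(0, 0, 0)
      dir <- c(1, 0, 0)
      ok <- TRUE
      for (i in seq_len(spec$nResidues)[-1]) {
        placed <- FALSE
        for (try in seq_len(200L)) {
          ## persistent direction keeps the chain open enough to stay
          ## self-avoiding while still folding back on itself
          prop <- dir + rnorm(3, sd = 0.9)
          prop <- prop / sqrt(sum(prop^2))
          cand <- xyz[i - 1L, ] + step * prop
          if (i > 2L) {
            d2 <- rowSums(sweep(xyz[seq_len(i - 2L), , drop = FALSE], 2,
                                cand)^2)
            if (min(d2) < clash^2) next
          }
          xyz[i, ] <- cand; dir <- prop; placed <- TRUE; break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) break
    }
    if (!ok) .stopf("scaffold generation failed after bounded retries")
    resno <- seq(spec$firstResidue, length.out = spec$nResidues)
    resname <- rep("ALA", spec$nResidues)
    resname[resno == spec$donorResidue] <- "LYS"
    resname[resno == spec$acceptorResidue] <- "GLU"
    atoms <- data.frame(serial = NA_integer_, atom_name = "CA",
                        residue_name = resname, residue_number = resno,
                        chain_id = "A", stringsAsFactors = FALSE)
    coords <- xyz
    ## acceptor side-chain carboxyl carbon, offset away from the chain centroid
    accRow <- which(resno == spec$acceptorResidue)
    donRow <- which(resno == spec$donorResidue)
    out <- xyz[accRow, ] - colMeans(xyz)
    out <- out / sqrt(sum(out^2))
    cd <- xyz[accRow, ] + 2.5 * out
    ## donor terminal nitrogen at bonded geometry from CD, pointing toward
    ## the donor C-alpha
    u <- xyz[donRow, ] - cd
    u <- u / sqrt(sum(u^2))
    nz <- cd + 3.0 * u
    ## insert side-chain atoms directly after their residues' C-alpha
    ins <- function(atoms, coords, afterRow, name, rname, rno, xyzRow) {
      n <- nrow(atoms)
      ord <- append(seq_len(n), n + 1L, after = afterRow)
      atoms <- rbind(atoms, data.frame(serial = NA_integer_, atom_name = name,
                                       residue_name = rname,
                                       residue_number = rno, chain_id = "A",
                                       stringsAsFactors = FALSE))[ord, ]
      coords <- rbind(coords, xyzRow)[ord, ]
      list(atoms = atoms, coords = coords)
    }
    tmp <- ins(atoms, coords, donRow, "NZ", "LYS", spec$donorResidue, nz)
    accRow2 <- which(tmp$atoms$residue_number == spec$acceptorResidue &
                     tmp$atoms$atom_name == "CA")
    tmp <- ins(tmp$atoms, tmp$coords, accRow2, "CD", "GLU",
               spec$acceptorResidue, cd)
    tmp$atoms$serial <- seq_len(nrow(tmp$atoms))
    structureModel(tmp$atoms, tmp$coords,
                   sprintf("synthetic-scaffold-%d", spec$nResidues))
  })
}

#' Dynamics specification for synthetic trajectories
#'
#' All numeric values are documented synthetic choices. Amplitudes are
#' Ornstein-Uhlenbeck stationary per-coordinate SDs in Angstrom (so the
#' closed-form C-alpha RMSF is sqrt(3) * amplitude); rates are events/ns;
#' bridge distances are Angstrom; pose angles are degrees of rotation of the
#' helix block about the z axis through its centroid (the inactive pose is
#' the scaffold's own, angle 0, so the scaffold doubles as the inactive-state
#' reference structure).
#'
#' @param nFrames frames per trajectory (default 10000; with the default
#'   100 ps interval that is the 1-microsecond production length).
#' @param frameIntervalPs sampling interval, ps (default 100).
#' @param coreAmplitude,ploopAmplitude,helixAmplitude OU stationary SDs, A.
#' @param ouCorrelationTime OU relaxation time, ps (default 100).
#' @param bridgeBondedMean,bridgeCleavedMean NZ-CD distance means, A.
#' @param bridgeNoiseSd Gaussian observation noise on the distance, A.
#' @param kCleave,kReform telegraph rates bonded->cleaved and back, events/ns.
#' @param helixActiveAngle,helixInactiveAngle pose rotations, degrees.
#' @param helixToInactive,helixToActive pose-switch rates, events/ns.
#' @param bridgeStart,helixStart "stationary" (draw from the stationary law)
#'   or an explicit start state ("bonded"/"cleaved", "active"/"inactive");
#'   used verbatim when the corresponding rates are both zero.
#' @param seed default seed carried with the spec (overridable per call).
#' @return validated list of class "DynamicsSpec"
#' @export
dynamicsSpec <- function(nFrames = 10000L, frameIntervalPs = 100,
                         coreAmplitude = 0.4, ploopAmplitude = 1.0,
                         helixAmplitude = 0.5, ouCorrelationTime = 100,
                         bridgeBondedMean = 3.0, bridgeCleavedMean = 8.0,
                         bridgeNoiseSd = 0.3, kCleave = 0.01, kReform = 0.01,
                         helixActiveAngle = 20, helixInactiveAngle = 0,
                         helixToInactive = 0.01, helixToActive = 0.01,
                         bridgeStart = "stationary", helixStart = "stationary",
                         seed = 1L) {
  stopifnot(nFrames >= 1L, frameIntervalPs > 0, ouCorrelationTime > 0)
  if (min(coreAmplitude, ploopAmplitude, helixAmplitude) < 0)
    .stopf("amplitudes must be >= 0")
  if (min(kCleave, kReform, helixToInactive, helixToActive) < 0)
    .stopf("rates must be >= 0")
  if (min(bridgeBondedMean, bridgeCleavedMean) <= 0)
    .stopf("bridge distance means must be > 0")
  structure(as.list(environment()), class = "DynamicsSpec")
}

## Exact two-state continuous-time telegraph chain observed at frame times.
## Returns integer states (1 = first state, 2 = second) of length n.
## rates are per ns; dtNs is the frame interval in ns.
.telegraphStates <- function(n, dtNs, k12, k21, start) {
  ktot <- k12 + k21
  if (ktot == 0) return(rep(start, n))
  pi2 <- k12 / ktot
  s <- integer(n)
  s[1] <- if (is.na(start)) (if (runif(1) < pi2) 2L else 1L) else start
  decay <- exp(-ktot * dtNs)
  ## exact one-step transition probabilities of the two-state chain
  p12 <- pi2 * (1 - decay)        # from state 1
  p21 <- (1 - pi2) * (1 - decay)  # from state 2
  u <- runif(n - 1L)
  for (k in seq_len(n - 1L)) {
    s[k + 1L] <- if (s[k] == 1L) (if (u[k] < p12) 2L else 1L)
                 else (if (u[k] < p21) 1L else 2L)
  }
  s
}

.rotZ <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

## Rotate a coordinate block about the z axis through its centroid.
.poseCoords <- function(block, deg) {
  ctr <- colMeans(block)
  sweep(sweep(block, 2, ctr) %*% t(.rotZ(deg)), 2, ctr, `+`)
}

#' Simulate a synthetic trajectory with known ground truth
#'
#' See \code{\link{dynamicsSpec}} for the model. The returned ground truth is
#' filled from closed forms: telegraph occupancy \code{kReform / (kCleave +
#' kReform)}, per-region RMSF \code{sqrt(3) * amplitude}, pose occupancies,
#' raw cleavage-event rate \code{pi_bonded * kCleave} per ns, and the
#' occupancy-weighted mean bridge distance.
#'
#' @param scaffold a \linkS4class{StructureModel} from \code{\link{makeScaffold}}.
#' @param dyn a \code{\link{dynamicsSpec}}.
#' @param spec the \code{\link{scaffoldSpec}} used to build the scaffold
#'   (region definitions).
#' @param seed integer; defaults to the spec's seed.
#' @param label trajectory label.
#' @return list(trajectory = \linkS4class{Trajectory}, groundTruth = list)
#' @export
simulateTrajectory <- function(scaffold, dyn = dynamicsSpec(),
                               spec = scaffoldSpec(), seed = dyn$seed,
                               label = "synthetic") {
  atoms <- scaffold@atoms
  N <- nrow(atoms)
  n <- dyn$nFrames
  dt <- dyn$frameIntervalPs
  withSeed(seed, {
    ## per-atom OU amplitude by region
    s <- rep(dyn$coreAmplitude, N)
    inR <- function(r) atoms$residue_number >= r[1] & atoms$residue_number <= r[2]
    s[inR(spec$ploopRange)] <- dyn$ploopAmplitude
    s[inR(spec$helixRange)] <- dyn$helixAmplitude
    a <- exp(-dt / dyn$ouCorrelationTime)
    scol <- rep(s, times = 3)                       # columns: (coord-major)
    x0 <- rnorm(3 * N) * scol
    disp <- matrix(NA_real_, n, 3 * N)
    disp[1, ] <- x0
    if (n > 1L) {
      E <- matrix(rnorm((n - 1L) * 3L * N), n - 1L) *
        rep(scol * sqrt(1 - a^2), each = n - 1L)
      y <- stats::filter(E, a, method = "recursive")
      disp[-1L, ] <- unclass(y) + outer(a^seq_len(n - 1L), x0)
    }
    dispArr <- array(disp, c(n, N, 3))
    frames <- array(rep(scaffold@coords, each = n), c(n, N, 3)) + dispArr
    ## helix pose switching (telegraph: state 1 = active, 2 = inactive)
    hidx <- which(inR(spec$helixRange))
    hStart <- switch(dyn$helixStart, stationary = NA_integer_,
                     active = 1L, inactive = 2L)
    hs <- .telegraphStates(n, dt / 1000, dyn$helixToInactive,
                           dyn$helixToActive, hStart)
    poseA <- .poseCoords(scaffold@coords[hidx, , drop = FALSE],
                         dyn$helixActiveAngle)
    poseI <- .poseCoords(scaffold@coords[hidx, , drop = FALSE],
                         dyn$helixInactiveAngle)
    poses <- array(NA_real_, c(2, length(hidx), 3))
    poses[1, , ] <- poseA; poses[2, , ] <- poseI
    frames[, hidx, ] <- poses[hs, , , drop = FALSE] +
      dispArr[, hidx, , drop = FALSE]
    ## salt-bridge distance telegraph (state 1 = bonded, 2 = cleaved)
    bStart <- switch(dyn$bridgeStart, stationary = NA_integer_,
                     bonded = 1L, cleaved = 2L)
    bs <- .telegraphStates(n, dt / 1000, dyn$kCleave, dyn$kReform, bStart)
    means <- c(dyn$bridgeBondedMean, dyn$bridgeCleavedMean)
    d <- means[bs] + rnorm(n) * dyn$bridgeNoiseSd
    d <- pmax(d, 0.5)
    nzIdx <- which(atoms$atom_name == "NZ")
    cdIdx <- which(atoms$atom_name == "CD")
    u <- scaffold@coords[nzIdx, ] - scaffold@coords[cdIdx, ]
    u <- u / sqrt(sum(u^2))
    frames[, nzIdx, ] <- frames[, cdIdx, ] + outer(d, u)
    traj <- trajectory(scaffold, frames, dt, label)
    ktot <- dyn$kCleave + dyn$kReform
    piB <- if (ktot > 0) dyn$kReform / ktot else
      (if (identical(dyn$bridgeStart, "cleaved")) 0 else 1)
    htot <- dyn$helixToInactive + dyn$helixToActive
    piAct <- if (htot > 0) dyn$helixToActive / htot else
      (if (identical(dyn$helixStart, "inactive")) 0 else 1)
    gt <- list(
      expectedFormedFraction = piB,
      expectedEventRatePerNs = piB * dyn$kCleave,
      bridgeCorrelationTimeNs = if (ktot > 0) 1 / ktot else Inf,
      expectedMeanDistance = piB * dyn$bridgeBondedMean +
        (1 - piB) * dyn$bridgeCleavedMean,
      rmsfPerRegion = c(core = sqrt(3) * dyn$coreAmplitude,
                        ploop = sqrt(3) * dyn$ploopAmplitude,
                        alphaC = sqrt(3) * dyn$helixAmplitude),
      poseOccupancy = c(active = piAct, inactive = 1 - piAct),
      helixCorrelationTimeNs = if (htot > 0) 1 / htot else Inf)
    list(trajectory = traj, groundTruth = gt)
  })
}

#' Named dynamics presets mirroring the qualitative study conditions
#'
#' \code{"WT-like"} and \code{"L858R-like"}: nonzero cleavage/reformation
#' rates (the bridge breaks and reforms frequently), active/inactive helix
#' pose mixing, higher P-loop amplitude. \code{"L747P-like"}: zero cleavage
#' rate with the bridge starting bonded (stably maintained), the helix locked
#' in a pose far from the inactive reference, and reduced P-loop amplitude.
#' All numbers are documented synthetic choices, not measured quantities.
#'
#' @param name one of "WT-like", "L858R-like", "L747P-like".
#' @return a \code{\link{dynamicsSpec}}
#' @export
dynamicsPreset <- function(name) {
  switch(name,
    "WT-like" = dynamicsSpec(kCleave = 0.01, kReform = 0.01,
                             ploopAmplitude = 1.0, coreAmplitude = 0.4,
                             helixAmplitude = 0.5, helixActiveAngle = 20,
                             helixToInactive = 0.01, helixToActive = 0.01),
    "L858R-like" = dynamicsSpec(kCleave = 0.012, kReform = 0.01,
                                ploopAmplitude = 0.9, coreAmplitude = 0.4,
                                helixAmplitude = 0.5, helixActiveAngle = 22,
                                helixToInactive = 0.012, helixToActive = 0.01),
    "L747P-like" = dynamicsSpec(kCleave = 0, kReform = 0.05,
                                ploopAmplitude = 0.5, coreAmplitude = 0.4,
                                helixAmplitude = 0.4, helixActiveAngle = 45,
                                helixToInactive = 0, helixToActive = 0,
                                bridgeStart = "bonded", helixStart = "active"),
    .stopf("unknown preset '%s'; available: WT-like, L858R-like, L747P-like",
           name))
}

## ---- Crooks-consistent work sampler -----------------------------------

#' Sample Crooks-consistent forward/reverse work values over a lambda schedule
#'
#' For each window with true free energy dG: forward work ~ Normal(dG +
#' beta*sigma^2/2, sigma^2) and reverse work ~ Normal(-dG + beta*sigma^2/2,
#' sigma^2), which satisfies the Crooks fluctuation relation
#' P_f(W)/P_r(-W) = exp(beta (W - dG)) exactly. Replica r adds a per-leg
#' offset ~ Normal(0, replicaSd) (shared across that leg's windows) and uses
#' a deterministically derived sub-seed.
#'
#' @param schedule data.frame with columns lambda_from, lambda_to, dG_true and
#'   optionally component ("coulomb"/"vdw") and environment
#'   ("complex"/"solvent"); defaults to 12 evenly spaced windows.
#' @param sigma work SD per window, kcal/mol.
#' @param n samples per direction per window.
#' @param temperature K.
#' @param replicas number of replicas.
#' @param replicaSd SD of the per-replica leg offset, kcal/mol (default 0).
#' @param seed integer.
#' @return data.frame in the \code{\link{readWorkTable}} layout, with the
#'   ground truth (per-window and total dG) as attribute \code{"groundTruth"}
#' @export
sampleCrooksWindows <- function(schedule = NULL, sigma = 1.0, n = 500L,
                                temperature = 300, replicas = 1L,
                                replicaSd = 0, seed = 1L) {
  if (sigma <= 0 || n < 2L) .stopf("need sigma > 0 and n >= 2")
  if (is.null(schedule)) {
    lam <- seq(0, 1, length.out = 13L)
    schedule <- data.frame(lambda_from = lam[-13], lambda_to = lam[-1],
                           dG_true = rep(-0.5, 12))
  }
  if (is.null(schedule$component)) schedule$component <- "vdw"
  if (is.null(schedule$environment)) schedule$environment <- "complex"
  beta <- 1 / (.kB * temperature)
  out <- vector("list", replicas)
  legKey <- paste(schedule$component, schedule$environment)
  for (r in seq_len(replicas)) {
    out[[r]] <- withSeed(deriveSeed(seed, r), {
      offs <- stats::setNames(rnorm(length(unique(legKey)), sd = replicaSd),
                              unique(legKey))
      rows <- lapply(seq_len(nrow(schedule)), function(i) {
        nWinLeg <- sum(legKey == legKey[i])
        dg <- schedule$dG_true[i] + offs[[legKey[i]]] / nWinLeg
        fw <- rnorm(n, dg + beta * sigma^2 / 2, sigma)
        rv <- rnorm(n, -dg + beta * sigma^2 / 2, sigma)
        data.frame(lambda_from = schedule$lambda_from[i],
                   lambda_to = schedule$lambda_to[i],
                   direction = rep(c("forward", "reverse"), each = n),
                   work_kcal_mol = c(fw, rv), replica = r,
                   component = schedule$component[i],
                   environment = schedule$environment[i],
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
  }
  tab <- do.call(rbind, out)
  gt <- stats::aggregate(dG_true ~ component + environment, schedule, sum)
  attr(tab, "groundTruth") <- list(perWindow = schedule, legTotals = gt,
                                   sigma = sigma, temperature = temperature,
                                   replicaSd = replicaSd)
  tab
}

#' Synthetic double-annihilation free-energy study with known ground truth
#'
#' Builds a complete work table (both components, both environments, the
#' replica layout of a five-replica complex / three-replica solvent protocol)
#' whose BAR-aggregated binding free energy has known component totals
#' \code{bindingCoulomb} and \code{bindingVdw} (binding = solvent leg minus
#' complex leg, so favourable binding is negative).
#'
#' @param bindingCoulomb,bindingVdw ground-truth binding components, kcal/mol.
#' @param solventCoulomb,solventVdw solvent annihilation leg totals, kcal/mol.
#' @param nWindows windows per leg (default 12).
#' @param sigma per-window work SD, kcal/mol.
#' @param n samples per direction per window.
#' @param complexReplicas,solventReplicas replica counts (defaults 5 and 3).
#' @param replicaSd per-replica leg offset SD, kcal/mol.
#' @param temperature K.
#' @param seed integer.
#' @return data.frame work table with attribute \code{"groundTruth"}
#'   (bindingCoulomb, bindingVdw, bindingTotal, replicaSd)
#' @export
syntheticFepStudy <- function(bindingCoulomb = -4.0, bindingVdw = -6.5,
                              solventCoulomb = 15.0, solventVdw = 4.0,
                              nWindows = 12L, sigma = 0.8, n = 400L,
                              complexReplicas = 5L, solventReplicas = 3L,
                              replicaSd = 0.1, temperature = 300, seed = 1L) {
  legTotals <- c(complex.coulomb = solventCoulomb - bindingCoulomb,
                 complex.vdw = solventVdw - bindingVdw,
                 solvent.coulomb = solventCoulomb,
                 solvent.vdw = solventVdw)
  lam <- seq(0, 1, length.out = nWindows + 1L)
  ## smooth uneven split of each leg total across its windows
  w <- 1 + 0.5 * sin(seq(0, pi, length.out = nWindows))
  w <- w / sum(w)
  mk <- function(total, comp, env) {
    data.frame(lambda_from = lam[-(nWindows + 1L)], lambda_to = lam[-1],
               dG_true = total * w, component = comp, environment = env,
               stringsAsFactors = FALSE)
  }
  schedC <- rbind(mk(legTotals[["complex.coulomb"]], "coulomb", "complex"),
                  mk(legTotals[["complex.vdw"]], "vdw", "complex"))
  schedS <- rbind(mk(legTotals[["solvent.coulomb"]], "coulomb", "solvent"),
                  mk(legTotals[["solvent.vdw"]], "vdw", "solvent"))
  tabC <- sampleCrooksWindows(schedC, sigma, n, temperature,
                              complexReplicas, replicaSd, deriveSeed(seed, 101))
  tabS <- sampleCrooksWindows(schedS, sigma, n, temperature,
                              solventReplicas, replicaSd, deriveSeed(seed, 202))
  tab <- rbind(tabC, tabS)
  attr(tab, "groundTruth") <- list(
    bindingCoulomb = bindingCoulomb, bindingVdw = bindingVdw,
    bindingTotal = bindingCoulomb + bindingVdw, legTotals = legTotals,
    sigma = sigma, replicaSd = replicaSd, temperature = temperature)
  tab
}
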