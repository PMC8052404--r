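#' @import methods
NULL

## Central containers. Coordinates are in Angstrom, times in picoseconds,
## residue numbers are author numbering (1-based), energies in kcal/mol.

#' StructureModel: a static set of atoms with identities and coordinates
#'
#' Holds one model of a structure: per-atom identities (serial, atom name,
#' residue name/number, chain) in a data.frame and an N x 3 coordinate matrix
#' in Angstrom. Atom order is stable and defines the coordinate indexing used
#' by every downstream operation.
#'
#' @slot atoms data.frame with columns serial, atom_name, residue_name,
#'   residue_number, chain_id (one row per atom).
#' @slot coords numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @slot label character scalar naming the structure.
#' @exportClass StructureModel
setClass("StructureModel",
  representation(atoms = "data.frame", coords = "matrix", label = "character"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("serial", "atom_name", "residue_name", "residue_number", "chain_id")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("structure must contain at least one atom")
  if (nrow(a) != nrow(object@coords) || ncol(object@coords) != 3L)
    return("coords must be an n_atoms x 3 matrix")
  if (!all(is.finite(object@coords))) return("coordinates must be finite")
  key <- paste(a$chain_id, a$residue_number, a$atom_name)
  if (anyDuplicated(key))
    return("(chain_id, residue_number, atom_name) must be unique within a model")
  TRUE
})

#' Trajectory: time-ordered coordinate frames over a fixed atom set
#'
#' @slot topology StructureModel defining atom identities and order.
#' @slot frames numeric array n_frames x n_atoms x 3 (Angstrom).
#' @slot frameInterval numeric scalar, time between frames (ps); frame k
#'   (1-based) is at time (k-1) * frameInterval.
#' @slot label character scalar.
#' @exportClass Trajectory
setClass("Trajectory",
  representation(topology = "StructureModel", frames = "array",
                 frameInterval = "numeric", label = "character"))

setValidity("Trajectory", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L || d[3] != 3L)
    return("frames must be an n_frames x n_atoms x 3 array")
  if (d[2] != nrow(object@topology@atoms))
    return("every frame must have exactly as many coordinates as the topology has atoms")
  if (d[1] < 1L) return("trajectory must contain at least one frame")
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0)
    return("frameInterval must be a single positive number (ps)")
  if (!all(is.finite(object@frames))) return("frame coordinates must be finite")
  TRUE
})

#' AtomSelection: resolved atom indices plus the query that produced them
#'
#' @slot indices integer vector of 1-based positions into the topology atom
#'   list, strictly increasing.
#' @slot descriptor character scalar describing the query.
#' @exportClass AtomSelection
setClass("AtomSelection",
  representation(indices = "integer", descriptor = "character"))

setValidity("AtomSelection", function(object) {
  i <- object@indices
  if (length(i) == 0L) return("selection must be non-empty")
  if (any(i < 1L) || is.unsorted(i, strictly = TRUE))
    return("indices must be strictly increasing positive integers")
  TRUE
})

#' TimeSeries: (time, value) samples with units and provenance
#'
#' @slot times numeric, ps, strictly increasing.
#' @slot values numeric, same length as times.
#' @slot unit character scalar (e.g. "A").
#' @slot label character scalar.
#' @slot windowNs numeric; NA for raw series, the smoothing window length (ns)
#'   for smoothed variants.
#' @exportClass TimeSeries
setClass("TimeSeries",
  representation(times = "numeric", values = "numeric", unit = "character",
                 label = "character", windowNs = "numeric"),
  prototype(windowNs = NA_real_, unit = "A", label = ""))

setValidity("TimeSeries", function(object) {
  if (length(object@times) != length(object@values))
    return("times and values must have equal length")
  if (length(object@times) == 0L) return("series must be non-empty")
  if (is.unsorted(object@times, strictly = TRUE))
    return("times must be strictly increasing")
  if (!all(is.finite(object@values))) return("values must be finite")
  TRUE
})

#' SuperpositionResult: optimal rigid transform of one point set onto another
#'
#' The transform maps mobile points p to rotation %*% p + translation.
#'
#' @slot rotation 3 x 3 proper rotation matrix (det +1).
#' @slot translation length-3 numeric (Angstrom).
#' @slot rmsd numeric scalar, minimised RMSD (Angstrom).
#' @slot illConditioned logical; TRUE when the point sets are (near) collinear
#'   so the rotation about the common axis is not determined (the optimum RMSD
#'   is still returned).
#' @exportClass SuperpositionResult
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", illConditioned = "logical"))

#' MeanStructure: iteratively aligned ensemble average
#'
#' @slot model StructureModel holding the averaged coordinates.
#' @slot nFramesUsed integer, pooled frame count.
#' @slot converged logical.
#' @slot iterations integer.
#' @exportClass MeanStructure
setClass("MeanStructure",
  representation(model = "StructureModel", nFramesUsed = "integer",
                 converged = "logical", iterations = "integer"))

#' RMSFProfile: per-residue root-mean-square fluctuation
#'
#' @slot residueNumbers integer vector.
#' @slot values numeric, Angstrom, one per residue, >= 0.
#' @slot regions named list of length-2 integer ranges (first, last residue)
#'   annotating e.g. the P-loop and the alpha-C helix.
#' @exportClass RMSFProfile
setClass("RMSFProfile",
  representation(residueNumbers = "integer", values = "numeric",
                 regions = "list"))

setValidity("RMSFProfile", function(object) {
  if (length(object@residueNumbers) != length(object@values))
    return("one value per residue required")
  if (any(object@values < 0)) return("RMSF values must be >= 0")
  rng <- range(object@residueNumbers)
  for (nm in names(object@regions)) {
    r <- object@regions[[nm]]
    if (length(r) != 2L || r[1] > r[2] || r[1] < rng[1] || r[2] > rng[2])
      return(sprintf("region '%s' must be a range within the residue list", nm))
  }
  TRUE
})

#' SaltBridgeResult: distance series, occupancy and event statistics
#'
#' @slot rawSeries list of TimeSeries, one per replica (distance, Angstrom).
#' @slot smoothedSeries list of TimeSeries (window-averaged).
#' @slot windowNs numeric, smoothing window (ns).
#' @slot formedFraction numeric per replica in [0,1]: fraction of raw frames
#'   with distance below the formed threshold at t >= analysisStart.
#' @slot nCleavageEvents integer per replica: dwell-filtered excursions of the
#'   smoothed series above the threshold at t >= analysisStart.
#' @slot ensembleMean,ensembleSd numeric (Angstrom): mean and SD across
#'   replicas of the per-replica time-averaged distance (t >= analysisStart).
#' @slot analysisStart numeric, ps.
#' @slot parameters named list echoing thresholds used.
#' @exportClass SaltBridgeResult
setClass("SaltBridgeResult",
  representation(rawSeries = "list", smoothedSeries = "list",
                 windowNs = "numeric", formedFraction = "numeric",
                 nCleavageEvents = "integer", ensembleMean = "numeric",
                 ensembleSd = "numeric", analysisStart = "numeric",
                 parameters = "list"))

setValidity("SaltBridgeResult", function(object) {
  n <- length(object@rawSeries)
  if (length(object@smoothedSeries) != n ||
      length(object@formedFraction) != n || length(object@nCleavageEvents) != n)
    return("per-replica slots must have one entry per replica")
  if (any(object@formedFraction < 0 | object@formedFraction > 1))
    return("formedFraction must lie in [0,1]")
  if (any(object@nCleavageEvents < 0L)) return("event counts must be >= 0")
  TRUE
})

#' RMSDDistribution: pooled per-frame RMSD samples plus histogram
#'
#' @slot samples numeric, per-frame RMSD (Angstrom), pooled over replicas.
#' @slot perReplicaMeans numeric, one per replica.
#' @slot breaks numeric histogram bin edges (Angstrom), fixed width from 0.
#' @slot density numeric, one per bin; integrates to 1.
#' @slot binWidth numeric (Angstrom).
#' @slot referenceLabel,alignDescriptor,measureDescriptor character.
#' @exportClass RMSDDistribution
setClass("RMSDDistribution",
  representation(samples = "numeric", perReplicaMeans = "numeric",
                 breaks = "numeric", density = "numeric", binWidth = "numeric",
                 referenceLabel = "character", alignDescriptor = "character",
                 measureDescriptor = "character"))

setValidity("RMSDDistribution", function(object) {
  if (any(object@samples < 0)) return("RMSD samples must be >= 0")
  if (length(object@density) != length(object@breaks) - 1L)
    return("density must have one entry per bin")
  mass <- sum(object@density * diff(object@breaks))
  if (abs(mass - 1) > 1e-8) return("histogram densities must integrate to 1")
  TRUE
})

#' WorkSamples: forward/reverse work values for one lambda window
#'
#' @slot lambdaFrom,lambdaTo numeric in [0,1].
#' @slot forward numeric work values (kcal/mol) for the from->to perturbation.
#' @slot reverse numeric work values (kcal/mol) for the to->from perturbation.
#' @slot temperature numeric, K.
#' @exportClass WorkSamples
setClass("WorkSamples",
  representation(lambdaFrom = "numeric", lambdaTo = "numeric",
                 forward = "numeric", reverse = "numeric",
                 temperature = "numeric"))

setValidity("WorkSamples", function(object) {
  if (length(object@forward) < 1L || length(object@reverse) < 1L)
    return("both forward and reverse sample sets must be non-empty")
  if (object@temperature <= 0) return("temperature must be positive (K)")
  for (l in c(object@lambdaFrom, object@lambdaTo))
    if (l < 0 || l > 1) return("lambda values must lie in [0,1]")
  TRUE
})

#' LegResult: free energy of one annihilation leg (one component, one
#' environment), chained over its lambda windows
#'
#' @slot name "coulomb" or "vdw".
#' @slot environment "complex" or "solvent".
#' @slot replica integer replica index.
#' @slot windowDGs numeric per window (kcal/mol).
#' @slot dG numeric, sum of windowDGs.
#' @slot se numeric >= 0, sqrt of summed per-window BAR variances.
#' @slot lowOverlap logical per window.
#' @exportClass LegResult
setClass("LegResult",
  representation(name = "character", environment = "character",
                 replica = "integer", windowDGs = "numeric", dG = "numeric",
                 se = "numeric", lowOverlap = "logical"))

setValidity("LegResult", function(object) {
  if (!object@name %in% c("coulomb", "vdw"))
    return("leg name must be 'coulomb' or 'vdw'")
  if (!object@environment %in% c("complex", "solvent"))
    return("environment must be 'complex' or 'solvent'")
  if (abs(object@dG - sum(object@windowDGs)) > 1e-9 * max(1, abs(object@dG)))
    return("dG must equal the sum of window dGs")
  if (object@se < 0) return("se must be >= 0")
  TRUE
})

#' BindingFreeEnergy: double-annihilation binding free energy with
#' Coulomb/van der Waals decomposition and replica spread
#'
#' Binding-favourable values are negative.
#'
#' @slot dGTotal,dGCoulomb,dGVdw numeric (kcal/mol), replica means.
#' @slot replicaSd numeric, SD across replica means of the total.
#' @slot nReplicas integer.
#' @slot perReplica data.frame(replica, coulomb, vdw, total).
#' @slot asymptoticSe numeric: BAR-propagated standard error of the total
#'   (reported alongside the replica spread, not in place of it).
#' @slot label character.
#' @exportClass BindingFreeEnergy
setClass("BindingFreeEnergy",
  representation(dGTotal = "numeric", dGCoulomb = "numeric", dGVdw = "numeric",
                 replicaSd = "numeric", nReplicas = "integer",
                 perReplica = "data.frame", asymptoticSe = "numeric",
                 label = "character"),
  prototype(label = ""))

setValidity("BindingFreeEnergy", function(object) {
  if (abs(object@dGTotal - (object@dGCoulomb + object@dGVdw)) > 1e-8)
    return("dGTotal must equal dGCoulomb + dGVdw")
  if (!is.na(object@replicaSd) && object@replicaSd < 0)
    return("replicaSd must be >= 0")
  TRUE
})
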