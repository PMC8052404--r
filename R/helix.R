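## Alpha-C helix orientation analysis: distribution of helix C-alpha RMSD
## against an inactive-state reference structure after global C-alpha
## alignment, plus an overlap coefficient between two such distributions.

#' Helix orientational RMSD distribution
#'
#' For every frame of every replica: superpose the frame onto the reference on
#' \code{alignOn} (by default all C-alpha atoms shared with the reference),
#' then measure the RMSD over the helix C-alpha atoms without re-fitting.
#' Samples are pooled over replicas into a fixed-width histogram starting at
#' zero (density-normalised). \code{excludeHelixFromAlignment} switches to the
#' stricter orientation-sensitive variant in which the helix atoms are removed
#' from the alignment set.
#'
#' @param trajectories Trajectory or list of replicas sharing a topology.
#' @param reference a \linkS4class{StructureModel} (any PDB-derived structure;
#'   matched by residue number + atom name).
#' @param alignOn AtomSelection for the fit; default: all C-alpha atoms.
#' @param helix AtomSelection of the helix C-alpha atoms.
#' @param binWidth histogram bin width, Angstrom (default 0.25).
#' @param excludeHelixFromAlignment logical (default FALSE).
#' @return an \linkS4class{RMSDDistribution}
#' @export
helixRmsdDistribution <- function(trajectories, reference, helix,
                                  alignOn = NULL, binWidth = 0.25,
                                  excludeHelixFromAlignment = FALSE) {
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  if (binWidth <= 0) .stopf("binWidth must be > 0")
  topo <- trajectories[[1]]@topology
  if (is.null(alignOn)) alignOn <- selectAtoms(topo, atomName = "CA")
  na <- nrow(topo@atoms)
  aidx <- .resolveSelection(alignOn, na, "alignOn")
  hidx <- .resolveSelection(helix, na, "helix")
  if (excludeHelixFromAlignment) {
    aidx <- setdiff(aidx, hidx)
    if (length(aidx) < 3L)
      .stopf("alignment set is empty after excluding the helix")
  }
  ## keep only alignment atoms present in the reference
  key <- with(topo@atoms, paste(residue_number, atom_name))
  refKey <- with(reference@atoms, paste(reference@atoms$residue_number,
                                        reference@atoms$atom_name))
  aidx <- aidx[key[aidx] %in% refKey]
  if (length(aidx) < 3L) .stopf("reference shares fewer than 3 alignment atoms")
  if (!all(key[hidx] %in% refKey)) {
    missing <- unique(topo@atoms$residue_number[hidx][!key[hidx] %in% refKey])
    .stopf("reference is missing helix residues: %s",
           paste(missing, collapse = ", "))
  }
  alignSel <- new("AtomSelection", indices = as.integer(sort(aidx)),
                  descriptor = if (excludeHelixFromAlignment)
                    "CA shared, helix excluded" else "CA shared")
  samples <- list(); repMeans <- numeric(length(trajectories))
  for (r in seq_along(trajectories)) {
    s <- rmsdSeries(trajectories[[r]], reference, alignSel, helix)
    samples[[r]] <- s@values
    repMeans[r] <- mean(s@values)
  }
  pooled <- unlist(samples)
  breaks <- seq(0, (floor(max(pooled) / binWidth) + 1) * binWidth,
                by = binWidth)
  h <- hist(pooled, breaks = breaks, plot = FALSE, right = FALSE)
  new("RMSDDistribution", samples = pooled, perReplicaMeans = repMeans,
      breaks = breaks, density = h$density, binWidth = binWidth,
      referenceLabel = reference@label,
      alignDescriptor = alignSel@descriptor,
      measureDescriptor = .selectionDescriptor(helix))
}

setMethod("show", "RMSDDistribution", function(object) {
  cat(sprintf(
    "RMSDDistribution vs '%s': %d samples, mean %.2f A (replicas: %s)\n",
    object@referenceLabel, length(object@samples), mean(object@samples),
    paste(sprintf("%.2f", object@perReplicaMeans), collapse = ", ")))
})

## Rebin a distribution's samples onto given breaks (density).
.rebin <- function(samples, breaks) {
  h <- hist(pmin(samples, max(breaks) - 1e-12), breaks = breaks, plot = FALSE,
            right = FALSE)
  h$density
}

#' Overlap coefficient between two RMSD distributions
#'
#' The two density histograms are rebinned to a common grid at the coarser of
#' the two bin widths and the overlap coefficient
#' \code{sum(pmin(d1, d2)) * binWidth} is returned: 0 for disjoint supports,
#' 1 for identical distributions. The per-replica mean difference
#' (mean(b) - mean(a)) is attached as attribute \code{"meanDifference"}.
#'
#' @param distA,distB \linkS4class{RMSDDistribution}s.
#' @return numeric in [0, 1]
#' @export
separationScore <- function(distA, distB) {
  bw <- max(distA@binWidth, distB@binWidth)
  top <- max(distA@samples, distB@samples)
  breaks <- seq(0, (floor(top / bw) + 1) * bw, by = bw)
  da <- .rebin(distA@samples, breaks)
  db <- .rebin(distB@samples, breaks)
  ov <- sum(pmin(da, db)) * bw
  attr(ov, "meanDifference") <- mean(distB@perReplicaMeans) -
    mean(distA@perReplicaMeans)
  ov
}
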