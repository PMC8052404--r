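## Salt-bridge distance analysis: per-frame donor-acceptor distance series,
## centered window smoothing, occupancy / cleavage-event statistics across
## replicas, and active/inactive conformation classification.
##
## The distance is taken between the atoms the selections name - for the
## kinase K745-E762 bridge that is the lysine side-chain terminal nitrogen
## (NZ) and the glutamate side-chain carboxyl carbon (CD), not the common
## N-O convention.

#' Distance time series between two atoms
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param a,b singleton \linkS4class{AtomSelection}s (or single indices).
#' @return a \linkS4class{TimeSeries} of Euclidean distances (Angstrom) on the
#'   trajectory clock
#' @export
pairDistanceSeries <- function(traj, a, b) {
  na <- nrow(traj@topology@atoms)
  ia <- .resolveSelection(a, na, "a")
  ib <- .resolveSelection(b, na, "b")
  if (length(ia) != 1L || length(ib) != 1L)
    .stopf("both selections must contain exactly one atom (got %d and %d)",
           length(ia), length(ib))
  d <- sqrt(rowSums((traj@frames[, ia, ] - traj@frames[, ib, ])^2))
  new("TimeSeries", times = frameTimes(traj), values = d, unit = "A",
      label = sprintf("dist[%s-%s](%s)", .selectionDescriptor(a),
                      .selectionDescriptor(b), traj@label))
}

#' Centered moving window average of a time series
#'
#' At each time t the output is the mean of all samples within
#' [t - w/2, t + w/2]; edges use the truncated window (no padding); output
#' times equal input times. Mean-preserving on interior windows; preserves
#' linear trends away from the edges.
#'
#' @param series a \linkS4class{TimeSeries}.
#' @param windowNs window length in ns; must be at least one sampling interval.
#' @return a \linkS4class{TimeSeries} with \code{windowNs} recorded
#' @export
windowAverage <- function(series, windowNs) {
  t <- series@times
  if (windowNs <= 0) .stopf("window must be > 0")
  w <- windowNs * 1000            # ps
  if (length(t) > 1L && w < min(diff(t)))
    .stopf("degenerate window: %g ns is smaller than the sampling interval",
           windowNs)
  half <- w / 2 * (1 + 1e-12)     # tolerate float jitter at window edges
  lo <- findInterval(t - half, t, left.open = TRUE) + 1L  # first index in window
  hi <- findInterval(t + half, t)                          # last index in window
  cs <- c(0, cumsum(series@values))
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  new("TimeSeries", times = t, values = out, unit = series@unit,
      label = paste0(series@label, " [smoothed]"), windowNs = windowNs)
}

## Count excursions of a smoothed series above `threshold` lasting at least
## `minEventPs`, within times >= startPs. Dwell-filtered, hysteresis-free.
.countCleavageEvents <- function(times, values, threshold, minEventPs,
                                 startPs) {
  keep <- times >= startPs
  v <- values[keep]; tt <- times[keep]
  if (!length(v)) return(0L)
  above <- v >= threshold
  r <- rle(above)
  dt <- if (length(tt) > 1L) tt[2] - tt[1] else 0
  dur <- r$lengths * dt           # run length x sampling interval
  keep <- r$values & dur >= minEventPs
  ## a cleavage event is a formed -> cleaved transition: a run that begins
  ## the window already cleaved is state, not an event
  if (length(keep) && r$values[1]) keep[1] <- FALSE
  sum(keep)
}

#' Salt-bridge occupancy and cleavage-event analysis across replicas
#'
#' Per replica: the raw donor-acceptor distance series and its window-averaged
#' version; the formed fraction (fraction of raw frames with distance below
#' \code{formedThreshold} at t >= \code{analysisStartNs}); and the number of
#' cleavage events, counted on the smoothed series as excursions at or above
#' the threshold lasting at least \code{minEventNs} (within the same analysis
#' window). Ensemble mean/SD are taken across replicas of the per-replica
#' time-averaged distance.
#'
#' @param trajectories Trajectory or list of replicas sharing a topology.
#' @param donor,acceptor singleton selections (e.g. Lys NZ and Glu CD).
#' @param formedThreshold formed-state distance cutoff, Angstrom (default 4.5,
#'   the conventional salt-bridge cutoff on this atom pair).
#' @param minEventNs dwell filter for cleavage events, ns (default 10, one
#'   smoothing window; suppresses single-frame recrossings).
#' @param windowNs smoothing window, ns (default 10).
#' @param analysisStartNs equilibration discarded before statistics, ns
#'   (default 100).
#' @return a \linkS4class{SaltBridgeResult}
#' @export
saltBridgeAnalysis <- function(trajectories, donor, acceptor,
                               formedThreshold = 4.5, minEventNs = 10,
                               windowNs = 10, analysisStartNs = 100) {
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  if (!length(trajectories)) .stopf("need at least one trajectory")
  if (formedThreshold <= 0 || minEventNs < 0 || windowNs <= 0)
    .stopf("thresholds must be positive")
  startPs <- analysisStartNs * 1000
  raw <- lapply(trajectories, pairDistanceSeries, a = donor, b = acceptor)
  for (s in raw) {
    if (max(s@times) < startPs)
      .stopf("analysis start (%g ns) is beyond the trajectory end (%g ns)",
             analysisStartNs, max(s@times) / 1000)
  }
  smoothed <- lapply(raw, windowAverage, windowNs = windowNs)
  formed <- vapply(raw, function(s) {
    keep <- s@times >= startPs
    mean(s@values[keep] < formedThreshold)
  }, 1.0)
  events <- vapply(smoothed, function(s) {
    .countCleavageEvents(s@times, s@values, formedThreshold,
                         minEventNs * 1000, startPs)
  }, 1L)
  repMeans <- vapply(raw, function(s) mean(s@values[s@times >= startPs]), 1.0)
  new("SaltBridgeResult",
      rawSeries = raw, smoothedSeries = smoothed, windowNs = windowNs,
      formedFraction = formed, nCleavageEvents = as.integer(events),
      ensembleMean = mean(repMeans),
      ensembleSd = if (length(repMeans) > 1L) sd(repMeans) else NA_real_,
      analysisStart = startPs,
      parameters = list(formedThreshold = formedThreshold,
                        minEventNs = minEventNs, windowNs = windowNs,
                        analysisStartNs = analysisStartNs))
}

setMethod("show", "SaltBridgeResult", function(object) {
  cat(sprintf(
    "SaltBridgeResult: %d replicas, ensemble mean %.2f A (sd %.2f)\n",
    length(object@rawSeries), object@ensembleMean, object@ensembleSd))
  cat(sprintf("  formed fraction: %s\n",
              paste(sprintf("%.3f", object@formedFraction), collapse = ", ")))
  cat(sprintf("  cleavage events: %s\n",
              paste(object@nCleavageEvents, collapse = ", ")))
})

#' Classify replicas as active-stabilized or dynamic
#'
#' A replica whose formed fraction is at least \code{stableFraction} is
#' labelled \code{"active-stabilized"} (the K745-E762 bridge is a feature of
#' the active kinase conformation); otherwise \code{"dynamic"}. The ensemble
#' label is the majority over replicas, with ties labelled \code{"dynamic"}.
#'
#' @param result a \linkS4class{SaltBridgeResult}.
#' @param stableFraction threshold in (0, 1] (default 0.9).
#' @return list with \code{replica} (character vector) and \code{ensemble}
#' @export
classifyConformation <- function(result, stableFraction = 0.9) {
  if (stableFraction <= 0 || stableFraction > 1)
    .stopf("stableFraction must lie in (0, 1]")
  lab <- ifelse(result@formedFraction >= stableFraction,
                "active-stabilized", "dynamic")
  nAct <- sum(lab == "active-stabilized")
  ens <- if (nAct * 2L > length(lab)) "active-stabilized" else "dynamic"
  list(replica = lab, ensemble = ens)
}
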