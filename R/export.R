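## TSV exporters. All files carry '#'-prefixed header lines echoing the
## selections and parameters that produced them; numeric columns use a fixed
## 6-decimal format so identical analyses yield byte-identical files.

#' Write a time series as TSV (time_ps, value columns)
#'
#' @param series a \linkS4class{TimeSeries}.
#' @param path output path.
#' @param extraHeader additional comment lines.
#' @return invisibly, the path
#' @export
writeTimeSeriesTSV <- function(series, path, extraHeader = character()) {
  hdr <- c(paste0("series: ", series@label),
           paste0("unit: ", series@unit),
           if (!is.na(series@windowNs))
             paste0("window_ns: ", series@windowNs),
           extraHeader)
  writeCommentedTSV(data.frame(time_ps = series@times, value = series@values),
                    path, hdr)
}

#' Write salt-bridge results: per-replica series and a summary table
#'
#' @param result a \linkS4class{SaltBridgeResult}.
#' @param dir output directory.
#' @param prefix file-name prefix (e.g. the variant label).
#' @return invisibly, the written paths
#' @export
writeSaltBridgeTSV <- function(result, dir, prefix = "saltbridge") {
  p <- result@parameters
  hdr <- c(sprintf("formed_threshold_A: %g", p$formedThreshold),
           sprintf("window_ns: %g", p$windowNs),
           sprintf("min_event_ns: %g", p$minEventNs),
           sprintf("analysis_start_ns: %g", p$analysisStartNs))
  paths <- character()
  for (r in seq_along(result@rawSeries)) {
    df <- data.frame(time_ps = result@rawSeries[[r]]@times,
                     raw_A = result@rawSeries[[r]]@values,
                     smoothed_A = result@smoothedSeries[[r]]@values)
    f <- file.path(dir, sprintf("%s_replica%d.tsv", prefix, r))
    writeCommentedTSV(df, f, c(hdr, sprintf("replica: %d", r)))
    paths <- c(paths, f)
  }
  sm <- data.frame(replica = seq_along(result@rawSeries),
                   formed_fraction = result@formedFraction,
                   n_events = result@nCleavageEvents,
                   mean_A = vapply(result@rawSeries, function(s)
                     mean(s@values[s@times >= result@analysisStart]), 1.0))
  f <- file.path(dir, paste0(prefix, "_summary.tsv"))
  writeCommentedTSV(sm, f, c(hdr,
    sprintf("ensemble_mean_A: %s", .fmt(result@ensembleMean)),
    sprintf("ensemble_sd_A: %s",
            if (is.na(result@ensembleSd)) "NA" else .fmt(result@ensembleSd))))
  invisible(c(paths, f))
}

#' Write an RMSF profile as TSV (residue_number, rmsf_A)
#'
#' @param profile an \linkS4class{RMSFProfile}.
#' @param path output path.
#' @param extraHeader additional comment lines (e.g. the selections used).
#' @return invisibly, the path
#' @export
writeRmsfTSV <- function(profile, path, extraHeader = character()) {
  hdr <- c(extraHeader, vapply(names(profile@regions), function(nm)
    sprintf("region %s: %d-%d", nm, profile@regions[[nm]][1],
            profile@regions[[nm]][2]), ""))
  writeCommentedTSV(data.frame(residue_number = profile@residueNumbers,
                               rmsf_A = profile@values), path, hdr)
}

#' Write an RMSD distribution: pooled samples and histogram TSVs
#'
#' @param dist an \linkS4class{RMSDDistribution}.
#' @param samplesPath,histPath output paths.
#' @return invisibly, the two paths
#' @export
writeRmsdDistributionTSV <- function(dist, samplesPath, histPath) {
  hdr <- c(paste0("reference: ", dist@referenceLabel),
           paste0("align: ", dist@alignDescriptor),
           paste0("measure: ", dist@measureDescriptor),
           sprintf("bin_width_A: %g", dist@binWidth))
  writeCommentedTSV(data.frame(sample = seq_along(dist@samples),
                               rmsd_A = dist@samples), samplesPath, hdr)
  nb <- length(dist@breaks) - 1L
  writeCommentedTSV(data.frame(bin_left_A = dist@breaks[-(nb + 1L)],
                               bin_right_A = dist@breaks[-1],
                               density = dist@density), histPath, hdr)
  invisible(c(samplesPath, histPath))
}
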