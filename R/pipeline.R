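## Config-driven orchestration: per-variant salt-bridge statistics, mean
## structure, RMSF profile and helix-orientation RMSD distribution; cross-
## variant conformation labels, separation scores and (optionally) binding
## free-energy comparison. One structured YAML config; outputs are plain-text
## TSV/PDB plus a manifest, deterministic under a fixed seed (no timestamps).

#' Read and validate a pipeline run configuration
#'
#' YAML schema (defaults in parentheses mirror the standard protocol:
#' 100 ps sampling, 10 ns smoothing window, analysis from 100 ns):
#' \preformatted{
#' seed: 1
#' output_dir: out
#' reference_structure: reference.pdb
#' frame_interval_ps: 100
#' variants:
#'   WT-like: [wt_rep1.pdb, wt_rep2.pdb, wt_rep3.pdb]
#' selections:
#'   donor:    {residue_number: 745, atom_name: NZ}
#'   acceptor: {residue_number: 762, atom_name: CD}
#'   helix_range: [752, 767]
#'   ploop_range: [718, 726]
#'   align_atom: CA
#' parameters:
#'   window_ns: 10
#'   analysis_start_ns: 100
#'   formed_threshold: 4.5
#'   min_event_ns: 10
#'   bin_width: 0.25
#'   stable_fraction: 0.9
#' fep:
#'   temperature: 300
#'   work_tables: {WT-like: wt_work.tsv}
#'   reference_label: WT-like
#' }
#'
#' @param path YAML file path.
#' @return validated config list of class "RunConfig"
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$variants) || !length(cfg$variants))
    .stopf("config must define at least one variant")
  if (is.null(cfg$reference_structure))
    .stopf("config must name a reference_structure")
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  cfg$reference_structure <- resolve(cfg$reference_structure)
  if (!file.exists(cfg$reference_structure))
    .stopf("reference structure not found: %s", cfg$reference_structure)
  for (v in names(cfg$variants)) {
    cfg$variants[[v]] <- vapply(cfg$variants[[v]], resolve, "")
    missing <- cfg$variants[[v]][!file.exists(cfg$variants[[v]])]
    if (length(missing))
      .stopf("variant '%s': trajectory not found: %s", v, missing[1])
  }
  defaults <- list(window_ns = 10, analysis_start_ns = 100,
                   formed_threshold = 4.5, min_event_ns = 10,
                   bin_width = 0.25, stable_fraction = 0.9)
  cfg$parameters <- utils::modifyList(defaults,
                                      as.list(cfg$parameters %||% list()))
  selDefaults <- list(
    donor = list(residue_number = 745, atom_name = "NZ"),
    acceptor = list(residue_number = 762, atom_name = "CD"),
    helix_range = c(752, 767), ploop_range = c(718, 726), align_atom = "CA")
  cfg$selections <- utils::modifyList(selDefaults,
                                      as.list(cfg$selections %||% list()))
  cfg$frame_interval_ps <- cfg$frame_interval_ps %||% 100
  cfg$seed <- cfg$seed %||% 1L
  ## output_dir is taken relative to the config file unless absolute
  od <- cfg$output_dir %||% "mdconf_out"
  if (!grepl("^(/|[A-Za-z]:)", od)) od <- file.path(base, od)
  cfg$output_dir <- od
  if (!is.null(cfg$fep)) {
    cfg$fep$temperature <- cfg$fep$temperature %||% 300
    for (lb in names(cfg$fep$work_tables)) {
      cfg$fep$work_tables[[lb]] <- resolve(cfg$fep$work_tables[[lb]])
      if (!file.exists(cfg$fep$work_tables[[lb]]))
        .stopf("work table not found: %s", cfg$fep$work_tables[[lb]])
    }
  }
  structure(cfg, class = "RunConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Per variant: salt-bridge analysis (per-replica TSV + summary), iterative
#' mean structure (written as PDB), C-alpha RMSF profile (TSV) and the helix
#' orientational RMSD distribution against the reference structure (samples +
#' histogram TSV). Cross-variant: conformation labels, pairwise separation
#' scores and, when work tables are configured, the binding free-energy
#' comparison table. A manifest records package version, seed and all
#' parameters. Any stage error aborts with the stage and variant named, and
#' partial outputs are removed.
#'
#' @param config a "RunConfig" from \code{\link{readRunConfig}} (or a path).
#' @return invisible list with the per-variant results, labels, separation
#'   scores, optional FEP table and the output file manifest
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  out <- config$output_dir %||% "mdconf_out"
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  par <- config$parameters
  sel <- config$selections
  stage <- function(what, variant, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed for '%s': %s", what, variant,
             conditionMessage(e)))
  }
  reference <- stage("read-reference", config$reference_structure,
                     readPDB(config$reference_structure))
  results <- list(); warningsLog <- character()
  for (v in names(config$variants)) {
    trajs <- stage("read-trajectories", v, lapply(
      config$variants[[v]], readTrajectory,
      frameInterval = config$frame_interval_ps))
    topo <- trajs[[1]]@topology
    donor <- stage("select", v, selectAtoms(
      topo, atomName = sel$donor$atom_name,
      residueNumber = sel$donor$residue_number))
    acceptor <- stage("select", v, selectAtoms(
      topo, atomName = sel$acceptor$atom_name,
      residueNumber = sel$acceptor$residue_number))
    ca <- stage("select", v, selectAtoms(topo, atomName = sel$align_atom))
    helixSel <- stage("select", v, selectAtoms(
      topo, atomName = sel$align_atom,
      residueNumber = unlist(sel$helix_range)))
    sb <- stage("saltbridge", v, saltBridgeAnalysis(
      trajs, donor, acceptor, formedThreshold = par$formed_threshold,
      minEventNs = par$min_event_ns, windowNs = par$window_ns,
      analysisStartNs = par$analysis_start_ns))
    written <- c(written, stage("write-saltbridge", v,
      writeSaltBridgeTSV(sb, out, paste0(v, "_saltbridge"))))
    ms <- stage("mean-structure", v, meanStructure(trajs, ca))
    if (!ms@converged)
      warningsLog <- c(warningsLog,
                       sprintf("mean structure for '%s' did not converge", v))
    msPath <- file.path(out, paste0(v, "_mean.pdb"))
    stage("write-mean", v, writePDB(ms@model, msPath))
    written <- c(written, msPath)
    regions <- list(ploop = as.integer(unlist(sel$ploop_range)),
                    alphaC = as.integer(unlist(sel$helix_range)))
    prof <- stage("rmsf", v, rmsf(trajs, alignOn = ca, measureOn = ca,
                                  mean = ms, regions = regions))
    rmsfPath <- file.path(out, paste0(v, "_rmsf.tsv"))
    stage("write-rmsf", v, writeRmsfTSV(prof, rmsfPath, c(
      sprintf("variant: %s", v),
      sprintf("align: all %s (choice recorded; flexible loops included)",
              sel$align_atom),
      sprintf("frames_pooled: %d", ms@nFramesUsed))))
    written <- c(written, rmsfPath)
    hd <- stage("helix-rmsd", v, helixRmsdDistribution(
      trajs, reference, helix = helixSel, alignOn = ca,
      binWidth = par$bin_width))
    sp <- file.path(out, paste0(v, "_helix_rmsd_samples.tsv"))
    hp <- file.path(out, paste0(v, "_helix_rmsd_hist.tsv"))
    stage("write-helix", v, writeRmsdDistributionTSV(hd, sp, hp))
    written <- c(written, sp, hp)
    results[[v]] <- list(saltbridge = sb, meanStructure = ms, rmsf = prof,
                         helixRmsd = hd)
  }
  labels <- lapply(results, function(r)
    classifyConformation(r$saltbridge, par$stable_fraction))
  vs <- names(results)
  sepRows <- list()
  if (length(vs) > 1L) {
    for (i in seq_along(vs)[-length(vs)]) for (j in seq(i + 1L, length(vs))) {
      ov <- separationScore(results[[vs[i]]]$helixRmsd,
                            results[[vs[j]]]$helixRmsd)
      sepRows[[length(sepRows) + 1L]] <- data.frame(
        variant_a = vs[i], variant_b = vs[j], overlap = as.numeric(ov),
        mean_difference_A = attr(ov, "meanDifference"),
        stringsAsFactors = FALSE)
    }
  }
  separation <- if (length(sepRows)) do.call(rbind, sepRows) else NULL
  fepTable <- NULL
  if (!is.null(config$fep) && length(config$fep$work_tables)) {
    bfes <- list()
    for (lb in names(config$fep$work_tables)) {
      bfes[[lb]] <- stage("fep", lb, fepAnalysis(
        config$fep$work_tables[[lb]], temperature = config$fep$temperature,
        label = lb))
      if (any(unlist(lapply(c(bfes[[lb]]@perReplica), is.na))))
        warningsLog <- c(warningsLog, sprintf("FEP '%s': missing values", lb))
    }
    if (length(bfes) >= 2L) {
      refLab <- config$fep$reference_label %||% names(bfes)[1]
      fepTable <- stage("fep-compare", refLab, compareMutants(bfes, refLab))
      fepPath <- file.path(out, "fep_comparison.tsv")
      writeCommentedTSV(fepTable, fepPath,
                        c(sprintf("reference: %s", refLab),
                          sprintf("temperature_K: %g", config$fep$temperature),
                          "energies: kcal/mol"))
      written <- c(written, fepPath)
    }
  }
  ## summary + manifest (no timestamps: reruns must be byte-identical)
  sumPath <- file.path(out, "summary.txt")
  con <- file(sumPath, "wt")
  for (v in vs) {
    r <- results[[v]]
    writeLines(sprintf(
      "%s: conformation %s; formed fraction %s; events %s; P-loop RMSF %s A; helix RMSD mean %s A",
      v, labels[[v]]$ensemble,
      paste(.fmt(r$saltbridge@formedFraction, 3), collapse = "/"),
      paste(r$saltbridge@nCleavageEvents, collapse = "/"),
      .fmt(regionRmsf(r$rmsf, "ploop"), 3),
      .fmt(mean(r$helixRmsd@samples), 3)), con)
  }
  if (!is.null(separation))
    for (k in seq_len(nrow(separation)))
      writeLines(sprintf("overlap %s vs %s: %s",
                         separation$variant_a[k], separation$variant_b[k],
                         .fmt(separation$overlap[k], 4)), con)
  for (w in warningsLog) writeLines(paste("WARNING:", w), con)
  close(con)
  written <- c(written, sumPath)
  manifest <- list(
    package = "mdconf",
    version = as.character(utils::packageVersion("mdconf")),
    seed = config$seed, frame_interval_ps = config$frame_interval_ps,
    parameters = par, selections = sel,
    variants = lapply(config$variants, basename),
    reference_structure = basename(config$reference_structure),
    warnings = as.list(warningsLog), outputs = basename(written))
  manPath <- file.path(out, "manifest.yaml")
  yaml::write_yaml(manifest, manPath)
  written <- c(written, manPath)
  ok <- TRUE
  invisible(list(results = results, labels = labels, separation = separation,
                 fep = fepTable, outputs = written, warnings = warningsLog))
}

#' Generate the full set of synthetic inputs for a demo run
#'
#' Writes a scaffold/reference PDB, per-preset multi-model PDB replica
#' trajectories, a pair of synthetic FEP work tables (the second with a pure
#' van der Waals weakening), a ground-truth sidecar and a ready-to-run config.
#'
#' @param dir output directory.
#' @param seed integer master seed.
#' @param presets preset names (default all three).
#' @param replicas trajectories per preset (default 3).
#' @param nFrames frames per trajectory (default 2000, i.e. 200 ns at the
#'   100 ps interval - a scaled-down demo of the microsecond protocol).
#' @param nResidues scaffold size (default 60).
#' @param analysisStartNs analysis window start for the config (default 20).
#' @return path to the written config file
#' @export
generateSyntheticInputs <- function(dir, seed = 1L,
                                    presets = c("WT-like", "L858R-like",
                                                "L747P-like"),
                                    replicas = 3L, nFrames = 2000L,
                                    nResidues = 60L, analysisStartNs = 20) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ## chain starting at 718 covers the P-loop, both bridge residues and the
  ## helix for any nResidues >= 50
  spec <- scaffoldSpec(nResidues = nResidues, firstResidue = 718L)
  scaffold <- makeScaffold(spec, seed = deriveSeed(seed, 7))
  refPath <- file.path(dir, "reference_inactive_synthetic.pdb")
  writePDB(scaffold, refPath)
  variants <- list(); gt <- list()
  for (p in presets) {
    dyn <- dynamicsPreset(p)
    dyn$nFrames <- as.integer(nFrames)
    paths <- character(replicas)
    for (r in seq_len(replicas)) {
      sim <- simulateTrajectory(scaffold, dyn, spec,
                                seed = deriveSeed(seed, 100 * match(p, presets) + r),
                                label = sprintf("%s-rep%d", p, r))
      paths[r] <- file.path(dir, sprintf("%s_rep%d.pdb", gsub("[^A-Za-z0-9]", "_", p), r))
      writeTrajectory(sim$trajectory, paths[r])
      gt[[p]] <- sim$groundTruth
    }
    variants[[p]] <- basename(paths)
  }
  workA <- syntheticFepStudy(seed = deriveSeed(seed, 11))
  workB <- syntheticFepStudy(bindingVdw = -6.5 + 2.5,
                             seed = deriveSeed(seed, 12))
  wa <- file.path(dir, "work_reference_like.tsv")
  wb <- file.path(dir, "work_vdw_weakened.tsv")
  utils::write.table(format(workA, digits = 10, trim = TRUE), wa, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(format(workB, digits = 10, trim = TRUE), wb, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(lapply(gt, function(g) lapply(g, unname)),
                   file.path(dir, "ground_truth.yaml"))
  cfg <- list(
    seed = seed, output_dir = "out",
    reference_structure = basename(refPath),
    frame_interval_ps = 100, variants = variants,
    selections = list(
      donor = list(residue_number = 745, atom_name = "NZ"),
      acceptor = list(residue_number = 762, atom_name = "CD"),
      helix_range = c(752, 767), ploop_range = c(718, 726),
      align_atom = "CA"),
    parameters = list(window_ns = 10, analysis_start_ns = analysisStartNs,
                      formed_threshold = 4.5, min_event_ns = 10,
                      bin_width = 0.25, stable_fraction = 0.9),
    fep = list(temperature = 300,
               work_tables = list("reference-like" = basename(wa),
                                  "vdw-weakened" = basename(wb)),
               reference_label = "reference-like"))
  cfgPath <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfgPath)
  cfgPath
}

#' Generate synthetic inputs and run the pipeline end-to-end
#'
#' @param dir working directory for inputs and outputs.
#' @param seed master seed (drives generation and is recorded in the config).
#' @param ... passed to \code{\link{generateSyntheticInputs}}.
#' @return the \code{\link{runPipeline}} result, invisibly
#' @export
runDemo <- function(dir = tempfile("mdconf-demo"), seed = 1L, ...) {
  cfgPath <- generateSyntheticInputs(dir, seed = seed, ...)
  runPipeline(cfgPath)
}
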