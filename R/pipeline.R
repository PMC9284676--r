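pipelineDefaults <- function() {
  list(consensus_threshold = 0.25, prune_weight_frac = 0.1,
       n_perm = 199L, transform = "euclidean", total_reads = 500000L)
}

#' Validate a pipeline configuration
#'
#' A configuration activates exactly one input mode: \code{simulation}
#' (parameters for \code{\link{simulationConfig}}) or \code{inputs} (paths
#' to an abundance TSV, a genome-size TSV, a hitsort TSV and/or a Newick
#' tree). Stage names: abundance, distances, njnet, gscorr, signal, hsho,
#' tandem. Missing required inputs for an enabled stage fail here, before
#' any computation starts.
#'
#' @param config list, or path to a YAML file with the same structure
#' @return the normalized config (invisibly usable by
#'   \code{\link{runPipeline}})
#' @export
validatePipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  hasSim <- !is.null(config$simulation)
  hasReal <- !is.null(config$inputs)
  if (hasSim == hasReal)
    stop("exactly one of 'simulation' or 'inputs' must be configured")
  allStages <- c("abundance", "distances", "njnet", "gscorr", "signal",
                 "hsho", "tandem")
  if (is.null(config$stages)) config$stages <- allStages
  bad <- setdiff(config$stages, allStages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(config$seed)) config$seed <- 1L
  config$seed <- as.integer(config$seed)
  th <- pipelineDefaults()
  th[names(config$thresholds)] <- config$thresholds
  config$thresholds <- th
  if (hasReal) {
    need <- list(abundance = c("abundance", "gscorr", "signal"),
                 genome_sizes = "gscorr",
                 hitsort = c("distances", "njnet", "hsho", "tandem"),
                 tree = c("gscorr", "signal"))
    for (input in names(need)) {
      stagesNeeding <- intersect(need[[input]], config$stages)
      if (length(stagesNeeding) && is.null(config$inputs[[input]]))
        stop("stage(s) ", paste(stagesNeeding, collapse = "/"),
             " require the missing input '", input, "'")
      p <- config$inputs[[input]]
      if (!is.null(p) && !file.exists(p))
        stop("input file not found: ", p)
    }
    if ("njnet" %in% config$stages && !"distances" %in% config$stages)
      config$stages <- c(config$stages, "distances")
  }
  config
}

#' Run the repeatome analysis pipeline
#'
#' Executes the enabled stages in dependency order on either a synthetic
#' dataset (simulation mode) or user-supplied files, writing plain-text
#' results plus a reproducibility manifest (package version, seed, full
#' parameter echo, per-file MD5 checksums) into \code{outDir}. Identical
#' configuration and seed reproduce byte-identical numeric outputs.
#'
#' @param config list or YAML path; see
#'   \code{\link{validatePipelineConfig}}
#' @param outDir output directory (created if needed)
#' @return (invisibly) list with per-stage results and the manifest
#' @export
runPipeline <- function(config, outDir = config$output_dir %||% tempfile("run")) {
  config <- validatePipelineConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  results <- list()
  timing <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- expr
    timing[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    r
  }
  ## ---- inputs ----
  if (!is.null(config$simulation)) {
    simArgs <- config$simulation
    if (is.null(simArgs$dataSeed)) simArgs$dataSeed <- config$seed
    if (is.null(simArgs$treeSeed)) simArgs$treeSeed <- config$seed + 1000L
    ds <- simulateRepeatome(do.call(simulationConfig, simArgs))
    abundance <- ds$abundance
    genomeSizes <- ds$genomeSizes
    hitGraph <- ds$hitGraph
    tree <- ds$tree
    writeLines(writeAbundanceTable(abundance), file.path(outDir, "abundance.tsv"))
    utils::write.table(genomeSizeRecords(genomeSizes),
                       file.path(outDir, "genome_sizes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(writeHitsort(hitGraph), file.path(outDir, "hitsort.tsv"))
    writeLines(serializeNewick(tree), file.path(outDir, "tree.nwk"))
    jsonlite::write_json(as.list(ds$clusterTruth),
                         file.path(outDir, "cluster_truth.json"),
                         auto_unbox = TRUE)
    results$dataset <- ds
  } else {
    inp <- config$inputs
    abundance <- if (!is.null(inp$abundance)) readAbundanceTable(inp$abundance)
    genomeSizes <- if (!is.null(inp$genome_sizes)) readGenomeSizeTable(inp$genome_sizes)
    hitGraph <- if (!is.null(inp$hitsort))
      readHitsort(inp$hitsort, speciesCodeLength = inp$species_code_length %||% 3L)
    tree <- if (!is.null(inp$tree)) parseNewick(readLines(inp$tree, warn = FALSE))
  }
  ## ---- stages ----
  if ("abundance" %in% config$stages) {
    s <- tick("abundance", summarizeAbundance(abundance))
    jsonlite::write_json(
      list(totalMean = s$totalMean, totalMin = s$totalMin,
           totalMax = s$totalMax, allMissingFamilies = s$allMissingFamilies),
      file.path(outDir, "abundance_summary.json"), auto_unbox = TRUE,
      digits = NA)
    utils::write.table(s$familySummary,
                       file.path(outDir, "family_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$abundance <- s
  }
  if (any(c("distances", "njnet") %in% config$stages)) {
    net <- tick("distances", repeatomeNetwork(hitGraph,
                                              transform = th$transform,
                                              threshold = th$consensus_threshold))
    for (cl in names(net$trees))
      writeLines(serializeNewick(net$trees[[cl]]),
                 file.path(outDir, paste0("nj_", cl, ".nwk")))
    utils::write.table(net$filterReport,
                       file.path(outDir, "cluster_filter_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$distances <- net
    if ("njnet" %in% config$stages)
      writeSplitsNexus(net$network, file.path(outDir, "consensus_network.nex"))
  }
  if ("gscorr" %in% config$stages) {
    res <- tick("gscorr", {
      am <- amountsMbp(abundance, genomeSizes)
      corr <- repeatGsCorrelation(am, genomeSizes, tree)
      gsr <- genomeSizeRecords(genomeSizes)
      gsv <- stats::setNames(gsr$cx1_mbp, gsr$sample)
      contrib <- pairwiseContribution(am, gsv[rownames(am)])
      merge(corr, contrib$contributions, by = "family", sort = FALSE)
    })
    utils::write.table(res, file.path(outDir, "gs_correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$gscorr <- res
  }
  if ("signal" %in% config$stages) {
    sig <- tick("signal", abundanceSignal(abundance, tree,
                                          nPerm = th$n_perm,
                                          seed = config$seed))
    utils::write.table(sig, file.path(outDir, "phylo_signal.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$signal <- sig
  }
  if ("hsho" %in% config$stages) {
    hs <- tick("hsho", {
      lapply(stats::setNames(nm = clusterIDs(hitGraph)), function(cl) {
        r <- hsHoRatios(hitGraph, cl)
        tryCatch(logRatioHistogram(r$rho), error = function(e) NULL)
      })
    })
    modes <- data.frame(
      cluster = names(hs),
      mode_log10 = vapply(hs, function(h) if (is.null(h)) NA_real_ else h$modeCenter, 1),
      conserved_fraction = vapply(hs, function(h) if (is.null(h)) NA_real_ else h$conservedFraction, 1),
      n_scored = vapply(hs, function(h) if (is.null(h)) NA_integer_ else h$nScored, 1L),
      stringsAsFactors = FALSE)
    utils::write.table(modes, file.path(outDir, "hsho_modes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$hsho <- hs
  }
  if ("tandem" %in% config$stages) {
    tnd <- tick("tandem", {
      lapply(stats::setNames(nm = clusterIDs(hitGraph)), function(cl) {
        sub <- clusterSubgraph(hitGraph, cl)
        loops <- simplifyAndCountLoops(asIgraph(sub), th$prune_weight_frac)
        data.frame(cluster = cl, n_reads = nrow(sub@nodes),
                   genome_proportion = clusterGenomeProportion(
                     nrow(sub@nodes), th$total_reads),
                   C = connectedComponentIndex(sub),
                   beta = loops$beta, shape = loops$shapeLabel,
                   stringsAsFactors = FALSE)
      })
    })
    utils::write.table(do.call(rbind, tnd),
                       file.path(outDir, "tandem_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$tandem <- tnd
  }
  ## ---- manifest ----
  outFiles <- setdiff(list.files(outDir), "manifest.json")
  manifest <- list(
    package = "repeatomeKit",
    version = as.character(utils::packageVersion("repeatomeKit")),
    seed = config$seed,
    stages = config$stages,
    thresholds = th,
    simulation = config$simulation,
    inputs = config$inputs,
    timing_s = timing,
    checksums = as.list(tools::md5sum(file.path(outDir, outFiles))))
  names(manifest$checksums) <- outFiles
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(results, list(manifest = manifest, outDir = outDir)))
}
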