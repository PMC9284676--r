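#' Configuration for the synthetic repeatome generator
#'
#' Bundles and validates the generator parameters. Defaults describe a
#' desk-scale comparative clustering experiment: 8 species, 12 repeat
#' clusters (8 evolving on the tree, 4 pure noise), 40 reads per species
#' per cluster, and a read-similarity graph whose interspecies connectivity
#' decays with tree distance.
#'
#' @param nSpecies number of species (tree tips)
#' @param treeSeed,dataSeed integer seeds; the tree and the data use
#'   separate streams so the same tree can carry replicate datasets
#' @param nSignalClusters clusters whose log-amounts evolve by Brownian
#'   motion on the tree
#' @param nNoiseClusters clusters with i.i.d. log-normal amounts
#' @param readsPerSpecies reads per species in every cluster graph
#' @param bmSigma2 Brownian-motion rate for log-amounts
#' @param pIn within-species edge probability in (0, 1]
#' @param conservatism ratio c = p_out / p_in in (0, 1]: 1 = interspecies
#'   hits as frequent as intraspecies (fully conserved repeat), small
#'   values = diversified repeat
#' @param decay similarity decay rate lambda >= 0 with tree distance
#' @param unclassifiedFraction fraction of the genome left unclassified
#'   (in [0, 1))
#' @param rootAmountMbp cluster amount (Mbp) at the tree root / the
#'   log-normal median for noise clusters
#' @param noiseSdLog log-sd of noise-cluster amounts
#' @return a validated list of class \code{SimulationConfig}
#' @export
simulationConfig <- function(nSpecies = 8L, treeSeed = 1L, dataSeed = 2L,
                             nSignalClusters = 8L, nNoiseClusters = 4L,
                             readsPerSpecies = 40L, bmSigma2 = 0.3,
                             pIn = 0.5, conservatism = 0.2, decay = 2,
                             unclassifiedFraction = 0.05,
                             rootAmountMbp = 150, noiseSdLog = 0.5) {
  cfg <- list(nSpecies = as.integer(nSpecies), treeSeed = as.integer(treeSeed),
              dataSeed = as.integer(dataSeed),
              nSignalClusters = as.integer(nSignalClusters),
              nNoiseClusters = as.integer(nNoiseClusters),
              readsPerSpecies = as.integer(readsPerSpecies),
              bmSigma2 = bmSigma2, pIn = pIn, conservatism = conservatism,
              decay = decay, unclassifiedFraction = unclassifiedFraction,
              rootAmountMbp = rootAmountMbp, noiseSdLog = noiseSdLog)
  stopifnot(cfg$nSpecies >= 2, cfg$readsPerSpecies >= 1,
            cfg$nSignalClusters >= 0, cfg$nNoiseClusters >= 0,
            cfg$nSignalClusters + cfg$nNoiseClusters >= 1,
            cfg$bmSigma2 >= 0, cfg$pIn > 0, cfg$pIn <= 1,
            cfg$conservatism > 0, cfg$conservatism <= 1, cfg$decay >= 0,
            cfg$unclassifiedFraction >= 0, cfg$unclassifiedFraction < 1,
            cfg$rootAmountMbp > 0, cfg$noiseSdLog >= 0)
  structure(cfg, class = "SimulationConfig")
}

sampleClusterEdges <- function(reads, species, pIn, cFactor, decay, dmat) {
  # reads: character vector of read ids; species: parallel species labels
  sp <- unique(species)
  from <- character(0); to <- character(0)
  for (i in seq_along(sp)) for (j in i:length(sp)) {
    ri <- reads[species == sp[i]]
    rj <- reads[species == sp[j]]
    if (i == j) {
      if (length(ri) < 2) next
      pairs <- utils::combn(ri, 2)
      p <- pIn
    } else {
      pairs <- rbind(rep(ri, times = length(rj)), rep(rj, each = length(ri)))
      p <- pIn * cFactor * exp(-decay * dmat[sp[i], sp[j]])
    }
    hit <- stats::runif(ncol(pairs)) < p
    if (any(hit)) {
      from <- c(from, pairs[1, hit])
      to <- c(to, pairs[2, hit])
    }
  }
  data.frame(from = from, to = to,
             weight = if (length(from))
               90 + sample.int(11L, length(from), replace = TRUE) - 1L
             else numeric(0),
             stringsAsFactors = FALSE)
}

#' Simulate a comparative repeatome dataset
#'
#' Generates, in a documented RNG order (tree, then cluster amounts, then
#' cluster graphs), a dataset with the statistical structure the downstream
#' analyses assume:
#' \itemize{
#'   \item a unit-depth Yule species tree;
#'   \item "signal" clusters whose per-species amount is
#'     exp(Brownian trait) in Mbp (tree-correlated, always positive) and
#'     "noise" clusters with i.i.d. log-normal amounts;
#'   \item genome sizes composed additively: 1Cx (Mbp) = sum of cluster
#'     amounts / (1 - unclassifiedFraction), so the unclassified share is
#'     exactly \code{unclassifiedFraction} of the genome;
#'   \item abundance percentages 100 x Mbp / 1Cx(Mbp);
#'   \item one read-similarity graph per cluster with within-species edge
#'     probability pIn and between-species probability
#'     pIn x c x exp(-lambda x tree distance).
#' }
#'
#' @param config a \code{\link{simulationConfig}}
#' @return list of class \code{SyntheticRepeatome} with elements
#'   \code{tree}, \code{abundance} (\linkS4class{RepeatAbundanceTable},
#'   \% of 1Cx incl. Unclassified and Total columns), \code{amountsMbp}
#'   (matrix, clusters only), \code{genomeSizes}
#'   (\linkS4class{GenomeSizeTable}), \code{hitGraph}
#'   (\linkS4class{HitGraph} over all clusters), \code{clusterTruth}
#'   (named character, "signal"/"noise"), \code{config}
#' @export
simulateRepeatome <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  tree <- simulateTree(config$nSpecies, config$treeSeed)
  species <- tree$tip.label
  dmat <- stats::cophenetic(tree)
  set.seed(config$dataSeed)
  nclust <- config$nSignalClusters + config$nNoiseClusters
  clusters <- sprintf("CL%02d", seq_len(nclust))
  truth <- rep(c("signal", "noise"),
               c(config$nSignalClusters, config$nNoiseClusters))
  names(truth) <- clusters
  amounts <- matrix(0, config$nSpecies, nclust,
                    dimnames = list(species, clusters))
  for (k in seq_len(nclust)) {
    amounts[, k] <- if (truth[k] == "signal")
      exp(simulateBMTraits(tree, config$bmSigma2,
                           rootValue = log(config$rootAmountMbp)))
    else
      stats::rlnorm(config$nSpecies, meanlog = log(config$rootAmountMbp),
                    sdlog = config$noiseSdLog)
  }
  gsMbp <- rowSums(amounts) / (1 - config$unclassifiedFraction)
  unclassified <- gsMbp - rowSums(amounts)
  pct <- cbind(100 * amounts / gsMbp, Unclassified = 100 * unclassified / gsMbp)
  pct <- cbind(pct, Total = rowSums(pct))
  nodes <- list(); edges <- list()
  for (k in seq_len(nclust)) {
    reads <- sprintf("%s_%s_%03d", rep(species, each = config$readsPerSpecies),
                     clusters[k], seq_len(config$readsPerSpecies))
    spOf <- rep(species, each = config$readsPerSpecies)
    nodes[[k]] <- data.frame(read = reads, species = spOf,
                             cluster = clusters[k], stringsAsFactors = FALSE)
    e <- sampleClusterEdges(reads, spOf, config$pIn, config$conservatism,
                            config$decay, dmat)
    edges[[k]] <- e
  }
  hg <- HitGraph(do.call(rbind, nodes), do.call(rbind, edges))
  gs <- GenomeSizeTable(sample = species, ploidy = 2L,
                        c2_pg = 2 * mbpToPg(gsMbp),
                        cx1_pg = mbpToPg(gsMbp), cx1_mbp = gsMbp)
  structure(list(tree = tree,
                 abundance = RepeatAbundanceTable(pct),
                 amountsMbp = amounts,
                 genomeSizes = gs,
                 hitGraph = hg,
                 clusterTruth = truth,
                 config = config),
            class = "SyntheticRepeatome")
}

#' @export
print.SyntheticRepeatome <- function(x, ...) {
  cat("SyntheticRepeatome:", x$config$nSpecies, "species,",
      length(x$clusterTruth), "clusters (",
      sum(x$clusterTruth == "signal"), "signal /",
      sum(x$clusterTruth == "noise"), "noise ),",
      nrow(x$hitGraph@edges), "similarity edges\n")
  invisible(x)
}
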