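#' Observed/expected interspecies edge-ratio matrix for a cluster
#'
#' The expected edge count between species s and t (and within a species)
#' is derived from a uniform random placement of the cluster's E edges over
#' all node pairs, conditioned on the per-species read counts:
#' expected_st = E x n_s n_t / C(N, 2) for s != t and
#' expected_ss = E x C(n_s, 2) / C(N, 2). The ratio is observed/expected;
#' when the expected count is zero (e.g. a single read of a species, on the
#' diagonal) the ratio is recorded as missing.
#'
#' @param graph a \linkS4class{HitGraph}
#' @param cluster cluster id to analyse
#' @return a \linkS4class{ClusterSimilarityMatrix}
#' @export
observedExpectedMatrix <- function(graph, cluster) {
  sub <- clusterSubgraph(graph, cluster)
  counts <- table(sub@nodes$species)
  sp <- names(counts)
  if (length(sp) < 2L)
    stop("cluster '", cluster, "' contains a single species")
  n <- as.integer(counts)
  names(n) <- sp
  N <- sum(n)
  E <- nrow(sub@edges)
  totalPairs <- N * (N - 1) / 2
  spOf <- sub@nodes$species[match(sub@edges$from, sub@nodes$read)]
  spTo <- sub@nodes$species[match(sub@edges$to, sub@nodes$read)]
  obs <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  if (E > 0) {
    a <- pmin(spOf, spTo); b <- pmax(spOf, spTo)
    tab <- table(factor(a, levels = sp), factor(b, levels = sp))
    obs <- matrix(as.numeric(tab + t(tab * (row(tab) != col(tab)))),
                  length(sp), dimnames = list(sp, sp))
    diag(obs) <- diag(tab)
  }
  expd <- outer(n, n) * E / totalPairs
  diag(expd) <- E * n * (n - 1) / 2 / totalPairs
  ratio <- obs / expd
  ratio[expd == 0 & obs == 0] <- NA_real_
  new("ClusterSimilarityMatrix", cluster = cluster, ratios = ratio,
      readCounts = n)
}

#' Euclidean distance between species similarity profiles
#'
#' Treats each species' row of the observed/expected ratio matrix
#' (including the diagonal columns) as its similarity profile and takes
#' Euclidean distances between profiles.
#'
#' @param sim a \linkS4class{ClusterSimilarityMatrix} without missing
#'   entries
#' @return a \linkS4class{DistanceMatrix} with transform \code{"euclidean"}
#' @export
euclideanProfileDistance <- function(sim) {
  m <- similarityRatios(sim)
  if (anyNA(m))
    stop("similarity matrix has missing entries; filter clusters first")
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  new("DistanceMatrix", d = d, transform = "euclidean", cluster = sim@cluster)
}

#' Inverse-similarity distance
#'
#' d(a, b) = 1 / S_ab for a != b, zero diagonal. All off-diagonal
#' similarities must be positive.
#'
#' @param sim a \linkS4class{ClusterSimilarityMatrix}
#' @return a \linkS4class{DistanceMatrix} with transform \code{"inverse"}
#' @export
inverseSimilarityDistance <- function(sim) {
  m <- similarityRatios(sim)
  off <- m[row(m) != col(m)]
  if (anyNA(off) || any(off <= 0))
    stop("inverse transform needs positive off-diagonal similarities; filter first")
  d <- 1 / m
  diag(d) <- 0
  new("DistanceMatrix", d = d, transform = "inverse", cluster = sim@cluster)
}

#' Filter clusters with complete similarity information
#'
#' Retains exactly the clusters whose ratio matrices cover all species of
#' the full set and have positive, non-missing off-diagonal entries;
#' clusters with incomplete information (missing species, NA, or zero
#' interspecies ratios) are discarded, with per-reason counts reported.
#'
#' @param matrices list of \linkS4class{ClusterSimilarityMatrix}
#' @param species optional full species set (default: union over clusters)
#' @return list with \code{retained} (the surviving matrices),
#'   \code{report} (data.frame: cluster, retained, reason)
#' @export
filterCompleteClusters <- function(matrices, species = NULL) {
  if (is.null(species))
    species <- sort(unique(unlist(lapply(matrices,
                                         function(m) rownames(m@ratios)))))
  rep <- lapply(matrices, function(m) {
    r <- m@ratios
    reason <- ""
    if (!all(species %in% rownames(r))) reason <- "missing species"
    else {
      off <- r[row(r) != col(r)]
      if (anyNA(off)) reason <- "NA ratio"
      else if (any(off == 0)) reason <- "zero interspecies ratio"
    }
    data.frame(cluster = m@cluster, retained = reason == "",
               reason = reason, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rep)
  list(retained = matrices[report$retained], report = report)
}
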