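asUndirectedIgraph <- function(graph) {
  if (is(graph, "HitGraph")) return(asIgraph(graph))
  if (igraph::is_igraph(graph)) {
    if (igraph::is_directed(graph))
      graph <- igraph::as_undirected(graph, mode = "collapse",
                                     edge.attr.comb = list(weight = "sum"))
    return(graph)
  }
  stop("expected a HitGraph or an igraph graph")
}

#' Connected component index of a cluster graph
#'
#' C = size of the largest connected component / number of nodes. Clean
#' tandem-repeat clusters have C near 1.
#'
#' @param graph a \linkS4class{HitGraph} or igraph graph (non-empty)
#' @return C in (0, 1]
#' @export
connectedComponentIndex <- function(graph) {
  g <- asUndirectedIgraph(graph)
  if (igraph::vcount(g) == 0) stop("empty graph")
  comp <- igraph::components(g)
  max(comp$csize) / igraph::vcount(g)
}

#' Simplify a graph and count its independent loops
#'
#' Operationalizes the visual classification of tandem-repeat cluster
#' graphs: low-weight edges (below \code{pruneWeightFrac} x median edge
#' weight) are removed, the graph is restricted to its largest connected
#' component, degree-1 nodes are iteratively trimmed, and the cycle rank
#' beta = E - V + components is computed (degree-2 chain contraction
#' leaves beta unchanged, so chains need not be contracted explicitly).
#' beta = 1 is a simple circular graph (type 1, one monomer family);
#' beta >= 2 is a multi-loop graph (type 2, e.g. two ribotypes sharing a
#' conserved gene). A graph that becomes a tree (beta = 0) is flagged
#' "linear/ambiguous".
#'
#' @param graph a \linkS4class{HitGraph} or igraph graph with edge weights
#' @param pruneWeightFrac prune edges lighter than this fraction of the
#'   median edge weight (default 0.1)
#' @return list with \code{beta}, \code{shapeType} (1, 2 or NA),
#'   \code{shapeLabel}, \code{nNodes}, \code{nEdges} (of the simplified
#'   largest component)
#' @export
simplifyAndCountLoops <- function(graph, pruneWeightFrac = 0.1) {
  g <- asUndirectedIgraph(graph)
  if (igraph::ecount(g) == 0)
    return(list(beta = 0L, shapeType = NA_integer_,
                shapeLabel = "linear/ambiguous", nNodes = igraph::vcount(g),
                nEdges = 0L))
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  # weight-mass median: the reference coverage is where half the total edge
  # weight lies, so a swarm of weight-1 error edges cannot drag it down
  ws <- sort(w)
  ref <- ws[which(cumsum(ws) >= sum(ws) / 2)[1]]
  g <- igraph::delete_edges(g, which(w < pruneWeightFrac * ref))
  comp <- igraph::components(g)
  g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  repeat {
    deg1 <- which(igraph::degree(g) <= 1)
    if (!length(deg1)) break
    g <- igraph::delete_vertices(g, deg1)
  }
  V <- igraph::vcount(g); E <- igraph::ecount(g)
  ncomp <- if (V > 0) igraph::components(g)$no else 0L
  beta <- E - V + ncomp
  shapeType <- if (beta == 1) 1L else if (beta >= 2) 2L else NA_integer_
  list(beta = as.integer(beta), shapeType = shapeType,
       shapeLabel = if (is.na(shapeType)) "linear/ambiguous"
         else as.character(shapeType),
       nNodes = V, nEdges = E)
}

#' k-mer (de Bruijn) graph of a read set
#'
#' Nodes are the distinct k-mers of the reads; a directed edge joins each
#' k-mer to its successor within a read, weighted by occurrence count.
#' Node attribute \code{count} holds total k-mer occurrences.
#'
#' @param reads character vector of read sequences (all of length >= k)
#' @param k k-mer length
#' @return a directed igraph graph with edge attribute \code{weight} and
#'   vertex attribute \code{count}
#' @export
kmerGraph <- function(reads, k = 11L) {
  if (any(nchar(reads) < k)) stop("all reads must be at least k long")
  kms <- lapply(reads, function(r) {
    n <- nchar(r)
    substring(r, 1:(n - k + 1L), k:n)
  })
  allOcc <- unlist(kms)
  nodeCount <- table(allOcc)
  from <- unlist(lapply(kms, function(x) x[-length(x)]))
  to <- unlist(lapply(kms, function(x) x[-1]))
  key <- paste(from, to, sep = ">")
  tab <- table(key)
  ft <- strsplit(names(tab), ">", fixed = TRUE)
  edges <- data.frame(from = vapply(ft, `[`, "", 1),
                      to = vapply(ft, `[`, "", 2),
                      weight = as.numeric(tab), stringsAsFactors = FALSE)
  verts <- data.frame(name = names(nodeCount),
                      count = as.numeric(nodeCount),
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = verts)
}

#' Greedy dominant-cycle k-mer score
#'
#' Builds the k-mer graph, walks greedily from the most frequent k-mer
#' always taking the heaviest unvisited successor, and closes a cycle when
#' the heaviest successor revisits the walk. The score is the summed
#' occurrence count of the k-mers on the cycle divided by the total k-mer
#' occurrences: near 1 for one cleanly circular monomer, near the dominant
#' ribotype's share for mixtures, 0 when no cycle exists.
#'
#' @param reads character vector of read sequences
#' @param k k-mer length (default 11)
#' @return score in [0, 1]
#' @export
kmerCycleScore <- function(reads, k = 11L) {
  g <- kmerGraph(reads, k)
  counts <- igraph::V(g)$count
  total <- sum(counts)
  adj <- igraph::as_adj_list(g, mode = "out")
  start <- which.max(counts)
  path <- integer(0)
  onPath <- logical(igraph::vcount(g))
  cur <- start
  cycle <- NULL
  for (step in seq_len(igraph::vcount(g) + 1L)) {
    path <- c(path, cur); onPath[cur] <- TRUE
    succ <- as.integer(adj[[cur]])
    if (!length(succ)) break
    # heaviest successor by edge weight
    ew <- igraph::E(g)$weight[igraph::get_edge_ids(g, rbind(rep(cur, length(succ)), succ))]
    best <- succ[order(-ew, succ)][1]
    if (onPath[best]) {
      cycle <- path[which(path == best)[1]:length(path)]
      break
    }
    cur <- best
  }
  if (is.null(cycle)) {
    warning("no cycle found in k-mer graph; score 0")
    return(0)
  }
  sum(counts[cycle]) / total
}

#' Classify a tandem-repeat cluster from its reads
#'
#' Runs the k-mer graph route: builds the de Bruijn graph of the reads
#' (collapsed to undirected weights for loop counting), prunes, trims and
#' counts loops, and reports the dominant-cycle k-mer score. The k-mer
#' graph of an error-free circular monomer is exactly one loop; two
#' ribotypes sharing a conserved gene give two loops joined at the shared
#' path, so the loop count is the operational "graph shape type".
#'
#' @param reads character vector of read sequences
#' @param k k-mer length
#' @param pruneWeightFrac pruning fraction for
#'   \code{\link{simplifyAndCountLoops}}
#' @return list with \code{beta}, \code{shapeType}, \code{shapeLabel},
#'   \code{kmerScore}
#' @export
classifyTandemCluster <- function(reads, k = 11L, pruneWeightFrac = 0.1) {
  g <- kmerGraph(reads, k)
  loops <- simplifyAndCountLoops(g, pruneWeightFrac)
  score <- suppressWarnings(kmerCycleScore(reads, k))
  c(loops[c("beta", "shapeType", "shapeLabel")], list(kmerScore = score))
}

#' Table-style metrics for a tandem-repeat cluster
#'
#' Combines the read-graph connected component index, the k-mer-graph loop
#' classification, the k-mer score and the cluster genome proportion into
#' one record.
#'
#' @param graph a \linkS4class{HitGraph} of the cluster's reads
#' @param reads the cluster's read sequences
#' @param nTotalReads total reads of the sample's analysis (for the genome
#'   proportion)
#' @param k k-mer length
#' @param pruneWeightFrac pruning fraction
#' @return data.frame with n_reads, genome_proportion, C, beta,
#'   shape_type, kmer_score
#' @export
tandemClusterMetrics <- function(graph, reads, nTotalReads = 500000L,
                                 k = 11L, pruneWeightFrac = 0.1) {
  cls <- classifyTandemCluster(reads, k, pruneWeightFrac)
  data.frame(
    n_reads = length(reads),
    genome_proportion = clusterGenomeProportion(length(reads), nTotalReads),
    C = connectedComponentIndex(graph),
    beta = cls$beta,
    shape_type = cls$shapeType,
    kmer_score = cls$kmerScore,
    stringsAsFactors = FALSE)
}
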