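randomSequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

circularSubstring <- function(seq, start, len) {
  # 1-based start on a circular sequence
  n <- nchar(seq)
  idx <- ((start - 1L + 0:(len - 1L)) %% n) + 1L
  paste(strsplit(seq, "", fixed = TRUE)[[1]][idx], collapse = "")
}

mutateReads <- function(reads, errorRate) {
  if (errorRate <= 0) return(reads)
  bases <- c("A", "C", "G", "T")
  vapply(reads, function(r) {
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(ch)) < errorRate)
    for (i in hit) ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

readKmers <- function(read, k) {
  n <- nchar(read)
  if (n < k) return(character(0))
  unique(substring(read, 1:(n - k + 1L), k:n))
}

#' Simulate a tandem-repeat (5S rDNA-like) read cluster
#'
#' Emulates the read cluster of a tandemly repeated satellite: reads are
#' sampled from random circular offsets of one or two monomer "ribotypes".
#' With two ribotypes, both monomers share an identical gene segment (the
#' conserved coding region) and differ elsewhere (the divergent intergenic
#' spacers), so the expected graph shape is a single loop (type 1) or two
#' loops joined at the shared gene (type 2). The read-similarity graph
#' connects reads sharing at least \code{minSharedKmers} k-mers, with the
#' shared-k-mer count as edge weight.
#'
#' @param monomerLength monomer length in bp (> readLength)
#' @param nRibotypes 1 or 2
#' @param sharedGeneLength length of the conserved segment shared between
#'   ribotypes (< monomerLength); ignored when nRibotypes = 1
#' @param nReads number of reads to sample
#' @param readLength read length in bp (< monomerLength)
#' @param kmerK k-mer length for the similarity graph
#' @param minSharedKmers minimum shared k-mers for an edge
#' @param errorRate per-base substitution error probability
#' @param seed integer seed (tree-independent local stream)
#' @param buildHitGraph build the read-pair similarity graph (set FALSE to
#'   skip the quadratic step when only the reads are needed)
#' @return list of class \code{SyntheticTandemCluster}: \code{reads}
#'   (character), \code{graph} (\linkS4class{HitGraph} or NULL),
#'   \code{truthType} (1 or 2), \code{ribotypes} (monomer sequences)
#' @export
simulateTandemCluster <- function(monomerLength = 300L, nRibotypes = 1L,
                                  sharedGeneLength = 120L, nReads = 150L,
                                  readLength = 100L, kmerK = 11L,
                                  minSharedKmers = 20L, errorRate = 0,
                                  seed = 1L, buildHitGraph = TRUE) {
  if (!nRibotypes %in% c(1L, 2L)) stop("nRibotypes must be 1 or 2")
  if (readLength >= monomerLength) stop("read length must be < monomer length")
  if (nRibotypes == 2L && sharedGeneLength >= monomerLength)
    stop("shared gene length must be < monomer length")
  set.seed(as.integer(seed))
  rib1 <- randomSequence(monomerLength)
  ribotypes <- rib1
  if (nRibotypes == 2L) {
    rib2 <- paste0(substr(rib1, 1L, sharedGeneLength),
                   randomSequence(monomerLength - sharedGeneLength))
    ribotypes <- c(rib1, rib2)
  }
  pick <- sample.int(nRibotypes, nReads, replace = TRUE)
  offset <- sample.int(monomerLength, nReads, replace = TRUE)
  reads <- vapply(seq_len(nReads), function(i)
    circularSubstring(ribotypes[pick[i]], offset[i], readLength), "")
  reads <- mutateReads(reads, errorRate)
  graph <- if (buildHitGraph)
    tandemHitGraph(reads, kmerK, minSharedKmers) else NULL
  structure(list(reads = reads, graph = graph, truthType = as.integer(nRibotypes),
                 ribotypes = ribotypes),
            class = "SyntheticTandemCluster")
}

#' Read-similarity graph from shared k-mer counts
#'
#' Connects every pair of reads sharing at least \code{minSharedKmers}
#' k-mers; the edge weight is the number of shared k-mers.
#'
#' @param reads character vector of read sequences
#' @param k k-mer length
#' @param minSharedKmers edge threshold
#' @param species species label for the reads (single-species cluster)
#' @param cluster cluster label
#' @return a \linkS4class{HitGraph}
#' @export
tandemHitGraph <- function(reads, k = 11L, minSharedKmers = 20L,
                           species = "TAN", cluster = "TR1") {
  ids <- sprintf("%s_%04d", species, seq_along(reads))
  kl <- lapply(reads, readKmers, k = k)
  allk <- unique(unlist(kl))
  # reads x kmers incidence; shared counts via sparse cross-product
  i <- rep(seq_along(reads), lengths(kl))
  j <- match(unlist(kl), allk)
  M <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(reads), length(allk)))
  S <- Matrix::tcrossprod(M)
  S <- methods::as(Matrix::triu(S, k = 1), "TsparseMatrix")
  keep <- S@x >= minSharedKmers
  edges <- data.frame(from = ids[S@i[keep] + 1L], to = ids[S@j[keep] + 1L],
                      weight = S@x[keep], stringsAsFactors = FALSE)
  nodes <- data.frame(read = ids, species = species, cluster = cluster,
                      stringsAsFactors = FALSE)
  HitGraph(nodes, edges)
}
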