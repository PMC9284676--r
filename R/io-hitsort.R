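#' Construct a HitGraph
#'
#' @param nodes data.frame with columns \code{read}, \code{species},
#'   \code{cluster}
#' @param edges data.frame with columns \code{from}, \code{to},
#'   \code{weight}
#' @return a validated \linkS4class{HitGraph}
#' @export
HitGraph <- function(nodes, edges) {
  nodes$read <- as.character(nodes$read)
  nodes$species <- as.character(nodes$species)
  nodes$cluster <- as.character(nodes$cluster)
  if (nrow(edges)) {
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    edges$weight <- as.numeric(edges$weight)
  }
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  new("HitGraph", nodes = nodes, edges = edges)
}

#' Parse a hitsort read-similarity edge list
#'
#' Each line is \code{readA<TAB>readB<TAB>weight} with an optional fourth
#' column naming the repeat cluster. Read names are prefixed by a
#' fixed-length species code (the naming convention of comparative
#' read-clustering runs); the code is decoded from the first
#' \code{speciesCodeLength} characters. Duplicate listings of the same
#' unordered read pair are collapsed keeping the maximum weight; self pairs
#' are skipped and counted in a warning.
#'
#' @param text character scalar (TSV content) or vector of lines
#' @param speciesCodeLength integer length of the species-code prefix
#' @param cluster cluster label used when the input has no cluster column
#' @return a \linkS4class{HitGraph}
#' @examples
#' g <- parseHitsort("AAA_1\tBBB_1\t90", speciesCodeLength = 3)
#' @export
parseHitsort <- function(text, speciesCodeLength = 3L, cluster = "CL1") {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty hitsort input")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 3L | nf > 4L)
  if (length(bad))
    stop(sprintf("malformed hitsort line %d: '%s'", lineno[bad[1]], lines[bad[1]]))
  from <- vapply(parts, `[`, "", 1L)
  to <- vapply(parts, `[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
  badw <- which(is.na(w) | w <= 0)
  if (length(badw))
    stop(sprintf("malformed hitsort line %d: bad weight '%s'",
                 lineno[badw[1]], vapply(parts, `[`, "", 3L)[badw[1]]))
  cl <- ifelse(nf == 4L, vapply(parts, function(p) p[4L] %||% "", ""), cluster)
  self <- from == to
  if (any(self)) {
    warning(sum(self), " self-pair line(s) skipped")
    from <- from[!self]; to <- to[!self]; w <- w[!self]; cl <- cl[!self]
  }
  if (!length(from)) stop("hitsort input contains no usable read pairs")
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, cl, sep = "\r")
  # collapse duplicates keeping max weight
  ord <- order(key, -w)
  first <- !duplicated(key[ord])
  a <- a[ord][first]; b <- b[ord][first]; w <- w[ord][first]; cl <- cl[ord][first]
  readcl <- data.frame(read = c(a, b), cluster = c(cl, cl),
                       stringsAsFactors = FALSE)
  readcl <- unique(readcl)
  nodes <- data.frame(read = readcl$read,
                      species = substr(readcl$read, 1L, speciesCodeLength),
                      cluster = readcl$cluster, stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$cluster, nodes$read), , drop = FALSE]
  HitGraph(nodes, data.frame(from = a, to = b, weight = w,
                             stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Read a hitsort TSV file
#' @param file path
#' @param ... passed to \code{\link{parseHitsort}}
#' @return a \linkS4class{HitGraph}
#' @export
readHitsort <- function(file, ...) parseHitsort(readLines(file, warn = FALSE), ...)

#' Serialize a HitGraph to hitsort TSV text
#'
#' Writes one \code{from<TAB>to<TAB>weight<TAB>cluster} line per edge
#' (cluster of the \code{from} read).
#' @param x a \linkS4class{HitGraph}
#' @return character scalar of TSV content
#' @export
writeHitsort <- function(x) {
  e <- x@edges
  cl <- x@nodes$cluster[match(e$from, x@nodes$read)]
  paste(sprintf("%s\t%s\t%s\t%s", e$from, e$to,
                format(e$weight, trim = TRUE, digits = 15), cl),
        collapse = "\n")
}

#' Restrict a HitGraph to one cluster
#' @param x a \linkS4class{HitGraph}
#' @param cluster cluster id
#' @return a \linkS4class{HitGraph} containing only that cluster's reads
#' @export
clusterSubgraph <- function(x, cluster) {
  nodes <- x@nodes[x@nodes$cluster == cluster, , drop = FALSE]
  if (!nrow(nodes)) stop("cluster '", cluster, "' not present in graph")
  edges <- x@edges[x@edges$from %in% nodes$read & x@edges$to %in% nodes$read, ,
                   drop = FALSE]
  HitGraph(nodes, edges)
}

#' Cluster ids present in a HitGraph
#' @param x a \linkS4class{HitGraph}
#' @return character vector of cluster labels
#' @export
clusterIDs <- function(x) sort(unique(x@nodes$cluster))
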