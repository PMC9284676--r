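#' @include AllClasses.R
NULL

#' Sample identifiers
#' @param x an object with samples
#' @return character vector of sample ids, in storage order
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' Repeat-family identifiers
#' @param x an object with repeat families
#' @return character vector of family ids, in storage order
#' @export
setGeneric("familyIDs", function(x) standardGeneric("familyIDs"))

#' Abundance values matrix
#' @param x a \linkS4class{RepeatAbundanceTable}
#' @return numeric matrix (samples x families, % of 1C); \code{NA} = missing
#' @export
setGeneric("abundanceValues", function(x) standardGeneric("abundanceValues"))

#' Sample group labels
#' @param x a \linkS4class{RepeatAbundanceTable}
#' @return named character vector (possibly empty)
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' Genome-size records
#' @param x a \linkS4class{GenomeSizeTable}
#' @return data.frame of per-sample genome sizes
#' @export
setGeneric("genomeSizeRecords", function(x) standardGeneric("genomeSizeRecords"))

#' Taxon labels of a split system or distance matrix
#' @param x a \linkS4class{SplitSet} or \linkS4class{DistanceMatrix}
#' @return character vector of taxon labels
#' @export
setGeneric("taxonLabels", function(x) standardGeneric("taxonLabels"))

#' Split list, weights and supports
#' @param x a \linkS4class{SplitSet}
#' @return \code{splitList}: list of canonical split sides;
#'   \code{splitWeights}/\code{splitSupport}: numeric vectors
#' @export
setGeneric("splitList", function(x) standardGeneric("splitList"))

#' @rdname splitList
#' @export
setGeneric("splitWeights", function(x) standardGeneric("splitWeights"))

#' @rdname splitList
#' @export
setGeneric("splitSupport", function(x) standardGeneric("splitSupport"))

#' Distance matrix values
#' @param x a \linkS4class{DistanceMatrix} or
#'   \linkS4class{ClusterSimilarityMatrix}
#' @return numeric matrix
#' @export
setGeneric("distanceValues", function(x) standardGeneric("distanceValues"))

#' Observed/expected similarity ratios
#' @param x a \linkS4class{ClusterSimilarityMatrix}
#' @return numeric matrix of observed/expected edge ratios
#' @export
setGeneric("similarityRatios", function(x) standardGeneric("similarityRatios"))

#' Convert to an igraph graph
#' @param x a \linkS4class{HitGraph}
#' @param cluster optional cluster id to restrict to
#' @return an \pkg{igraph} undirected graph with vertex attributes
#'   \code{species} and \code{cluster} and edge attribute \code{weight}
#' @export
setGeneric("asIgraph", function(x, cluster = NULL) standardGeneric("asIgraph"))

## ---- methods ----

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "RepeatAbundanceTable", function(x) rownames(x@values))

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "GenomeSizeTable", function(x) x@records$sample)

#' @rdname familyIDs
#' @export
setMethod("familyIDs", "RepeatAbundanceTable", function(x) colnames(x@values))

#' @rdname abundanceValues
#' @export
setMethod("abundanceValues", "RepeatAbundanceTable", function(x) x@values)

#' @rdname groupLabels
#' @export
setMethod("groupLabels", "RepeatAbundanceTable", function(x) x@groupLabels)

#' @rdname genomeSizeRecords
#' @export
setMethod("genomeSizeRecords", "GenomeSizeTable", function(x) x@records)

#' @rdname taxonLabels
#' @export
setMethod("taxonLabels", "SplitSet", function(x) x@taxa)

#' @rdname taxonLabels
#' @export
setMethod("taxonLabels", "DistanceMatrix", function(x) rownames(x@d))

#' @rdname splitList
#' @export
setMethod("splitList", "SplitSet", function(x) x@splits)

#' @rdname splitList
#' @export
setMethod("splitWeights", "SplitSet", function(x) x@weights)

#' @rdname splitList
#' @export
setMethod("splitSupport", "SplitSet", function(x) x@support)

#' @rdname distanceValues
#' @export
setMethod("distanceValues", "DistanceMatrix", function(x) x@d)

#' @rdname similarityRatios
#' @export
setMethod("similarityRatios", "ClusterSimilarityMatrix", function(x) x@ratios)

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "HitGraph", function(x, cluster = NULL) {
  nodes <- x@nodes
  edges <- x@edges
  if (!is.null(cluster)) {
    nodes <- nodes[nodes$cluster %in% cluster, , drop = FALSE]
    edges <- edges[edges$from %in% nodes$read & edges$to %in% nodes$read, ,
                   drop = FALSE]
  }
  igraph::graph_from_data_frame(
    d = edges[, c("from", "to", "weight")],
    directed = FALSE,
    vertices = data.frame(name = nodes$read, species = nodes$species,
                          cluster = nodes$cluster))
})
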