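#' @import methods
NULL

#' RepeatAbundanceTable: samples x repeat-family genome proportions
#'
#' Holds repeat-family abundances expressed as percent of the holoploid
#' genome (1C) for a set of samples, as estimated by comparative or
#' individual read-clustering analyses. Missing cells (not assayed) are
#' stored as \code{NA} and are distinct from measured zeros.
#'
#' @slot values numeric matrix, samples in rows, repeat families in columns;
#'   entries are percentages of 1C, non-negative or \code{NA}.
#' @slot groupLabels named character vector mapping sample id to an optional
#'   group label (e.g. broad-leaved / fine-leaved / Schedonorus); may be
#'   empty.
#' @export
setClass("RepeatAbundanceTable",
  representation(values = "matrix", groupLabels = "character"),
  prototype(values = matrix(numeric(0), 0, 0), groupLabels = character(0)))

setValidity("RepeatAbundanceTable", function(object) {
  v <- object@values
  msg <- character(0)
  if (!is.numeric(v)) msg <- c(msg, "'values' must be a numeric matrix")
  if (is.null(rownames(v)) && nrow(v) > 0)
    msg <- c(msg, "samples (rownames) must be labelled")
  if (anyDuplicated(rownames(v)))
    msg <- c(msg, "duplicate sample ids")
  if (anyDuplicated(colnames(v)))
    msg <- c(msg, "duplicate family ids")
  if (any(v < 0, na.rm = TRUE))
    msg <- c(msg, "negative abundance entries")
  tot <- rowSums(v, na.rm = TRUE)
  # a designated total column must not be double-counted in the check
  if ("Total" %in% colnames(v)) tot <- tot - ifelse(is.na(v[, "Total"]), 0, v[, "Total"])
  if (any(tot > 100 + 1e-8))
    msg <- c(msg, "per-sample total abundance exceeds 100% of 1C")
  if (length(object@groupLabels) &&
      !all(names(object@groupLabels) %in% rownames(v)))
    msg <- c(msg, "groupLabels name unknown samples")
  if (length(msg)) msg else TRUE
})

#' GenomeSizeTable: holoploid/monoploid genome sizes per sample
#'
#' @slot records data.frame with columns \code{sample}, \code{ploidy},
#'   \code{c2_pg} (holoploid 2C in pg), \code{cx1_pg} (monoploid 1Cx in pg),
#'   \code{cx1_mbp} (monoploid 1Cx in Mbp). \code{ploidy}, \code{c2_pg} may
#'   be \code{NA}; derived columns are checked for internal consistency.
#' @export
setClass("GenomeSizeTable", representation(records = "data.frame"))

setValidity("GenomeSizeTable", function(object) {
  r <- object@records
  need <- c("sample", "ploidy", "c2_pg", "cx1_pg", "cx1_mbp")
  if (!all(need %in% names(r)))
    return(paste("missing columns:", paste(setdiff(need, names(r)), collapse = ", ")))
  msg <- character(0)
  if (anyDuplicated(r$sample)) msg <- c(msg, "duplicate sample ids")
  ok <- !is.na(r$c2_pg) & !is.na(r$ploidy) & !is.na(r$cx1_pg)
  # 1Cx = 2C / ploidy, within the rounding of the printed tables (2 d.p.)
  if (any(abs(r$c2_pg[ok] / r$ploidy[ok] - r$cx1_pg[ok]) > 0.006))
    msg <- c(msg, "cx1_pg inconsistent with c2_pg / ploidy")
  ok2 <- !is.na(r$cx1_pg) & !is.na(r$cx1_mbp)
  # published 1Cx pg values are rounded to 2 d.p., so allow 0.006 x 978
  if (any(abs(r$cx1_pg[ok2] * 978 - r$cx1_mbp[ok2]) > 6))
    msg <- c(msg, "cx1_mbp inconsistent with cx1_pg * 978")
  if (length(msg)) msg else TRUE
})

#' HitGraph: undirected read-similarity graph
#'
#' The in-memory analogue of a comparative clustering "hitsort" edge list:
#' nodes are reads carrying a species code and a cluster label, edges are
#' pairwise similarity hits with a positive weight.
#'
#' @slot nodes data.frame with columns \code{read} (unique id),
#'   \code{species}, \code{cluster}.
#' @slot edges data.frame with columns \code{from}, \code{to} (read ids)
#'   and \code{weight} (> 0). Undirected; no self edges; at most one edge
#'   per unordered pair.
#' @export
setClass("HitGraph", representation(nodes = "data.frame", edges = "data.frame"))

setValidity("HitGraph", function(object) {
  n <- object@nodes; e <- object@edges
  msg <- character(0)
  if (!all(c("read", "species", "cluster") %in% names(n)))
    msg <- c(msg, "nodes need read/species/cluster columns")
  if (!all(c("from", "to", "weight") %in% names(e)))
    msg <- c(msg, "edges need from/to/weight columns")
  if (length(msg)) return(msg)
  if (anyDuplicated(n$read)) msg <- c(msg, "duplicate read ids")
  if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self edges not allowed")
    if (!all(c(e$from, e$to) %in% n$read))
      msg <- c(msg, "edge endpoint not among declared nodes")
    if (any(e$weight <= 0)) msg <- c(msg, "edge weights must be > 0")
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges for a read pair")
  }
  if (length(msg)) msg else TRUE
})

#' ClusterSimilarityMatrix: species x species observed/expected edge ratios
#'
#' @slot cluster character(1) cluster id.
#' @slot ratios symmetric numeric matrix of observed/expected edge-count
#'   ratios; diagonal entries are the intra-species ratios. \code{NA} marks
#'   undefined ratios (expected count of zero).
#' @slot readCounts named integer vector, reads per species in the cluster.
#' @export
setClass("ClusterSimilarityMatrix",
  representation(cluster = "character", ratios = "matrix",
                 readCounts = "integer"))

setValidity("ClusterSimilarityMatrix", function(object) {
  m <- object@ratios
  msg <- character(0)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    msg <- c(msg, "ratio matrix must be square with matching dimnames")
  else if (!isTRUE(all.equal(m, t(m), tolerance = 1e-9, check.attributes = FALSE)))
    msg <- c(msg, "ratio matrix must be symmetric")
  if (any(m < 0, na.rm = TRUE)) msg <- c(msg, "ratios must be >= 0")
  if (!identical(sort(names(object@readCounts)), sort(rownames(m))))
    msg <- c(msg, "readCounts must name every species in the matrix")
  if (length(msg)) msg else TRUE
})

#' DistanceMatrix: symmetric species distance matrix with a transform tag
#'
#' @slot d symmetric non-negative numeric matrix with zero diagonal.
#' @slot transform character(1), one of \code{"euclidean"} or
#'   \code{"inverse"} (which similarity-to-distance transform produced it),
#'   or \code{"none"} for externally supplied matrices.
#' @slot cluster character(1) source cluster id ("" if not applicable).
#' @export
setClass("DistanceMatrix",
  representation(d = "matrix", transform = "character", cluster = "character"),
  prototype(transform = "none", cluster = ""))

setValidity("DistanceMatrix", function(object) {
  m <- object@d
  msg <- character(0)
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  if (!all(is.finite(m))) msg <- c(msg, "entries must be finite")
  else {
    if (max(abs(m - t(m))) > 1e-9) msg <- c(msg, "matrix must be symmetric")
    if (any(diag(m) != 0)) msg <- c(msg, "diagonal must be zero")
    if (any(m < 0)) msg <- c(msg, "distances must be non-negative")
  }
  if (is.null(rownames(m))) msg <- c(msg, "species labels required")
  if (!object@transform %in% c("euclidean", "inverse", "none"))
    msg <- c(msg, "unknown transform tag")
  if (length(msg)) msg else TRUE
})

#' SplitSet: weighted bipartitions of a taxon set
#'
#' The product of split decomposition / consensus-network construction:
#' a list of bipartitions of the taxon set, each with a weight (branch
#' length) and a support frequency.
#'
#' @slot taxa character vector of taxon labels (unique).
#' @slot splits list of character vectors; each split is stored canonically
#'   as the side containing \code{taxa[1]}.
#' @slot weights numeric vector of split weights (>= 0).
#' @slot support numeric vector of support frequencies in [0, 1].
#' @export
setClass("SplitSet",
  representation(taxa = "character", splits = "list",
                 weights = "numeric", support = "numeric"))

setValidity("SplitSet", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@taxa)) msg <- c(msg, "duplicate taxa")
  ns <- length(object@splits)
  if (length(object@weights) != ns || length(object@support) != ns)
    msg <- c(msg, "weights/support must match number of splits")
  if (any(!is.finite(object@weights)) || any(object@weights < 0))
    msg <- c(msg, "weights must be finite and >= 0")
  if (ns && (any(object@support < 0) || any(object@support > 1)))
    msg <- c(msg, "support must lie in [0, 1]")
  for (s in object@splits) {
    if (!all(s %in% object@taxa)) { msg <- c(msg, "split names unknown taxon"); break }
    if (length(s) == 0 || length(s) == length(object@taxa)) {
      msg <- c(msg, "split sides must be proper non-empty subsets"); break
    }
    if (length(object@taxa) && !(object@taxa[1] %in% s)) {
      msg <- c(msg, "splits must be stored canonically (side containing first taxon)")
      break
    }
  }
  keys <- vapply(object@splits, function(s) paste(sort(s), collapse = "|"), "")
  if (anyDuplicated(keys)) msg <- c(msg, "duplicate splits")
  if (length(msg)) msg else TRUE
})

## ---- show methods ----

setMethod("show", "RepeatAbundanceTable", function(object) {
  v <- object@values
  cat("RepeatAbundanceTable:", nrow(v), "samples x", ncol(v),
      "repeat families (% of 1C)\n")
  if (nrow(v)) {
    cat("  samples: ", paste(utils::head(rownames(v), 4), collapse = ", "),
        if (nrow(v) > 4) ", ..." else "", "\n", sep = "")
    cat("  missing cells:", sum(is.na(v)), "\n")
  }
  if (length(object@groupLabels))
    cat("  groups:", paste(names(table(object@groupLabels)), collapse = ", "), "\n")
})

setMethod("show", "GenomeSizeTable", function(object) {
  r <- object@records
  cat("GenomeSizeTable:", nrow(r), "samples,",
      sum(!is.na(r$c2_pg)), "with 2C measurements\n")
})

setMethod("show", "HitGraph", function(object) {
  cat("HitGraph:", nrow(object@nodes), "reads,", nrow(object@edges),
      "similarity edges\n")
  cat("  species:", length(unique(object@nodes$species)),
      " clusters:", length(unique(object@nodes$cluster)), "\n")
})

setMethod("show", "ClusterSimilarityMatrix", function(object) {
  cat("ClusterSimilarityMatrix [", object@cluster, "]: ",
      nrow(object@ratios), " species\n", sep = "")
})

setMethod("show", "DistanceMatrix", function(object) {
  cat("DistanceMatrix (", object@transform, "): ", nrow(object@d),
      " species", if (nzchar(object@cluster)) paste0(", cluster ", object@cluster),
      "\n", sep = "")
})

setMethod("show", "SplitSet", function(object) {
  cat("SplitSet:", length(object@taxa), "taxa,", length(object@splits),
      "splits (", sum(vapply(object@splits, length, 1L) > 1 &
                      vapply(object@splits, length, 1L) < length(object@taxa) - 1),
      "nontrivial )\n")
})
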