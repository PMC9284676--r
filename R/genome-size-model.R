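#' Phylogenetically independent contrasts (Felsenstein pruning)
#'
#' Standardized contrasts for a tip trait on a fully bifurcating rooted
#' tree: at each internal node the contrast is (x_i - x_j) / sqrt(v_i +
#' v_j), the ancestral value is the 1/v-weighted mean of the children, and
#' the parent edge is augmented by v_i v_j / (v_i + v_j).
#'
#' @param tree rooted, fully bifurcating \code{phylo} tree with strictly
#'   positive branch lengths
#' @param trait named numeric vector over all tips
#' @return list with \code{contrasts} and \code{variances} (expected
#'   variances, the sums of adjusted child branch lengths), both of length
#'   n - 1, named by internal node number
#' @export
independentContrasts <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"))
  if (any(tabulate(tree$edge[, 1]) > 2))
    stop("tree contains polytomies; resolve them (e.g. ape::multi2di) first")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  ntip <- length(tree$tip.label)
  if (!all(tree$tip.label %in% names(trait)))
    stop("trait must be defined on every tip")
  term <- tree$edge[, 2] <= ntip
  if (any(tree$edge.length[term] <= 0))
    stop("zero-length terminal branches are not allowed")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  nnode <- tree$Nnode
  x <- numeric(ntip + nnode)
  v <- numeric(ntip + nnode)  # extra variance carried up each node
  x[seq_len(ntip)] <- trait[tree$tip.label]
  # child edges per internal node
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  contrasts <- numeric(nnode)
  variances <- numeric(nnode)
  names(contrasts) <- names(variances) <- character(nnode)
  done <- c(rep(TRUE, ntip), rep(FALSE, nnode))
  root <- ntip + 1L
  stack <- root
  while (length(stack)) {
    node <- stack[length(stack)]
    ek <- kids[[as.character(node)]]
    ch <- tree$edge[ek, 2]
    pending <- ch[!done[ch]]
    if (length(pending)) { stack <- c(stack, pending); next }
    stack <- stack[-length(stack)]
    vi <- tree$edge.length[ek[1]] + v[ch[1]]
    vj <- tree$edge.length[ek[2]] + v[ch[2]]
    idx <- node - ntip
    contrasts[idx] <- (x[ch[1]] - x[ch[2]]) / sqrt(vi + vj)
    variances[idx] <- vi + vj
    names(contrasts)[idx] <- names(variances)[idx] <- as.character(node)
    x[node] <- (x[ch[1]] / vi + x[ch[2]] / vj) / (1 / vi + 1 / vj)
    v[node] <- vi * vj / (vi + vj)
    done[node] <- TRUE
  }
  list(contrasts = contrasts, variances = variances)
}

#' Pearson correlation with t-based two-sided p-value
#'
#' For contrast vectors use \code{center = FALSE}: contrasts have
#' expectation zero, so the correlation is computed through the origin
#' without re-centering.
#'
#' @param x,y numeric vectors of equal length n >= 3
#' @param center logical; re-center the variables (standard Pearson) or not
#'   (through-the-origin convention for contrasts)
#' @return list with \code{r}, \code{r.squared}, \code{p.value}, \code{n}
#' @export
pearsonTest <- function(x, y, center = TRUE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (center) { x <- x - mean(x); y <- y - mean(y) }
  sx <- sum(x^2); sy <- sum(y^2)
  if (sx == 0 || sy == 0) stop("zero variance in x or y")
  r <- sum(x * y) / sqrt(sx * sy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, r.squared = r^2, p.value = p, n = n)
}

#' Absolute repeat amounts (Mbp) from genome proportions
#'
#' Reconstructs per-sample absolute repeat amounts as
#' (percent of 1C) / 100 x 1Cx (Mbp).
#'
#' @param abundance a \linkS4class{RepeatAbundanceTable} (% of 1C)
#' @param genomeSizes a \linkS4class{GenomeSizeTable}
#' @param totalColumn total column to drop from the amounts
#' @return numeric matrix of amounts in Mbp (samples with known 1Cx only)
#' @export
amountsMbp <- function(abundance, genomeSizes, totalColumn = "Total") {
  v <- abundanceValues(abundance)
  v <- v[, setdiff(colnames(v), totalColumn), drop = FALSE]
  gs <- genomeSizeRecords(genomeSizes)
  gs <- gs[!is.na(gs$cx1_mbp), , drop = FALSE]
  shared <- intersect(rownames(v), gs$sample)
  if (!length(shared)) stop("no samples shared between abundance and genome sizes")
  cx <- gs$cx1_mbp[match(shared, gs$sample)]
  sweep(v[shared, , drop = FALSE] / 100, 1, cx, `*`)
}

#' PIC-corrected correlation of repeat amounts with genome size
#'
#' For each repeat family, computes independent contrasts of the family's
#' absolute amount (Mbp) and of the monoploid genome size (1Cx, Mbp) on the
#' shared tree, then correlates the two contrast vectors through the
#' origin. Families whose contrasts are degenerate (constant amounts) are
#' reported as not testable.
#'
#' @param amounts numeric matrix of absolute amounts in Mbp (samples x
#'   families), e.g. from \code{\link{amountsMbp}}
#' @param genomeSizes a \linkS4class{GenomeSizeTable} (1Cx Mbp used)
#' @param tree rooted bifurcating \code{phylo}; tips must be a subset of
#'   the samples that carry both amounts and genome sizes
#' @return data.frame with family, r, r.squared, p.value, n (number of
#'   contrasts) and testable flag
#' @export
repeatGsCorrelation <- function(amounts, genomeSizes, tree) {
  gs <- genomeSizeRecords(genomeSizes)
  gs <- gs[!is.na(gs$cx1_mbp), , drop = FALSE]
  usable <- intersect(rownames(amounts), gs$sample)
  missing <- setdiff(tree$tip.label, usable)
  if (length(missing))
    stop("tree tips without amount/genome-size data: ",
         paste(missing, collapse = ", "))
  if (length(tree$tip.label) < 4L) stop("need at least 4 usable tips")
  cx <- gs$cx1_mbp[match(tree$tip.label, gs$sample)]
  names(cx) <- tree$tip.label
  picGS <- independentContrasts(tree, cx)$contrasts
  res <- lapply(colnames(amounts), function(f) {
    a <- amounts[tree$tip.label, f]
    names(a) <- tree$tip.label
    if (anyNA(a) || diff(range(a)) == 0)
      return(data.frame(family = f, r = NA_real_, r.squared = NA_real_,
                        p.value = NA_real_, n = NA_integer_, testable = FALSE,
                        stringsAsFactors = FALSE))
    picA <- independentContrasts(tree, a)$contrasts
    ct <- tryCatch(pearsonTest(picA, picGS, center = FALSE),
                   error = function(e) NULL)
    if (is.null(ct))
      data.frame(family = f, r = NA_real_, r.squared = NA_real_,
                 p.value = NA_real_, n = NA_integer_, testable = FALSE,
                 stringsAsFactors = FALSE)
    else
      data.frame(family = f, r = ct$r, r.squared = ct$r.squared,
                 p.value = ct$p.value, n = ct$n, testable = TRUE,
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Average contribution of each repeat family to pairwise genome-size
#' differences
#'
#' For every unordered sample pair (a, b) ordered so that GS_a > GS_b, the
#' family share is 100 x (A_fa - A_fb) / (GS_a - GS_b); the contribution is
#' the mean share over pairs. Pairs whose genome sizes differ by less than
#' \code{floorFrac} of the mean genome size are excluded to avoid division
#' blow-ups. Contributions can be negative (families anti-correlated with
#' genome size). Also reports each family's min/max absolute amount.
#'
#' @param amounts numeric matrix of absolute amounts in Mbp (samples x
#'   families)
#' @param genomeSizesMbp named numeric vector of genome sizes (Mbp) for the
#'   same samples
#' @param floorFrac relative exclusion floor for near-equal genome sizes
#'   (default 0.01 = 1% of the mean genome size)
#' @return list with \code{contributions} (data.frame: family,
#'   contribution_pct, min_mbp, max_mbp), \code{nPairs},
#'   \code{nPairsExcluded}
#' @export
pairwiseContribution <- function(amounts, genomeSizesMbp, floorFrac = 0.01) {
  samples <- intersect(rownames(amounts), names(genomeSizesMbp))
  if (length(samples) < 2L) stop("need >= 2 samples with amounts and sizes")
  A <- amounts[samples, , drop = FALSE]
  gs <- genomeSizesMbp[samples]
  pairs <- utils::combn(length(samples), 2)
  dGS <- gs[pairs[1, ]] - gs[pairs[2, ]]
  # orient each pair so the larger genome comes first
  flip <- dGS < 0
  hi <- ifelse(flip, pairs[2, ], pairs[1, ])
  lo <- ifelse(flip, pairs[1, ], pairs[2, ])
  diff <- gs[hi] - gs[lo]
  keep <- diff >= floorFrac * mean(gs)
  if (!any(keep)) stop("all sample pairs excluded by the genome-size floor")
  shares <- 100 * (A[hi[keep], , drop = FALSE] - A[lo[keep], , drop = FALSE]) /
    diff[keep]
  contrib <- colMeans(shares, na.rm = TRUE)
  list(contributions = data.frame(
         family = colnames(A),
         contribution_pct = unname(contrib),
         min_mbp = apply(A, 2, min, na.rm = TRUE),
         max_mbp = apply(A, 2, max, na.rm = TRUE),
         row.names = NULL, stringsAsFactors = FALSE),
       nPairs = sum(keep), nPairsExcluded = sum(!keep))
}
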