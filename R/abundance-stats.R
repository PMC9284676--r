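#' Convert a DNA mass in picograms to megabase pairs
#'
#' Uses the standard conversion 1 pg = 978 Mbp.
#' @param mass_pg non-negative numeric, DNA mass in pg
#' @return genome size in Mbp
#' @examples
#' pgToMbp(5.09) # 4978.02
#' @export
pgToMbp <- function(mass_pg) {
  if (any(mass_pg < 0, na.rm = TRUE)) stop("mass must be non-negative")
  mass_pg * 978
}

#' Convert megabase pairs to picograms (inverse of pgToMbp)
#' @param size_mbp non-negative numeric, size in Mbp
#' @return DNA mass in pg
#' @export
mbpToPg <- function(size_mbp) {
  if (any(size_mbp < 0, na.rm = TRUE)) stop("size must be non-negative")
  size_mbp / 978
}

#' Monoploid genome size (1Cx) from holoploid 2C value and ploidy
#'
#' 1Cx = 2C / ploidy: the DNA amount of one basic chromosome set.
#' @param c2_pg holoploid genome size 2C in pg (> 0)
#' @param ploidy even integer ploidy level >= 2
#' @return monoploid genome size 1Cx in pg
#' @examples
#' monoploidSize(20.36, 4) # 5.09
#' @export
monoploidSize <- function(c2_pg, ploidy) {
  if (any(c2_pg <= 0, na.rm = TRUE)) stop("2C value must be positive")
  if (any(ploidy < 2 | ploidy %% 2 != 0, na.rm = TRUE))
    stop("ploidy must be an even integer >= 2")
  c2_pg / ploidy
}

#' Genome proportion of a read cluster
#'
#' The percentage of the genome attributed to a cluster in a
#' fixed-input read-clustering run: 100 x reads-in-cluster / total reads.
#' @param n_cluster_reads reads assigned to the cluster (0..total)
#' @param n_total_reads total reads in the analysis (> 0)
#' @return percent of the genome
#' @examples
#' clusterGenomeProportion(331, 500000) # 0.0662
#' @export
clusterGenomeProportion <- function(n_cluster_reads, n_total_reads) {
  if (any(n_total_reads <= 0)) stop("total read count must be > 0")
  if (any(n_cluster_reads < 0 | n_cluster_reads > n_total_reads))
    stop("cluster read count must lie in [0, total]")
  100 * n_cluster_reads / n_total_reads
}

#' Summarize a repeat-abundance table
#'
#' Per-family mean/min/max of genome proportions over non-missing entries,
#' per-sample total proportions, and overall statistics of the totals.
#' Totals come from a designated total column when present, otherwise from
#' row sums over non-missing families. All-missing families are flagged and
#' excluded from the family summary.
#'
#' @param x a \linkS4class{RepeatAbundanceTable}
#' @param totalColumn name of the total column (used if present)
#' @return list with \code{familySummary} (data.frame: family, mean, min,
#'   max, n), \code{sampleTotals} (named numeric), \code{totalMean},
#'   \code{totalMin}, \code{totalMax}, and \code{allMissingFamilies}
#' @export
summarizeAbundance <- function(x, totalColumn = "Total") {
  v <- abundanceValues(x)
  if (!nrow(v) || !ncol(v)) stop("empty abundance table")
  hasTotal <- totalColumn %in% colnames(v)
  fam <- v[, setdiff(colnames(v), totalColumn), drop = FALSE]
  nobs <- colSums(!is.na(fam))
  allMissing <- colnames(fam)[nobs == 0]
  keep <- nobs > 0
  fs <- data.frame(
    family = colnames(fam)[keep],
    mean = colMeans(fam[, keep, drop = FALSE], na.rm = TRUE),
    min = apply(fam[, keep, drop = FALSE], 2, min, na.rm = TRUE),
    max = apply(fam[, keep, drop = FALSE], 2, max, na.rm = TRUE),
    n = nobs[keep],
    row.names = NULL, stringsAsFactors = FALSE)
  totals <- if (hasTotal) v[, totalColumn] else rowSums(fam, na.rm = TRUE)
  names(totals) <- rownames(v)
  tv <- totals[!is.na(totals)]
  list(familySummary = fs,
       sampleTotals = totals,
       totalMean = mean(tv), totalMin = min(tv), totalMax = max(tv),
       allMissingFamilies = allMissing)
}

#' Kruskal-Wallis rank test for group differences in repeat abundance
#'
#' Tie-corrected H statistic with a chi-square upper-tail p-value on k - 1
#' degrees of freedom (delegates to \code{stats::kruskal.test}). When every
#' value is identical the statistic is defined as 0 with p = 1.
#'
#' @param values numeric vector
#' @param groups group labels, same length as \code{values}; >= 2 non-empty
#'   groups required
#' @return list with \code{H}, \code{df}, \code{p.value}, \code{n}
#' @examples
#' kruskalWallis(c(1, 2, 3, 4), c("a", "a", "b", "b")) # H = 2.4
#' @export
kruskalWallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  if (length(unique(groups)) < 2L) stop("need at least 2 non-empty groups")
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = length(unique(groups)) - 1L, p.value = 1,
                n = length(values)))
  kt <- stats::kruskal.test(values, factor(groups))
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value, n = length(values))
}

#' Per-family Kruskal-Wallis tests across sample groups
#'
#' Applies \code{\link{kruskalWallis}} to each repeat family of an
#' abundance table, using the table's group labels (or a caller-supplied
#' grouping). p-values are reported raw (no multiple-testing correction).
#'
#' @param x a \linkS4class{RepeatAbundanceTable}
#' @param groups optional named group vector; defaults to
#'   \code{groupLabels(x)}
#' @param totalColumn total column to exclude from testing
#' @return data.frame with family, H, df, p.value, n
#' @export
familyKruskalWallis <- function(x, groups = NULL, totalColumn = "Total") {
  v <- abundanceValues(x)
  if (is.null(groups)) groups <- groupLabels(x)
  if (!length(groups)) stop("no group labels available")
  g <- groups[rownames(v)]
  fams <- setdiff(colnames(v), totalColumn)
  res <- lapply(fams, function(f) {
    r <- tryCatch(kruskalWallis(v[, f], g), error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(family = f, H = r$H, df = r$df, p.value = r$p.value, n = r$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
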