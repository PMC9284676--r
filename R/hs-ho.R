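#' Per-read same-species (Hs) and other-species (Ho) hit counts
#'
#' For every read in a cluster subgraph, counts its similarity-graph
#' neighbours from the same species (Hs) and from all other species (Ho).
#'
#' @param graph a \linkS4class{HitGraph}
#' @param cluster cluster id (repeat family) to analyse
#' @return data.frame with read, species, Hs, Ho
#' @export
readHitCounts <- function(graph, cluster) {
  sub <- clusterSubgraph(graph, cluster)
  sp <- sub@nodes$species
  names(sp) <- sub@nodes$read
  hs <- ho <- integer(nrow(sub@nodes))
  names(hs) <- names(ho) <- sub@nodes$read
  if (nrow(sub@edges)) {
    same <- sp[sub@edges$from] == sp[sub@edges$to]
    for (v in c("from", "to")) {
      t1 <- table(sub@edges[[v]][same])
      hs[names(t1)] <- hs[names(t1)] + as.integer(t1)
      t2 <- table(sub@edges[[v]][!same])
      ho[names(t2)] <- ho[names(t2)] + as.integer(t2)
    }
  }
  data.frame(read = sub@nodes$read, species = unname(sp),
             Hs = unname(hs), Ho = unname(ho), stringsAsFactors = FALSE)
}

#' Per-capita normalized Hs/Ho ratio
#'
#' Corrects for unequal species sampling: a read of species s with n_s
#' same-species reads among N total has n_s - 1 potential intraspecific
#' partners and N - n_s interspecific ones, so
#' rho = (Hs / (n_s - 1)) / (Ho / (N - n_s)). A conserved repeat hits both
#' pools at the same per-capita rate (rho of about 1, log10 of about 0);
#' a diversified repeat hits mostly its own species (rho >> 1). Reads with
#' Hs = Ho = 0 are excluded (NA); zero denominators are capped/floored at
#' the histogram limits so extreme reads remain evidence.
#'
#' @param hs,ho hit counts (vectors)
#' @param nSpeciesReads reads of the read's species in the cluster (>= 2)
#' @param nTotalReads total reads in the cluster (> nSpeciesReads)
#' @param logRange histogram limits on the log10 scale, used to cap
#'   infinite ratios
#' @return numeric vector of ratios (NA = unscored read)
#' @export
hsHoRatio <- function(hs, ho, nSpeciesReads, nTotalReads,
                      logRange = c(-2, 3)) {
  if (any(nSpeciesReads < 2)) stop("need at least 2 reads of the species")
  if (any(nTotalReads <= nSpeciesReads))
    stop("total reads must exceed the species' reads")
  rs <- hs / (nSpeciesReads - 1)
  ro <- ho / (nTotalReads - nSpeciesReads)
  rho <- rs / ro
  rho[hs == 0 & ho == 0] <- NA_real_
  rho[hs > 0 & ho == 0] <- 10^logRange[2]
  rho[hs == 0 & ho > 0] <- 10^logRange[1]
  rho
}

#' Hs/Ho ratios for every read of a cluster
#'
#' @param graph a \linkS4class{HitGraph}
#' @param cluster cluster id
#' @param logRange histogram limits (log10)
#' @return data.frame from \code{\link{readHitCounts}} plus \code{rho} and
#'   \code{log10rho}
#' @export
hsHoRatios <- function(graph, cluster, logRange = c(-2, 3)) {
  counts <- readHitCounts(graph, cluster)
  nsp <- table(counts$species)
  ns <- as.integer(nsp[counts$species])
  counts$rho <- hsHoRatio(counts$Hs, counts$Ho, ns, nrow(counts), logRange)
  counts$log10rho <- log10(counts$rho)
  counts
}

#' Histogram of log10 Hs/Ho ratios
#'
#' Bins the scored reads' log10 ratios; by default 40 bins over
#' [-2, 3] on the log10 axis. Capped values land in the edge bins. Also
#' reports the mode bin centre and the fraction of reads with
#' |log10 rho| < 0.2 (the "conserved core").
#'
#' @param ratios numeric vector of rho values (NA entries are dropped)
#' @param bins number of bins
#' @param logRange axis limits on the log10 scale
#' @return list of class \code{RatioHistogram}: \code{breaks} (bin edges,
#'   log10), \code{counts}, \code{mids}, \code{modeCenter},
#'   \code{conservedFraction}, \code{nScored}
#' @export
logRatioHistogram <- function(ratios, bins = 40L, logRange = c(-2, 3)) {
  lr <- log10(ratios[!is.na(ratios)])
  if (!length(lr)) stop("no scored reads")
  lr <- pmin(pmax(lr, logRange[1]), logRange[2])
  breaks <- seq(logRange[1], logRange[2], length.out = bins + 1L)
  idx <- findInterval(lr, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  mode <- mids[which.max(counts)]
  structure(list(breaks = breaks, counts = counts, mids = mids,
                 modeCenter = mode,
                 conservedFraction = mean(abs(lr) < 0.2),
                 nScored = length(lr)),
            class = "RatioHistogram")
}

#' @export
print.RatioHistogram <- function(x, ...) {
  cat("RatioHistogram:", x$nScored, "reads in", length(x$counts),
      "bins; mode at log10 =", format(x$modeCenter, digits = 3),
      "; conserved fraction", format(x$conservedFraction, digits = 3), "\n")
  invisible(x)
}
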