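#' Construct a RepeatAbundanceTable
#'
#' @param values numeric matrix with sample rownames and family colnames;
#'   percentages of the holoploid genome (1C). \code{NA} marks a cell that
#'   was not assayed; an explicit 0 means measured-as-zero.
#' @param groupLabels optional named character vector sample -> group.
#' @return a validated \linkS4class{RepeatAbundanceTable}
#' @examples
#' m <- matrix(c(1.5, 2, 0, 3), 2, byrow = TRUE,
#'             dimnames = list(c("A", "B"), c("Angela", "Retand")))
#' RepeatAbundanceTable(m)
#' @export
RepeatAbundanceTable <- function(values, groupLabels = character(0)) {
  storage.mode(values) <- "double"
  new("RepeatAbundanceTable", values = values, groupLabels = groupLabels)
}

#' Parse a TSV repeat-abundance table
#'
#' Expects a header row of repeat-family labels, a first column of sample
#' ids, and a numeric body. Blank cells and the literal \code{NA} are
#' treated as missing (distinct from 0). Column order is preserved.
#' Non-sample metadata columns (\code{group}, \code{lineage}) are consumed
#' into group labels rather than the value matrix.
#'
#' @param text character scalar (TSV content) or a character vector of lines.
#' @param groupColumn name of an optional column holding sample group labels.
#' @return a \linkS4class{RepeatAbundanceTable}
#' @export
parseAbundanceTable <- function(text, groupColumn = "group") {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("abundance table needs a header and >= 1 sample row")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  ncol <- length(header)
  samples <- character(length(body))
  cells <- matrix(NA_character_, length(body), ncol - 1L)
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != ncol)
      stop(sprintf("row %d ('%s') has %d fields, expected %d",
                   i + 1L, row[1], length(row), ncol))
    samples[i] <- row[1]
    cells[i, ] <- row[-1]
  }
  if (anyDuplicated(samples))
    stop("duplicate sample id: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  famcols <- header[-1]
  meta <- famcols %in% c(groupColumn, "lineage")
  groups <- character(0)
  if (any(famcols == groupColumn)) {
    groups <- cells[, which(famcols == groupColumn)[1]]
    names(groups) <- samples
  }
  vals <- cells[, !meta, drop = FALSE]
  fam <- famcols[!meta]
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(samples, fam))
  for (j in seq_len(ncol(vals))) {
    raw <- trimws(vals[, j])
    missing <- raw == "" | raw == "NA"
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!missing & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at row %d (sample %s), column '%s'",
                   raw[bad[1]], bad[1] + 1L, samples[bad[1]], fam[j]))
    num[missing] <- NA_real_
    m[, j] <- num
  }
  RepeatAbundanceTable(m, groupLabels = groups)
}

#' Read a repeat-abundance TSV file
#' @param file path to a TSV file
#' @param ... passed to \code{\link{parseAbundanceTable}}
#' @return a \linkS4class{RepeatAbundanceTable}
#' @export
readAbundanceTable <- function(file, ...)
  parseAbundanceTable(readLines(file, warn = FALSE), ...)

#' Serialize a RepeatAbundanceTable to TSV text
#' @param x a \linkS4class{RepeatAbundanceTable}
#' @return character scalar of TSV content (missing cells written as NA)
#' @export
writeAbundanceTable <- function(x) {
  v <- abundanceValues(x)
  hdr <- paste(c("sample", colnames(v)), collapse = "\t")
  rows <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i],
            ifelse(is.na(v[i, ]), "NA", format(v[i, ], trim = TRUE, digits = 15))),
          collapse = "\t"), "")
  paste(c(hdr, rows), collapse = "\n")
}

#' Construct a GenomeSizeTable
#'
#' Derived quantities are filled in where they can be computed: 1Cx (pg) as
#' 2C / ploidy and 1Cx (Mbp) as 1Cx (pg) x 978.
#'
#' @param sample character vector of sample ids
#' @param ploidy integer ploidy levels (even, >= 2) or NA
#' @param c2_pg holoploid 2C genome size in pg, or NA
#' @param cx1_pg monoploid 1Cx in pg; computed from c2_pg/ploidy when NA
#' @param cx1_mbp monoploid 1Cx in Mbp; computed from cx1_pg when NA
#' @return a validated \linkS4class{GenomeSizeTable}
#' @export
GenomeSizeTable <- function(sample, ploidy = NA_integer_, c2_pg = NA_real_,
                            cx1_pg = NA_real_, cx1_mbp = NA_real_) {
  n <- length(sample)
  r <- data.frame(sample = as.character(sample),
                  ploidy = rep_len(as.integer(ploidy), n),
                  c2_pg = rep_len(as.numeric(c2_pg), n),
                  cx1_pg = rep_len(as.numeric(cx1_pg), n),
                  cx1_mbp = rep_len(as.numeric(cx1_mbp), n),
                  stringsAsFactors = FALSE)
  fill <- is.na(r$cx1_pg) & !is.na(r$c2_pg) & !is.na(r$ploidy)
  r$cx1_pg[fill] <- r$c2_pg[fill] / r$ploidy[fill]
  fill2 <- is.na(r$cx1_mbp) & !is.na(r$cx1_pg)
  r$cx1_mbp[fill2] <- pgToMbp(r$cx1_pg[fill2])
  new("GenomeSizeTable", records = r)
}

#' Read a genome-size TSV file
#'
#' Expects columns \code{sample} and any of \code{ploidy}, \code{c2_pg},
#' \code{cx1_pg}, \code{cx1_mbp}; extra columns are ignored.
#' @param file path to a TSV file
#' @return a \linkS4class{GenomeSizeTable}
#' @export
readGenomeSizeTable <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!"sample" %in% names(d)) stop("genome-size table needs a 'sample' column")
  get <- function(col, default) if (col %in% names(d)) d[[col]] else default
  GenomeSizeTable(sample = d$sample,
                  ploidy = get("ploidy", NA_integer_),
                  c2_pg = get("c2_pg", NA_real_),
                  cx1_pg = get("cx1_pg", NA_real_),
                  cx1_mbp = get("cx1_mbp", NA_real_))
}

#' Bundled Loliinae repeat genome-proportion table
#'
#' Published per-sample repeat-family genome proportions (% of 1C) for 47
#' Loliinae grass samples from individual read-clustering analyses,
#' including the per-sample \code{Total} column.
#' @return a \linkS4class{RepeatAbundanceTable}
#' @export
loliinaeRepeatProportions <- function() {
  readAbundanceTable(system.file("extdata", "loliinae_repeat_proportions.tsv",
                                 package = "repeatomeKit", mustWork = TRUE))
}

#' Bundled Loliinae genome-size table
#'
#' Holoploid (2C, pg) and monoploid (1Cx, pg and Mbp) genome sizes with
#' ploidy levels for the 47 Loliinae samples (23 with flow-cytometry 2C
#' measurements).
#' @return a \linkS4class{GenomeSizeTable}
#' @export
loliinaeGenomeSizes <- function() {
  readGenomeSizeTable(system.file("extdata", "loliinae_genome_sizes.tsv",
                                  package = "repeatomeKit", mustWork = TRUE))
}

#' Bundled Loliinae 5S rDNA tandem-cluster graph parameters
#'
#' Per-sample 5S rDNA cluster descriptors: reads in cluster, genome
#' proportion (%), repeat unit size, k-mer coverage, connected component
#' index and graph shape type (1 = single loop, 2 = two loops).
#' @return data.frame
#' @export
loliinae5SClusters <- function() {
  utils::read.delim(system.file("extdata", "loliinae_5s_clusters.tsv",
                                package = "repeatomeKit", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}
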