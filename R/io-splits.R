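#' Construct a SplitSet
#'
#' Splits are canonicalized to the side containing the first taxon, so a
#' split and its complement are the same object and duplicates collapse.
#'
#' @param taxa character vector of taxon labels
#' @param splits list of character vectors (either side of each split)
#' @param weights numeric split weights (default 1)
#' @param support numeric support frequencies in [0, 1] (default 1)
#' @return a validated \linkS4class{SplitSet}
#' @export
SplitSet <- function(taxa, splits = list(), weights = rep(1, length(splits)),
                     support = rep(1, length(splits))) {
  taxa <- as.character(taxa)
  canon <- lapply(splits, function(s) {
    s <- as.character(s)
    if (length(taxa) && !(taxa[1] %in% s)) s <- setdiff(taxa, s)
    sort(s)
  })
  if (length(canon)) {
    keys <- vapply(canon, paste, "", collapse = "|")
    if (anyDuplicated(keys)) {
      keep <- !duplicated(keys)
      canon <- canon[keep]; weights <- weights[keep]; support <- support[keep]
    }
  }
  new("SplitSet", taxa = taxa, splits = canon,
      weights = as.numeric(weights), support = as.numeric(support))
}

splitKey <- function(s) paste(sort(s), collapse = "|")

#' Is a split nontrivial?
#'
#' A split is nontrivial when both sides contain at least two taxa.
#' @param x a \linkS4class{SplitSet}
#' @return logical vector, one entry per split
#' @export
isNontrivialSplit <- function(x) {
  n <- length(x@taxa)
  sz <- vapply(x@splits, length, 1L)
  sz >= 2L & sz <= n - 2L
}

quoteNexusLabel <- function(x) {
  ifelse(grepl("[^A-Za-z0-9_.]", x), paste0("'", gsub("'", "''", x), "'"), x)
}

#' Write a SplitSet as a SplitsTree-compatible NEXUS file
#'
#' Emits a TAXA block and a SPLITS block with weights and confidences
#' (support frequencies). Taxa with spaces or other special characters are
#' quoted. The output is re-readable with \code{\link{readSplitsNexus}}.
#'
#' @param x a \linkS4class{SplitSet}
#' @param file optional path; when \code{NULL} the text is returned
#' @return character scalar of NEXUS content (invisibly when written)
#' @export
writeSplitsNexus <- function(x, file = NULL) {
  stopifnot(is(x, "SplitSet"))
  taxa <- x@taxa
  if (!length(taxa)) stop("empty taxon set")
  idx <- lapply(x@splits, function(s) sort(match(s, taxa)))
  out <- c(
    "#NEXUS",
    "BEGIN TAXA;",
    sprintf("DIMENSIONS NTAX=%d;", length(taxa)),
    "TAXLABELS",
    sprintf("  [%d] %s", seq_along(taxa), quoteNexusLabel(taxa)),
    ";",
    "END;",
    "BEGIN SPLITS;",
    sprintf("DIMENSIONS NTAX=%d NSPLITS=%d;", length(taxa), length(idx)),
    "FORMAT labels=left weights=yes confidences=yes intervals=no;",
    "MATRIX")
  if (length(idx))
    out <- c(out, sprintf("\t%d\t%.8g\t%.8g\t%s,", seq_along(idx),
                          x@weights, x@support,
                          vapply(idx, paste, "", collapse = " ")))
  out <- c(out, ";", "END;")
  text <- paste(out, collapse = "\n")
  if (is.null(file)) return(text)
  writeLines(text, file)
  invisible(text)
}

#' Read a SPLITS-block NEXUS file back into a SplitSet
#' @param file path, or a character vector of lines via \code{text}
#' @param text optional character content instead of a file
#' @return a \linkS4class{SplitSet}
#' @export
readSplitsNexus <- function(file = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(file, warn = FALSE)
    else if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- trimws(lines)
  tstart <- grep("^TAXLABELS$", lines, ignore.case = TRUE)
  if (!length(tstart)) stop("no TAXLABELS found")
  taxa <- character(0)
  i <- tstart[1] + 1L
  while (i <= length(lines) && lines[i] != ";") {
    lab <- sub("^\\[\\d+\\]\\s*", "", lines[i])
    if (grepl("^'", lab)) lab <- gsub("''", "'", sub("^'(.*)'$", "\\1", lab))
    taxa <- c(taxa, lab)
    i <- i + 1L
  }
  mstart <- grep("^MATRIX$", lines, ignore.case = TRUE)
  mstart <- mstart[mstart > i][1]
  if (is.na(mstart)) stop("no SPLITS MATRIX found")
  splits <- list(); weights <- numeric(0); support <- numeric(0)
  j <- mstart + 1L
  while (j <= length(lines) && lines[j] != ";") {
    row <- sub(",$", "", lines[j])
    f <- strsplit(row, "\\s+")[[1]]
    # row label, weight, confidence, then the taxon indices of one side
    if (length(f) >= 4L) {
      weights <- c(weights, as.numeric(f[2]))
      support <- c(support, as.numeric(f[3]))
      splits <- c(splits, list(taxa[as.integer(f[-(1:3)])]))
    }
    j <- j + 1L
  }
  SplitSet(taxa, splits, weights, support)
}
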