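#' Write a distance matrix in lower-triangle PHYLIP format
#'
#' Header line gives the number of taxa; each following line is the taxon
#' label and its distances to the preceding taxa, fixed at six decimals.
#'
#' @param d a \linkS4class{DistanceMatrix} or a labelled square symmetric
#'   numeric matrix with zero diagonal
#' @param file optional path; when \code{NULL} the text is returned
#' @return character scalar of PHYLIP content (invisibly when written)
#' @export
writeDistancePhylip <- function(d, file = NULL) {
  m <- if (is(d, "DistanceMatrix")) distanceValues(d) else d
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (max(abs(m - t(m))) > 1e-9) stop("matrix asymmetric beyond 1e-9")
  labs <- rownames(m)
  if (is.null(labs)) labs <- paste0("T", seq_len(nrow(m)))
  out <- as.character(nrow(m))
  for (i in seq_len(nrow(m))) {
    row <- if (i > 1) paste(sprintf("%.6f", m[i, seq_len(i - 1L)]), collapse = " ")
      else ""
    out <- c(out, trimws(paste(sprintf("%-12s", labs[i]), row)))
  }
  text <- paste(out, collapse = "\n")
  if (is.null(file)) return(text)
  writeLines(text, file)
  invisible(text)
}

#' Read a lower-triangle PHYLIP distance matrix
#' @param file path, or content via \code{text}
#' @param text optional character content instead of a file
#' @return a \linkS4class{DistanceMatrix} with transform tag \code{"none"}
#' @export
readDistancePhylip <- function(file = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(file, warn = FALSE)
    else if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) != n + 1L)
    stop("malformed PHYLIP distance file")
  labs <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    labs[i] <- f[1]
    vals <- as.numeric(f[-1])
    if (length(vals) != i - 1L)
      stop(sprintf("row %d has %d distances, expected %d", i, length(vals), i - 1L))
    m[i, seq_len(i - 1L)] <- vals
    m[seq_len(i - 1L), i] <- vals
  }
  dimnames(m) <- list(labs, labs)
  new("DistanceMatrix", d = m, transform = "none", cluster = "")
}
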