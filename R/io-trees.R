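#' Parse a Newick tree
#'
#' Thin validating wrapper around \code{ape::read.tree}: checks balanced
#' parentheses, unique tip labels and finite branch lengths.
#'
#' @param text character scalar of Newick content
#' @return an \code{ape} \code{phylo} tree
#' @export
parseNewick <- function(text) {
  text <- trimws(paste(text, collapse = ""))
  if (!nzchar(text)) stop("empty Newick input")
  open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (open != close)
    stop("unbalanced parentheses in Newick string (", open, " '(' vs ",
         close, " ')')")
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("could not parse Newick string")
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels")
  if (!is.null(tr$edge.length) && !all(is.finite(tr$edge.length)))
    stop("non-finite branch lengths")
  tr
}

#' Serialize a tree to Newick
#' @param tree an \code{ape} \code{phylo} tree
#' @return character scalar (Newick, with branch lengths if present)
#' @export
serializeNewick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}
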