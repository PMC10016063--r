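#' Read a Newick tree with normalised support values
#'
#' Parses Newick text (or a file containing it) into an ape `phylo` object.
#' Numeric internal-node labels are interpreted as branch support: values in
#' (1, 100] are taken to be percentages and divided by 100 on ingest so that
#' all supports live on a single `[0, 1]` scale. Non-numeric labels become
#' `NA` support.
#'
#' @param x Newick text, or the path of a file holding one tree.
#' @return A `phylo` object; if the source carried internal labels,
#'   `$node.label` is a numeric support vector in `[0, 1]` (NA where absent).
#' @examples
#' tr <- read_newick("((A:1,B:2)97:1,C:3);")
#' tr$node.label # support 0.97 on the AB edge
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  txt <- if (!grepl("[();]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    x
  }
  tr <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tr)) {
    abort(paste0("Newick parse error (check parentheses/commas): ", substr(txt, 1, 60)))
  }
  if (!is.null(tr$node.label)) {
    tr$node.label <- normalise_support(tr$node.label)
  }
  tr
}

# character labels -> numeric supports in [0,1]; >1 treated as percentage
normalise_support <- function(lab) {
  sup <- suppressWarnings(as.numeric(lab))
  sup[!is.na(sup) & sup > 1] <- sup[!is.na(sup) & sup > 1] / 100
  if (any(!is.na(sup) & (sup < 0 | sup > 1))) {
    abort("support values must lie in [0, 1] (or [0, 100] as percentages)")
  }
  sup
}

#' Write a tree to Newick
#'
#' Numeric node labels (supports in `[0, 1]`) are serialised with enough
#' significant digits to round-trip through [read_newick()].
#'
#' @param tree A `phylo` object.
#' @param path Optional output file; when `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$node.label) && is.numeric(tree$node.label)) {
    lab <- ifelse(is.na(tree$node.label), "",
      vapply(tree$node.label, function(s) sprintf("%.10g", s), character(1))
    )
    tree$node.label <- lab
  }
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) {
    return(txt)
  }
  writeLines(txt, path)
  invisible(txt)
}
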