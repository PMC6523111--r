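#' Read a rooted phylogeny from Newick
#'
#' Thin, validating wrapper around [ape::read.tree()]. The tree is used
#' exactly as written: no re-rooting is performed, polytomies are kept,
#' and internal node labels / support values are retained but ignored by
#' every computation in this package.
#'
#' Edges without a branch length are assigned unit length (1.0) with a
#' warning; parsimony reconstructions are length-agnostic and unit lengths
#' keep distance-based stages defined.
#'
#' @param x Path to a Newick file, or a Newick string (must contain "(").
#' @return A rooted `phylo` object with unique non-empty tip labels and
#'   non-negative branch lengths.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' patristic_distances(tr)
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  tr <- if (grepl("(", x, fixed = TRUE)) {
    ape::read.tree(text = x)
  } else {
    ape::read.tree(file = x)
  }
  if (is.null(tr)) stop("input does not parse as Newick", call. = FALSE)
  validate_phylo(tr)
}

#' Write a phylogeny to Newick
#'
#' Branch lengths are emitted with 6 significant digits by default; raise
#' `digits` when an exact numeric round-trip matters.
#'
#' @param tree A `phylo` object.
#' @param path Optional output file; if `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL, digits = 6) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

# Enforce the structural contract every downstream stage assumes.
validate_phylo <- function(tr) {
  tips <- tr$tip.label
  if (any(!nzchar(tips))) stop("empty tip label", call. = FALSE)
  dup <- unique(tips[duplicated(tips)])
  if (length(dup) > 0) {
    stop("duplicate tip label ", paste(dup, collapse = ", "), call. = FALSE)
  }
  n_edge <- nrow(tr$edge)
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 1.0", call. = FALSE)
    tr$edge.length <- rep(1, n_edge)
  } else if (anyNA(tr$edge.length)) {
    warning("missing branch lengths defaulted to 1.0", call. = FALSE)
    tr$edge.length[is.na(tr$edge.length)] <- 1
  }
  if (any(tr$edge.length < 0)) stop("negative branch length", call. = FALSE)
  # exactly one root: every node but one has one parent
  child <- tr$edge[, 2]
  if (anyDuplicated(child) > 0) stop("node with more than one parent", call. = FALSE)
  tr
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the unique path between every pair of tips,
#' in the tree's branch-length units.
#'
#' @param tree A `phylo` object with at least 2 tips.
#' @return A symmetric numeric matrix with zero diagonal, rows and columns
#'   named by tip label.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2) stop("degenerate tree: fewer than 2 tips", call. = FALSE)
  tree <- validate_phylo(tree)
  ape::cophenetic.phylo(tree)
}
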