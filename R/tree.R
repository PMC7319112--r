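#' Dated phylogenetic trees
#'
#' A `dated_tree` wraps an [ape::read.tree()] `"phylo"` object together with
#' node ages (Ma before present, computed from root-to-node path lengths) and
#' an ultrametricity flag.  All downstream machinery — clade delimitation by a
#' stem-age time slice, Brownian-motion rate fitting, and the phylogenetic
#' covariance of the regression — runs off these ages.
#'
#' Ages are defined as `max(tip depth) - node depth`, so in an exactly
#' ultrametric tree every tip has age 0 and the root has age equal to the tree
#' height.  Published dated trees carry rounding noise, so trees whose tip
#' depths differ by more than `tol * root_age` are flagged (not rejected):
#' `is_ultrametric(x)` is `FALSE` and a warning is issued at construction.
#'
#' @param phy an object of class `"phylo"` with branch lengths (Ma).
#' @param tol relative ultrametricity tolerance, as a fraction of root age.
#' @return An object of class `dated_tree`: a list with elements `phy`
#'   (the `"phylo"` object), `ages` (numeric vector indexed by ape node id,
#'   tips first), `root_age`, `ultrametric` (logical) and `tol`.
#' @seealso [parse_newick()], [delimit_clades()], [phylo_vcv()]
#' @export
dated_tree <- function(phy, tol = 1e-6) {
  if (!inherits(phy, "phylo")) {
    stop("'phy' must be a \"phylo\" object", call. = FALSE)
  }
  if (is.null(phy$edge.length)) {
    stop("tree has no branch lengths; a dated tree requires them", call. = FALSE)
  }
  if (any(phy$edge.length < 0)) {
    stop("negative branch lengths are not allowed in a dated tree", call. = FALSE)
  }
  if (anyDuplicated(phy$tip.label)) {
    stop("tip labels must be unique", call. = FALSE)
  }
  ntip <- length(phy$tip.label)
  depths <- ape::node.depth.edgelength(phy)
  height <- max(depths[seq_len(ntip)])
  ages <- height - depths
  ultra <- max(abs(ages[seq_len(ntip)])) <= tol * max(height, .Machine$double.eps)
  if (!ultra) {
    warning("tree is not ultrametric within tolerance; flagging, not rejecting",
            call. = FALSE)
  }
  structure(
    list(phy = phy, ages = ages, root_age = ages[ntip + 1L],
         ultrametric = ultra, tol = tol),
    class = "dated_tree"
  )
}

#' Parse a Newick string into a dated tree
#'
#' @param text a Newick string with branch lengths in Ma.
#' @param tol relative ultrametricity tolerance (see [dated_tree()]).
#' @return A [dated_tree()].
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$root_age     # 2
#' tip_ages(tr)    # all 0
#' @export
parse_newick <- function(text, tol = 1e-6) {
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("malformed Newick string", call. = FALSE)
  dated_tree(phy, tol = tol)
}

#' Read a dated tree from a Newick file
#' @param path path to a Newick file.
#' @param tol relative ultrametricity tolerance.
#' @return A [dated_tree()].
#' @export
read_dated_tree <- function(path, tol = 1e-6) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not read a tree from ", path, call. = FALSE)
  dated_tree(phy, tol = tol)
}

#' Write a dated tree to a Newick file
#' @param tree a [dated_tree()] or `"phylo"` object.
#' @param path output path.
#' @export
write_dated_tree <- function(tree, path) {
  phy <- as_phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @export
print.dated_tree <- function(x, ...) {
  cat("Dated phylogenetic tree:", length(x$phy$tip.label), "tips, root age",
      format(x$root_age, digits = 6), "Ma",
      if (!x$ultrametric) "(flagged non-ultrametric)" else "", "\n")
  invisible(x)
}

#' Coerce to ape's "phylo"
#' @param tree a [dated_tree()] or `"phylo"` object.
#' @return The underlying `"phylo"` object.
#' @export
as_phylo <- function(tree) {
  if (inherits(tree, "dated_tree")) tree$phy
  else if (inherits(tree, "phylo")) tree
  else stop("not a tree", call. = FALSE)
}

#' Node and tip ages
#'
#' @param tree a [dated_tree()].
#' @return `node_ages()`: ages (Ma) for all nodes in ape numbering (tips
#'   `1..Ntip`, then internals). `tip_ages()`: the tip entries, named by label.
#' @export
node_ages <- function(tree) {
  if (!inherits(tree, "dated_tree")) tree <- dated_tree(as_phylo(tree))
  tree$ages
}

#' @rdname node_ages
#' @export
tip_ages <- function(tree) {
  if (!inherits(tree, "dated_tree")) tree <- dated_tree(as_phylo(tree))
  stats::setNames(tree$ages[seq_along(tree$phy$tip.label)], tree$phy$tip.label)
}

#' @rdname node_ages
#' @export
is_ultrametric <- function(tree) {
  if (!inherits(tree, "dated_tree")) tree <- dated_tree(as_phylo(tree))
  tree$ultrametric
}
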