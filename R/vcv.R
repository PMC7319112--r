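#' Phylogenetic covariance matrix under Brownian motion
#'
#' `C[i, j]` is the shared root-to-MRCA path length (Ma) between labels i and
#' j; the diagonal is each label's root-to-tip depth.  Pagel's lambda
#' multiplies the off-diagonal entries only, so `lambda = 0` gives a diagonal
#' (star-like) matrix and `lambda = 1` the pure Brownian-motion covariance.
#'
#' @param tree a [dated_tree()] or `"phylo"` object.
#' @param labels optional subset of tip labels; the rows/columns returned, in
#'   this order.  Unknown labels are an error.
#' @param lambda optional multiplier in \[0, 1\] for the off-diagonals.
#' @return A symmetric positive semi-definite matrix with `dimnames` set to
#'   the labels, and attribute `"lambda"` if one was applied.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' phylo_vcv(tr)            # C[A,B] = 1, C[A,C] = 0, diagonal 2
#' phylo_vcv(tr, lambda = 0)
#' @export
phylo_vcv <- function(tree, labels = NULL, lambda = NULL) {
  phy <- as_phylo(tree)
  C <- ape::vcv.phylo(phy)
  if (!is.null(labels)) {
    missing <- setdiff(labels, rownames(C))
    if (length(missing)) {
      stop("unknown label(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    C <- C[labels, labels, drop = FALSE]
  }
  if (!is.null(lambda)) {
    stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0, lambda <= 1)
    d <- diag(C)
    C <- C * lambda
    diag(C) <- d
    attr(C, "lambda") <- lambda
  }
  C
}
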