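#' Multivariate Brownian-motion rate matrix by maximum likelihood
#'
#' Fits a multivariate Brownian-motion model to continuous traits on a dated
#' tree.  For each trait the ancestral root state is the GLS estimate
#' `a_k = (1' C^-1 1)^-1 1' C^-1 x_k` with `C` the Brownian phylogenetic
#' covariance of the tree; the evolutionary rate matrix is then
#' `R = (X - 1 a')' C^-1 (X - 1 a') / n` (the ML estimator, divisor `n`).
#' The diagonal entries of `R` are the per-trait rates sigma^2 (trait
#' units^2 per Ma); off-diagonals are evolutionary covariances.
#'
#' @param traits numeric matrix, species x traits, rownames matching tip
#'   labels of `tree`; at least 2 species, no missing values.
#' @param tree a [dated_tree()] or `"phylo"`; pruned internally to the trait
#'   species.
#' @return An object of class `bm_rates`: list with `rates` (named per-trait
#'   sigma^2), `R` (full rate matrix), `root` (per-trait root estimates) and
#'   `n` (number of species).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' x <- cbind(size = c(A = 1, B = 2, C = 4))
#' bm_rate_matrix(x, tr)$rates
#' @export
bm_rate_matrix <- function(traits, tree) {
  traits <- as.matrix(traits)
  if (is.null(rownames(traits))) stop("'traits' needs species rownames", call. = FALSE)
  if (anyNA(traits)) stop("'traits' must have no missing values", call. = FALSE)
  n <- nrow(traits)
  if (n < 2L) stop("at least 2 species are required to estimate a rate", call. = FALSE)
  phy <- as_phylo(tree)
  miss <- setdiff(rownames(traits), phy$tip.label)
  if (length(miss)) {
    stop("species not in tree: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (length(phy$tip.label) > n) phy <- ape::keep.tip(phy, rownames(traits))
  C <- ape::vcv.phylo(phy)[rownames(traits), rownames(traits)]
  L <- tryCatch(chol(C), error = function(e) {
    stop("phylogenetic covariance is singular (zero-length tip pairs?); ",
         "resolve duplicate tips or drop one of each pair", call. = FALSE)
  })
  # whiten: solve L' u = v  =>  u = (L')^-1 v, so u'u = v' C^-1 v
  one_w <- backsolve(L, rep(1, n), transpose = TRUE)
  X_w <- backsolve(L, traits, transpose = TRUE)
  root <- drop(crossprod(one_w, X_w)) / sum(one_w^2)
  resid_w <- X_w - outer(one_w, root)
  R <- crossprod(resid_w) / n
  dimnames(R) <- list(colnames(traits), colnames(traits))
  structure(
    list(rates = stats::setNames(diag(R), colnames(traits)), R = R,
         root = stats::setNames(root, colnames(traits)), n = n),
    class = "bm_rates"
  )
}

#' @export
print.bm_rates <- function(x, ...) {
  cat("Brownian-motion ML fit:", x$n, "species,", length(x$rates), "trait(s)\n")
  cat("per-trait rates sigma^2:\n")
  print(x$rates)
  invisible(x)
}

#' Clade-level niche-evolution rate
#'
#' For every multispecies clade, fits the multivariate Brownian-motion model
#' on the clade's crown subtree and sums the per-trait rates (the diagonal of
#' the rate matrix); the summed rates are then scaled by their maximum across
#' clades so the final rate `c` lies in (0, 1\].  Traits are z-standardized
#' across all species first (unit variance) so that the sum is not dominated
#' by trait measurement units.  Singleton clades carry no rate information
#' and are excluded (recorded in the `"excluded"` attribute).
#'
#' @param traits species x traits matrix covering all clade members.
#' @param tree the full [dated_tree()].
#' @param clades a [delimit_clades()] result.
#' @param standardize z-standardize traits across species first (default TRUE).
#' @return data.frame `clade_id`, `c_raw` (summed rates), `c` (max-scaled),
#'   with excluded singleton clade ids in `attr(, "excluded")`.
#' @export
clade_niche_rate <- function(traits, tree, clades, standardize = TRUE) {
  stopifnot(inherits(clades, "clade_set"))
  traits <- as.matrix(traits)
  if (standardize) {
    traits <- scale(traits)
    traits[, attr(traits, "scaled:scale") == 0] <- 0  # constant traits: rate 0
  }
  phy <- as_phylo(tree)
  multi <- clades$table$clade_id[clades$table$n_species > 1L]
  if (length(multi) == 0L) {
    stop("no multispecies clade to estimate a rate from", call. = FALSE)
  }
  c_raw <- vapply(multi, function(cid) {
    sp <- clades$members[[cid]]
    sum(bm_rate_matrix(traits[sp, , drop = FALSE], phy)$rates)
  }, 1)
  out <- data.frame(clade_id = multi, c_raw = c_raw, c = c_raw / max(c_raw),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded") <- setdiff(clades$table$clade_id, multi)
  out
}
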