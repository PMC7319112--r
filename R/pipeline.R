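#' Compute all four clade components from raw inputs
#'
#' The end-to-end component stage: delimits clades on the dated tree at the
#' stem-age `cutoff`, then computes for every multispecies clade
#' * `d` — net diversification by the stem-age method-of-moments estimator
#'   ([net_diversification()], extinction fraction `eps`),
#' * `a` — rarefied suitable-cell count ([clade_area()]; `rarefy_to`
#'   defaults to the smallest multispecies clade, removing richness bias),
#' * `b` — mean within-clade competition index ([competition_index()] over
#'   Schoener's D x geographic overlap, min-max rescaled across all pairs),
#' * `c` — max-scaled summed Brownian trait rates ([clade_niche_rate()]).
#' Singleton clades are listed in the `"singletons"` attribute and excluded
#' from the regression table (they carry `d = 0` and no pairwise or rate
#' information).
#'
#' @param tree a [dated_tree()].
#' @param grid a [suitability_grid()].
#' @param occ named list of occupied cell ids per species.
#' @param traits species x traits matrix.
#' @param cutoff stem-age slice in Ma.
#' @param eps relative extinction fraction for `d` (default 0.9).
#' @param threshold suitability cutoff for cell counting (default 0.5).
#' @param reps rarefaction replicates (default 100).
#' @param rarefy_to rarefaction depth; default: smallest multispecies clade.
#' @param seed seed for the rarefaction draws (recorded in provenance).
#' @param overlap_method geographic overlap variant (`"simpson"` or
#'   `"jaccard"`).
#' @return data.frame (class `clade_components`) with columns `clade_id`,
#'   `n_species`, `stem_age`, `d`, `a`, `b`, `c`; attributes `params`
#'   (provenance), `singletons`, and `clades` (the [delimit_clades()]
#'   result).
#' @export
compute_components <- function(tree, grid, occ, traits, cutoff,
                               eps = 0.9, threshold = 0.5, reps = 100,
                               rarefy_to = NULL, seed = 1,
                               overlap_method = "simpson") {
  clades <- delimit_clades(tree, cutoff)
  tab <- clades$table[clades$table$n_species > 1L, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no multispecies clade at this cutoff", call. = FALSE)
  if (is.null(rarefy_to)) rarefy_to <- min(tab$n_species)

  tab$d <- net_diversification(tab$n_species, tab$stem_age, eps = eps)
  tab$a <- vapply(tab$clade_id, function(cid)
    clade_area(grid, clades$members[[cid]], threshold = threshold,
               rarefy_to = min(rarefy_to, length(clades$members[[cid]])),
               reps = reps, seed = seed), 1)
  comp <- competition_index(
    clade_pair_overlaps(grid, occ, clades, method = overlap_method))
  tab$b <- comp$clades$b[match(tab$clade_id, comp$clades$clade_id)]
  cn <- clade_niche_rate(traits, tree, clades)
  tab$c <- cn$c[match(tab$clade_id, cn$clade_id)]
  rownames(tab) <- NULL

  attr(tab, "params") <- list(cutoff = cutoff, eps = eps,
                              threshold = threshold, reps = reps,
                              rarefy_to = rarefy_to, seed = seed,
                              overlap_method = overlap_method)
  attr(tab, "singletons") <- clades$table$clade_id[clades$table$n_species == 1L]
  attr(tab, "clades") <- clades
  class(tab) <- c("clade_components", class(tab))
  tab
}

#' Run the full analysis in one call
#'
#' [compute_components()] followed by [clade_backbone_tree()] and
#' [eva_pgls()]; equivalent to running the stages separately on the same
#' inputs and parameters.
#'
#' @inheritParams compute_components
#' @param formula model formula string (default `"d ~ ln(a) + b + ln(c)"`).
#' @param estimate_lambda profile Pagel's lambda (default FALSE).
#' @return List with `components` (the clade table) and `fit` (the
#'   [eva_pgls()] result).
#' @export
run_eva <- function(tree, grid, occ, traits, cutoff,
                    formula = "d ~ ln(a) + b + ln(c)",
                    eps = 0.9, threshold = 0.5, reps = 100,
                    rarefy_to = NULL, seed = 1, overlap_method = "simpson",
                    estimate_lambda = FALSE) {
  components <- compute_components(tree, grid, occ, traits, cutoff,
                                   eps = eps, threshold = threshold,
                                   reps = reps, rarefy_to = rarefy_to,
                                   seed = seed,
                                   overlap_method = overlap_method)
  backbone <- clade_backbone_tree(tree, attr(components, "clades"))
  fit <- eva_pgls(components, backbone, formula = formula,
                  estimate_lambda = estimate_lambda)
  list(components = components, fit = fit)
}
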