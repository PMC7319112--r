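#' Schoener's niche overlap D
#'
#' `D = 1 - 0.5 * sum(|p_i - q_i|)` over cells, with each suitability vector
#' first normalized to sum to 1.  Symmetric, in \[0, 1\]; 1 iff the normalized
#' vectors are identical, 0 iff the supports are disjoint; invariant to
#' uniform rescaling of either vector.
#'
#' @param p,q nonnegative suitability vectors over the same cell universe,
#'   each with positive sum.
#' @return Overlap in \[0, 1\].
#' @examples
#' schoener_D(c(1, 1, 0), c(0, 1, 1))  # 0.5
#' @export
schoener_D <- function(p, q) {
  if (length(p) != length(q)) {
    stop("'p' and 'q' must share the same cell universe", call. = FALSE)
  }
  if (any(p < 0) || any(q < 0)) stop("suitabilities must be nonnegative", call. = FALSE)
  sp <- sum(p); sq <- sum(q)
  if (sp <= 0 || sq <= 0) stop("zero-sum suitability vector", call. = FALSE)
  1 - 0.5 * sum(abs(p / sp - q / sq))
}

#' Geographic range overlap between two occurrence cell sets
#'
#' Default is the Szymkiewicz–Simpson coefficient, intersection over the
#' smaller range: `|A n B| / min(|A|, |B|)`.  It is 1 whenever one range is
#' nested in the other, which makes it robust to the large range-size
#' asymmetries typical of comparative range data; Jaccard
#' (`|A n B| / |A u B|`) is available as an alternative.
#'
#' @param occ1,occ2 nonempty vectors of occupied cell ids.
#' @param method `"simpson"` (default) or `"jaccard"`.
#' @return Overlap in \[0, 1\].
#' @examples
#' geographic_overlap(1:4, 3:8)  # 2 / min(4, 6) = 0.5
#' @export
geographic_overlap <- function(occ1, occ2, method = c("simpson", "jaccard")) {
  method <- match.arg(method)
  occ1 <- unique(occ1); occ2 <- unique(occ2)
  if (length(occ1) == 0L || length(occ2) == 0L) {
    stop("occurrence sets must be nonempty", call. = FALSE)
  }
  inter <- length(intersect(occ1, occ2))
  denom <- switch(method,
    simpson = min(length(occ1), length(occ2)),
    jaccard = length(union(occ1, occ2))
  )
  inter / denom
}

#' Within-clade competition index from pairwise overlaps
#'
#' Takes one row per within-clade species pair, carrying the pair's niche
#' overlap (Schoener's D) and geographic overlap.  Each overlap is min–max
#' rescaled to \[0, 1\] across *all* pairs of *all* clades (one common scale,
#' keeping clade scores comparable), the per-pair index is the product of the
#' two rescaled overlaps, and the clade-level competition score is the mean
#' of its pairs' indices.  By construction a pair with either rescaled
#' overlap 0 scores 0, and a pair maximal in both (same potential niche, same
#' realized range) scores 1.  If an overlap has zero range across pairs it is
#' passed through unscaled with a warning.
#'
#' @param pairs data.frame with columns `clade_id`, `niche_overlap`,
#'   `geo_overlap` (both in \[0, 1\]); one row per within-clade species pair.
#' @return List with `pairs` (input plus `index` column) and `clades`
#'   (data.frame `clade_id`, `b` — the mean index, in \[0, 1\]).
#' @export
competition_index <- function(pairs) {
  need <- c("clade_id", "niche_overlap", "geo_overlap")
  if (!all(need %in% names(pairs))) {
    stop("'pairs' needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(pairs) < 1L) stop("at least one species pair is required", call. = FALSE)
  ov <- as.matrix(pairs[, c("niche_overlap", "geo_overlap")])
  if (any(ov < 0) || any(ov > 1)) stop("overlaps must lie in [0, 1]", call. = FALSE)

  rescale01 <- function(x, what) {
    r <- range(x)
    if (diff(r) == 0) {
      warning("zero range in ", what, " across pairs; passing through unscaled",
              call. = FALSE)
      x
    } else (x - r[1]) / diff(r)
  }
  pairs$index <- rescale01(ov[, 1L], "niche overlap") *
    rescale01(ov[, 2L], "geographic overlap")
  b <- tapply(pairs$index, pairs$clade_id, mean)
  clades <- data.frame(clade_id = names(b), b = as.numeric(b),
                       stringsAsFactors = FALSE, row.names = NULL)
  list(pairs = pairs, clades = clades)
}

#' Pairwise overlaps for every within-clade species pair
#'
#' Convenience builder for [competition_index()]: enumerates all unordered
#' species pairs within each multispecies clade and computes Schoener's D on
#' the suitability grid and geographic overlap on the occurrence sets.
#'
#' @param grid a [suitability_grid()].
#' @param occ a named list of occupied cell ids per species.
#' @param clades a [delimit_clades()] result.
#' @param method geographic overlap variant, see [geographic_overlap()].
#' @return data.frame `clade_id`, `sp1`, `sp2`, `niche_overlap`, `geo_overlap`.
#' @export
clade_pair_overlaps <- function(grid, occ, clades, method = "simpson") {
  stopifnot(inherits(clades, "clade_set"))
  out <- list()
  for (cid in clades$table$clade_id[clades$table$n_species > 1L]) {
    sp <- clades$members[[cid]]
    miss <- setdiff(sp, rownames(grid))
    if (length(miss)) {
      stop("species missing from grid: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    idx <- utils::combn(sp, 2L)
    for (k in seq_len(ncol(idx))) {
      s1 <- idx[1L, k]; s2 <- idx[2L, k]
      out[[length(out) + 1L]] <- data.frame(
        clade_id = cid, sp1 = s1, sp2 = s2,
        niche_overlap = schoener_D(grid[s1, ], grid[s2, ]),
        geo_overlap = geographic_overlap(occ[[s1]], occ[[s2]], method = method),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
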