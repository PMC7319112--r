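#' Suitability grids
#'
#' A suitability grid stores, for every species, a suitability value in
#' \[0, 1\] over a shared universe of grid cells.  Internally it is a numeric
#' matrix with species as rows and cell ids as column names; every species
#' must have at least one nonzero cell.
#'
#' @param x numeric matrix, species x cells, values in \[0, 1\], with species
#'   rownames and cell-id colnames.
#' @return The validated matrix with class `suitability_grid` prepended.
#' @export
suitability_grid <- function(x) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("grid needs species rownames and cell-id colnames", call. = FALSE)
  }
  if (any(x < 0) || any(x > 1)) stop("suitabilities must lie in [0, 1]", call. = FALSE)
  if (any(rowSums(x) <= 0)) {
    stop("every species needs at least one nonzero cell", call. = FALSE)
  }
  class(x) <- c("suitability_grid", class(x))
  x
}

#' Rarefied suitable-area size of a clade
#'
#' The raw arena size of a clade is the number of grid cells in which at
#' least one member species is suitable (suitability >= `threshold`).  Raw
#' counts grow with species richness, so clades are rarefied to a common
#' richness: each replicate draws `rarefy_to` member species without
#' replacement, counts the union of their suitable cells, and the replicate
#' counts are averaged.  With `rarefy_to = length(members)` the result is the
#' deterministic union count.
#'
#' @param grid a [suitability_grid()] (or plain species x cells matrix).
#' @param members nonempty character vector of member species.
#' @param threshold suitability cutoff for counting a cell as suitable;
#'   binary grids pass through unchanged at the default 0.5.
#' @param rarefy_to species count to rarefy to, `<= length(members)`.
#' @param reps number of rarefaction replicates (ignored when no subsampling
#'   happens).
#' @param seed optional integer seed for the rarefaction draws; the caller's
#'   RNG state is restored afterwards.
#' @return Mean suitable-cell count over replicates (possibly fractional).
#' @examples
#' g <- suitability_grid(rbind(A = c(1, 1, 0), B = c(0, 1, 1)))
#' colnames(g) <- as.character(1:3)
#' clade_area(g, c("A", "B"), rarefy_to = 2)  # union: 3 cells
#' @export
clade_area <- function(grid, members, threshold = 0.5,
                       rarefy_to = length(members), reps = 100, seed = NULL) {
  if (length(members) == 0L) stop("'members' must be nonempty", call. = FALSE)
  miss <- setdiff(members, rownames(grid))
  if (length(miss)) {
    stop("species missing from grid: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(rarefy_to >= 1L, rarefy_to <= length(members), reps >= 1L)
  suit <- unclass(grid)[members, , drop = FALSE] >= threshold

  if (rarefy_to == length(members)) {
    return(sum(colSums(suit) > 0L))
  }
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  counts <- vapply(seq_len(reps), function(i) {
    draw <- sample(length(members), rarefy_to)
    sum(colSums(suit[draw, , drop = FALSE]) > 0L)
  }, 1)
  mean(counts)
}
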