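#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the generator with the package's default study
#' conditions: 100 extant species from a birth-death process (speciation
#' 0.1 /Ma, extinction 0.05 /Ma), a time slice chosen to delimit about 30
#' clades, 11 continuous niche traits evolving by Brownian motion at unit
#' rate, a 50 x 40 grid (2,000 cells) of suitability surfaces, and a
#' clade-level response with standardized effects mirroring the conifer case
#' study (no area effect, a strong negative competition effect, a weak
#' positive niche-rate effect).  When `sigma2` is `NULL` the residual
#' variance is set to `1 - sum(beta[-intercept]^2)` so the generated response
#' has (expected) unit variance and the `beta` values are directly
#' standardized effects.
#'
#' @param seed integer seed; all generator randomness flows through it.
#' @param n_species number of extant tips.
#' @param birth,death speciation and extinction rates per lineage per Ma.
#' @param cutoff stem-age slice in Ma, or `NULL` to place the slice where the
#'   tree has `n_clades_target` lineages.
#' @param n_clades_target target number of clades when `cutoff` is `NULL`.
#' @param n_traits number of continuous traits.
#' @param trait_rates per-trait Brownian rates (recycled to `n_traits`).
#' @param grid_nx,grid_ny grid dimensions (cells = `grid_nx * grid_ny`).
#' @param niche_width Gaussian niche breadth in environmental units.
#' @param niche_signal Brownian signal in niche centers (TRUE: centers evolve
#'   on the tree, so close relatives overlap more).
#' @param occ_prob occupancy probability multiplier on suitability.
#' @param beta named standardized effects: `intercept`, `a` (on ln area),
#'   `b` (competition), `c` (on ln niche rate).
#' @param beta_bc optional two-way interaction effect of `b` and `c`.
#' @param sigma2 residual variance of the clade response (`NULL`: complement
#'   to unit total variance).
#' @param eps,threshold,reps pipeline parameters recorded alongside.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_species = 100, birth = 0.1, death = 0.05,
                       cutoff = NULL, n_clades_target = 30, n_traits = 11,
                       trait_rates = 1, grid_nx = 50, grid_ny = 40,
                       niche_width = 0.25, niche_signal = TRUE,
                       occ_prob = 0.8,
                       beta = c(intercept = 0.6, a = 0, b = -0.58, c = 0.17),
                       beta_bc = 0, sigma2 = NULL,
                       eps = 0.9, threshold = 0.5, reps = 100) {
  stopifnot(birth > death, death >= 0, n_species >= 2, n_traits >= 1,
            grid_nx >= 1, grid_ny >= 1, niche_width > 0,
            all(is.finite(beta)), length(beta) == 4)
  if (is.null(names(beta))) names(beta) <- c("intercept", "a", "b", "c")
  if (is.null(sigma2)) sigma2 <- max(1 - sum(beta[-1]^2) - beta_bc^2, 0.05)
  structure(
    list(seed = seed, n_species = n_species, birth = birth, death = death,
         cutoff = cutoff, n_clades_target = n_clades_target,
         n_traits = n_traits,
         trait_rates = rep_len(trait_rates, n_traits),
         grid_nx = grid_nx, grid_ny = grid_ny, niche_width = niche_width,
         niche_signal = niche_signal, occ_prob = occ_prob,
         beta = beta, beta_bc = beta_bc, sigma2 = sigma2,
         eps = eps, threshold = threshold, reps = reps),
    class = "sim_config"
  )
}

#' Simulate a dated birth-death tree with a fixed number of extant tips
#'
#' Wraps the constant-rate birth-death simulator conditioned on the number
#' of extant species ([ape::rphylo()]), returning the reconstructed
#' (extant-only) ultrametric tree as a [dated_tree()] with tips relabeled
#' `s001, s002, ...`.  Identical seed, identical tree.
#'
#' @param n_species number of extant tips (>= 2).
#' @param birth,death rates per lineage per Ma; `birth > death >= 0`.
#' @param seed optional integer seed.
#' @return A [dated_tree()].
#' @export
simulate_bd_tree <- function(n_species, birth, death = 0, seed = NULL) {
  stopifnot(n_species >= 2, birth > death, death >= 0)
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rphylo(n_species, birth = birth, death = death)
  phy$tip.label <- sprintf("s%03d", seq_len(n_species))
  dated_tree(phy)
}

# symmetric PSD square root via eigendecomposition (tolerates zero rates)
psd_sqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' Simulate multivariate Brownian traits on a tree
#'
#' Draws tip values from the matrix-normal distribution of multivariate
#' Brownian motion: `vec(X) ~ N(vec(1 root'), R (x) C)` with `C` the tree's
#' Brownian covariance and `R` the trait rate matrix.  A zero rate matrix
#' returns the root state for every species.
#'
#' @param tree a [dated_tree()] or `"phylo"`.
#' @param rate_matrix trait rate matrix (k x k, PSD) or a vector of per-trait
#'   rates (treated as independent traits).
#' @param root root state per trait (recycled; default 0).
#' @param seed optional integer seed.
#' @return species x traits matrix with tip labels as rownames and
#'   `trait_01 ...` colnames.
#' @export
simulate_bm_traits <- function(tree, rate_matrix, root = 0, seed = NULL) {
  phy <- as_phylo(tree)
  if (is.vector(rate_matrix)) rate_matrix <- diag(rate_matrix, length(rate_matrix))
  k <- ncol(rate_matrix)
  n <- length(phy$tip.label)
  root <- rep_len(root, k)
  if (!is.null(seed)) set.seed(seed)
  C <- ape::vcv.phylo(phy)
  A <- t(chol(C))                      # lower, A A' = C
  B <- psd_sqrt(rate_matrix)           # symmetric, B B = R
  Z <- matrix(stats::rnorm(n * k), n, k)
  X <- sweep(A %*% Z %*% B, 2, root, `+`)
  dimnames(X) <- list(rownames(C), sprintf("trait_%02d", seq_len(k)))
  X[phy$tip.label, , drop = FALSE]
}

#' Gaussian suitability of one species over an environmental surface
#'
#' `exp(-||env - center||^2 / (2 width^2))` per cell: the unimodal niche
#' kernel used by [simulate_grids()].  Exposed so overlap properties (e.g.
#' Schoener's D falling monotonically with niche-center distance) can be
#' explored directly.
#'
#' @param env cells x 2 matrix of environmental coordinates.
#' @param center length-2 niche center.
#' @param width niche breadth (> 0).
#' @return Suitability vector in (0, 1\].
#' @export
gaussian_suitability <- function(env, center, width) {
  d2 <- rowSums(sweep(env, 2, center)^2)
  exp(-d2 / (2 * width^2))
}

#' Simulate suitability grids and occurrence sets
#'
#' Builds a synthetic environmental surface (a two-dimensional gradient
#' warped by smooth sinusoidal noise) over a `grid_nx x grid_ny` cell
#' lattice, gives each species a Gaussian suitability surface around its
#' niche center, and samples occurrences as Bernoulli draws with probability
#' `occ_prob * suitability` (every species is guaranteed its best cell).
#' Niche centers either evolve by Brownian motion on the tree (default, so
#' phylogenetic relatedness translates into niche overlap) or are drawn
#' independently.  Pairwise Schoener's D decreases monotonically with the
#' distance between niche centers.
#'
#' @param tree a [dated_tree()] supplying the species set (and, with
#'   `niche_signal`, the covariance of the niche centers).
#' @param config a [sim_config()].
#' @param seed optional integer seed (defaults to `config$seed + 1`).
#' @return List with `grid` (a [suitability_grid()]), `occ` (named list of
#'   occupied cell ids), `env` (cells x 2 environmental coordinates) and
#'   `centers` (species x 2 niche centers).
#' @export
simulate_grids <- function(tree, config = sim_config(), seed = NULL) {
  phy <- as_phylo(tree)
  species <- phy$tip.label
  if (is.null(seed)) seed <- config$seed + 1L
  set.seed(seed)
  nx <- config$grid_nx; ny <- config$grid_ny
  xy <- expand.grid(x = seq(0, 1, length.out = nx),
                    y = seq(0, 1, length.out = ny))
  env <- cbind(e1 = xy$x + 0.10 * sin(2 * pi * 2 * xy$y),
               e2 = xy$y + 0.10 * sin(2 * pi * 2 * xy$x))
  cells <- sprintf("c%04d", seq_len(nrow(env)))
  rownames(env) <- cells

  if (isTRUE(config$niche_signal)) {
    raw <- simulate_bm_traits(phy, diag(2))[species, , drop = FALSE]
    centers <- apply(raw, 2, function(v) {
      if (diff(range(v)) == 0) rep(0.5, length(v))
      else 0.1 + 0.8 * (v - min(v)) / diff(range(v))
    })
  } else {
    centers <- cbind(stats::runif(length(species), 0.1, 0.9),
                     stats::runif(length(species), 0.1, 0.9))
  }
  rownames(centers) <- species
  colnames(centers) <- c("e1", "e2")

  grid <- t(vapply(species, function(sp)
    gaussian_suitability(env, centers[sp, ], config$niche_width),
    numeric(nrow(env))))
  colnames(grid) <- cells
  grid <- suitability_grid(grid)

  occ <- lapply(species, function(sp) {
    p <- pmin(config$occ_prob * grid[sp, ], 1)
    hit <- cells[stats::runif(length(p)) < p]
    if (length(hit) == 0L) hit <- cells[which.max(grid[sp, ])]
    hit
  })
  names(occ) <- species
  list(grid = grid, occ = occ, env = env, centers = centers)
}

#' Simulate the clade-level response with known effects
#'
#' Given a clade table with components `a`, `b`, `c`, generates the response
#' `d = b0 + b_a z(ln a) + b_b z(b) + b_c z(ln c) [+ b_bc z(b) z(c)] + e`
#' with `e ~ N(0, sigma2 * C / max(diag C))` — phylogenetically correlated
#' residuals whose tip variance is `sigma2`.  The generating effects are
#' recorded in the `"truth"` attribute for recovery experiments.
#'
#' @param components data.frame with `clade_id`, `a`, `b`, `c` (a and c
#'   strictly positive).
#' @param C clade-level phylogenetic covariance (rows matched by `clade_id`).
#' @param beta named effects `intercept`, `a`, `b`, `c` on the standardized
#'   scale.
#' @param beta_bc interaction effect (default 0).
#' @param sigma2 residual variance at the tips.
#' @param seed optional integer seed.
#' @return `components` with a `d` column and a `"truth"` attribute.
#' @export
simulate_components_response <- function(components, C,
                                         beta = c(intercept = 0.6, a = 0,
                                                  b = -0.58, c = 0.17),
                                         beta_bc = 0, sigma2 = 0.6,
                                         seed = NULL) {
  stopifnot(all(c("clade_id", "a", "b", "c") %in% names(components)),
            all(components$a > 0), all(components$c > 0))
  C <- C[components$clade_id, components$clade_id]
  if (!is.null(seed)) set.seed(seed)
  za <- zscore(log(components$a))
  zb <- zscore(components$b)
  zc <- zscore(log(components$c))
  Cn <- C / max(diag(C))
  eps <- sqrt(sigma2) * drop(t(chol(Cn)) %*% stats::rnorm(nrow(C)))
  components$d <- beta[["intercept"]] + beta[["a"]] * za + beta[["b"]] * zb +
    beta[["c"]] * zc + beta_bc * zb * zc + eps
  attr(components, "truth") <- list(beta = beta, beta_bc = beta_bc,
                                    sigma2 = sigma2, seed = seed)
  components
}

#' Simulate a complete synthetic dataset
#'
#' Runs every generator in sequence under one seed: birth-death tree, clade
#' delimitation (slice at `config$cutoff`, or placed where the tree has
#' `n_clades_target` lineages), Brownian traits, suitability grids and
#' occurrences, the clade components `a`, `b`, `c` computed by the package's
#' own estimators, and the response `d` drawn from the known-effects model on
#' the clade backbone tree.  The generating parameters are returned in
#' `$truth` (and written as a `truth.json` sidecar by [write_eva_dataset()]).
#'
#' @param config a [sim_config()].
#' @return List of class `eva_dataset`: `tree`, `clades`, `backbone`,
#'   `traits`, `grid`, `occ`, `components` (multispecies clades, with
#'   simulated `d`), `config`, `truth`.
#' @export
simulate_eva_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  tree <- simulate_bd_tree(config$n_species, config$birth, config$death,
                           seed = config$seed)
  cutoff <- config$cutoff
  if (is.null(cutoff)) {
    bt <- sort(ape::branching.times(tree$phy), decreasing = TRUE)
    k <- min(config$n_clades_target, length(bt))
    cutoff <- if (k < 2) bt[1] * 0.5 else (bt[k - 1] + bt[k]) / 2
  }
  clades <- delimit_clades(tree, cutoff)
  backbone <- clade_backbone_tree(tree, clades)
  traits <- simulate_bm_traits(tree, diag(config$trait_rates),
                               seed = config$seed + 2L)
  layers <- simulate_grids(tree, config, seed = config$seed + 1L)

  tab <- clades$table[clades$table$n_species > 1L, , drop = FALSE]
  if (nrow(tab) < 3L) {
    stop("fewer than 3 multispecies clades generated; raise n_species or ",
         "lower the cutoff", call. = FALSE)
  }
  rarefy_to <- min(tab$n_species)
  tab$a <- vapply(tab$clade_id, function(cid)
    clade_area(layers$grid, clades$members[[cid]],
               threshold = config$threshold, rarefy_to = rarefy_to,
               reps = config$reps, seed = config$seed + 3L), 1)
  comp <- competition_index(clade_pair_overlaps(layers$grid, layers$occ, clades))
  tab$b <- comp$clades$b[match(tab$clade_id, comp$clades$clade_id)]
  cn <- clade_niche_rate(traits, tree, clades)
  tab$c <- cn$c[match(tab$clade_id, cn$clade_id)]

  Cb <- phylo_vcv(backbone, labels = tab$clade_id)
  tab <- simulate_components_response(tab, Cb, beta = config$beta,
                                      beta_bc = config$beta_bc,
                                      sigma2 = config$sigma2,
                                      seed = config$seed + 4L)
  rownames(tab) <- NULL
  truth <- list(beta = as.list(config$beta), beta_bc = config$beta_bc,
                sigma2 = config$sigma2, cutoff = cutoff, seed = config$seed)
  structure(
    list(tree = tree, clades = clades, backbone = backbone, traits = traits,
         grid = layers$grid, occ = layers$occ, components = tab,
         config = config, truth = truth),
    class = "eva_dataset"
  )
}

#' @export
print.eva_dataset <- function(x, ...) {
  cat("Synthetic dataset:", length(x$tree$phy$tip.label), "species,",
      nrow(x$clades$table), "clades (", nrow(x$components),
      "multispecies ), seed", x$config$seed, "\n")
  invisible(x)
}
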