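test_that("net diversification matches hand-computed values", {
  # values computed by hand from (1/t) * log(n(1-eps)+eps)
  expect_equal(net_diversification(1, 50, eps = 0.9), 0)
  expect_equal(net_diversification(10, 34, eps = 0.9), 0.01887805548, tolerance = 1e-9)
  expect_equal(net_diversification(10, 10, eps = 0), 0.2302585093, tolerance = 1e-9)
  expect_equal(net_diversification(2, 33.9, eps = 0.9), 0.002811509729, tolerance = 1e-9)
  expect_equal(net_diversification(52, 34, eps = 0.9), 0.05318496386, tolerance = 1e-9)
  expect_equal(net_diversification(3, 100, eps = 0), 0.01098612289, tolerance = 1e-9)
  expect_equal(net_diversification(5, 80, eps = 0.625), 0.01145363415, tolerance = 1e-9)

  expect_error(net_diversification(5, 0, 0.9), "positive")
  expect_error(net_diversification(5, 10, 1), "\\[0, 1\\)")
  expect_error(net_diversification(2.5, 10, 0), "integer")
})

test_that("net diversification is monotone in n, t and eps", {
  for (eps in c(0, 0.5, 0.9)) {
    r_n <- net_diversification(2:20, 30, eps)
    expect_true(all(diff(r_n) > 0))
    r_t <- net_diversification(10, seq(5, 100, by = 5), eps)
    expect_true(all(diff(r_t) < 0))
  }
  r_eps <- vapply(c(0, 0.25, 0.5, 0.75, 0.9), function(e)
    net_diversification(10, 30, e), 1)
  expect_true(all(diff(r_eps) < 0))
})

test_that("Schoener's D matches its definition and invariances", {
  expect_equal(schoener_D(c(2, 5, 1), c(2, 5, 1)), 1)
  expect_equal(schoener_D(c(1, 1, 0, 0), c(0, 0, 3, 2)), 0)
  expect_equal(schoener_D(c(0.5, 0.5, 0), c(0, 0.5, 0.5)), 0.5)

  set.seed(42)
  for (i in 1:20) {
    p <- stats::runif(30); q <- stats::runif(30)
    D <- schoener_D(p, q)
    expect_gte(D, 0); expect_lte(D, 1)
    expect_equal(D, schoener_D(q, p))                # symmetry
    expect_equal(D, schoener_D(3.7 * p, 0.2 * q))    # rescaling invariance
  }
  expect_error(schoener_D(c(0, 0), c(1, 1)), "zero-sum")
  expect_error(schoener_D(1:3, 1:4), "universe")
})

test_that("geographic overlap is intersection over the smaller range", {
  expect_equal(geographic_overlap(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(geographic_overlap(1:3, 7:9), 0)
  expect_equal(geographic_overlap(1:4, 3:8), 0.5)        # 2 / min(4, 6)
  expect_equal(geographic_overlap(1:2, 1:10), 1)         # nested range
  expect_equal(geographic_overlap(1:4, 3:8, method = "jaccard"), 0.25)
  expect_equal(geographic_overlap(1:4, 3:8),
               geographic_overlap(3:8, 1:4))
  expect_error(geographic_overlap(integer(0), 1:3), "nonempty")
})

test_that("competition index rescales globally, multiplies and averages", {
  pairs <- data.frame(
    clade_id = c("x", "x", "y"),
    niche_overlap = c(0.2, 0.8, 0.5),
    geo_overlap = c(0.1, 0.9, 0.9)
  )
  res <- competition_index(pairs)
  # rescaled niche: (0, 1, 0.5); rescaled geo: (0, 1, 1)
  expect_equal(res$pairs$index, c(0, 1, 0.5))
  expect_equal(res$clades$b[res$clades$clade_id == "x"], 0.5)
  expect_equal(res$clades$b[res$clades$clade_id == "y"], 0.5)
  expect_true(all(res$clades$b >= 0 & res$clades$b <= 1))

  # anchors: minimal pair scores 0; maximal-in-both pair scores 1
  expect_equal(min(res$pairs$index), 0)
  expect_equal(max(res$pairs$index), 1)

  # order invariance of clade scores
  res2 <- competition_index(pairs[c(3, 1, 2), ])
  expect_equal(res2$clades[order(res2$clades$clade_id), ],
               res$clades[order(res$clades$clade_id), ],
               ignore_attr = TRUE)

  # zero range in one overlap passes through unscaled, with a warning
  flat <- data.frame(clade_id = "x", niche_overlap = c(0.4, 0.4),
                     geo_overlap = c(0, 1))
  expect_warning(res3 <- competition_index(flat), "zero range")
  expect_equal(res3$pairs$index, c(0, 0.4))
})

test_that("clade area counts suitable-cell unions, rarefied by subsampling", {
  g <- toy_grid()
  # singleton and full-union cases are deterministic
  expect_equal(clade_area(g, "D", rarefy_to = 1), 3)
  expect_equal(clade_area(g, c("A", "B"), rarefy_to = 2), 3)
  expect_equal(clade_area(g, c("A", "B", "C", "D"), rarefy_to = 4), 5)

  # rarefy_to = 1 converges to the mean of the members' own counts
  est <- clade_area(g, c("A", "D"), rarefy_to = 1, reps = 4000, seed = 1)
  expect_equal(est, exact_rarefied_area(g, c("A", "D"), 1), tolerance = 0.05)

  # exact enumeration oracle for a 3-member clade at rarefy_to = 2
  est2 <- clade_area(g, c("A", "B", "D"), rarefy_to = 2, reps = 4000, seed = 2)
  expect_equal(est2, exact_rarefied_area(g, c("A", "B", "D"), 2),
               tolerance = 0.05)

  # unrarefied area is monotone nondecreasing as species are added
  a1 <- clade_area(g, c("A"))
  a2 <- clade_area(g, c("A", "C"))
  a3 <- clade_area(g, c("A", "C", "E"))
  expect_true(a1 <= a2 && a2 <= a3)

  expect_error(clade_area(g, c("A", "Z")), "missing from grid")
})

test_that("rarefaction draws are reproducible under a seed", {
  g <- toy_grid()
  a1 <- clade_area(g, c("A", "B", "C"), rarefy_to = 1, reps = 50, seed = 7)
  a2 <- clade_area(g, c("A", "B", "C"), rarefy_to = 1, reps = 50, seed = 7)
  expect_identical(a1, a2)
})

test_that("Brownian rate fitting matches closed forms", {
  # constant trait: rate exactly zero
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  fit <- bm_rate_matrix(cbind(x = c(A = 3, B = 3, C = 3)), tr)
  expect_equal(unname(fit$rates), 0)

  # star tree with unit depth: the ML variance about the mean (divisor n)
  st <- star_tree(8)
  set.seed(2)
  x <- cbind(x = stats::setNames(stats::rnorm(8), st$phy$tip.label))
  fit2 <- bm_rate_matrix(x, st)
  expect_equal(unname(fit2$rates), mean((x - mean(x))^2))
  expect_equal(unname(fit2$root), mean(x))
})

test_that("Brownian rates are recovered from simulated data", {
  set.seed(31)
  tr <- simulate_bd_tree(80, 0.1, 0.02)
  ests <- replicate(40, {
    x <- simulate_bm_traits(tr, rate_matrix = diag(2))
    bm_rate_matrix(x, tr)$rates
  })
  mc_se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 1), 3 * mc_se + 1 / 80)  # ML bias is order 1/n
})

test_that("clade niche rate sums subtree rates and max-scales across clades", {
  tr <- toy_tree()
  cs <- delimit_clades(tr, 10)
  cn <- clade_niche_rate(toy_traits(), tr, cs)
  # hand computation: global z-scoring, then a two-tip clade with crown age T
  # and tip difference dz has summed rate dz^2 / (4 T)
  expect_equal(cn$c_raw[cn$clade_id == "clade_03"], 0)
  expect_equal(max(cn$c), 1)
  expect_equal(cn$c[cn$clade_id == "clade_01"], 32 / 45, tolerance = 1e-9)
  expect_equal(cn$c[cn$clade_id == "clade_02"], 1)

  # dual route: ratio of direct bm_rate_matrix fits on the crown subtrees
  z <- scale(toy_traits())
  r1 <- sum(bm_rate_matrix(z[c("A", "B"), , drop = FALSE], tr)$rates)
  r2 <- sum(bm_rate_matrix(z[c("C", "D"), , drop = FALSE], tr)$rates)
  expect_equal(cn$c[cn$clade_id == "clade_01"], r1 / r2, tolerance = 1e-12)
})
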