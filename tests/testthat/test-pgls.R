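# hand-coded multivariate normal log-density; the brute-force likelihood
# oracle used to check the GLS profile likelihood independently
dmvnorm_log <- function(y, mu, Sigma) {
  n <- length(y)
  ev <- eigen(Sigma, symmetric = TRUE)
  logdet <- sum(log(ev$values))
  q <- drop(crossprod(ev$vectors, y - mu))
  -0.5 * (n * log(2 * pi) + logdet + sum(q^2 / ev$values))
}

test_that("formula parsing handles transforms and interactions", {
  spec <- parse_eva_formula("d ~ ln(a) + b + ln(c) + b:c")
  expect_equal(spec$response$name, "d")
  expect_equal(vapply(spec$terms, `[[`, "", "name"), c("a", "b", "c"))
  expect_equal(vapply(spec$terms, `[[`, "", "transform"),
               c("ln", "identity", "ln"))
  expect_equal(spec$interactions[[1]], c("b", "c"))

  expect_error(parse_eva_formula("d ~ a + b:z"), "undeclared")
  expect_error(parse_eva_formula("d + a"), "~")
})

test_that("design building transforms then standardizes to unit SD", {
  comp <- data.frame(clade_id = paste0("k", 1:3),
                     d = c(1, 2, 4), a = c(1, exp(1), exp(2)))
  des <- build_design(comp, "d ~ ln(a)")
  # ln column (1, e, e^2) -> equally spaced -> (-1.2247, 0, 1.2247)
  expect_equal(unname(des$X[, "ln(a)"]), c(-1, 0, 1) * sqrt(1.5),
               tolerance = 1e-9)
  expect_equal(mean(des$X[, "ln(a)"]), 0)
  expect_equal(colnames(des$X), c("ln(a)", "(Intercept)"))

  # predictor equal to the response: standardized slope exactly 1
  comp2 <- data.frame(clade_id = paste0("k", 1:6),
                      d = c(3, 1, 4, 1, 5, 9), b = c(3, 1, 4, 1, 5, 9))
  des2 <- build_design(comp2, "d ~ b")
  fit <- pgls_fit(des2$y, des2$X, diag(6))
  expect_equal(unname(fit$coefficients["b"]), 1, tolerance = 1e-10)

  # case-study-shaped model: three standardized mains plus intercept
  comp3 <- data.frame(clade_id = paste0("k", 1:5), d = stats::rnorm(5),
                      a = c(10, 20, 5, 80, 40), b = stats::runif(5),
                      c = c(0.1, 0.5, 1, 0.2, 0.7))
  des3 <- build_design(comp3, "d ~ ln(a) + b + ln(c)")
  expect_equal(colnames(des3$X), c("ln(a)", "b", "ln(c)", "(Intercept)"))
  expect_equal(unname(colMeans(des3$X[, 1:3])), rep(0, 3), tolerance = 1e-12)

  # errors name the offender
  comp3$a[2] <- -1
  expect_error(build_design(comp3, "d ~ ln(a)"), "k2")
  comp3$a <- 7
  expect_error(build_design(comp3, "d ~ a"), "zero-variance")
})

test_that("GLS with identity covariance equals ordinary least squares", {
  set.seed(14)
  for (i in 1:5) {
    n <- 25
    X <- cbind(x1 = stats::rnorm(n), x2 = stats::rnorm(n), `(Intercept)` = 1)
    y <- drop(X %*% c(0.5, -1, 2)) + stats::rnorm(n)
    fit <- pgls_fit(y, X, diag(n))
    ls <- summary(stats::lm(y ~ x1 + x2, data = data.frame(X)))
    expect_equal(unname(fit$coefficients[c("(Intercept)", "x1", "x2")]),
                 unname(ls$coefficients[, 1]), tolerance = 1e-8)
    expect_equal(unname(fit$se[c("(Intercept)", "x1", "x2")]),
                 unname(ls$coefficients[, 2]), tolerance = 1e-8)
    expect_equal(unname(fit$p[c("(Intercept)", "x1", "x2")]),
                 unname(ls$coefficients[, 4]), tolerance = 1e-8)
  }
})

test_that("GLS matches an independent phylogenetic regression fit", {
  suppressWarnings({
    set.seed(3)
    tr <- simulate_bd_tree(30, 0.1, 0.03)
    phy <- tr$phy
    x1 <- stats::rnorm(30); x2 <- stats::rnorm(30)
    C <- phylo_vcv(tr)
    y <- 1 + 0.5 * x1 - 0.3 * x2 +
      drop(t(chol(C / max(diag(C)))) %*% stats::rnorm(30))
    df <- data.frame(y, x1, x2, row.names = phy$tip.label)
    g <- nlme::gls(y ~ x1 + x2, data = df,
                   correlation = ape::corBrownian(phy = phy, form = ~1),
                   method = "ML")
    X <- cbind(x1 = x1, x2 = x2, `(Intercept)` = 1)
    rownames(X) <- phy$tip.label
    f <- pgls_fit(stats::setNames(y, phy$tip.label), X, C)
  })
  expect_equal(unname(f$coefficients[c("(Intercept)", "x1", "x2")]),
               unname(stats::coef(g)), tolerance = 1e-7)
  expect_equal(unname(f$se[c("(Intercept)", "x1", "x2")]),
               unname(sqrt(diag(stats::vcov(g)))), tolerance = 1e-6)
  expect_equal(f$logLik, as.numeric(stats::logLik(g)), tolerance = 1e-7)
})

test_that("exact linear responses are fit without residual variance", {
  set.seed(8)
  X <- cbind(x = stats::rnorm(10), `(Intercept)` = 1)
  beta <- c(-0.6, 2)
  C <- phylo_vcv(simulate_bd_tree(10, 0.1, 0))
  fit <- pgls_fit(drop(X %*% beta), X, C)
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-8)
  expect_lt(fit$sigma2, 1e-16)
})

test_that("estimates are invariant to covariance scale and row permutation", {
  set.seed(21)
  tr <- simulate_bd_tree(20, 0.1, 0.04)
  C <- phylo_vcv(tr)
  X <- cbind(x = stats::rnorm(20), `(Intercept)` = 1)
  rownames(X) <- rownames(C)
  y <- stats::setNames(drop(X %*% c(1, 0)) + stats::rnorm(20), rownames(C))
  f1 <- pgls_fit(y, X, C)
  f2 <- pgls_fit(y, X, 5 * C)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
  expect_equal(f1$sigma2, 5 * f2$sigma2, tolerance = 1e-9)
  expect_equal(f1$t, f2$t, tolerance = 1e-9)

  perm <- sample(20)
  f3 <- pgls_fit(y[perm], X[perm, ], C[perm, perm])
  expect_equal(f1$coefficients, f3$coefficients, tolerance = 1e-9)
  expect_equal(f1$logLik, f3$logLik, tolerance = 1e-9)
})

test_that("collinear designs raise an informative error", {
  X <- cbind(x1 = 1:8, x2 = 2 * (1:8), `(Intercept)` = 1)
  expect_error(pgls_fit(stats::rnorm(8), X, diag(8)), "collinear")
})

test_that("likelihood R2 matches a brute-force likelihood evaluation", {
  # tiny fixed dataset; the oracle maximizes the hand-coded density by optim
  y <- c(0.2, -1.1, 0.6, 1.4, -0.3)
  x <- c(1, 2, 3, 4, 5)
  tr <- parse_newick("(((A:1,B:1):1,C:2):1,(D:2,E:2):1);")
  C <- phylo_vcv(tr)
  X <- cbind(x = x, `(Intercept)` = 1)
  rownames(X) <- names(y) <- rownames(C)

  brute_ml <- function(Xm) {
    nll <- function(par) {
      k <- ncol(Xm)
      -dmvnorm_log(y, drop(Xm %*% par[seq_len(k)]), exp(par[k + 1]) * C)
    }
    opt <- stats::optim(rep(0, ncol(Xm) + 1), nll, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    -opt$value
  }
  full <- pgls_fit(y, X, C)
  null <- pgls_fit(y, X[, 2, drop = FALSE], C)
  expect_equal(full$logLik, brute_ml(X), tolerance = 1e-5)
  expect_equal(null$logLik, brute_ml(X[, 2, drop = FALSE]), tolerance = 1e-5)

  r2 <- r2_lik(full, null)
  r2_oracle <- 1 - exp(-2 * (brute_ml(X) - brute_ml(X[, 2, drop = FALSE])) / 5)
  expect_equal(r2$r2, r2_oracle, tolerance = 1e-4)
  expect_equal(r2$adj_r2, 1 - (1 - r2$r2) * 4 / 3, tolerance = 1e-9)

  # intercept-only "full" model: R2 exactly 0
  expect_equal(r2_lik(null, null)$r2, 0)
})

test_that("partial r2 is bounded by the full-model R2 and well defined", {
  set.seed(100)
  ds <- simulate_eva_dataset(sim_config(seed = 100, n_species = 80))
  res <- eva_pgls(ds$components, ds$backbone)
  pr2 <- res$table$partial_r2[!is.na(res$table$partial_r2)]
  expect_true(all(pr2 >= 0 & pr2 <= 1))
  expect_true(all(pr2 <= res$r2 + 1e-8))
  expect_true(res$r2 >= 0 && res$r2 < 1)
  expect_gt(res$adj_r2, -1)

  # dropping a predictor never increases the maximized likelihood
  design <- build_design(ds$components, "d ~ ln(a) + b + ln(c)")
  C <- phylo_vcv(ds$backbone, labels = rownames(design$X))
  full <- pgls_fit(design$y, design$X, C)
  for (drop_col in c("ln(a)", "b", "ln(c)")) {
    keep <- setdiff(colnames(design$X), drop_col)
    red <- pgls_fit(design$y, design$X[, keep], C)
    expect_lte(red$logLik, full$logLik + 1e-8)
    expect_error(partial_r2(red, full), "nested")
  }
})

test_that("Pagel's lambda profiling tracks the residual structure", {
  set.seed(55)
  tr <- simulate_bd_tree(60, 0.1, 0.02)
  C <- phylo_vcv(tr)
  X <- cbind(`(Intercept)` = rep(1, 60))
  rownames(X) <- rownames(C)
  # iid residuals: lambda should collapse toward 0
  y_iid <- stats::setNames(stats::rnorm(60), rownames(C))
  f0 <- pgls_fit(y_iid, X, C, estimate_lambda = TRUE)
  expect_lt(f0$lambda, 0.3)
  # Brownian residuals: lambda should stay high
  y_bm <- stats::setNames(drop(t(chol(C)) %*% stats::rnorm(60)), rownames(C))
  f1 <- pgls_fit(y_bm, X, C, estimate_lambda = TRUE)
  expect_gt(f1$lambda, 0.7)
  # lambda = 0 yields the diagonal-covariance (OLS) fit
  fd <- pgls_fit(y_iid, X, phylo_vcv(tr, lambda = 0))
  expect_equal(unname(fd$coefficients), mean(y_iid), tolerance = 1e-9)
})

test_that("interaction terms enter as products of standardized mains", {
  set.seed(77)
  comp <- data.frame(clade_id = paste0("k", 1:30),
                     a = exp(stats::rnorm(30)), b = stats::runif(30),
                     c = stats::runif(30, 0.1, 1), d = stats::rnorm(30))
  des <- build_design(comp, "d ~ ln(a) + b + ln(c) + b:c")
  expect_true("b:c" %in% colnames(des$X))
  expect_equal(des$X[, "b:c"], des$X[, "b"] * des$X[, "ln(c)"],
               tolerance = 1e-12)
  # the interaction model still fits and reports a finite likelihood
  C <- diag(30)
  dimnames(C) <- list(comp$clade_id, comp$clade_id)
  fit <- pgls_fit(des$y, des$X, C)
  expect_true(is.finite(fit$logLik))
})
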