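#' Parse a component-model formula
#'
#' Accepts the compact formula syntax used throughout the package, e.g.
#' `"d ~ ln(a) + b + ln(c)"` or `"d ~ ln(a) + b + ln(c) + b:c"`.  Each term
#' is a component column, optionally wrapped in `ln()` for a natural-log
#' transform; `x:y` denotes a two-way interaction of declared main effects.
#'
#' @param text formula string.
#' @return An object of class `model_spec`: list with `response` (name,
#'   transform), `terms` (list of main effects, each name + transform) and
#'   `interactions` (list of character pairs).
#' @export
parse_eva_formula <- function(text) {
  parts <- strsplit(text, "~", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("formula must contain exactly one '~'", call. = FALSE)
  parse_term <- function(s) {
    s <- trimws(s)
    m <- regmatches(s, regexec("^ln\\(\\s*([^)]+?)\\s*\\)$", s))[[1]]
    if (length(m) == 2L) list(name = m[2], transform = "ln")
    else if (grepl("^[A-Za-z_.][A-Za-z0-9_.]*$", s)) list(name = s, transform = "identity")
    else stop("cannot parse term '", s, "'", call. = FALSE)
  }
  response <- parse_term(parts[1])
  rhs <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
  rhs <- rhs[nzchar(rhs)]
  is_int <- grepl(":", rhs, fixed = TRUE)
  terms <- lapply(rhs[!is_int], parse_term)
  interactions <- lapply(rhs[is_int], function(s) {
    v <- trimws(strsplit(s, ":", fixed = TRUE)[[1]])
    if (length(v) != 2L) stop("only two-way interactions are supported", call. = FALSE)
    v
  })
  main_names <- vapply(terms, `[[`, "", "name")
  for (ia in interactions) {
    if (!all(ia %in% main_names)) {
      stop("interaction ", paste(ia, collapse = ":"),
           " references undeclared main effects", call. = FALSE)
    }
  }
  structure(list(response = response, terms = terms,
                 interactions = interactions, text = text),
            class = "model_spec")
}

# z-score with population SD (divisor n); matches the package's standardized-
# coefficient convention.  Slopes are invariant to the n vs n-1 choice.
zscore <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("zero-variance column cannot be standardized", call. = FALSE)
  (x - mean(x)) / s
}

#' Build a standardized design matrix from a component table
#'
#' Applies the per-term transforms of the model spec, then z-standardizes the
#' response and every non-intercept column (mean 0, SD 1, population SD) so
#' the fitted coefficients are standardized slopes.  Interaction columns are
#' products of the standardized main effects (not re-standardized), and an
#' intercept column is appended.
#'
#' @param components data.frame with one row per clade, containing every
#'   column the model references (typically `d`, `a`, `b`, `c`) and a
#'   `clade_id` column used as row labels.
#' @param spec a [parse_eva_formula()] result or formula string.
#' @return List with `y` (standardized response), `X` (design matrix, row
#'   names = clade ids), and `spec`.
#' @export
build_design <- function(components, spec) {
  if (is.character(spec)) spec <- parse_eva_formula(spec)
  stopifnot(inherits(spec, "model_spec"))
  labels <- if ("clade_id" %in% names(components)) components$clade_id
            else rownames(components)

  get_col <- function(term) {
    if (!term$name %in% names(components)) {
      stop("component column '", term$name, "' not found", call. = FALSE)
    }
    x <- components[[term$name]]
    if (anyNA(x)) stop("missing values in column '", term$name, "'", call. = FALSE)
    if (term$transform == "ln") {
      if (any(x <= 0)) {
        bad <- labels[x <= 0]
        stop("ln(", term$name, ") undefined: nonpositive value for ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      x <- log(x)
    }
    x
  }

  y <- zscore(get_col(spec$response))
  main <- lapply(spec$terms, get_col)
  names(main) <- vapply(spec$terms, function(t)
    if (t$transform == "ln") paste0("ln(", t$name, ")") else t$name, "")
  Xcols <- lapply(main, zscore)
  std_by_name <- stats::setNames(Xcols, vapply(spec$terms, `[[`, "", "name"))
  for (ia in spec$interactions) {
    Xcols[[paste(ia, collapse = ":")]] <- std_by_name[[ia[1]]] * std_by_name[[ia[2]]]
  }
  Xcols[["(Intercept)"]] <- rep(1, length(y))
  X <- do.call(cbind, Xcols)
  rownames(X) <- labels
  names(y) <- labels
  list(y = y, X = X, spec = spec)
}

# core GLS algebra on a fixed covariance; returns coefficients, SEs and the
# maximized (profile) ML log-likelihood
gls_core <- function(y, X, C) {
  n <- length(y)
  p <- ncol(X)
  L <- tryCatch(chol(C), error = function(e)
    stop("covariance matrix is not positive definite", call. = FALSE))
  yw <- backsolve(L, y, transpose = TRUE)
  Xw <- backsolve(L, X, transpose = TRUE)
  A <- crossprod(Xw)
  qrA <- qr(A)
  if (qrA$rank < p) {
    dep <- colnames(X)[qrA$pivot[seq.int(qrA$rank + 1L, p)]]
    stop("collinear design; offending term(s): ", paste(dep, collapse = ", "),
         call. = FALSE)
  }
  beta <- solve(qrA, crossprod(Xw, yw))
  res_w <- yw - Xw %*% beta
  rss <- sum(res_w^2)
  sigma2 <- rss / (n - p)                       # unbiased scale for SEs
  se <- sqrt(pmax(diag(solve(qrA)) * sigma2, 0))
  tval <- drop(beta) / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  sigma2_ml <- rss / n
  logdetC <- 2 * sum(log(diag(L)))
  ll <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetC + n)
  list(coefficients = drop(beta), se = se, t = tval, p = pval,
       sigma2 = sigma2, logLik = ll, n = n, p_coef = p,
       residuals = drop(y - X %*% beta))
}

#' Phylogenetic generalized least squares fit
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma^2 C)` by generalized least squares:
#' `beta = (X' C^-1 X)^-1 X' C^-1 y`, with residual scale
#' `sigma^2 = RSS_C / (n - p)` for the standard errors, t statistics with
#' `n - p` degrees of freedom and two-sided p values.  The reported
#' log-likelihood is the maximized ML value (scale profiled out with divisor
#' `n`), which feeds the likelihood-based R-squared machinery.  With
#' `estimate_lambda = TRUE`, Pagel's lambda is profiled on \[0, 1\] by ML
#' (off-diagonals of `C` multiplied by lambda).
#'
#' The estimates are invariant to multiplying `C` by a positive scalar (the
#' scale is absorbed into sigma^2) and, with `C = I`, reduce to ordinary
#' least squares.
#'
#' @param y response vector.
#' @param X design matrix (include an intercept column if wanted); rows
#'   aligned with `y` and `C`.
#' @param C phylogenetic covariance matrix, positive definite.
#' @param estimate_lambda profile Pagel's lambda by ML (default FALSE: pure
#'   Brownian motion, lambda = 1).
#' @return An object of class `pgls_fit`: coefficient table (`estimate`,
#'   `se`, `t`, `p`), `sigma2`, `logLik`, `lambda`, `n`, `p_coef`,
#'   `residuals`.
#' @export
pgls_fit <- function(y, X, C, estimate_lambda = FALSE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(y) != nrow(X) || nrow(C) != length(y) || ncol(C) != length(y)) {
    stop("y, X and C must have aligned rows", call. = FALSE)
  }
  if (!is.null(rownames(C)) && !is.null(rownames(X)) &&
      !identical(rownames(C), rownames(X))) {
    if (!setequal(rownames(C), rownames(X))) {
      stop("row labels of X and C differ", call. = FALSE)
    }
    C <- C[rownames(X), rownames(X)]
  }
  lambda <- NA_real_
  if (estimate_lambda) {
    d <- diag(C)
    with_lambda <- function(l) { Cl <- C * l; diag(Cl) <- d; Cl }
    obj <- function(l) gls_core(y, X, with_lambda(l))$logLik
    opt <- stats::optimize(obj, interval = c(0, 1), maximum = TRUE, tol = 1e-6)
    # compare against the boundaries, optimize() can miss them
    cand <- c(opt$maximum, 0, 1)
    lls <- c(opt$objective, obj(0), obj(1))
    lambda <- cand[which.max(lls)]
    C <- with_lambda(lambda)
  }
  core <- gls_core(y, X, C)
  structure(
    list(coefficients = stats::setNames(core$coefficients, colnames(X)),
         se = stats::setNames(core$se, colnames(X)),
         t = stats::setNames(core$t, colnames(X)),
         p = stats::setNames(core$p, colnames(X)),
         sigma2 = core$sigma2, logLik = core$logLik, lambda = lambda,
         n = core$n, p_coef = core$p_coef, residuals = core$residuals),
    class = "pgls_fit"
  )
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Generalized least squares fit (phylogenetic covariance), n =", x$n, "\n")
  tab <- data.frame(estimate = x$coefficients, se = x$se, t = x$t, p = x$p)
  print(round(tab, 4))
  cat("sigma2 =", format(x$sigma2, digits = 4),
      " logLik =", format(x$logLik, digits = 6))
  if (!is.na(x$lambda)) cat("  lambda =", format(x$lambda, digits = 4))
  cat("\n")
  invisible(x)
}

#' Likelihood-based R-squared of a GLS model
#'
#' `R2 = 1 - exp(-2 (ll_full - ll_null) / n)` where the null model is
#' intercept-only under the same covariance structure — the likelihood-ratio
#' R-squared of Cox–Snell form adapted to phylogenetic regression.  The
#' adjusted version applies the classical small-sample correction
#' `1 - (1 - R2) (n - 1) / (n - p)`.
#'
#' @param full a [pgls_fit()] of the model of interest.
#' @param null the intercept-only [pgls_fit()] on the same data and
#'   covariance.
#' @return List with `r2` and `adj_r2`.
#' @export
r2_lik <- function(full, null) {
  stopifnot(inherits(full, "pgls_fit"), inherits(null, "pgls_fit"),
            full$n == null$n)
  if (full$logLik < null$logLik - 1e-8) {
    stop("full model has lower likelihood than the null; ",
         "refit (check nesting / optimization)", call. = FALSE)
  }
  n <- full$n
  r2 <- 1 - exp(-2 * (full$logLik - null$logLik) / n)
  r2 <- min(max(r2, 0), 1 - .Machine$double.eps)
  adj <- 1 - (1 - r2) * (n - 1) / (n - full$p_coef)
  list(r2 = r2, adj_r2 = adj)
}

#' Per-predictor partial r-squared
#'
#' `partial r2 = 1 - exp(-2 (ll_full - ll_reduced) / n)`, clipped at 0, where
#' the reduced model drops the target predictor (and any interaction
#' containing it) under the same covariance.
#'
#' @param full the full-model [pgls_fit()].
#' @param reduced the [pgls_fit()] without the target predictor.
#' @return Partial r-squared in \[0, 1\].
#' @export
partial_r2 <- function(full, reduced) {
  stopifnot(inherits(full, "pgls_fit"), inherits(reduced, "pgls_fit"),
            full$n == reduced$n)
  if (reduced$p_coef >= full$p_coef) {
    stop("'reduced' must be nested in 'full' (fewer coefficients)", call. = FALSE)
  }
  r2 <- 1 - exp(-2 * (full$logLik - reduced$logLik) / full$n)
  min(max(r2, 0), 1)
}

#' Fit the component regression on a clade table
#'
#' One-stop fit of the clade-level regression (default
#' `d ~ ln(a) + b + ln(c)`) by phylogenetic generalized least squares:
#' builds the standardized design from the component table, the Brownian
#' covariance from the clade-level tree, fits the full model, the
#' intercept-only null, and one reduced model per main effect (dropping that
#' effect and any interaction containing it) for partial r-squared.
#'
#' @param components clade component table (`clade_id`, `d`, `a`, `b`, `c`,
#'   ...); rows are matched to tree tips by `clade_id`.
#' @param tree the clade-level [dated_tree()] (one tip per clade), e.g. from
#'   [clade_backbone_tree()]; tips not in `components` are dropped.
#' @param formula model formula string (see [parse_eva_formula()]).
#' @param estimate_lambda profile Pagel's lambda by ML (default FALSE).
#' @return An object of class `eva_pgls`: list with `table` (per-term
#'   estimate, SE, t, p, partial r2), `r2`, `adj_r2`, `logLik`, `lambda`,
#'   `sigma2`, `n`, `formula`, and the underlying `fit`.
#' @export
eva_pgls <- function(components, tree, formula = "d ~ ln(a) + b + ln(c)",
                     estimate_lambda = FALSE) {
  spec <- parse_eva_formula(formula)
  design <- build_design(components, spec)
  C <- phylo_vcv(tree, labels = rownames(design$X))
  fit <- pgls_fit(design$y, design$X, C, estimate_lambda = estimate_lambda)
  Cfit <- C
  if (!is.na(fit$lambda)) {
    d <- diag(C); Cfit <- C * fit$lambda; diag(Cfit) <- d
  }
  null <- pgls_fit(design$y, design$X[, "(Intercept)", drop = FALSE], Cfit)
  r2 <- r2_lik(fit, null)

  main_names <- vapply(spec$terms, `[[`, "", "name")
  col_of <- function(nm) {
    t <- spec$terms[[match(nm, main_names)]]
    if (t$transform == "ln") paste0("ln(", t$name, ")") else t$name
  }
  pr2 <- vapply(main_names, function(nm) {
    drop_cols <- col_of(nm)
    for (ia in spec$interactions) {
      if (nm %in% ia) drop_cols <- c(drop_cols, paste(ia, collapse = ":"))
    }
    keep <- setdiff(colnames(design$X), drop_cols)
    reduced <- pgls_fit(design$y, design$X[, keep, drop = FALSE], Cfit)
    partial_r2(fit, reduced)
  }, 1)
  pr2_full <- stats::setNames(rep(NA_real_, length(fit$coefficients)),
                              names(fit$coefficients))
  pr2_full[vapply(main_names, col_of, "")] <- pr2

  tab <- data.frame(
    term = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    se = unname(fit$se),
    t = unname(fit$t),
    p = unname(fit$p),
    partial_r2 = unname(pr2_full),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(
    list(table = tab, r2 = r2$r2, adj_r2 = r2$adj_r2, logLik = fit$logLik,
         lambda = fit$lambda, sigma2 = fit$sigma2, n = fit$n,
         formula = formula, fit = fit),
    class = "eva_pgls"
  )
}

#' @export
print.eva_pgls <- function(x, ...) {
  cat("Clade-component regression:", x$formula, " (n =", x$n, "clades)\n\n")
  tab <- x$table
  tab$estimate <- round(tab$estimate, 3)
  tab$se <- round(tab$se, 3)
  tab$t <- round(tab$t, 3)
  tab$p <- signif(tab$p, 3)
  tab$partial_r2 <- round(tab$partial_r2, 3)
  print(tab)
  cat("\nR2 (likelihood) =", round(x$r2, 3),
      " adjusted R2 =", round(x$adj_r2, 3))
  if (!is.na(x$lambda)) cat("  lambda =", round(x$lambda, 3))
  cat("\n")
  invisible(x)
}
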