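---
title: "Clade diversification in evolutionary arenas: models and methods"
author: "evarena"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clade diversification in evolutionary arenas: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The package quantifies, for a set of clades cut from a dated species-level
phylogeny, how net diversification relates to three properties of the arena
in which each clade evolves: the abiotic environment available to it, the
intensity of biotic interaction among its species, and how fast its niche
evolves. The working regression is

$$ d \sim \ln(a) + b + \ln(c), $$

fitted by phylogenetic generalized least squares (PGLS) across clades, with

* **d** — net diversification rate (speciation minus extinction, per lineage
  per Ma), estimated per clade by the stem-age method-of-moments formula
  $r = \tfrac{1}{t}\,\ln\{n(1-\varepsilon)+\varepsilon\}$, where $n$ is the
  clade's extant richness, $t$ its stem age in Ma, and $\varepsilon$ the
  assumed relative extinction fraction (extinction/speciation). The default
  $\varepsilon = 0.9$ reflects the high turnover expected in old plant
  lineages; with $\varepsilon = 0$ the formula reduces to $\ln(n)/t$, and a
  monotypic clade always gets $d = 0$.
* **a** — abiotic arena size: the number of grid cells in which at least one
  member species finds suitable conditions. Because a union over more
  species is mechanically larger, every clade is rarefied to a common
  richness (the smallest multispecies clade) by repeated subsampling before
  counting.
* **b** — within-clade competition: for every pair of species in a clade,
  the product of their potential-niche overlap (Schoener's
  $D = 1 - \tfrac12\sum_i |\hat p_i - \hat q_i|$ on suitability surfaces
  normalized to sum to one) and their realized geographic overlap; the two
  overlap vectors are min–max rescaled to $[0,1]$ across *all* pairs before
  multiplying, and pair scores are averaged per clade.
* **c** — niche-evolution rate: the per-trait rates of a multivariate
  Brownian-motion model (the diagonal of the evolutionary rate matrix
  estimated by maximum likelihood on the clade's crown subtree), summed over
  traits and scaled by the maximum across clades so that $c \in (0, 1]$.

The ln transforms of `a` and `c` reduce the strong right skew of cell counts
and rates; `b` is already bounded. The response and every predictor column
are z-scored before fitting, so reported slopes are standardized
coefficients.

## Clade delimitation and the clade-level tree

Clades are delimited by slicing the dated tree at a fixed age: every edge
whose parent is at least as old as the cutoff and whose child is younger
defines one group (the tips descending from the child). The groups are
reciprocally monophyletic, jointly partition the tips, and satisfy
stem age $\ge$ cutoff with crown age $<$ cutoff for multispecies groups; a
stem age exactly at the cutoff joins the older side. Terminal edges spanning
the slice yield single-species groups, which are excluded from the
regression (they carry $d = 0$ by construction and no pairwise or rate
information).

The regression needs a tree with one tip per clade. We collapse each clade
through its stem: on an ultrametric tree, keeping a single exemplar tip per
clade leaves exactly the backbone with each terminal edge running from the
clade's stem node to the present, so stem ages — the $t$ of the estimator —
are preserved and the backbone stays ultrametric. This stem-collapse choice
(rather than, say, cutting tips at crown nodes) is the package's design
decision; it keeps the covariance of the regression consistent with the ages
used for $d$.

## The PGLS machinery

With $C$ the Brownian covariance of the clade tree (shared root-to-MRCA path
lengths), the fit is
$\hat\beta = (X^\top C^{-1} X)^{-1} X^\top C^{-1} y$, with residual scale
$\hat\sigma^2 = \mathrm{RSS}_C/(n-p)$ for standard errors and t tests on
$n-p$ degrees of freedom. The reported log-likelihood is the maximized ML
value (scale profiled out with divisor $n$); goodness of fit is the
likelihood-ratio $R^2 = 1 - \exp\{-2(\ell_{\text{full}} -
\ell_{\text{null}})/n\}$ against the intercept-only model under the same
covariance, with the classical $\tfrac{n-1}{n-p}$ small-sample adjustment,
and each predictor's partial $r^2$ uses the same formula against the model
dropping that predictor (and any interaction containing it). Pagel's
$\lambda$ — multiplying the off-diagonals of $C$ — can be profiled on
$[0,1]$ by ML; the default is pure Brownian motion ($\lambda = 1$), the
default of standard phylogenetic regression tools. Interactions such as
`b:c` are products of the standardized main effects.

Numerical choices worth knowing:

* All covariance solves go through a Cholesky factor; a non-positive-definite
  $C$ (e.g. duplicated zero-length tips) is an explicit error, as is a rank-
  deficient design (the offending columns are named).
* Standardization uses the population SD (divisor $n$). Slopes are invariant
  to the $n$ vs $n-1$ convention because the factor cancels between response
  and predictor; the convention only fixes the printed design columns.
* Ultrametricity is checked to a relative tolerance of $10^{-6}$ of the root
  age; published dated trees carry rounding noise, so violations flag the
  tree rather than reject it. Polytomies are accepted as hard.
* $\lambda$ profiling compares the interior optimum against both boundaries,
  since the likelihood is frequently maximized at $\lambda \in \{0, 1\}$.

## What the synthetic generator emulates

Every stage is testable without external data through a generator whose
defaults define the package's study conditions, chosen once to resemble a
medium-sized plant radiation:

* a reconstructed birth–death tree with 100 extant species (speciation
  0.1 /Ma, extinction 0.05 /Ma — a relative extinction fraction of 0.5,
  enough to create realistic stem/crown age gaps);
* the delimitation slice placed, by default, where the tree carries ~30
  lineages (the midpoint between the 29th and 30th oldest branching times),
  yielding a mix of multispecies clades and singletons like empirical
  cutoffs do;
* 11 traits under independent unit-rate Brownian motion;
* a 50 × 40 cell lattice (2,000 cells) with a smoothly warped two-dimensional
  gradient as environment; each species gets a Gaussian suitability kernel
  (breadth 0.25) around a niche center that itself evolves by Brownian
  motion on the tree, so relatedness translates into niche overlap, and
  Schoener's $D$ falls monotonically with niche-center distance;
* occurrences as Bernoulli draws with probability 0.8 × suitability (each
  species keeps at least its best cell);
* a clade-level response $d = \beta_0 + \beta_a z(\ln a) + \beta_b z(b) +
  \beta_c z(\ln c) + \epsilon$ with $\epsilon \sim N(0, \sigma^2
  C/\max\mathrm{diag}\,C)$ — Brownian-correlated residuals with tip variance
  $\sigma^2$. Default effects mirror the conifer case study (intercept 0.6,
  area 0, competition −0.58, niche rate 0.17); by default $\sigma^2$ is the
  complement to unit total variance ($1 - \sum\beta^2 \approx 0.635$), so
  the $\beta$ are true standardized effects and the generated response sits
  on the standardized scale.

Recovery experiments therefore fit on the generator's response scale
directly (standardized predictors, raw response): the estimates are then
unbiased estimates of the generating standardized effects, and the intercept
is recoverable. The empirical pipeline z-scores the response too — a pure
rescaling that leaves t statistics, p values, power and $R^2$ untouched.
Note that z-scoring a phylogenetically correlated response by its naive
sample SD slightly inflates slope magnitudes (the sample SD underestimates
the residual scale under correlation), which is why the recovery experiment
does not re-standardize.

What the generator does *not* emulate: real geography and climate (the
environmental surface is a synthetic gradient, so absolute area sizes are
not comparable to real cell counts); niche models fitted to occurrence data
(suitability surfaces are the truth here, not estimates); trait models
beyond Brownian motion; diversification rate shifts within clades; and
between-clade competition. Passing tests on synthetic data show the
estimators and the regression are correct and calibrated under the stated
model — not that the model is adequate for any particular empirical system.

## Component parameters

| parameter | default | units | role |
|---|---|---|---|
| `eps` | 0.9 | – | relative extinction fraction in the $d$ estimator |
| `cutoff` | data-dependent | Ma | stem-age slice for clade delimitation |
| `threshold` | 0.5 | suitability | cell counts as suitable when ≥ threshold (binary grids pass through) |
| `rarefy_to` | min multispecies clade size | species | common richness for area rarefaction |
| `reps` | 100 | – | rarefaction replicates (seed recorded in provenance) |
| `overlap_method` | `"simpson"` | – | geographic overlap: intersection over the smaller range; `"jaccard"` optional |
| `estimate_lambda` | `FALSE` | – | profile Pagel's λ instead of pure Brownian residuals |

Two decisions were genuinely open and are resolved as follows. The
geographic-overlap formula: intersection over the smaller range
(Szymkiewicz–Simpson), because conifer-like range-size asymmetries make
Jaccard collapse toward zero for nested ranges that plainly do interact;
Jaccard remains available. The min–max rescaling of pair overlaps: one
common scale across all pairs of all clades, keeping clade scores
comparable — a per-clade scale would make $b$ incommensurable between
clades. The multivariate Brownian fit is per clade on its crown subtree
(on globally z-standardized traits so no trait's units dominate the sum);
a global fit with clade-specific rate multipliers would be the natural
alternative and is noted as future work.

## Problem sizes used by the test suite

The statistical checks run at sizes chosen for stable Monte-Carlo estimates:
parameter recovery at 200 clades × 500 replicates, test calibration at 41
clades × 1,000 null replicates, Brownian-rate recovery on a 200-tip tree ×
200 replicates, and the power context at the case-study size of 41 clades ×
400 replicates with a true standardized competition effect of −0.58.
Monte-Carlo tolerances are three standard errors of the respective means
(plus the $O(1/n)$ ML bias allowance for variance-type estimators).

## Worked example

```{r example}
library(evarena)

ds <- simulate_eva_dataset(sim_config(seed = 1))
fit <- eva_pgls(ds$components, ds$backbone)
print(fit)

# power context at the case-study sample size
recover_effects(n_clades = 41, reps = 400, seed = 1)
```

## Known limitations

* The $d$ estimator conditions on clade survival and fixed $\varepsilon$;
  it cannot separate speciation from extinction, and rates are assumed
  constant within clades.
* Rarefied area treats all cells as exchangeable; common and rare
  environments count equally.
* The competition index is within-clade only and symmetric; it
  underestimates interactions with species outside the clade.
* The min–max rescaling of overlaps makes $b$ depend on the pair ensemble:
  adding clades can change existing scores.
* The likelihood $R^2$ is not variance-explained in the OLS sense; its
  adjusted version can be negative for models no better than the null.
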