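#' Delimit clades by a stem-age time slice
#'
#' Cuts the tree at `cutoff` Ma and returns the maximal groups whose stem edge
#' spans the slice: every edge with parent age >= cutoff and child age <
#' cutoff defines one group (the tips descending from the child).  Groups are
#' therefore reciprocally monophyletic, have stem age >= cutoff, and — when
#' they contain more than one species — crown age < cutoff.  Lineages whose
#' terminal edge itself spans the slice become single-species groups.  The
#' groups always partition the tips: each tip's root path crosses the slice
#' exactly once because ages decrease from root to tip.
#'
#' A stem age exactly equal to the cutoff counts as spanning (the tie goes to
#' the older group).  If the cutoff exceeds the root age no edge spans the
#' slice; all tips are returned as one group with a warning.
#'
#' @param tree a [dated_tree()] (or `"phylo"`, coerced).
#' @param cutoff time slice in Ma before present; must be positive.
#' @return An object of class `clade_set`: list with `table` (data.frame:
#'   `clade_id`, `n_species`, `stem_age`, `crown_age` — `NA` for singletons),
#'   `members` (named list of species per clade) and `cutoff`.
#' @examples
#' tr <- parse_newick("((A:10,B:10):30,(C:25,D:25):15);")
#' cs <- delimit_clades(tr, 20)   # {A,B} plus singletons {C}, {D}
#' cs$table
#' @export
delimit_clades <- function(tree, cutoff) {
  if (!inherits(tree, "dated_tree")) tree <- dated_tree(as_phylo(tree))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("'cutoff' must be a single positive age in Ma", call. = FALSE)
  }
  phy <- tree$phy
  ages <- tree$ages
  ntip <- length(phy$tip.label)

  if (cutoff > tree$root_age) {
    warning("cutoff ", cutoff, " Ma is older than the root age (",
            format(tree$root_age, digits = 6),
            " Ma); returning a single clade of all tips", call. = FALSE)
    members <- list(clade_01 = phy$tip.label)
    tab <- data.frame(
      clade_id = "clade_01", n_species = ntip,
      stem_age = tree$root_age,
      crown_age = if (ntip > 1L) tree$root_age else NA_real_,
      stringsAsFactors = FALSE
    )
    return(structure(list(table = tab, members = members, cutoff = cutoff),
                     class = "clade_set"))
  }

  crosses <- ages[phy$edge[, 1L]] >= cutoff & ages[phy$edge[, 2L]] < cutoff
  kids <- phy$edge[crosses, 2L]
  stems <- ages[phy$edge[crosses, 1L]]

  pp <- ape::prop.part(phy)  # tip sets per internal node (root-first order)
  member_list <- lapply(kids, function(node) {
    if (node <= ntip) phy$tip.label[node]
    else phy$tip.label[pp[[node - ntip]]]
  })
  crowns <- ifelse(kids <= ntip, NA_real_, ages[kids])

  # stable order: by first (smallest-index) member tip in the tree
  ord <- order(vapply(member_list, function(m) min(match(m, phy$tip.label)), 1))
  member_list <- member_list[ord]
  ids <- sprintf("clade_%02d", seq_along(member_list))
  names(member_list) <- ids

  tab <- data.frame(
    clade_id = ids,
    n_species = vapply(member_list, length, 1L),
    stem_age = stems[ord],
    crown_age = crowns[ord],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(list(table = tab, members = member_list, cutoff = cutoff),
            class = "clade_set")
}

#' @export
print.clade_set <- function(x, ...) {
  multi <- sum(x$table$n_species > 1L)
  cat("Clade set at", x$cutoff, "Ma slice:", nrow(x$table), "groups (",
      multi, "with >1 species ),", sum(x$table$n_species), "tips\n")
  invisible(x)
}

#' Collapse a tree to one tip per clade
#'
#' Builds the clade-level backbone tree: each clade's subtree is replaced by a
#' single terminal edge from its stem node to the present, so the resulting
#' tree has one tip per clade at age 0, preserves the backbone topology and
#' node ages, and each terminal edge length equals the clade's stem age.  On
#' an ultrametric tree this is achieved exactly by retaining one exemplar tip
#' per clade (the suppressed degree-two stem node merges the stem edge with
#' the exemplar's path to the present).
#'
#' @param tree the [dated_tree()] the clades were delimited on.
#' @param clades a [delimit_clades()] result from the same tree.
#' @return A [dated_tree()] whose tip labels are the `clade_id`s.
#' @export
clade_backbone_tree <- function(tree, clades) {
  if (!inherits(tree, "dated_tree")) tree <- dated_tree(as_phylo(tree))
  stopifnot(inherits(clades, "clade_set"))
  phy <- tree$phy
  all_members <- unlist(clades$members, use.names = FALSE)
  if (!setequal(all_members, phy$tip.label) ||
      length(all_members) != length(phy$tip.label)) {
    stop("clade set does not partition the tips of this tree", call. = FALSE)
  }
  exemplar <- vapply(clades$members, `[[`, "", 1L)
  if (length(exemplar) == 1L) {
    # degenerate single-clade backbone: one terminal edge of stem-age length
    nwk <- sprintf("(%s:%.10g);", names(exemplar), clades$table$stem_age[1L])
    return(parse_newick(nwk))
  }
  sub <- ape::keep.tip(phy, exemplar)
  sub$tip.label <- names(exemplar)[match(sub$tip.label, exemplar)]
  out <- dated_tree(sub, tol = tree$tol)
  # terminal edges must run stem node -> present
  stopifnot(all(abs(tip_ages(out)) <= tree$tol * max(out$root_age, 1)))
  out
}

#' Write a clade set to CSV
#'
#' Columns: `clade_id`, `n_species`, `stem_age`, `crown_age`, `members`
#' (semicolon-joined species names).
#'
#' @param clades a [delimit_clades()] result.
#' @param path output CSV path.
#' @export
write_clades_csv <- function(clades, path) {
  stopifnot(inherits(clades, "clade_set"))
  tab <- clades$table
  tab$members <- vapply(clades$members[tab$clade_id], paste, "", collapse = ";")
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
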