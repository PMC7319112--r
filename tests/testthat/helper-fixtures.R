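# Shared fixtures, built in code.

# three-cherry toy: clades {A,B}, {C,D}, {E,F} at a 10 Ma slice
toy_tree <- function() {
  parse_newick("(((A:5,B:5):10,(C:8,D:8):7):5,(E:4,F:4):16);")
}

toy_grid <- function() {
  m <- rbind(
    A = c(1, 1, 0, 0, 0, 0),
    B = c(0, 1, 1, 0, 0, 0),
    C = c(0, 0, 1, 1, 0, 0),
    D = c(0, 0, 1, 1, 1, 0),
    E = c(0, 0, 0, 0, 1, 1),
    F = c(0, 0, 0, 0, 1, 1)
  )
  colnames(m) <- paste0("c", 1:6)
  suitability_grid(m)
}

toy_occ <- function() {
  list(A = "c1", B = "c2", C = c("c3", "c4"), D = "c4",
       E = c("c5", "c6"), F = "c6")
}

toy_traits <- function() {
  cbind(trait_01 = c(A = 0, B = 2, C = 0, D = 3, E = 1, F = 1))
}

# exact expectation of the rarefied cell count by enumerating every
# rarefy_to-subset of the members (feasible for small clades); the
# independent oracle for clade_area()
exact_rarefied_area <- function(grid, members, rarefy_to, threshold = 0.5) {
  suit <- unclass(grid)[members, , drop = FALSE] >= threshold
  draws <- utils::combn(length(members), rarefy_to)
  mean(apply(draws, 2, function(ix)
    sum(colSums(suit[ix, , drop = FALSE]) > 0)))
}

# star tree over n tips with given depth
star_tree <- function(n, depth = 1) {
  labs <- paste0("t", seq_len(n))
  parse_newick(paste0("(", paste0(labs, ":", depth, collapse = ","), ");"))
}
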