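# Shared fixtures: small trees built in code.

# A design tree with an extra co-located occupant at the root: root holds
# two names (the identical-sequence case), two leaf children.
two_occupant_tree <- function() {
  labeled_tree(
    parent = c(0L, 1L, 1L),
    children = list(2:3, integer(0), integer(0)),
    names = list(c("S", "Sdup"), "S1", "S2"),
    blen = c(NA, 1, 1))
}

# Caterpillar with distinct branch lengths, for adaptive-collapse checks.
caterpillar_tree <- function() {
  parse_newick("(((A:0,B:1)ab:2,C:3)abc:1,D:2)root;")
}

# Brute-force oracle for the adaptive cutoff: smallest candidate branch
# length whose fixed collapse reaches <= target leaves.
adaptive_oracle <- function(tree, target) {
  if (n_leaves(tree) <= target) return(-Inf)
  cands <- sort(unique(tree$blen[seq_along(tree$blen) != tree$root]))
  for (ct in cands) {
    if (collapse_fixed(tree, ct)$n_leaves <= target) return(ct)
  }
  cands[length(cands)]
}

# Random leaf-only tree with positive branch lengths, via a random
# resolution of a design tree (gives anonymous internal nodes).
random_leafy_tree <- function(days, seed, extra_blen = 0) {
  resolve_random(build_design_tree(days), seed = seed, extra_blen = extra_blen)
}
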