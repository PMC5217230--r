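test_that("parent_child_relations expands names across branches", {
  d2 <- build_design_tree(2)
  rel <- parent_child_relations(d2)
  expect_equal(nrow(rel), 2L)
  expect_setequal(paste(rel$parent, rel$child), c("S S1", "S S2"))

  chain <- parse_newick("((S11:1)S1:1,S2:1)S;")
  rel2 <- parent_child_relations(chain)
  expect_setequal(paste(rel2$parent, rel2$child),
                  c("S S1", "S S2", "S1 S11"))

  # multi-name node: expansion across the branch plus co-location pairs
  t <- parse_newick("(X:1)S1|S11;")
  rel3 <- parent_child_relations(t)
  branch <- rel3[!rel3$colocated, ]
  coloc <- rel3[rel3$colocated, ]
  expect_setequal(paste(branch$parent, branch$child), c("S1 X", "S11 X"))
  expect_setequal(paste(coloc$parent, coloc$child), c("S1 S11", "S11 S1"))

  # anonymous ends emit nothing
  anon <- parse_newick("((A:1,B:1):1,C:1);")
  expect_equal(nrow(parent_child_relations(anon)), 0L)
})

test_that("parent_child_score counts recovered true relations", {
  d2 <- build_design_tree(2)
  expect_equal(parent_child_score(d2, d2), 1.0)
  inferred <- parse_newick("(S2:1,(S1:1)S:0);")
  expect_equal(parent_child_score(inferred, d2), 0.5)
  # co-located pair satisfies the true relation (S, S11)
  coloc <- parse_newick("(S1:1,S2:1)S|S11;")
  truth3 <- parse_newick("(S1:1,S2:1,S11:0)S;")
  expect_equal(parent_child_score(coloc, truth3), 1.0)
  # single-node truth has no relation
  expect_error(parent_child_score(d2, parse_newick("S;")), "undefined")
})

test_that("parent_child_score ignores child order in both trees", {
  d3 <- build_design_tree(3)
  flipped <- parse_newick("((S22:1,S21:1)S2:1,(S12:1,S11:1)S1:1)S;")
  expect_equal(parent_child_score(flipped, d3), 1.0)
  expect_equal(parent_child_score(d3, flipped), 1.0)
  expect_equal(clade_score(flipped, d3), 1.0)
})

test_that("clades list strict descendants including internal names", {
  expect_equal(clades(parse_newick("S;")), list())
  d2 <- build_design_tree(2)
  expect_equal(clades(d2), list(c("S1", "S2")))
  d3 <- build_design_tree(3)
  cl <- clades(d3)
  expect_setequal(
    vapply(cl, paste, character(1), collapse = ","),
    c("S1,S11,S12,S2,S21,S22", "S11,S12", "S21,S22"))
  # anonymous internal nodes still contribute clades
  anon <- parse_newick("((A:1,B:1):1,C:1);")
  expect_setequal(vapply(clades(anon), paste, character(1), collapse = ","),
                  c("A,B", "A,B,C"))
})

test_that("clade_score matches exactly, with multiset semantics", {
  d3 <- build_design_tree(3)
  expect_equal(clade_score(d3, d3), 1.0)
  swapped <- parse_newick("((S11:1,S21:1)S1:1,(S12:1,S22:1)S2:1)S;")
  expect_equal(clade_score(swapped, d3), 1 / 3)
  expect_error(clade_score(d3, parse_newick("A;")), "undefined")
  # duplicate identical truth clades need distinct inferred matches
  truth <- parse_newick("((A:1):1)R;")   # R and the anonymous node: {A} twice
  tc <- clades(truth)
  expect_equal(sum(vapply(tc, identical, logical(1), "A")), 2L)
  inferred <- parse_newick("(A:1)R;")    # only one {A} clade
  expect_equal(clade_score(inferred, truth), 0.5)
})

test_that("clade sets agree with ape bipartitions on leaf-only trees", {
  skip_if_not_installed("ape")
  set.seed(5)
  for (rep in 1:5) {
    ap <- ape::rtree(10, rooted = TRUE)
    ours <- parse_newick(ape::write.tree(ap))
    got <- sort(vapply(clades(ours), paste, character(1), collapse = ","))
    pp <- ape::prop.part(ap)
    want <- sort(vapply(pp, function(i) {
      paste(sort(attr(pp, "labels")[i]), collapse = ",")
    }, character(1)))
    expect_equal(got, want)
  }
})

test_that("rooted topology counts follow the double factorial", {
  expect_equal(rooted_tree_count(1), 1)
  expect_equal(rooted_tree_count(2), 1)
  expect_equal(rooted_tree_count(3), 3)
  expect_equal(rooted_tree_count(4), 15)
  expect_error(rooted_tree_count(0), "n_leaves")
  # brute force: the enumeration machinery itself counts (2n-3)!!
  for (n in 2:6) {
    topos <- phylobench:::enumerate_local_topologies(n)
    expect_equal(length(topos), rooted_tree_count(n))
    # all enumerated shapes are distinct
    keys <- vapply(topos, function(tp) paste(deparse(tp), collapse = ""),
                   character(1))
    expect_equal(anyDuplicated(keys), 0L)
  }
})

test_that("count_resolutions multiplies per-node topology counts", {
  expect_equal(count_resolutions(build_design_tree(2)), 3)
  expect_equal(count_resolutions(build_design_tree(3)), 27)
  expect_equal(count_resolutions(two_occupant_tree()), 15)
  # unoccupied internal nodes contribute factor 1
  leafy <- random_leafy_tree(3, seed = 1)
  expect_equal(count_resolutions(leafy), 1)
  d8 <- build_design_tree(8)
  expect_equal(count_resolutions(d8), 3^127)
  expect_equal(count_resolutions(d8) / 3.9e60, 1, tolerance = 0.01)
})

test_that("resolve_random produces leaf-only bifurcating trees that collapse back", {
  for (days in 2:4) {
    truth <- build_design_tree(days)
    for (s in 1:5) {
      r <- resolve_random(truth, seed = s)
      # every name on a leaf, all internal nodes anonymous and binary
      internal <- which(lengths(r$children) > 0L)
      expect_true(all(lengths(r$names[internal]) == 0L))
      expect_true(all(lengths(r$children[internal]) == 2L))
      expect_setequal(tree_names(r), tree_names(truth))
      expect_equal(n_leaves(r), n_nodes(truth))
      back <- collapse_fixed(r, 0)$tree
      expect_true(tree_equal(back, truth, use_blen = TRUE))
      expect_equal(parent_child_score(back, truth), 1.0)
      expect_equal(clade_score(back, truth), 1.0)
    }
  }
  # reproducibility and the identity case
  t2 <- build_design_tree(2)
  expect_true(tree_equal(resolve_random(t2, seed = 7),
                         resolve_random(t2, seed = 7), use_blen = TRUE))
  leafy <- random_leafy_tree(2, seed = 1)
  expect_true(tree_equal(resolve_random(leafy, seed = 1), leafy))
  # unsupported shape: occupied node without exactly two children
  expect_error(resolve_random(parse_newick("((A:1)S1:1,B:1)S;")),
               "unsupported shape")
})

test_that("the three single-occupant resolutions appear uniformly", {
  t2 <- build_design_tree(2)
  all3 <- enumerate_resolutions(t2)
  expect_equal(length(all3), 3L)
  keys <- vapply(all3, function(x) phylobench:::canonical_form(x),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
  draws <- vapply(1:3000, function(s) {
    phylobench:::canonical_form(resolve_random(t2, seed = s))
  }, character(1))
  tab <- table(factor(draws, levels = keys))
  expect_true(all(tab > 0))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.001)
})

test_that("exhaustive resolutions match the count and collapse to truth", {
  cases <- list(build_design_tree(2), build_design_tree(3), two_occupant_tree())
  for (truth in cases) {
    all_res <- enumerate_resolutions(truth)
    expect_equal(length(all_res), count_resolutions(truth))
    keys <- vapply(all_res, phylobench:::canonical_form, character(1))
    expect_equal(anyDuplicated(keys), 0L)
    for (r in all_res) {
      back <- collapse_fixed(r, 0)$tree
      expect_true(tree_equal(back, truth))
    }
  }
})
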