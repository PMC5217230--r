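#' Parent-child relations of a labeled tree
#'
#' A rooted tree with named nodes can be described as a list of parent-child
#' relations: for every branch from node `P` to child `C`, one ordered pair
#' `(p, c)` per name `p` at `P` and name `c` at `C` (the parent is the node
#' nearer the root). A branch touching an anonymous node contributes no pair
#' for that end. Nodes holding several co-located names (created by
#' collapsing) additionally contribute every ordered pair of distinct
#' co-located names, flagged `colocated`: co-location is the collapsed
#' representation of a zero-length true branch, and scoring treats it as
#' satisfying the corresponding true relation.
#'
#' @param tree A [labeled_tree()].
#' @return A data frame with columns `parent`, `child` and logical
#'   `colocated`.
#' @examples
#' parent_child_relations(build_design_tree(2))
#' @export
parent_child_relations <- function(tree) {
  ps <- character(0); cs <- character(0); co <- logical(0)
  for (i in seq_along(tree$parent)) {
    p <- tree$parent[i]
    if (p != 0L && length(tree$names[[p]]) && length(tree$names[[i]])) {
      grid <- expand.grid(parent = tree$names[[p]], child = tree$names[[i]],
                          stringsAsFactors = FALSE)
      ps <- c(ps, grid$parent); cs <- c(cs, grid$child)
      co <- c(co, rep(FALSE, nrow(grid)))
    }
    nm <- tree$names[[i]]
    if (length(nm) >= 2L) {
      grid <- expand.grid(parent = nm, child = nm, stringsAsFactors = FALSE)
      grid <- grid[grid$parent != grid$child, , drop = FALSE]
      ps <- c(ps, grid$parent); cs <- c(cs, grid$child)
      co <- c(co, rep(TRUE, nrow(grid)))
    }
  }
  data.frame(parent = ps, child = cs, colocated = co,
             stringsAsFactors = FALSE)
}

#' Fraction of true parent-child relations recovered
#'
#' Scores an inferred (typically collapsed) tree against the known tree:
#' the fraction of the known tree's parent-child relations that are present
#' in the inferred tree. A true relation `(p, c)` counts as recovered when
#' the inferred tree has the pair across a branch, or when `p` and `c` sit
#' co-located on one inferred node (the collapse representation of a
#' zero-length branch). The denominator is the known tree's relation count,
#' so names missing from the inferred tree simply count as unrecovered.
#'
#' @param inferred,truth [labeled_tree()] objects; `truth` must have at
#'   least one relation.
#' @return A fraction in `[0, 1]`; 1 exactly when every true branch is
#'   recovered.
#' @export
parent_child_score <- function(inferred, truth) {
  rt <- parent_child_relations(truth)
  rt <- rt[!rt$colocated, , drop = FALSE]
  if (nrow(rt) == 0L)
    stop("truth tree has no parent-child relation; score undefined", call. = FALSE)
  ri <- parent_child_relations(inferred)
  key <- function(p, c) paste0(p, "\x1f", c)
  branch_keys <- key(ri$parent[!ri$colocated], ri$child[!ri$colocated])
  coloc_keys <- key(ri$parent[ri$colocated], ri$child[ri$colocated])
  truth_keys <- key(rt$parent, rt$child)
  matched <- truth_keys %in% branch_keys | truth_keys %in% coloc_keys
  sum(matched) / nrow(rt)
}

#' Labeled clades of a tree
#'
#' For each internal node (a node with at least one child), the set of all
#' sample names strictly descendant from it - including names on internal
#' descendant nodes, not just leaves. The node's own names are excluded.
#' Anonymous internal nodes still contribute their clade.
#'
#' @param tree A [labeled_tree()].
#' @return A list of sorted character vectors, one per internal node (a
#'   multiset: duplicates are retained).
#' @examples
#' clades(build_design_tree(3))
#' @export
clades <- function(tree) {
  desc <- vector("list", n_nodes(tree))
  # accumulate names bottom-up in reverse of a DFS ordering
  order <- dfs_order(tree)
  for (i in rev(order)) {
    kids <- tree$children[[i]]
    val <- unlist(lapply(kids, function(k) c(tree$names[[k]], desc[[k]])),
                  use.names = FALSE)
    desc[[i]] <- if (is.null(val)) character(0) else val
  }
  internal <- which(lengths(tree$children) > 0L)
  lapply(internal, function(i) sort(desc[[i]]))
}

dfs_order <- function(tree) {
  out <- integer(0)
  stack <- tree$root
  while (length(stack)) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, i)
    stack <- c(stack, rev(tree$children[[i]]))
  }
  out
}

#' Fraction of true clades recovered
#'
#' The fraction of the known tree's labeled clades that also occur in the
#' inferred tree. Matching is exact set equality with multiset semantics:
#' duplicate identical clades in the known tree each require a distinct
#' matching inferred clade. This is the labeled-clade variant of
#' Robinson-Foulds agreement: internal-node names participate in the clades,
#' unlike leaf-set bipartition implementations.
#'
#' @param inferred,truth [labeled_tree()] objects; `truth` must have at
#'   least one internal node.
#' @return A fraction in `[0, 1]`.
#' @export
clade_score <- function(inferred, truth) {
  ct <- clades(truth)
  if (length(ct) == 0L)
    stop("truth tree has no internal node; clade score undefined", call. = FALSE)
  ci <- clades(inferred)
  keyify <- function(sets) vapply(sets, paste, character(1), collapse = "\x1f")
  tk <- table(keyify(ct)); ik <- table(keyify(ci))
  common <- intersect(names(tk), names(ik))
  matched <- sum(pmin(tk[common], ik[common]))
  as.numeric(matched) / length(ct)
}

#' Number of labeled rooted bifurcating topologies
#'
#' The count of distinct rooted, bifurcating, leaf-labeled trees on
#' `n_leaves` leaves: the double factorial `(2n - 3)!!` for `n >= 2`
#' (1, 1, 3, 15, 105, 945, ...), and 1 for a single leaf. 15 is the count
#' for 4 leaves - the number of ways two identical-sequence occupants of one
#' internal node can be resolved as leaves.
#'
#' @param n_leaves Integer >= 1.
#' @return A double (the counts overflow integers quickly).
#' @examples
#' rooted_tree_count(4)  # 15
#' @export
rooted_tree_count <- function(n_leaves) {
  n_leaves <- as.integer(n_leaves)
  if (is.na(n_leaves) || n_leaves < 1L)
    stop("n_leaves must be an integer >= 1", call. = FALSE)
  if (n_leaves <= 2L) return(1)
  prod(seq(3, 2 * n_leaves - 3, by = 2))
}

#' Number of equally good leaf-only resolutions of an ancestral tree
#'
#' Every internal node occupied by `m >= 1` sample names, with `c` child
#' subtrees, can be resolved into a local rooted bifurcating tree on
#' `m + c` units (occupants as leaves on short branches, children as
#' subtrees) in `rooted_tree_count(m + c)` ways, independently across
#' nodes. For a fully sampled binary design tree (every internal node holds
#' one ancestor, two children) this is 3 per node, hence `3^k` overall -
#' `3^127 ~ 3.9e60` for the 255-sample experiment, which is why unlabeled
#' tree distances are uninformative on such data.
#'
#' @param truth A [labeled_tree()] whose occupied internal nodes are to be
#'   resolved.
#' @return A double; 1 when no internal node is occupied.
#' @examples
#' count_resolutions(build_design_tree(8))  # 3^127
#' @export
count_resolutions <- function(truth) {
  internal <- which(lengths(truth$children) > 0L)
  counts <- vapply(internal, function(i) {
    m <- length(truth$names[[i]])
    if (m == 0L) return(1)
    rooted_tree_count(m + length(truth$children[[i]]))
  }, numeric(1))
  prod(counts)
}

# ---- resolution machinery -------------------------------------------------

# Local topologies on k labeled units, as nested lists:
#   tip  = list(unit = j)
#   fork = list(kids = list(a, b))
# Built by inserting unit j on any of the 2(j-1)-1 edges (one edge above
# every node, including the root edge); this enumerates/draws uniformly the
# (2k-3)!! rooted bifurcating shapes.
local_tip <- function(j) list(unit = j)

local_n_edges <- function(topo) {
  if (!is.null(topo$unit)) 1L
  else 1L + local_n_edges(topo$kids[[1]]) + local_n_edges(topo$kids[[2]])
}

local_insert <- function(topo, edge, unit) {
  # edge counted in preorder (node itself first, then children)
  if (edge == 1L) return(list(kids = list(topo, local_tip(unit))))
  stopifnot(is.null(topo$unit))
  left <- topo$kids[[1]]
  nl <- local_n_edges(left)
  if (edge - 1L <= nl)
    list(kids = list(local_insert(left, edge - 1L, unit), topo$kids[[2]]))
  else
    list(kids = list(left, local_insert(topo$kids[[2]], edge - 1L - nl, unit)))
}

random_local_topology <- function(k) {
  topo <- local_tip(1L)
  for (j in seq_len(k)[-1]) {
    e <- sample.int(local_n_edges(topo), 1L)
    topo <- local_insert(topo, e, j)
  }
  topo
}

enumerate_local_topologies <- function(k) {
  topos <- list(local_tip(1L))
  for (j in seq_len(k)[-1]) {
    topos <- unlist(lapply(topos, function(tp) {
      lapply(seq_len(local_n_edges(tp)), function(e) local_insert(tp, e, j))
    }), recursive = FALSE)
  }
  topos
}

# Rebuild `truth` with each occupied internal node replaced according to the
# chosen local topology. `choices` maps node index (as character) to a local
# topology on m + c units (occupants first, then children in stored order).
resolve_with_choices <- function(truth, choices, extra_blen = 0) {
  build <- function(i) {
    kids <- lapply(truth$children[[i]], build)
    m <- length(truth$names[[i]])
    c_ <- length(kids)
    bl <- if (i == truth$root) NULL else truth$blen[i]
    if (c_ == 0L || m == 0L) {
      return(list(names = truth$names[[i]], blen = bl, day = truth$day[i],
                  children = kids))
    }
    topo <- choices[[as.character(i)]]
    unit_node <- function(j) {
      if (j <= m)
        list(names = truth$names[[i]][j], blen = extra_blen,
             day = truth$day[i], children = list())
      else
        kids[[j - m]]
    }
    materialize <- function(tp, top) {
      if (!is.null(tp$unit)) {
        nd <- unit_node(tp$unit)
        if (top) nd$blen <- bl
        return(nd)
      }
      list(names = character(0),
           blen = if (top) bl else extra_blen,
           day = NA_integer_,
           children = list(materialize(tp$kids[[1]], FALSE),
                           materialize(tp$kids[[2]], FALSE)))
    }
    materialize(topo, TRUE)
  }
  tree_from_nested(build(truth$root))
}

occupied_internal <- function(truth) {
  which(lengths(truth$children) > 0L & lengths(truth$names) > 0L)
}

check_resolvable <- function(truth) {
  occ <- occupied_internal(truth)
  bad <- occ[lengths(truth$children[occ]) != 2L]
  if (length(bad))
    stop("unsupported shape: occupied internal node(s) with != 2 children ",
         "(node ", paste(bad, collapse = ", "), ")", call. = FALSE)
  occ
}

#' Randomly resolve ancestral occupants as leaves
#'
#' Converts a tree with sampled ancestors on internal nodes into a
#' bifurcating leaf-only tree of the kind standard phylogenetic methods
#' produce: each internal occupant is detached and re-attached as a leaf on
#' a branch of length `extra_blen`, in one of the three equally good
#' configurations for a single occupant with two children (sister to the
#' left child, sister to the right child, or outgroup to both), chosen
#' uniformly and independently per node. Nodes holding several co-located
#' occupants are resolved uniformly among all rooted bifurcating
#' arrangements of occupants plus children (15 for two occupants and two
#' children). With `extra_blen = 0`, collapsing the result at cutoff 0
#' reconstructs the input exactly.
#'
#' @param truth A [labeled_tree()]; every occupied internal node must have
#'   exactly two children.
#' @param seed Optional integer; when given, the RNG state is set locally
#'   and restored on exit, so the resolution is reproducible.
#' @param extra_blen Length of the newly created branches (default 0).
#' @return A leaf-only bifurcating [labeled_tree()] with the same names.
#' @examples
#' t <- build_design_tree(2)
#' resolve_random(t, seed = 1)
#' @export
resolve_random <- function(truth, seed = NULL, extra_blen = 0) {
  stopifnot(extra_blen >= 0)
  occ <- check_resolvable(truth)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  choices <- list()
  for (i in occ) {
    k <- length(truth$names[[i]]) + length(truth$children[[i]])
    choices[[as.character(i)]] <- random_local_topology(k)
  }
  resolve_with_choices(truth, choices, extra_blen)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Enumerate all leaf-only resolutions of an ancestral tree
#'
#' Exhaustively generates every bifurcating leaf-only tree obtainable by
#' resolving the occupants of each occupied internal node, i.e. the
#' [count_resolutions()] equally good trees. Intended for small trees
#' (the count grows as 3 per occupied node); used as the brute-force oracle
#' for the resolution combinatorics.
#'
#' @inheritParams resolve_random
#' @return A list of [labeled_tree()] objects of length
#'   `count_resolutions(truth)`.
#' @export
enumerate_resolutions <- function(truth, extra_blen = 0) {
  occ <- check_resolvable(truth)
  if (!length(occ)) return(list(truth))
  per_node <- lapply(occ, function(i) {
    enumerate_local_topologies(length(truth$names[[i]]) +
                                 length(truth$children[[i]]))
  })
  idx <- lapply(per_node, seq_along)
  grid <- expand.grid(idx, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(r) {
    choices <- stats::setNames(
      lapply(seq_along(occ), function(j) per_node[[j]][[grid[r, j]]]),
      as.character(occ))
    resolve_with_choices(truth, choices, extra_blen)
  })
}
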