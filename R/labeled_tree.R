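#' Labeled rooted trees
#'
#' A `labeled_tree` is a rooted tree whose every node carries a (possibly
#' empty, possibly multi-element) set of sample names and a branch length to
#' its parent. It is the single container shared by known design trees,
#' inferred trees read from Newick, and collapsed trees, and it deliberately
#' admits shapes that leaf-centric phylogenetic containers reject: named
#' internal nodes, anonymous internal nodes, nodes holding several names
#' (created by collapsing chains of short branches), internal nodes with a
#' single child, and negative branch lengths (distance methods occasionally
#' emit them).
#'
#' @param parent Integer vector; `parent[i]` is the index of node `i`'s
#'   parent, `0L` for the root. Exactly one node must have parent `0L`.
#' @param children List of integer vectors; `children[[i]]` are the child
#'   indices of node `i` in display order. Must be consistent with `parent`.
#' @param names List of character vectors; `names[[i]]` is the ordered set of
#'   sample names at node `i` (`character(0)` for anonymous nodes). A sample
#'   name may appear at most once in the whole tree.
#' @param blen Numeric vector of branch lengths to the parent; the root's
#'   entry is ignored (stored as `NA`). Negative lengths are allowed and are
#'   never clamped.
#' @param day Optional integer vector of sampling days (`NA` when unknown).
#'
#' @return An object of class `labeled_tree`: a list with fields `parent`,
#'   `children`, `names`, `blen`, `day` and `root` (index of the root node).
#' @seealso [parse_newick()], [build_design_tree()], [collapse_fixed()]
#' @export
labeled_tree <- function(parent, children, names, blen,
                         day = rep(NA_integer_, length(parent))) {
  tree <- structure(
    list(parent = as.integer(parent),
         children = children,
         names = names,
         blen = as.numeric(blen),
         day = as.integer(day),
         root = which(as.integer(parent) == 0L)[1]),
    class = "labeled_tree")
  validate_labeled_tree(tree)
  tree
}

validate_labeled_tree <- function(tree) {
  n <- length(tree$parent)
  if (n < 1L) stop("a labeled_tree needs at least one node", call. = FALSE)
  roots <- which(tree$parent == 0L)
  if (length(roots) != 1L)
    stop("tree must have exactly one root, found ", length(roots), call. = FALSE)
  if (length(tree$children) != n || length(tree$names) != n ||
      length(tree$blen) != n || length(tree$day) != n)
    stop("field lengths disagree with node count", call. = FALSE)
  # parent/children consistency
  for (i in seq_len(n)) {
    for (k in tree$children[[i]]) {
      if (k < 1L || k > n || tree$parent[k] != i)
        stop("children/parent relation inconsistent at node ", i, call. = FALSE)
    }
  }
  # connectivity + acyclicity: walk down from the root
  seen <- logical(n)
  stack <- roots
  while (length(stack)) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (seen[i]) stop("cycle detected in tree", call. = FALSE)
    seen[i] <- TRUE
    stack <- c(stack, tree$children[[i]])
  }
  if (!all(seen))
    stop("tree is not connected: ", sum(!seen), " unreachable node(s)", call. = FALSE)
  nm <- unlist(tree$names, use.names = FALSE)
  if (anyDuplicated(nm))
    stop("duplicate sample name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  invisible(tree)
}

#' Basic tree accessors
#'
#' `n_nodes()` and `n_leaves()` count nodes and leaves (nodes without
#' children); `tree_names()` returns all sample names in the tree;
#' `leaf_indices()` returns the node indices of the leaves.
#'
#' @param tree A `labeled_tree`.
#' @return An integer count, or a character vector for `tree_names()`.
#' @export
n_nodes <- function(tree) length(tree$parent)

#' @rdname n_nodes
#' @export
n_leaves <- function(tree) sum(lengths(tree$children) == 0L)

#' @rdname n_nodes
#' @export
leaf_indices <- function(tree) which(lengths(tree$children) == 0L)

#' @rdname n_nodes
#' @export
tree_names <- function(tree) unlist(tree$names, use.names = FALSE)

#' Compare two labeled trees for equality
#'
#' Trees are compared as rooted trees with name sets on nodes: equal when a
#' bijection of nodes preserves the parent relation and every node's name
#' set. Child order is ignored (it carries no information). Branch lengths
#' are compared only when `use_blen = TRUE`, to `tol`.
#'
#' @param a,b `labeled_tree` objects.
#' @param use_blen Compare branch lengths as well as shape and names.
#' @param tol Absolute tolerance on branch lengths when `use_blen = TRUE`.
#' @return `TRUE` or `FALSE`.
#' @export
tree_equal <- function(a, b, use_blen = FALSE, tol = 1e-9) {
  canonical_form(a, use_blen = use_blen, tol = tol) ==
    canonical_form(b, use_blen = use_blen, tol = tol)
}

# Canonical serialization: children sorted by their own canonical strings,
# so the form is invariant to child order.
canonical_form <- function(tree, use_blen = FALSE, tol = 1e-9) {
  rec <- function(i) {
    label <- paste(sort(tree$names[[i]]), collapse = "|")
    kids <- vapply(tree$children[[i]], rec, character(1))
    body <- if (length(kids)) paste0("(", paste(sort(kids), collapse = ","), ")") else ""
    bl <- ""
    if (use_blen && i != tree$root)
      bl <- paste0(":", format(round(tree$blen[i] / tol) * tol, digits = 15))
    paste0(body, label, bl)
  }
  rec(tree$root)
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat(sprintf("labeled_tree: %d nodes, %d leaves, %d named node(s)\n",
              n_nodes(x), n_leaves(x), sum(lengths(x$names) > 0L)))
  nm <- tree_names(x)
  if (length(nm))
    cat("  names: ", paste(utils::head(nm, 8), collapse = ", "),
        if (length(nm) > 8) ", ..." else "", "\n", sep = "")
  cat("  newick: ", abbreviate_string(write_newick(x), 70), "\n", sep = "")
  invisible(x)
}

abbreviate_string <- function(s, width) {
  if (nchar(s) <= width) s else paste0(substr(s, 1, width - 3), "...")
}

# Internal builder used by operations that construct trees recursively from
# nested node lists: node = list(names=, blen=, day=, children=list(...)).
tree_from_nested <- function(nested) {
  parent <- integer(0); children <- list(); names <- list()
  blen <- numeric(0); day <- integer(0)
  add <- function(node, parent_idx) {
    idx <- length(parent) + 1L
    parent[idx] <<- parent_idx
    children[[idx]] <<- integer(0)
    names[[idx]] <<- as.character(node$names)
    blen[idx] <<- if (is.null(node$blen)) NA_real_ else as.numeric(node$blen)
    day[idx] <<- if (is.null(node$day)) NA_integer_ else as.integer(node$day)
    if (parent_idx > 0L)
      children[[parent_idx]] <<- c(children[[parent_idx]], idx)
    for (ch in node$children) add(ch, idx)
    idx
  }
  add(nested, 0L)
  labeled_tree(parent, children, names, blen, day)
}
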