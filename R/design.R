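#' Parameters of the serial-passage experiment
#'
#' The experiment grows a culture for `days` days; each day every growing
#' culture is split into `split` daughter cultures and a sample is taken.
#' The founder sample is named `root_name` (the convention names descendants
#' by appending the daughter index: S, then S1 and S2, then S11, S12, S21,
#' S22, and so on), so the schedule itself fixes a known phylogeny in which
#' every sampled ancestor sits at an internal node.
#'
#' @param days Number of days (integer >= 1).
#' @param split Daughters per culture per day (integer >= 2; the experiment
#'   modeled here used 2).
#' @param root_name Name of the founder sample (default `"S"`).
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(days, split = 2L, root_name = "S") {
  days <- as.integer(days); split <- as.integer(split)
  if (is.na(days) || days < 1L) stop("days must be an integer >= 1", call. = FALSE)
  if (is.na(split) || split < 2L) stop("split must be an integer >= 2", call. = FALSE)
  if (!is.character(root_name) || !nzchar(root_name))
    stop("root_name must be a non-empty string", call. = FALSE)
  structure(list(days = days, split = split, root_name = root_name),
            class = "experiment_design")
}

as_design <- function(design) {
  if (inherits(design, "experiment_design")) return(design)
  if (is.numeric(design)) return(experiment_design(design))
  stop("design must be an experiment_design or a day count", call. = FALSE)
}

#' Build the known design tree ("ideal tree") of the experiment
#'
#' Every node sampled on day `d` (1-based) carries exactly one name; node
#' `X`'s children are named `X1`, `X2`, ... up to `split`. Branch lengths are
#' 1.0 (one day per split) and `day` is recorded on every node. With 8 days
#' and binary splits the tree has 255 nodes: 128 leaves and 127 internal
#' nodes, all of them named - the defining feature of a sampled-ancestor
#' benchmark.
#'
#' @param design An [experiment_design()] (or a day count, for convenience).
#' @return A [labeled_tree()] in which every node is singly named.
#' @examples
#' build_design_tree(experiment_design(days = 3))
#' @export
build_design_tree <- function(design) {
  design <- as_design(design)
  d <- design$days; s <- design$split
  n <- as.integer((s^d - 1) / (s - 1))
  parent <- integer(n); children <- vector("list", n)
  names_ <- vector("list", n); blen <- rep(1, n); day <- integer(n)
  names_[[1]] <- design$root_name; day[1] <- 1L; blen[1] <- NA_real_
  children[] <- list(integer(0))
  nxt <- 2L
  # breadth-first: nodes are laid out day by day
  frontier <- 1L
  for (dd in seq_len(d - 1L)) {
    new_frontier <- integer(0)
    for (p in frontier) {
      kid_idx <- nxt + seq_len(s) - 1L
      children[[p]] <- kid_idx
      for (j in seq_len(s)) {
        k <- kid_idx[j]
        parent[k] <- p
        names_[[k]] <- paste0(names_[[p]], j)
        day[k] <- dd + 1L
      }
      nxt <- nxt + s
      new_frontier <- c(new_frontier, kid_idx)
    }
    frontier <- new_frontier
  }
  labeled_tree(parent, children, names_, blen, day)
}

#' Per-day sample counts of a design
#'
#' Element `d` is the number of cultures sampled on day `d`:
#' `split^(d-1)`. The sum equals the total node count of the design tree
#' (255 for 8 days of binary splitting: 1, 2, 4, ..., 128).
#'
#' @param design An [experiment_design()].
#' @return Integer vector of length `days`.
#' @export
sample_counts <- function(design) {
  design <- as_design(design)
  as.integer(design$split^(seq_len(design$days) - 1L))
}

#' Day of a sample from its design name
#'
#' Under the naming convention the day is the name length beyond the root
#' name plus one (`S` is day 1, `S21` is day 3).
#'
#' @param name Character vector of design names.
#' @param root_name The founder's name.
#' @return Integer vector of sampling days.
#' @export
design_day_from_name <- function(name, root_name = "S") {
  as.integer(nchar(name) - nchar(root_name) + 1L)
}

#' Restrict a known tree to the observed (sequenced) samples
#'
#' Models partial sequencing success: only `observed` samples have genome
#' sequences, so the benchmark tree must describe the relationships among
#' those alone. Every node none of whose names was observed is dissolved -
#' its children re-attach to the nearest surviving ancestor with branch
#' lengths summed along the dissolved path - so each surviving branch spans
#' the full path between consecutive observed samples. The root is special:
#' when unobserved it is kept as an anonymous node if at least two observed
#' lineages descend from it (keeping the clade set well defined); with a
#' single surviving lineage the chain is contracted and the earliest
#' surviving node becomes the root. No re-rooting beyond that is attempted.
#'
#' @param tree A [labeled_tree()].
#' @param observed Character vector of observed sample names (must all occur
#'   in `tree`).
#' @return A [labeled_tree()] carrying exactly the observed names.
#' @export
restrict_to_observed <- function(tree, observed) {
  observed <- as.character(observed)
  known <- tree_names(tree)
  unknown <- setdiff(observed, known)
  if (length(unknown))
    stop("observed name(s) not in tree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!length(observed)) stop("observed set is empty", call. = FALSE)

  # returns a list of nested subtrees to hang from the nearest kept ancestor
  rec <- function(i, acc) {
    bl <- if (i == tree$root) NA_real_ else tree$blen[i]
    keep_names <- intersect(tree$names[[i]], observed)
    if (length(keep_names)) {
      kids <- unlist(lapply(tree$children[[i]], rec, acc = 0), recursive = FALSE)
      list(list(names = keep_names, blen = bl + acc, day = tree$day[i],
                children = kids))
    } else {
      unlist(lapply(tree$children[[i]], rec, acc = acc + bl), recursive = FALSE)
    }
  }

  root <- tree$root
  if (length(intersect(tree$names[[root]], observed))) {
    nested <- rec(root, 0)[[1]]
    nested$blen <- NULL
  } else {
    kids <- unlist(lapply(tree$children[[root]], rec, acc = 0), recursive = FALSE)
    if (length(kids) == 0L) stop("no observed samples under the root", call. = FALSE)
    if (length(kids) >= 2L) {
      nested <- list(names = character(0), blen = NULL, day = NA_integer_,
                     children = kids)
    } else {
      nested <- kids[[1]]
      nested$blen <- NULL
    }
  }
  tree_from_nested(nested)
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("experiment_design: %d days, %d-way daily splits, root '%s'\n",
              x$days, x$split, x$root_name))
  cat("  samples/day: ", paste(sample_counts(x), collapse = ", "),
      " (total ", sum(sample_counts(x)), ")\n", sep = "")
  invisible(x)
}
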