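ACGT <- c("A", "C", "G", "T")
ACGT_CODES <- utf8ToInt("ACGT")

#' Simulate the serial-passage mutation-accumulation experiment
#'
#' Generates consensus genome sequences with the statistical structure of an
#' in vitro evolution experiment on a hypermutator strain: a founder genome
#' grows for `days` days, the culture is split `split` ways daily, and each
#' daughter's consensus accrues `K ~ Poisson(mu)` substitutions at distinct
#' positions (the consensus of a daily bottlenecked population - within-day
#' double hits are not modeled, across days a site can mutate again). The
#' substitution spectrum is mutT-like: with probability `at_to_gc_bias` a
#' mutation picks an A or T site and applies A->C / T->G; otherwise a uniform
#' site changes to a uniform different base. Sequencing success is partial:
#' each sample is observed independently with probability `seq_success_prob`
#' (the motivating experiment sequenced 101 of its 255 samples), or an
#' explicit `observed_names` list can be supplied.
#'
#' Defaults mirror that experiment: 8 days of binary splits, 3.3 mutations
#' per genome per day (the rate observed there; the plate-assay expectation
#' was about 5.4), bias 0.9, success probability 101/255. The default
#' 100 kb genome keeps homoplasy negligible at desk scale; use 4.6e6 for a
#' realistically sized E. coli genome.
#'
#' @param days,split,root_name Design parameters, as [experiment_design()].
#' @param genome_length Genome length in bases (>= 1).
#' @param mu Expected mutations per genome per day (>= 0).
#' @param at_to_gc_bias Probability a mutation is an A->C / T->G change.
#' @param seq_success_prob Probability each sample yields a sequence.
#' @param observed_names Optional explicit set of observed sample names
#'   (overrides `seq_success_prob`).
#' @param root_genome Optional founder genome string; drawn uniformly over
#'   A/C/G/T when `NULL`.
#' @param fixed_count When `TRUE`, every branch receives exactly
#'   `round(mu)` mutations instead of a Poisson draw - an underdispersion
#'   mimic (observed per-day counts in such experiments can vary less than
#'   Poisson).
#' @param seed Optional integer seed; RNG state is restored on exit.
#' @return An object of class `simulated_experiment`: list with
#'   `sequences` (named character vector, all samples), `truth` (a
#'   [labeled_tree()] whose branch lengths are realized mutation counts),
#'   `metadata` (data frame: name, day, observed, realized_branch_muts) and
#'   `config`.
#' @examples
#' sim <- simulate_experiment(days = 3, genome_length = 1000, seed = 1)
#' sim$metadata
#' @export
simulate_experiment <- function(days = 8, split = 2, root_name = "S",
                                genome_length = 1e5, mu = 3.3,
                                at_to_gc_bias = 0.9,
                                seq_success_prob = 101 / 255,
                                observed_names = NULL,
                                root_genome = NULL,
                                fixed_count = FALSE,
                                seed = NULL) {
  design <- experiment_design(days, split, root_name)
  genome_length <- as.integer(genome_length)
  if (is.na(genome_length) || genome_length < 1L)
    stop("genome_length must be >= 1", call. = FALSE)
  if (mu < 0) stop("mu must be >= 0", call. = FALSE)
  if (at_to_gc_bias < 0 || at_to_gc_bias > 1 ||
      seq_success_prob < 0 || seq_success_prob > 1)
    stop("probabilities must be in [0, 1]", call. = FALSE)
  if (genome_length < mu * 10)
    warning("genome_length < 10 * mu: homoplasy within branches is no ",
            "longer negligible", call. = FALSE)

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }

  tree <- build_design_tree(design)
  n <- n_nodes(tree)
  if (is.null(root_genome)) {
    root_codes <- sample(ACGT_CODES, genome_length, replace = TRUE)
  } else {
    stopifnot(is.character(root_genome), length(root_genome) == 1L)
    if (nchar(root_genome) != genome_length)
      genome_length <- nchar(root_genome)
    root_codes <- utf8ToInt(root_genome)
    if (!all(root_codes %in% ACGT_CODES))
      stop("root_genome must contain only A/C/G/T", call. = FALSE)
  }

  sequences <- character(n)
  realized <- numeric(n)
  # DFS carrying the genome down the tree; per-node deltas relative to the
  # parent keep memory at one working genome plus the output strings
  rec <- function(i, codes) {
    sequences[i] <<- intToUtf8(codes)
    for (k in tree$children[[i]]) {
      K <- if (fixed_count) round(mu) else stats::rpois(1L, mu)
      if (K > genome_length)
        stop("drawn mutation count exceeds genome length", call. = FALSE)
      realized[k] <<- K
      rec(k, mutate_codes(codes, K, at_to_gc_bias))
    }
  }
  # deep trees would exhaust the C stack only far beyond this design's size
  rec(tree$root, root_codes)

  nm <- vapply(tree$names, `[`, character(1), 1L)
  names(sequences) <- nm
  truth <- tree
  truth$blen <- realized
  truth$blen[truth$root] <- NA_real_

  if (!is.null(observed_names)) {
    unknown <- setdiff(observed_names, nm)
    if (length(unknown))
      stop("observed_names not in design: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    observed <- nm %in% observed_names
  } else {
    observed <- stats::runif(n) < seq_success_prob
  }

  metadata <- data.frame(name = nm, day = tree$day, observed = observed,
                         realized_branch_muts = ifelse(seq_along(nm) == tree$root,
                                                       NA, realized),
                         stringsAsFactors = FALSE)
  structure(list(sequences = sequences, truth = truth, metadata = metadata,
                 config = list(days = design$days, split = design$split,
                               root_name = design$root_name,
                               genome_length = genome_length, mu = mu,
                               at_to_gc_bias = at_to_gc_bias,
                               seq_success_prob = seq_success_prob,
                               fixed_count = fixed_count, seed = seed)),
            class = "simulated_experiment")
}

# Core mutation step on an integer (UTF-8 code) genome vector: exactly n_mut
# distinct positions change.
mutate_codes <- function(codes, n_mut, at_to_gc_bias) {
  if (n_mut == 0L) return(codes)
  L <- length(codes)
  if (n_mut > L) stop("n_mut exceeds genome length", call. = FALSE)
  A <- ACGT_CODES[1]; C <- ACGT_CODES[2]; G <- ACGT_CODES[3]; T <- ACGT_CODES[4]
  at_pool <- which(codes == A | codes == T)
  used <- logical(L)
  warned <- FALSE
  for (j in seq_len(n_mut)) {
    biased <- at_to_gc_bias > 0 && stats::runif(1) < at_to_gc_bias
    if (biased && length(at_pool)) {
      k <- if (length(at_pool) == 1L) 1L else sample.int(length(at_pool), 1L)
      pos <- at_pool[k]
      at_pool <- at_pool[-k]
      codes[pos] <- if (codes[pos] == A) C else G
      used[pos] <- TRUE
    } else {
      if (biased && !warned) {
        warning("no unused A/T site left; falling back to unbiased mutation",
                call. = FALSE)
        warned <- TRUE
      }
      repeat {
        pos <- sample.int(L, 1L)
        if (!used[pos]) break
      }
      old <- codes[pos]
      codes[pos] <- sample(setdiff(ACGT_CODES, old), 1L)
      used[pos] <- TRUE
      at_pool <- at_pool[at_pool != pos]
    }
  }
  codes
}

#' Apply point mutations to a genome string
#'
#' Exactly `n_mut` distinct positions are substituted. With probability
#' `at_to_gc_bias` each mutation picks an unused A or T site and applies the
#' mutT-lesion change A->C (T->G on the complementary-strand convention);
#' otherwise a uniformly chosen unused site changes to a uniformly chosen
#' different base. When the bias is positive but no unused A/T site remains,
#' the mutation falls back to unbiased with a warning.
#'
#' @param seq Genome string over A/C/G/T.
#' @param n_mut Number of substitutions (<= nchar(seq)).
#' @param at_to_gc_bias Probability in `[0, 1]` of the biased change.
#' @return The mutated genome string.
#' @examples
#' mutate_genome("AAAA", 4, at_to_gc_bias = 1)  # "CCCC"
#' @export
mutate_genome <- function(seq, n_mut, at_to_gc_bias = 0.9) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (at_to_gc_bias < 0 || at_to_gc_bias > 1)
    stop("at_to_gc_bias must be in [0, 1]", call. = FALSE)
  intToUtf8(mutate_codes(utf8ToInt(seq), as.integer(n_mut), at_to_gc_bias))
}

#' Count differing positions between two equal-length genomes
#'
#' Positions where either sequence carries a non-A/C/G/T symbol (e.g. `N`)
#' are skipped; the number of skipped positions is attached as attribute
#' `"skipped"`.
#'
#' @param seq_a,seq_b Genome strings of equal length.
#' @return Integer count of differing unambiguous positions, with attribute
#'   `skipped`.
#' @examples
#' hamming_diffs("ACGT", "ACCT")  # 1
#' @export
hamming_diffs <- function(seq_a, seq_b) {
  a <- utf8ToInt(seq_a); b <- utf8ToInt(seq_b)
  if (length(a) != length(b))
    stop("sequences have unequal lengths (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  valid <- (a %in% ACGT_CODES) & (b %in% ACGT_CODES)
  structure(sum(a[valid] != b[valid]), skipped = sum(!valid))
}

#' Write simulated experiment outputs
#'
#' Writes the observed samples' sequences as FASTA, the realized true tree
#' and the design-time tree as Newick, and the per-sample metadata as TSV.
#'
#' @param sim A `simulated_experiment`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_experiment <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  obs <- sim$metadata$name[sim$metadata$observed]
  paths <- c(fasta = file.path(dir, "observed.fasta"),
             truth = file.path(dir, "truth.nwk"),
             design = file.path(dir, "design.nwk"),
             metadata = file.path(dir, "metadata.tsv"))
  seqs <- Biostrings::DNAStringSet(sim$sequences[obs])
  Biostrings::writeXStringSet(seqs, paths["fasta"])
  write_newick(sim$truth, paths["truth"])
  design <- build_design_tree(experiment_design(sim$config$days,
                                                sim$config$split,
                                                sim$config$root_name))
  write_newick(design, paths["design"])
  utils::write.table(sim$metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a FASTA file as a named vector of genome strings
#'
#' @param file Path to a FASTA file.
#' @return Named character vector.
#' @export
read_fasta_sequences <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  stats::setNames(as.character(x), names(x))
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat(sprintf(
    "simulated_experiment: %d samples (%d observed), %d bp genomes, mu = %g/day\n",
    nrow(x$metadata), sum(x$metadata$observed), x$config$genome_length,
    x$config$mu))
  cat(sprintf("  realized mutations: mean %.2f per branch\n",
              mean(x$metadata$realized_branch_muts, na.rm = TRUE)))
  invisible(x)
}
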