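test_that("mutate_genome applies exactly n_mut substitutions with the mutT spectrum", {
  expect_equal(mutate_genome("ACGT", 0), "ACGT")
  expect_equal(mutate_genome("AAAA", 4, at_to_gc_bias = 1), "CCCC")
  expect_equal(mutate_genome("TTTT", 4, at_to_gc_bias = 1), "GGGG")

  set.seed(31)
  g <- paste(sample(c("A", "C", "G", "T"), 2e4, replace = TRUE), collapse = "")
  m <- mutate_genome(g, 500, at_to_gc_bias = 1)
  a <- strsplit(g, "")[[1]]; b <- strsplit(m, "")[[1]]
  changed <- which(a != b)
  expect_equal(length(changed), 500L)
  # fully biased spectrum: only A->C and T->G
  expect_true(all((a[changed] == "A" & b[changed] == "C") |
                    (a[changed] == "T" & b[changed] == "G")))

  m0 <- mutate_genome(g, 300, at_to_gc_bias = 0)
  b0 <- strsplit(m0, "")[[1]]
  expect_equal(sum(a != b0), 300L)

  # bias > 0 with no A/T sites falls back with a warning
  expect_warning(out <- mutate_genome("CCGG", 2, at_to_gc_bias = 1),
                 "falling back")
  expect_equal(sum(strsplit(out, "")[[1]] != c("C", "C", "G", "G")), 2L)
  expect_error(mutate_genome("ACGT", 5), "exceeds genome length")
})

test_that("hamming_diffs counts unambiguous mismatches and reports skips", {
  expect_equal(as.integer(hamming_diffs("ACGT", "ACGT")), 0L)
  expect_equal(as.integer(hamming_diffs("ACGT", "ACCT")), 1L)
  d <- hamming_diffs("ANGT", "ACCT")
  expect_equal(as.integer(d), 1L)
  expect_equal(attr(d, "skipped"), 1L)
  expect_error(hamming_diffs("ACG", "ACGT"), "unequal")
})

test_that("simulate_experiment mirrors the design and its bookkeeping", {
  sim <- simulate_experiment(days = 8, genome_length = 2000, mu = 0.5,
                             seed = 5)
  expect_equal(length(sim$sequences), 255L)
  expect_equal(nrow(sim$metadata), 255L)
  expect_true(tree_equal(sim$truth, build_design_tree(8)))  # names + shape
  expect_equal(sim$metadata$day, build_design_tree(8)$day)

  # mu = 0: everything identical, all realized branch lengths 0
  sim0 <- simulate_experiment(days = 3, genome_length = 500, mu = 0, seed = 1)
  expect_equal(length(unique(sim0$sequences)), 1L)
  expect_true(all(sim0$truth$blen[-sim0$truth$root] == 0))

  # determinism: same seed, byte-identical sequences
  a <- simulate_experiment(days = 3, genome_length = 300, seed = 11)
  b <- simulate_experiment(days = 3, genome_length = 300, seed = 11)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$metadata, b$metadata)

  # explicit observed list is honored exactly
  obs <- c("S", "S11", "S22")
  s2 <- simulate_experiment(days = 3, genome_length = 300, seed = 2,
                            observed_names = obs)
  expect_setequal(s2$metadata$name[s2$metadata$observed], obs)
  expect_error(simulate_experiment(days = 2, genome_length = 100, seed = 1,
                                   observed_names = "Z"), "not in design")
  expect_warning(simulate_experiment(days = 2, genome_length = 40, mu = 5,
                                     seed = 1), "homoplasy")
})

test_that("parent-child hamming distances equal realized branch counts", {
  sim <- simulate_experiment(days = 5, genome_length = 5e4, mu = 3.3,
                             seed = 9)
  tr <- sim$truth
  nm <- vapply(tr$names, `[`, character(1), 1L)
  ok <- 0L; total <- 0L
  for (i in seq_along(tr$parent)) {
    p <- tr$parent[i]
    if (p == 0L) next
    d <- as.integer(hamming_diffs(sim$sequences[[nm[i]]], sim$sequences[[nm[p]]]))
    expect_lte(d, tr$blen[i])  # homoplasy can only reduce the distance
    total <- total + 1L
    if (d == tr$blen[i]) ok <- ok + 1L
  }
  # at 50 kb and ~3.3 mutations/branch, within-path double hits are rare
  expect_gte(ok / total, 0.95)
})

test_that("pairwise distances are bounded by path sums of realized counts", {
  sim <- simulate_experiment(days = 4, genome_length = 2e4, mu = 4, seed = 13)
  tr <- sim$truth
  nm <- vapply(tr$names, `[`, character(1), 1L)
  path_to_root <- function(i) {
    out <- integer(0)
    while (tr$parent[i] != 0L) { out <- c(out, i); i <- tr$parent[i] }
    out
  }
  set.seed(1)
  pairs <- replicate(10, sample(seq_along(nm), 2), simplify = FALSE)
  for (pr in pairs) {
    pa <- path_to_root(pr[1]); pb <- path_to_root(pr[2])
    path_sum <- sum(tr$blen[setdiff(pa, pb)]) + sum(tr$blen[setdiff(pb, pa)])
    d <- as.integer(hamming_diffs(sim$sequences[[nm[pr[1]]]],
                                  sim$sequences[[nm[pr[2]]]]))
    expect_lte(d, path_sum)
  }
})

test_that("per-branch mutation counts behave like Poisson(mu) draws", {
  mu <- 3.3
  counts <- unlist(lapply(1:8, function(s) {
    sim <- simulate_experiment(days = 6, genome_length = 1000, mu = mu,
                               seed = 100 + s)
    sim$metadata$realized_branch_muts[-1]
  }))
  n <- length(counts)            # 8 x 62 = 496 branches
  se <- sqrt(mu / n)
  expect_lt(abs(mean(counts) - mu), 3 * se)
  # dispersion index of Poisson counts is ~1
  expect_lt(abs(stats::var(counts) / mean(counts) - 1), 0.25)
  # fixed-count mode: no within-branch variance at integer mu
  simf <- simulate_experiment(days = 5, genome_length = 1000, mu = 3,
                              fixed_count = TRUE, seed = 3)
  expect_true(all(simf$metadata$realized_branch_muts[-1] == 3))
})

test_that("sequencing success filters samples binomially", {
  p <- 101 / 255
  obs <- vapply(1:20, function(s) {
    sim <- simulate_experiment(days = 6, genome_length = 50, mu = 0,
                               seq_success_prob = p, seed = 200 + s)
    sum(sim$metadata$observed)
  }, numeric(1))
  total <- 63 * 20
  se <- sqrt(p * (1 - p) * total)
  expect_lt(abs(sum(obs) - p * total), 4 * se)
})

test_that("experiment outputs round-trip through FASTA/Newick/TSV", {
  sim <- simulate_experiment(days = 3, genome_length = 400, mu = 2, seed = 21,
                             seq_success_prob = 1)
  dir <- withr::local_tempdir()
  paths <- write_experiment(sim, dir)
  seqs <- read_fasta_sequences(paths["fasta"])
  expect_equal(seqs[names(sim$sequences)], sim$sequences)
  expect_true(tree_equal(read_newick(paths["truth"]), sim$truth,
                         use_blen = TRUE))
  md <- utils::read.delim(paths["metadata"])
  expect_equal(md$name, sim$metadata$name)
})
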