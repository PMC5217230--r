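Package: phylobench
Title: Benchmarking Whole-Genome Phylogenies Against a Known Sampled-Ancestor Tree
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking whole-genome phylogeny reconstruction
    against a known experiment-design phylogeny that contains sampled
    ancestors. Provides a labeled-tree container whose internal nodes may
    carry sample names, generation of the serial-passage design tree,
    collapsing of short branches so sequences can occupy internal nodes
    (fixed cutoff and adaptive target-leaf-count strategies), two
    labeled-tree similarity measures (parent-child relations and labeled
    clades), enumeration of the ancestral-placement resolutions of
    bifurcating leaf-only trees, a mutation-accumulation simulator for a
    hypermutator serial-passage experiment (Poisson substitutions per genome
    per day with an AT-to-GC biased spectrum), and mutation-rate estimators
    including the diffs-to-root per-day estimator and plate-assay fold-change
    arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
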