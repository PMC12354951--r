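Package: guidegraph
Title: Guide RNA Editing-Efficiency Prediction with Sequence-and-Structure Graphs
Version: 0.1.0
Authors@R:
    person("Maintainer", "guidegraph", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Represents each single guide RNA (sgRNA) as a graph whose nodes
    are nucleotides and whose edges combine backbone adjacency (sequential
    edges) with secondary-structure base pairs (structural edges), and fits a
    graph-attention regression network to predict editing efficiency on the
    0-100 percent scale. Includes a self-contained Nussinov-style base-pair
    maximization predictor for dot-bracket secondary structures, readers for
    guide tables, FASTA and Vienna structure files, per-nucleotide embedding
    matrices, train/test machinery with sequence-similarity redundancy
    filtering and label-permutation significance tests, attention-based
    per-position importance profiles, and a synthetic-data generator with a
    planted efficiency function for end-to-end testing.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
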