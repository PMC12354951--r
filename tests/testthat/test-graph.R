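test_that("one_hot_features follows the fixed A/C/G/U column order", {
  expect_equal(one_hot_features("A"), matrix(c(1, 0, 0, 0), 1,
                                             dimnames = list(NULL, c("A", "C", "G", "U"))))
  expect_equal(unname(one_hot_features("T")[1, ]), c(0, 0, 0, 1))  # T -> U
  expect_equal(unname(one_hot_features("acgu")),
               diag(4))                                            # case folding
  expect_error(one_hot_features("N"), class = "gg_format_error")
  expect_equal(unname(one_hot_features("N", ambiguity = "uniform")[1, ]), rep(0.25, 4))
  m <- one_hot_features("GGAUCCA")
  expect_equal(rowSums(m), rep(1, 7))
})

test_that("embedding loader enforces ids and shapes", {
  mats <- list(g1 = matrix(rnorm(20 * 6), 20), g2 = matrix(rnorm(20 * 6), 20))
  path <- tempfile()
  write_embedding_features(mats, path)

  back <- load_embedding_features(path, c("g2", "g1"), lengths = c(20L, 20L))
  expect_identical(names(back), c("g2", "g1"))
  expect_equal(back$g1, mats$g1, tolerance = 1e-12)

  expect_identical(load_embedding_features(path, character(0)),
                   setNames(list(), character(0)))
  expect_error(load_embedding_features(path, c("g1", "gX")),
               class = "gg_format_error", regexp = "gX")
  expect_error(load_embedding_features(path, "g1", lengths = 19L),
               class = "gg_contract_error", regexp = "g1")
})

test_that("build_edges emits reciprocal typed arcs in stable order", {
  chain <- build_edges(20L, parse_dot_bracket(strrep(".", 20)))
  expect_equal(nrow(chain), 38L)
  expect_true(all(chain$type == "sequential"))
  expect_true(all(abs(chain$src - chain$dst) == 1L))

  s <- parse_dot_bracket("((...))")
  arcs <- build_edges(7L, s)
  expect_equal(sum(arcs$type == "sequential"), 12L)
  expect_equal(sum(arcs$type == "structural"), 4L)
  # reciprocal arcs for every undirected edge
  key <- paste(arcs$src, arcs$dst)
  rev_key <- paste(arcs$dst, arcs$src)
  expect_true(all(rev_key %in% key))
  # structural arcs span >= 2
  expect_true(all(abs(arcs$src - arcs$dst)[arcs$type == "structural"] >= 2L))
  # bit-stable ordering
  expect_identical(arcs, build_edges(7L, s))

  single <- build_edges(1L, parse_dot_bracket("."))
  expect_equal(nrow(single), 0L)

  expect_error(build_edges(5L, parse_dot_bracket("((...))")),
               class = "gg_contract_error")
})

test_that("build_graph couples features, edges and label", {
  rec <- guide_record("g", strrep("ACGU", 5), efficiency = 62.5)
  g <- build_graph(rec)
  expect_s3_class(g, "guide_graph")
  expect_equal(g$meta$n_nodes, 20L)
  expect_equal(nrow(g$node_features), 20L)
  expect_equal(g$label, 62.5)
  expect_equal(sum(g$arcs$type == "sequential"), 38L)

  # extended-mode record: node count tracks the full given sequence
  ext <- guide_record("ext", random_rna(95))
  ge <- build_graph(ext, graph_build_config(mode = "extended"))
  expect_equal(ge$meta$n_nodes, 95L)
  expect_equal(ge$meta$mode, "extended")

  expect_error(build_graph(rec, features = matrix(0, 19, 4)),
               class = "gg_contract_error", regexp = "g")
})

test_that("build_dataset preserves order and supports skip mode", {
  set.seed(5)
  recs <- lapply(1:3, function(i) guide_record(sprintf("r%d", i), random_rna(20),
                                               efficiency = 50))
  graphs <- build_dataset(recs)
  expect_length(graphs, 3L)
  expect_identical(vapply(graphs, function(g) g$meta$id, character(1)),
                   c("r1", "r2", "r3"))
  expect_length(build_dataset(list()), 0L)

  # a record whose supplied structure mismatches its length fails alone
  bad_structures <- list(r1 = predict_structure(recs[[1]]$sequence),
                         r2 = parse_dot_bracket("(...)"),
                         r3 = predict_structure(recs[[3]]$sequence))
  expect_error(build_dataset(recs, structure_source = bad_structures),
               class = "gg_contract_error")
  kept <- build_dataset(recs, structure_source = bad_structures, on_error = "skip")
  expect_length(kept, 2L)
  fails <- attr(kept, "failures")
  expect_identical(fails$id, "r2")

  # rebuilding from identical inputs is bit-identical
  expect_identical(build_dataset(recs), graphs)
})

test_that("structural arc count equals the pair count of the structure", {
  set.seed(11)
  for (rep in seq_len(20)) {
    seq <- random_rna(20)
    s <- predict_structure(seq)
    g <- build_graph(guide_record("x", seq), s = s)
    expect_equal(sum(g$arcs$type == "structural"), 2L * nrow(s$pairs))
    expect_equal(sum(g$arcs$type == "sequential"), 2L * (20L - 1L))
  }
})

test_that("drop_structural_edges leaves the backbone chain", {
  g <- build_graph(guide_record("x", "GGGGAAAACCCCAAAAAAAA"))
  expect_gt(sum(g$arcs$type == "structural"), 0L)
  g2 <- drop_structural_edges(g)
  expect_equal(sum(g2$arcs$type == "structural"), 0L)
  expect_equal(sum(g2$arcs$type == "sequential"), 38L)
})
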