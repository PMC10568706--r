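test_that("a ring-only seed expands through additions only", {
  m <- small_trained_model()
  opt <- optimize_molecule("c1ccccc1", "qed", m, fragment_steps = 1L,
                           atom_steps = 10L, rng_seed = 5L)
  expect_gt(nrow(opt$results), 0)
  expect_true(all(opt$results$action == "add"))
})

test_that("tree bookkeeping is conserved", {
  m <- small_trained_model()
  opt <- optimize_molecule("CCOc1ccncc1", "qed", m, fragment_steps = 6L,
                           atom_steps = 12L, rng_seed = 21L)
  expect_identical(opt$root_visits, 6L)
  ns <- opt$node_stats
  visited <- ns[ns$visits > 0, ]
  expect_true(all(visited$mean_value >= -1 & visited$mean_value <= 1))
  # the root is visited exactly once per completed cycle
  expect_identical(ns$visits[1], opt$n_cycles)
})

test_that("identical seeds give identical runs; different seeds differ", {
  m <- small_trained_model()
  o1 <- optimize_molecule("CCOc1ccccc1", "qed", m, fragment_steps = 3L,
                          atom_steps = 10L, rng_seed = 77L)
  o2 <- optimize_molecule("CCOc1ccccc1", "qed", m, fragment_steps = 3L,
                          atom_steps = 10L, rng_seed = 77L)
  expect_identical(o1$results, o2$results)
  expect_identical(o1$trace, o2$trace)
  o3 <- optimize_molecule("CCOc1ccccc1", "qed", m, fragment_steps = 3L,
                          atom_steps = 10L, rng_seed = 78L)
  expect_false(identical(o1$results, o3$results))
})

test_that("every emitted molecule is valid and scores are monotone", {
  m <- small_trained_model()
  opt <- optimize_molecule("CC(=O)Nc1ccccc1", "qed", m, fragment_steps = 5L,
                           atom_steps = 15L, rng_seed = 3L)
  for (s in opt$results$smiles) {
    g <- parse_smiles(s)
    expect_true(all(free_valence(g) >= 0))
  }
  rep <- rank_and_report(opt, top_k = 10L)
  expect_identical(rep$score, sort(rep$score, decreasing = TRUE))
  expect_true(all(rep$similarity >= 0 & rep$similarity <= 1))
  expect_identical(rep$rank, seq_len(nrow(rep)))
})

test_that("protected substructures are never removed", {
  m <- small_trained_model()
  protect <- "c1ccncc1"
  opt <- optimize_molecule("CCCCOc1ccncc1", "qed", m, fragment_steps = 6L,
                           atom_steps = 10L, rng_seed = 12L,
                           protect = protect)
  pat <- parse_smiles(protect)
  for (s in opt$results$smiles) {
    expect_true(moltree:::contains_subgraph(parse_smiles(s), pat), info = s)
  }
  expect_error(
    optimize_molecule("CCCC", "qed", m, fragment_steps = 2L,
                      atom_steps = 5L, protect = protect, rng_seed = 1L),
    "protected substructure")
})

test_that("vocabulary fingerprints guard the search entry point", {
  m <- small_trained_model()
  m$fingerprint <- "deadbeef"
  expect_error(optimize_molecule("CCO", "qed", m, fragment_steps = 1L),
               "vocabularies")
})

test_that("tidy/glance/autoplot surface the run", {
  m <- small_trained_model()
  opt <- optimize_molecule("CCOc1ccccc1", "qed", m, fragment_steps = 3L,
                           atom_steps = 8L, rng_seed = 9L)
  td <- tidy(opt)
  expect_true(all(c("smiles", "score", "action", "cycle") %in% names(td)))
  td2 <- tidy(opt, similarity = TRUE)
  expect_true(all(td2$similarity >= 0 & td2$similarity <= 1))
  gl <- glance(opt)
  expect_identical(nrow(gl), 1L)
  expect_gte(gl$best_score, max(td$score))
  expect_s3_class(ggplot2::autoplot(opt), "ggplot")
  expect_s3_class(plot_score_distribution(opt), "ggplot")
  expect_s3_class(ggplot2::autoplot(small_trained_model()), "ggplot")
  expect_s3_class(tidy(m), "tbl_df")
  expect_identical(nrow(glance(m)), 1L)
})
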