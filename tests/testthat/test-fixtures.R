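test_that("the procedural corpus is reproducible and valid", {
  a <- generate_fixture_corpus(n = 25, seed = 4)
  b <- generate_fixture_corpus(n = 25, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a, generate_fixture_corpus(n = 25, seed = 5)))
  for (s in a) {
    g <- parse_smiles(s)
    expect_true(all(free_valence(g) >= 0))
    expect_true(moltree:::graph_connected(g))
  }
})

test_that("ring-free corpora fragment into single pieces", {
  smis <- generate_fixture_corpus(n = 20, ring_probability = 0,
                                  seed = 8)
  for (s in smis)
    expect_length(fragment_molecule(parse_smiles(s)), 1)
  # with rings present, a nonzero share of molecules split
  smis2 <- generate_fixture_corpus(n = 30, ring_probability = 1, seed = 8)
  n_split <- sum(vapply(smis2, function(s)
    length(fragment_molecule(parse_smiles(s))) > 1, logical(1)))
  expect_gt(n_split, 0)
})

test_that("the bundled corpus loads and feeds the pipeline", {
  smis <- moltree_example_corpus()
  expect_gte(length(smis), 400)
  sub <- smis[1:20]
  expect_true(all(!is.na(canonical_smiles(sub))))
})

test_that("seed selection respects the score band", {
  smis <- c("CCO", "CCN", "CC(=O)Oc1ccccc1C(=O)O",
            "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "c1ccccc1")
  sf <- score_function("qed")
  picked <- select_seed_molecules(smis, sf, lo = 0.3, hi = 0.9, n = 2L,
                                  seed = 2)
  for (s in picked) {
    q <- qed_score(s)
    expect_gte(q, 0.3); expect_lte(q, 0.9)
  }
  expect_error(
    select_seed_molecules(smis, sf, lo = 0.98, hi = 0.99, n = 1L),
    "insufficient candidates")
})
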