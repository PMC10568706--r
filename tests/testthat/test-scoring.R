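test_that("QED is deterministic, bounded, and tracks drug-likeness", {
  b1 <- qed_score("c1ccccc1")
  expect_gt(b1, 0); expect_lt(b1, 1)
  expect_identical(b1, qed_score(parse_smiles("c1ccccc1")))
  # a decorated drug-like molecule scores above both tiny and greasy ones
  ibu <- qed_score("CC(C)Cc1ccc(cc1)C(C)C(=O)O")
  expect_gt(ibu, qed_score("CCO"))
  expect_gt(ibu, qed_score("CCCCCCCCCCCCCCCC"))
})

test_that("penalized logP decomposes as logP - SA - ring penalty", {
  g6 <- parse_smiles("C1CCCCC1")
  expect_identical(moltree:::max_ring_size(g6), 6L)
  # no ring larger than 6: zero ring penalty
  expect_equal(penalized_logp(g6),
               moltree:::ob_properties(g6)$logp - sa_heuristic(g6))
  g8 <- parse_smiles("C1CCCCCCC1")
  expect_equal(penalized_logp(g8),
               moltree:::ob_properties(g8)$logp - sa_heuristic(g8) - 2)
  # a longer alkyl chain raises the logP term (directional check)
  expect_gt(moltree:::ob_properties(parse_smiles("CCCCCCCCc1ccccc1"))$logp,
            moltree:::ob_properties(parse_smiles("Cc1ccccc1"))$logp)
  expect_identical(penalized_logp("CCO"), penalized_logp("CCO"))
})

test_that("aromaticity and rotatable-bond counts follow the conventions", {
  expect_identical(moltree:::count_aromatic_rings(parse_smiles("c1ccccc1")), 1L)
  expect_identical(moltree:::count_aromatic_rings(parse_smiles("C1CCCCC1")), 0L)
  expect_identical(moltree:::count_aromatic_rings(parse_smiles("c1ccc2ccccc2c1")), 2L)
  expect_identical(moltree:::count_aromatic_rings(parse_smiles("c1ccsc1")), 1L)
  expect_identical(moltree:::count_aromatic_rings(parse_smiles("c1cc[nH]c1")), 1L)
  # quinone-like exocyclic doubles break aromaticity
  expect_identical(moltree:::count_aromatic_rings(parse_smiles("O=C1C=CC(=O)C=C1")), 0L)
  expect_identical(moltree:::count_rotatable_bonds(parse_smiles("CCCC")), 1L)
  expect_identical(moltree:::count_rotatable_bonds(parse_smiles("c1ccccc1")), 0L)
  expect_identical(moltree:::count_rotatable_bonds(parse_smiles("CCOc1ccccc1")), 2L)
})

test_that("ECFP4 Tanimoto is a proper similarity", {
  expect_identical(tanimoto_ecfp4("c1ccccc1", "c1ccccc1"), 1)
  bt <- tanimoto_ecfp4("c1ccccc1", "Cc1ccccc1")
  expect_gt(bt, 0); expect_lt(bt, 1)
  expect_identical(tanimoto_ecfp4("CCO", "CC(=O)O"),
                   tanimoto_ecfp4("CC(=O)O", "CCO"))
  # similar pairs score above dissimilar pairs
  expect_gt(tanimoto_ecfp4("CCOc1ccccc1", "CCCOc1ccccc1"),
            tanimoto_ecfp4("CCOc1ccccc1", "NC(N)=O"))
})

test_that("score caching is keyed by canonical structure", {
  calls <- 0L
  sf <- score_function(function(g) { calls <<- calls + 1L; n_atoms(g) },
                       name = "count")
  g <- parse_smiles("CCO")
  expect_identical(score_mol(sf, g), 3L)
  expect_identical(score_mol(sf, parse_smiles("OCC")), 3L)
  expect_identical(calls, 1L) # same canonical SMILES: cache hit
  bad <- score_function(function(g) NA_real_)
  expect_error(score_mol(bad, g), "non-finite")
})

test_that("similarity-constrained scores gate by threshold", {
  base <- score_function("qed")
  seed <- "CCOc1ccccc1"
  sc0 <- similarity_constrained_score(base, seed, delta = 0)
  sc1 <- similarity_constrained_score(base, seed, delta = 1)
  g <- parse_smiles("CCCCCCN")
  expect_identical(score_mol(sc0, g), qed_score(g)) # delta 0: base everywhere
  expect_identical(score_mol(sc1, parse_smiles(seed)), qed_score(seed))
  expect_identical(score_mol(sc1, g), -Inf)
})

test_that("generation metrics match their definitions", {
  gen <- c("CCO", "OCC", "c1ccccc1", "not-a-molecule")
  met <- generation_metrics(gen, corpus = c("CCO"), seed = "CCO")
  expect_equal(met$validity, 3 / 4)
  expect_equal(met$novelty, 1 / 3)          # benzene only, of 3 valid
  expect_equal(met$uniqueness, 2 / 3)       # CCO counted twice
  expect_length(met$similarity, 3)
  expect_identical(met$similarity[1], 1)    # CCO vs itself
  met2 <- generation_metrics(c("CCO", "CCN"), corpus = c("CCO", "CCN"))
  expect_identical(met2$novelty, 0)
  expect_identical(met2$uniqueness, 1)
})
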