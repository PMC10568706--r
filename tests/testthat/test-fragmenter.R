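test_that("ring/non-ring cutting matches the worked examples", {
  benzene <- parse_smiles("c1ccccc1")
  expect_length(fragment_molecule(benzene), 1)
  expect_identical(write_smiles(fragment_molecule(benzene)[[1]]),
                   write_smiles(benzene))

  tol <- fragment_molecule(parse_smiles("Cc1ccccc1"))
  expect_setequal(vapply(tol, write_smiles, character(1)),
                  c("C", write_smiles(benzene)))

  # the internal C-C of the ethyl group is not cut
  eb <- fragment_molecule(parse_smiles("CCc1ccccc1"))
  expect_setequal(vapply(eb, write_smiles, character(1)),
                  c("CC", write_smiles(benzene)))
})

test_that("fragmentation matches a brute-force oracle and conserves atoms", {
  for (s in test_molecules(40)) {
    g <- parse_smiles(s)
    frs <- fragment_molecule(g)
    expect_identical(sort(vapply(frs, write_smiles, character(1))),
                     oracle_fragments(g), info = s)
    # cutting never creates or deletes atoms
    expect_identical(sum(vapply(frs, n_atoms, integer(1))), n_atoms(g))
    # fixed point: no fragment has a bond with exactly one ring endpoint
    for (f in frs) expect_length(fragment_molecule(f), 1)
  }
})

test_that("corpus building deduplicates and aggregates counts", {
  corp <- build_corpus(c("Cc1ccccc1"), quiet = TRUE)
  expect_identical(nrow(corp), 2L)

  corp2 <- build_corpus(c("c1ccccc1", "c1ccccc1"), quiet = TRUE)
  expect_identical(nrow(corp2), 1L)
  expect_identical(corp2$source_count, 2L)

  expect_error(build_corpus(character(0), quiet = TRUE), "empty corpus")

  # unparsable lines are skipped, oversized fragments dropped
  expect_message(
    corp3 <- build_corpus(c("xxx", "CCO", "CCCCCCCCCC"), max_atoms = 5),
    "skipping")
  expect_true(all(corp3$n_atoms <= 5))
  expect_true("CCO" %in% corp3$smiles)
})

test_that("corpus files round-trip and summaries are weighted", {
  corp <- build_corpus(c("Cc1ccccc1", "CCO", "Cc1ccccc1"), quiet = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(corp, path)
  expect_identical(read_corpus(path)$smiles, corp$smiles)

  sm <- corpus_summary(corp)
  expect_identical(sm$n_fragments, sum(corp$source_count))
  expect_identical(sm$n_unique, nrow(corp))
  expect_gt(sm$mw_mean, 0)
  expect_equal(sm$atoms_mean,
               sum(corp$n_atoms * corp$source_count) / sum(corp$source_count))
})
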