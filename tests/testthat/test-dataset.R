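test_that("serialization yields n + 1 teacher-forcing steps", {
  # single atom: (empty -> C), (1-atom -> stop)
  st <- serialize_fragment(parse_smiles("C"))
  expect_length(st, 2)
  expect_identical(st[[1]]$atom_label, 1L)
  expect_length(st[[1]]$bond_labels, 0)
  expect_identical(st[[2]]$atom_label, VOCAB$stop_index)
  expect_length(st[[2]]$bond_labels, 0)

  # two-atom chain: middle step carries one "single" bond label
  st2 <- serialize_fragment(parse_smiles("CC"))
  expect_length(st2, 3)
  expect_identical(st2[[2]]$bond_labels, 1L)

  # benzene: 7 steps; the final atom closes the ring with exactly two
  # non-"none" labels
  st3 <- serialize_fragment(parse_smiles("c1ccccc1"))
  expect_length(st3, 7)
  expect_identical(sum(st3[[6]]$bond_labels != 4L), 2L)
  # every non-stop step after the first connects the new atom
  for (t in 2:6) expect_gte(sum(st3[[t]]$bond_labels != 4L), 1L)

  expect_error(serialize_fragment(parse_smiles("CCCC"), max_atoms = 3),
               "too large")
})

test_that("replaying steps reconstructs every corpus fragment", {
  corp <- build_corpus(test_molecules(25), quiet = TRUE)
  steps <- build_training_steps(corp)
  for (i in seq_len(nrow(corp))) {
    g <- replay_steps(steps[[i]], VOCAB)
    expect_identical(write_smiles(g), corp$smiles[i])
  }
  # intermediate states are connected and valence-valid by construction
  some <- steps[[which.max(corp$n_atoms)]]
  for (st in some) {
    if (length(st$atoms) > 0) {
      g <- mol_graph(st$atoms, st$bonds, VOCAB, check = TRUE)
      expect_true(all(free_valence(g) >= 0))
    }
  }
})

test_that("train/test split is reproducible and by-fragment", {
  corp <- tibble::tibble(smiles = sprintf("mol%02d", 1:10))
  sp <- split_train_test(corp, ratio = 0.8, seed = 11)
  expect_identical(nrow(sp$train), 8L)
  expect_identical(nrow(sp$test), 2L)
  expect_length(intersect(sp$train$smiles, sp$test$smiles), 0)
  sp2 <- split_train_test(corp, ratio = 0.8, seed = 11)
  expect_identical(sp, sp2)
  sp3 <- split_train_test(as.list(1:4), ratio = 0.5, seed = 1)
  expect_length(sp3$train, 2)
  expect_error(split_train_test(corp, ratio = 1.2), "ratio")
})

test_that("apply_step grows states exactly as serialization describes", {
  frag <- parse_smiles(write_smiles(parse_smiles("CC(=O)O")))
  steps <- serialize_fragment(frag)
  g <- mol_graph(integer(0), NULL, VOCAB, check = FALSE)
  for (st in steps) {
    if (st$atom_label == VOCAB$stop_index) break
    g <- apply_step(g, st$atom_label, st$bond_labels)
  }
  expect_identical(write_smiles(g), write_smiles(frag))
})
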