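test_that("vocabularies have the fixed output dimensions and valences", {
  v <- atom_vocab()
  expect_length(v$elements, 9)
  expect_identical(v$stop_index, 10L)
  expect_identical(unname(v$max_valence[c("C", "N", "O", "S")]),
                   c(4L, 3L, 2L, 6L))
  b <- bond_vocab()
  expect_identical(b$orders, 1:3)
  expect_identical(b$none_index, 4L)
  # fingerprint distinguishes vocabularies and is stable
  expect_identical(vocab_fingerprint(v), vocab_fingerprint(atom_vocab()))
  expect_false(identical(vocab_fingerprint(v),
                         vocab_fingerprint(atom_vocab(c("C", "N", "O")))))
})

test_that("SMILES parse produces kekulized, valence-valid graphs", {
  g <- parse_smiles("C")
  expect_identical(n_atoms(g), 1L)
  expect_identical(nrow(g$bonds), 0L)

  benzene <- parse_smiles("c1ccccc1")
  expect_identical(n_atoms(benzene), 6L)
  expect_identical(nrow(benzene$bonds), 6L)
  expect_identical(sort(benzene$bonds[, 3]), c(1L, 1L, 1L, 2L, 2L, 2L))

  aniline <- parse_smiles("C1=CC=CC=C1N")
  expect_identical(n_atoms(aniline), 7L)
  expect_identical(nrow(aniline$bonds), 7L)

  expect_error(parse_smiles("C1CC"), "invalid SMILES")
  expect_error(parse_smiles("[SiH4]"), "Si")
  expect_error(parse_smiles("CC.O"), "disconnected")
  # charges are stripped; impossible-after-stripping valence is rejected
  expect_error(parse_smiles("C[N+](C)(C)C"), "valence")
  expect_identical(write_smiles(parse_smiles("CC[NH3+]")), "CCN")
})

test_that("canonical writing round-trips a molecule corpus", {
  for (s in test_molecules(30)) {
    g <- parse_smiles(s)
    s2 <- write_smiles(g)
    g2 <- parse_smiles(s2)
    expect_identical(write_smiles(g2), s2)
    expect_identical(n_atoms(g2), n_atoms(g))
    expect_identical(nrow(g2$bonds), nrow(g$bonds))
    expect_identical(sort(table(element_symbols(g2))),
                     sort(table(element_symbols(g))))
  }
})

test_that("free valence follows max valence minus bond orders", {
  expect_identical(free_valence(parse_smiles("C"), 1L), 4L)
  benzene <- parse_smiles("c1ccccc1")
  expect_identical(free_valence(benzene), rep(1L, 6))
  hcn <- parse_smiles("C#N")
  expect_identical(free_valence(hcn, 2L), 0L)
  expect_error(free_valence(benzene, 9L), "out of range")
})

test_that("BFS ordering is deterministic with ascending-index tie-break", {
  expect_identical(bfs_order(parse_smiles("C"), 1L), 1L)
  # path graph from an end
  chain <- mol_graph(c("C", "C", "C"), rbind(c(1L, 2L, 1L), c(2L, 3L, 1L)))
  expect_identical(bfs_order(chain, 1L), c(1L, 2L, 3L))
  expect_identical(bfs_order(chain, 3L), c(3L, 2L, 1L))
  # star from the center: leaves in ascending index order
  star <- mol_graph(rep("C", 5),
                    rbind(c(2L, 1L, 1L), c(2L, 3L, 1L), c(2L, 4L, 1L),
                          c(2L, 5L, 1L)))
  expect_identical(bfs_order(star, 2L), c(2L, 1L, 3L, 4L, 5L))
  expect_error(bfs_order(chain, 9L), "out of range")
})

test_that("attach_fragment forms one single bond and validates valence", {
  benzene <- parse_smiles("c1ccccc1")
  toluene <- attach_fragment(benzene, parse_smiles("C"), 1L, 1L)
  expect_identical(write_smiles(toluene), write_smiles(parse_smiles("Cc1ccccc1")))
  expect_identical(write_smiles(attach_fragment(parse_smiles("C"),
                                                parse_smiles("C"), 1L, 1L)),
                   "CC")
  # saturated parent atom is rejected
  hcn <- parse_smiles("C#N")
  expect_error(attach_fragment(hcn, parse_smiles("C"), 2L, 1L),
               "valence violation")
})

test_that("removal enumeration matches the printed examples", {
  expect_length(enumerate_removals(parse_smiles("c1ccccc1")), 0)
  rem <- enumerate_removals(parse_smiles("CCc1ccccc1"))
  expect_setequal(names(rem),
                  c(write_smiles(parse_smiles("Cc1ccccc1")),
                    write_smiles(parse_smiles("c1ccccc1"))))
  # ethane: both components are a single carbon; tie collapses to one child
  rem2 <- enumerate_removals(parse_smiles("CC"))
  expect_identical(names(rem2), "C")
})

test_that("removal enumeration equals the brute-force oracle", {
  for (s in test_molecules(40)) {
    g <- parse_smiles(s)
    expect_identical(sort(names(enumerate_removals(g))), oracle_removals(g),
                     info = s)
  }
})

test_that("every emitted graph respects valence under random edits", {
  set.seed(99)
  mols <- test_molecules(20)
  pieces <- lapply(c("C", "O", "N", "C=O", "C#N"), parse_smiles)
  for (i in seq_len(60)) {
    g <- parse_smiles(sample(mols, 1))
    piece <- pieces[[sample(length(pieces), 1)]]
    sites <- which(free_valence(g) >= 1L)
    if (length(sites) > 0 && free_valence(piece, 1L) >= 1L) {
      g2 <- attach_fragment(g, piece, sample(sites, 1), 1L)
      expect_true(all(free_valence(g2) >= 0L))
      for (child in enumerate_removals(g2))
        expect_true(all(free_valence(child) >= 0L))
    }
  }
})
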