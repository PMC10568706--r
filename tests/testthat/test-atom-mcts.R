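test_that("terminal detection follows the stop/no-bond rule", {
  expect_true(is_terminal(NULL)) # stop label or saturated state
  expect_true(is_terminal(list(atom_label = 1L, bond_labels = c(4L, 4L))))
  expect_false(is_terminal(list(atom_label = 1L, bond_labels = c(4L, 1L))))
})

test_that("the inner search scores attached molecules only", {
  m <- small_trained_model()
  sf <- score_function("qed")
  parent <- parse_smiles("c1ccccc1")
  set.seed(31)
  res <- run_atom_search(parent, 1L, sf, m, n_steps = 25L)
  expect_gt(nrow(res), 0)
  expect_lte(nrow(res), 25) # at most one scored molecule per cycle
  expect_identical(attr(res, "root_visits"), 25L)
  for (i in seq_len(nrow(res))) {
    g <- parse_smiles(res$smiles[i])
    # every result is parent + fragment: strictly more atoms, valid
    expect_gte(n_atoms(g), n_atoms(parent) + 1L)
    expect_true(all(free_valence(g) >= 0))
    # the reward really is the evaluation of the attached molecule
    expect_equal(res$score[i], qed_score(g), tolerance = 1e-12)
  }
  expect_identical(res$score, sort(res$score, decreasing = TRUE))
})

test_that("a saturated site is rejected", {
  m <- small_trained_model()
  hcn <- parse_smiles("C#N")
  expect_error(run_atom_search(hcn, 2L, score_function("qed"), m, 5L),
               "free valence")
})

test_that("fragment sizes vary across seeds", {
  m <- small_trained_model()
  sf <- score_function("qed")
  parent <- parse_smiles("Cc1ccccc1")
  site <- which(free_valence(parent) >= 1L)[1]
  sizes <- unlist(lapply(1:6, function(sd) {
    set.seed(sd * 101)
    res <- run_atom_search(parent, site, sf, m, n_steps = 8L)
    res$frag_atoms
  }))
  expect_gt(length(sizes), 3)
  expect_gt(stats::var(sizes), 0)
})

test_that("the search finds at least the single-atom baseline", {
  # over enough cycles the best attachment should not be worse than the
  # best single heavy atom glued to the same site
  m <- small_trained_model()
  sf <- score_function("qed")
  parent <- parse_smiles("CCOc1ccccc1")
  site <- 1L
  baseline <- max(vapply(seq_along(VOCAB$elements), function(el) {
    piece <- mol_graph(el, NULL, VOCAB)
    if (free_valence(piece, 1L) < 1L) return(-Inf)
    score_mol(sf, attach_fragment(parent, piece, site, 1L))
  }, numeric(1)))
  best <- vapply(1:5, function(sd) {
    set.seed(sd)
    res <- run_atom_search(parent, site, sf, m, n_steps = 60L)
    max(res$score)
  }, numeric(1))
  expect_gte(stats::median(best), baseline)
})
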