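# Shared fixtures and independent oracles for the test suite.

VOCAB <- atom_vocab()

# small model configuration used by unit tests (fast; same code paths)
tiny_config <- function() {
  model_config(mpnn_layers = 2L, hidden_dim = 16L, atom_hidden = 8L,
               gru_state_dim = 12L, atom_embed_dim = 6L, bond_hidden = 8L)
}

# ---- independent oracles (deliberately not using package internals) ----

# connected components by plain BFS over an edge list
oracle_components <- function(n, edges) {
  comp <- integer(n)
  k <- 0L
  adj <- vector("list", n)
  if (NROW(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- k; queue <- c(queue, w) }
    }
  }
  comp
}

# brute-force removal children: delete each single bond in turn, test the
# split by component counting, keep the larger side (canonical-SMILES
# sort on ties), deduplicate
oracle_removals <- function(g) {
  out <- character(0)
  if (nrow(g$bonds) == 0) return(out)
  for (r in seq_len(nrow(g$bonds))) {
    if (g$bonds[r, 3] != 1L) next
    edges <- g$bonds[-r, 1:2, drop = FALSE]
    comp <- oracle_components(length(g$atoms), edges)
    if (max(comp) != 2L) next
    side1 <- which(comp == comp[g$bonds[r, 1]])
    side2 <- which(comp != comp[g$bonds[r, 1]])
    keep <- if (length(side1) > length(side2)) side1
            else if (length(side2) > length(side1)) side2
            else {
              s1 <- write_smiles(subgraph_of(g, side1))
              s2 <- write_smiles(subgraph_of(g, side2))
              if (s1 <= s2) side1 else side2
            }
    out <- c(out, write_smiles(subgraph_of(g, keep)))
  }
  sort(unique(out))
}

# brute-force ring/non-ring fragmentation: an atom is in a ring iff some
# bond incident to it lies on a cycle, tested by "deleting the bond keeps
# the graph connected"; cut all bonds with exactly one ring endpoint
oracle_fragments <- function(g) {
  n <- length(g$atoms)
  if (nrow(g$bonds) == 0) return(write_smiles(g))
  on_cycle <- vapply(seq_len(nrow(g$bonds)), function(r) {
    edges <- g$bonds[-r, 1:2, drop = FALSE]
    comp <- oracle_components(n, edges)
    comp[g$bonds[r, 1]] == comp[g$bonds[r, 2]]
  }, logical(1))
  in_ring <- logical(n)
  in_ring[g$bonds[on_cycle, 1]] <- TRUE
  in_ring[g$bonds[on_cycle, 2]] <- TRUE
  cut <- xor(in_ring[g$bonds[, 1]], in_ring[g$bonds[, 2]])
  edges <- g$bonds[!cut, , drop = FALSE]
  comp <- oracle_components(n, edges[, 1:2, drop = FALSE])
  sort(vapply(seq_len(max(comp)), function(k) {
    sub <- subgraph_of(mol_graph(g$atoms, edges, g$vocab, check = FALSE),
                       which(comp == k))
    write_smiles(sub)
  }, character(1)))
}

subgraph_of <- function(g, idx) {
  idx <- sort(idx)
  pos <- match(seq_along(g$atoms), idx)
  keep <- g$bonds[!is.na(pos[g$bonds[, 1]]) & !is.na(pos[g$bonds[, 2]]), ,
                  drop = FALSE]
  if (nrow(keep) > 0) {
    keep[, 1] <- pos[keep[, 1]]
    keep[, 2] <- pos[keep[, 2]]
  }
  mol_graph(g$atoms[idx], keep, g$vocab, check = FALSE)
}

# ---- cached expensive fixtures (built once per test run) ----

.moltree_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .moltree_test_cache, inherits = FALSE))
    assign(key, force(expr), envir = .moltree_test_cache)
  get(key, envir = .moltree_test_cache, inherits = FALSE)
}

# a small random molecule set for property tests
test_molecules <- function(n = 40, seed = 123) {
  cached(paste0("mols_", n, "_", seed),
         unique(generate_fixture_corpus(n = n, seed = seed)))
}

# small trained generator shared by search unit tests: ~30 molecules,
# short training, enough for the searches to run meaningfully
small_trained_model <- function() {
  cached("small_model", {
    smis <- generate_fixture_corpus(n = 30, seed = 555)
    corp <- build_corpus(smis, quiet = TRUE)
    steps <- build_training_steps(corp)
    train_generator(init_generator(seed = 7),
                    steps,
                    train_config(learning_rate = 1e-3, batch_size = 32L,
                                 epochs = 3L, seed = 7),
                    quiet = TRUE)
  })
}

# ---- study-scale fixtures for the acceptance checks -------------------
# Built once and reused: generator trained on the bundled fixture corpus
# (20 epochs at the reference hyperparameters), and the 10-seed QED
# optimization batch (20 fragment-wise x 100 atom-wise cycles per seed).

acceptance_model <- function() {
  cached("acc_model", {
    corpus <- build_corpus(moltree_example_corpus(), quiet = TRUE)
    steps <- build_training_steps(corpus)
    train_generator(init_generator(seed = 101L), steps,
                    train_config(learning_rate = 1e-4, batch_size = 128L,
                                 epochs = 20L, seed = 202L),
                    quiet = TRUE)
  })
}

acceptance_runs <- function() {
  cached("acc_runs", {
    model <- acceptance_model()
    seeds <- select_seed_molecules(unique(moltree_example_corpus()),
                                  score_function("qed"),
                                  lo = 0.6, hi = 0.7, n = 10L, seed = 303L)
    lapply(seq_along(seeds), function(i) {
      optimize_molecule(seeds[i], "qed", model,
                        fragment_steps = 20L, atom_steps = 100L,
                        rng_seed = 400L + i)
    })
  })
}

# the frozen tiny-corpus memorization protocol (10 fragments, 20 epochs)
overfit_fragments <- function() {
  unique(vapply(c("Cc1ccccc1", "CCO", "c1ccncc1", "CC(C)O", "c1ccccc1",
                  "CCN", "C1CCCCC1", "CC(=O)O", "c1ccsc1", "CCOC"),
                function(s) write_smiles(parse_smiles(s)), character(1),
                USE.NAMES = FALSE))
}

overfit_model <- function() {
  cached("overfit_model", {
    stepsL <- lapply(overfit_fragments(),
                     function(s) serialize_fragment(parse_smiles(s)))
    train_generator(init_generator(seed = 1L), stepsL,
                    train_config(learning_rate = 2e-3, batch_size = 4L,
                                 epochs = 20L, seed = 1L),
                    quiet = TRUE)
  })
}
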