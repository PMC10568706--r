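test_that("prediction heads emit proper probability vectors", {
  m <- init_generator(VOCAB, tiny_config(), seed = 5)
  g <- parse_smiles("CC(=O)O")
  pa <- predict_atom(m, g)
  expect_length(pa, 10)
  expect_true(all(pa >= 0))
  expect_equal(sum(pa), 1, tolerance = 1e-6)
  # empty state is served by the zero-vector convention
  empty <- mol_graph(integer(0), NULL, VOCAB, check = FALSE)
  expect_equal(sum(predict_atom(m, empty)), 1, tolerance = 1e-6)

  pb <- predict_bonds(m, g, atom_label = 1L)
  expect_identical(dim(pb), c(4L, 4L))
  expect_equal(rowSums(pb), rep(1, 4), tolerance = 1e-6)
  expect_error(predict_bonds(m, g, VOCAB$stop_index), "stop label")
})

test_that("the encoder is permutation-invariant at the graph level", {
  m <- init_generator(VOCAB, tiny_config(), seed = 5)
  g <- parse_smiles("CC(=O)Oc1ccccc1C(=O)O")
  perm <- withr::with_seed(1, sample(n_atoms(g)))
  pos <- match(seq_len(n_atoms(g)), perm)
  bonds <- g$bonds
  bonds[, 1] <- pos[g$bonds[, 1]]
  bonds[, 2] <- pos[g$bonds[, 2]]
  gp <- mol_graph(g$atoms[perm], bonds, VOCAB)
  e1 <- moltree:::encode_graph(m, g)
  e2 <- moltree:::encode_graph(m, gp)
  expect_equal(e1$h_g, e2$h_g, tolerance = 1e-10)
  # single-atom graph: pooled vector equals the one node row
  e3 <- moltree:::encode_graph(m, parse_smiles("C"))
  expect_equal(drop(e3$h_n), e3$h_g, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_config()
  m <- init_generator(VOCAB, cfg, seed = 42)
  # perturb away from ReLU kinks at exactly zero
  m$params <- withr::with_seed(11, lapply(m$params, function(p)
    p + matrix(stats::rnorm(length(p), 0, 0.05), nrow(p))))
  steps <- unlist(lapply(c("C", "CCO", "c1ccccc1", "C#N"),
                         function(s) serialize_fragment(parse_smiles(s))),
                  recursive = FALSE)
  ccfg <- moltree:::cpp_cfg(m)
  res <- moltree:::mt_batch_grad(m$params, steps, ccfg, TRUE)
  h <- 1e-6
  set.seed(7)
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (k in sample(length(p), min(2, length(p)))) {
      p2 <- m$params
      p2[[nm]][k] <- p2[[nm]][k] + h
      lp <- moltree:::mt_batch_grad(p2, steps, ccfg, FALSE)$loss
      p2[[nm]][k] <- p2[[nm]][k] - 2 * h
      lm <- moltree:::mt_batch_grad(p2, steps, ccfg, FALSE)$loss
      expect_equal(res$grads[[nm]][k], (lp - lm) / (2 * h),
                   tolerance = 1e-3, info = nm)
    }
  }
})

test_that("training reduces the loss and is seed-deterministic", {
  steps <- lapply(c("CCO", "CCN", "Cc1ccccc1", "CC(=O)O"),
                  function(s) serialize_fragment(parse_smiles(s)))
  m0 <- init_generator(VOCAB, tiny_config(), seed = 3)
  tc <- train_config(learning_rate = 1e-3, batch_size = 4L, epochs = 8L,
                     seed = 9)
  m1 <- train_generator(m0, steps, tc, quiet = TRUE)
  expect_lt(dplyr::last(m1$log$train_loss), m1$log$train_loss[1])
  m2 <- train_generator(m0, steps, tc, quiet = TRUE)
  expect_identical(m1$log$train_loss, m2$log$train_loss)
  expect_identical(m1$params, m2$params)
  # held-out loss is logged when test steps are supplied
  m3 <- train_generator(m0, steps[1:3], train_config(epochs = 2L, seed = 1),
                        test_steps = steps[4], quiet = TRUE)
  expect_true(all(is.finite(m3$log$test_loss)))
  expect_error(train_generator(m0, list(), tc), "empty training set")
})

test_that("stop steps carry no bond-loss term", {
  m <- init_generator(VOCAB, tiny_config(), seed = 2)
  ccfg <- moltree:::cpp_cfg(m)
  stop_step <- serialize_fragment(parse_smiles("CC"))[[3]]
  expect_identical(stop_step$atom_label, VOCAB$stop_index)
  res <- moltree:::mt_batch_grad(m$params, list(stop_step), ccfg, FALSE)
  expect_identical(res$n_bond_terms, 0L)
  expect_identical(res$loss, res$loss_atom)
})

test_that("masked sampling never violates valence", {
  m <- small_trained_model()
  xp <- compile_generator(m)
  set.seed(17)
  n_checked <- 0
  for (i in 1:300) {
    ro <- moltree:::mt_x_rollout(xp, integer(0), matrix(0L, 0, 3), 12L,
                                 stats::runif(200), TRUE, FALSE)
    if (length(ro$atoms) == 0) next
    g <- mol_graph(as.integer(ro$atoms), ro$bonds, VOCAB, check = TRUE)
    expect_true(all(free_valence(g) >= 0))
    expect_true(moltree:::graph_connected(g))
    # the attachment reservation holds on atom 1
    expect_gte(free_valence(g, 1L), 1L)
    n_checked <- n_checked + n_atoms(g)
  }
  expect_gt(n_checked, 300) # enough sampled steps to mean something
})

test_that("saturated sampling states return STOP", {
  m <- init_generator(VOCAB, tiny_config(), seed = 5)
  # every atom saturated: nitrogen triple-bonded to carbon, C capped off
  g <- parse_smiles("C#N")
  g$bonds <- rbind(g$bonds) # unchanged; C has free valence 1, N has 0
  res <- sample_step(m, g, reserve = c(1L, 0L)) # reserve the last C slot
  expect_null(res)
})

test_that("checkpoints round-trip and guard the vocabulary", {
  m <- small_trained_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(m, path)
  m2 <- read_checkpoint(path)
  expect_equal(m2$params, m$params, tolerance = 1e-12)
  expect_identical(m2$fingerprint, m$fingerprint)
  expect_identical(m2$config$hidden_dim, m$config$hidden_dim)
  # a tampered fingerprint is rejected
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$fingerprint <- "00000000"
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  expect_error(read_checkpoint(path), "fingerprint")
})

test_that("float inference engine agrees with the double path", {
  m <- small_trained_model()
  xp <- compile_generator(m)
  for (s in c("C", "CCO", "c1ccncc1", "CC(=O)Oc1ccccc1")) {
    g <- parse_smiles(s)
    pa_d <- unname(predict_atom(m, g))
    pa_f <- moltree:::mt_x_atom_probs(xp, g$atoms, g$bonds)
    expect_equal(pa_d, pa_f, tolerance = 1e-5)
  }
})
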