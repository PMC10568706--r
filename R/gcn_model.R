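#' Generator model configuration
#'
#' Architecture of the three-part fragment generator: a message-passing
#' encoder over the molecular graph, a fully connected atom-prediction
#' head, and a GRU bond-prediction head. Defaults are the architecture
#' used throughout the package: a 6-layer encoder with 128-dimensional
#' node hidden states and sum pooling, a 64-unit hidden layer in each
#' head, a 2-layer GRU with 256-dimensional state initialized from the
#' concatenation of the 64-dimensional atom embedding and the graph
#' vector, ReLU activations, and softmax outputs.
#'
#' `flavor = "mpnn"` (default) uses edge-conditioned message passing with
#' one weight matrix per bond order (the 3-dimensional edge features);
#' `flavor = "gcn"` is a plain symmetric-normalized graph convolution that
#' ignores bond orders.
#'
#' @param mpnn_layers Number of encoder layers.
#' @param hidden_dim Node hidden state width.
#' @param atom_hidden Hidden width of the atom head.
#' @param gru_state_dim GRU state width (2 layers).
#' @param atom_embed_dim Width of the atom-label embedding fed to the GRU
#'   initial state.
#' @param bond_hidden Hidden width of the bond output head.
#' @param flavor `"mpnn"` or `"gcn"`.
#' @return A list of class `mt_model_config`.
#' @export
model_config <- function(mpnn_layers = 6L, hidden_dim = 128L,
                         atom_hidden = 64L, gru_state_dim = 256L,
                         atom_embed_dim = 64L, bond_hidden = 64L,
                         flavor = c("mpnn", "gcn")) {
  flavor <- match.arg(flavor)
  cfg <- list(mpnn_layers = as.integer(mpnn_layers),
              hidden_dim = as.integer(hidden_dim),
              atom_hidden = as.integer(atom_hidden),
              bond_gru_layers = 2L,
              gru_state_dim = as.integer(gru_state_dim),
              atom_embed_dim = as.integer(atom_embed_dim),
              bond_hidden = as.integer(bond_hidden),
              flavor = flavor)
  stopifnot(all(unlist(cfg[1:7]) > 0))
  structure(cfg, class = "mt_model_config")
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Steps per parameter update.
#' @param epochs Number of passes over the training steps.
#' @param seed Integer seed controlling initialization and shuffling.
#' @param clip_norm Global gradient-norm clip.
#' @return A list of class `mt_train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 128L,
                         epochs = 50L, seed = 1L, clip_norm = 5) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1, clip_norm > 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 seed = as.integer(seed),
                 clip_norm = clip_norm),
            class = "mt_train_config")
}

# C++-side config list
cpp_cfg <- function(model) {
  list(mpnn_layers = model$config$mpnn_layers,
       flavor = model$config$flavor,
       n_elements = length(model$vocab$elements))
}

# Glorot-uniform matrix
glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize an untrained generator
#'
#' @param vocab An [atom_vocab()].
#' @param config A [model_config()].
#' @param seed Integer seed for the random initialization.
#' @return An object of class `mt_generator`: fields `params` (named list
#'   of matrices), `config`, `vocab`, `fingerprint` and `log` (training
#'   history tibble, empty until [train_generator()]).
#' @export
init_generator <- function(vocab = atom_vocab(), config = model_config(),
                           seed = 1L) {
  nel <- length(vocab$elements)
  D <- config$hidden_dim
  S <- config$gru_state_dim
  E <- config$atom_embed_dim
  Ah <- config$atom_hidden
  Bh <- config$bond_hidden
  nW <- if (config$flavor == "mpnn") 3L else 1L
  params <- withr::with_seed(seed, {
    p <- list()
    din <- nel
    for (l in seq_len(config$mpnn_layers)) {
      for (b in 0:nW) p[[paste0("enc_W", b, "_", l)]] <- glorot(din, D)
      # unused message weights of the plain-GCN flavor stay as zero
      # placeholders so both flavors share one parameter layout
      if (nW == 1L) {
        p[[paste0("enc_W2_", l)]] <- matrix(0, din, D)
        p[[paste0("enc_W3_", l)]] <- matrix(0, din, D)
      }
      p[[paste0("enc_b_", l)]] <- matrix(0, 1, D)
      din <- D
    }
    p$atom_W1 <- glorot(D, Ah); p$atom_b1 <- matrix(0.01, 1, Ah)
    p$atom_W2 <- glorot(Ah, nel + 1L); p$atom_b2 <- matrix(0, 1, nel + 1L)
    p$emb <- glorot(nel, E)
    p$init_W <- glorot(E + D, 2L * S); p$init_b <- matrix(0, 1, 2L * S)
    p$gru1_Wx <- glorot(D, 3L * S); p$gru1_Wh <- glorot(S, 3L * S)
    p$gru1_bx <- matrix(0, 1, 3L * S); p$gru1_bh <- matrix(0, 1, 3L * S)
    p$gru2_Wx <- glorot(S, 3L * S); p$gru2_Wh <- glorot(S, 3L * S)
    p$gru2_bx <- matrix(0, 1, 3L * S); p$gru2_bh <- matrix(0, 1, 3L * S)
    p$bond_W1 <- glorot(S, Bh); p$bond_b1 <- matrix(0.01, 1, Bh)
    p$bond_W2 <- glorot(Bh, 4L); p$bond_b2 <- matrix(0, 1, 4L)
    p
  })
  structure(list(params = params, config = config, vocab = vocab,
                 fingerprint = vocab_fingerprint(vocab),
                 log = tibble::tibble(epoch = integer(0),
                                      train_loss = numeric(0),
                                      test_loss = numeric(0))),
            class = "mt_generator")
}

#' @export
print.mt_generator <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat("<mt_generator> ", x$config$flavor, " encoder, ",
      x$config$mpnn_layers, " layers x ", x$config$hidden_dim,
      " dims; ", format(np, big.mark = ","), " parameters\n", sep = "")
  if (nrow(x$log) > 0) {
    last <- x$log[nrow(x$log), ]
    cat("  trained ", last$epoch, " epochs; train loss/step ",
        signif(last$train_loss, 4), "\n", sep = "")
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

# flatten a fragment-wise step list into one flat list of steps
flatten_steps <- function(steps_by_fragment) {
  if (length(steps_by_fragment) > 0 &&
      !is.null(steps_by_fragment[[1]]$atom_label)) {
    return(steps_by_fragment) # already flat
  }
  unlist(steps_by_fragment, recursive = FALSE, use.names = FALSE)
}

#' Train the generator with teacher forcing
#'
#' Minimizes the summed cross-entropy of the atom and bond heads over all
#' generation steps with Adam. The bond head always consumes the label
#' atom (not the atom head's prediction), and stop steps contribute no
#' bond-loss term. Gradients are clipped at a global norm; the loss that
#' is logged is the mean per step.
#'
#' @param model An [init_generator()] model (its vocabulary is used).
#' @param steps Training steps: the output of [build_training_steps()]
#'   (per-fragment lists) or an already-flat list of steps.
#' @param train_cfg A [train_config()].
#' @param test_steps Optional held-out steps; when given, the test loss is
#'   logged each epoch.
#' @param snapshot_epochs Integer vector of epochs whose parameters should
#'   be kept (stored in `model$snapshots`); the returned model always
#'   carries the final-epoch parameters.
#' @param quiet Suppress the per-epoch message.
#' @return The trained `mt_generator` with a filled `log`.
#' @export
train_generator <- function(model, steps, train_cfg = train_config(),
                            test_steps = NULL, snapshot_epochs = integer(0),
                            quiet = FALSE) {
  stopifnot(inherits(model, "mt_generator"))
  steps <- flatten_steps(steps)
  if (length(steps) == 0) stop("empty training set", call. = FALSE)
  if (!is.null(test_steps)) test_steps <- flatten_steps(test_steps)
  cfg <- cpp_cfg(model)
  params <- model$params
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- adam_m
  adam_t <- 0L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- train_cfg$learning_rate
  log <- list()
  snapshots <- list()
  withr::with_seed(train_cfg$seed, {
    for (epoch in seq_len(train_cfg$epochs)) {
      ord <- sample.int(length(steps))
      total <- 0
      for (start in seq(1, length(ord), by = train_cfg$batch_size)) {
        idx <- ord[start:min(start + train_cfg$batch_size - 1L, length(ord))]
        res <- mt_batch_grad(params, steps[idx], cfg, TRUE)
        total <- total + res$loss
        g <- res$grads
        # average over the batch, clip at global norm
        nb <- length(idx)
        gn <- sqrt(sum(vapply(g, function(m) sum(m^2), numeric(1)))) / nb
        scale <- if (gn > train_cfg$clip_norm) train_cfg$clip_norm / gn else 1
        adam_t <- adam_t + 1L
        corr <- lr * sqrt(1 - b2^adam_t) / (1 - b1^adam_t)
        for (nm in names(params)) {
          gm <- g[[nm]] * (scale / nb)
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * gm
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * gm^2
          params[[nm]] <- params[[nm]] -
            corr * adam_m[[nm]] / (sqrt(adam_v[[nm]]) + eps)
        }
      }
      train_loss <- total / length(steps)
      test_loss <- NA_real_
      if (!is.null(test_steps) && length(test_steps) > 0) {
        test_loss <- mt_batch_grad(params, test_steps, cfg, FALSE)$loss /
          length(test_steps)
      }
      log[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = train_loss,
                                     test_loss = test_loss)
      if (epoch %in% snapshot_epochs) snapshots[[as.character(epoch)]] <- params
      if (!quiet)
        message(sprintf("epoch %3d  train %.4f%s", epoch, train_loss,
                        if (is.na(test_loss)) ""
                        else sprintf("  test %.4f", test_loss)))
    }
  })
  model$params <- params
  model$log <- dplyr::bind_rows(log)
  if (length(snapshots) > 0) model$snapshots <- snapshots
  model
}

# mean per-step loss of a step set under the current parameters
generator_loss <- function(model, steps) {
  steps <- flatten_steps(steps)
  mt_batch_grad(model$params, steps, cpp_cfg(model), FALSE)$loss /
    length(steps)
}

#' Encode a molecular graph
#'
#' Runs the message-passing encoder and returns the per-node hidden
#' states `h_n` (rows in atom order) and the graph vector `h_g`, which
#' is their elementwise sum (sum pooling). The empty state encodes to a
#' zero graph vector by convention.
#'
#' @param model An `mt_generator`.
#' @param g A [mol_graph()] (possibly empty).
#' @return A list with `h_n` (matrix) and `h_g` (numeric vector).
#' @export
encode_graph <- function(model, g) {
  if (n_atoms(g) == 0) {
    return(list(h_n = matrix(0, 0, model$config$hidden_dim),
                h_g = rep(0, model$config$hidden_dim)))
  }
  enc <- mt_encode(model$params, g$atoms, g$bonds, cpp_cfg(model))
  list(h_n = enc$h_n, h_g = drop(enc$h_g))
}

#' Predict the next-atom distribution for a partial fragment
#'
#' @param model A trained `mt_generator`.
#' @param g A partial fragment ([mol_graph()]), possibly empty.
#' @return Probability vector over the 10 atom labels (last = stop).
#' @export
predict_atom <- function(model, g) {
  enc <- encode_graph(model, g)
  p <- drop(mt_atom_probs(model$params, matrix(enc$h_g, nrow = 1)))
  names(p) <- c(model$vocab$elements, "<stop>")
  p
}

#' Predict bond distributions for a hypothetical new atom
#'
#' Teacher-forcing view of the bond head: given the state graph and the
#' label of the incoming atom, returns one probability vector over
#' {single, double, triple, none} per existing atom, in BFS (= state row)
#' order, without valence masking.
#'
#' @param model A trained `mt_generator`.
#' @param g The state graph (>= 1 atom).
#' @param atom_label Element index of the incoming atom (must not be the
#'   stop label).
#' @return Matrix `n_atoms(g)` x 4 of probabilities.
#' @export
predict_bonds <- function(model, g, atom_label) {
  if (atom_label == model$vocab$stop_index)
    stop("cannot predict bonds for the stop label", call. = FALSE)
  stopifnot(n_atoms(g) >= 1)
  enc <- encode_graph(model, g)
  mt_bond_probs(model$params, enc$h_n, matrix(enc$h_g, nrow = 1),
                as.integer(atom_label))
}

#' Sample one generation step under valence masking
#'
#' Samples an atom label from the atom head; if it is not the stop label,
#' samples a bond label for each existing atom sequentially, masking any
#' bond order that would exceed the free valence of either endpoint (the
#' mask shrinks as orders accumulate on the new atom). Returns `NULL`
#' (STOP) when the stop label is sampled, when the state is saturated, or
#' when every bond label comes out "none" — a disconnected atom is treated
#' as the terminal signal.
#'
#' Randomness is drawn from R's RNG, so results are reproducible under
#' `set.seed()`. With `greedy = TRUE` both heads use the arg-max instead.
#'
#' @param model A trained `mt_generator`.
#' @param g The partial fragment (possibly empty).
#' @param greedy Deterministic arg-max decoding.
#' @param reserve Integer vector of per-atom valence reservations (same
#'   length as the state, usually all 0 with 1 on the future attachment
#'   atom) subtracted from the free valence before masking.
#' @return `NULL` for STOP, otherwise a list with `atom_label`,
#'   `bond_labels` and `prob` (joint probability of the sampled move under
#'   the masked distributions).
#' @export
sample_step <- function(model, g, greedy = FALSE, reserve = NULL) {
  vocab <- model$vocab
  n <- n_atoms(g)
  free <- free_valence(g)
  if (!is.null(reserve)) {
    stopifnot(length(reserve) == n)
    free <- pmax(free - as.integer(reserve), 0L)
  }
  if (n > 0 && all(free == 0L)) return(NULL) # saturated state
  enc <- encode_graph(model, g)
  pa <- drop(mt_atom_probs(model$params, matrix(enc$h_g, nrow = 1)))
  lab <- if (greedy) which.max(pa) else {
    sample.int(length(pa), 1L, prob = pa)
  }
  if (lab == vocab$stop_index) return(NULL)
  if (n == 0) {
    return(list(atom_label = lab, bond_labels = integer(0), prob = pa[lab]))
  }
  bs <- mt_sample_bonds(model$params, enc$h_n, matrix(enc$h_g, nrow = 1),
                        as.integer(lab), free,
                        vocab$max_valence[[lab]],
                        stats::runif(n), greedy)
  if (all(bs$labels == 4L)) return(NULL) # no bond predicted: terminal
  list(atom_label = lab, bond_labels = as.integer(bs$labels),
       prob = pa[lab] * bs$prob)
}

#' Sample a complete fragment from scratch
#'
#' Repeatedly applies [sample_step()] from the empty state until STOP or
#' until `max_atoms` is reached. When `reserve_attachment` is `TRUE` the
#' first atom keeps one unit of valence free, so the fragment can later be
#' attached to a parent molecule by a single bond.
#'
#' @param model A trained `mt_generator`.
#' @param max_atoms Hard cap on fragment size.
#' @param greedy Deterministic arg-max decoding.
#' @param reserve_attachment Keep one valence unit free on atom 1.
#' @return A [mol_graph()] (possibly empty when the model stops
#'   immediately).
#' @export
sample_fragment <- function(model, max_atoms = 15L, greedy = FALSE,
                            reserve_attachment = TRUE) {
  g <- mol_graph(integer(0), NULL, model$vocab, check = FALSE)
  while (n_atoms(g) < max_atoms) {
    res <- reserve_on_first(model, g, greedy, reserve_attachment)
    if (is.null(res)) break
    g <- apply_step(g, res$atom_label, res$bond_labels)
  }
  g
}

reserve_on_first <- function(model, g, greedy, reserve_attachment) {
  reserve <- NULL
  if (reserve_attachment && n_atoms(g) > 0) {
    reserve <- integer(n_atoms(g))
    reserve[1] <- 1L
  }
  sample_step(model, g, greedy = greedy, reserve = reserve)
}

#' Save / load a generator checkpoint
#'
#' Checkpoints are self-describing JSON: model configuration, vocabulary
#' (elements, valences and fingerprint) and all weight matrices.
#' [read_checkpoint()] refuses a file whose vocabulary fingerprint does
#' not match the vocabulary it reconstructs, and search entry points
#' refuse models whose fingerprint differs from the vocabulary of their
#' input molecules.
#'
#' @param model An `mt_generator`.
#' @param path Output path (`.json`).
#' @return `write_checkpoint` returns `path` invisibly; `read_checkpoint`
#'   returns the `mt_generator`.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mt_generator"))
  obj <- list(
    package = "moltree",
    config = unclass(model$config),
    vocab = list(elements = model$vocab$elements,
                 max_valence = as.integer(model$vocab$max_valence)),
    fingerprint = model$fingerprint,
    log = as.data.frame(model$log),
    params = model$params
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vocab <- atom_vocab(obj$vocab$elements,
                      stats::setNames(obj$vocab$max_valence,
                                      obj$vocab$elements))
  if (!identical(vocab_fingerprint(vocab), obj$fingerprint))
    stop("checkpoint vocabulary fingerprint mismatch", call. = FALSE)
  cfg <- do.call(model_config, obj$config[c("mpnn_layers", "hidden_dim",
                                            "atom_hidden", "gru_state_dim",
                                            "atom_embed_dim", "bond_hidden",
                                            "flavor")])
  params <- lapply(obj$params, function(m) {
    if (is.null(dim(m))) matrix(m, nrow = 1) else as.matrix(m)
  })
  structure(list(params = params, config = cfg, vocab = vocab,
                 fingerprint = obj$fingerprint,
                 log = tibble::as_tibble(obj$log)),
            class = "mt_generator")
}
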