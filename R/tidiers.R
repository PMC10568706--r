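#' Tidy an optimization run
#'
#' Returns the generated molecules as one row per distinct structure,
#' with score, producing action (`add`/`remove`), cycle of first
#' appearance and ECFP4 Tanimoto similarity to the seed.
#'
#' @param x An `mt_optimization` from [optimize_molecule()].
#' @param similarity Compute the similarity column (adds a fingerprint
#'   calculation per molecule).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mt_optimization <- function(x, similarity = FALSE, ...) {
  out <- x$results
  if (similarity && nrow(out) > 0) {
    seed <- parse_smiles(x$seed_smiles)
    out$similarity <- vapply(out$smiles, function(s)
      tanimoto_ecfp4(s, seed), numeric(1), USE.NAMES = FALSE)
  }
  out
}

#' Summarize an optimization run in one row
#'
#' @param x An `mt_optimization`.
#' @param ... Unused.
#' @return A one-row tibble: seed score, best/top-50-mean generated
#'   score, number of distinct molecules, tree size and root visits.
#' @export
glance.mt_optimization <- function(x, ...) {
  scores <- x$results$score[is.finite(x$results$score)]
  tibble::tibble(
    seed_score = x$seed_score,
    best_score = if (length(scores)) max(scores) else NA_real_,
    top50_mean = if (length(scores)) mean(utils::head(sort(scores,
      decreasing = TRUE), 50)) else NA_real_,
    n_molecules = nrow(x$results),
    n_nodes = x$n_nodes,
    root_visits = x$root_visits,
    n_cycles = x$n_cycles
  )
}

#' Tidy a generator's training history
#'
#' @param x An `mt_generator`.
#' @param ... Unused.
#' @return The per-epoch loss tibble (`epoch`, `train_loss`,
#'   `test_loss`).
#' @export
tidy.mt_generator <- function(x, ...) x$log

#' Summarize a trained generator in one row
#'
#' @param x An `mt_generator`.
#' @param ... Unused.
#' @return A one-row tibble with architecture and final losses.
#' @export
glance.mt_generator <- function(x, ...) {
  last <- if (nrow(x$log) > 0) x$log[nrow(x$log), ] else
    tibble::tibble(epoch = 0L, train_loss = NA_real_, test_loss = NA_real_)
  tibble::tibble(
    flavor = x$config$flavor,
    layers = x$config$mpnn_layers,
    hidden_dim = x$config$hidden_dim,
    n_parameters = sum(vapply(x$params, length, numeric(1))),
    epochs = last$epoch,
    train_loss = last$train_loss,
    test_loss = last$test_loss
  )
}
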