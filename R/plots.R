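#' Plot the search trace of an optimization run
#'
#' Best raw score found so far against the outer search cycle.
#'
#' @param object An `mt_optimization`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mt_optimization <- function(object, ...) {
  df <- object$trace
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle, y = .data$best_score)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = object$seed_score, linetype = 2,
                        colour = "grey40") +
    ggplot2::annotate("text", x = max(df$cycle), y = object$seed_score,
                      label = "seed", hjust = 1, vjust = -0.5, size = 3,
                      colour = "grey40") +
    ggplot2::labs(x = "fragment-wise cycle",
                  y = paste("best", object$score_name),
                  title = paste("Optimization of", object$seed_smiles)) +
    ggplot2::theme_minimal()
}

#' Plot a generator's training curve
#'
#' @param object An `mt_generator` with a training log.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mt_generator <- function(object, ...) {
  stopifnot(nrow(object$log) > 0)
  df <- tidyr::pivot_longer(object$log, -"epoch", names_to = "set",
                            values_to = "loss")
  df <- df[!is.na(df$loss), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy / step", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Score distributions of generated vs. seed molecules
#'
#' Histogram of the scores of all distinct generated molecules, with the
#' seed score marked — the conventional before/after view of an
#' optimization batch.
#'
#' @param opts A single `mt_optimization` or a list of them.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(opts, bins = 30) {
  if (inherits(opts, "mt_optimization")) opts <- list(opts)
  gen <- dplyr::bind_rows(lapply(opts, function(o) {
    tibble::tibble(score = o$results$score[is.finite(o$results$score)],
                   set = "generated")
  }))
  seeds <- tibble::tibble(
    score = vapply(opts, `[[`, numeric(1), "seed_score"), set = "seed")
  df <- dplyr::bind_rows(gen, seeds)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$set)) +
    ggplot2::geom_histogram(bins = bins, position = "identity",
                            alpha = 0.6) +
    ggplot2::labs(x = "score", y = "molecules", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
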