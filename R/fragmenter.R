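#' Cut a molecule into training fragments
#'
#' Applies the corpus-building rule of the generator: every bond that
#' connects a ring atom to a non-ring atom is broken, and the resulting
#' connected components are returned. A molecule with no ring/non-ring
#' bond (benzene, or a fully acyclic molecule) is returned whole. Open
#' valences created by the cuts are satisfied by implicit hydrogens, so
#' every fragment is itself a plain, valid molecule.
#'
#' Ring membership is decided on the parent molecule (an atom is in a ring
#' if it touches any cycle edge), not re-derived on the fragments.
#'
#' @param g A connected [mol_graph()].
#' @return A list of connected, valence-valid [mol_graph()] fragments.
#' @examples
#' length(fragment_molecule(parse_smiles("c1ccccc1")))  # 1
#' length(fragment_molecule(parse_smiles("Cc1ccccc1"))) # 2
#' @export
fragment_molecule <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  if (nrow(g$bonds) == 0) return(list(g))
  inring <- ring_atoms(g)
  cut <- which(xor(inring[g$bonds[, 1]], inring[g$bonds[, 2]]))
  if (length(cut) == 0) return(list(g))
  keep <- g$bonds[-cut, , drop = FALSE]
  gcut <- mol_graph(g$atoms, keep, g$vocab, check = FALSE)
  nb <- neighbor_list(gcut)
  comp <- integer(length(g$atoms))
  k <- 0L
  for (start in seq_along(g$atoms)) {
    if (comp[start] > 0L) next
    k <- k + 1L
    queue <- start
    comp[start] <- k
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in nb[[v]]) if (comp[w] == 0L) { comp[w] <- k; queue <- c(queue, w) }
    }
  }
  lapply(seq_len(k), function(ci) induced_subgraph_mol(gcut, which(comp == ci)))
}

#' Build a fragment corpus from a molecule collection
#'
#' Parses a one-SMILES-per-line file (or character vector), cuts every
#' molecule with [fragment_molecule()], and aggregates the fragments by
#' canonical SMILES. Unparsable lines are skipped with a message.
#' Fragments larger than `max_atoms` are dropped (the generator's rollout
#' is capped, so oversized fragments would never be produced anyway).
#'
#' @param smiles Path to a SMILES file, or a character vector of SMILES.
#' @param vocab An [atom_vocab()].
#' @param max_atoms Drop fragments with more heavy atoms than this.
#' @param quiet Suppress progress messages.
#' @return A tibble with columns `smiles` (canonical fragment),
#'   `source_count` (number of corpus fragments collapsing onto it) and
#'   `n_atoms`, sorted by decreasing `source_count`.
#' @export
build_corpus <- function(smiles, vocab = atom_vocab(), max_atoms = 25L,
                         quiet = FALSE) {
  if (length(smiles) == 1L && file.exists(smiles))
    smiles <- read_smiles_file(smiles)
  frag_smiles <- character(0)
  n_bad <- 0L
  n_dropped <- 0L
  for (s in smiles) {
    g <- tryCatch(parse_smiles(s, vocab), error = function(e) NULL)
    if (is.null(g)) {
      n_bad <- n_bad + 1L
      if (!quiet) message("skipping unparsable/out-of-vocabulary line: ", s)
      next
    }
    for (f in fragment_molecule(g)) {
      if (n_atoms(f) > max_atoms) {
        n_dropped <- n_dropped + 1L
        next
      }
      frag_smiles <- c(frag_smiles, write_smiles(f))
    }
  }
  if (length(frag_smiles) == 0)
    stop("empty corpus: no usable fragments were produced", call. = FALSE)
  if (!quiet && n_dropped > 0)
    message(n_dropped, " fragment(s) above ", max_atoms, " atoms dropped")
  tab <- table(frag_smiles)
  out <- tibble::tibble(
    smiles = names(tab),
    source_count = as.integer(tab)
  )
  out$n_atoms <- vapply(out$smiles,
                        function(s) n_atoms(parse_smiles(s, vocab)),
                        integer(1), USE.NAMES = FALSE)
  dplyr::arrange(out, dplyr::desc(.data$source_count), .data$smiles)
}

#' Summary statistics of a fragment corpus
#'
#' Mean and standard deviation of molecular weight and heavy-atom count,
#' the two figures conventionally reported for fragment training sets.
#' Statistics are weighted by `source_count` (each occurrence in the
#' source collection counts once).
#'
#' @param corpus A tibble from [build_corpus()].
#' @param vocab An [atom_vocab()].
#' @return A one-row tibble: `n_fragments`, `n_unique`, `mw_mean`, `mw_sd`,
#'   `atoms_mean`, `atoms_sd`.
#' @export
corpus_summary <- function(corpus, vocab = atom_vocab()) {
  mw <- vapply(corpus$smiles, smiles_mol_weight, numeric(1),
               USE.NAMES = FALSE)
  w <- corpus$source_count
  wmean <- function(x) sum(x * w) / sum(w)
  wsd <- function(x) sqrt(sum(w * (x - wmean(x))^2) / max(sum(w) - 1, 1))
  tibble::tibble(
    n_fragments = sum(w),
    n_unique = nrow(corpus),
    mw_mean = wmean(mw), mw_sd = wsd(mw),
    atoms_mean = wmean(corpus$n_atoms), atoms_sd = wsd(corpus$n_atoms)
  )
}

#' Write / read a fragment corpus as TSV
#'
#' @param corpus A tibble from [build_corpus()].
#' @param path File path.
#' @return `write_corpus` returns `path` invisibly; `read_corpus` returns
#'   the corpus tibble.
#' @export
write_corpus <- function(corpus, path) {
  utils::write.table(corpus, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}
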