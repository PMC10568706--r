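#' Procedural drug-like fixture molecules
#'
#' Offline stand-in for a screening collection: small drug-like molecules
#' assembled from common ring systems, substituents and linkers using the
#' package's own graph primitives, so every product is connected,
#' kekulized and valence-valid by construction. The generator emulates
#' the gross composition of drug-like collections (aromatic and
#' saturated rings bearing a few polar/halogen substituents, molecular
#' weights roughly 100-350); it does not emulate real-compound
#' diversity, stereochemistry or charge states.
#'
#' @param n Number of molecules.
#' @param max_atoms Heavy-atom cap per molecule.
#' @param ring_probability Probability that a molecule is built around a
#'   ring system (otherwise an acyclic scaffold).
#' @param element_weights Optional named non-negative weights over
#'   element symbols, tilting the substituent choice toward groups whose
#'   attachment atom is that element.
#' @param seed Integer seed; the corpus is reproducible under it.
#' @param vocab An [atom_vocab()].
#' @return Character vector of `n` canonical SMILES.
#' @export
generate_fixture_corpus <- function(n = 500L, max_atoms = 28L,
                                    ring_probability = 0.8,
                                    element_weights = NULL, seed = 1L,
                                    vocab = atom_vocab()) {
  stopifnot(n >= 1, ring_probability >= 0, ring_probability <= 1)
  rings <- c("c1ccccc1", "c1ccncc1", "c1cncnc1", "C1CCCCC1", "C1CCNCC1",
             "C1CCOCC1", "C1CCNC1", "C1CCOC1", "c1ccsc1", "c1ccoc1",
             "c1cc[nH]c1", "c1cnc[nH]1", "C1CNCCN1", "C1COCCN1")
  subs <- c("C", "CC", "CCC", "C(C)C", "C(C)(C)C", "O", "OC", "OCC",
            "N", "NC", "N(C)C", "F", "Cl", "Br", "C=O", "C(=O)O",
            "C(=O)N", "C(=O)C", "C#N", "S", "SC", "C(F)(F)F", "CO",
            "CN", "CCO", "CCN")
  linkers <- c("C", "CC", "CO", "CN", "CCO")
  ring_g <- lapply(rings, parse_smiles, vocab = vocab)
  sub_g <- lapply(subs, parse_smiles, vocab = vocab)
  link_g <- lapply(linkers, parse_smiles, vocab = vocab)
  sub_w <- rep(1, length(subs))
  if (!is.null(element_weights)) {
    first_el <- vapply(sub_g, function(g) element_symbols(g)[1], character(1))
    w <- element_weights[first_el]
    w[is.na(w)] <- 1
    sub_w <- as.numeric(w)
  }

  rand_site <- function(g) {
    fr <- which(free_valence(g) >= 1L)
    if (length(fr) == 0) return(NA_integer_)
    if (length(fr) == 1L) fr else sample(fr, 1L)
  }
  add_piece <- function(g, piece) {
    if (n_atoms(g) + n_atoms(piece) > max_atoms) return(g)
    site <- rand_site(g)
    if (is.na(site) || free_valence(piece, 1L) < 1L) return(g)
    attach_fragment(g, piece, site, 1L)
  }

  withr::with_seed(as.integer(seed), {
    vapply(seq_len(n), function(i) {
      if (stats::runif(1) < ring_probability) {
        g <- ring_g[[sample(length(ring_g), 1L)]]
        # sometimes a second ring, joined directly or through a linker
        if (stats::runif(1) < 0.35) {
          if (stats::runif(1) < 0.5)
            g <- add_piece(g, link_g[[sample(length(link_g), 1L)]])
          g <- add_piece(g, ring_g[[sample(length(ring_g), 1L)]])
        }
      } else {
        g <- sub_g[[sample(length(sub_g), 1L, prob = sub_w)]]
        g <- add_piece(g, sub_g[[sample(length(sub_g), 1L, prob = sub_w)]])
      }
      for (k in seq_len(sample(0:4, 1L))) {
        g <- add_piece(g, sub_g[[sample(length(sub_g), 1L, prob = sub_w)]])
      }
      write_smiles(g)
    }, character(1))
  })
}

#' Bundled fixture corpus
#'
#' Reads the synthetic drug-like SMILES list shipped with the package
#' (500 molecules produced by [generate_fixture_corpus()] with its
#' default settings and seed 20260101).
#'
#' @return Character vector of SMILES.
#' @export
moltree_example_corpus <- function() {
  path <- system.file("extdata", "synthetic_druglike_500.smi",
                      package = "moltree", mustWork = TRUE)
  read_smiles_file(path)
}

#' Select seed molecules within a score band
#'
#' Mirrors the seed-selection protocol of the optimization experiments:
#' molecules whose score lies in `[lo, hi]` are collected and `n` of
#' them are drawn at random.
#'
#' @param smiles Character vector of candidate SMILES.
#' @param sf A [score_function()] (or name accepted by
#'   [score_function()]).
#' @param lo,hi Score band (inclusive), `lo < hi`.
#' @param n Number of seeds to draw.
#' @param seed Integer RNG seed for the draw.
#' @param vocab An [atom_vocab()].
#' @return Character vector of `n` SMILES with scores inside the band.
#' @export
select_seed_molecules <- function(smiles, sf = "qed", lo = 0.6, hi = 0.7,
                                  n = 10L, seed = 1L,
                                  vocab = atom_vocab()) {
  stopifnot(lo < hi, n >= 1)
  if (!inherits(sf, "score_function")) sf <- score_function(sf)
  scores <- vapply(smiles, function(s) {
    g <- tryCatch(parse_smiles(s, vocab), error = function(e) NULL)
    if (is.null(g)) return(NA_real_)
    score_mol(sf, g)
  }, numeric(1), USE.NAMES = FALSE)
  ok <- which(!is.na(scores) & scores >= lo & scores <= hi)
  if (length(ok) < n)
    stop("insufficient candidates: only ", length(ok),
         " molecules score within [", lo, ", ", hi, "]", call. = FALSE)
  pick <- withr::with_seed(as.integer(seed), sample(ok, n))
  smiles[pick]
}
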