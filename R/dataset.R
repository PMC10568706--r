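#' Serialize a fragment into supervised generation steps
#'
#' Turns a fragment of n atoms into n + 1 teacher-forcing steps. Atoms are
#' arranged in deterministic BFS order from `root`; step t presents the
#' induced subgraph on the first t atoms as the state, the element of atom
#' t + 1 as the atom label, and, for each of the t existing atoms (in BFS
#' order), the order of its bond to the new atom or the "none" label. The
#' final step carries the stop label and no bond labels. Step 0 has an
#' empty state, so the first atom of a fragment is modelled as well.
#'
#' @param frag A connected [mol_graph()].
#' @param root BFS root (default atom 1; [build_training_steps()] first
#'   canonicalizes the fragment so that atom 1 is the first atom of the
#'   canonical ordering).
#' @param max_atoms Error when the fragment exceeds this size.
#' @return A list of steps; each step is a list with fields `atoms`
#'   (element indices of the state, BFS order), `bonds` (state bond matrix
#'   re-indexed to BFS positions), `atom_label` (1..10, stop = 10) and
#'   `bond_labels` (integer vector over 1..4, none = 4, one per state atom).
#' @export
serialize_fragment <- function(frag, root = 1L, max_atoms = 25L) {
  n <- n_atoms(frag)
  if (n > max_atoms)
    stop("fragment too large: ", n, " atoms (max_atoms = ", max_atoms, ")",
         call. = FALSE)
  stopifnot(n >= 1L)
  ord <- bfs_order(frag, root)
  vocab <- frag$vocab
  # bond order lookup between original atom indices
  bond_env <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(frag$bonds) > 0) {
    for (r in seq_len(nrow(frag$bonds))) {
      key <- paste0(frag$bonds[r, 1], "_", frag$bonds[r, 2])
      assign(key, frag$bonds[r, 3], envir = bond_env)
    }
  }
  get_order <- function(a, b) {
    key <- paste0(min(a, b), "_", max(a, b))
    if (exists(key, envir = bond_env)) get(key, envir = bond_env) else NULL
  }
  steps <- vector("list", n + 1L)
  state_bonds <- matrix(integer(0), ncol = 3)
  for (t in 0:(n - 1L)) {
    newa <- ord[t + 1L]
    bl <- integer(t)
    if (t > 0) {
      for (k in seq_len(t)) {
        o <- get_order(ord[k], newa)
        bl[k] <- if (is.null(o)) 4L else o
      }
    }
    steps[[t + 1L]] <- list(
      atoms = frag$atoms[ord[seq_len(t)]],
      bonds = state_bonds,
      atom_label = frag$atoms[newa],
      bond_labels = bl
    )
    # grow the state for the next step
    add <- which(bl != 4L)
    if (length(add) > 0) {
      state_bonds <- rbind(state_bonds,
                           cbind(add, rep(t + 1L, length(add)), bl[add]))
    }
  }
  steps[[n + 1L]] <- list(
    atoms = frag$atoms[ord],
    bonds = state_bonds,
    atom_label = vocab$stop_index,
    bond_labels = integer(0)
  )
  steps
}

#' Rebuild a fragment from its generation steps
#'
#' The inverse of [serialize_fragment()]: applies each (atom, bonds) step
#' to the growing state. Used both as the round-trip check on training
#' data and as the state-update rule during sampling.
#'
#' @param steps A list of steps as produced by [serialize_fragment()].
#' @param vocab An [atom_vocab()].
#' @return A [mol_graph()].
#' @export
replay_steps <- function(steps, vocab = atom_vocab()) {
  atoms <- integer(0)
  bonds <- matrix(integer(0), ncol = 3)
  for (st in steps) {
    if (st$atom_label == vocab$stop_index) break
    atoms <- c(atoms, st$atom_label)
    t <- length(atoms)
    add <- which(st$bond_labels != 4L)
    if (length(add) > 0) {
      bonds <- rbind(bonds, cbind(add, rep(t, length(add)),
                                  st$bond_labels[add]))
    }
  }
  mol_graph(atoms, bonds, vocab, check = TRUE)
}

#' Apply one generation step to a partial fragment
#'
#' Adds one atom and its bonds (the payload of a [serialize_fragment()]
#' step or a [sample_step()] draw) to the growing state.
#'
#' @param g The partial fragment ([mol_graph()]).
#' @param atom_label Element index of the new atom (not the stop label).
#' @param bond_labels Integer vector over 1..4 (none = 4), one per
#'   existing atom.
#' @return The grown, valence-checked [mol_graph()].
#' @export
apply_step <- function(g, atom_label, bond_labels) {
  t <- n_atoms(g)
  stopifnot(length(bond_labels) == t)
  add <- which(bond_labels != 4L)
  bonds <- g$bonds
  if (length(add) > 0) {
    bonds <- rbind(bonds, cbind(add, rep(t + 1L, length(add)),
                                as.integer(bond_labels[add])))
  }
  mol_graph(c(g$atoms, as.integer(atom_label)), bonds, g$vocab, check = TRUE)
}

#' Serialize a whole corpus into training steps
#'
#' Every fragment is first canonicalized (parsed back from its canonical
#' SMILES) so that serialization is rooted at atom 1 of the canonical atom
#' ordering — one deterministic serialization per fragment.
#'
#' @param corpus Tibble from [build_corpus()] (or any tibble with a
#'   `smiles` column).
#' @param vocab An [atom_vocab()].
#' @param max_atoms Passed to [serialize_fragment()].
#' @param weighting `"uniform"` serializes each distinct fragment once;
#'   `"source_count"` replicates each fragment's steps by its
#'   `source_count`, so frequent fragments weigh more during training.
#' @return A list with one element per fragment, each a list of steps;
#'   names are the fragment SMILES.
#' @export
build_training_steps <- function(corpus, vocab = atom_vocab(),
                                 max_atoms = 25L,
                                 weighting = c("uniform", "source_count")) {
  weighting <- match.arg(weighting)
  out <- lapply(corpus$smiles, function(s) {
    serialize_fragment(parse_smiles(s, vocab), root = 1L,
                       max_atoms = max_atoms)
  })
  names(out) <- corpus$smiles
  if (weighting == "source_count" && !is.null(corpus$source_count)) {
    out <- rep(out, times = corpus$source_count)
  }
  out
}

#' Split a corpus into training and test parts
#'
#' The split is by fragment (all steps of one fragment land on the same
#' side) and reproducible under `seed`.
#'
#' @param x A tibble (e.g. from [build_corpus()]) or a list.
#' @param ratio Fraction assigned to the training part, in (0, 1).
#' @param seed Integer seed.
#' @return A list with elements `train` and `test` of the same type as `x`.
#' @export
split_train_test <- function(x, ratio = 0.8, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  n_train <- round(n * ratio)
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  if (is.data.frame(x)) {
    list(train = x[sort(idx), , drop = FALSE],
         test = x[setdiff(seq_len(n), idx), , drop = FALSE])
  } else {
    list(train = x[sort(idx)], test = x[setdiff(seq_len(n), idx)])
  }
}
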