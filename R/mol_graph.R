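#' Molecular graphs
#'
#' `mol_graph` is the state object of both tree searches: a hydrogen-implicit,
#' kekulized molecular graph. Atoms are indices into an [atom_vocab()];
#' bonds are rows `(i, j, order)` with `i < j` and order in 1:3 (aromatic
#' rings are always stored as alternating Kekule single/double bonds).
#'
#' @param atoms Integer vector of element indices into `vocab$elements`,
#'   or a character vector of element symbols.
#' @param bonds Integer matrix with 3 columns `(i, j, order)`; may have zero
#'   rows. A `NULL` is treated as no bonds.
#' @param vocab An [atom_vocab()].
#' @param check If `TRUE` (default), validate indices, orders and valence.
#' @return An object of class `mol_graph`.
#' @examples
#' v <- atom_vocab()
#' g <- mol_graph(c("C", "O"), rbind(c(1L, 2L, 1L)), v)
#' n_atoms(g)
#' @export
mol_graph <- function(atoms, bonds = NULL, vocab = atom_vocab(), check = TRUE) {
  if (is.character(atoms)) {
    idx <- match(atoms, vocab$elements)
    if (anyNA(idx))
      stop("element not in vocabulary: ",
           paste(unique(atoms[is.na(idx)]), collapse = ", "), call. = FALSE)
    atoms <- idx
  }
  atoms <- as.integer(atoms)
  if (is.null(bonds) || NROW(bonds) == 0) {
    bonds <- matrix(integer(0), ncol = 3)
  } else {
    bonds <- matrix(as.integer(bonds), ncol = 3)
    swap <- bonds[, 1] > bonds[, 2]
    if (any(swap)) bonds[swap, 1:2] <- bonds[swap, 2:1]
  }
  colnames(bonds) <- c("i", "j", "order")
  g <- structure(list(atoms = atoms, bonds = bonds, vocab = vocab),
                 class = "mol_graph")
  if (check) {
    n <- length(atoms)
    if (any(atoms < 1L | atoms > length(vocab$elements)))
      stop("atom index out of vocabulary range", call. = FALSE)
    if (nrow(bonds) > 0) {
      if (any(bonds[, 1:2] < 1L) || any(bonds[, 1:2] > n))
        stop("bond refers to a nonexistent atom", call. = FALSE)
      if (any(bonds[, 1] == bonds[, 2]))
        stop("self-bond is not allowed", call. = FALSE)
      if (any(bonds[, 3] < 1L | bonds[, 3] > 3L))
        stop("bond order must be 1, 2 or 3 (kekulized)", call. = FALSE)
      key <- bonds[, 1] * (n + 1) + bonds[, 2]
      if (anyDuplicated(key))
        stop("duplicate bond between the same atom pair", call. = FALSE)
    }
    bad <- which(free_valence(g) < 0L)
    if (length(bad) > 0)
      stop("valence exceeded at atom(s) ",
           paste(bad, collapse = ", "), " (",
           paste(vocab$elements[atoms[bad]], collapse = ", "), ")",
           call. = FALSE)
  }
  g
}

#' Number of heavy atoms in a graph
#' @param g A [mol_graph()].
#' @return Integer.
#' @export
n_atoms <- function(g) length(g$atoms)

#' Element symbols of a graph's atoms
#' @param g A [mol_graph()].
#' @return Character vector.
#' @export
element_symbols <- function(g) g$vocab$elements[g$atoms]

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", n_atoms(x), " atoms, ", nrow(x$bonds), " bonds",
      sep = "")
  if (n_atoms(x) > 0 && n_atoms(x) <= 60) {
    sm <- tryCatch(write_smiles(x), error = function(e) NULL)
    if (!is.null(sm)) cat(": ", sm, sep = "")
  }
  cat("\n")
  invisible(x)
}

# per-atom sum of bond orders (heavy neighbors only, H implicit)
bond_order_sums <- function(g) {
  s <- numeric(length(g$atoms))
  if (nrow(g$bonds) > 0) {
    for (r in seq_len(nrow(g$bonds))) {
      s[g$bonds[r, 1]] <- s[g$bonds[r, 1]] + g$bonds[r, 3]
      s[g$bonds[r, 2]] <- s[g$bonds[r, 2]] + g$bonds[r, 3]
    }
  }
  as.integer(s)
}

# per-atom heavy-neighbor count
degrees <- function(g) {
  d <- integer(length(g$atoms))
  if (nrow(g$bonds) > 0) {
    t1 <- tabulate(g$bonds[, 1], nbins = length(g$atoms))
    t2 <- tabulate(g$bonds[, 2], nbins = length(g$atoms))
    d <- t1 + t2
  }
  d
}

#' Free valence of atoms
#'
#' Number of additional single-bond equivalents an atom can accept:
#' the element's maximum valence minus the current bond-order sum. Atoms
#' with free valence 0 are excluded from bonding during generation.
#'
#' @param g A [mol_graph()].
#' @param i Atom index, or `NULL` (default) for all atoms at once.
#' @return Integer vector (scalar when `i` is given).
#' @export
free_valence <- function(g, i = NULL) {
  fv <- g$vocab$max_valence[g$atoms] - bond_order_sums(g)
  names(fv) <- NULL
  if (is.null(i)) return(as.integer(fv))
  if (any(i < 1L | i > length(g$atoms)))
    stop("atom index out of range: ", paste(i, collapse = ", "), call. = FALSE)
  as.integer(fv[i])
}

# neighbor list: for each atom, integer vector of neighbors (ascending)
neighbor_list <- function(g) {
  n <- length(g$atoms)
  nb <- vector("list", n)
  if (nrow(g$bonds) > 0) {
    for (r in seq_len(nrow(g$bonds))) {
      i <- g$bonds[r, 1]; j <- g$bonds[r, 2]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  lapply(nb, function(x) if (is.null(x)) integer(0) else sort(x))
}

#' Breadth-first ordering of atoms
#'
#' Deterministic BFS used to serialize fragments into training sequences:
#' among frontier atoms of equal depth, neighbors are visited in ascending
#' atom-index order.
#'
#' @param g A connected [mol_graph()].
#' @param root Atom index to start from.
#' @return Integer permutation of `1:n_atoms(g)`, starting with `root`.
#' @export
bfs_order <- function(g, root = 1L) {
  n <- length(g$atoms)
  if (root < 1L || root > n)
    stop("atom index out of range: ", root, call. = FALSE)
  nb <- neighbor_list(g)
  seen <- logical(n)
  order <- integer(n)
  order[1] <- root
  seen[root] <- TRUE
  head <- 1L; tail <- 1L
  while (head <= tail && tail < n) {
    for (v in nb[[order[head]]]) {
      if (!seen[v]) {
        tail <- tail + 1L
        order[tail] <- v
        seen[v] <- TRUE
      }
    }
    head <- head + 1L
  }
  if (tail < n) stop("graph is not connected", call. = FALSE)
  order
}

# connectivity test by BFS (TRUE for empty/single-atom graphs)
graph_connected <- function(g) {
  n <- length(g$atoms)
  if (n <= 1L) return(TRUE)
  !inherits(tryCatch(bfs_order(g, 1L), error = function(e) e), "error")
}

# induced subgraph on `idx`, atoms re-indexed in the order given
induced_subgraph_mol <- function(g, idx) {
  pos <- match(seq_along(g$atoms), idx)
  keep <- g$bonds[!is.na(pos[g$bonds[, 1]]) & !is.na(pos[g$bonds[, 2]]), ,
                  drop = FALSE]
  if (nrow(keep) > 0) {
    keep[, 1] <- pos[keep[, 1]]
    keep[, 2] <- pos[keep[, 2]]
  }
  mol_graph(g$atoms[idx], keep, g$vocab, check = FALSE)
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    d = as.data.frame(g$bonds[, 1:2, drop = FALSE]),
    directed = FALSE,
    vertices = data.frame(name = seq_along(g$atoms))
  )
}

# indices of bond rows that sit in a ring (= non-bridge edges)
ring_bond_rows <- function(g) {
  if (nrow(g$bonds) == 0) return(integer(0))
  ig <- as_igraph(g)
  br <- igraph::bridges(ig)
  setdiff(seq_len(nrow(g$bonds)), as.integer(br))
}

# logical: atom participates in at least one ring
ring_atoms <- function(g) {
  inring <- logical(length(g$atoms))
  rr <- ring_bond_rows(g)
  if (length(rr) > 0) {
    inring[g$bonds[rr, 1]] <- TRUE
    inring[g$bonds[rr, 2]] <- TRUE
  }
  inring
}

#' Enumerate fragment-removal children
#'
#' The removal action of the outer (fragment-wise) search: for every
#' acyclic single bond whose deletion splits the molecule in two, keep the
#' connected component with the larger number of atoms as a child. Children
#' are deduplicated by canonical SMILES. A tie in component size is broken
#' by keeping the component whose canonical SMILES sorts first.
#'
#' @param g A connected [mol_graph()] with at least one atom.
#' @return A named list of [mol_graph()] children; names are canonical
#'   SMILES. Empty when no bond qualifies (e.g. a pure ring system).
#' @export
enumerate_removals <- function(g) {
  out <- structure(list(), names = character(0))
  if (nrow(g$bonds) == 0) return(out)
  rings <- ring_bond_rows(g)
  cand <- which(g$bonds[, 3] == 1L)
  cand <- setdiff(cand, rings)
  if (length(cand) == 0) return(out)
  for (r in cand) {
    i <- g$bonds[r, 1]
    # deleting a bridge always yields exactly two components; collect the
    # side containing i by BFS that may not cross bond row r
    comp_i <- component_without_bond(g, r, start = i)
    comp_j <- setdiff(seq_along(g$atoms), comp_i)
    if (length(comp_i) > length(comp_j)) {
      keep <- comp_i
    } else if (length(comp_j) > length(comp_i)) {
      keep <- comp_j
    } else {
      gi <- induced_subgraph_mol(g, sort(comp_i))
      gj <- induced_subgraph_mol(g, sort(comp_j))
      si <- write_smiles(gi); sj <- write_smiles(gj)
      keep <- if (si <= sj) comp_i else comp_j
    }
    child <- induced_subgraph_mol(g, sort(keep))
    sm <- write_smiles(child)
    if (!sm %in% names(out)) out[[sm]] <- child
  }
  out
}

# atoms reachable from `start` when bond row `r` is removed
component_without_bond <- function(g, r, start) {
  nb <- neighbor_list(g)
  bi <- g$bonds[r, 1]; bj <- g$bonds[r, 2]
  seen <- logical(length(g$atoms))
  seen[start] <- TRUE
  queue <- start
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in nb[[v]]) {
      if ((v == bi && w == bj) || (v == bj && w == bi)) next
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  which(seen)
}

#' Attach a fragment to a parent molecule by one single bond
#'
#' The addition primitive of both searches: forms the disjoint union of
#' `parent` and `frag` and adds a single bond between `parent_atom` and
#' `fragment_atom`. Both attachment atoms must have free valence of at
#' least 1; otherwise the site is unusable and an error is signalled.
#'
#' @param parent,frag [mol_graph()] objects sharing the same vocabulary.
#' @param parent_atom Atom index in `parent` with free valence >= 1.
#' @param fragment_atom Atom index in `frag` with free valence >= 1.
#' @return A connected, valence-valid [mol_graph()]. Fragment atoms are
#'   appended after the parent's atoms.
#' @export
attach_fragment <- function(parent, frag, parent_atom, fragment_atom = 1L) {
  if (free_valence(parent, parent_atom) < 1L)
    stop("valence violation: parent atom ", parent_atom,
         " has no free valence", call. = FALSE)
  if (free_valence(frag, fragment_atom) < 1L)
    stop("valence violation: fragment atom ", fragment_atom,
         " has no free valence", call. = FALSE)
  np <- length(parent$atoms)
  fb <- frag$bonds
  if (nrow(fb) > 0) fb[, 1:2] <- fb[, 1:2] + np
  bonds <- rbind(parent$bonds, fb,
                 c(parent_atom, fragment_atom + np, 1L))
  mol_graph(c(parent$atoms, frag$atoms), bonds, parent$vocab, check = TRUE)
}
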