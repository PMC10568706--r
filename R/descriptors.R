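# Physicochemical descriptors. logP, TPSA, MW and H-bond donor/acceptor
# counts come from OpenBabel in a single conversion call per molecule;
# rotatable bonds, ring perception and aromaticity are computed on the
# package's own graphs.

ATOMIC_MASS <- c(C = 12.011, N = 14.007, O = 15.999, F = 18.998,
                 P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904,
                 I = 126.904)
H_MASS <- 1.008

#' Molecular weight of a graph
#'
#' Average-mass molecular weight including implicit hydrogens (every unit
#' of free valence carries one hydrogen).
#'
#' @param g A [mol_graph()].
#' @return Numeric scalar (g/mol).
#' @export
mol_weight <- function(g) {
  sum(ATOMIC_MASS[element_symbols(g)]) + H_MASS * sum(free_valence(g))
}

smiles_mol_weight <- function(s, vocab = atom_vocab()) {
  mol_weight(parse_smiles(s, vocab))
}

# one OpenBabel call: canonical SMILES + logP TPSA MW HBA HBD
ob_properties <- function(g) {
  opts <- data.frame(names = "append", args = "logP TPSA MW HBA1 HBD")
  out <- quiet_ob(ChemmineOB::convertFormat("SDF", "CAN", mol_to_molblock(g),
                                            options = opts))
  fields <- strsplit(trimws(out), "[\t ]+")[[1]]
  if (length(fields) < 6)
    stop("descriptor computation failed for graph", call. = FALSE)
  list(cansmi = fields[1],
       logp = as.numeric(fields[2]),
       tpsa = as.numeric(fields[3]),
       mw = as.numeric(fields[4]),
       hba = as.integer(fields[5]),
       hbd = as.integer(fields[6]))
}

# smallest rings: for every cycle bond, the shortest cycle through it
# (atom-index sets, deduplicated) -- a practical stand-in for the SSSR
find_rings <- function(g) {
  rr <- ring_bond_rows(g)
  if (length(rr) == 0) return(list())
  nb <- neighbor_list(g)
  rings <- list()
  seen <- character(0)
  for (r in rr) {
    i <- g$bonds[r, 1]; j <- g$bonds[r, 2]
    # BFS from i to j avoiding the bond (i, j)
    n <- length(g$atoms)
    prev <- integer(n); dist <- rep(NA_integer_, n)
    dist[i] <- 0L
    queue <- i
    while (length(queue) > 0 && is.na(dist[j])) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in nb[[v]]) {
        if ((v == i && w == j) || (v == j && w == i)) next
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          prev[w] <- v
          queue <- c(queue, w)
        }
      }
    }
    if (is.na(dist[j])) next
    path <- j
    while (path[1] != i) path <- c(prev[path[1]], path)
    key <- paste(sort(path), collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- path
    }
  }
  rings
}

# Hueckel-style aromaticity test on one ring: every member must be
# sp2-compatible, and the pi-electron count must be 4n + 2.
# pi contributions: atom with a double bond inside the ring -> 1;
# N/O/S with only single ring bonds and no exocyclic double bond -> 2
# (lone pair); carbon with an exocyclic double bond -> 0; anything else
# disqualifies the ring.
is_aromatic_ring <- function(g, ring) {
  rset <- ring
  electrons <- 0L
  for (a in rset) {
    rows <- which(g$bonds[, 1] == a | g$bonds[, 2] == a)
    orders <- g$bonds[rows, 3]
    partner <- ifelse(g$bonds[rows, 1] == a, g$bonds[rows, 2],
                      g$bonds[rows, 1])
    in_ring <- partner %in% rset
    sym <- element_symbols(g)[a]
    if (any(orders == 2 & in_ring)) {
      electrons <- electrons + 1L
    } else if (any(orders == 2 & !in_ring)) {
      if (sym == "C") next # exocyclic double bond: contributes 0
      return(FALSE)
    } else if (sym %in% c("N", "O", "S")) {
      electrons <- electrons + 2L # lone pair
    } else {
      return(FALSE) # saturated carbon
    }
  }
  electrons >= 2 && (electrons - 2L) %% 4L == 0L
}

count_aromatic_rings <- function(g) {
  rings <- find_rings(g)
  if (length(rings) == 0) return(0L)
  sum(vapply(rings, function(r) is_aromatic_ring(g, r), logical(1)))
}

# acyclic single bonds between two non-terminal heavy atoms (the common
# definition, without the amide exception)
count_rotatable_bonds <- function(g) {
  if (nrow(g$bonds) == 0) return(0L)
  deg <- degrees(g)
  rr <- ring_bond_rows(g)
  cand <- setdiff(which(g$bonds[, 3] == 1L), rr)
  sum(deg[g$bonds[cand, 1]] >= 2L & deg[g$bonds[cand, 2]] >= 2L)
}

max_ring_size <- function(g) {
  rings <- find_rings(g)
  if (length(rings) == 0) return(0L)
  max(vapply(rings, length, integer(1)))
}

#' Descriptor set of a molecule
#'
#' The eight properties entering the drug-likeness score plus the
#' canonical SMILES: molecular weight, octanol/water logP (OpenBabel's
#' Wildman-Crippen implementation), H-bond acceptor and donor counts,
#' topological polar surface area, rotatable bonds, aromatic ring count
#' and the structural-alert count (always 0 here; see the package
#' vignette for the approximations).
#'
#' @param g A [mol_graph()].
#' @return A named list.
#' @export
mol_descriptors <- function(g) {
  ob <- ob_properties(g)
  list(cansmi = ob$cansmi, mw = ob$mw, alogp = ob$logp, hba = ob$hba,
       hbd = ob$hbd, psa = ob$tpsa, rotb = count_rotatable_bonds(g),
       arom = count_aromatic_rings(g), alerts = 0L)
}
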