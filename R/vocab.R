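#' Atom vocabulary
#'
#' The fixed set of heavy elements the generator can emit, plus a sentinel
#' "stop" label meaning termination of fragment growth. The default is the
#' nine heavy elements of drug-like screening collections (C, N, O, F, P, S,
#' Cl, Br, I), so the atom-prediction head of the generator has 10 output
#' classes. Hydrogens are implicit throughout: valence accounting compares
#' the heavy-atom bond-order sum against each element's maximum valence.
#'
#' @param elements Character vector of element symbols, in a fixed order.
#' @param max_valence Named integer vector of maximum valences, one per
#'   element. Defaults cover the standard nine-element set.
#' @return An object of class `atom_vocab` with fields `elements`,
#'   `max_valence` and `stop_index` (`length(elements) + 1`).
#' @examples
#' v <- atom_vocab()
#' v$stop_index # 10
#' @export
atom_vocab <- function(elements = c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
                       max_valence = NULL) {
  default_val <- c(C = 4L, N = 3L, O = 2L, F = 1L, P = 5L, S = 6L,
                   Cl = 1L, Br = 1L, I = 1L)
  if (is.null(max_valence)) {
    missing <- setdiff(elements, names(default_val))
    if (length(missing) > 0)
      stop("no default maximum valence for element(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    max_valence <- default_val[elements]
  }
  stopifnot(length(elements) == length(max_valence), !anyDuplicated(elements))
  structure(
    list(elements = as.character(elements),
         max_valence = stats::setNames(as.integer(max_valence), elements),
         stop_index = length(elements) + 1L),
    class = "atom_vocab"
  )
}

#' @export
print.atom_vocab <- function(x, ...) {
  cat("<atom_vocab> ", length(x$elements), " elements + stop label\n", sep = "")
  cat("  ", paste0(x$elements, "(", x$max_valence, ")", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Bond vocabulary
#'
#' Bond orders the model distinguishes: single, double, triple, plus a
#' sentinel "none" label (index 4) meaning no bond. There is deliberately no
#' aromatic label: molecules are always handled as Kekule structures in
#' which aromatic rings carry alternating single and double bonds, so the
#' bond-prediction head has 4 output classes.
#'
#' @return An object of class `bond_vocab` with fields `orders` (1:3) and
#'   `none_index` (4).
#' @export
bond_vocab <- function() {
  structure(list(orders = 1:3, none_index = 4L), class = "bond_vocab")
}

#' Fingerprint of an atom vocabulary
#'
#' A short deterministic hash of the element list and valence table, stored
#' in generator checkpoints so that a model trained under one vocabulary
#' refuses to run under another.
#'
#' @param vocab An [atom_vocab()].
#' @return A character scalar (hex digits).
#' @export
vocab_fingerprint <- function(vocab) {
  stopifnot(inherits(vocab, "atom_vocab"))
  s <- paste(vocab$elements, vocab$max_valence, collapse = ";", sep = ":")
  bytes <- utf8ToInt(s)
  # 32-bit FNV-1a in doubles; bytes only touch the low 8 bits, so the xor
  # can be done on the low byte alone and stays inside R's integer range
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # h * 16777619 mod 2^32 without exceeding double precision
    h <- ((h %% 65536) * 16777619 + ((h %/% 65536 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}
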