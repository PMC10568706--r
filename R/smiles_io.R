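#' Parse a SMILES string into a molecular graph
#'
#' Parsing and kekulization are delegated to OpenBabel (via ChemmineR /
#' ChemmineOB); the resulting atom and bond blocks are converted into a
#' [mol_graph()]. Stereochemistry annotations and formal charges are
#' stripped on input: the search and the generator operate on 2-D,
#' hydrogen-implicit, neutral topological graphs. Molecules that are not
#' valence-valid after charge stripping (e.g. quaternary ammonium) are
#' rejected, as are disconnected (multi-component) inputs and molecules
#' containing elements outside the vocabulary.
#'
#' @param s A single SMILES string.
#' @param vocab An [atom_vocab()].
#' @return A connected, kekulized, valence-valid [mol_graph()] whose
#'   `provenance` attribute holds the canonical SMILES.
#' @examples
#' g <- parse_smiles("c1ccccc1")
#' n_atoms(g)        # 6
#' sort(g$bonds[, 3]) # alternating Kekule orders: 1 1 1 2 2 2
#' @export
parse_smiles <- function(s, vocab = atom_vocab()) {
  stopifnot(is.character(s), length(s) == 1L)
  s0 <- strip_stereo_charges(s)
  block <- quiet_ob(tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", s0),
    error = function(e) ""))
  if (is.na(block) || !nzchar(block))
    stop("invalid SMILES: ", s, call. = FALSE)
  molblock_to_graph(block, vocab, source = s)
}

# remove stereo bonds/centres and bracket charges from raw SMILES text
strip_stereo_charges <- function(s) {
  s <- gsub("[/\\\\]", "", s)
  s <- gsub("@{1,2}", "", s)
  # charges occur only inside brackets: [N+], [O-], [NH3+], [Fe+2] ...
  m <- gregexpr("\\[[^][]*\\]", s)
  regmatches(s, m) <- lapply(regmatches(s, m),
                             function(v) gsub("[+-][0-9]*", "", v))
  s
}

# ChemmineOB prints parser warnings straight to stderr; keep them quiet
quiet_ob <- function(expr) {
  suppressMessages(suppressWarnings(expr))
}

# minimal V2000 molblock reader: OpenBabel's SDF output is kekulized and
# fixed-width, which is all we need (ChemmineR's SDF container rejects
# single-atom records, so counts/atom/bond lines are read directly)
molblock_to_graph <- function(block, vocab, source = NULL) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4)
    stop("invalid SMILES: ", source, call. = FALSE)
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1)
    stop("invalid SMILES: ", source, call. = FALSE)
  atom_lines <- lines[5:(4 + na)]
  syms <- trimws(substr(atom_lines, 32, 34))
  idx <- match(syms, vocab$elements)
  if (anyNA(idx))
    stop("element not in vocabulary: ",
         paste(unique(syms[is.na(idx)]), collapse = ", "),
         if (!is.null(source)) paste0(" (in ", source, ")"),
         call. = FALSE)
  bonds <- NULL
  if (nb > 0) {
    bl <- lines[(5 + na):(4 + na + nb)]
    bonds <- cbind(as.integer(substr(bl, 1, 3)),
                   as.integer(substr(bl, 4, 6)),
                   as.integer(substr(bl, 7, 9)))
    if (any(is.na(bonds)))
      stop("malformed bond block", call. = FALSE)
    if (any(bonds[, 3] > 3L))
      stop("non-kekulized bond order in parsed structure",
           if (!is.null(source)) paste0(" (in ", source, ")"), call. = FALSE)
  }
  g <- mol_graph(idx, bonds, vocab, check = TRUE)
  if (!graph_connected(g))
    stop("molecule is disconnected (multi-component SMILES)",
         if (!is.null(source)) paste0(": ", source), call. = FALSE)
  g
}

# V2000 molblock text for a graph (zero coordinates; topology only)
mol_to_molblock <- function(g) {
  n <- length(g$atoms)
  nb <- nrow(g$bonds)
  lines <- c(
    "",
    " moltree",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
  )
  if (n > 0) {
    lines <- c(lines, sprintf(
      "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      element_symbols(g)))
  }
  if (nb > 0) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              g$bonds[, 1], g$bonds[, 2], g$bonds[, 3]))
  }
  paste(c(lines, "M  END", "$$$$"), collapse = "\n")
}

#' Write a molecular graph as canonical SMILES
#'
#' Serializes the graph to a molblock and asks OpenBabel for the canonical
#' SMILES, which is also the deduplication key used throughout the package.
#'
#' @param g A valence-valid [mol_graph()] with at least one atom.
#' @return A single canonical SMILES string.
#' @examples
#' write_smiles(parse_smiles("OCC")) # "CCO"
#' @export
write_smiles <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  if (length(g$atoms) == 0)
    stop("cannot write SMILES for an empty graph", call. = FALSE)
  block <- mol_to_molblock(g)
  out <- quiet_ob(tryCatch(ChemmineOB::convertFormat("SDF", "CAN", block),
                           error = function(e) ""))
  out <- strsplit(out, "[\t\n]")[[1]][1]
  if (length(out) == 0 || is.na(out) || !nzchar(out)) {
    # occasional transient conversion failures: retry once
    out <- quiet_ob(tryCatch(ChemmineOB::convertFormat("SDF", "CAN", block),
                             error = function(e) ""))
    out <- strsplit(out, "[\t\n]")[[1]][1]
  }
  if (length(out) == 0 || is.na(out) || !nzchar(out))
    stop("SMILES writer failed", call. = FALSE)
  out
}

#' Canonicalize a SMILES string
#'
#' @param s A SMILES string (vectorized).
#' @return Canonical SMILES of the same length; `NA` where invalid.
#' @export
canonical_smiles <- function(s) {
  vapply(s, function(x) {
    out <- quiet_ob(tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", strip_stereo_charges(x)),
      error = function(e) ""))
    out <- strsplit(out, "[\t\n]")[[1]][1]
    if (length(out) == 0 || is.na(out) || !nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# parse(write(g)): same molecule with atoms in canonical order
canonicalize_graph <- function(g) {
  parse_smiles(write_smiles(g), g$vocab)
}

#' Test two graphs for chemical identity
#'
#' Graph isomorphism is decided by equality of canonical SMILES.
#'
#' @param a,b [mol_graph()] objects.
#' @return Logical scalar.
#' @export
same_molecule <- function(a, b) {
  identical(write_smiles(a), write_smiles(b))
}

#' Read a one-SMILES-per-line file
#'
#' @param path File path; blank lines and lines starting with `#` are
#'   skipped. Only the first whitespace-separated token of each line is
#'   used, so "SMILES name" files work too.
#' @return Character vector of SMILES.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vapply(strsplit(lines, "[[:space:]]+"), `[[`, character(1), 1L)
}
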