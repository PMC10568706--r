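#' Built-in evaluation functions and generation-quality metrics
#'
#' @name scoring
NULL

# Asymmetric double sigmoid desirability parameters for the eight QED
# properties (Bickerton et al. 2012, Nature Chemistry 4:90, Table 1 of
# the supplement), and the "mean" property weights from the same work.
QED_ADS <- list(
  MW     = c(a = 2.817065973, b = 392.5754953, c = 290.7489764,
             d = 2.419764353, e = 49.22325677, f = 65.37051707,
             dmax = 104.9805561),
  ALOGP  = c(a = 3.172690585, b = 137.8624751, c = 2.534937431,
             d = 4.581497897, e = 0.822739154, f = 0.576295591,
             dmax = 131.3186604),
  HBA    = c(a = 2.948620388, b = 160.4605972, c = 3.615294657,
             d = 4.435986202, e = 0.290141953, f = 1.300669958,
             dmax = 148.7763046),
  HBD    = c(a = 1.618662227, b = 1010.051101, c = 0.985094388,
             d = 0.000000001, e = 0.713820843, f = 0.920922555,
             dmax = 258.1632616),
  PSA    = c(a = 1.876861559, b = 125.2232657, c = 62.90773554,
             d = 87.83366614, e = 12.01999824, f = 28.51324732,
             dmax = 104.5686167),
  ROTB   = c(a = 0.010000000, b = 272.4121427, c = 2.558379970,
             d = 1.565547684, e = 1.271567166, f = 2.758063707,
             dmax = 105.4420403),
  AROM   = c(a = 3.217788970, b = 957.7374108, c = 2.274627939,
             d = 0.000000001, e = 1.317690384, f = 0.375760881,
             dmax = 312.3372610),
  ALERTS = c(a = 0.010000000, b = 1199.094025, c = -0.09002883,
             d = 0.000000001, e = 0.185904477, f = 0.875193782,
             dmax = 417.7253140)
)
QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                 PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

qed_ads <- function(x, p) {
  exp1 <- 1 + exp(-(x - p[["c"]] + p[["d"]] / 2) / p[["e"]])
  exp2 <- 1 + exp(-(x - p[["c"]] - p[["d"]] / 2) / p[["f"]])
  (p[["a"]] + p[["b"]] / exp1 * (1 - 1 / exp2)) / p[["dmax"]]
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Weighted geometric mean of desirability transforms of eight
#' physicochemical properties, on the published desirability curves and
#' "mean" weights. Values lie in (0, 1); higher is more drug-like. See
#' the vignette for the descriptor-level approximations this
#' implementation makes.
#'
#' @param g A [mol_graph()] or a SMILES string.
#' @param vocab Vocabulary used when `g` is a SMILES string.
#' @return Numeric scalar in (0, 1).
#' @export
qed_score <- function(g, vocab = atom_vocab()) {
  if (is.character(g)) g <- parse_smiles(g, vocab)
  d <- mol_descriptors(g)
  x <- c(MW = d$mw, ALOGP = d$alogp, HBA = d$hba, HBD = d$hbd,
         PSA = d$psa, ROTB = d$rotb, AROM = d$arom, ALERTS = d$alerts)
  di <- vapply(names(QED_ADS),
               function(nm) max(qed_ads(x[[nm]], QED_ADS[[nm]]), 1e-10),
               numeric(1))
  exp(sum(QED_WEIGHTS * log(di)) / sum(QED_WEIGHTS))
}

#' Synthetic-complexity heuristic
#'
#' A lightweight stand-in for fragment-contribution synthetic
#' accessibility scores, built from the complexity terms such scores
#' penalize: heavy-atom count, ring fusion, macrocycles and quaternary
#' branching. Roughly on a 1 (easy) to 10 (hard) scale and monotone in
#' each ingredient.
#'
#' @param g A [mol_graph()].
#' @return Numeric scalar.
#' @export
sa_heuristic <- function(g) {
  n <- n_atoms(g)
  rings <- find_rings(g)
  ring_member_counts <- table(unlist(rings))
  fused_atoms <- sum(ring_member_counts >= 2)
  macro <- if (length(rings) == 0) 0L else
    sum(vapply(rings, length, integer(1)) > 8L)
  quart <- sum(degrees(g) >= 4L)
  sa <- 1 + 0.4 * sqrt(max(n - 10, 0)) + 0.25 * fused_atoms +
    1.0 * macro + 0.3 * quart
  min(sa, 10)
}

#' Penalized logP
#'
#' The standard unbounded optimization target: octanol/water logP minus a
#' synthetic-complexity penalty minus a large-ring penalty (number of
#' ring atoms beyond 6 in the largest ring). Terms are left on their
#' natural scales (no z-scoring).
#'
#' @param g A [mol_graph()] or a SMILES string.
#' @param vocab Vocabulary used when `g` is a SMILES string.
#' @return Numeric scalar.
#' @export
penalized_logp <- function(g, vocab = atom_vocab()) {
  if (is.character(g)) g <- parse_smiles(g, vocab)
  ob <- ob_properties(g)
  ring_pen <- max(0L, max_ring_size(g) - 6L)
  ob$logp - sa_heuristic(g) - ring_pen
}

# ---- ECFP4 fingerprint -------------------------------------------------

# deterministic hash of an integer vector into [0, 2^31); 31 * 2^31 is
# far below double precision, so plain arithmetic is exact
hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + x) %% 2147483648
  h
}

#' ECFP4 fingerprint bit set
#'
#' Extended-connectivity fingerprint of radius 2: atoms start from an
#' invariant built from element, degree, bond-order sum, implicit
#' hydrogen count and ring membership, then neighbourhood identifiers
#' are iteratively hashed for two rounds and folded into `nbits` bits.
#'
#' @param g A [mol_graph()] or SMILES string.
#' @param nbits Fingerprint length (default 2048).
#' @param vocab Vocabulary used when `g` is a SMILES string.
#' @return Sorted integer vector of set bit positions (0-based).
#' @export
ecfp4_bits <- function(g, nbits = 2048L, vocab = atom_vocab()) {
  if (is.character(g)) g <- parse_smiles(g, vocab)
  n <- n_atoms(g)
  if (n == 0) return(integer(0))
  deg <- degrees(g)
  bos <- bond_order_sums(g)
  fv <- free_valence(g)
  inring <- ring_atoms(g)
  ids <- vapply(seq_len(n), function(i) {
    hash_ints(c(g$atoms[i], deg[i], bos[i], fv[i], as.integer(inring[i])))
  }, numeric(1))
  all_ids <- ids
  nb <- neighbor_list(g)
  border <- function(a, b) {
    rows <- which((g$bonds[, 1] == min(a, b)) & (g$bonds[, 2] == max(a, b)))
    g$bonds[rows[1], 3]
  }
  for (radius in 1:2) {
    new_ids <- vapply(seq_len(n), function(i) {
      pairs <- lapply(nb[[i]], function(j) c(border(i, j), ids[j]))
      if (length(pairs) > 0) {
        ord <- order(vapply(pairs, `[`, numeric(1), 1L),
                     vapply(pairs, `[`, numeric(1), 2L))
        pairs <- pairs[ord]
      }
      hash_ints(c(radius, ids[i], unlist(pairs)))
    }, numeric(1))
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  sort(unique(as.integer(all_ids %% nbits)))
}

#' Tanimoto similarity on ECFP4 fingerprints
#'
#' @param a,b [mol_graph()] objects or SMILES strings.
#' @param nbits Fingerprint length.
#' @param vocab Vocabulary used for SMILES inputs.
#' @return Numeric in \[0, 1\]; 1 for identical structures.
#' @export
tanimoto_ecfp4 <- function(a, b, nbits = 2048L, vocab = atom_vocab()) {
  ba <- ecfp4_bits(a, nbits, vocab)
  bb <- ecfp4_bits(b, nbits, vocab)
  if (length(ba) == 0 && length(bb) == 0) return(1)
  length(intersect(ba, bb)) / length(union(ba, bb))
}

# ---- score-function objects -------------------------------------------

#' Evaluation functions for the search
#'
#' Wraps a scoring rule as a `score_function` object: a pure function
#' from molecule to finite real plus an optional declared range (used to
#' pick the reward squashing automatically). Built-ins: `"qed"` (range
#' 0..1) and `"plogp"` (unbounded). A user function taking a
#' [mol_graph()] and returning a finite numeric can be supplied directly.
#' Scores are cached by canonical SMILES, so repeated evaluation of the
#' same structure is free and bit-for-bit identical.
#'
#' @param score `"qed"`, `"plogp"`, or a function `(mol_graph) -> numeric`.
#' @param range Optional numeric length-2 declared range of a custom
#'   score.
#' @param name Display name for a custom score.
#' @return A `score_function` object; call it via [score_mol()].
#' @export
score_function <- function(score = "qed", range = NULL, name = NULL) {
  if (is.character(score)) {
    score <- match.arg(score, c("qed", "plogp"))
    fn <- switch(score, qed = qed_score, plogp = penalized_logp)
    range <- switch(score, qed = c(0, 1), plogp = NULL)
    name <- score
  } else {
    stopifnot(is.function(score))
    fn <- score
    if (is.null(name)) name <- "custom"
  }
  structure(list(fn = fn, name = name, range = range,
                 cache = new.env(hash = TRUE, parent = emptyenv())),
            class = "score_function")
}

#' @export
print.score_function <- function(x, ...) {
  cat("<score_function> ", x$name,
      if (!is.null(x$range)) paste0(" range [", x$range[1], ", ",
                                    x$range[2], "]"),
      "; ", length(ls(x$cache)), " cached\n", sep = "")
  invisible(x)
}

#' Evaluate a score function on a molecule
#'
#' @param sf A [score_function()].
#' @param g A [mol_graph()].
#' @param smiles Optional pre-computed canonical SMILES (cache key);
#'   computed when missing.
#' @return Numeric scalar.
#' @export
score_mol <- function(sf, g, smiles = NULL) {
  if (is.null(smiles)) smiles <- write_smiles(g)
  if (exists(smiles, envir = sf$cache, inherits = FALSE))
    return(get(smiles, envir = sf$cache, inherits = FALSE))
  val <- sf$fn(g)
  if (!(is.finite(val) || identical(val, -Inf)))
    stop("score function returned a non-finite value for ", smiles,
         call. = FALSE)
  assign(smiles, val, envir = sf$cache)
  val
}

#' Similarity-constrained score
#'
#' Wraps a base score so that molecules whose ECFP4 Tanimoto similarity
#' to `seed` falls below `delta` receive `-Inf` and are never selected.
#'
#' @param base A [score_function()].
#' @param seed Seed molecule ([mol_graph()] or SMILES).
#' @param delta Similarity threshold in \[0, 1\].
#' @param vocab Vocabulary for SMILES input.
#' @return A new `score_function`.
#' @export
similarity_constrained_score <- function(base, seed, delta = 0.4,
                                         vocab = atom_vocab()) {
  stopifnot(delta >= 0, delta <= 1)
  if (is.character(seed)) seed <- parse_smiles(seed, vocab)
  seed_bits <- ecfp4_bits(seed)
  fn <- function(g) {
    bits <- ecfp4_bits(g)
    sim <- if (length(bits) == 0 && length(seed_bits) == 0) 1 else
      length(intersect(bits, seed_bits)) / length(union(bits, seed_bits))
    if (sim >= delta) base$fn(g) else -Inf
  }
  score_function(fn, range = base$range,
                 name = paste0(base$name, "_sim", delta))
}

#' Generation-quality metrics
#'
#' Standard generative-model metrics over a set of generated SMILES:
#' validity (fraction that parse and satisfy valence), novelty (fraction
#' of valid molecules absent from the training corpus), uniqueness
#' (fraction of non-duplicated canonical structures among the valid
#' ones), and the distribution of ECFP4 Tanimoto similarity to the seed.
#'
#' @param generated Character vector of SMILES.
#' @param corpus Character vector of training SMILES (or a corpus
#'   tibble); used for novelty. May be `NULL`.
#' @param seed Seed SMILES (or [mol_graph()]); used for similarity. May
#'   be `NULL`.
#' @param vocab An [atom_vocab()].
#' @return A list with `validity`, `novelty`, `uniqueness`, `similarity`
#'   (numeric vector) and `n`.
#' @export
generation_metrics <- function(generated, corpus = NULL, seed = NULL,
                               vocab = atom_vocab()) {
  stopifnot(length(generated) > 0)
  parsed <- lapply(generated, function(s) {
    tryCatch(parse_smiles(s, vocab), error = function(e) NULL)
  })
  ok <- !vapply(parsed, is.null, logical(1))
  validity <- mean(ok)
  valid_cans <- vapply(parsed[ok], write_smiles, character(1))
  novelty <- NA_real_
  if (!is.null(corpus)) {
    if (is.data.frame(corpus)) corpus <- corpus$smiles
    corpus_cans <- stats::na.omit(canonical_smiles(corpus))
    novelty <- if (length(valid_cans) == 0) NA_real_ else
      mean(!valid_cans %in% corpus_cans)
  }
  uniqueness <- if (length(valid_cans) == 0) NA_real_ else
    length(unique(valid_cans)) / length(valid_cans)
  similarity <- NULL
  if (!is.null(seed)) {
    if (is.character(seed)) seed <- parse_smiles(seed, vocab)
    seed_bits <- ecfp4_bits(seed)
    similarity <- vapply(parsed[ok], function(g) {
      bits <- ecfp4_bits(g)
      length(intersect(bits, seed_bits)) / length(union(bits, seed_bits))
    }, numeric(1))
  }
  list(validity = validity, novelty = novelty, uniqueness = uniqueness,
       similarity = similarity, n = length(generated))
}
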