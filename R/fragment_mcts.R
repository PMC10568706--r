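#' Optimize a molecule by fragment-wise tree search
#'
#' The main entry point. Starting from `seed`, an outer Monte Carlo tree
#' search edits the molecule fragment by fragment. Each cycle: (1) a leaf
#' is selected by UCB1; (2) the leaf is expanded with removal children
#' (every acyclic single bond whose deletion splits the molecule; the
#' larger component survives) and with addition children produced by the
#' inner atom-wise search ([run_atom_search()]) at a uniformly chosen
#' free-valence site, filtered epsilon-greedily to at most `m_add`
#' molecules; (3) all new children are scored by the evaluation function
#' (evaluation replaces rollout — a molecule has no natural terminal
#' state, and the child molecules are themselves complete); (4) the
#' maximum squashed child reward is backpropagated along the path to the
#' root, incrementing each visit count by one.
#'
#' Every child ever added to the tree is a complete, valence-valid
#' molecule and is recorded; the ranked set is returned. With a
#' `protect` substructure, removal children that no longer contain the
#' protected subgraph are discarded.
#'
#' @param seed Starting molecule: SMILES string or [mol_graph()].
#' @param score A [score_function()], or `"qed"` / `"plogp"`.
#' @param model A trained `mt_generator`.
#' @param fragment_steps Outer search cycles (presets used in the
#'   package's experiments: 20 for unconstrained QED, 2 for constrained
#'   penalized logP).
#' @param atom_steps Inner search cycles per expansion (100 in all
#'   presets).
#' @param epsilon With probability `epsilon` the addition children are a
#'   random draw from the inner-search results instead of the top
#'   scorers.
#' @param m_add Maximum addition children kept per expansion.
#' @param c_explore UCB1 exploration constant, shared by both searches.
#' @param transform Reward squashing ([reward_transform()]); chosen from
#'   the score's declared range when `NULL`.
#' @param protect Optional substructure (SMILES) that must survive every
#'   removal.
#' @param max_fragment_atoms Size cap for generated fragments.
#' @param k_expand Inner-search expansion breadth.
#' @param rng_seed Optional integer; when given, the whole run is
#'   reproducible.
#' @param vocab Vocabulary used when `seed` is a SMILES string.
#' @param verbose Print per-cycle progress.
#' @return An object of class `mt_optimization`: `results` (tibble of
#'   distinct generated molecules with scores, ranked), `seed_smiles`,
#'   `seed_score`, `trace` (per-cycle best score and tree size),
#'   `root_visits`, `n_cycles` and settings.
#' @export
optimize_molecule <- function(seed, score = "qed", model,
                              fragment_steps = 20L, atom_steps = 100L,
                              epsilon = 0.2, m_add = 5L,
                              c_explore = sqrt(2), transform = NULL,
                              protect = NULL, max_fragment_atoms = 15L,
                              k_expand = 5L, rng_seed = NULL,
                              vocab = atom_vocab(), verbose = FALSE) {
  if (!is.null(rng_seed)) {
    return(withr::with_seed(as.integer(rng_seed),
      optimize_molecule(seed, score, model, fragment_steps, atom_steps,
                        epsilon, m_add, c_explore, transform, protect,
                        max_fragment_atoms, k_expand, rng_seed = NULL,
                        vocab = vocab, verbose = verbose)))
  }
  if (is.character(seed)) seed <- parse_smiles(seed, vocab)
  vocab <- seed$vocab
  if (!identical(vocab_fingerprint(vocab), model$fingerprint))
    stop("model and molecule vocabularies do not match", call. = FALSE)
  sf <- if (inherits(score, "score_function")) score else score_function(score)
  if (is.null(transform)) transform <- default_transform(sf)
  stopifnot(fragment_steps >= 1, epsilon >= 0, epsilon <= 1, m_add >= 1)
  xp <- compile_generator(model)

  protect_graph <- NULL
  if (!is.null(protect)) {
    protect_graph <- if (is.character(protect)) parse_smiles(protect, vocab)
                     else protect
    if (!contains_subgraph(seed, protect_graph))
      stop("seed does not contain the protected substructure", call. = FALSE)
  }

  new_node <- function(g, smiles, raw, parent_id) {
    e <- new.env(parent = emptyenv())
    e$mol <- g; e$smiles <- smiles; e$raw <- raw
    e$value_sum <- 0; e$visits <- 0L
    e$children <- integer(0); e$parent <- parent_id
    e$expanded <- FALSE; e$terminal <- FALSE
    e
  }
  seed_smiles <- write_smiles(seed)
  seed_raw <- score_mol(sf, seed, seed_smiles)
  nodes <- list(new_node(seed, seed_smiles, seed_raw, 0L))
  in_tree <- new.env(hash = TRUE, parent = emptyenv())
  assign(seed_smiles, TRUE, envir = in_tree)

  registry <- list()
  trace <- list()
  best <- seed_raw

  for (cycle in seq_len(fragment_steps)) {
    # ---- selection ----
    v <- 1L
    while (nodes[[v]]$expanded && length(nodes[[v]]$children) > 0) {
      ch <- nodes[[v]]$children
      ucb <- vapply(ch, function(ci) {
        nd <- nodes[[ci]]
        ucb1(if (nd$visits > 0) nd$value_sum / nd$visits else 0,
             nd$visits, nodes[[v]]$visits, c_explore)
      }, numeric(1))
      v <- ch[which.max(ucb)]
    }
    leaf <- nodes[[v]]

    if (leaf$terminal) {
      backprop(nodes, v, squash(leaf$raw, transform))
      trace[[cycle]] <- tibble::tibble(cycle = cycle, best_score = best,
                                       n_nodes = length(nodes))
      next
    }

    # ---- expansion ----
    children <- list() # each: list(g, smiles, raw, action)
    rem <- enumerate_removals(leaf$mol)
    for (smi in names(rem)) {
      child <- rem[[smi]]
      if (!is.null(protect_graph) &&
          !contains_subgraph(child, protect_graph)) next
      if (exists(smi, envir = in_tree, inherits = FALSE)) next
      children[[length(children) + 1L]] <-
        list(g = child, smiles = smi, raw = score_mol(sf, child, smi),
             action = "remove")
    }
    sites <- which(free_valence(leaf$mol) >= 1L)
    if (length(sites) > 0) {
      site <- if (length(sites) == 1L) sites else sample(sites, 1L)
      adds <- run_atom_search(leaf$mol, site, sf, model,
                              n_steps = atom_steps, transform = transform,
                              c_explore = c_explore, k_expand = k_expand,
                              max_fragment_atoms = max_fragment_atoms,
                              xp = xp)
      adds <- adds[!vapply(adds$smiles, exists, logical(1),
                           envir = in_tree, inherits = FALSE), ,
                   drop = FALSE]
      if (nrow(adds) > 0) {
        take <- min(m_add, nrow(adds))
        pick <- if (stats::runif(1) < epsilon) sample(nrow(adds), take)
                else seq_len(take) # adds is sorted by score
        for (i in pick) {
          children[[length(children) + 1L]] <-
            list(g = parse_smiles(adds$smiles[i], vocab),
                 smiles = adds$smiles[i], raw = adds$score[i],
                 action = "add")
        }
      }
    }

    leaf$expanded <- TRUE
    if (length(children) == 0) {
      leaf$terminal <- TRUE
      if (v == 1L)
        stop("no expandable site: the seed cannot be edited", call. = FALSE)
      backprop(nodes, v, squash(leaf$raw, transform))
      trace[[cycle]] <- tibble::tibble(cycle = cycle, best_score = best,
                                       n_nodes = length(nodes))
      next
    }

    ids <- integer(0)
    for (chd in children) {
      nodes[[length(nodes) + 1L]] <- new_node(chd$g, chd$smiles, chd$raw, v)
      ids <- c(ids, length(nodes))
      assign(chd$smiles, TRUE, envir = in_tree)
      registry[[length(registry) + 1L]] <-
        tibble::tibble(smiles = chd$smiles, score = chd$raw,
                       action = chd$action, cycle = cycle)
      if (is.finite(chd$raw) && chd$raw > best) best <- chd$raw
    }
    leaf$children <- ids

    # ---- evaluation + backpropagation (max child reward) ----
    r_star <- max(squash(vapply(children, `[[`, numeric(1), "raw"),
                         transform))
    backprop(nodes, v, r_star)
    trace[[cycle]] <- tibble::tibble(cycle = cycle, best_score = best,
                                     n_nodes = length(nodes))
    if (verbose)
      message(sprintf("cycle %3d: %d nodes, best %s = %.4f", cycle,
                      length(nodes), sf$name, best))
  }

  results <- if (length(registry) == 0) {
    tibble::tibble(smiles = character(0), score = numeric(0),
                   action = character(0), cycle = integer(0))
  } else {
    dplyr::arrange(
      dplyr::distinct(dplyr::bind_rows(registry), .data$smiles,
                      .keep_all = TRUE),
      dplyr::desc(.data$score))
  }
  structure(list(results = results,
                 seed_smiles = seed_smiles,
                 seed_score = seed_raw,
                 score_name = sf$name,
                 trace = dplyr::bind_rows(trace),
                 root_visits = nodes[[1]]$visits,
                 n_cycles = fragment_steps,
                 n_nodes = length(nodes),
                 node_stats = node_stats(nodes),
                 settings = list(fragment_steps = fragment_steps,
                                 atom_steps = atom_steps, epsilon = epsilon,
                                 m_add = m_add, c_explore = c_explore,
                                 max_fragment_atoms = max_fragment_atoms,
                                 k_expand = k_expand)),
            class = "mt_optimization")
}

backprop <- function(nodes, v, reward) {
  while (v != 0L) {
    nodes[[v]]$visits <- nodes[[v]]$visits + 1L
    nodes[[v]]$value_sum <- nodes[[v]]$value_sum + reward
    v <- nodes[[v]]$parent
  }
  invisible(NULL)
}

node_stats <- function(nodes) {
  tibble::tibble(
    id = seq_along(nodes),
    visits = vapply(nodes, function(n) n$visits, integer(1)),
    mean_value = vapply(nodes, function(n) {
      if (n$visits > 0) n$value_sum / n$visits else NA_real_
    }, numeric(1))
  )
}

# exact subgraph containment (elements and bond orders must match),
# decided by VF2 on colored graphs
contains_subgraph <- function(g, pattern) {
  if (n_atoms(pattern) > n_atoms(g)) return(FALSE)
  ig <- as_igraph_colored(g)
  ip <- as_igraph_colored(pattern)
  # note: in the underlying vf2 call the "1" colors belong to the target
  igraph::subgraph_isomorphic(ip, ig, method = "vf2",
                              vertex.color1 = igraph::V(ig)$color,
                              vertex.color2 = igraph::V(ip)$color,
                              edge.color1 = igraph::E(ig)$color,
                              edge.color2 = igraph::E(ip)$color)
}

as_igraph_colored <- function(g) {
  ig <- as_igraph(g)
  igraph::V(ig)$color <- g$atoms
  igraph::E(ig)$color <- if (nrow(g$bonds) > 0) g$bonds[, 3] else integer(0)
  ig
}

#' @export
print.mt_optimization <- function(x, ...) {
  cat("<mt_optimization> ", x$score_name, " optimization of ",
      x$seed_smiles, "\n", sep = "")
  cat("  ", x$n_cycles, " cycles, ", x$n_nodes, " tree nodes, ",
      nrow(x$results), " distinct molecules\n", sep = "")
  cat("  seed score ", signif(x$seed_score, 4), " -> best ",
      signif(max(c(x$seed_score, x$results$score)), 4), "\n", sep = "")
  invisible(x)
}

#' Ranked report of an optimization run
#'
#' Top-`top_k` generated molecules with raw score and ECFP4 Tanimoto
#' similarity to the seed, plus the conventional summary rows (best,
#' 2nd, 3rd, `top_k`-th and mean of the top `top_k`).
#'
#' @param opt An `mt_optimization`.
#' @param top_k Table depth (default 50).
#' @return A tibble `rank`, `smiles`, `score`, `similarity`.
#' @export
rank_and_report <- function(opt, top_k = 50L) {
  stopifnot(inherits(opt, "mt_optimization"), nrow(opt$results) > 0)
  res <- utils::head(opt$results, top_k)
  seed <- parse_smiles(opt$seed_smiles)
  tibble::tibble(
    rank = seq_len(nrow(res)),
    smiles = res$smiles,
    score = res$score,
    similarity = vapply(res$smiles, function(s)
      tanimoto_ecfp4(s, seed), numeric(1), USE.NAMES = FALSE)
  )
}
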