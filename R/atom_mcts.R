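#' Inner search: grow one fragment atom by atom
#'
#' Monte Carlo tree search over partial fragments. Each node holds a
#' partial fragment (the root is empty); one path through the tree spells
#' out one fragment, one atom per node. A cycle runs UCB1 selection to a
#' leaf, expands the leaf with the `k_expand` most probable
#' (atom, bonds) proposals of the generator under valence masking,
#' completes the best new child to termination by temperature-1 sampling
#' (rollout), attaches the completed fragment to the parent molecule at
#' `parent_site` through a single bond from the fragment's first atom,
#' scores the resulting molecule, and backpropagates the squashed score.
#'
#' A proposal is terminal when the model emits the stop label or predicts
#' no bond; fragment size is capped at `max_fragment_atoms`. The
#' fragment's first atom keeps one valence unit in reserve throughout
#' generation so the attachment bond always exists.
#'
#' @param parent The molecule being edited ([mol_graph()]).
#' @param parent_site Atom index in `parent` with free valence >= 1.
#' @param sf A [score_function()].
#' @param model A trained `mt_generator`.
#' @param n_steps Number of search cycles.
#' @param transform A [reward_transform()] (default picked from the score
#'   range).
#' @param c_explore UCB1 exploration constant.
#' @param k_expand Children added per expansion.
#' @param max_fragment_atoms Rollout size cap.
#' @param xp Optional pre-compiled inference model (built internally when
#'   missing).
#' @return A tibble of distinct scored molecules: `smiles`, `score`,
#'   `frag_smiles`, `frag_atoms`, plus attribute `root_visits`.
#' @export
run_atom_search <- function(parent, parent_site, sf, model,
                            n_steps = 100L, transform = NULL,
                            c_explore = sqrt(2), k_expand = 5L,
                            max_fragment_atoms = 15L, xp = NULL) {
  stopifnot(inherits(parent, "mol_graph"), n_steps >= 1)
  if (free_valence(parent, parent_site) < 1L)
    stop("parent site ", parent_site, " has no free valence", call. = FALSE)
  if (is.null(transform)) transform <- default_transform(sf)
  if (is.null(xp)) xp <- compile_generator(model)
  vocab <- model$vocab
  empty_bonds <- matrix(integer(0), ncol = 3)

  new_node <- function(atoms, bonds, parent_id, terminal = FALSE) {
    e <- new.env(parent = emptyenv())
    e$atoms <- atoms; e$bonds <- bonds
    e$value_sum <- 0; e$visits <- 0L
    e$children <- integer(0)
    e$parent <- parent_id
    e$expanded <- FALSE
    e$terminal <- terminal
    e$reward <- NULL # cached squashed reward of terminal nodes
    e
  }
  nodes <- list(new_node(integer(0), empty_bonds, 0L))

  # free valences of a partial state with the attachment reservation
  free_adj <- function(atoms, bonds) {
    if (length(atoms) == 0) return(integer(0))
    fv <- vocab$max_valence[atoms]
    if (nrow(bonds) > 0) {
      for (r in seq_len(nrow(bonds))) {
        fv[bonds[r, 1]] <- fv[bonds[r, 1]] - bonds[r, 3]
        fv[bonds[r, 2]] <- fv[bonds[r, 2]] - bonds[r, 3]
      }
    }
    fv[1] <- max(fv[1] - 1L, 0L)
    as.integer(fv)
  }

  results <- new.env(hash = TRUE, parent = emptyenv())
  parent_reward <- NULL # lazily computed squashed score of the parent
  score_fragment <- function(atoms, bonds) {
    # empty fragment: the edit is "no change"; score the parent itself
    if (length(atoms) == 0) {
      if (is.null(parent_reward))
        parent_reward <<- squash(score_mol(sf, parent), transform)
      return(parent_reward)
    }
    frag <- mol_graph(atoms, bonds, vocab, check = TRUE)
    mol <- attach_fragment(parent, frag, parent_site, 1L)
    # a (rare, transient) canonicalization or scoring failure is treated
    # as a no-change edit: nothing is collected, the search moves on
    smi <- tryCatch(write_smiles(mol), error = function(e) NULL)
    if (is.null(smi)) {
      if (is.null(parent_reward))
        parent_reward <<- squash(score_mol(sf, parent), transform)
      return(parent_reward)
    }
    raw <- score_mol(sf, mol, smi)
    if (!exists(smi, envir = results, inherits = FALSE) ||
        get(smi, envir = results)$score < raw) {
      assign(smi, list(score = raw,
                       frag_smiles = write_smiles(frag),
                       frag_atoms = length(atoms)),
             envir = results)
    }
    squash(raw, transform)
  }

  for (cycle in seq_len(n_steps)) {
    # selection
    v <- 1L
    while (nodes[[v]]$expanded && length(nodes[[v]]$children) > 0) {
      ch <- nodes[[v]]$children
      scores <- vapply(ch, function(ci) {
        node <- nodes[[ci]]
        ucb1(if (node$visits > 0) node$value_sum / node$visits else 0,
             node$visits, nodes[[v]]$visits, c_explore)
      }, numeric(1))
      v <- ch[which.max(scores)]
    }
    leaf <- nodes[[v]]

    if (leaf$terminal) {
      if (is.null(leaf$reward))
        leaf$reward <- score_fragment(leaf$atoms, leaf$bonds)
      reward <- leaf$reward
      rollout_id <- v
    } else {
      # expansion
      fv <- free_adj(leaf$atoms, leaf$bonds)
      can_grow <- length(leaf$atoms) < max_fragment_atoms &&
        (length(fv) == 0 || any(fv > 0))
      new_ids <- integer(0)
      if (can_grow) {
        prop <- mt_x_expand(xp, leaf$atoms, leaf$bonds, fv,
                            as.integer(k_expand))
        keep <- which(prop$keep)
        if (length(keep) > 0) {
          ord <- keep[order(prop$probs[keep], decreasing = TRUE)]
          for (r in ord) {
            atoms2 <- c(leaf$atoms, prop$atom_labels[r])
            bonds2 <- leaf$bonds
            bl <- prop$bond_labels[r, , drop = TRUE]
            add <- which(bl != 4L)
            if (length(add) > 0) {
              bonds2 <- rbind(bonds2,
                              cbind(add, rep(length(atoms2), length(add)),
                                    bl[add]))
            }
            nodes[[length(nodes) + 1L]] <- new_node(atoms2, bonds2, v)
            new_ids <- c(new_ids, length(nodes))
          }
        }
        if (prop$has_stop) {
          nodes[[length(nodes) + 1L]] <- new_node(leaf$atoms, leaf$bonds,
                                                  v, terminal = TRUE)
          new_ids <- c(new_ids, length(nodes))
        }
      }
      leaf$expanded <- TRUE
      if (length(new_ids) == 0) {
        # dead end: the partial fragment is complete as it stands
        leaf$terminal <- TRUE
        leaf$reward <- score_fragment(leaf$atoms, leaf$bonds)
        reward <- leaf$reward
        rollout_id <- v
      } else {
        leaf$children <- new_ids
        rollout_id <- new_ids[1]
        target <- nodes[[rollout_id]]
        if (target$terminal) {
          target$reward <- score_fragment(target$atoms, target$bonds)
          reward <- target$reward
        } else {
          n_unif <- (max_fragment_atoms + 2L)^2
          ro <- mt_x_rollout(xp, target$atoms, target$bonds,
                             as.integer(max_fragment_atoms),
                             stats::runif(n_unif), TRUE, FALSE)
          reward <- score_fragment(as.integer(ro$atoms), ro$bonds)
        }
      }
    }

    # backpropagation
    u <- rollout_id
    while (u != 0L) {
      nodes[[u]]$visits <- nodes[[u]]$visits + 1L
      nodes[[u]]$value_sum <- nodes[[u]]$value_sum + reward
      u <- nodes[[u]]$parent
    }
  }

  smis <- ls(results)
  out <- if (length(smis) == 0) {
    tibble::tibble(smiles = character(0), score = numeric(0),
                   frag_smiles = character(0), frag_atoms = integer(0))
  } else {
    recs <- lapply(smis, function(s) get(s, envir = results))
    tibble::tibble(
      smiles = smis,
      score = vapply(recs, `[[`, numeric(1), "score"),
      frag_smiles = vapply(recs, `[[`, character(1), "frag_smiles"),
      frag_atoms = vapply(recs, `[[`, integer(1), "frag_atoms")
    )
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$score))
  attr(out, "root_visits") <- nodes[[1]]$visits
  out
}

#' Is a sampled proposal terminal?
#'
#' The terminal rule of the atom-wise search: a proposal ends fragment
#' growth when the model emits the stop label or predicts no bond for
#' the new atom. [sample_step()] returns `NULL` in exactly these cases.
#'
#' @param proposal Result of [sample_step()].
#' @return Logical.
#' @export
is_terminal <- function(proposal) {
  is.null(proposal) ||
    (length(proposal$bond_labels) > 0 && all(proposal$bond_labels == 4L))
}

#' Compile a generator for fast search-time inference
#'
#' Builds the single-precision inference engine used by the searches.
#' The handle is session-local (an external pointer) and is rebuilt
#' automatically when needed.
#'
#' @param model A trained `mt_generator`.
#' @return An external pointer.
#' @export
compile_generator <- function(model) {
  mt_compile(model$params, cpp_cfg(model), unname(model$vocab$max_valence))
}
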