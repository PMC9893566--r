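# Decoding: (1) generate a junction tree from the latent vector with a
# GRU-driven depth-first sequence model (a topological head decides
# expand/backtrack, a label head picks the child fragment); (2) reassemble the
# molecular graph by enumerating chemically valid attachment configurations at
# every tree edge and keeping the candidate scored best against the latent
# vector. Chemical validity of the output is guaranteed by construction:
# candidates violating valence rules are filtered before scoring.

# --- GRU + heads -------------------------------------------------------------

gru_cell <- function(x, h, P) {
  xh <- ag_concat_cols(x, h)
  zg <- ag_sigmoid(ag_linear(xh, P$dt_wz, P$dt_bz))
  r <- ag_sigmoid(ag_linear(xh, P$dt_wr, P$dt_br))
  hh <- ag_tanh(ag_linear(ag_concat_cols(x, ag_mul(r, h)), P$dt_wh, P$dt_bh))
  ag_add(h, ag_mul(zg, ag_sub(hh, h)))
}

topo_logit <- function(h, z, P) {
  c1 <- ag_relu(ag_linear(ag_concat_cols(h, z), P$dt_wt1, P$dt_bt1))
  ag_linear(c1, P$dt_wt2, P$dt_bt2)
}

label_logits <- function(h, z, P) {
  c1 <- ag_relu(ag_linear(ag_concat_cols(h, z), P$dt_wl1, P$dt_bl1))
  ag_linear(c1, P$dt_wl2, P$dt_bl2)
}

token_embed <- function(idx, P) ag_rows(P$dt_embed, idx)

as_latent_vector <- function(z, model) {
  if (inherits(z, "jtprop_latent")) z <- z$z
  z <- as.numeric(z)
  if (length(z) != model$dec_cfg$input_dim) {
    stop(sprintf("latent vector has length %d; decoder expects %d",
                 length(z), model$dec_cfg$input_dim), call. = FALSE)
  }
  matrix(z, 1L)
}

# --- tree generation ---------------------------------------------------------

#' Generate a junction tree from a latent vector
#'
#' Depth-first generation: starting from a root fragment predicted from the
#' latent vector, a topological head (sigmoid, expand threshold 0.5) decides
#' at each visit whether to expand a new child or backtrack, and a label head
#' (softmax over the vocabulary) picks the child fragment. Generation stops
#' when the walk returns past the root or the node budget
#' (`max_decode_steps`) is reached; hitting the budget returns the partial
#' tree flagged `truncated` with a warning.
#'
#' @param z A numeric latent vector (stacked, length `input_dim`) or a
#'   `jtprop_latent`.
#' @param model A `jtprop_model`.
#' @param max_nodes Optional override of the node budget.
#' @return A list with `tree` (a `jtprop_dectree`: node labels/fragments and
#'   oriented edges), `steps` (tibble of per-decision records), and
#'   `truncated`.
#' @export
decode_tree <- function(z, model, max_nodes = NULL) {
  stopifnot(inherits(model, "jtprop_model"))
  if (is.null(max_nodes)) max_nodes <- model$dec_cfg$max_decode_steps
  V <- length(model$vocabulary)
  stopifnot(V >= 1L)
  zn <- ag_input(as_latent_vector(z, model))
  P <- lapply(model$params, ag_input)
  BT <- model$enc_cfg$vocab_size + 1L

  h0 <- ag_relu(ag_linear(zn, P$dt_winit, P$dt_binit))
  rl <- label_logits(h0, zn, P)$value[1, seq_len(V)]
  root_lab <- which.max(rl)
  labels <- root_lab
  edges <- matrix(integer(0), 0L, 2L)
  steps <- list(list(action = "expand", parent = NA_integer_,
                     label = root_lab, score = max(rl)))
  h <- gru_cell(token_embed(root_lab, P), h0, P)
  stack <- 1L
  truncated <- FALSE
  while (length(stack)) {
    tv <- 1 / (1 + exp(-topo_logit(h, zn, P)$value[1L]))
    want_expand <- tv >= 0.5
    if (want_expand && length(labels) >= max_nodes) {
      truncated <- TRUE
      want_expand <- FALSE
    }
    if (want_expand) {
      ll <- label_logits(h, zn, P)$value[1, seq_len(V)]
      lab <- which.max(ll)
      labels <- c(labels, lab)
      child <- length(labels)
      edges <- rbind(edges, c(stack[length(stack)], child))
      steps[[length(steps) + 1L]] <- list(action = "expand",
                                          parent = stack[length(stack)],
                                          label = lab, score = tv)
      h <- gru_cell(token_embed(lab, P), h, P)
      stack <- c(stack, child)
    } else {
      steps[[length(steps) + 1L]] <- list(action = "backtrack",
                                          parent = stack[length(stack)],
                                          label = NA_integer_, score = tv)
      stack <- stack[-length(stack)]
      h <- gru_cell(token_embed(BT, P), h, P)
    }
  }
  tree <- structure(list(
    labels = labels,
    fragments = model$vocabulary$fragments[labels],
    edges = edges
  ), class = "jtprop_dectree")
  steps <- tibble::tibble(
    action = vapply(steps, `[[`, character(1), "action"),
    parent = vapply(steps, `[[`, integer(1), "parent"),
    label = vapply(steps, `[[`, integer(1), "label"),
    score = vapply(steps, `[[`, numeric(1), "score")
  )
  if (truncated) {
    w <- simpleWarning(sprintf(
      "tree generation hit the %d-node budget; returning the partial tree",
      max_nodes))
    class(w) <- c("jtprop_truncation", class(w))
    w$partial_tree <- tree
    warning(w)
  }
  list(tree = tree, steps = steps, truncated = truncated)
}

#' @export
print.jtprop_dectree <- function(x, ...) {
  cat(sprintf("<decoded tree> %d node(s): %s\n", length(x$labels),
              paste(x$fragments, collapse = " ")))
  invisible(x)
}

# --- teacher forcing ---------------------------------------------------------

# Depth-first decision sequence of a ground-truth tree (root = node 1,
# children visited in increasing (vocabulary label, node index) order).
# Returns the per-step targets used for the teacher-forced loss and the edge
# visit order reused by assembly.
teacher_sequence <- function(tree, vocab) {
  n <- length(tree$nodes)
  labels <- vapply(tree$nodes, function(cl) vocab_index(vocab, cl$fragment),
                   integer(1))
  adj <- lapply(seq_len(n), function(i) integer(0))
  if (nrow(tree$edges)) {
    for (k in seq_len(nrow(tree$edges))) {
      i <- tree$edges[k, 1L]; j <- tree$edges[k, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  children <- lapply(seq_len(n), function(i) integer(0))
  parent <- rep(NA_integer_, n)
  # root at node 1; BFS to orient, then sort children deterministically
  queue <- 1L; seen <- c(1L)
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    for (v in adj[[u]]) {
      if (!(v %in% seen)) {
        parent[v] <- u
        children[[u]] <- c(children[[u]], v)
        seen <- c(seen, v)
        queue <- c(queue, v)
      }
    }
  }
  for (i in seq_len(n)) {
    ch <- children[[i]]
    children[[i]] <- ch[order(labels[ch], ch)]
  }
  # simulate the generation loop
  decisions <- list()
  edge_order <- matrix(integer(0), 0L, 2L)
  nxt <- rep(1L, n)  # next-child pointer
  stack <- 1L
  while (length(stack)) {
    top <- stack[length(stack)]
    ch <- children[[top]]
    if (nxt[top] <= length(ch)) {
      child <- ch[nxt[top]]
      nxt[top] <- nxt[top] + 1L
      decisions[[length(decisions) + 1L]] <- list(type = "topo", target = 1,
                                                  token = labels[child])
      decisions[[length(decisions) + 1L]] <- list(type = "label",
                                                  target = labels[child])
      edge_order <- rbind(edge_order, c(top, child))
      stack <- c(stack, child)
    } else {
      decisions[[length(decisions) + 1L]] <- list(type = "topo", target = 0,
                                                  token = NA_integer_)
      stack <- stack[-length(stack)]
    }
  }
  list(labels = labels, root_label = labels[1L], decisions = decisions,
       edge_order = edge_order, children = children, parent = parent)
}

# Teacher-forced tree-decoder loss (autograd node). Mirrors decode_tree's
# state updates with ground-truth actions.
tree_teacher_loss <- function(seq, zn, P, model) {
  BT <- model$enc_cfg$vocab_size + 1L
  h0 <- ag_relu(ag_linear(zn, P$dt_winit, P$dt_binit))
  loss <- ag_softmax_ce(label_logits(h0, zn, P), seq$root_label)
  h <- gru_cell(token_embed(seq$root_label, P), h0, P)
  for (d in seq$decisions) {
    if (d$type == "topo") {
      loss <- ag_add(loss, ag_bce_logit(topo_logit(h, zn, P), d$target))
      if (d$target == 0) h <- gru_cell(token_embed(BT, P), h, P)
    } else {
      loss <- ag_add(loss, ag_softmax_ce(label_logits(h, zn, P), d$target))
      h <- gru_cell(token_embed(d$target, P), h, P)
    }
  }
  loss
}

# --- attachment enumeration --------------------------------------------------

# Enumerate chemically valid ways to attach fragment graph `frag` to the
# current partial molecule at the parent cluster's atoms. A candidate merges
# either one atom (substituent/spiro/junction) or one bond (fused) of the
# fragment onto the parent cluster; element, charge, bond order and combined
# valence must all be compatible. Returns candidates in deterministic
# enumeration order.
attach_candidates <- function(state, parent_atoms, frag) {
  fa <- frag$atoms; fb <- frag$bonds
  ev_state <- explicit_valence(state$atoms, state$bonds)
  ev_frag <- explicit_valence(fa, fb)
  allow_state <- allowed_valence(state$atoms$element, state$atoms$charge)
  cands <- list()
  # single-atom merges
  for (a in parent_atoms) {
    for (b in seq_len(nrow(fa))) {
      if (state$atoms$element[a] == fa$element[b] &&
          state$atoms$charge[a] == fa$charge[b] &&
          ev_state[a] + ev_frag[b] <= allow_state[a]) {
        cands[[length(cands) + 1L]] <- stats::setNames(a, b)
      }
    }
  }
  # bond (fused) merges: only for ring-bearing child fragments — a bare bond
  # fragment overlapping a whole parent bond would add nothing
  if (nrow(fb) > 1L && length(parent_atoms) >= 2L) {
    pb <- which(state$bonds$a1 %in% parent_atoms &
                  state$bonds$a2 %in% parent_atoms)
    for (i in pb) {
      a1 <- state$bonds$a1[i]; a2 <- state$bonds$a2[i]
      o <- state$bonds$order[i]
      for (j in seq_len(nrow(fb))) {
        if (fb$order[j] != o) next
        for (orient in 1:2) {
          b1 <- if (orient == 1L) fb$a1[j] else fb$a2[j]
          b2 <- if (orient == 1L) fb$a2[j] else fb$a1[j]
          ok <- state$atoms$element[a1] == fa$element[b1] &&
            state$atoms$element[a2] == fa$element[b2] &&
            state$atoms$charge[a1] == fa$charge[b1] &&
            state$atoms$charge[a2] == fa$charge[b2] &&
            ev_state[a1] + ev_frag[b1] - o <= allow_state[a1] &&
            ev_state[a2] + ev_frag[b2] - o <= allow_state[a2]
          if (ok) cands[[length(cands) + 1L]] <- stats::setNames(c(a1, a2), c(b1, b2))
        }
      }
    }
  }
  cands
}

# Materialize a candidate: returns the new state plus the child cluster's atom
# ids in the new state.
apply_candidate <- function(state, frag, cand) {
  fa <- frag$atoms; fb <- frag$bonds
  nf <- nrow(fa)
  merged_frag <- as.integer(names(cand))
  map <- integer(nf)
  map[merged_frag] <- unname(cand)
  new_ids <- setdiff(seq_len(nf), merged_frag)
  off <- nrow(state$atoms)
  if (length(new_ids)) map[new_ids] <- off + seq_along(new_ids)
  atoms <- rbind(state$atoms[, c("element", "charge")],
                 fa[new_ids, c("element", "charge")])
  add <- if (nrow(fb)) {
    keep <- !(fb$a1 %in% merged_frag & fb$a2 %in% merged_frag)
    tibble::tibble(a1 = map[fb$a1[keep]], a2 = map[fb$a2[keep]],
                   order = fb$order[keep])
  } else fb
  bonds <- rbind(state$bonds, add)
  list(state = list(atoms = atoms, bonds = bonds), child_atoms = map)
}

# --- candidate scoring -------------------------------------------------------

# Scoring looks at the candidate's local neighborhood only: the subgraph
# induced on the parent cluster's atoms, everything already bonded to them
# (one bond out), and the merged child fragment. The one-bond context is what
# distinguishes positional isomers — without it, attaching at different sites
# of a symmetric parent gives isomorphic candidate graphs — while keeping the
# scored graphs small no matter how large the partial molecule has grown.
candidate_constants <- function(state, parent_atoms, frag, cand, model) {
  app <- apply_candidate(state, frag, cand)
  nb <- state$bonds[state$bonds$a1 %in% parent_atoms |
                      state$bonds$a2 %in% parent_atoms, ]
  ids <- sort(unique(c(parent_atoms, nb$a1, nb$a2, app$child_atoms)))
  remap <- match(seq_len(nrow(app$state$atoms)), ids)
  keep <- app$state$bonds$a1 %in% ids & app$state$bonds$a2 %in% ids
  atoms <- app$state$atoms[ids, , drop = FALSE]
  bonds <- tibble::tibble(a1 = remap[app$state$bonds$a1[keep]],
                          a2 = remap[app$state$bonds$a2[keep]],
                          order = app$state$bonds$order[keep])
  graph_constants(atoms, bonds, model$dec_cfg$atom_feature_dim)
}

assembly_z_gate <- function(zn, P) {
  ag_relu(ag_linear(zn, P$da_wz, P$da_bz))
}

assembly_score <- function(cst, zgate, P, model) {
  hmol <- mpnn_embed(cst, P, "da_", model$dec_cfg$assembly_mpnn_iterations)
  hout <- ag_relu(ag_linear(hmol, P$da_wout, P$da_bout))
  ag_sum(ag_mul(hout, zgate))
}

# --- graph assembly ----------------------------------------------------------

# Visit order of a tree's edges: for decoded trees the recorded creation order
# (already depth-first, parent before child); for decomposition trees the
# teacher-sequence order.
assembly_plan <- function(tree, model) {
  if (inherits(tree, "jtprop_dectree")) {
    list(labels = tree$labels, edges = tree$edges)
  } else {
    seq <- teacher_sequence(tree, model$vocabulary)
    list(labels = seq$labels, edges = seq$edge_order)
  }
}

#' Assemble a molecule from a junction tree under latent guidance
#'
#' Walks the tree depth-first from its root; at every edge, all chemically
#' valid attachment configurations between the child fragment and the already
#' assembled parent cluster are enumerated, scored by the assembly
#' message-passing network against the latent vector, and the best-scoring
#' candidate is kept (greedy, ties to the lowest enumeration index). The
#' output molecule always sanitizes: invalid candidates are filtered before
#' scoring.
#'
#' @param tree A `jtprop_dectree` (from [decode_tree()]) or `jtprop_jtree`.
#' @param z Latent vector or `jtprop_latent`.
#' @param model A `jtprop_model`.
#' @param on_failure `"error"`: a node with no valid attachment raises an
#'   assembly error carrying the partial molecule; `"skip"`: that subtree is
#'   dropped and assembly continues (used by [decode()] so that decoding
#'   always yields a valid molecule).
#' @return A `jtprop_molecule`.
#' @export
assemble_graph <- function(tree, z, model, on_failure = c("error", "skip")) {
  on_failure <- match.arg(on_failure)
  plan <- assembly_plan(tree, model)
  labels <- plan$labels
  frags <- model$frag_graphs[labels]
  zn <- ag_input(as_latent_vector(z, model))
  P <- lapply(model$params, ag_input)
  zgate <- assembly_z_gate(zn, P)

  root <- frags[[1L]]
  state <- list(atoms = root$atoms[, c("element", "charge")],
                bonds = root$bonds)
  cluster_atoms <- vector("list", length(labels))
  cluster_atoms[[1L]] <- seq_len(nrow(root$atoms))
  dropped <- logical(length(labels))

  if (nrow(plan$edges)) {
    for (k in seq_len(nrow(plan$edges))) {
      pnode <- plan$edges[k, 1L]; cnode <- plan$edges[k, 2L]
      if (dropped[pnode]) { dropped[cnode] <- TRUE; next }
      cands <- attach_candidates(state, cluster_atoms[[pnode]], frags[[cnode]])
      if (!length(cands)) {
        if (on_failure == "error") {
          e <- simpleError(sprintf(
            "no valid attachment for fragment '%s' at tree node %d",
            model$vocabulary$fragments[labels[cnode]], cnode))
          class(e) <- c("jtprop_assembly_error", class(e))
          e$partial <- state
          stop(e)
        }
        dropped[cnode] <- TRUE
        next
      }
      pick <- 1L
      if (length(cands) > 1L) {
        scores <- vapply(cands, function(cd) {
          cst <- candidate_constants(state, cluster_atoms[[pnode]],
                                     frags[[cnode]], cd, model)
          assembly_score(cst, zgate, P, model)$value[1L]
        }, numeric(1))
        pick <- which.max(scores)
      }
      app <- apply_candidate(state, frags[[cnode]], cands[[pick]])
      state <- app$state
      cluster_atoms[[cnode]] <- app$child_atoms
    }
  }
  molecule_from_tables(state$atoms, state$bonds)
}

#' Decode a molecule from a latent vector
#'
#' Composition of [decode_tree()] and [assemble_graph()] (with skip-on-failure
#' so the result is always a chemically valid molecule). Deterministic for
#' fixed weights and input.
#'
#' @param z Latent vector (stacked) or `jtprop_latent`.
#' @param model A `jtprop_model`.
#' @param max_nodes Optional tree-node budget override.
#' @return A `jtprop_molecule`.
#' @export
decode <- function(z, model, max_nodes = NULL) {
  dt <- suppressWarnings(decode_tree(z, model, max_nodes = max_nodes))
  assemble_graph(dt$tree, z, model, on_failure = "skip")
}

# --- teacher-forced assembly supervision -------------------------------------

# Precompute, for one molecule, the scored assembly decisions implied by its
# true junction tree: at each visited edge, the candidate set and which
# candidates reproduce the true partial molecule (graph isomorphism with
# element/charge vertex colors and order edge colors). Steps with a single
# candidate carry no signal and are dropped.
assembly_teacher_steps <- function(m, tree, seq, model) {
  n <- length(tree$nodes)
  cluster_ids <- lapply(tree$nodes, function(cl) cl$atom_ids)
  covered <- cluster_ids[[1L]]
  steps <- list()
  if (nrow(seq$edge_order) == 0L) return(steps)
  for (k in seq_len(nrow(seq$edge_order))) {
    pnode <- seq$edge_order[k, 1L]; cnode <- seq$edge_order[k, 2L]
    sub <- induced_subgraph_tables(m, covered)
    state <- list(atoms = sub$atoms, bonds = sub$bonds)
    pa <- match(intersect(cluster_ids[[pnode]], sort(covered)), sort(covered))
    frag <- model$frag_graphs[[seq$labels[cnode]]]
    cands <- attach_candidates(state, pa, frag)
    next_cov <- sort(union(covered, cluster_ids[[cnode]]))
    truth <- induced_subgraph_tables(m, next_cov)
    correct <- which(vapply(cands, function(cd) {
      app <- apply_candidate(state, frag, cd)
      graphs_isomorphic(app$state, truth)
    }, logical(1)))
    if (!length(correct)) {
      stop(sprintf("no assembly candidate reproduces '%s' at tree node %d",
                   m$smiles, cnode), call. = FALSE)
    }
    if (length(cands) > 1L) {
      csts <- lapply(cands, function(cd) {
        candidate_constants(state, pa, frag, cd, model)
      })
      steps[[length(steps) + 1L]] <- list(csts = csts, correct = correct)
    }
    covered <- next_cov
  }
  steps
}

assembly_teacher_loss <- function(steps, zn, P, model) {
  loss <- NULL
  zgate <- assembly_z_gate(zn, P)
  for (st in steps) {
    scores <- lapply(st$csts, assembly_score, zgate = zgate, P = P,
                     model = model)
    l <- ag_softmax_ce(ag_rbind(scores), st$correct)
    loss <- if (is.null(loss)) l else ag_add(loss, l)
  }
  loss
}

# Colored graph isomorphism on atom/bond tables (igraph VF2).
graphs_isomorphic <- function(g1, g2) {
  a1 <- g1$atoms; a2 <- g2$atoms
  if (nrow(a1) != nrow(a2) || nrow(g1$bonds) != nrow(g2$bonds)) return(FALSE)
  key1 <- paste(a1$element, a1$charge)
  key2 <- paste(a2$element, a2$charge)
  if (!identical(sort(key1), sort(key2))) return(FALSE)
  if (!identical(sort(g1$bonds$order), sort(g2$bonds$order))) return(FALSE)
  lev <- unique(c(key1, key2))
  mk <- function(g, key) {
    ig <- igraph::graph_from_edgelist(cbind(g$bonds$a1, g$bonds$a2),
                                      directed = FALSE)
    if (igraph::vcount(ig) < nrow(g$atoms)) {
      ig <- igraph::add_vertices(ig, nrow(g$atoms) - igraph::vcount(ig))
    }
    ig
  }
  igraph::isomorphic(mk(g1), mk(g2), method = "vf2",
                     vertex.color1 = match(key1, lev),
                     vertex.color2 = match(key2, lev),
                     edge.color1 = g1$bonds$order,
                     edge.color2 = g2$bonds$order)
}
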