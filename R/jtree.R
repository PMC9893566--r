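#' Junction-tree decomposition of a molecule
#'
#' Decomposes a molecule into clusters — SSSR rings (rings sharing more than
#' two atoms are merged into one bridged cluster), all non-ring bonds, and a
#' single-atom cluster for every atom that belongs to three or more clusters —
#' then connects clusters that share atoms and keeps a deterministic maximum
#' spanning tree (edge weight = number of shared atoms, ties broken by the
#' lowest cluster-index pair). Because molecules are always built on canonical
#' atom order, the decomposition is deterministic and invariant to how the
#' input SMILES was spelled.
#'
#' @param m A `jtprop_molecule` with at least one atom.
#' @return An object of class `jtprop_jtree`: list with `nodes` (list of
#'   clusters, each with `kind` in ring/bond/atom, `atom_ids`, and canonical
#'   `fragment`), `edges` (2-column matrix of node indices, possibly 0 rows),
#'   and `molecule`.
#' @examples
#' t <- tree_decompose(parse_smiles("CC1C(O)CC1C1CC1"))
#' length(t$nodes)  # 5 clusters
#' nrow(t$edges)    # 4 tree edges
#' @export
tree_decompose <- function(m) {
  stopifnot(inherits(m, "jtprop_molecule"))
  n_atoms <- nrow(m$atoms)
  if (n_atoms < 1L) stop("molecule has no atoms", call. = FALSE)

  rings <- sssr(m)
  ring_sets <- lapply(rings, sort)
  # merge rings sharing > 2 atoms (bridged systems) until stable
  repeat {
    merged <- FALSE
    if (length(ring_sets) >= 2L) {
      for (i in seq_len(length(ring_sets) - 1L)) {
        for (j in seq((i + 1L), length(ring_sets))) {
          if (length(intersect(ring_sets[[i]], ring_sets[[j]])) > 2L) {
            ring_sets[[i]] <- sort(union(ring_sets[[i]], ring_sets[[j]]))
            ring_sets[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  # deterministic ring ordering by member atoms
  if (length(ring_sets)) {
    ring_sets <- ring_sets[order(vapply(ring_sets, function(s)
      paste(sprintf("%04d", s), collapse = ","), character(1)))]
  }

  in_ring_bond <- function(a, b) {
    any(vapply(ring_sets, function(s) (a %in% s) && (b %in% s), logical(1)))
  }
  nonring <- which(!mapply(in_ring_bond, m$bonds$a1, m$bonds$a2))

  clusters <- c(
    lapply(ring_sets, function(s) list(kind = "ring", atom_ids = s)),
    lapply(nonring, function(i) list(
      kind = "bond",
      atom_ids = sort(c(m$bonds$a1[i], m$bonds$a2[i]))))
  )
  if (!length(clusters)) {
    # single atom, no bonds
    clusters <- list(list(kind = "atom", atom_ids = 1L))
  } else {
    membership <- integer(n_atoms)
    for (cl in clusters) membership[cl$atom_ids] <- membership[cl$atom_ids] + 1L
    for (a in which(membership >= 3L)) {
      clusters[[length(clusters) + 1L]] <- list(kind = "atom", atom_ids = a)
    }
  }

  nc <- length(clusters)
  edges <- NULL
  if (nc > 1L) {
    cand <- list()
    for (i in seq_len(nc - 1L)) {
      for (j in seq((i + 1L), nc)) {
        w <- length(intersect(clusters[[i]]$atom_ids, clusters[[j]]$atom_ids))
        if (w > 0L) cand[[length(cand) + 1L]] <- c(i, j, w)
      }
    }
    if (!length(cand)) {
      stop(sprintf("disconnected cluster graph for '%s'", m$smiles), call. = FALSE)
    }
    cm <- do.call(rbind, cand)
    cm <- cm[order(-cm[, 3L], cm[, 1L], cm[, 2L]), , drop = FALSE]
    # Kruskal maximum spanning tree
    parent <- seq_len(nc)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    keep <- logical(nrow(cm))
    for (k in seq_len(nrow(cm))) {
      ra <- find(cm[k, 1L]); rb <- find(cm[k, 2L])
      if (ra != rb) { parent[ra] <- rb; keep[k] <- TRUE }
    }
    edges <- cm[keep, c(1L, 2L), drop = FALSE]
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
    if (nrow(edges) != nc - 1L) {
      stop(sprintf("cluster graph of '%s' is not connected", m$smiles), call. = FALSE)
    }
  } else {
    edges <- matrix(integer(0), 0L, 2L)
  }

  frags <- cluster_fragments(m, clusters)
  for (k in seq_len(nc)) clusters[[k]]$fragment <- frags[k]

  t <- list(nodes = clusters, edges = edges, molecule = m)
  class(t) <- "jtprop_jtree"
  t
}

# Canonical fragment SMILES for each cluster: induced subgraph on the cluster
# atoms (kekulized orders and formal charges inherited from the parent),
# canonicalized in one OpenBabel batch.
cluster_fragments <- function(m, clusters) {
  blocks <- vapply(seq_along(clusters), function(k) {
    ids <- clusters[[k]]$atom_ids
    sub <- induced_subgraph_tables(m, ids)
    build_molblock(sub$atoms, sub$bonds, title = paste0("jt", k))
  }, character(1))
  frags <- ob_molblocks_to_cansmi(blocks)
  if (anyNA(frags)) {
    stop(sprintf("cannot canonicalize fragment(s) of '%s'", m$smiles), call. = FALSE)
  }
  frags
}

induced_subgraph_tables <- function(m, ids) {
  ids <- sort(ids)
  remap <- match(seq_len(nrow(m$atoms)), ids)
  keep <- m$bonds$a1 %in% ids & m$bonds$a2 %in% ids
  list(
    atoms = m$atoms[ids, c("element", "charge"), drop = FALSE],
    bonds = tibble::tibble(
      a1 = remap[m$bonds$a1[keep]],
      a2 = remap[m$bonds$a2[keep]],
      order = m$bonds$order[keep]
    )
  )
}

#' @export
print.jtprop_jtree <- function(x, ...) {
  cat(sprintf("<junction tree> %d cluster(s), %d edge(s) for %s\n",
              length(x$nodes), nrow(x$edges), x$molecule$smiles))
  for (k in seq_along(x$nodes)) {
    cl <- x$nodes[[k]]
    cat(sprintf("  [%d] %-5s %-12s atoms {%s}\n", k, cl$kind, cl$fragment,
                paste(cl$atom_ids, collapse = ",")))
  }
  invisible(x)
}
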