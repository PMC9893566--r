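# Ring perception: smallest set of smallest rings (SSSR) on the heavy-atom
# graph. The ring count is |E| - |V| + components (molecules here are
# connected, so one component); candidate rings are the shortest cycle through
# each edge, and a greedy pass keeps candidates that are linearly independent
# over GF(2) in edge space.

ring_count <- function(m) {
  nrow(m$bonds) - nrow(m$atoms) + 1L
}

# Returns a list of integer vectors of atom indices (each a ring, unordered
# membership but stored in traversal order).
sssr <- function(m) {
  n_rings <- ring_count(m)
  if (n_rings <= 0L) return(list())
  nb <- nrow(m$bonds)
  g <- igraph::graph_from_edgelist(cbind(m$bonds$a1, m$bonds$a2),
                                   directed = FALSE)
  if (igraph::vcount(g) < nrow(m$atoms)) {
    g <- igraph::add_vertices(g, nrow(m$atoms) - igraph::vcount(g))
  }
  # shortest cycle through each edge
  cands <- list()
  for (e in seq_len(nb)) {
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = m$bonds$a1[e], to = m$bonds$a2[e], output = "vpath"))
    path <- as.integer(sp$vpath[[1]])
    if (length(path) >= 3L) cands[[length(cands) + 1L]] <- path
  }
  if (!length(cands)) return(list())
  # order candidates by size, then by sorted member atoms for determinism
  keys <- vapply(cands, function(p) {
    paste(sprintf("%04d", c(length(p), sort(p))), collapse = ",")
  }, character(1))
  cands <- cands[order(vapply(cands, length, integer(1)), keys)]
  cands <- cands[!duplicated(vapply(cands, function(p) paste(sort(p), collapse = ","), character(1)))]

  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  all_keys <- edge_key(m$bonds$a1, m$bonds$a2)
  ring_edge_vec <- function(path) {
    k <- length(path)
    ek <- edge_key(path, path[c(2:k, 1L)])
    sort(match(ek, all_keys))
  }
  # GF(2) independence via set-XOR Gaussian elimination on edge-id sets
  basis <- list()
  chosen <- list()
  for (p in cands) {
    v <- ring_edge_vec(p)
    for (b in basis) {
      if (length(v) && v[1L] == b[1L]) {
        v <- sort(c(setdiff(v, b), setdiff(b, v)))
      }
    }
    if (length(v)) {
      basis[[length(basis) + 1L]] <- v
      basis <- basis[order(vapply(basis, `[`, numeric(1), 1L))]
      chosen[[length(chosen) + 1L]] <- p
      if (length(chosen) == n_rings) break
    }
  }
  chosen
}
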