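# Feature construction for the two message-passing encoders and the assembly
# scorer. The atom feature vector is element one-hot + degree one-hot +
# formal-charge one-hot + aromaticity flag, padded (or truncated) to the
# configured width; tree nodes are one-hot over the vocabulary index.

.feat_elements <- c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I")

atom_feature_matrix <- function(atoms, bonds, dim) {
  n <- nrow(atoms)
  deg <- tabulate(c(bonds$a1, bonds$a2), nbins = n)
  arom <- if ("aromatic" %in% names(atoms)) as.numeric(atoms$aromatic) else rep(0, n)
  X <- matrix(0, n, 10L + 6L + 5L + 1L)
  ei <- match(atoms$element, .feat_elements)
  ei[is.na(ei)] <- 10L
  X[cbind(seq_len(n), ei)] <- 1
  X[cbind(seq_len(n), 10L + pmin(deg, 5L) + 1L)] <- 1
  X[cbind(seq_len(n), 16L + pmin(pmax(atoms$charge, -2L), 2L) + 3L)] <- 1
  X[, 22L] <- arom
  if (dim >= ncol(X)) {
    cbind(X, matrix(0, n, dim - ncol(X)))
  } else {
    X[, seq_len(dim), drop = FALSE]
  }
}

# Directed-edge constants for message passing: for each bond, two directed
# edges. E holds bond-order one-hots; S scatters edge messages to their
# destination atoms.
graph_constants <- function(atoms, bonds, feature_dim) {
  n <- nrow(atoms)
  m <- nrow(bonds)
  src <- c(bonds$a1, bonds$a2)
  dst <- c(bonds$a2, bonds$a1)
  E <- matrix(0, 2L * m, 3L)
  if (m > 0L) {
    ord <- pmin(c(bonds$order, bonds$order), 3L)
    E[cbind(seq_len(2L * m), ord)] <- 1
  }
  S <- matrix(0, n, 2L * m)
  if (m > 0L) S[cbind(dst, seq_len(2L * m))] <- 1
  list(
    X = atom_feature_matrix(atoms, bonds, feature_dim),
    src = src, S = S, E = E, n_edges = 2L * m
  )
}

tree_constants <- function(tree, vocab, vocab_width) {
  idx <- vapply(tree$nodes, function(cl) vocab_index(vocab, cl$fragment),
                integer(1))
  n <- length(idx)
  X <- matrix(0, n, vocab_width)
  X[cbind(seq_len(n), idx)] <- 1
  e <- tree$edges
  src <- c(e[, 1L], e[, 2L])
  dst <- c(e[, 2L], e[, 1L])
  S <- matrix(0, n, length(src))
  if (length(src)) S[cbind(dst, seq_along(src))] <- 1
  list(X = X, src = src, S = S, E = NULL, n_edges = length(src), labels = idx)
}

# Shared MPNN trunk (autograd). P is a wrapped parameter list; names are
# resolved with the given prefix. X0/S/E are plain matrices (constants).
mpnn_embed <- function(cst, P, prefix, iterations) {
  p <- function(nm) P[[paste0(prefix, nm)]]
  Xn <- ag_input(cst$X)
  H0 <- ag_matmul(Xn, p("win"))
  H <- ag_relu(H0)
  if (cst$n_edges > 0L) {
    Sn <- ag_input(cst$S)
    En <- if (!is.null(cst$E)) ag_input(cst$E) else NULL
    for (t in seq_len(iterations)) {
      Msg <- ag_linear(ag_rows(H, cst$src), p("wmsg"), p("bmsg"))
      if (!is.null(En)) Msg <- ag_add(Msg, ag_matmul(En, p("wedge")))
      Msg <- ag_relu(Msg)
      H <- ag_relu(ag_add(H0, ag_linear(ag_matmul(Sn, Msg), p("wagg"),
                                        p("bagg"))))
    }
  }
  ag_colsums(H)
}
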