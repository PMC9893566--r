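# Minimal tape-based reverse-mode automatic differentiation on dense matrices.
# Every neural component in the package (encoders, tree decoder, assembly
# scorer, regressor) is expressed in these primitives, so one backward pass
# serves training, the finite-difference-checked regressor gradient, and the
# latent-space search. Nodes are environments; ids give a topological order.

.ag_counter <- new.env(parent = emptyenv())
.ag_counter$id <- 0
.ag_counter$sweep <- 0

ag_next_id <- function() {
  .ag_counter$id <- .ag_counter$id + 1
  .ag_counter$id
}

# Create a graph node. `backfn(node)` must push node$grad into its parents'
# $grad fields (allocating zeros on first touch).
ag_node <- function(value, parents = list(), backfn = NULL, requires = FALSE) {
  if (!is.matrix(value)) value <- matrix(value, nrow = 1L)
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$grad <- NULL
  e$requires <- requires || any(vapply(parents, function(p) p$requires, logical(1)))
  e$id <- ag_next_id()
  class(e) <- "ag_node"
  e
}

ag_input <- function(x, requires = FALSE) ag_node(x, requires = requires)

ag_accum <- function(node, g) {
  if (!node$requires) return(invisible(NULL))
  if (is.null(node$grad)) {
    node$grad <- g
  } else {
    node$grad <- node$grad + g
  }
  invisible(NULL)
}

ag_value <- function(x) if (inherits(x, "ag_node")) x$value else x

# --- primitive operations ----------------------------------------------------

ag_matmul <- function(a, b) {
  ag_node(a$value %*% b$value, list(a, b), function(n) {
    if (a$requires) ag_accum(a, n$grad %*% t(b$value))
    if (b$requires) ag_accum(b, t(a$value) %*% n$grad)
  })
}

# Elementwise binary op with row-vector broadcasting (1 x k against m x k).
# The backward closures recompute any expansion from the parents' stored
# values instead of capturing expanded copies (keeps live graphs small).
ag_expand <- function(v, rows) {
  if (nrow(v) == 1L && rows > 1L) matrix(v, rows, ncol(v), byrow = TRUE) else v
}

ag_broadcast2 <- function(a, b, f, dfa, dfb) {
  av <- a$value; bv <- b$value
  rows <- max(nrow(av), nrow(bv))
  ba <- nrow(av) == 1L && rows > 1L   # a broadcast over rows of b
  bb <- nrow(bv) == 1L && rows > 1L
  ag_node(f(ag_expand(av, rows), ag_expand(bv, rows)), list(a, b), function(n) {
    if (a$requires) {
      g <- dfa(n$grad, ag_expand(a$value, rows), ag_expand(b$value, rows))
      if (ba) g <- matrix(colSums(g), 1L)
      ag_accum(a, g)
    }
    if (b$requires) {
      g <- dfb(n$grad, ag_expand(a$value, rows), ag_expand(b$value, rows))
      if (bb) g <- matrix(colSums(g), 1L)
      ag_accum(b, g)
    }
  })
}

# Fused affine layer x %*% W + b (b a 1 x k bias row): one node instead of a
# matmul + broadcast add, the hot path of every network in the package.
ag_linear <- function(x, W, b) {
  v <- x$value %*% W$value
  v <- v + matrix(b$value, nrow(v), ncol(v), byrow = TRUE)
  ag_node(v, list(x, W, b), function(n) {
    if (x$requires) ag_accum(x, n$grad %*% t(W$value))
    if (W$requires) ag_accum(W, t(x$value) %*% n$grad)
    if (b$requires) ag_accum(b, matrix(colSums(n$grad), 1L))
  })
}

ag_add <- function(a, b) ag_broadcast2(a, b, `+`,
  function(g, x, y) g, function(g, x, y) g)

ag_sub <- function(a, b) ag_broadcast2(a, b, `-`,
  function(g, x, y) g, function(g, x, y) -g)

ag_mul <- function(a, b) ag_broadcast2(a, b, `*`,
  function(g, x, y) g * y, function(g, x, y) g * x)

ag_div <- function(a, b) ag_broadcast2(a, b, `/`,
  function(g, x, y) g / y, function(g, x, y) -g * x / (y * y))

ag_scale <- function(a, s) {
  ag_node(a$value * s, list(a), function(n) {
    if (a$requires) ag_accum(a, n$grad * s)
  })
}

ag_relu <- function(a) {
  v <- pmax(a$value, 0)
  ag_node(v, list(a), function(n) {
    if (a$requires) ag_accum(a, n$grad * (a$value > 0))
  })
}

ag_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-a$value))
  ag_node(v, list(a), function(n) {
    if (a$requires) ag_accum(a, n$grad * v * (1 - v))
  })
}

ag_tanh <- function(a) {
  v <- tanh(a$value)
  ag_node(v, list(a), function(n) {
    if (a$requires) ag_accum(a, n$grad * (1 - v * v))
  })
}

ag_exp <- function(a) {
  v <- exp(a$value)
  ag_node(v, list(a), function(n) {
    if (a$requires) ag_accum(a, n$grad * v)
  })
}

ag_sqrt <- function(a) {
  v <- sqrt(a$value)
  ag_node(v, list(a), function(n) {
    if (a$requires) ag_accum(a, n$grad * 0.5 / v)
  })
}

ag_abs <- function(a) {
  ag_node(abs(a$value), list(a), function(n) {
    # subgradient 0 at the kink
    if (a$requires) ag_accum(a, n$grad * sign(a$value))
  })
}

# |x|^p for constant p >= 1, applied elementwise to a nonnegative input.
ag_powc <- function(a, p) {
  if (p == 1) return(a)
  v <- a$value^p
  ag_node(v, list(a), function(n) {
    if (a$requires) ag_accum(a, n$grad * p * a$value^(p - 1))
  })
}

ag_sum <- function(a) {
  ag_node(matrix(sum(a$value), 1L, 1L), list(a), function(n) {
    if (a$requires) ag_accum(a, matrix(n$grad[1L], nrow(a$value), ncol(a$value)))
  })
}

ag_mean <- function(a) ag_scale(ag_sum(a), 1 / length(a$value))

ag_colmeans <- function(a) {
  m <- nrow(a$value)
  ag_node(matrix(colMeans(a$value), 1L), list(a), function(n) {
    if (a$requires) ag_accum(a, matrix(n$grad / m, m, ncol(a$value), byrow = TRUE))
  })
}

ag_colsums <- function(a) {
  ag_node(matrix(colSums(a$value), 1L), list(a), function(n) {
    if (a$requires) ag_accum(a, matrix(n$grad, nrow(a$value), ncol(a$value), byrow = TRUE))
  })
}

ag_rows <- function(a, idx) {
  ag_node(a$value[idx, , drop = FALSE], list(a), function(n) {
    if (a$requires) {
      g <- matrix(0, nrow(a$value), ncol(a$value))
      for (k in seq_along(idx)) g[idx[k], ] <- g[idx[k], ] + n$grad[k, ]
      ag_accum(a, g)
    }
  })
}

ag_concat_cols <- function(a, b) {
  na <- ncol(a$value)
  ag_node(cbind(a$value, b$value), list(a, b), function(n) {
    if (a$requires) ag_accum(a, n$grad[, seq_len(na), drop = FALSE])
    if (b$requires) ag_accum(b, n$grad[, -seq_len(na), drop = FALSE])
  })
}

ag_rbind <- function(nodes) {
  rows <- vapply(nodes, function(x) nrow(x$value), integer(1))
  ag_node(do.call(rbind, lapply(nodes, function(x) x$value)), nodes, function(n) {
    off <- 0L
    for (k in seq_along(nodes)) {
      if (nodes[[k]]$requires) {
        ag_accum(nodes[[k]], n$grad[off + seq_len(rows[k]), , drop = FALSE])
      }
      off <- off + rows[k]
    }
  })
}

# Cross-entropy of a softmax over a 1 x K logit row against a set of correct
# classes: loss = -log sum_{k in target} softmax(logits)_k.
ag_softmax_ce <- function(logits, target) {
  l <- logits$value
  l <- l - max(l)
  p <- exp(l) / sum(exp(l))
  pt <- sum(p[target])
  ag_node(matrix(-log(max(pt, 1e-12)), 1L, 1L), list(logits), function(n) {
    if (logits$requires) {
      g <- p
      g[target] <- g[target] * (1 - 1 / max(pt, 1e-12))
      ag_accum(logits, n$grad[1L] * g)
    }
  })
}

# Binary cross-entropy from a scalar logit: softplus(x) - t * x.
ag_bce_logit <- function(logit, target) {
  x <- logit$value[1L]
  sp <- if (x > 30) x else log1p(exp(x))
  ag_node(matrix(sp - target * x, 1L, 1L), list(logit), function(n) {
    if (logit$requires) {
      ag_accum(logit, matrix(n$grad[1L] * (1 / (1 + exp(-x)) - target), 1L, 1L))
    }
  })
}

# --- backward pass -----------------------------------------------------------

ag_backward <- function(loss) {
  stopifnot(inherits(loss, "ag_node"), length(loss$value) == 1L)
  # collect reachable subgraph (iterative DFS), then sweep in decreasing id.
  # Visited nodes are stamped with a per-backward sweep number; keying an
  # environment by as.character(id) instead would intern one fresh R symbol
  # per node forever and degrade the garbage collector over long runs.
  sweep <- .ag_counter$sweep + 1
  .ag_counter$sweep <- sweep
  nodes <- vector("list", 256L)
  count <- 0L
  stack <- list(loss)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (identical(nd$swept, sweep) || !nd$requires) next
    nd$swept <- sweep
    count <- count + 1L
    if (count > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[count]] <- nd
    for (p in nd$parents) if (p$requires && !identical(p$swept, sweep)) {
      stack[[length(stack) + 1L]] <- p
    }
  }
  nodes <- nodes[seq_len(count)]
  ord <- order(vapply(nodes, function(n) n$id, numeric(1)), decreasing = TRUE)
  loss$grad <- matrix(1, 1L, 1L)
  for (nd in nodes[ord]) {
    if (!is.null(nd$backfn) && !is.null(nd$grad)) nd$backfn(nd)
  }
  invisible(loss)
}

# --- parameter handling ------------------------------------------------------

# Wrap a named list of plain matrices as trainable graph inputs.
ag_wrap_params <- function(params) {
  lapply(params, ag_input, requires = TRUE)
}

ag_collect_grads <- function(wrapped) {
  lapply(wrapped, function(p) {
    if (is.null(p$grad)) matrix(0, nrow(p$value), ncol(p$value)) else p$grad
  })
}

# Xavier-uniform initialization; `rng` is a function(n) drawing uniforms so the
# caller controls the stream.
xavier_init <- function(nin, nout, rng) {
  b <- sqrt(6 / (nin + nout))
  matrix((rng(nin * nout) * 2 - 1) * b, nin, nout)
}

# --- Adam optimizer ----------------------------------------------------------

adam_state <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, clip = 50) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (!is.finite(gn)) stop("non-finite gradient in optimizer step", call. = FALSE)
  if (gn > clip) grads <- lapply(grads, function(g) g * (clip / gn))
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}
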