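# The reverse-mode engine underlies every gradient in the package; this
# checks a composite expression exercising all primitive backward rules
# against central finite differences.
test_that("reverse-mode gradients of a composite network match finite differences", {
  ag <- asNamespace("jtprop")
  set.seed(2)
  W1 <- matrix(rnorm(12), 3, 4)
  b1 <- matrix(rnorm(4), 1)
  W2 <- matrix(rnorm(8), 4, 2)
  X <- matrix(rnorm(9), 3, 3)

  forward <- function(W1, b1, W2) {
    w1 <- ag$ag_input(W1, TRUE)
    bn1 <- ag$ag_input(b1, TRUE)
    w2 <- ag$ag_input(W2, TRUE)
    xn <- ag$ag_input(X)
    h <- ag$ag_relu(ag$ag_add(ag$ag_matmul(xn, w1), bn1))
    h <- ag$ag_sigmoid(ag$ag_matmul(h, w2))
    h <- ag$ag_concat_cols(h, ag$ag_tanh(h))
    r <- ag$ag_rows(h, c(1L, 3L, 2L, 1L))
    cm <- ag$ag_colmeans(ag$ag_mul(r, r))
    s <- ag$ag_sum(ag$ag_sqrt(ag$ag_add(cm, ag$ag_input(matrix(1, 1, 4)))))
    l <- ag$ag_add(s, ag$ag_softmax_ce(ag$ag_rows(h, 1L), 2L))
    l <- ag$ag_add(l, ag$ag_bce_logit(ag$ag_sum(ag$ag_abs(r)), 1))
    list(loss = l, params = list(W1 = w1, b1 = bn1, W2 = w2))
  }

  res <- forward(W1, b1, W2)
  ag$ag_backward(res$loss)
  val <- function(W1, b1, W2) forward(W1, b1, W2)$loss$value[1L]
  h <- 1e-6
  for (nm in c("W1", "b1", "W2")) {
    target <- get(nm)
    fd <- target * 0
    for (i in seq_along(target)) {
      up <- target; up[i] <- up[i] + h
      dn <- target; dn[i] <- dn[i] - h
      args_up <- list(W1 = W1, b1 = b1, W2 = W2); args_up[[nm]] <- up
      args_dn <- list(W1 = W1, b1 = b1, W2 = W2); args_dn[[nm]] <- dn
      fd[i] <- (do.call(val, args_up) - do.call(val, args_dn)) / (2 * h)
    }
    g <- res$params[[nm]]$grad
    expect_lt(max(abs(g - fd)), 1e-6)
  }
})

test_that("the GRU decoder cell backpropagates correctly through time", {
  ag <- asNamespace("jtprop")
  model <- untrained_model()
  set.seed(3)
  z <- matrix(rnorm(model$dec_cfg$input_dim), 1)
  loss_of <- function(params, requires = FALSE) {
    P <- lapply(params, ag$ag_input, requires = requires)
    zn <- ag$ag_input(z)
    h <- ag$ag_relu(ag$ag_add(ag$ag_matmul(zn, P$dt_winit), P$dt_binit))
    l <- ag$ag_softmax_ce(ag$label_logits(h, zn, P), 2L)
    for (tok in c(2L, 5L, 1L)) {
      h <- ag$gru_cell(ag$token_embed(tok, P), h, P)
      l <- ag$ag_add(l, ag$ag_bce_logit(ag$topo_logit(h, zn, P), 1))
    }
    list(loss = l, P = P)
  }
  res <- loss_of(model$params, requires = TRUE)
  ag$ag_backward(res$loss)
  h <- 1e-6
  for (nm in c("dt_wz", "dt_wh", "dt_embed", "dt_wt1")) {
    idx <- c(1L, 5L)
    for (i in idx) {
      pu <- model$params; pu[[nm]][i] <- pu[[nm]][i] + h
      pd <- model$params; pd[[nm]][i] <- pd[[nm]][i] - h
      fd <- (loss_of(pu)$loss$value[1] - loss_of(pd)$loss$value[1]) / (2 * h)
      expect_equal(res$P[[nm]]$grad[i], fd, tolerance = 1e-5)
    }
  }
})
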