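# Property regressor: feed-forward network from the stacked latent mean to a
# scalar property value. Two ReLU hidden layers, batch normalization after the
# second, linear output. In evaluation mode the batch-norm uses running
# statistics, so predictions and their gradients are deterministic functions
# of the input — a requirement for latent-space search.

regressor_forward <- function(zn, P, stats, train = FALSE, eps = 1e-5) {
  h1 <- ag_relu(ag_linear(zn, P$rg_w1, P$rg_b1))
  h2 <- ag_relu(ag_linear(h1, P$rg_w2, P$rg_b2))
  if (train && nrow(zn$value) > 1L) {
    mu <- ag_colmeans(h2)
    d <- ag_sub(h2, mu)
    v <- ag_colmeans(ag_mul(d, d))
    xhat <- ag_div(d, ag_sqrt(ag_add(v, ag_input(matrix(eps, 1, ncol(v$value))))))
    batch_stats <- list(mean = mu$value, var = v$value)
  } else {
    xhat <- ag_div(ag_sub(h2, ag_input(stats$mean)),
                   ag_input(sqrt(stats$var + eps)))
    batch_stats <- NULL
  }
  out <- ag_linear(ag_add(ag_mul(xhat, P$rg_gamma), P$rg_beta), P$rg_w3,
                   P$rg_b3)
  list(out = out, batch_stats = batch_stats)
}

#' Predict the property value from a latent mean vector
#'
#' Evaluation-mode forward pass of the regressor (batch-norm running
#' statistics); deterministic for fixed weights and input.
#'
#' @param z_mean Numeric vector of length `input_dim` (the stacked latent
#'   mean), a matrix of row vectors, or a `jtprop_latent`.
#' @param model A `jtprop_model`.
#' @return Numeric vector of predictions (scalar for a single input).
#' @export
predict_property <- function(z_mean, model) {
  stopifnot(inherits(model, "jtprop_model"))
  if (inherits(z_mean, "jtprop_latent")) z_mean <- z_mean$z
  zm <- if (is.matrix(z_mean)) z_mean else matrix(z_mean, 1L)
  if (ncol(zm) != model$reg_cfg$input_dim) {
    stop(sprintf("latent input has width %d; regressor expects %d",
                 ncol(zm), model$reg_cfg$input_dim), call. = FALSE)
  }
  P <- lapply(model$params, ag_input)
  as.numeric(regressor_forward(ag_input(zm), P, model$reg_stats)$out$value)
}

#' Gradient of the predicted property with respect to the latent input
#'
#' Reverse-mode gradient of the evaluation-mode regressor; matches central
#' finite differences.
#'
#' @param z_mean Numeric latent vector.
#' @param model A `jtprop_model`.
#' @return Numeric gradient vector of the same length.
#' @export
predict_property_gradient <- function(z_mean, model) {
  zm <- matrix(as.numeric(z_mean), 1L)
  P <- lapply(model$params, ag_input)
  zn <- ag_input(zm, requires = TRUE)
  out <- regressor_forward(zn, P, model$reg_stats)$out
  ag_backward(out)
  as.numeric(zn$grad)
}

#' Mean absolute error
#'
#' @param predicted,true Numeric vectors, or `predicted` may be a two-column
#'   data frame of (predicted, true) pairs.
#' @return Scalar MAE.
#' @examples
#' mae(c(1, 2), c(1, 3))  # 0.5
#' @export
mae <- function(predicted, true = NULL) {
  if (is.data.frame(predicted)) {
    true <- predicted[[2L]]
    predicted <- predicted[[1L]]
  }
  if (length(predicted) == 0L) stop("mae of an empty list", call. = FALSE)
  stopifnot(length(predicted) == length(true))
  mean(abs(predicted - true))
}
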