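# The two variational encoders: a message-passing network over the junction
# tree (nodes one-hot over the vocabulary, 1 iteration) and an edge-conditioned
# message-passing network over the molecular graph (atom features, 3
# iterations), each followed by a feature layer and linear heads for the
# Gaussian mean and log-variance. The two latents are stacked into one vector.

enc_head_forward <- function(readout, P, prefix) {
  p <- function(nm) P[[paste0(prefix, nm)]]
  feat <- ag_relu(ag_linear(readout, p("wfeat"), p("bfeat")))
  list(mu = ag_linear(feat, p("wmu"), p("bmu")),
       lv = ag_linear(feat, p("wlv"), p("blv")))
}

enc_tree_forward <- function(cst, P, cfg) {
  readout <- mpnn_embed(cst, P, "te_", cfg$tree_mpnn_iterations)
  enc_head_forward(readout, P, "te_")
}

enc_graph_forward <- function(cst, P, cfg) {
  readout <- mpnn_embed(cst, P, "ge_", cfg$graph_mpnn_iterations)
  enc_head_forward(readout, P, "ge_")
}

#' Encode a junction tree into its Gaussian latent
#'
#' Runs the tree message-passing encoder. Every cluster fragment must be in
#' the model's vocabulary; an out-of-vocabulary fragment raises an error
#' naming it.
#'
#' @param tree A `jtprop_jtree`.
#' @param model A `jtprop_model`.
#' @return A list with `mean` and `log_variance` (numeric vectors of
#'   `latent_dim`).
#' @export
encode_tree <- function(tree, model) {
  stopifnot(inherits(tree, "jtprop_jtree"), inherits(model, "jtprop_model"))
  cst <- tree_constants(tree, model$vocabulary, model$enc_cfg$vocab_size)
  P <- lapply(model$params, ag_input)
  out <- enc_tree_forward(cst, P, model$enc_cfg)
  list(mean = as.numeric(out$mu$value), log_variance = as.numeric(out$lv$value))
}

#' Encode a molecular graph into its Gaussian latent
#'
#' Runs the edge-conditioned graph message-passing encoder for exactly
#' `graph_mpnn_iterations` rounds. A single-atom molecule (no bonds) is valid:
#' no messages are passed.
#'
#' @param m A `jtprop_molecule`.
#' @param model A `jtprop_model`.
#' @return A list with `mean` and `log_variance`.
#' @export
encode_graph <- function(m, model) {
  stopifnot(inherits(m, "jtprop_molecule"), inherits(model, "jtprop_model"))
  cst <- graph_constants(m$atoms, m$bonds, model$enc_cfg$atom_feature_dim)
  P <- lapply(model$params, ag_input)
  out <- enc_graph_forward(cst, P, model$enc_cfg)
  list(mean = as.numeric(out$mu$value), log_variance = as.numeric(out$lv$value))
}

#' Encode a molecule into its stacked latent code
#'
#' Computes both Gaussian latents (junction tree and molecular graph) and the
#' stacked vector `z`. With `sample = TRUE`, `z` is drawn by the
#' reparameterization `z = mean + exp(log_variance / 2) * eps`,
#' `eps ~ N(0, I)`, using the given seed; otherwise `z` is the stacked means.
#'
#' @param m A `jtprop_molecule` or SMILES string.
#' @param model A `jtprop_model`.
#' @param sample Draw from the posterior instead of returning the means.
#' @param seed Seed for the posterior draw (required reproducibility handle).
#' @return A `jtprop_latent`: list with `tree`, `graph` (each mean /
#'   log_variance) and `z`.
#' @export
encode <- function(m, model, sample = FALSE, seed = NULL) {
  if (is.character(m)) m <- parse_smiles(m)
  tree <- tree_decompose(m)
  lt <- encode_tree(tree, model)
  lg <- encode_graph(m, model)
  mu <- c(lt$mean, lg$mean)
  z <- mu
  if (sample) {
    lv <- c(lt$log_variance, lg$log_variance)
    if (!is.null(seed)) {
      old <- preserve_rng()
      on.exit(restore_rng(old))
      set.seed(as.integer(seed))
    }
    z <- mu + exp(lv / 2) * stats::rnorm(length(mu))
  }
  structure(list(tree = lt, graph = lg, z = z), class = "jtprop_latent")
}

#' Kullback-Leibler divergence of a latent code from the standard normal
#'
#' Closed form of `KL(N(mean, diag(var)) || N(0, I))` summed over the tree and
#' graph blocks: `0.5 * sum(mean^2 + var - 1 - log(var))`.
#'
#' @param l A `jtprop_latent` (or a list with `mean` / `log_variance`).
#' @return Nonnegative scalar.
#' @export
kl_divergence <- function(l) {
  block <- function(b) {
    mu <- b$mean; lv <- b$log_variance
    0.5 * sum(mu^2 + exp(lv) - 1 - lv)
  }
  if (!is.null(l$tree)) block(l$tree) + block(l$graph) else block(l)
}

# Autograd KL from mu / lv nodes (training path).
kl_forward <- function(mu, lv) {
  var <- ag_exp(lv)
  ag_scale(ag_sum(ag_sub(ag_add(ag_mul(mu, mu), var),
                         ag_add(ag_input(matrix(1, 1, ncol(lv$value))), lv))),
           0.5)
}
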