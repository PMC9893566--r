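#' Model configurations
#'
#' Configuration constructors for the two encoders, the decoder, and the
#' property regressor. Defaults are the full-scale architecture (vocabulary
#' 2327, hidden width 612, latent width 128 per branch, regressor hidden 1024,
#' one tree message-passing iteration, three graph iterations); the `desk_*`
#' variants give a small preset (hidden 64, latent 16) for desk-scale models
#' where the full widths are unnecessary.
#'
#' The regressor input defaults to the stacked latent mean length
#' (2 x latent_dim, 256 at full scale). The architecture table's printed
#' regressor input of 612 conflicts with the 128+128 stacked vector it is fed;
#' both wirings are constructible via `input_dim`.
#'
#' @param vocab_size Width of the tree one-hot encoding.
#' @param atom_feature_dim Atom feature width for the graph encoder.
#' @param hidden_dim Hidden width of the message-passing trunks.
#' @param latent_dim Width of each Gaussian latent branch.
#' @param tree_mpnn_iterations,graph_mpnn_iterations Message-passing rounds.
#' @return A config object (a validated list).
#' @rdname configs
#' @export
encoder_config <- function(vocab_size = 2327L, atom_feature_dim = 50L,
                           hidden_dim = 612L, latent_dim = 128L,
                           tree_mpnn_iterations = 1L,
                           graph_mpnn_iterations = 3L) {
  cfg <- list(vocab_size = as.integer(vocab_size),
              atom_feature_dim = as.integer(atom_feature_dim),
              hidden_dim = as.integer(hidden_dim),
              latent_dim = as.integer(latent_dim),
              tree_mpnn_iterations = as.integer(tree_mpnn_iterations),
              graph_mpnn_iterations = as.integer(graph_mpnn_iterations))
  stopifnot(all(vapply(cfg, function(x) length(x) == 1L && !is.na(x) && x >= 1L,
                       logical(1))))
  structure(cfg, class = "jtprop_encoder_config")
}

#' @param input_dim Latent input width of the decoder (stacked vector) or the
#'   regressor.
#' @param assembly_mpnn_iterations Message-passing rounds of the assembly scorer.
#' @param max_decode_steps Upper bound on generated tree nodes.
#' @rdname configs
#' @export
decoder_config <- function(input_dim = 256L, hidden_dim = 612L,
                           vocab_size = 2327L, assembly_mpnn_iterations = 3L,
                           max_decode_steps = 60L,
                           atom_feature_dim = 50L) {
  cfg <- list(input_dim = as.integer(input_dim),
              hidden_dim = as.integer(hidden_dim),
              vocab_size = as.integer(vocab_size),
              assembly_mpnn_iterations = as.integer(assembly_mpnn_iterations),
              max_decode_steps = as.integer(max_decode_steps),
              atom_feature_dim = as.integer(atom_feature_dim))
  stopifnot(all(vapply(cfg, function(x) length(x) == 1L && !is.na(x) && x >= 1L,
                       logical(1))))
  structure(cfg, class = "jtprop_decoder_config")
}

#' @rdname configs
#' @export
regressor_config <- function(input_dim = 256L, hidden_dim = 1024L) {
  cfg <- list(input_dim = as.integer(input_dim),
              hidden_dim = as.integer(hidden_dim))
  stopifnot(all(vapply(cfg, function(x) length(x) == 1L && !is.na(x) && x >= 1L,
                       logical(1))))
  structure(cfg, class = "jtprop_regressor_config")
}

#' @rdname configs
#' @export
desk_encoder_config <- function(vocab_size, hidden_dim = 64L, latent_dim = 16L) {
  encoder_config(vocab_size = vocab_size, hidden_dim = hidden_dim,
                 latent_dim = latent_dim)
}

#' @rdname configs
#' @export
desk_decoder_config <- function(vocab_size, hidden_dim = 64L, latent_dim = 16L,
                                max_decode_steps = 15L) {
  decoder_config(input_dim = 2L * latent_dim, hidden_dim = hidden_dim,
                 vocab_size = vocab_size, max_decode_steps = max_decode_steps)
}

#' Initialize a full model (encoders + decoder + regressor)
#'
#' Creates all weight matrices with seeded Xavier-uniform initialization and
#' caches the parsed fragment graphs of the vocabulary (used by graph
#' assembly). The vocabulary may be shorter than the configured one-hot width.
#'
#' @param vocabulary A `jtprop_vocabulary`.
#' @param enc_cfg,dec_cfg,reg_cfg Configuration objects; `NULL` derives
#'   desk-scale configs from the vocabulary.
#' @param seed Integer seed for weight initialization.
#' @return A `jtprop_model`.
#' @export
jtprop_model <- function(vocabulary, enc_cfg = NULL, dec_cfg = NULL,
                         reg_cfg = NULL, seed = 1L) {
  stopifnot(inherits(vocabulary, "jtprop_vocabulary"))
  V <- length(vocabulary)
  if (is.null(enc_cfg)) enc_cfg <- desk_encoder_config(vocab_size = max(V, 1L))
  if (is.null(dec_cfg)) dec_cfg <- desk_decoder_config(
    vocab_size = enc_cfg$vocab_size, hidden_dim = enc_cfg$hidden_dim,
    latent_dim = enc_cfg$latent_dim)
  if (is.null(reg_cfg)) reg_cfg <- regressor_config(
    input_dim = 2L * enc_cfg$latent_dim,
    hidden_dim = max(64L, 4L * enc_cfg$latent_dim))
  if (V > enc_cfg$vocab_size) {
    stop("vocabulary larger than the configured one-hot width", call. = FALSE)
  }
  stopifnot(dec_cfg$vocab_size == enc_cfg$vocab_size)

  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(as.integer(seed))
  rng <- stats::runif
  h <- enc_cfg$hidden_dim
  l <- enc_cfg$latent_dim
  fd <- enc_cfg$atom_feature_dim
  dh <- dec_cfg$hidden_dim
  di <- dec_cfg$input_dim
  Vw <- enc_cfg$vocab_size

  params <- list(
    # tree encoder
    te_win = xavier_init(Vw, h, rng),
    te_wmsg = xavier_init(h, h, rng), te_bmsg = matrix(0, 1, h),
    te_wagg = xavier_init(h, h, rng), te_bagg = matrix(0, 1, h),
    te_wfeat = xavier_init(h, h, rng), te_bfeat = matrix(0, 1, h),
    te_wmu = xavier_init(h, l, rng), te_bmu = matrix(0, 1, l),
    te_wlv = xavier_init(h, l, rng), te_blv = matrix(0, 1, l),
    # graph encoder
    ge_win = xavier_init(fd, h, rng),
    ge_wmsg = xavier_init(h, h, rng), ge_bmsg = matrix(0, 1, h),
    ge_wedge = xavier_init(3L, h, rng),
    ge_wagg = xavier_init(h, h, rng), ge_bagg = matrix(0, 1, h),
    ge_wfeat = xavier_init(h, h, rng), ge_bfeat = matrix(0, 1, h),
    ge_wmu = xavier_init(h, l, rng), ge_bmu = matrix(0, 1, l),
    ge_wlv = xavier_init(h, l, rng), ge_blv = matrix(0, 1, l),
    # tree decoder (GRU over the depth-first decision sequence)
    dt_winit = xavier_init(di, dh, rng), dt_binit = matrix(0, 1, dh),
    dt_embed = xavier_init(Vw + 1L, dh, rng),  # fragment tokens + backtrack
    dt_wz = xavier_init(2L * dh, dh, rng), dt_bz = matrix(0, 1, dh),
    dt_wr = xavier_init(2L * dh, dh, rng), dt_br = matrix(0, 1, dh),
    dt_wh = xavier_init(2L * dh, dh, rng), dt_bh = matrix(0, 1, dh),
    dt_wt1 = xavier_init(dh + di, dh, rng), dt_bt1 = matrix(0, 1, dh),
    dt_wt2 = xavier_init(dh, 1L, rng), dt_bt2 = matrix(0, 1, 1),
    dt_wl1 = xavier_init(dh + di, dh, rng), dt_bl1 = matrix(0, 1, dh),
    dt_wl2 = xavier_init(dh, Vw, rng), dt_bl2 = matrix(0, 1, Vw),
    # assembly scorer
    da_win = xavier_init(fd, dh, rng),
    da_wmsg = xavier_init(dh, dh, rng), da_bmsg = matrix(0, 1, dh),
    da_wedge = xavier_init(3L, dh, rng),
    da_wagg = xavier_init(dh, dh, rng), da_bagg = matrix(0, 1, dh),
    da_wout = xavier_init(dh, dh, rng), da_bout = matrix(0, 1, dh),
    da_wz = xavier_init(di, dh, rng), da_bz = matrix(0, 1, dh),
    # regressor
    rg_w1 = xavier_init(reg_cfg$input_dim, reg_cfg$hidden_dim, rng),
    rg_b1 = matrix(0, 1, reg_cfg$hidden_dim),
    rg_w2 = xavier_init(reg_cfg$hidden_dim, reg_cfg$hidden_dim, rng),
    rg_b2 = matrix(0, 1, reg_cfg$hidden_dim),
    rg_gamma = matrix(1, 1, reg_cfg$hidden_dim),
    rg_beta = matrix(0, 1, reg_cfg$hidden_dim),
    rg_w3 = xavier_init(reg_cfg$hidden_dim, 1L, rng),
    rg_b3 = matrix(0, 1, 1)
  )

  model <- list(
    vocabulary = vocabulary,
    enc_cfg = enc_cfg, dec_cfg = dec_cfg, reg_cfg = reg_cfg,
    params = params,
    reg_stats = list(mean = matrix(0, 1, reg_cfg$hidden_dim),
                     var = matrix(1, 1, reg_cfg$hidden_dim)),
    frag_graphs = lapply(vocabulary$fragments, parse_smiles),
    seed = as.integer(seed),
    history = list()
  )
  class(model) <- "jtprop_model"
  model
}

#' @export
print.jtprop_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(paste0("<jtprop model> vocab %d/%d, hidden %d, latent 2x%d, ",
                     "regressor hidden %d (%s parameters)\n"),
              length(x$vocabulary), x$enc_cfg$vocab_size,
              x$enc_cfg$hidden_dim, x$enc_cfg$latent_dim,
              x$reg_cfg$hidden_dim, format(np, big.mark = ",")))
  invisible(x)
}

# Named parameter groups, used for freeze contracts and optimizer scoping.
model_component_params <- function(model,
                                   component = c("encoder", "decoder",
                                                 "regressor")) {
  component <- match.arg(component)
  prefix <- switch(component,
                   encoder = c("te_", "ge_"),
                   decoder = c("dt_", "da_"),
                   regressor = "rg_")
  keep <- Reduce(`|`, lapply(prefix, function(p) startsWith(names(model$params), p)))
  model$params[keep]
}

#' Checksum of a model component's weights
#'
#' A cheap deterministic fingerprint (sums and sums of squares of every
#' weight matrix) used to verify the freeze contracts of the fine-tuning
#' strategies: a component whose weights were not touched keeps an identical
#' checksum.
#'
#' @param model A `jtprop_model`.
#' @param component One of "encoder", "decoder", "regressor".
#' @return A character scalar.
#' @export
model_checksum <- function(model, component) {
  p <- model_component_params(model, component)
  vals <- unlist(lapply(p, function(x) c(sum(x), sum(x * x))))
  paste(sprintf("%.12e", vals), collapse = "|")
}

# --- checkpoints -------------------------------------------------------------

.checkpoint_version <- "jtprop-checkpoint-1"

#' Save / load a model checkpoint
#'
#' Checkpoints are versioned and echo their configuration; loading a
#' checkpoint whose configuration does not match `expected_cfg` fails loudly.
#'
#' @param model A `jtprop_model`.
#' @param path File path.
#' @rdname checkpoint
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "jtprop_model"))
  obj <- list(version = .checkpoint_version,
              enc_cfg = model$enc_cfg, dec_cfg = model$dec_cfg,
              reg_cfg = model$reg_cfg, model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @param expected_cfg Optional `jtprop_encoder_config` the checkpoint must match.
#' @rdname checkpoint
#' @export
load_checkpoint <- function(path, expected_cfg = NULL) {
  if (!file.exists(path)) stop(sprintf("checkpoint '%s' not found", path),
                               call. = FALSE)
  obj <- readRDS(path)
  if (!identical(obj$version, .checkpoint_version)) {
    stop(sprintf("checkpoint '%s' has unsupported version '%s'", path,
                 if (is.null(obj$version)) "<none>" else obj$version),
         call. = FALSE)
  }
  if (!is.null(expected_cfg) && !identical(unclass(obj$enc_cfg),
                                           unclass(expected_cfg))) {
    stop(sprintf("checkpoint '%s' was written with a different encoder configuration",
                 path), call. = FALSE)
  }
  obj$model
}

# --- RNG hygiene -------------------------------------------------------------

preserve_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
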