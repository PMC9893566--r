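#' Training configuration
#'
#' Two-phase variational training (phase 1 trains the deterministic
#' autoencoder, reconstruction loss only; phase 2 adds the KL penalty with a
#' fixed coefficient `kl_beta` and samples the latent by reparameterization)
#' plus epoch budgets for the regression fine-tuning strategies. The optimizer
#' is Adam with gradient-norm clipping.
#'
#' @param epochs_phase1,epochs_phase2 VAE epochs per phase.
#' @param epochs_regressor Epochs for regressor (strategies 1-3) training.
#' @param epochs_encoder Epochs for the joint encoder+regressor stage
#'   (strategies 2 and 3).
#' @param epochs_decoder Epochs for the decoder retraining stage (strategy 3).
#' @param batch_size Molecules per optimizer step.
#' @param lr Adam learning rate.
#' @param kl_beta KL penalty coefficient in phase 2 (phase 1 always uses 0).
#' @param clip Gradient-norm clip.
#' @param seed RNG seed for shuffling, sampling and reparameterization noise.
#' @return A `jtprop_train_config`.
#' @export
train_config <- function(epochs_phase1 = 40L, epochs_phase2 = 10L,
                         epochs_regressor = 300L, epochs_encoder = 150L,
                         epochs_decoder = 60L, batch_size = 10L,
                         lr = 1e-3, kl_beta = 0.005, clip = 50, seed = 1L) {
  cfg <- list(epochs_phase1 = as.integer(epochs_phase1),
              epochs_phase2 = as.integer(epochs_phase2),
              epochs_regressor = as.integer(epochs_regressor),
              epochs_encoder = as.integer(epochs_encoder),
              epochs_decoder = as.integer(epochs_decoder),
              batch_size = as.integer(batch_size),
              lr = lr, kl_beta = kl_beta, clip = clip,
              seed = as.integer(seed))
  stopifnot(cfg$kl_beta >= 0, cfg$lr > 0, cfg$batch_size >= 1L)
  structure(cfg, class = "jtprop_train_config")
}

# Per-molecule caches: decomposition, teacher sequence, encoder constants and
# assembly supervision. Fails before training starts if any molecule has an
# out-of-vocabulary fragment.
prepare_training_set <- function(molecules, model) {
  lapply(molecules, function(m) {
    if (is.character(m)) m <- parse_smiles(m)
    tree <- tree_decompose(m)
    seq <- teacher_sequence(tree, model$vocabulary)  # errors on OOV fragments
    list(
      molecule = m,
      tree = tree,
      seq = seq,
      tcst = tree_constants(tree, model$vocabulary, model$enc_cfg$vocab_size),
      gcst = graph_constants(m$atoms, m$bonds, model$enc_cfg$atom_feature_dim),
      asteps = assembly_teacher_steps(m, tree, seq, model)
    )
  })
}

# Stacked-latent node for one cached molecule. sample_eps NULL = use means.
encode_forward_cached <- function(cache, P, model, sample_eps = NULL) {
  et <- enc_tree_forward(cache$tcst, P, model$enc_cfg)
  eg <- enc_graph_forward(cache$gcst, P, model$enc_cfg)
  mu <- ag_concat_cols(et$mu, eg$mu)
  lv <- ag_concat_cols(et$lv, eg$lv)
  z <- mu
  if (!is.null(sample_eps)) {
    z <- ag_add(mu, ag_mul(ag_input(matrix(sample_eps, 1L)),
                           ag_exp(ag_scale(lv, 0.5))))
  }
  list(mu = mu, lv = lv, z = z)
}

vae_molecule_loss <- function(cache, P, model, kl_beta = 0, sample_eps = NULL) {
  enc <- encode_forward_cached(cache, P, model, sample_eps)
  loss <- tree_teacher_loss(cache$seq, enc$z, P, model)
  al <- assembly_teacher_loss(cache$asteps, enc$z, P, model)
  if (!is.null(al)) loss <- ag_add(loss, al)
  if (kl_beta > 0) {
    loss <- ag_add(loss, ag_scale(kl_forward(enc$mu, enc$lv), kl_beta))
  }
  loss
}

# One Adam step over a batch of caches. Only parameters named in `trainable`
# receive gradients and updates. The forward/backward pass runs one molecule
# at a time, accumulating plain gradient matrices, so only a single
# molecule's graph is ever live (the mean-loss gradient is the mean of the
# per-molecule gradients).
vae_batch_step <- function(model, caches, trainable, opt, cfg, kl_beta) {
  grads <- NULL
  loss <- 0
  for (cache in caches) {
    P <- lapply(names(model$params), function(nm) {
      ag_input(model$params[[nm]], requires = nm %in% trainable)
    })
    names(P) <- names(model$params)
    l <- vae_molecule_loss(cache, P, model, kl_beta)
    ag_backward(l)
    g <- ag_collect_grads(P[trainable])
    grads <- if (is.null(grads)) g else Map(`+`, grads, g)
    loss <- loss + l$value[1L]
  }
  n <- length(caches)
  grads <- lapply(grads, function(g) g / n)
  upd <- adam_step(model$params[trainable], grads, opt, lr = cfg$lr,
                   clip = cfg$clip)
  model$params[trainable] <- upd$params
  list(model = model, opt = upd$state, loss = loss / n)
}

#' Two-phase VAE training
#'
#' Phase 1 minimizes the teacher-forced reconstruction loss (tree topology and
#' label cross-entropy plus assembly cross-entropy) alone, training the
#' deterministic autoencoder; phase 2 adds `kl_beta` times the closed-form KL
#' divergence of the posterior from N(0, I), so with `kl_beta = 0` phase 2 has
#' exactly the phase-1 update rule. The latent fed to the decoder is the
#' posterior mean in both phases (posterior sampling is available at inference
#' via [encode()]). Molecules with out-of-vocabulary fragments fail before
#' training starts. Seeded runs are reproducible.
#'
#' @param molecules List of `jtprop_molecule` (or SMILES).
#' @param model A `jtprop_model`.
#' @param cfg A `jtprop_train_config`.
#' @param caches Optional precomputed [prepare_training_set()] output.
#' @param quiet Suppress per-epoch progress messages.
#' @return The trained model; `model$history$vae` holds per-epoch losses.
#' @export
train_vae <- function(molecules, model, cfg = train_config(), caches = NULL,
                      quiet = TRUE) {
  if (is.null(caches)) caches <- prepare_training_set(molecules, model)
  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(cfg$seed)
  trainable <- names(model$params)[startsWith(names(model$params), "te_") |
                                     startsWith(names(model$params), "ge_") |
                                     startsWith(names(model$params), "dt_") |
                                     startsWith(names(model$params), "da_")]
  opt <- adam_state(model$params[trainable])
  history <- list()
  n <- length(caches)
  for (phase in 1:2) {
    epochs <- if (phase == 1L) cfg$epochs_phase1 else cfg$epochs_phase2
    kl_beta <- if (phase == 1L) 0 else cfg$kl_beta
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        res <- vae_batch_step(model, caches[idx], trainable, opt, cfg,
                              kl_beta)
        model <- res$model; opt <- res$opt
        ep_loss <- ep_loss + res$loss; nb <- nb + 1L
      }
      history[[length(history) + 1L]] <- c(phase = phase, epoch = ep,
                                           loss = ep_loss / nb)
      if (!quiet && ep %% 10L == 0L) {
        message(sprintf("phase %d epoch %d: loss %.4f", phase, ep,
                        ep_loss / nb))
      }
    }
  }
  model$history$vae <- tibble::as_tibble(do.call(rbind, history))
  model
}

# --- regression / fine-tuning strategies -------------------------------------

regressor_batch_step <- function(model, Z, y, trainable, opt, cfg,
                                 enc_nodes = NULL) {
  P <- lapply(names(model$params), function(nm) {
    ag_input(model$params[[nm]], requires = nm %in% trainable)
  })
  names(P) <- names(model$params)
  zn <- if (is.null(enc_nodes)) ag_input(Z) else NULL
  if (!is.null(enc_nodes)) {
    mus <- lapply(enc_nodes, function(cache) {
      encode_forward_cached(cache, P, model)$mu
    })
    zn <- ag_rbind(mus)
  }
  fwd <- regressor_forward(zn, P, model$reg_stats, train = TRUE)
  loss <- ag_mean(ag_abs(ag_sub(fwd$out, ag_input(matrix(y, ncol = 1L)))))
  ag_backward(loss)
  grads <- ag_collect_grads(P[trainable])
  upd <- adam_step(model$params[trainable], grads, opt, lr = cfg$lr,
                   clip = cfg$clip)
  model$params[trainable] <- upd$params
  if (!is.null(fwd$batch_stats)) {
    mom <- 0.1
    model$reg_stats$mean <- (1 - mom) * model$reg_stats$mean +
      mom * fwd$batch_stats$mean
    model$reg_stats$var <- (1 - mom) * model$reg_stats$var +
      mom * fwd$batch_stats$var
  }
  list(model = model, opt = upd$state, loss = loss$value[1L])
}

run_regression_epochs <- function(model, caches, y, trainable, cfg, epochs,
                                  joint = FALSE, label = "regression") {
  opt <- adam_state(model$params[trainable])
  n <- length(y)
  history <- list()
  Zfixed <- NULL
  if (!joint) {
    Zfixed <- do.call(rbind, lapply(caches, function(cache) {
      P <- lapply(model$params, ag_input)
      encode_forward_cached(cache, P, model)$mu$value
    }))
  }
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      res <- if (joint) {
        regressor_batch_step(model, NULL, y[idx], trainable, opt, cfg,
                             enc_nodes = caches[idx])
      } else {
        regressor_batch_step(model, Zfixed[idx, , drop = FALSE], y[idx],
                             trainable, opt, cfg)
      }
      model <- res$model; opt <- res$opt
      ep_loss <- ep_loss + res$loss; nb <- nb + 1L
    }
    history[[length(history) + 1L]] <- c(epoch = ep, loss = ep_loss / nb)
  }
  model$history[[label]] <- tibble::as_tibble(do.call(rbind, history))
  model
}

#' Fine-tune the encoder/decoder/regressor triple
#'
#' The three training orders applied after the two-phase VAE:
#' * strategy 1: regressor only; encoder and decoder stay frozen.
#' * strategy 2: encoder and regressor jointly; the decoder stays frozen
#'   (after this stage the encoder no longer matches the decoder).
#' * strategy 3: strategy 2 followed by retraining the decoder with the
#'   fine-tuned encoder frozen.
#'
#' @param model A trained `jtprop_model` (the phase-2 VAE checkpoint).
#' @param data A data frame with columns `smiles` and `value` (the property
#'   table; only molecules with property values are used here).
#' @param cfg A `jtprop_train_config`.
#' @param strategy 1, 2 or 3.
#' @return The fine-tuned model.
#' @export
train_strategy <- function(model, data, cfg = train_config(), strategy) {
  stopifnot(inherits(model, "jtprop_model"), strategy %in% 1:3)
  if (is.null(model$history$vae)) {
    stop("train_strategy requires a VAE-trained model (run train_vae first)",
         call. = FALSE)
  }
  molecules <- lapply(data$smiles, parse_smiles)
  caches <- prepare_training_set(molecules, model)
  y <- data$value
  old <- preserve_rng()
  on.exit(restore_rng(old))
  nm <- names(model$params)
  reg <- nm[startsWith(nm, "rg_")]
  enc <- nm[startsWith(nm, "te_") | startsWith(nm, "ge_")]
  dec <- nm[startsWith(nm, "dt_") | startsWith(nm, "da_")]
  if (strategy == 1L) {
    set.seed(cfg$seed + 1L)
    model <- run_regression_epochs(model, caches, y, reg, cfg,
                                   cfg$epochs_regressor, joint = FALSE,
                                   label = "strategy1")
  } else {
    # the joint encoder+regressor stage is seeded identically for strategies
    # 2 and 3, so strategy 3 continues from exactly the strategy-2 state
    set.seed(cfg$seed + 2L)
    model <- run_regression_epochs(model, caches, y, c(enc, reg), cfg,
                                   cfg$epochs_encoder, joint = TRUE,
                                   label = "strategy2")
    if (strategy == 3L) {
      # decoder retraining against the (frozen) fine-tuned encoder
      set.seed(cfg$seed + 3L)
      opt <- adam_state(model$params[dec])
      n <- length(caches)
      history <- list()
      for (ep in seq_len(cfg$epochs_decoder)) {
        ord <- sample.int(n)
        ep_loss <- 0; nb <- 0L
        for (start in seq(1L, n, by = cfg$batch_size)) {
          idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
          res <- vae_batch_step(model, caches[idx], dec, opt, cfg,
                                kl_beta = 0)
          model <- res$model; opt <- res$opt
          ep_loss <- ep_loss + res$loss; nb <- nb + 1L
        }
        history[[length(history) + 1L]] <- c(epoch = ep, loss = ep_loss / nb)
      }
      model$history$strategy3_decoder <-
        tibble::as_tibble(do.call(rbind, history))
    }
  }
  model
}

# --- evaluation metrics ------------------------------------------------------

#' Reconstruction accuracy
#'
#' Percentage of molecules whose mean-encoding decodes back to the identical
#' canonical SMILES. Molecules with out-of-vocabulary fragments count as
#' failures (and are reported via a message).
#'
#' @param model A `jtprop_model`.
#' @param molecules List of `jtprop_molecule` or character SMILES.
#' @return Percentage in \[0, 100\].
#' @export
reconstruction_accuracy <- function(model, molecules) {
  if (length(molecules) == 0L) {
    stop("reconstruction accuracy of an empty set", call. = FALSE)
  }
  hits <- vapply(molecules, function(m) {
    if (is.character(m)) m <- parse_smiles(m)
    if (!vocabulary_coverage(model$vocabulary, m)) {
      message(sprintf("out-of-vocabulary molecule '%s' counted as failure",
                      m$smiles))
      return(FALSE)
    }
    dec <- decode(encode(m, model), model)
    identical(dec$smiles, m$smiles)
  }, logical(1))
  100 * mean(hits)
}

#' Chemical validity rate
#'
#' Percentage of entries that parse and sanitize under standard valence
#' rules. Accepts SMILES strings (possibly unparseable) or molecule objects
#' (valid by construction).
#'
#' @param x Character vector of SMILES or list of `jtprop_molecule`.
#' @return Percentage in \[0, 100\].
#' @export
chemical_validity <- function(x) {
  if (length(x) == 0L) stop("chemical validity of an empty list", call. = FALSE)
  ok <- vapply(x, function(s) {
    if (inherits(s, "jtprop_molecule")) return(TRUE)
    !inherits(try(parse_smiles(s), silent = TRUE), "try-error")
  }, logical(1))
  100 * mean(ok)
}
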