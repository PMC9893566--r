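# Shared desk-scale study objects, built once per test run and cached.
# Conditions: 40 synthetic fixture molecules (seed 7), 20/8/12
# train/validation/test split, desk model (hidden 64, latent 2x16, seed 3),
# two-phase VAE training 100+20 epochs at lr 2e-3 (seed 11); the property
# table for regression covers the train and validation splits.

.test_cache <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  if (is.null(.test_cache[[name]])) .test_cache[[name]] <- fn()
  .test_cache[[name]]
}

desk_fixtures <- function() cached("fixtures", function() {
  fx <- generate_fixture_set(fixture_spec(n_molecules = 40L, seed = 7L))
  sp <- make_splits(fx, split_spec(validation_count = 8L, test_count = 12L,
                                   seed = 7L))
  list(fx = fx, sp = sp)
})

desk_vocab <- function() cached("vocab", function() {
  build_vocabulary(desk_fixtures()$sp$train$molecule)
})

untrained_model <- function() cached("untrained", function() {
  jtprop_model(desk_vocab(), seed = 3L)
})

desk_train_cfg <- function() {
  train_config(epochs_phase1 = 100L, epochs_phase2 = 20L, lr = 2e-3,
               seed = 11L)
}

# Trained VAE plus the three fine-tuning strategies (the expensive shared
# build; ~10 minutes on one CPU).
desk_pipeline <- function() cached("pipeline", function() {
  d <- desk_fixtures()
  train <- d$sp$train
  cfg <- desk_train_cfg()
  vae <- train_vae(train$molecule, untrained_model(), cfg)
  props <- rbind(train[, c("smiles", "value")],
                 d$sp$validation[, c("smiles", "value")])
  m1 <- train_strategy(vae, props, cfg, strategy = 1L)
  m2 <- train_strategy(vae, props, cfg, strategy = 2L)
  m3 <- train_strategy(vae, props, cfg, strategy = 3L)
  list(vae = vae, m1 = m1, m2 = m2, m3 = m3, train = train,
       validation = d$sp$validation, test = d$sp$test)
})

# Hand-wire the regressor so that, in evaluation mode, it computes exactly
# f(z) = sum(w * z): first hidden unit carries relu(w.z), second relu(-w.z),
# the identity batch-norm leaves them alone, and the output head subtracts.
linear_regressor_model <- function(w, base = NULL) {
  if (is.null(base)) base <- untrained_model()
  d <- base$reg_cfg$input_dim
  h <- base$reg_cfg$hidden_dim
  stopifnot(length(w) == d, h >= 2L)
  p <- base$params
  p$rg_w1 <- matrix(0, d, h); p$rg_w1[, 1L] <- w; p$rg_w1[, 2L] <- -w
  p$rg_b1 <- matrix(0, 1L, h)
  p$rg_w2 <- matrix(0, h, h); p$rg_w2[1L, 1L] <- 1; p$rg_w2[2L, 2L] <- 1
  p$rg_b2 <- matrix(0, 1L, h)
  p$rg_gamma <- matrix(1, 1L, h); p$rg_beta <- matrix(0, 1L, h)
  p$rg_w3 <- matrix(0, h, 1L); p$rg_w3[1L, 1L] <- 1; p$rg_w3[2L, 1L] <- -1
  p$rg_b3 <- matrix(0, 1L, 1L)
  base$params <- p
  # running var of 1 - eps makes the evaluation-mode batch-norm an exact
  # identity (the forward pass adds eps = 1e-5 back)
  base$reg_stats <- list(mean = matrix(0, 1L, h),
                         var = matrix(1 - 1e-5, 1L, h))
  base
}

expect_valid_jtree <- function(t, m) {
  expect_s3_class(t, "jtprop_jtree")
  expect_equal(nrow(t$edges), length(t$nodes) - 1L)
  covered <- sort(unique(unlist(lapply(t$nodes, `[[`, "atom_ids"))))
  expect_equal(covered, seq_len(nrow(m$atoms)))
  if (nrow(t$edges)) {
    for (k in seq_len(nrow(t$edges))) {
      shared <- intersect(t$nodes[[t$edges[k, 1L]]]$atom_ids,
                          t$nodes[[t$edges[k, 2L]]]$atom_ids)
      expect_gte(length(shared), 1L)
    }
  }
}
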