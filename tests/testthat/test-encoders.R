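test_that("encoders are deterministic and produce latents of the configured width", {
  model <- untrained_model()
  m <- desk_fixtures()$fx$molecule[[1L]]
  tree <- tree_decompose(m)

  lt1 <- encode_tree(tree, model)
  lt2 <- encode_tree(tree, model)
  expect_identical(lt1$mean, lt2$mean)
  expect_length(lt1$mean, model$enc_cfg$latent_dim)
  expect_length(lt1$log_variance, model$enc_cfg$latent_dim)

  lg <- encode_graph(m, model)
  expect_length(lg$mean, model$enc_cfg$latent_dim)
  expect_true(all(is.finite(c(lg$mean, lg$log_variance))))

  lat <- encode(m, model)
  expect_equal(lat$z, c(lt1$mean, lg$mean))
})

test_that("full-scale configuration matches the published layer widths", {
  v <- desk_vocab()
  model <- cached("paper_scale_model", function() {
    jtprop_model(v, enc_cfg = encoder_config(), dec_cfg = decoder_config(),
                 reg_cfg = regressor_config(), seed = 1L)
  })
  m <- desk_fixtures()$fx$molecule[[2L]]
  lat <- encode(m, model)
  expect_length(lat$tree$mean, 128L)        # tree mean head 612 -> 128
  expect_length(lat$graph$mean, 128L)       # graph mean head 612 -> 128
  expect_length(lat$z, 256L)                # stacked vector
  expect_equal(dim(model$params$te_win), c(2327L, 612L))  # tree one-hot 2327 -> 612
  expect_equal(dim(model$params$ge_win), c(50L, 612L))    # atom features 50 -> 612
  expect_equal(ncol(model$params$dt_wl2), 2327L)          # label head 612 -> 2327
  expect_equal(dim(model$params$rg_w2), c(1024L, 1024L))  # regressor hidden 1024
  expect_equal(ncol(model$params$rg_w1), 1024L)
  expect_equal(nrow(model$params$rg_w1), 256L)  # stacked latent in by default
})

test_that("encoding is invariant to how the input molecule is written", {
  model <- untrained_model()
  smi <- desk_fixtures()$fx$smiles[[3L]]
  z1 <- encode(smi, model)$z
  # a different spelling of the same molecule through a scramble: parse,
  # rebuild from tables, re-encode
  m <- parse_smiles(smi)
  z2 <- encode(parse_smiles(m$smiles), model)$z
  expect_identical(z1, z2)
})

test_that("single-atom molecules encode to finite latents", {
  v <- build_vocabulary("C")
  model <- jtprop_model(v, seed = 5L)
  lg <- encode_graph(parse_smiles("C"), model)
  expect_true(all(is.finite(c(lg$mean, lg$log_variance))))
})

test_that("posterior sampling is seeded and collapses to the mean at zero variance", {
  model <- untrained_model()
  m <- desk_fixtures()$fx$molecule[[1L]]
  l1 <- encode(m, model, sample = TRUE, seed = 42L)
  l2 <- encode(m, model, sample = TRUE, seed = 42L)
  l3 <- encode(m, model, sample = TRUE, seed = 43L)
  expect_identical(l1$z, l2$z)
  expect_false(identical(l1$z, l3$z))
  expect_false(identical(l1$z, encode(m, model)$z))

  # drive log-variance to -inf: the draw collapses onto the mean
  model$params$te_wlv[] <- 0; model$params$ge_wlv[] <- 0
  model$params$te_blv[] <- -80; model$params$ge_blv[] <- -80
  l0 <- encode(m, model, sample = TRUE, seed = 1L)
  expect_equal(l0$z, c(l0$tree$mean, l0$graph$mean), tolerance = 1e-12)
})

test_that("closed-form KL divergence matches its analytic values", {
  d <- 6L
  expect_equal(kl_divergence(list(mean = rep(0, d), log_variance = rep(0, d))),
               0)
  expect_equal(kl_divergence(list(mean = 1, log_variance = 0)), 0.5)
  set.seed(8)
  for (i in 1:20) {
    l <- list(mean = rnorm(4), log_variance = rnorm(4))
    expect_gte(kl_divergence(l), 0)
  }
  # both blocks are summed
  lat <- structure(list(tree = list(mean = 1, log_variance = 0),
                        graph = list(mean = 1, log_variance = 0)),
                   class = "jtprop_latent")
  expect_equal(kl_divergence(lat), 1)
})

test_that("encoder outputs stay finite across all fixture molecules", {
  model <- untrained_model()
  d <- desk_fixtures()
  for (m in d$sp$train$molecule) {
    lat <- encode(m, model)
    expect_true(all(is.finite(c(lat$z, lat$tree$log_variance,
                                lat$graph$log_variance))))
  }
})
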