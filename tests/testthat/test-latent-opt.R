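test_that("the property loss and its subgradient behave analytically", {
  base <- untrained_model()
  set.seed(41)
  w <- rnorm(base$reg_cfg$input_dim)
  model <- linear_regressor_model(w, base)
  z <- rnorm(length(w))

  spec1 <- property_spec(target_value = sum(w * z))
  expect_equal(property_loss(z, spec1, model), 0, tolerance = 1e-12)

  spec2 <- property_spec(target_value = sum(w * z) + 0.5)
  expect_equal(property_loss(z, spec2, model), 0.5, tolerance = 1e-10)

  # subgradient vs finite differences away from the kink, p = 1 and p = 2
  for (p in c(1, 2)) {
    spec <- property_spec(target_value = sum(w * z) + 1.3, p_norm = p)
    lg <- jtprop:::property_loss_grad(z, spec, model)
    h <- 1e-5
    fd <- vapply(1:4, function(i) {
      e <- rep(0, length(z)); e[i] <- h
      (property_loss(z + e, spec, model) - property_loss(z - e, spec, model)) / (2 * h)
    }, numeric(1))
    expect_equal(lg$grad[1:4], fd, tolerance = 1e-5)
  }
})

test_that("gradient descent stops immediately at a converged start and is inert at lr 0", {
  base <- untrained_model()
  set.seed(42)
  w <- rnorm(base$reg_cfg$input_dim)
  model <- linear_regressor_model(w, base)
  z0 <- rnorm(length(w))

  cfg <- opt_config(sum(w * z0), lr = 0.1, max_iterations = 50L,
                    tolerance = 1e-3)
  res <- optimize_A(z0, cfg, model)
  expect_identical(res$z, z0)
  expect_equal(nrow(res$trace), 1L)
  expect_equal(attr(res$trace, "status"), "converged")

  cfg0 <- opt_config(sum(w * z0) + 5, lr = 0, max_iterations = 5L,
                     tolerance = 1e-6)
  res0 <- optimize_A(z0, cfg0, model)
  expect_identical(res0$z, z0)
  expect_equal(attr(res0$trace, "status"), "budget-exhausted")
})

test_that("algorithm B returns a decodable molecule whose trace predictions are consistent", {
  p <- desk_pipeline()
  model <- p$m1
  m <- p$train$molecule[[1L]]
  z0 <- encode(m, model)$z
  cfg <- opt_config(p$train$value[1L], lr = 0.05, max_iterations = 20L,
                    reencode_period = 5L, noise_scale = 0, seed = 2L)
  res <- optimize_B(z0, cfg, model)
  expect_s3_class(res$molecule, "jtprop_molecule")
  expect_true(all(res$trace$loss >= 0))
  expect_lte(nrow(res$trace), 2L * (cfg$max_iterations + 1L))
  # the trace plots without error
  expect_s3_class(ggplot2::autoplot(res$trace), "ggplot")
  # every recorded decoded point's prediction equals the regressor applied to
  # the re-encoded mean of that molecule
  dec_rows <- which(!is.na(res$trace$smiles))
  expect_gte(length(dec_rows), 1L)
  for (i in dec_rows) {
    zm <- encode(res$trace$smiles[i], model)$z
    expect_equal(res$trace$predicted[i], predict_property(zm, model),
                 tolerance = 1e-10)
  }
})

test_that("gaussian initialization is seeded with standard-normal moments", {
  cfg <- opt_config(0, seed = 9L)
  expect_identical(init_gaussian(16L, cfg), init_gaussian(16L, cfg))
  draws <- vapply(1:4000, function(i) {
    init_gaussian(4L, opt_config(0, seed = i))
  }, numeric(4))
  expect_true(all(abs(rowMeans(draws)) < 4 / sqrt(4000)))
  v <- apply(draws, 1L, stats::var)
  expect_true(all(abs(v - 1) < 0.1))
})

test_that("closest-by-value initialization picks the nearest value with stable ties", {
  cfg <- opt_config(-5.2, noise_scale = 0)
  ts <- tibble::tibble(latent = list(c(1, 0), c(0, 1)), value = c(-6, -5))
  expect_equal(init_ctv(ts, cfg), c(0, 1))
  cfg_tie <- opt_config(-5.5, noise_scale = 0)
  expect_equal(init_ctv(ts, cfg_tie), c(1, 0))  # equidistant: lowest index
  expect_identical(init_ctv(ts, cfg), init_ctv(ts, cfg))
  expect_error(init_ctv(ts[0, ], cfg), "non-empty")
  # with noise_scale 1 the perturbation is seeded and nonzero
  cfg_n <- opt_config(-5.2, noise_scale = 1, seed = 3L)
  n1 <- init_ctv(ts, cfg_n)
  expect_identical(n1, init_ctv(ts, cfg_n))
  expect_false(identical(n1, c(0, 1)))
})

test_that("closest-by-hidden-vector initialization minimizes latent distance", {
  p <- desk_pipeline()
  model <- p$m1
  train <- p$train
  ts <- tibble::tibble(
    latent = lapply(train$smiles, function(s) encode(s, model)$z),
    value = train$value)
  cfg <- opt_config(0, noise_scale = 0)
  # a training molecule's own embedding is at distance 0
  expect_equal(init_chv(train$molecule[[4L]], ts, model, cfg),
               as.numeric(ts$latent[[4L]]))
  # the choice agrees with an independent distance computation
  q <- parse_smiles("CCO")
  zq <- encode(q, model)$z
  d2 <- vapply(ts$latent, function(zi) sum((zi - zq)^2), numeric(1))
  expect_equal(init_chv(q, ts, model, cfg),
               as.numeric(ts$latent[[which.min(d2)]]))
  expect_error(init_chv(q, ts[0, ], model, cfg), "non-empty")
})

test_that("guided recovery reports a rate within range on a small subset", {
  p <- desk_pipeline()
  model <- p$m1
  sub <- p$train[1:3, ]
  ts <- tibble::tibble(
    latent = lapply(p$train$smiles, function(s) encode(s, model)$z),
    value = p$train$value)
  cfg <- opt_config(0, lr = 0.05, max_iterations = 20L, reencode_period = 5L,
                    noise_scale = 0, seed = 1L)
  rate <- guided_recovery_rate(sub, model, init_mode = "chv", algorithm = "B",
                               cfg = cfg, train_set = ts)
  expect_gte(rate, 0)
  expect_lte(rate, 100)
})
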