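test_that("training is seed-reproducible and phase 2 with zero KL equals phase 1", {
  train <- utils::head(desk_fixtures()$sp$train$molecule, 6L)
  model <- untrained_model()
  cfg <- train_config(epochs_phase1 = 2L, epochs_phase2 = 0L, lr = 2e-3,
                      seed = 5L)
  a <- train_vae(train, model, cfg)
  b <- train_vae(train, model, cfg)
  expect_identical(a$params, b$params)
  expect_identical(utils::tail(a$history$vae$loss, 1L),
                   utils::tail(b$history$vae$loss, 1L))

  # with kl_beta = 0, a phase-2 epoch applies exactly the phase-1 update rule
  cfg12 <- train_config(epochs_phase1 = 1L, epochs_phase2 = 1L, kl_beta = 0,
                        lr = 2e-3, seed = 5L)
  cfg20 <- train_config(epochs_phase1 = 2L, epochs_phase2 = 0L, kl_beta = 0,
                        lr = 2e-3, seed = 5L)
  expect_identical(train_vae(train, model, cfg12)$params,
                   train_vae(train, model, cfg20)$params)
})

test_that("out-of-vocabulary molecules fail before training starts", {
  model <- jtprop_model(build_vocabulary("CCO"), seed = 1L)
  expect_error(train_vae(list(parse_smiles("CCN")), model,
                         train_config(epochs_phase1 = 1L, epochs_phase2 = 0L)),
               "not in the vocabulary")
})

test_that("teacher-forced reconstruction loss decreases over training", {
  p <- desk_pipeline()
  h <- p$vae$history$vae
  expect_lt(utils::tail(h$loss, 1L), h$loss[1L])
  expect_lt(h$loss[min(30L, nrow(h))], h$loss[1L])
})

test_that("chemical validity handles mixed valid and invalid input", {
  expect_equal(chemical_validity(c("CC", "CCO")), 100)
  expect_equal(chemical_validity(c("CC", "C(C)(C)(C)(C)C")), 50)
  expect_equal(chemical_validity(c("CC", "C1CC", "xx", "CCO")), 50)
  expect_error(chemical_validity(character(0)), "empty")
})

test_that("reconstruction accuracy counts exact canonical matches", {
  p <- desk_pipeline()
  expect_error(reconstruction_accuracy(p$vae, list()), "empty")
  # out-of-vocabulary molecules count as failures
  expect_message(
    acc <- reconstruction_accuracy(p$vae, list(parse_smiles("C=C"))),
    "out-of-vocabulary")
  expect_equal(acc, 0)
})

test_that("splits are disjoint, exhaustive and reproducible", {
  d <- tibble::tibble(smiles = sprintf("m%03d", 1:100))
  sp1 <- make_splits(d, split_spec(validation_count = 10L, test_count = 20L,
                                   seed = 3L))
  sp2 <- make_splits(d, split_spec(validation_count = 10L, test_count = 20L,
                                   seed = 3L))
  expect_equal(nrow(sp1$train), 70L)
  expect_equal(nrow(sp1$validation), 10L)
  expect_equal(nrow(sp1$test), 20L)
  all_ids <- sort(c(sp1$train$smiles, sp1$validation$smiles, sp1$test$smiles))
  expect_equal(all_ids, sort(d$smiles))
  expect_length(intersect(sp1$train$smiles, sp1$test$smiles), 0L)
  expect_length(intersect(sp1$validation$smiles, sp1$test$smiles), 0L)
  expect_identical(sp1$test$smiles, sp2$test$smiles)
  expect_error(make_splits(d, split_spec(60L, 60L)), "held-out")
})

test_that("checkpoints round-trip and reject mismatched configurations", {
  model <- untrained_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path, expected_cfg = model$enc_cfg)
  expect_identical(back$params, model$params)
  expect_error(load_checkpoint(path, expected_cfg = encoder_config()),
               "different encoder configuration")
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(version = "other"), bad)
  expect_error(load_checkpoint(bad), "unsupported version")
})
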