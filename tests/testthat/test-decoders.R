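test_that("tree generation is deterministic and honors the node budget", {
  model <- untrained_model()
  set.seed(21)
  z <- rnorm(model$dec_cfg$input_dim)
  d1 <- suppressWarnings(decode_tree(z, model))
  d2 <- suppressWarnings(decode_tree(z, model))
  expect_identical(d1$tree$labels, d2$tree$labels)
  expect_identical(d1$tree$edges, d2$tree$edges)

  one <- suppressWarnings(decode_tree(z, model, max_nodes = 1L))
  expect_length(one$tree$labels, 1L)
  expect_equal(nrow(one$tree$edges), 0L)
})

test_that("hitting the node budget raises a truncation condition carrying the partial tree", {
  model <- untrained_model()
  # force the topological head to always expand
  model$params$dt_wt1[] <- 0; model$params$dt_wt2[] <- 0
  model$params$dt_bt2[] <- 10
  w <- tryCatch(
    decode_tree(rep(0, model$dec_cfg$input_dim), model, max_nodes = 3L),
    warning = function(w) w)
  expect_s3_class(w, "jtprop_truncation")
  expect_length(w$partial_tree$labels, 3L)
})

test_that("single-node trees assemble to their own fragment", {
  model <- untrained_model()
  i <- match("CC", model$vocabulary$fragments)
  tree <- structure(list(labels = i, fragments = "CC",
                         edges = matrix(integer(0), 0L, 2L)),
                    class = "jtprop_dectree")
  m <- assemble_graph(tree, rep(0, model$dec_cfg$input_dim), model)
  expect_equal(m$smiles, "CC")
})

test_that("attachment enumeration matches brute-force expectations", {
  model <- untrained_model()
  frag_cc <- parse_smiles("CC")
  frag_co <- parse_smiles("CO")
  state <- list(atoms = frag_cc$atoms[, c("element", "charge")],
                bonds = frag_cc$bonds)
  # CC + CO sharing one atom: only the two C-on-C merges are chemically
  # possible (the O end cannot merge onto a carbon)
  cands <- jtprop:::attach_candidates(state, 1:2, frag_co)
  expect_length(cands, 2L)
  merged_state_atoms <- sort(vapply(cands, unname, integer(1)))
  expect_equal(merged_state_atoms, c(1L, 2L))
  expect_true(all(vapply(cands, function(cd) {
    frag_co$atoms$element[as.integer(names(cd))] == "C"
  }, logical(1))))

  # cyclopentane + cyclopropane: 15 spiro merges (5 x 3 C-C atom pairs) and
  # 30 fused-bond merges (5 x 3 bond pairs x 2 orientations), all valid
  ring5 <- parse_smiles("C1CCCC1")
  ring3 <- parse_smiles("C1CC1")
  state5 <- list(atoms = ring5$atoms[, c("element", "charge")],
                 bonds = ring5$bonds)
  cands2 <- jtprop:::attach_candidates(state5, 1:5, ring3)
  expect_length(cands2, 45L)
  expect_equal(sum(vapply(cands2, length, integer(1)) == 1L), 15L)
  expect_equal(sum(vapply(cands2, length, integer(1)) == 2L), 30L)
})

test_that("assembly supervision finds a correct candidate for every fixture edge", {
  model <- untrained_model()
  train <- desk_fixtures()$sp$train
  caches <- jtprop:::prepare_training_set(utils::head(train$molecule, 8L),
                                          model)
  expect_length(caches, 8L)
  # teacher-forced reconstruction of the true tree always has >= 1 correct
  # candidate at every scored step (asserted inside assembly_teacher_steps)
  for (cache in caches) {
    for (st in cache$asteps) expect_gte(length(st$correct), 1L)
  }
})

test_that("decoding always yields valid molecules, even under random weights", {
  model <- untrained_model()
  set.seed(31)
  for (i in 1:25) {
    m <- decode(rnorm(model$dec_cfg$input_dim), model)
    expect_s3_class(m, "jtprop_molecule")
    # construction re-parses through the sanitizer, so this cannot fail
    expect_length(jtprop:::valence_violations(m$atoms, m$bonds), 0L)
  }
  m0 <- decode(rep(0, model$dec_cfg$input_dim), model)
  expect_s3_class(m0, "jtprop_molecule")
})

test_that("decoding is a deterministic function of the latent vector", {
  model <- untrained_model()
  set.seed(32)
  z <- rnorm(model$dec_cfg$input_dim)
  expect_identical(decode(z, model)$smiles, decode(z, model)$smiles)
})

test_that("an impossible attachment errors directly but is skipped inside decode", {
  # two F-F fragments can never share an atom (fluorine is monovalent), so a
  # 2-node tree of them has no valid attachment
  v <- build_vocabulary("FF")
  model <- jtprop_model(v, seed = 1L)
  tree <- structure(list(labels = c(1L, 1L), fragments = c("FF", "FF"),
                         edges = matrix(c(1L, 2L), 1L)),
                    class = "jtprop_dectree")
  z0 <- rep(0, model$dec_cfg$input_dim)
  err <- tryCatch(assemble_graph(tree, z0, model, on_failure = "error"),
                  error = function(e) e)
  expect_s3_class(err, "jtprop_assembly_error")
  expect_false(is.null(err$partial))
  # skip mode drops the unattachable subtree and still returns a valid molecule
  m <- assemble_graph(tree, z0, model, on_failure = "skip")
  expect_equal(m$smiles, "FF")
})
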