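test_that("parse_smiles builds sanitized molecules and rejects invalid input", {
  m <- parse_smiles("CC")
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(nrow(m$bonds), 1L)

  # the showcased two-ring molecule: 9 heavy atoms, 2 rings
  m2 <- parse_smiles("CC1C(O)CC1C1CC1")
  expect_equal(nrow(m2$atoms), 9L)
  expect_equal(jtprop:::ring_count(m2), 2L)

  expect_error(parse_smiles("C1CC"), "cannot parse")
  expect_error(parse_smiles(""), "non-empty")
  expect_error(parse_smiles("C(C)(C)(C)(C)C"), "valence violation")
  expect_error(parse_smiles("CC.CC"), "disconnected")
})

test_that("canonicalization is spelling-invariant, idempotent and stereo-free", {
  expect_identical(canonical_smiles("OCC"), canonical_smiles("CCO"))
  expect_identical(canonical_smiles("C(O)C"), canonical_smiles("CCO"))
  for (s in c("CCO", "CC1C(O)CC1C1CC1", "c1ccccc1", "CC(N)C(=O)O")) {
    can <- canonical_smiles(s)
    expect_identical(canonical_smiles(can), can)
  }
  # aromatic spelling and its kekulized spelling map to one string
  expect_identical(canonical_smiles("c1c2ccccc2co1"),
                   canonical_smiles("C1=C2C=CC=CC2=CO1"))
  # stereo and isotope annotations are stripped on parse
  expect_identical(canonical_smiles("C[C@@H](N)C(=O)O"),
                   canonical_smiles("CC(N)C(=O)O"))
  expect_identical(canonical_smiles("F/C=C/F"), canonical_smiles("FC=CF"))
  expect_identical(canonical_smiles("[13CH4]"), canonical_smiles("C"))
  # formal charges are kept
  expect_match(canonical_smiles("CC(=O)[O-]"), "O-", fixed = TRUE)
})

test_that("tree decomposition covers the molecule with a connected acyclic cluster tree", {
  t1 <- tree_decompose(parse_smiles("CC"))
  expect_length(t1$nodes, 1L)
  expect_equal(t1$nodes[[1L]]$kind, "bond")
  expect_equal(nrow(t1$edges), 0L)

  t2 <- tree_decompose(parse_smiles("c1ccccc1"))
  expect_length(t2$nodes, 1L)
  expect_equal(t2$nodes[[1L]]$kind, "ring")

  # 5 clusters: one 4-ring, one 3-ring, three non-ring bonds; 4 tree edges
  m <- parse_smiles("CC1C(O)CC1C1CC1")
  t3 <- tree_decompose(m)
  expect_length(t3$nodes, 5L)
  expect_equal(nrow(t3$edges), 4L)
  kinds <- vapply(t3$nodes, `[[`, character(1), "kind")
  expect_equal(sort(kinds), c("bond", "bond", "bond", "ring", "ring"))
  ring_sizes <- sort(vapply(t3$nodes[kinds == "ring"],
                            function(cl) length(cl$atom_ids), integer(1)))
  expect_equal(ring_sizes, c(3L, 4L))
  frags <- sort(vapply(t3$nodes, `[[`, character(1), "fragment"))
  expect_equal(frags, c("C1CC1", "C1CCC1", "CC", "CC", "CO"))
  expect_valid_jtree(t3, m)

  # atoms on >= 3 clusters get a single-atom junction cluster
  t4 <- tree_decompose(parse_smiles("CC(C)(C)C"))
  expect_equal(sort(vapply(t4$nodes, `[[`, character(1), "kind")),
               c("atom", rep("bond", 4L)))
})

test_that("decomposition invariants hold across the fixture set", {
  d <- desk_fixtures()
  for (m in d$fx$molecule) {
    expect_valid_jtree(tree_decompose(m), m)
  }
})

test_that("decomposition is invariant under input renumbering", {
  pairs <- list(c("CC1C(O)CC1C1CC1", "OC1CC(C2CC2)C1C"),
                c("CCO", "OCC"),
                c("CC1(C)CC1", "C1C(C)(C)C1"))
  for (p in pairs) {
    # the two spellings really are one molecule ...
    expect_identical(canonical_smiles(p[1L]), canonical_smiles(p[2L]))
    t1 <- tree_decompose(parse_smiles(p[1L]))
    t2 <- tree_decompose(parse_smiles(p[2L]))
    # ... and give isomorphic trees with identical fragment multisets
    expect_equal(sort(vapply(t1$nodes, `[[`, character(1), "fragment")),
                 sort(vapply(t2$nodes, `[[`, character(1), "fragment")))
    expect_equal(nrow(t1$edges), nrow(t2$edges))
  }
})

test_that("ring perception agrees with an independent toolkit on fixtures", {
  smiles <- utils::head(desk_fixtures()$fx$smiles, 10L)
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "for s in sys.argv[1:]:",
    "    m = Chem.MolFromSmiles(s)",
    "    print(m.GetRingInfo().NumRings())",
    sep = "\n")
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script), shQuote(smiles)),
            stdout = TRUE, stderr = FALSE))
  expect_equal(as.integer(out),
               vapply(smiles,
                      function(s) jtprop:::ring_count(parse_smiles(s)),
                      integer(1), USE.NAMES = FALSE))
})

test_that("vocabulary construction is deterministic and order-independent", {
  v <- build_vocabulary(c("CCO", "CCC"))
  expect_equal(v$fragments, c("CC", "CO"))
  expect_warning(v0 <- build_vocabulary(list()), "empty")
  expect_length(v0, 0L)

  d <- desk_fixtures()
  set.seed(4)
  perm <- sample(nrow(d$fx))
  v1 <- build_vocabulary(d$fx$molecule)
  v2 <- build_vocabulary(d$fx$molecule[perm])
  expect_identical(v1$fragments, v2$fragments)
})

test_that("vocabulary coverage and out-of-vocabulary errors behave as specified", {
  m <- parse_smiles("CCO")
  v <- build_vocabulary(list(m))
  expect_true(vocabulary_coverage(v, m))
  expect_false(vocabulary_coverage(build_vocabulary("CC"), parse_smiles("CO")))
  expect_error(jtprop:::vocab_index(v, "C1CCCCC1"), "out-of-vocabulary")

  # vocabulary built on the train split covers validation and test
  d <- desk_fixtures()
  v <- desk_vocab()
  held <- c(d$sp$validation$molecule, d$sp$test$molecule)
  expect_true(all(vapply(held, function(m) vocabulary_coverage(v, m),
                         logical(1))))
})

test_that("vocabulary and .smi files round-trip exactly", {
  v <- desk_vocab()
  path <- withr::local_tempfile(fileext = ".txt")
  write_vocabulary(v, path)
  expect_identical(read_vocabulary(path)$fragments, v$fragments)

  smi <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("# a comment", "CCO mol1", "", "CC mol2"), smi)
  tab <- read_smi(smi)
  expect_equal(tab$smiles, c("CCO", "CC"))
  expect_equal(tab$id, c("mol1", "mol2"))
})
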