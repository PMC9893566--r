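# Synthetic desk-scale fixtures: small valid molecules assembled from a
# closed fragment pool (rings of size 3-6 and single bonds over C, N, O, F,
# mirroring the composition of small-organic benchmark sets with up to nine
# heavy atoms), plus a deterministic composition/topology surrogate property
# standing in for DFT-computed HOMO energies. The pool is closed under
# junction-tree decomposition, so vocabularies built on one split cover the
# others.

.fixture_ring_pool <- c("C1CC1", "C1OC1", "C1CCC1", "C1CCCC1", "C1CCOC1",
                        "C1CCNC1", "C1CCCCC1")
.fixture_bond_pool <- c("CC", "CO", "CN", "CF")

#' Fixture-generation specification
#'
#' @param n_molecules Number of distinct molecules to generate.
#' @param max_heavy_atoms Heavy-atom cap (default 9).
#' @param a_C,a_O,a_N,a_ring,intercept Surrogate-property coefficients:
#'   value = intercept + a_C*nC + a_O*nO + a_N*nN + a_ring*nRings + noise.
#' @param noise_sd Gaussian noise standard deviation (surrogate units).
#' @param seed RNG seed.
#' @return A `jtprop_fixture_spec`.
#' @export
fixture_spec <- function(n_molecules = 40L, max_heavy_atoms = 9L,
                         a_C = 0.05, a_O = -0.1, a_N = 0.07, a_ring = -0.2,
                         intercept = -6.0, noise_sd = 0.01, seed = 1L) {
  stopifnot(n_molecules >= 1L, max_heavy_atoms >= 2L, noise_sd >= 0)
  structure(list(n_molecules = as.integer(n_molecules),
                 max_heavy_atoms = as.integer(max_heavy_atoms),
                 a_C = a_C, a_O = a_O, a_N = a_N, a_ring = a_ring,
                 intercept = intercept, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "jtprop_fixture_spec")
}

surrogate_property <- function(m, spec, noise = 0) {
  counts <- table(m$atoms$element)
  cnt <- function(el) if (el %in% names(counts)) counts[[el]] else 0L
  spec$intercept + spec$a_C * cnt("C") + spec$a_O * cnt("O") +
    spec$a_N * cnt("N") + spec$a_ring * ring_count(m) + noise
}

# Random growth of one molecule in graph space: start from a pool fragment,
# then repeatedly merge bond or ring fragments at atoms with free valence.
grow_fixture_molecule <- function(spec, frag_graphs) {
  rng <- seq(min(3L, spec$max_heavy_atoms), spec$max_heavy_atoms)
  target <- rng[sample.int(length(rng), 1L)]
  sizes <- vapply(frag_graphs, function(f) nrow(f$atoms), integer(1))
  ok0 <- which(sizes <= target)
  f0 <- frag_graphs[[ok0[sample.int(length(ok0), 1L)]]]
  atoms <- f0$atoms[, c("element", "charge")]
  bonds <- f0$bonds
  repeat {
    n <- nrow(atoms)
    if (n >= target || stats::runif(1) < 0.2) break
    free <- allowed_valence(atoms$element, atoms$charge) -
      explicit_valence(atoms, bonds)
    room <- spec$max_heavy_atoms - n
    choices <- which((sizes - 1L) <= room)
    if (!length(choices)) break
    f <- frag_graphs[[choices[sample.int(length(choices), 1L)]]]
    # merge a random fragment atom with matching element onto a random site
    fev <- explicit_valence(f$atoms, f$bonds)
    cand <- list()
    for (a in seq_len(n)) {
      for (b in seq_len(nrow(f$atoms))) {
        if (atoms$element[a] == f$atoms$element[b] &&
            free[a] >= fev[b]) {
          cand[[length(cand) + 1L]] <- c(a, b)
        }
      }
    }
    if (!length(cand)) break
    pick <- cand[[sample(length(cand), 1L)]]
    app <- apply_candidate(list(atoms = atoms, bonds = bonds), f,
                           stats::setNames(pick[1L], pick[2L]))
    atoms <- app$state$atoms
    bonds <- app$state$bonds
  }
  list(atoms = atoms, bonds = bonds)
}

#' Generate a synthetic fixture set
#'
#' Deterministic under the seed: molecules are grown by random fragment
#' assembly (rejection-sampling chemically invalid combinations), deduplicated
#' by canonical SMILES, and annotated with the surrogate property.
#'
#' @param spec A `jtprop_fixture_spec`.
#' @return A tibble with columns `smiles`, `value`, and list-column
#'   `molecule`.
#' @export
generate_fixture_set <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "jtprop_fixture_spec"))
  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(spec$seed)
  frag_graphs <- lapply(c(.fixture_ring_pool, .fixture_bond_pool), parse_smiles)
  seen <- character(0)
  out <- list()
  attempts <- 0L
  max_attempts <- 60L * spec$n_molecules
  while (length(out) < spec$n_molecules && attempts < max_attempts) {
    attempts <- attempts + 1L
    g <- grow_fixture_molecule(spec, frag_graphs)
    m <- tryCatch(molecule_from_tables(g$atoms, g$bonds),
                  error = function(e) NULL)
    if (is.null(m) || m$smiles %in% seen) next
    seen <- c(seen, m$smiles)
    noise <- if (spec$noise_sd > 0) stats::rnorm(1, 0, spec$noise_sd) else 0
    out[[length(out) + 1L]] <- list(m = m, v = surrogate_property(m, spec, noise))
  }
  if (length(out) < spec$n_molecules) {
    stop(sprintf("could only generate %d of %d distinct molecules within the attempt budget",
                 length(out), spec$n_molecules), call. = FALSE)
  }
  tibble::tibble(
    smiles = vapply(out, function(x) x$m$smiles, character(1)),
    value = vapply(out, function(x) x$v, numeric(1)),
    molecule = lapply(out, function(x) x$m)
  )
}

#' Split specification and dataset splitting
#'
#' Disjoint, exhaustive, seed-reproducible train/validation/test splits.
#' Full-scale defaults hold out 2500 validation and 5000 test molecules.
#'
#' @param validation_count,test_count Held-out sizes.
#' @param seed RNG seed.
#' @rdname splits
#' @export
split_spec <- function(validation_count = 2500L, test_count = 5000L,
                       seed = 1L) {
  structure(list(validation_count = as.integer(validation_count),
                 test_count = as.integer(test_count),
                 seed = as.integer(seed)),
            class = "jtprop_split_spec")
}

#' @param dataset A data frame (one molecule per row).
#' @param spec A `jtprop_split_spec`.
#' @return A list of tibbles `train`, `validation`, `test`.
#' @rdname splits
#' @export
make_splits <- function(dataset, spec = split_spec()) {
  n <- nrow(dataset)
  held <- spec$validation_count + spec$test_count
  if (held > n) {
    stop(sprintf("requested %d held-out molecules but the dataset has %d",
                 held, n), call. = FALSE)
  }
  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(spec$seed)
  perm <- sample.int(n)
  val_idx <- perm[seq_len(spec$validation_count)]
  test_idx <- perm[spec$validation_count + seq_len(spec$test_count)]
  train_idx <- sort(setdiff(perm, c(val_idx, test_idx)))
  list(train = dataset[train_idx, , drop = FALSE],
       validation = dataset[sort(val_idx), , drop = FALSE],
       test = dataset[sort(test_idx), , drop = FALSE])
}
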