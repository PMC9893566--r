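#' Parse a SMILES string into a sanitized molecule
#'
#' Parses one SMILES string, strips stereochemistry and isotope annotations,
#' canonicalizes it (OpenBabel canonical SMILES with aromaticity perception),
#' and builds a kekulized heavy-atom graph. Atom order in the returned graph
#' follows the canonical SMILES, so every downstream computation (junction-tree
#' decomposition, encoding) is invariant to how the input molecule was written.
#' Molecules violating standard valence rules are rejected.
#'
#' @param s A single non-empty SMILES string.
#' @return An object of class `jtprop_molecule`: a list with `atoms` (tibble of
#'   `element`, `charge`, `degree`, `aromatic`), `bonds` (tibble of `a1`, `a2`,
#'   `order`, kekulized), and `smiles` (the canonical SMILES).
#' @examples
#' m <- parse_smiles("OCC")
#' m$smiles           # same as parse_smiles("CCO")$smiles
#' nrow(m$atoms)      # 3 heavy atoms
#' @export
parse_smiles <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(trimws(s))) {
    stop("SMILES input must be a single non-empty string", call. = FALSE)
  }
  s <- trimws(s)
  plain <- strip_stereo_isotopes(s)
  can <- ob_canonical(plain)
  if (is.na(can)) {
    stop(sprintf("cannot parse SMILES '%s': not a valid molecule", s),
         call. = FALSE)
  }
  if (grepl(".", can, fixed = TRUE)) {
    stop(sprintf("SMILES '%s' has multiple disconnected fragments; only single connected molecules are supported", s),
         call. = FALSE)
  }
  block <- ob_smiles_to_molblocks(can)
  if (is.na(block)) {
    stop(sprintf("cannot build structure for SMILES '%s'", s), call. = FALSE)
  }
  g <- parse_molblock(block)
  molecule_from_tables(g$atoms, g$bonds, smiles = can, input = s)
}

# Assemble a jtprop_molecule from atom/bond tables. When `smiles` is NULL the
# canonical SMILES is computed from the graph. Valence is always checked.
molecule_from_tables <- function(atoms, bonds, smiles = NULL, input = NULL) {
  if (is.null(smiles)) {
    can <- ob_molblocks_to_cansmi(build_molblock(atoms, bonds))
    if (is.na(can)) stop("cannot canonicalize assembled molecule", call. = FALSE)
    # re-parse from canonical form so atom order is canonical
    return(parse_smiles(can))
  }
  bad <- valence_violations(atoms, bonds)
  if (length(bad)) {
    lab <- if (is.null(input)) smiles else input
    stop(sprintf("valence violation in '%s' at atom(s) %s (%s)", lab,
                 paste(bad, collapse = ", "),
                 paste(atoms$element[bad], collapse = ", ")),
         call. = FALSE)
  }
  deg <- tabulate(c(bonds$a1, bonds$a2), nbins = nrow(atoms))
  atoms$degree <- deg
  atoms$aromatic <- smiles_aromatic_flags(smiles, atoms$element)
  m <- list(atoms = atoms, bonds = bonds, smiles = smiles)
  class(m) <- "jtprop_molecule"
  m
}

#' Canonical SMILES of a molecule
#'
#' Deterministic and idempotent: canonicalizing a canonical string returns it
#' unchanged, and any two spellings of the same molecule map to one string.
#'
#' @param m A `jtprop_molecule` or a SMILES string.
#' @return A canonical SMILES string.
#' @export
canonical_smiles <- function(m) {
  if (inherits(m, "jtprop_molecule")) return(m$smiles)
  parse_smiles(m)$smiles
}

#' @export
print.jtprop_molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s  (%d heavy atoms, %d bonds, %d ring(s))\n",
              x$smiles, nrow(x$atoms), nrow(x$bonds), ring_count(x)))
  invisible(x)
}

# --- valence -----------------------------------------------------------------

.base_valence <- c(B = 3, C = 4, N = 3, O = 2, F = 1, P = 5, S = 6,
                   Cl = 1, Br = 1, I = 1, H = 1, Si = 4)

# Maximum allowed explicit valence (sum of bond orders) for an element with a
# formal charge. Positive charge raises N/O/P capacity; any charge on carbon
# lowers it; anions lose capacity.
allowed_valence <- function(element, charge) {
  v <- .base_valence[element]
  v[is.na(v)] <- 8  # unknown elements: permissive
  up <- element %in% c("N", "O", "P", "S", "F", "Cl", "Br", "I")
  v[up] <- v[up] + charge[up]
  isC <- element %in% c("C", "B", "Si")
  v[isC] <- v[isC] - abs(charge[isC])
  pmax(v, 0)
}

explicit_valence <- function(atoms, bonds) {
  v <- numeric(nrow(atoms))
  for (i in seq_len(nrow(bonds))) {
    v[bonds$a1[i]] <- v[bonds$a1[i]] + bonds$order[i]
    v[bonds$a2[i]] <- v[bonds$a2[i]] + bonds$order[i]
  }
  v
}

valence_violations <- function(atoms, bonds) {
  which(explicit_valence(atoms, bonds) >
          allowed_valence(atoms$element, atoms$charge))
}

# --- aromaticity flags -------------------------------------------------------

# Per-atom aromatic flags read off the canonical SMILES text. The tokenizer
# walks the string in atom order, which matches the MOL-block atom order of the
# same string; if the element sequences disagree the flags fall back to FALSE.
smiles_aromatic_flags <- function(smiles, elements) {
  n <- length(elements)
  flags <- logical(n)
  toks <- smiles_atom_tokens(smiles)
  if (length(toks$element) == n &&
      all(toupper(toks$element) == toupper(elements))) {
    flags <- toks$aromatic
  }
  flags
}

smiles_atom_tokens <- function(s) {
  chars <- strsplit(s, "")[[1]]
  element <- character(0); aromatic <- logical(0)
  i <- 1L
  two_letter <- c("Cl", "Br", "Si")
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      body <- sub("^[0-9]*", "", body)
      el <- regmatches(body, regexpr("^[A-Za-z][a-z]?", body))
      arom <- grepl("^[a-z]", el)
      # 'Cl'/'Br' are two-letter; lone lowercase is aromatic organic
      if (nchar(el) == 2L && !(paste0(toupper(substr(el, 1, 1)), substr(el, 2, 2)) %in% two_letter)) {
        el <- substr(el, 1L, 1L)
      }
      element <- c(element, paste0(toupper(substr(el, 1, 1)), substring(el, 2)))
      aromatic <- c(aromatic, arom)
      i <- j + 1L
    } else if (ch %in% c("C", "N", "O", "P", "S", "F", "B", "I")) {
      nxt <- if (i < length(chars)) chars[i + 1L] else ""
      if (ch == "C" && nxt == "l") { element <- c(element, "Cl"); i <- i + 1L }
      else if (ch == "B" && nxt == "r") { element <- c(element, "Br"); i <- i + 1L }
      else element <- c(element, ch)
      aromatic <- c(aromatic, FALSE)
      i <- i + 1L
    } else if (ch %in% c("c", "n", "o", "p", "s", "b")) {
      element <- c(element, toupper(ch))
      aromatic <- c(aromatic, TRUE)
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  list(element = element, aromatic = aromatic)
}
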