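# OpenBabel bridge (via ChemmineOB). All SMILES canonicalization and
# SMILES <-> MOL-block conversion goes through here; the rest of the package
# works on plain atom/bond tables.

# Strip stereochemistry and isotope annotations from a SMILES string, textually.
# Bracket atoms keep their explicit hydrogen counts, so removing '@' markers
# preserves the constitution; '/' and '\' become plain single bonds; leading
# digits inside brackets (isotopes) are dropped.
strip_stereo_isotopes <- function(s) {
  s <- gsub("[/\\\\]", "", s)
  s <- gsub("@{1,2}(TH|AL|SP|TB|OH)?[0-9]*", "", s)
  s <- gsub("\\[[0-9]+", "[", s)
  s
}

ob_convert <- function(from, to, source) {
  out <- tryCatch(
    ChemmineOB::convertFormat(from = from, to = to, source = source),
    error = function(e) ""
  )
  out
}

# Canonical SMILES for a character vector. Valid inputs are converted in one
# batch keyed by synthetic titles; any molecule OpenBabel rejects comes back NA
# (a rejected line aborts the remainder of a batch, so stragglers are retried
# one by one).
ob_canonical <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  titles <- paste0("jt", seq_len(n))
  src <- paste(paste(smiles, titles), collapse = "\n")
  out <- ob_convert("SMI", "CAN", src)
  res <- rep(NA_character_, n)
  if (nzchar(out)) {
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (p in parts) {
      if (length(p) >= 2L) {
        idx <- match(trimws(p[2L]), titles)
        if (!is.na(idx)) res[idx] <- trimws(p[1L])
      }
    }
  }
  retry <- which(is.na(res) | !nzchar(res))
  for (i in retry) {
    out <- ob_convert("SMI", "CAN", paste(smiles[i], "jt1"))
    if (nzchar(out)) {
      val <- trimws(strsplit(out, "\t", fixed = TRUE)[[1]][1L])
      if (nzchar(val)) res[i] <- val
    }
  }
  res[!nzchar(res) | is.na(res)] <- NA_character_
  res
}

# Convert SMILES (assumed valid) to kekulized V2000 MOL blocks, one per input.
ob_smiles_to_molblocks <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  titles <- paste0("jt", seq_len(n))
  src <- paste(paste(smiles, titles), collapse = "\n")
  out <- ob_convert("SMI", "SDF", src)
  blocks <- strsplit(out, "\\$\\$\\$\\$\n?")[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  res <- rep(NA_character_, n)
  for (b in blocks) {
    title <- trimws(strsplit(b, "\n", fixed = TRUE)[[1]][1L])
    idx <- match(title, titles)
    if (!is.na(idx)) res[idx] <- b
  }
  res
}

# Canonical SMILES from V2000 MOL blocks built by the package.
ob_molblocks_to_cansmi <- function(blocks) {
  n <- length(blocks)
  if (n == 0L) return(character(0))
  src <- paste0(paste(blocks, collapse = "\n$$$$\n"), "\n$$$$\n")
  out <- ob_convert("SDF", "CAN", src)
  res <- rep(NA_character_, n)
  if (nzchar(out)) {
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (p in parts) {
      title <- if (length(p) >= 2L) trimws(p[2L]) else ""
      idx <- suppressWarnings(as.integer(sub("^jt", "", title)))
      if (!is.na(idx) && idx >= 1L && idx <= n) res[idx] <- trimws(p[1L])
    }
  }
  res
}

# Parse a V2000 MOL block into atom and bond tables (element, formal charge,
# bond order). Coordinates, stereo parity and isotope fields are ignored.
parse_molblock <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  counts <- lines[4L]
  natoms <- as.integer(substr(counts, 1L, 3L))
  nbonds <- as.integer(substr(counts, 4L, 6L))
  if (is.na(natoms) || is.na(nbonds)) stop("malformed MOL block", call. = FALSE)
  element <- character(natoms)
  charge <- integer(natoms)
  for (i in seq_len(natoms)) {
    element[i] <- trimws(substr(lines[4L + i], 32L, 34L))
  }
  a1 <- integer(nbonds); a2 <- integer(nbonds); order <- integer(nbonds)
  for (i in seq_len(nbonds)) {
    ln <- lines[4L + natoms + i]
    a1[i] <- as.integer(substr(ln, 1L, 3L))
    a2[i] <- as.integer(substr(ln, 4L, 6L))
    order[i] <- as.integer(substr(ln, 7L, 9L))
  }
  for (ln in lines[grepl("^M  CHG", lines)]) {
    fields <- as.integer(strsplit(trimws(substr(ln, 7L, nchar(ln))), "\\s+")[[1]])
    k <- fields[1L]
    for (j in seq_len(k)) {
      charge[fields[2L * j]] <- fields[2L * j + 1L]
    }
  }
  list(
    atoms = tibble::tibble(element = element, charge = charge),
    bonds = tibble::tibble(a1 = a1, a2 = a2, order = order)
  )
}

# Build a V2000 MOL block (zero coordinates) from atom/bond tables.
build_molblock <- function(atoms, bonds, title = "jt1") {
  n <- nrow(atoms); nb <- nrow(bonds)
  header <- c(title, " jtprop", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  atom_lines <- sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    atoms$element)
  bond_lines <- if (nb > 0L) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds$a1, bonds$a2, bonds$order)
  } else character(0)
  chg <- which(atoms$charge != 0L)
  chg_lines <- if (length(chg)) {
    sprintf("M  CHG  1 %3d %3d", chg, atoms$charge[chg])
  } else character(0)
  paste(c(header, atom_lines, bond_lines, chg_lines, "M  END"), collapse = "\n")
}
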