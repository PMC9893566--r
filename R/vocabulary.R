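#' Build a cluster-fragment vocabulary from a set of molecules
#'
#' Decomposes every molecule into its junction-tree clusters and collects the
#' unique canonical fragment SMILES, ordered lexicographically (C-locale radix
#' sort), so the result is independent of dataset order. The vocabulary indexes
#' the one-hot encoding of tree nodes.
#'
#' @param molecules A list of `jtprop_molecule` objects, a character vector of
#'   SMILES, or a list of pre-computed `jtprop_jtree` objects.
#' @return A `jtprop_vocabulary`: character vector of fragments with an index.
#' @examples
#' v <- build_vocabulary(c("CCO", "CCC"))
#' length(v)  # 2 fragments: CC and CO
#' @export
build_vocabulary <- function(molecules) {
  if (length(molecules) == 0L) {
    warning("empty dataset: building an empty vocabulary")
    return(new_vocabulary(character(0)))
  }
  frags <- unlist(lapply(molecules, function(m) {
    t <- if (inherits(m, "jtprop_jtree")) m else {
      if (is.character(m)) m <- parse_smiles(m)
      tree_decompose(m)
    }
    vapply(t$nodes, function(cl) cl$fragment, character(1))
  }))
  new_vocabulary(sort(unique(frags), method = "radix"))
}

new_vocabulary <- function(fragments) {
  stopifnot(!anyDuplicated(fragments))
  v <- list(fragments = fragments)
  class(v) <- "jtprop_vocabulary"
  v
}

#' @export
length.jtprop_vocabulary <- function(x) length(x$fragments)

#' @export
print.jtprop_vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d fragment(s)\n", length(x)))
  if (length(x)) cat(" ", paste(utils::head(x$fragments, 20L), collapse = " "),
                     if (length(x) > 20L) "..." else "", "\n")
  invisible(x)
}

vocab_index <- function(v, fragment) {
  i <- match(fragment, v$fragments)
  if (is.na(i)) {
    stop(sprintf("fragment '%s' is not in the vocabulary (out-of-vocabulary cluster)",
                 fragment), call. = FALSE)
  }
  i
}

#' Does a vocabulary cover a molecule?
#'
#' TRUE iff every junction-tree cluster fragment of the molecule is in the
#' vocabulary.
#'
#' @param v A `jtprop_vocabulary`.
#' @param m A `jtprop_molecule` (or SMILES string).
#' @return Logical scalar.
#' @export
vocabulary_coverage <- function(v, m) {
  if (is.character(m)) m <- parse_smiles(m)
  t <- if (inherits(m, "jtprop_jtree")) m else tree_decompose(m)
  all(vapply(t$nodes, function(cl) cl$fragment %in% v$fragments, logical(1)))
}

#' Read / write a vocabulary file
#'
#' One fragment SMILES per line; order is significant (it defines the one-hot
#' indices). `#`-prefixed lines are ignored on read.
#'
#' @param path File path.
#' @rdname vocabulary_io
#' @export
read_vocabulary <- function(path) {
  if (!file.exists(path)) stop(sprintf("vocabulary file '%s' not found", path),
                               call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  new_vocabulary(lines)
}

#' @param v A `jtprop_vocabulary`.
#' @rdname vocabulary_io
#' @export
write_vocabulary <- function(v, path) {
  writeLines(v$fragments, path)
  invisible(path)
}

#' Read a .smi file
#'
#' One SMILES per line with an optional whitespace-separated identifier;
#' `#`-prefixed comment lines are ignored.
#'
#' @param path File path.
#' @return A tibble with columns `smiles` and `id`.
#' @export
read_smi <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file '%s' not found", path),
                               call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\\s+")
  tibble::tibble(
    smiles = vapply(parts, `[`, character(1), 1L),
    id = vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_,
                character(1))
  )
}

#' @param smiles Character vector of SMILES (optionally named; names become ids).
#' @rdname read_smi
#' @export
write_smi <- function(smiles, path) {
  ids <- names(smiles)
  lines <- if (is.null(ids)) smiles else paste(smiles, ids)
  writeLines(lines, path)
  invisible(path)
}
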