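#' The canonical amino-acid alphabet
#'
#' The twenty standard amino acids in one-letter alphabetical order. This
#' fixed ordering is used everywhere in the package: logits and probability
#' matrix columns, position-frequency-matrix columns, and index-table rows.
#' A single convention prevents silent column-permutation bugs between the
#' design engine, the oracle, and the evaluation code.
#'
#' @format A character vector of length 20.
#' @export
aa_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Hydrophilic residue class
#'
#' The six hydrophilic amino acids (R, K, D, E, N, Q) as conventionally
#' coloured blue in sequence logos of designed binders.
#'
#' @format A character vector of length 6.
#' @export
aa_hydrophilic <- c("R", "K", "D", "E", "N", "Q")

# Split sequences into residue characters, validating against the canonical
# alphabet. Non-canonical codes (X, B, Z, U, lower case, gaps) are rejected
# with an error naming the offending sequence and position; they are never
# silently scored.
split_residues <- function(sequences, arg = "sequence") {
  if (!is.character(sequences) || length(sequences) < 1L) {
    abort(paste0("`", arg, "` must be a character vector of length >= 1."),
          class = "solpep_validation_error")
  }
  chars <- strsplit(sequences, "", fixed = TRUE)
  for (i in seq_along(chars)) {
    bad <- which(!chars[[i]] %in% aa_alphabet)
    if (length(bad) > 0L) {
      abort(sprintf(
        "Non-canonical residue '%s' at position %d of %s \"%s\".",
        chars[[i]][bad[1L]], bad[1L], arg, sequences[i]),
        class = "solpep_validation_error")
    }
    if (length(chars[[i]]) == 0L) {
      abort(sprintf("Empty %s at element %d.", arg, i),
            class = "solpep_validation_error")
    }
  }
  chars
}

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
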