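#' Initialize a soft sequence from seeded random logits
#'
#' A soft sequence relaxes a discrete peptide of length `length` into an
#' unconstrained logits matrix (`length` x 20, columns in the fixed
#' alphabetical residue order). Logits are drawn i.i.d. Normal(0, 0.01)
#' from a local RNG stream: identical `(length, seed)` pairs give bitwise
#' identical matrices and the caller's RNG state is untouched. The small
#' spread keeps the initial distributions near uniform so early gradients,
#' not the draw, dominate the optimization while the noise still breaks
#' ties between equally preferred residues in a seed-dependent way.
#'
#' @param length Binder length (positions), >= 1.
#' @param seed Integer seed.
#' @param temperature Initial softmax temperature (the soft-stage value).
#' @return An object of class `soft_seq`: list with `logits`,
#'   `temperature`, `mode` (`"soft"`, `"temp"` or `"hard"`), and, after
#'   [to_probs()], `probs` and `soft_probs`.
#' @export
init_logits <- function(length, seed, temperature = 1) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
      length < 1 || length != as.integer(length)) {
    abort("`length` must be a single integer >= 1.",
          class = "solpep_invalid_config")
  }
  n <- as.integer(length)
  logits <- with_local_seed(seed,
                            matrix(rnorm(n * 20L, mean = 0, sd = 0.01),
                                   nrow = n, ncol = 20L))
  colnames(logits) <- aa_alphabet
  new_soft_seq(logits, temperature = temperature, mode = "soft")
}

new_soft_seq <- function(logits, temperature, mode) {
  stopifnot(is.matrix(logits), ncol(logits) == 20L,
            mode %in% c("soft", "temp", "hard"),
            is.numeric(temperature), temperature > 0)
  structure(list(logits = logits, temperature = temperature, mode = mode,
                 probs = NULL, soft_probs = NULL),
            class = "soft_seq")
}

row_softmax <- function(m) {
  shifted <- m - apply(m, 1L, max)
  e <- exp(shifted)
  e / rowSums(e)
}

row_argmax <- function(m) apply(m, 1L, which.max)  # first max: alphabetical tie-break

#' Materialize per-position residue probabilities
#'
#' In `soft` and `temp` modes each row of `probs` is the softmax of the
#' corresponding logits row divided by the temperature. In `hard` mode each
#' row is exactly one-hot at the row argmax (ties broken toward the lowest
#' alphabetical index), while `soft_probs` retains the tempered softmax so
#' gradients can flow straight-through the discretization.
#'
#' @param s A `soft_seq`.
#' @return `s` with `probs` (and `soft_probs`) filled.
#' @export
to_probs <- function(s) {
  stopifnot(inherits(s, "soft_seq"))
  if (!all(is.finite(s$logits))) {
    abort("Non-finite logits; cannot compute probabilities.",
          class = "solpep_numeric_error")
  }
  soft <- row_softmax(s$logits / s$temperature)
  if (s$mode == "hard") {
    idx <- row_argmax(s$logits)
    hard <- matrix(0, nrow = nrow(s$logits), ncol = 20L,
                   dimnames = list(NULL, aa_alphabet))
    hard[cbind(seq_along(idx), idx)] <- 1
    s$probs <- hard
  } else {
    s$probs <- soft
  }
  s$soft_probs <- soft
  s
}

#' Decode a soft sequence to a residue string
#'
#' Takes the argmax residue of each logits row (ties to the lowest
#' alphabetical index).
#'
#' @param s A `soft_seq`.
#' @return A character scalar of length-`N` residues.
#' @export
decode_sequence <- function(s) {
  stopifnot(inherits(s, "soft_seq"))
  paste(aa_alphabet[row_argmax(s$logits)], collapse = "")
}

# One-hot encode a canonical residue string as an N x 20 probability matrix.
#' One-hot probability matrix for a discrete peptide
#'
#' @param sequence A canonical residue string.
#' @return An `N x 20` matrix with a single 1 per row, columns in the fixed
#'   alphabetical residue order.
#' @export
one_hot <- function(sequence) {
  chars <- split_residues(sequence)[[1L]]
  m <- matrix(0, nrow = length(chars), ncol = 20L,
              dimnames = list(NULL, aa_alphabet))
  m[cbind(seq_along(chars), match(chars, aa_alphabet))] <- 1
  m
}

# Wrap a fixed probability matrix as a hard-mode soft_seq whose logits give
# back the same argmax (used for scoring discrete sequences on the soft path).
soft_seq_from_probs <- function(probs, temperature = 1, mode = "soft") {
  s <- new_soft_seq(log(pmax(probs, 1e-12)), temperature = temperature,
                    mode = mode)
  s$probs <- probs
  s$soft_probs <- probs
  s
}

#' @export
print.soft_seq <- function(x, ...) {
  cat(sprintf("<soft_seq: %d positions, mode=%s, T=%g>\n",
              nrow(x$logits), x$mode, x$temperature))
  invisible(x)
}
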