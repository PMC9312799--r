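#' Score discrete peptides with an oriented solubility index
#'
#' The plain per-residue mean of the normalized, loss-oriented index values
#' over the sequence — the discrete form of [solubility_loss()], with which
#' it agrees exactly at one-hot probabilities.
#'
#' @param sequence Character vector of canonical residue strings.
#' @param table A normalized, loss-oriented `aa_index`.
#' @param type `"arithmetic"` (default) or `"geometric"` mean.
#' @return A numeric vector of scores in \[0, 1\].
#' @examples
#' score_sequence("ETFSDLWKLLPEN", solubility_index("hydropathy"))
#' @export
score_sequence <- function(sequence, table, type = c("arithmetic", "geometric")) {
  type <- match.arg(type)
  v <- index_values(table)
  chars <- split_residues(sequence)
  vapply(chars, function(ch) {
    vals <- v[ch]
    if (type == "arithmetic") mean(vals)
    else if (any(vals == 0)) 0 else exp(mean(log(vals)))
  }, numeric(1))
}

new_candidates <- function(sequence, origin,
                           seed = NA_integer_, weight = NA_real_,
                           index_name = NA_character_,
                           solubility_score = NA_real_,
                           affinity_score = NA_real_) {
  tibble::tibble(sequence = sequence,
                 origin = origin,
                 seed = as.integer(seed),
                 weight = as.numeric(weight),
                 index_name = index_name,
                 solubility_score = as.numeric(solubility_score),
                 affinity_score = as.numeric(affinity_score),
                 passed_filter = NA)
}

#' Generate uniform-random baseline peptides
#'
#' `n` sequences of the given length with residues drawn uniformly from the
#' 20-letter canonical alphabet; deterministic per seed, leaving the
#' caller's RNG untouched.
#'
#' @param n Number of sequences.
#' @param length Sequence length.
#' @param seed Integer seed.
#' @return A candidate tibble (columns `sequence`, `origin = "random"`,
#'   `seed`, score and verdict columns initialized to `NA`).
#' @export
gen_random_sequences <- function(n, length, seed) {
  if (n < 1 || length < 1) {
    abort("`n` and `length` must be >= 1.", class = "solpep_invalid_config")
  }
  draws <- with_local_seed(seed,
    matrix(sample(aa_alphabet, n * length, replace = TRUE), nrow = n))
  new_candidates(apply(draws, 1L, paste, collapse = ""),
                 origin = "random", seed = seed)
}

#' Enumerate all single-residue substitutions of a reference peptide
#'
#' Every sequence at Hamming distance exactly 1 from the reference: all 19
#' alternative residues at each position, position-major and alphabetical
#' within a position, excluding the reference itself. A length-`N`
#' reference yields `19 * N` unique variants (247 for the 13-residue p53
#' transactivation peptide).
#'
#' @param reference A canonical residue string.
#' @return A candidate tibble with `origin = "substitution"`.
#' @export
gen_single_substitutions <- function(reference) {
  chars <- split_residues(reference, arg = "reference")[[1L]]
  variants <- unlist(lapply(seq_along(chars), function(i) {
    vapply(setdiff(aa_alphabet, chars[i]), function(r) {
      mutated <- chars
      mutated[i] <- r
      paste(mutated, collapse = "")
    }, character(1))
  }), use.names = FALSE)
  new_candidates(variants, origin = "substitution")
}

#' Dual-threshold filtering of candidate peptides
#'
#' A candidate passes iff its solubility score is strictly greater than
#' `sol_threshold` AND its affinity score is strictly less than
#' `aff_threshold`. Affinity scores are binding free energies, so lower
#' (more negative) means stronger binding; records sitting exactly at a
#' threshold fail. The reference thresholds used in the original screen are
#' the logS and docking affinity of the PDIQ+'N' peptide (0.4420 and
#' -22.5).
#'
#' @param records A candidate tibble; every record must carry both scores.
#' @param sol_threshold Solubility (e.g. logS) threshold.
#' @param aff_threshold Affinity (binding free energy) threshold.
#' @param keep_all Return all records annotated with `passed_filter`
#'   instead of only the survivors.
#' @return Survivors in input order with `passed_filter = TRUE` (default),
#'   or every record with its verdict when `keep_all = TRUE`.
#' @export
filter_candidates <- function(records, sol_threshold, aff_threshold,
                              keep_all = FALSE) {
  needed <- c("sequence", "solubility_score", "affinity_score")
  if (!all(needed %in% names(records))) {
    abort("Records must have sequence, solubility_score and affinity_score columns.",
          class = "solpep_validation_error")
  }
  missing <- which(is.na(records$solubility_score) |
                     is.na(records$affinity_score))
  if (length(missing) > 0L) {
    abort(sprintf("Record %d (\"%s\") is missing a solubility or affinity score.",
                  missing[1L], records$sequence[missing[1L]]),
          class = "solpep_validation_error")
  }
  out <- dplyr::mutate(records,
    passed_filter = .data$solubility_score > sol_threshold &
                    .data$affinity_score < aff_threshold)
  if (keep_all) out else dplyr::filter(out, .data$passed_filter)
}

#' Build a position frequency matrix from aligned peptides
#'
#' Counts of each canonical residue at each position over an equal-length
#' sequence set, plus the count matrix normalized to per-position
#' frequencies — the input for a sequence logo.
#'
#' @param sequences A character vector of equal-length canonical residue
#'   strings, or a candidate tibble with a `sequence` column.
#' @return A `pfm`: list with `counts` and `frequencies` (`N x 20`
#'   matrices, columns in the fixed residue order), `n_sequences` and
#'   `length`.
#' @export
build_pfm <- function(sequences) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  chars <- split_residues(sequences)
  lens <- lengths(chars)
  if (length(unique(lens)) != 1L) {
    abort("All sequences must have equal length to build a PFM.",
          class = "solpep_validation_error")
  }
  n_pos <- lens[1L]
  counts <- matrix(0L, nrow = n_pos, ncol = 20L,
                   dimnames = list(NULL, aa_alphabet))
  for (ch in chars) {
    idx <- cbind(seq_len(n_pos), match(ch, aa_alphabet))
    counts[idx] <- counts[idx] + 1L
  }
  structure(list(counts = counts,
                 frequencies = counts / length(chars),
                 n_sequences = length(chars),
                 length = n_pos),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm: %d positions x 20 residues, %d sequences>\n",
              x$length, x$n_sequences))
  invisible(x)
}

#' Tidy a position frequency matrix
#'
#' @param x A `pfm`.
#' @param ... Unused.
#' @return A long tibble with columns `position`, `residue`, `count`,
#'   `frequency`.
#' @export
tidy.pfm <- function(x, ...) {
  tibble::tibble(position = rep(seq_len(x$length), times = 20L),
                 residue = rep(aa_alphabet, each = x$length),
                 count = as.integer(x$counts),
                 frequency = as.vector(x$frequencies))
}

#' Sequence-logo style plot of a position frequency matrix
#'
#' Residue letters stacked per position with heights proportional to their
#' frequencies, coloured by the conventional hydrophilic (blue) / neutral
#' (green) / hydrophobic (black) classes.
#'
#' @param object A `pfm`.
#' @param min_frequency Residues below this frequency are omitted from the
#'   stack for legibility.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pfm <- function(object, min_frequency = 0.01, ...) {
  classes <- c(stats::setNames(rep("hydrophilic", 6), aa_hydrophilic),
               stats::setNames(rep("neutral", 6), c("S", "G", "H", "T", "A", "P")),
               stats::setNames(rep("hydrophobic", 8),
                               c("Y", "V", "M", "C", "L", "F", "I", "W")))
  df <- tidy(object) |>
    dplyr::filter(.data$frequency >= min_frequency) |>
    dplyr::arrange(.data$position, .data$frequency) |>
    dplyr::group_by(.data$position) |>
    dplyr::mutate(ytop = cumsum(.data$frequency),
                  ymid = .data$ytop - .data$frequency / 2,
                  class = classes[.data$residue]) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$ymid)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$residue,
                                    size = .data$frequency,
                                    colour = .data$class),
                       fontface = "bold", show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(hydrophilic = "#1f77b4",
                                            neutral = "#2ca02c",
                                            hydrophobic = "black")) +
    ggplot2::scale_size_continuous(range = c(2, 8)) +
    ggplot2::scale_x_continuous(breaks = seq_len(object$length)) +
    ggplot2::labs(x = "position", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Fraction of residues belonging to a residue class
#'
#' @param sequence Character vector of canonical residue strings.
#' @param residues The residue class; defaults to the hydrophilic class
#'   R, K, D, E, N, Q used in binder logo colouring.
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
residue_fraction <- function(sequence, residues = aa_hydrophilic) {
  chars <- split_residues(sequence)
  vapply(chars, function(ch) mean(ch %in% residues), numeric(1))
}

#' @rdname residue_fraction
#' @export
hydrophilic_fraction <- function(sequence) {
  residue_fraction(sequence, aa_hydrophilic)
}
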