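#' Read and write peptide FASTA files
#'
#' Thin tibble-oriented wrappers around Biostrings' amino-acid FASTA
#' reader/writer. `write_fasta` output is deterministic byte-for-byte for
#' identical input.
#'
#' @param path FASTA file path.
#' @param x A tibble with `name` and `sequence` columns, or a named
#'   character vector of sequences.
#' @return `read_fasta`: a tibble with `name` and `sequence`;
#'   `write_fasta`: `path`, invisibly.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  tibble::tibble(name = names(set), sequence = unname(as.character(set)))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  if (is.data.frame(x)) {
    seqs <- stats::setNames(x$sequence, x$name)
  } else {
    seqs <- x
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort("FASTA records must be named.", class = "solpep_validation_error")
  }
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), filepath = path)
  invisible(path)
}

candidate_col_types <- readr::cols(
  sequence = readr::col_character(),
  origin = readr::col_character(),
  seed = readr::col_integer(),
  weight = readr::col_double(),
  index_name = readr::col_character(),
  solubility_score = readr::col_double(),
  affinity_score = readr::col_double(),
  passed_filter = readr::col_logical()
)

#' Read and write candidate-record CSV files
#'
#' The CSV schema is the candidate tibble: `sequence`, `origin`, `seed`,
#' `weight`, `index_name`, `solubility_score`, `affinity_score`,
#' `passed_filter`. External per-sequence solubility (logS) and docking
#' affinity tables only need `sequence`, `solubility_score` and
#' `affinity_score`; missing columns are filled with `NA`.
#'
#' @param path CSV file path.
#' @param records A candidate tibble.
#' @return `read_candidates`: a candidate tibble; `write_candidates`:
#'   `path`, invisibly.
#' @export
read_candidates <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "?"),
                        progress = FALSE)
  if (!"sequence" %in% names(df)) {
    abort("Candidate CSV must have a `sequence` column.",
          class = "solpep_validation_error")
  }
  base <- new_candidates(as.character(df$sequence),
                         origin = if ("origin" %in% names(df))
                           as.character(df$origin) else "external")
  for (col in c("seed", "weight", "index_name", "solubility_score",
                "affinity_score", "passed_filter")) {
    if (col %in% names(df)) base[[col]] <- df[[col]]
  }
  base
}

#' @rdname read_candidates
#' @export
write_candidates <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Export a position frequency matrix as delimited text
#'
#' Tab-delimited: `position` column followed by the 20 residue columns
#' (counts or frequencies), consumable by standard logo-drawing tools.
#'
#' @param pfm A `pfm` from [build_pfm()].
#' @param path Output path.
#' @param what `"frequencies"` (default) or `"counts"`.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path, what = c("frequencies", "counts")) {
  what <- match.arg(what)
  m <- pfm[[what]]
  df <- tibble::as_tibble(as.data.frame(m))
  df <- dplyr::bind_cols(tibble::tibble(position = seq_len(nrow(m))), df)
  readr::write_tsv(df, path)
  invisible(path)
}
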