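#' Load a bundled amino-acid solubility index
#'
#' Reads one of the three bundled per-residue solubility scales — the
#' membrane-buried hydrophobicity scale (`"hydrophobicity"`), the
#' Kyte-Doolittle hydropathy scale (`"hydropathy"`), or the
#' solubility-weighted index (`"swi"`) — or any user-supplied two-column
#' tab-delimited file (residue one-letter code, numeric value; `#` comments
#' allowed). The returned table carries raw values only; call
#' [normalize_index()] to min-max scale (and, for SWI-type indices, invert)
#' the values before they can serve as a loss.
#'
#' @param name Index identifier; one of the bundled names above unless
#'   `path` is given.
#' @param path Optional path to a two-column delimited file overriding the
#'   bundled data.
#' @return A tibble of class `aa_index` with columns `residue`, `raw` and
#'   `normalized` (all `NA` until normalized), rows in the fixed
#'   alphabetical residue order, and attributes `index_name` and
#'   `loss_oriented`.
#' @seealso [normalize_index()], [solubility_index()]
#' @examples
#' load_index("hydropathy")
#' @export
load_index <- function(name, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "indices", paste0(name, ".tsv"),
                        package = "solpep")
    if (!nzchar(path)) {
      abort(sprintf("No bundled index named \"%s\".", name),
            class = "solpep_invalid_config")
    }
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2L)) {
    abort(sprintf("Malformed index file \"%s\": expected 2 tab-separated columns.",
                  path),
          class = "solpep_malformed_table")
  }
  residue <- trimws(vapply(fields, `[[`, "", 1L))
  value_chr <- trimws(vapply(fields, `[[`, "", 2L))
  value <- suppressWarnings(as.numeric(value_chr))
  if (anyNA(value)) {
    abort(sprintf("Non-numeric index value \"%s\" for residue \"%s\".",
                  value_chr[which(is.na(value))[1L]],
                  residue[which(is.na(value))[1L]]),
          class = "solpep_parse_error")
  }
  unknown <- setdiff(residue, aa_alphabet)
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown residue code \"%s\" in index \"%s\".",
                  unknown[1L], name),
          class = "solpep_malformed_table")
  }
  if (anyDuplicated(residue)) {
    abort(sprintf("Duplicate residue row \"%s\" in index \"%s\".",
                  residue[duplicated(residue)][1L], name),
          class = "solpep_malformed_table")
  }
  if (length(residue) != 20L) {
    abort(sprintf("Index \"%s\" has %d residue rows; exactly 20 required.",
                  name, length(residue)),
          class = "solpep_malformed_table")
  }
  ord <- match(aa_alphabet, residue)
  new_aa_index(
    tibble::tibble(residue = aa_alphabet,
                   raw = value[ord],
                   normalized = NA_real_),
    index_name = name, loss_oriented = FALSE)
}

new_aa_index <- function(df, index_name, loss_oriented) {
  structure(df,
            class = c("aa_index", class(tibble::tibble())),
            index_name = index_name,
            loss_oriented = loss_oriented)
}

#' Min-max normalize (and optionally invert) an index table
#'
#' Rescales the raw per-residue values to span exactly \[0, 1\]:
#' `normalized = (raw - min) / (max - min)`. With `invert = TRUE` the
#' normalized values are flipped (`1 - normalized`), which is required for
#' solubility-favouring scales such as SWI so that, for every oriented
#' table, a *larger* value always means *worse for solubility* and the
#' table can be used directly as a loss term.
#'
#' @param table An `aa_index` from [load_index()].
#' @param invert Flip the normalized values (use for SWI-type indices).
#' @return A new `aa_index` with the `normalized` column filled and
#'   attribute `loss_oriented` recording whether inversion was applied.
#'   The input is not modified.
#' @export
normalize_index <- function(table, invert = FALSE) {
  stopifnot(inherits(table, "aa_index"))
  raw <- table$raw
  if (anyNA(raw)) {
    abort("Index table has no raw values to normalize.",
          class = "solpep_state_error")
  }
  rng <- range(raw)
  if (rng[1L] == rng[2L]) {
    abort("All raw index values are identical; cannot min-max normalize.",
          class = "solpep_degenerate_range")
  }
  norm <- (raw - rng[1L]) / (rng[2L] - rng[1L])
  if (invert) norm <- 1 - norm
  out <- table
  out$normalized <- norm
  new_aa_index(tibble::as_tibble(out),
               index_name = attr(table, "index_name"),
               loss_oriented = isTRUE(invert))
}

#' Load, normalize and orient a solubility index in one call
#'
#' Convenience wrapper around [load_index()] and [normalize_index()].
#' The SWI scale is inverted after normalization (high SWI favours
#' solubility); the two hydrophobicity-type scales are used as normalized.
#'
#' @inheritParams load_index
#' @param invert Whether to invert after normalization. Defaults to `TRUE`
#'   exactly for the bundled `"swi"` index.
#' @return An oriented `aa_index` ready for [solubility_loss()].
#' @examples
#' tab <- solubility_index("swi")
#' index_values(tab)
#' @export
solubility_index <- function(name, path = NULL, invert = identical(name, "swi")) {
  normalize_index(load_index(name, path = path), invert = invert)
}

#' Extract oriented per-residue loss values
#'
#' @param table A normalized `aa_index`.
#' @return A named numeric vector (names = residues in alphabetical order)
#'   of normalized, loss-oriented values in \[0, 1\].
#' @export
index_values <- function(table) {
  stopifnot(inherits(table, "aa_index"))
  if (anyNA(table$normalized)) {
    abort("Index table is not normalized; call normalize_index() first.",
          class = "solpep_state_error")
  }
  stats::setNames(table$normalized, table$residue)
}

#' @export
print.aa_index <- function(x, ...) {
  cat(sprintf("<aa_index: %s%s>\n", attr(x, "index_name"),
              if (isTRUE(attr(x, "loss_oriented"))) ", inverted" else ""))
  NextMethod()
}
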