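#' Default surrogate interface-preference profile
#'
#' A deterministic `N x 20` matrix of per-position residue favourabilities
#' in \[0, 1\] emulating the hydrophobic interface preference that
#' structure-prediction oracles show when hallucinating binders
#' unconstrained: a central core (positions 4 to `min(11, N)`, 1-based)
#' strongly prefers the aromatic/hydrophobic residues W, Y, F and L
#' (preference 1.0) and disfavours the hydrophilic residues R, K, D, E, N,
#' Q (preference 0.1, other residues 0.2); flanking positions are much
#' flatter (0.8 everywhere, 1.0 for W/Y/F/L) so the binding signal
#' concentrates in the core. Every row attains a maximum of 1. Because
#' W/Y/F/L score poorly on all three oriented solubility indices, this
#' profile puts the binding objective in deliberate tension with the
#' solubility loss, so weight sweeps exhibit a genuine trade-off.
#'
#' @param length Binder length, >= 1.
#' @return An `interface_profile`: `N x 20` matrix (columns in the fixed
#'   alphabetical residue order) with class attribute.
#' @export
default_profile <- function(length) {
  if (!is.numeric(length) || length(length) != 1L || length < 1 ||
      length != as.integer(length)) {
    abort("`length` must be a single integer >= 1.",
          class = "solpep_invalid_config")
  }
  n <- as.integer(length)
  hydrophobic_core <- c("W", "Y", "F", "L")
  flank <- stats::setNames(rep(0.8, 20L), aa_alphabet)
  flank[hydrophobic_core] <- 1.0
  core <- stats::setNames(rep(0.2, 20L), aa_alphabet)
  core[hydrophobic_core] <- 1.0
  core[aa_hydrophilic] <- 0.1
  m <- matrix(rep(flank, each = n), nrow = n, ncol = 20L,
              dimnames = list(NULL, aa_alphabet))
  if (n >= 4L) {
    core_rows <- 4L:min(11L, n)
    m[core_rows, ] <- matrix(rep(core, each = length(core_rows)),
                             nrow = length(core_rows))
  }
  structure(m, class = c("interface_profile", "matrix", "array"))
}

#' Evaluate the surrogate binding oracle on a soft sequence
#'
#' The surrogate's interface loss is `1 - (1/N) * sum_i sum_r
#' probs[i, r] * preference[i, r]`: 0 when every position puts all mass on
#' a residue the profile fully prefers, 1 when all mass sits on
#' zero-preference residues. A second "confidence" loss is reported as a
#' constant 0 so that multi-component loss weighting is exercised end to
#' end. Both losses are linear in the probabilities; analytic gradients
#' with respect to the probability matrix are returned alongside.
#'
#' @param s A `soft_seq`.
#' @param profile An [default_profile()]-shaped matrix matching `s`.
#' @return An `oracle_output`: list with `losses` (named numeric) and
#'   `grads` (named list of `N x 20` d(loss)/d(probs) matrices).
#' @export
surrogate_evaluate <- function(s, profile) {
  stopifnot(inherits(s, "soft_seq"))
  if (is.null(s$probs)) s <- to_probs(s)
  if (!is.matrix(profile) || !identical(dim(profile), dim(s$probs))) {
    abort(sprintf("Profile shape (%s) does not match the sequence (%s).",
                  paste(dim(profile), collapse = "x"),
                  paste(dim(s$probs), collapse = "x")),
          class = "solpep_invalid_config")
  }
  n <- nrow(profile)
  interface <- 1 - sum(s$probs * profile) / n
  structure(list(
    losses = c(interface = interface, confidence = 0),
    grads = list(interface = -profile / n,
                 confidence = matrix(0, n, 20L,
                                     dimnames = list(NULL, aa_alphabet))),
    gradient_available = TRUE),
    class = "oracle_output")
}

#' Analytic gradient of the surrogate interface loss w.r.t. the logits
#'
#' @inheritParams surrogate_evaluate
#' @return An `N x 20` matrix of partial derivatives.
#' @export
interface_loss_grad <- function(s, profile) {
  if (is.null(s$probs)) s <- to_probs(s)
  out <- surrogate_evaluate(s, profile)
  backprop_softmax(out$grads$interface, s$soft_probs, s$temperature)
}

#' Construct a binding oracle from an interface profile
#'
#' Any binding-evaluation backend can drive the design loop by satisfying
#' this contract: an object with an `evaluate(soft_seq)` function returning
#' an `oracle_output` whose `losses` are finite, non-negative scalars and
#' whose `grads` give d(loss)/d(probs). This constructor wraps the
#' deterministic surrogate; an adapter around a real structure-prediction
#' oracle would implement the same interface.
#'
#' @param profile An interface preference matrix; defaults require `length`.
#' @param length Binder length used when `profile` is missing.
#' @return A `binding_oracle` object.
#' @export
surrogate_oracle <- function(profile = NULL, length = NULL) {
  if (is.null(profile)) {
    if (is.null(length)) {
      abort("Provide either a profile or a length.",
            class = "solpep_invalid_config")
    }
    profile <- default_profile(length)
  }
  structure(list(name = "surrogate",
                 length = nrow(profile),
                 profile = profile,
                 evaluate = function(s) surrogate_evaluate(s, profile)),
            class = "binding_oracle")
}

#' Write / read an interface profile as delimited text
#'
#' Tab-delimited, one row per position, columns named by residue.
#'
#' @param profile An interface profile matrix.
#' @param path File path.
#' @return `write_profile` returns `path` invisibly; `read_profile` returns
#'   an `interface_profile`.
#' @export
write_profile <- function(profile, path) {
  df <- tibble::as_tibble(as.data.frame(unclass(profile)))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "d"),
                        progress = FALSE)
  if (!identical(names(df), aa_alphabet)) {
    abort("Profile file must have exactly the 20 residue columns in alphabetical order.",
          class = "solpep_malformed_table")
  }
  m <- as.matrix(df)
  dimnames(m) <- list(NULL, aa_alphabet)
  structure(m, class = c("interface_profile", "matrix", "array"))
}
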