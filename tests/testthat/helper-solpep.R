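# Shared fixtures and independent oracles for the test suite.

P53_PEPTIDE <- "ETFSDLWKLLPEN"
INDEX_NAMES <- c("hydrophobicity", "hydropathy", "swi")

oriented_tables <- function() {
  stats::setNames(lapply(INDEX_NAMES, solubility_index), INDEX_NAMES)
}

# Wrap a discrete sequence as a hard-mode soft_seq whose one-hot probs
# decode back to the sequence (exercises the soft loss path at one-hot).
hard_seq <- function(sequence) {
  s <- init_logits(nchar(sequence), seed = 0L)
  s$logits <- one_hot(sequence) * 10
  s$mode <- "hard"
  to_probs(s)
}

# Independent brute-force oracle: per-residue table lookup and plain mean.
lookup_mean <- function(sequence, table) {
  v <- index_values(table)
  mean(v[strsplit(sequence, "")[[1]]])
}

# Independent central finite-difference gradient of f(logits_matrix).
numeric_grad <- function(f, logits, h = 1e-6) {
  g <- matrix(0, nrow(logits), ncol(logits))
  for (i in seq_len(nrow(logits))) {
    for (j in seq_len(ncol(logits))) {
      up <- logits; up[i, j] <- up[i, j] + h
      dn <- logits; dn[i, j] <- dn[i, j] - h
      g[i, j] <- (f(up) - f(dn)) / (2 * h)
    }
  }
  g
}

max_rel_error <- function(analytic, numeric) {
  max(abs(analytic - numeric)) / max(abs(numeric))
}

tiny_schedule <- function() stage_schedule(10L, 10L, 3L)
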