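#' Differentiable solubility loss of a soft sequence
#'
#' The expected normalized index value per position, averaged over
#' positions: `(1/N) * sum_i sum_r probs[i, r] * v[r]`, where `v` are the
#' oriented per-residue values of the index table (larger = worse for
#' solubility). At one-hot probabilities this reduces exactly to the plain
#' mean of the per-residue table lookups over the discrete sequence. The
#' value always lies in \[0, 1\] and is linear — hence differentiable — in
#' the probabilities.
#'
#' `type = "geometric"` replaces the arithmetic mean of the per-position
#' expectations by their geometric mean (0 if any position's expectation is
#' 0). It is provided for sensitivity checks only; the arithmetic form is
#' the default and the one used throughout the design engine.
#'
#' @param s A `soft_seq` (probabilities are materialized if absent).
#' @param table A normalized, loss-oriented `aa_index`.
#' @param type `"arithmetic"` (default) or `"geometric"`.
#' @return A single number in \[0, 1\].
#' @examples
#' tab <- solubility_index("hydropathy")
#' s <- to_probs(init_logits(13, seed = 1))
#' solubility_loss(s, tab)
#' @export
solubility_loss <- function(s, table, type = c("arithmetic", "geometric")) {
  type <- match.arg(type)
  stopifnot(inherits(s, "soft_seq"))
  v <- index_values(table)           # state error if not normalized
  if (is.null(s$probs)) s <- to_probs(s)
  per_pos <- as.vector(s$probs %*% v)
  if (type == "arithmetic") {
    mean(per_pos)
  } else {
    if (any(per_pos == 0)) 0 else exp(mean(log(per_pos)))
  }
}

# d(solubility_loss)/d(probs): constant matrix v/N replicated over rows.
sol_grad_probs <- function(n, v) {
  matrix(v, nrow = n, ncol = 20L, byrow = TRUE,
         dimnames = list(NULL, aa_alphabet)) / n
}

# Back-propagate a d(loss)/d(probs) matrix through the tempered row softmax:
# dL/dlogits[i,] = p_i * (g_i - <g_i, p_i>) / T, with p the soft
# probabilities (straight-through in hard mode).
backprop_softmax <- function(grad_probs, soft_probs, temperature) {
  inner <- rowSums(grad_probs * soft_probs)
  soft_probs * (grad_probs - inner) / temperature
}

#' Analytic gradient of the solubility loss w.r.t. the logits
#'
#' @inheritParams solubility_loss
#' @return An `N x 20` matrix of partial derivatives.
#' @export
solubility_loss_grad <- function(s, table) {
  v <- index_values(table)
  if (is.null(s$probs)) s <- to_probs(s)
  backprop_softmax(sol_grad_probs(nrow(s$logits), v), s$soft_probs,
                   s$temperature)
}

#' Loss weights for the multi-objective design loss
#'
#' @param solubility Non-negative weight on the solubility loss. The sweep
#'   used when studying the solubility trade-off is
#'   `c(0.0, 0.1, 0.3, 0.5, 0.7, 1.0)`.
#' @param oracle Named non-negative weights on the oracle losses, e.g.
#'   `c(interface = 1, confidence = 0)`.
#' @return A `loss_weights` object.
#' @export
loss_weights <- function(solubility = 0, oracle = c(interface = 1, confidence = 0)) {
  w <- c(solubility = unname(solubility), oracle)
  if (!is.numeric(w) || anyNA(w) || any(!is.finite(w)) || any(w < 0)) {
    abort("All loss weights must be finite and >= 0.",
          class = "solpep_invalid_config")
  }
  if (length(oracle) > 0L &&
      (is.null(names(oracle)) || any(!nzchar(names(oracle))))) {
    abort("Oracle weights must be named.", class = "solpep_invalid_config")
  }
  structure(list(solubility = unname(solubility), oracle = oracle),
            class = "loss_weights")
}

#' Combine oracle losses and the solubility loss into a total
#'
#' `total = sum_k oracle_weight[k] * oracle_loss[k] + solubility_weight * sol`.
#' Every oracle weight with a non-zero value must have a matching loss in
#' `oracle_out`. With a solubility weight of 0 the total is the pure oracle
#' loss (the unconstrained-design baseline).
#'
#' @param oracle_out An `oracle_output` (see [surrogate_evaluate()]) or a
#'   named numeric vector of oracle losses.
#' @param sol The solubility loss value.
#' @param weights A [loss_weights()] object.
#' @return A list with `total`, `components` (raw named losses, including
#'   `solubility`), and `weighted` (each component times its weight).
#' @export
combined_loss <- function(oracle_out, sol, weights) {
  stopifnot(inherits(weights, "loss_weights"))
  losses <- if (inherits(oracle_out, "oracle_output")) oracle_out$losses
            else oracle_out
  if (!is.numeric(sol) || length(sol) != 1L || !is.finite(sol)) {
    abort("Solubility loss must be a finite scalar.",
          class = "solpep_numeric_error")
  }
  active <- names(weights$oracle)[weights$oracle > 0]
  missing <- setdiff(active, names(losses))
  if (length(missing) > 0L) {
    abort(sprintf("Oracle did not report loss \"%s\" required by the weights.",
                  missing[1L]),
          class = "solpep_invalid_config")
  }
  if (any(!is.finite(losses))) {
    abort("Oracle returned a non-finite loss.", class = "solpep_numeric_error")
  }
  used <- intersect(names(weights$oracle), names(losses))
  weighted <- c(solubility = weights$solubility * sol,
                stats::setNames(weights$oracle[used] * losses[used], used))
  list(total = sum(weighted),
       components = c(solubility = sol, losses[used]),
       weighted = weighted)
}

#' Stage schedule for the three-stage optimization
#'
#' Iteration counts default to the standard 100 soft, 100 annealed and 10
#' hard steps. The temperature anneals linearly from `temp_start` to
#' `temp_end` across the middle stage; the optimizer takes fixed-size steps
#' along the globally L2-normalized gradient.
#'
#' @param soft_iter,temp_iter,hard_iter Positive iteration counts.
#' @param temp_start,temp_end Softmax temperatures, `temp_end <= temp_start`.
#' @param step_size Gradient-descent step length applied to the normalized
#'   gradient.
#' @return A `stage_schedule` object.
#' @export
stage_schedule <- function(soft_iter = 100L, temp_iter = 100L, hard_iter = 10L,
                           temp_start = 1, temp_end = 0.01, step_size = 0.1) {
  iters <- c(soft_iter, temp_iter, hard_iter)
  if (any(iters < 1) || any(iters != as.integer(iters))) {
    abort("Stage iteration counts must be integers >= 1.",
          class = "solpep_invalid_config")
  }
  if (!(temp_start > 0 && temp_end > 0 && temp_end <= temp_start)) {
    abort("Temperatures must be positive with temp_end <= temp_start.",
          class = "solpep_invalid_config")
  }
  if (!(step_size > 0)) {
    abort("step_size must be positive.", class = "solpep_invalid_config")
  }
  structure(list(soft_iter = as.integer(soft_iter),
                 temp_iter = as.integer(temp_iter),
                 hard_iter = as.integer(hard_iter),
                 temp_start = temp_start, temp_end = temp_end,
                 step_size = step_size),
            class = "stage_schedule")
}
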