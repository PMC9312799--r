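#' Three-stage gradient design of a binder sequence
#'
#' Hallucinates a peptide of the given length against a binding oracle
#' while co-minimizing the solubility loss. The logits are optimized by
#' plain gradient descent (fixed step along the globally L2-normalized
#' gradient) through three stages: `soft_iter` steps at the fixed starting
#' temperature, `temp_iter` steps while the temperature anneals linearly to
#' `temp_end` (sharpening the per-position distributions), and `hard_iter`
#' steps in hard mode where the forward pass uses the one-hot argmax
#' sequence and gradients flow straight-through the tempered softmax.
#' Every iteration records the decoded sequence and the loss breakdown;
#' the best sequence is the hard-stage record with the lowest total loss
#' (ties to the earliest iteration), so its loss is the true loss of the
#' discrete sequence.
#'
#' @param length Binder length (number of designed positions). The
#'   solubility loss runs over these positions only; the binding target is
#'   represented solely through the oracle.
#' @param seed Integer seed for the logits initialization.
#' @param oracle A `binding_oracle` (e.g. [surrogate_oracle()]).
#' @param table A normalized, loss-oriented `aa_index`.
#' @param weights A [loss_weights()] object.
#' @param schedule A [stage_schedule()] object.
#' @return A `design_result`: list with `trajectory` (tibble: iteration,
#'   stage, temperature, total and per-component losses, decoded sequence),
#'   `best_sequence`, `best_loss`, `seed`, `length`, `weights`, `schedule`
#'   and `index_name`.
#' @examples
#' tab <- solubility_index("hydropathy")
#' res <- design_binder(13, seed = 1, oracle = surrogate_oracle(length = 13),
#'                      table = tab, weights = loss_weights(solubility = 0.5),
#'                      schedule = stage_schedule(20, 20, 5))
#' glance(res)
#' @export
design_binder <- function(length, seed, oracle, table,
                          weights = loss_weights(),
                          schedule = stage_schedule()) {
  stopifnot(inherits(oracle, "binding_oracle"),
            inherits(schedule, "stage_schedule"),
            inherits(weights, "loss_weights"))
  v <- index_values(table)
  s <- init_logits(length, seed, temperature = schedule$temp_start)
  n <- as.integer(length)

  stages <- c(rep("soft", schedule$soft_iter),
              rep("temp", schedule$temp_iter),
              rep("hard", schedule$hard_iter))
  anneal <- schedule$temp_start +
    (schedule$temp_end - schedule$temp_start) *
      seq_len(schedule$temp_iter) / schedule$temp_iter
  temps <- c(rep(schedule$temp_start, schedule$soft_iter), anneal,
             rep(schedule$temp_end, schedule$hard_iter))
  total_iter <- length(stages)

  sol_gp <- sol_grad_probs(n, v)
  rows <- vector("list", total_iter)
  for (it in seq_len(total_iter)) {
    s$mode <- stages[it]
    s$temperature <- temps[it]
    s <- to_probs(s)

    oout <- oracle$evaluate(s)
    if (any(!is.finite(oout$losses))) {
      abort(sprintf("Oracle returned a non-finite loss at iteration %d (%s stage).",
                    it, stages[it]),
            class = "solpep_numeric_error")
    }
    sol <- solubility_loss(s, table)
    cl <- combined_loss(oout, sol, weights)

    rows[[it]] <- tibble::tibble(
      iteration = it, stage = stages[it], temperature = temps[it],
      total = cl$total, !!!as.list(cl$components),
      sequence = decode_sequence(s))

    grad_probs <- weights$solubility * sol_gp
    for (k in names(weights$oracle)) {
      if (weights$oracle[[k]] > 0) {
        grad_probs <- grad_probs + weights$oracle[[k]] * oout$grads[[k]]
      }
    }
    grad_logits <- backprop_softmax(grad_probs, s$soft_probs, s$temperature)
    nrm <- sqrt(sum(grad_logits^2))
    if (nrm > 0) grad_logits <- grad_logits / nrm
    s$logits <- s$logits - schedule$step_size * grad_logits
  }

  trajectory <- dplyr::bind_rows(rows)
  best <- select_best(trajectory)
  structure(list(trajectory = trajectory,
                 best_sequence = best$sequence,
                 best_loss = best$loss,
                 seed = as.integer(seed),
                 length = n,
                 weights = weights,
                 schedule = schedule,
                 index_name = attr(table, "index_name")),
            class = "design_result")
}

#' Select the best sequence from a design trajectory
#'
#' The decoded sequence of the hard-stage iteration with minimal total
#' loss; ties are broken toward the earliest iteration.
#'
#' @param trajectory A trajectory tibble with columns `stage`, `total` and
#'   `sequence` (as produced by [design_binder()]).
#' @return A list with `sequence` and `loss`.
#' @export
select_best <- function(trajectory) {
  hard <- dplyr::filter(trajectory, .data$stage == "hard")
  if (nrow(hard) == 0L) {
    abort("Trajectory contains no hard-stage records.",
          class = "solpep_state_error")
  }
  i <- which.min(hard$total)  # which.min takes the first minimum: earliest wins
  list(sequence = hard$sequence[i], loss = hard$total[i])
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("<design_result: N=%d seed=%d index=%s>\n", x$length, x$seed,
              x$index_name))
  cat(sprintf("  best sequence: %s (total loss %.6f)\n",
              x$best_sequence, x$best_loss))
  invisible(x)
}

#' Tidy the full loss trajectory of a design run
#'
#' @param x A `design_result`.
#' @param ... Unused.
#' @return The trajectory tibble: one row per iteration with the stage,
#'   temperature, total and per-component losses and decoded sequence.
#' @export
tidy.design_result <- function(x, ...) x$trajectory

#' One-row summary of a design run
#'
#' @param x A `design_result`.
#' @param ... Unused.
#' @return A one-row tibble with the seed, binder length, index, solubility
#'   weight, best sequence and its total and solubility losses.
#' @export
glance.design_result <- function(x, ...) {
  hard <- dplyr::filter(x$trajectory, .data$stage == "hard")
  i <- which.min(hard$total)
  tibble::tibble(seed = x$seed,
                 length = x$length,
                 index_name = x$index_name,
                 solubility_weight = x$weights$solubility,
                 best_sequence = x$best_sequence,
                 best_loss = x$best_loss,
                 best_solubility = hard$solubility[i],
                 n_iterations = nrow(x$trajectory))
}

#' Plot the loss trajectory of a design run
#'
#' Loss components against iteration, with the stage boundaries marked.
#'
#' @param object A `design_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.design_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object$trajectory, "iteration", "stage", "total",
                  "solubility", dplyr::any_of(c("interface", "confidence"))),
    cols = -c("iteration", "stage"),
    names_to = "component", values_to = "loss")
  breaks <- cumsum(c(object$schedule$soft_iter, object$schedule$temp_iter))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$loss,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = breaks + 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "iteration", y = "loss", colour = NULL,
                  title = sprintf("Design trajectory (seed %d, %s, w=%g)",
                                  object$seed, object$index_name,
                                  object$weights$solubility)) +
    ggplot2::theme_minimal()
}
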