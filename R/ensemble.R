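# The ensemble combiner: per-gene classifier margins are weighted by a
# vector learned with batch gradient descent (delta rule) on the squared
# training error, and the sign of the weighted sum is the final call.

#' Assemble a margin matrix from base-classifier posteriors
#'
#' Each base model contributes one column of margins
#' m = p_pos - p_neg in \[-1, 1\]; rows are training genes.
#'
#' @param posteriors named list of posterior tibbles (`gene`, `p_pos`,
#'   `p_neg`), one per base model, over the same genes.
#' @return numeric matrix genes x models with dimnames.
#' @export
margin_matrix <- function(posteriors) {
  genes <- posteriors[[1]]$gene
  M <- vapply(posteriors, function(p) {
    if (!identical(p$gene, genes)) {
      p <- p[match(genes, p$gene), ]
    }
    p$p_pos - p$p_neg
  }, numeric(length(genes)))
  M <- matrix(M, nrow = length(genes),
              dimnames = list(genes, names(posteriors)))
  if (any(abs(M) > 1 + 1e-9)) abort("margins must lie in [-1, 1]")
  M
}

#' Ensemble score and prediction
#'
#' The ensemble score of a gene is the weighted sum of its base-classifier
#' margins; the predicted class is +1 (disease) for a strictly positive
#' score and -1 otherwise (ties go to the non-disease class).
#'
#' @param a weight vector (one weight per base model).
#' @param M margin matrix (rows genes, columns models) or a single margin
#'   row.
#' @return for `ensemble_score`, numeric scores; for `ensemble_predict`,
#'   integer class labels in \{-1, +1\}.
#' @export
ensemble_score <- function(a, M) {
  if (is.vector(M)) M <- matrix(M, nrow = 1)
  if (length(a) != ncol(M)) abort("weight / margin length mismatch")
  as.numeric(M %*% a)
}

#' @rdname ensemble_score
#' @export
ensemble_predict <- function(a, M) {
  s <- ensemble_score(a, M)
  ifelse(s > 0, 1L, -1L)
}

#' Learn ensemble weights by gradient descent
#'
#' Minimizes E = 1/2 sum_i (y_i - s_i)^2, where s_i is the continuous
#' ensemble score of training gene i, by the batch delta rule:
#' delta_a_j = eta_t sum_i (y_i - s_i) m_ij, with a decaying learning rate
#' eta_t = eta0 / (1 + t / decay_halflife). Weights start uniform on
#' \[0, 1) under the mandatory seed. Stops when the L1 norm of the update
#' drops below `tol` or at `max_iter`.
#'
#' @param M margin matrix (rows training genes, columns base models).
#' @param y labels in \{-1, +1\}, one per row of `M`.
#' @param eta0 initial learning rate (default 0.001).
#' @param tol L1 convergence tolerance on the update (default 1e-6).
#' @param max_iter iteration cap (default 10000).
#' @param seed RNG seed for the random initial weights (required).
#' @param decay_halflife iterations after which the learning rate has
#'   halved (default 100).
#' @return an `epu_ensemble`: list with `weights` (named by model),
#'   `history` (tibble `iteration`, `error` of the continuous E per
#'   iteration), `iterations`, `converged`, `training_error` (hard-label
#'   squared error 1/2 sum (y - o)^2) and `training_accuracy`.
#' @export
train_weights <- function(M, y, eta0 = 0.001, tol = 1e-6, max_iter = 10000L,
                          seed, decay_halflife = 100) {
  if (nrow(M) == 0) abort("empty margin matrix")
  if (length(y) != nrow(M)) abort("one label per margin row required")
  if (!all(y %in% c(-1, 1))) abort("labels must be -1 or +1")
  if (length(unique(y)) == 1) warn("all training labels are one class")
  k <- ncol(M)
  a <- with_seed_(seed, runif(k))
  history <- numeric(max_iter)
  iterations <- 0L
  converged <- FALSE
  for (t in seq_len(max_iter) - 1L) {
    s <- as.numeric(M %*% a)
    resid <- y - s
    history[t + 1L] <- 0.5 * sum(resid^2)
    eta <- eta0 / (1 + t / decay_halflife)
    delta <- eta * as.numeric(crossprod(M, resid))
    a <- a + delta
    iterations <- t + 1L
    if (sum(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  o <- ifelse(as.numeric(M %*% a) > 0, 1, -1)
  structure(list(
    weights = setNames(a, colnames(M)),
    history = tibble::tibble(iteration = seq_len(iterations),
                             error = history[seq_len(iterations)]),
    iterations = iterations,
    converged = converged,
    training_error = 0.5 * sum((y - o)^2),
    training_accuracy = mean(o == y),
    seed = seed
  ), class = "epu_ensemble")
}

#' @exportS3Method base::print
print.epu_ensemble <- function(x, ...) {
  cat(sprintf("<epu_ensemble> weights (%s), %d iterations%s, training accuracy %.3f\n",
              paste(sprintf("%s=%.3f", names(x$weights) %||%
                              seq_along(x$weights), x$weights), collapse = ", "),
              x$iterations, if (x$converged) "" else " (not converged)",
              x$training_accuracy))
  invisible(x)
}

#' Tidy an ensemble fit
#' @param x an `epu_ensemble`.
#' @param ... unused.
#' @return a tibble with one row per base model (`model`, `weight`).
#' @export
tidy.epu_ensemble <- function(x, ...) {
  tibble::tibble(model = names(x$weights) %||% as.character(seq_along(x$weights)),
                 weight = unname(x$weights))
}

#' One-row summary of an ensemble fit
#' @param x an `epu_ensemble`.
#' @param ... unused.
#' @return a one-row tibble with iterations, convergence flag, final
#'   continuous error, hard-label training error and training accuracy.
#' @export
glance.epu_ensemble <- function(x, ...) {
  tibble::tibble(iterations = x$iterations, converged = x$converged,
                 final_error = x$history$error[x$iterations],
                 training_error = x$training_error,
                 training_accuracy = x$training_accuracy)
}

#' Plot the ensemble training error curve
#' @param object an `epu_ensemble`.
#' @param ... unused.
#' @return a ggplot of the squared-error history per iteration.
#' @export
autoplot.epu_ensemble <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$iteration, y = .data$error)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "iteration", y = "squared training error",
                  title = "Ensemble gradient descent") +
    ggplot2::theme_minimal()
}
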