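# Random walk with restart from signed seeds, and combination of the three
# per-network converged score vectors into one integrated score.

#' Random walk with restart
#'
#' Iterates R_t = (1 - alpha) W R_(t-1) + alpha R_0 (with R_1 = R_0) on the
#' column-oriented transition matrix until the L1 difference between
#' consecutive iterates drops below `tol` or `max_iter` is reached. `alpha`
#' is the restart probability: the fraction of flow returned to the seed
#' nodes at every step.
#'
#' @param T a `transition_matrix` (from [to_transition()]).
#' @param r0 seed scores (named numeric / `seed_scores`); genes absent from
#'   the network are ignored, network genes absent from `r0` start at 0.
#' @param alpha restart probability in (0, 1\] (default 0.7).
#' @param tol L1 convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 1000; hitting it flags
#'   non-convergence).
#' @return a `propagation_result`: list with `scores` (named numeric over the
#'   network's nodes), `iterations`, `delta`, `alpha`, `converged`.
#' @export
rwr <- function(T, r0, alpha = 0.7, tol = 1e-6, max_iter = 1000L) {
  if (alpha <= 0 || alpha > 1) abort("alpha must be in (0, 1]")
  nodes <- T$nodes
  R0 <- setNames(numeric(length(nodes)), nodes)
  common <- intersect(names(r0), nodes)
  R0[common] <- r0[common]
  Rt <- R0
  iterations <- 1L
  delta <- Inf
  converged <- FALSE
  while (iterations < max_iter) {
    Rn <- as.numeric((1 - alpha) * (T$Wt %*% Rt)) + alpha * R0
    delta <- sum(abs(Rn - Rt))
    Rt <- setNames(Rn, nodes)
    iterations <- iterations + 1L
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(scores = Rt, iterations = iterations, delta = delta,
                 alpha = alpha, converged = converged),
            class = "propagation_result")
}

#' @exportS3Method base::print
print.propagation_result <- function(x, ...) {
  cat(sprintf("<propagation_result> %d genes, %d iterations, L1 delta %.2e%s\n",
              length(x$scores), x$iterations, x$delta,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Integrated score across networks
#'
#' Combines the converged per-network scores of each gene into one integrated
#' score. By default the arithmetic mean over the three networks is used,
#' treating absence from a network as a zero score (always dividing by the
#' number of networks); with `mean_over_present = TRUE` the divisor is the
#' number of networks a gene appears in.
#'
#' @param ... `propagation_result` objects (typically PPI, GO, GE).
#' @param mean_over_present divide by per-gene network count instead of the
#'   total network count (default `FALSE`).
#' @return named numeric vector of integrated scores over the union gene set.
#' @export
integrate_scores <- function(..., mean_over_present = FALSE) {
  results <- list(...)
  if (length(results) == 1 && is.list(results[[1]]) &&
      !inherits(results[[1]], "propagation_result")) {
    results <- results[[1]]
  }
  genes <- sort(unique(unlist(lapply(results, function(r) names(r$scores)))))
  total <- setNames(numeric(length(genes)), genes)
  count <- setNames(numeric(length(genes)), genes)
  for (r in results) {
    total[names(r$scores)] <- total[names(r$scores)] + r$scores
    count[names(r$scores)] <- count[names(r$scores)] + 1
  }
  div <- if (mean_over_present) pmax(count, 1) else length(results)
  total / div
}
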