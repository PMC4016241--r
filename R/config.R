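#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline in one nested list, with
#' the defaults used throughout: restart probability 0.7 and L1 tolerance
#' 1e-6 for the random walk, 5 nearest neighbours for network sparsification,
#' up to 1000 GO features per sub-ontology, k = 3 for the weighted
#' k-nearest-neighbour model, Laplace smoothing 1 for the weighted naive
#' Bayes, learning rate 0.001 for the ensemble gradient descent, and the
#' logistic phenotype filter constants c = -15, d = log(9999).
#'
#' @param ... named overrides. Names use `$` paths into the default list,
#'   e.g. `epu_config(propagation = list(alpha = 0.5))` replaces only
#'   `propagation$alpha`.
#'
#' @return a nested named list of class `epu_config`.
#' @export
#'
#' @examples
#' cfg <- epu_config(knn = list(k = 5))
#' cfg$knn$k
#' cfg$propagation$alpha
epu_config <- function(...) {
  defaults <- list(
    network = list(
      k_neighbors = 5L,
      logistic = list(c = -15, d = log(9999)),
      use_abs_weights = TRUE
    ),
    features = list(
      n_go_features = 1000L,
      wang = list(w_is_a = 0.8, w_part_of = 0.6)
    ),
    seed = list(balance_include_cp = TRUE),
    propagation = list(
      alpha = 0.7, tol = 1e-6, max_iter = 1000L,
      mean_over_present = FALSE
    ),
    knn = list(k = 3L),
    nb = list(laplace = 1),
    svm = list(
      kernel = "linear",
      cost_grid = c(0.1, 1, 10),
      level_multipliers = c(P = 1, RN = 1, LP = 0.5, LN = 0.5, WN = 0.25),
      cv_folds = 3L,
      rbf_gamma = NULL
    ),
    ensemble = list(
      eta0 = 0.001, tol = 1e-6, max_iter = 10000L, decay_halflife = 100
    ),
    eval = list(n_groups = 10L, outer_folds = 3L, inner_folds = 0L)
  )
  overrides <- list(...)
  cfg <- modify_list_deep(defaults, overrides)
  structure(cfg, class = "epu_config")
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}
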