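# End-to-end experimental protocol: resampled unlabeled sets with |U| = |P|,
# outer 3-fold cross-validation, inner-fold (or leave-one-out) soft labels
# for ensemble training, and precision / recall / F-measure reporting, plus
# a genome-wide candidate ranking. An explicit leakage assertion guarantees
# that held-out test genes never reach any training stage.

#' F-measure
#'
#' Harmonic mean of precision and recall; 0 when both are 0.
#'
#' @param p,r precision and recall in \[0, 1\] (vectorized).
#' @return numeric F-measure(s).
#' @export
#'
#' @examples
#' f_measure(0.881, 0.877)  # 0.879 to 3 significant figures
f_measure <- function(p, r) {
  if (any(p < 0 | p > 1 | r < 0 | r > 1)) abort("precision and recall must be in [0, 1]")
  ifelse(p + r == 0, 0, 2 * p * r / (p + r))
}

#' Resample unlabeled gene sets
#'
#' Draws `n_groups` independent uniform samples without replacement from the
#' universe (minus `P`), each of size |P|, each seeded deterministically so
#' reruns reproduce the same groups.
#'
#' @param universe candidate unlabeled genes (already excluding known
#'   disease genes).
#' @param P positive gene set.
#' @param n_groups number of resamples.
#' @param seed base seed; group g uses `seed + g`.
#' @return list of character vectors, each of length `length(P)`.
#' @export
sample_unlabeled <- function(universe, P, n_groups, seed) {
  cand <- setdiff(universe, P)
  if (length(cand) < length(P)) abort("universe too small for |U| = |P| sampling")
  lapply(seq_len(n_groups), function(g) {
    with_seed_(seed + g, sort(sample(cand, length(P))))
  })
}

#' Experiment plan
#'
#' @param n_groups number of unlabeled resamples (default 10).
#' @param outer_folds outer cross-validation folds (default 3).
#' @param inner_folds folds for the soft-label stage; 0 means leave-one-out
#'   (default 0).
#' @param seed base seed for all randomness in the run.
#' @return an `experiment_plan` list.
#' @export
experiment_plan <- function(n_groups = 10L, outer_folds = 3L,
                            inner_folds = 0L, seed = 1L) {
  structure(list(n_groups = as.integer(n_groups),
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "experiment_plan")
}

# ---- pipeline stages ----------------------------------------------------

# Inputs that do not depend on the P/U split or fold: networks from PPI and
# expression, filtered phenotype similarities, label-free feature blocks and
# per-namespace candidate GO blocks over the whole gene universe.
build_static_inputs <- function(bundle, config = epu_config()) {
  ppi <- build_ppi_network(bundle$ppi_edges, nodes = bundle$genes)
  ge <- build_expression_network(bundle$expression,
                                 k = config$network$k_neighbors)
  sims_f <- filter_phenotype_network(bundle$phenotype_sim,
                                     c = config$network$logistic$c,
                                     d = config$network$logistic$d)
  w1 <- config$features$wang$w_is_a
  w2 <- config$features$wang$w_part_of
  annotated <- unlist(bundle$go_annotations, use.names = FALSE)
  go_blocks <- list()
  for (ns in intersect(c("MF", "BP", "CC"), names(bundle$ontology))) {
    dag <- bundle$ontology[[ns]]
    candidates <- sort(unique(intersect(dag$terms, annotated)))
    if (length(candidates) == 0) next
    go_blocks[[ns]] <- go_feature_block(bundle$genes, candidates,
                                        bundle$go_annotations, dag, w1, w2)
  }
  doms <- sort(unique(unlist(bundle$domain_annotations, use.names = FALSE)))
  domain_block <- NULL
  if (length(doms) > 0) {
    domain_block <- matrix(0, length(bundle$genes), length(doms),
                           dimnames = list(bundle$genes, doms))
    for (g in bundle$genes) {
      has <- intersect(bundle$domain_annotations[[g]] %||% character(), doms)
      domain_block[g, has] <- 1
    }
  }
  topo_block <- topology_features(bundle$genes, ppi)
  list(ppi = ppi, ge = ge, sims_f = sims_f, go_blocks = go_blocks,
       domain_block = domain_block, topo_block = topo_block)
}

# Select GO feature columns for this fold (class-mean-difference score on
# training genes only) and assemble the fold's feature matrix.
fold_feature_matrix <- function(static, P_tr, U_tr, config) {
  n_go <- config$features$n_go_features
  blocks <- list(); kinds <- character(); anchors <- character()
  for (ns in names(static$go_blocks)) {
    B <- static$go_blocks[[ns]]
    score <- abs(colMeans(B[P_tr, , drop = FALSE]) -
                   colMeans(B[U_tr, , drop = FALSE]))
    ord <- order_desc_ties_asc(score, colnames(B))
    sel <- colnames(B)[ord[seq_len(min(n_go, ncol(B)))]]
    blocks <- c(blocks, list(B[, sel, drop = FALSE]))
    kinds <- c(kinds, rep(ns, length(sel)))
    anchors <- c(anchors, sel)
  }
  if (!is.null(static$domain_block)) {
    blocks <- c(blocks, list(static$domain_block))
    kinds <- c(kinds, rep("DOMAIN", ncol(static$domain_block)))
    anchors <- c(anchors, colnames(static$domain_block))
  }
  blocks <- c(blocks, list(static$topo_block))
  kinds <- c(kinds, rep("TOPO", ncol(static$topo_block)))
  anchors <- c(anchors, colnames(static$topo_block))
  V <- do.call(cbind, blocks)
  new_gene_feature_matrix(rownames(V), kinds, anchors, V)
}

# Seeding + propagation + partitioning for one training split. `exclude`
# bars genes (full positive list, current test fold) from the candidate
# positive seeds.
fold_context <- function(static, bundle, P_tr, U_tr, exclude, config) {
  V <- fold_feature_matrix(static, P_tr, U_tr, config)
  go_net <- build_go_network(V, k = config$network$k_neighbors)
  cp <- suppressWarnings(
    extract_candidate_positives(P_tr, bundle$phenotype_assoc, static$sims_f,
                                exclude = exclude))
  pr <- positive_representative(P_tr, V)
  rn <- extract_reliable_negatives(U_tr, pr, V)
  r0 <- suppressWarnings(
    init_seed_scores(P_tr, cp, rn, nodes = bundle$genes,
                     balance_include_cp = config$seed$balance_include_cp))
  al <- config$propagation$alpha
  tl <- config$propagation$tol
  mi <- config$propagation$max_iter
  ua <- config$network$use_abs_weights
  props <- list(
    PPI = rwr(to_transition(static$ppi, ua), r0, al, tl, mi),
    GO = rwr(to_transition(go_net, ua), r0, al, tl, mi),
    GE = rwr(to_transition(static$ge, ua), r0, al, tl, mi)
  )
  int <- integrate_scores(props,
                          mean_over_present = config$propagation$mean_over_present)
  u_prime <- setdiff(U_tr, rn)
  lv <- partition_levels(u_prime, int)
  list(V = V, int = int, cp = cp, rn = as.character(rn), u_prime = u_prime,
       levels = lv, P_tr = P_tr, U_tr = U_tr, props = props)
}

# Fit the three base models on the context's pools, minus `exclude` (for the
# inner soft-label stage). Returns a list of posterior closures.
fit_base_models <- function(ctx, config, exclude = character()) {
  P <- setdiff(ctx$P_tr, exclude)
  rn <- setdiff(ctx$rn, exclude)
  up <- setdiff(ctx$u_prime, exclude)
  lv <- structure(list(LP = setdiff(ctx$levels$LP, exclude),
                       LN = setdiff(ctx$levels$LN, exclude),
                       WN = setdiff(ctx$levels$WN, exclude)),
                  class = "level_partition")
  pool <- c(P, rn, up)
  V <- ctx$V
  int <- ctx$int
  k <- min(config$knn$k, length(pool) - 1L)
  wnb <- wnb_fit(P, rn, up, int, V, laplace = config$nb$laplace)
  msvm <- msvm_fit(P, rn, lv, V, config)
  list(
    WKNN = function(genes) wknn_posterior(genes, pool, int, V, k),
    WNB = function(genes) wnb_posterior(wnb, genes, V),
    MSVM = function(genes) msvm_posterior(msvm, genes, V)
  )
}

predict_margins <- function(models, genes) {
  margin_matrix(lapply(models, function(f) f(genes)))
}

#' Soft-label margin matrix for ensemble training
#'
#' Every training gene is held out in turn (leave-one-out when
#' `inner_folds = 0`, otherwise grouped into `inner_folds` stratified inner
#' folds); the three base models are refitted without the held-out genes and
#' their margins recorded. The result is the matrix the ensemble weights are
#' trained on.
#'
#' @param ctx a fold context (internal; see [run_experiment()]).
#' @param config an [epu_config()].
#' @param inner_folds 0 for leave-one-out, else the number of inner folds.
#' @return list with `M` (margin matrix over P_tr then U_tr rows) and `y`
#'   (+1 for positives, -1 for unlabeled-as-negative).
#' @keywords internal
soft_label_matrix <- function(ctx, config, inner_folds = 0L) {
  train <- c(ctx$P_tr, ctx$U_tr)
  y <- ifelse(train %in% ctx$P_tr, 1, -1)
  if (inner_folds <= 0L || inner_folds >= length(train)) {
    groups <- seq_along(train)  # LOOCV
  } else {
    groups <- integer(length(train))
    groups[y > 0] <- rep_len(seq_len(inner_folds), sum(y > 0))
    groups[y < 0] <- rep_len(seq_len(inner_folds), sum(y < 0))
  }
  M <- matrix(NA_real_, length(train), 3,
              dimnames = list(train, c("WKNN", "WNB", "MSVM")))
  for (h in unique(groups)) {
    held <- train[groups == h]
    models <- fit_base_models(ctx, config, exclude = held)
    M[held, ] <- predict_margins(models, held)
  }
  list(M = M, y = y)
}

assert_no_leakage <- function(test_genes, ctx, M) {
  stages <- list(
    positive_seeds = ctx$P_tr,
    candidate_positive_seeds = ctx$cp$gene,
    reliable_negatives = ctx$rn,
    unlabeled_training = ctx$u_prime,
    ensemble_training = rownames(M)
  )
  for (nm in names(stages)) {
    leak <- intersect(test_genes, stages[[nm]])
    if (length(leak) > 0) {
      abort(sprintf("leakage: test gene(s) %s present in stage '%s'",
                    paste(utils::head(leak, 3), collapse = ", "), nm))
    }
  }
  TRUE
}

binary_metrics <- function(pred, truth_pos) {
  tp <- sum(pred > 0 & truth_pos); fp <- sum(pred > 0 & !truth_pos)
  fn <- sum(pred <= 0 & truth_pos); tn <- sum(pred <= 0 & !truth_pos)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  tibble::tibble(precision = p, recall = r, f = f_measure(p, r),
                 tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Run the full evaluation protocol
#'
#' For each resampled unlabeled group and each outer fold: extracts seeds
#' from the training split, propagates them over the three networks, fits
#' the three base models, learns ensemble weights on inner-fold soft labels,
#' and scores the held-out fold. Unlabeled genes count as negatives for the
#' metrics. Also produces a genome-wide candidate ranking by the averaged
#' ensemble score, and asserts at every fold that no test gene reached any
#' training stage.
#'
#' @param bundle a `synthetic_bundle` (or any list with the same fields).
#' @param plan an [experiment_plan()].
#' @param config an [epu_config()].
#' @return an `epu_report`: list with `rows` (per group/fold/model metric
#'   tibble), `macro` (per-model averages), `ranking` (tibble `gene`,
#'   `score`, `rank`, `top_frac` over genes outside the positive list),
#'   `leakage_ok`, `plan`, `config`.
#' @export
run_experiment <- function(bundle, plan = experiment_plan(),
                           config = epu_config()) {
  P <- bundle$positives
  known <- union(P, names(bundle$phenotype_assoc$g2ph))
  universe <- setdiff(bundle$genes, known)
  static <- build_static_inputs(bundle, config)
  u_groups <- sample_unlabeled(universe, P, plan$n_groups, plan$seed)

  rows <- list()
  rank_scores <- list()
  leakage_ok <- TRUE
  for (g in seq_len(plan$n_groups)) {
    U <- u_groups[[g]]
    nf <- plan$outer_folds
    fold_of <- with_seed_(plan$seed + 31L * g, {
      fp <- sample(rep_len(seq_len(nf), length(P)))
      fu <- sample(rep_len(seq_len(nf), length(U)))
      setNames(c(fp, fu), c(P, U))
    })
    for (fold in seq_len(nf)) {
      P_tr <- P[fold_of[P] != fold]
      U_tr <- U[fold_of[U] != fold]
      test <- c(P[fold_of[P] == fold], U[fold_of[U] == fold])
      ctx <- fold_context(static, bundle, P_tr, U_tr,
                          exclude = union(P, test), config)
      soft <- soft_label_matrix(ctx, config, plan$inner_folds)
      leakage_ok <- leakage_ok && assert_no_leakage(test, ctx, soft$M)
      ens <- train_weights(soft$M, soft$y,
                           eta0 = config$ensemble$eta0,
                           tol = config$ensemble$tol,
                           max_iter = config$ensemble$max_iter,
                           seed = plan$seed + 104729L + 100L * g + fold,
                           decay_halflife = config$ensemble$decay_halflife)
      models <- fit_base_models(ctx, config)
      Mt <- predict_margins(models, test)
      truth_pos <- test %in% P
      for (m in colnames(Mt)) {
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(group = g, fold = fold, model = m),
          binary_metrics(ifelse(Mt[, m] > 0, 1, -1), truth_pos))
      }
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(group = g, fold = fold, model = "EPU"),
        binary_metrics(ensemble_predict(ens$weights, Mt), truth_pos))
    }
    # genome-wide ranking: train on the full group, score everything else
    ctx_full <- fold_context(static, bundle, P, U, exclude = P, config)
    soft_full <- soft_label_matrix(ctx_full, config, plan$inner_folds)
    ens_full <- train_weights(soft_full$M, soft_full$y,
                              eta0 = config$ensemble$eta0,
                              tol = config$ensemble$tol,
                              max_iter = config$ensemble$max_iter,
                              seed = plan$seed + 224737L + g,
                              decay_halflife = config$ensemble$decay_halflife)
    models_full <- fit_base_models(ctx_full, config)
    score_genes <- setdiff(bundle$genes, P)
    Ms <- predict_margins(models_full, score_genes)
    rank_scores[[g]] <- setNames(ensemble_score(ens_full$weights, Ms),
                                 score_genes)
  }
  rows <- dplyr::bind_rows(rows)
  macro <- rows |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(precision = mean(.data$precision),
                     recall = mean(.data$recall),
                     f = mean(.data$f), .groups = "drop")
  avg <- Reduce(`+`, rank_scores) / length(rank_scores)
  ord <- order_desc_ties_asc(avg, names(avg))
  ranking <- tibble::tibble(gene = names(avg)[ord], score = avg[ord],
                            rank = seq_along(avg),
                            top_frac = seq_along(avg) / length(avg))
  structure(list(rows = rows, macro = macro, ranking = ranking,
                 leakage_ok = leakage_ok, plan = plan, config = config),
            class = "epu_report")
}

#' @exportS3Method base::print
print.epu_report <- function(x, ...) {
  cat(sprintf("<epu_report> %d groups x %d folds (leakage check %s)\n",
              x$plan$n_groups, x$plan$outer_folds,
              if (x$leakage_ok) "passed" else "FAILED"))
  print(x$macro)
  invisible(x)
}

#' Plot per-model evaluation metrics
#' @param object an `epu_report`.
#' @param ... unused.
#' @return a ggplot bar chart of macro precision / recall / F per model.
#' @export
autoplot.epu_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$macro, c("precision", "recall", "f"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, title = "Model comparison") +
    ggplot2::theme_minimal()
}

#' Summarise hidden-positive recovery from a report and ground truth
#'
#' @param report an `epu_report`.
#' @param truth tibble with `gene`, `is_hidden` (from a bundle's ground
#'   truth).
#' @param top_frac ranking cutoff (default 0.2).
#' @return one-row tibble: number of hidden positives, how many rank inside
#'   the cutoff, the recovery frequency and its enrichment over the random
#'   expectation (`top_frac`).
#' @export
hidden_recovery <- function(report, truth, top_frac = 0.2) {
  hidden <- truth$gene[truth$is_hidden == 1]
  rk <- report$ranking
  in_top <- rk$gene[rk$top_frac <= top_frac]
  n_hit <- length(intersect(hidden, in_top))
  freq <- if (length(hidden) == 0) 0 else n_hit / length(hidden)
  tibble::tibble(n_hidden = length(hidden), n_in_top = n_hit,
                 frequency = freq, enrichment = freq / top_frac)
}
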