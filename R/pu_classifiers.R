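# The three weighted positive-unlabeled base models: weighted
# k-nearest-neighbour, weighted multinomial naive Bayes, and a multi-level
# cost-weighted support vector machine. Each emits a two-class posterior
# (p_pos, p_neg) per gene.

#' Weighted k-nearest-neighbour posterior
#'
#' For each query gene, finds its k nearest training genes by Euclidean
#' distance on the feature matrix (ties by ascending gene id; the query gene
#' itself is excluded when it appears in the training pool), splits them by
#' the sign of the integrated score, and accumulates score magnitudes:
#' p_pos is the positive score mass over the total mass, (0.5, 0.5) when the
#' total mass is zero.
#'
#' @param genes query gene ids.
#' @param train training gene ids carrying integrated scores.
#' @param int_score named numeric integrated scores (covers `train`).
#' @param V a `gene_feature_matrix`.
#' @param k number of neighbours (default 3).
#' @return tibble with columns `gene`, `p_pos`, `p_neg`.
#' @export
wknn_posterior <- function(genes, train, int_score, V, k = 3) {
  if (k <= 0) abort("k must be positive")
  if (k > length(train)) abort("k exceeds the training pool size")
  Xt <- V$V[train, , drop = FALSE]
  out <- vapply(genes, function(g) {
    pool <- train
    Xp <- Xt
    if (g %in% pool) {
      keep <- pool != g
      if (sum(keep) < k) abort("k exceeds the training pool size after self-exclusion")
      pool <- pool[keep]
      Xp <- Xp[keep, , drop = FALSE]
    }
    x <- V$V[g, ]
    d <- sqrt(colSums((t(Xp) - x)^2))
    ord <- order(d, pool, method = "radix")
    nb <- pool[ord[seq_len(k)]]
    s <- int_score[nb]
    pos <- sum(s[s >= 0])
    neg <- sum(abs(s[s < 0]))
    if (pos + neg == 0) 0.5 else pos / (pos + neg)
  }, 0.0)
  out <- unname(out)
  tibble::tibble(gene = genes, p_pos = out, p_neg = 1 - out)
}

#' Weighted naive Bayes for PU-weighted genes
#'
#' Multinomial-style naive Bayes with fractional, confidence-weighted counts:
#' the positive pool is P (weight 1) plus the unlabeled genes with positive
#' integrated score (weighted by the score); the negative pool is RN (weight
#' 1) plus the unlabeled genes with negative integrated score (weighted by
#' its magnitude). Feature likelihoods use Laplace smoothing; class priors
#' are fixed at 0.5. Feature values must be nonnegative (the GO, domain and
#' scaled topology blocks are).
#'
#' @param P,RN positive / reliable-negative gene sets.
#' @param u_prime remaining unlabeled genes.
#' @param int_score named numeric integrated scores.
#' @param V a `gene_feature_matrix`.
#' @param laplace smoothing constant (default 1).
#' @return a `wnb_model`.
#' @export
wnb_fit <- function(P, RN, u_prime, int_score, V, laplace = 1) {
  up <- u_prime[int_score[u_prime] > 0]
  un <- u_prime[int_score[u_prime] < 0]
  pos_genes <- c(P, up)
  pos_w <- c(rep(1, length(P)), int_score[up])
  neg_genes <- c(RN, un)
  neg_w <- c(rep(1, length(RN)), abs(int_score[un]))
  if (length(pos_genes) == 0) abort("empty positive pool")
  if (length(neg_genes) == 0) abort("empty negative pool")
  m <- ncol(V$V)
  s_pos <- colSums(V$V[pos_genes, , drop = FALSE] * pos_w)
  s_neg <- colSums(V$V[neg_genes, , drop = FALSE] * neg_w)
  structure(list(
    logp_pos = log((laplace + s_pos) / (m * laplace + sum(s_pos))),
    logp_neg = log((laplace + s_neg) / (m * laplace + sum(s_neg))),
    log_prior = log(0.5)
  ), class = "wnb_model")
}

#' @rdname wnb_fit
#' @param model a fitted `wnb_model`.
#' @param genes query gene ids.
#' @return for `wnb_posterior`, a tibble `gene`, `p_pos`, `p_neg`.
#' @export
wnb_posterior <- function(model, genes, V) {
  X <- V$V[genes, , drop = FALSE]
  lp <- model$log_prior + as.numeric(X %*% model$logp_pos)
  ln <- model$log_prior + as.numeric(X %*% model$logp_neg)
  p_pos <- vapply(seq_along(lp), function(i)
    exp(lp[i] - logsumexp(c(lp[i], ln[i]))), 0.0)
  tibble::tibble(gene = genes, p_pos = p_pos, p_neg = 1 - p_pos)
}

#' Partition unlabeled genes into likely-positive / likely-negative / weak
#'
#' Thresholds are the class-conditional means of the integrated score:
#' LP are the genes at or above the mean positive score, LN those at or
#' below the mean negative score, WN the rest. Invariant under positive
#' rescaling of the scores.
#'
#' @param u_prime remaining unlabeled genes.
#' @param int_score named numeric integrated scores.
#' @return a `level_partition`: list with `LP`, `LN`, `WN`.
#' @export
partition_levels <- function(u_prime, int_score) {
  s <- int_score[u_prime]
  pos <- s[s > 0]
  neg <- s[s < 0]
  mu_pos <- if (length(pos) > 0) mean(pos) else Inf
  mu_neg <- if (length(neg) > 0) mean(neg) else -Inf
  LP <- u_prime[s >= mu_pos]
  LN <- u_prime[s <= mu_neg]
  WN <- setdiff(u_prime, c(LP, LN))
  structure(list(LP = LP, LN = LN, WN = WN), class = "level_partition")
}

# --- weighted soft-margin SVM (primal, squared hinge) --------------------

# minimize 0.5 ||w||^2 + sum_i C_i * max(0, 1 - y_i f(x_i))^2
# linear: f(x) = x.w + b, solved over (w, b) by BFGS with analytic gradient.
# rbf: f(x) = sum_j beta_j K(x_j, x) + b with penalty 0.5 beta' K beta.
svm_primal_fit <- function(X, y, C, kernel = "linear", gamma = NULL) {
  n <- nrow(X)
  if (kernel == "linear") {
    p <- ncol(X)
    fn <- function(par) {
      w <- par[seq_len(p)]; b <- par[p + 1]
      marg <- 1 - y * (as.numeric(X %*% w) + b)
      act <- marg > 0
      0.5 * sum(w^2) + sum(C[act] * marg[act]^2)
    }
    gr <- function(par) {
      w <- par[seq_len(p)]; b <- par[p + 1]
      marg <- 1 - y * (as.numeric(X %*% w) + b)
      act <- marg > 0
      coefs <- ifelse(act, 2 * C * marg * y, 0)
      c(w - as.numeric(crossprod(X, coefs)), -sum(coefs))
    }
    fit <- optim(numeric(p + 1), fn, gr, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    list(kernel = "linear", w = fit$par[seq_len(p)], b = fit$par[p + 1])
  } else if (kernel == "rbf") {
    gamma <- gamma %||% (1 / ncol(X))
    K <- rbf_kernel(X, X, gamma)
    fn <- function(par) {
      beta <- par[seq_len(n)]; b <- par[n + 1]
      marg <- 1 - y * (as.numeric(K %*% beta) + b)
      act <- marg > 0
      0.5 * sum(beta * (K %*% beta)) + sum(C[act] * marg[act]^2)
    }
    gr <- function(par) {
      beta <- par[seq_len(n)]; b <- par[n + 1]
      marg <- 1 - y * (as.numeric(K %*% beta) + b)
      act <- marg > 0
      coefs <- ifelse(act, 2 * C * marg * y, 0)
      c(as.numeric(K %*% (beta - coefs)), -sum(coefs))
    }
    fit <- optim(numeric(n + 1), fn, gr, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    list(kernel = "rbf", beta = fit$par[seq_len(n)], b = fit$par[n + 1],
         X = X, gamma = gamma)
  } else {
    abort(sprintf("unknown kernel '%s'", kernel))
  }
}

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  D2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(D2, 0))
}

svm_decision <- function(fit, X) {
  if (fit$kernel == "linear") {
    as.numeric(X %*% fit$w) + fit$b
  } else {
    as.numeric(rbf_kernel(X, fit$X, fit$gamma) %*% fit$beta) + fit$b
  }
}

# Platt-style sigmoid calibration of decision values, with Platt's target
# smoothing so separable fits stay finite.
platt_fit <- function(f, y) {
  n_pos <- sum(y > 0); n_neg <- sum(y < 0)
  t <- ifelse(y > 0, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  # p = 1/(1+exp(z)); NLL = sum softplus(z) - (1-t) z, computed stably
  nll <- function(par) {
    z <- par[1] * f + par[2]
    sp <- pmax(z, 0) + log1p(exp(-abs(z)))
    sum(sp - (1 - t) * z)
  }
  fit <- optim(c(-1, 0), nll, method = "BFGS", control = list(maxit = 200))
  list(A = fit$par[1], B = fit$par[2])
}

platt_prob <- function(platt, f) {
  1 / (1 + exp(platt$A * f + platt$B))
}

#' Multi-level weighted support vector machine
#'
#' Soft-margin SVM over five training strata: P and LP carry label +1, RN,
#' LN and WN label -1, each with its own misclassification cost so that less
#' trustworthy labels incur smaller slack penalties. Costs are
#' `base_C * multiplier` with the per-set multipliers from the config; the
#' base cost is chosen by stratified internal cross-validation on F-measure
#' over `cost_grid` unless explicit per-set `costs` are supplied. Posteriors
#' come from a Platt-style sigmoid fitted on the training decision values.
#'
#' @param P,RN positive / reliable-negative gene sets (both non-empty
#'   together with the levels, one per class).
#' @param levels a `level_partition` (from [partition_levels()]).
#' @param V a `gene_feature_matrix`.
#' @param config an [epu_config()]; `config$svm` holds kernel, cost grid,
#'   level multipliers and CV fold count.
#' @param costs optional named per-set absolute costs
#'   (`c(P=, RN=, LP=, LN=, WN=)`) bypassing the grid search.
#' @return an `msvm_model`.
#' @export
msvm_fit <- function(P, RN, levels, V, config = epu_config(), costs = NULL) {
  sets <- list(P = P, LP = levels$LP, RN = RN, LN = levels$LN, WN = levels$WN)
  genes <- unlist(sets, use.names = FALSE)
  set_of <- rep(names(sets), lengths(sets))
  y <- ifelse(set_of %in% c("P", "LP"), 1, -1)
  if (!any(y > 0) || !any(y < 0)) abort("degenerate single-class training set")
  X <- V$V[genes, , drop = FALSE]
  kernel <- config$svm$kernel
  gamma <- config$svm$rbf_gamma
  mult <- config$svm$level_multipliers

  if (!is.null(costs)) {
    C <- unname(costs[set_of])
    best_C <- NA_real_
  } else {
    grid <- config$svm$cost_grid
    best_C <- select_base_cost(X, y, set_of, mult, grid, kernel, gamma,
                               n_folds = config$svm$cv_folds)
    C <- best_C * unname(mult[set_of])
  }
  fit <- svm_primal_fit(X, y, C, kernel, gamma)
  f <- svm_decision(fit, X)
  platt <- platt_fit(f, y)
  structure(list(fit = fit, platt = platt, genes = genes, y = y,
                 base_C = best_C, costs = setNames(C, genes)),
            class = "msvm_model")
}

select_base_cost <- function(X, y, set_of, mult, grid, kernel, gamma, n_folds = 3) {
  if (length(grid) == 1) return(grid)
  n_folds <- min(n_folds, sum(y > 0), sum(y < 0))
  if (n_folds < 2) return(grid[ceiling(length(grid) / 2)])
  # deterministic stratified folds: cycle fold ids within each class
  fold <- integer(length(y))
  fold[y > 0] <- rep_len(seq_len(n_folds), sum(y > 0))
  fold[y < 0] <- rep_len(seq_len(n_folds), sum(y < 0))
  scores <- vapply(grid, function(base_C) {
    C <- base_C * unname(mult[set_of])
    pred <- numeric(length(y))
    for (h in seq_len(n_folds)) {
      tr <- fold != h
      if (!any(y[tr] > 0) || !any(y[tr] < 0)) return(-1)
      f <- svm_primal_fit(X[tr, , drop = FALSE], y[tr], C[tr], kernel, gamma)
      pred[!tr] <- svm_decision(f, X[!tr, , drop = FALSE])
    }
    tp <- sum(pred > 0 & y > 0); fp <- sum(pred > 0 & y < 0)
    fn <- sum(pred <= 0 & y > 0)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f_measure(p, r)
  }, 0.0)
  grid[which.max(scores)]
}

#' @rdname msvm_fit
#' @param model a fitted `msvm_model`.
#' @param genes query gene ids.
#' @return for `msvm_posterior`, a tibble `gene`, `p_pos`, `p_neg`.
#' @export
msvm_posterior <- function(model, genes, V) {
  f <- svm_decision(model$fit, V$V[genes, , drop = FALSE])
  p <- platt_prob(model$platt, f)
  tibble::tibble(gene = genes, p_pos = p, p_neg = 1 - p)
}

#' @rdname msvm_fit
#' @export
msvm_decision_values <- function(model, genes, V) {
  setNames(svm_decision(model$fit, V$V[genes, , drop = FALSE]), genes)
}
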