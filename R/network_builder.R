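# Construction of the three gene similarity networks (PPI, co-expression,
# GO-feature distance) and the logistic-filtered phenotype network, plus the
# row-normalized transition form consumed by the random walk.

new_gene_network <- function(name, nodes, W) {
  dimnames(W) <- list(nodes, nodes)
  structure(list(name = name, nodes = nodes, W = W), class = "gene_network")
}

#' @exportS3Method base::print
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network:%s> %d nodes, %d edges\n", x$name,
              length(x$nodes), Matrix::nnzero(x$W) / 2))
  invisible(x)
}

#' Pearson similarity between two profiles
#'
#' Standard Pearson correlation, with the convention that a zero-variance
#' profile has similarity 0 to everything (flagged via the `zero_variance`
#' attribute) rather than NA.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return a number in \[-1, 1\].
#' @export
#'
#' @examples
#' pearson_similarity(c(1, 2, 3), c(2, 4, 6))   # 1
#' pearson_similarity(c(1, 2, 3), c(1, 3, 2))   # 0.5
pearson_similarity <- function(x, y) {
  if (length(x) != length(y)) abort("profile length mismatch")
  if (length(x) < 2) abort("profiles must have length >= 2")
  zv <- stats::sd(x) == 0 || stats::sd(y) == 0
  r <- if (zv) 0 else cor(x, y)
  structure(r, zero_variance = zv)
}

# Top-k neighbour selection with union symmetrization. `S` is a dense
# similarity (descending = closer) matrix with node names; returns a sparse
# symmetric weight matrix with zero diagonal, keeping an edge if it is in
# either endpoint's top-k list. Ties: descending score then ascending id.
knn_union_sparsify <- function(S, nodes, k) {
  n <- length(nodes)
  if (k <= 0) abort("k must be positive")
  k <- min(k, n - 1L)
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n)) {
    s <- S[i, ]
    s[i] <- -Inf
    ord <- order_desc_ties_asc(s, nodes)
    top <- ord[seq_len(k)]
    ii <- c(ii, rep.int(i, k)); jj <- c(jj, top)
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  A <- A + Matrix::t(A)
  A@x[] <- 1  # union mask
  W <- A * S
  Matrix::diag(W) <- 0
  Matrix::drop0(W)
}

#' Build the co-expression similarity network
#'
#' All-pairs Pearson similarity over expression profiles, sparsified by
#' keeping each gene's top-`k` most similar partners and symmetrizing by
#' union. Edge weights are the (signed) Pearson similarities; genes with a
#' constant profile have similarity 0 to all others.
#'
#' @param expr an `expression_table`.
#' @param k neighbours per gene (default 5; capped at n - 1).
#' @return a `gene_network` named `"GE"`.
#' @export
build_expression_network <- function(expr, k = 5) {
  nodes <- expr$genes
  X <- expr$values
  sds <- apply(X, 1, stats::sd)
  S <- suppressWarnings(cor(t(X)))
  S[is.na(S)] <- 0
  S[sds == 0, ] <- 0
  S[, sds == 0] <- 0
  W <- knn_union_sparsify(S, nodes, k)
  net <- new_gene_network("GE", nodes, W)
  attr(net, "zero_variance_genes") <- nodes[sds == 0]
  net
}

#' Build the GO similarity network
#'
#' Euclidean distance between genes on the GO blocks of the feature matrix,
#' converted to an edge weight w = 1 / (1 + Dis) in (0, 1\], sparsified to the
#' top-`k` nearest genes per gene and union-symmetrized.
#'
#' @param feat a `gene_feature_matrix` with a non-empty GO block.
#' @param k neighbours per gene (default 5).
#' @return a `gene_network` named `"GO"`.
#' @export
build_go_network <- function(feat, k = 5) {
  go_cols <- feat$kind %in% c("MF", "BP", "CC")
  if (!any(go_cols)) abort("feature matrix has an empty GO block")
  X <- feat$V[, go_cols, drop = FALSE]
  D <- as.matrix(dist(X))
  S <- 1 / (1 + D)
  W <- knn_union_sparsify(S, feat$genes, k)
  new_gene_network("GO", feat$genes, W)
}

#' Build the protein-interaction network
#'
#' Binary symmetric adjacency from a loaded edge set; no sparsification.
#' Nodes listed in `nodes` but absent from the edges get zero rows/columns.
#'
#' @param edges an `edge_set` (from [read_edge_list()]).
#' @param nodes optional node universe; defaults to the genes in `edges`.
#' @return a `gene_network` named `"PPI"`.
#' @export
build_ppi_network <- function(edges, nodes = NULL) {
  nodes <- nodes %||% sort(unique(c(edges$from, edges$to)))
  missing <- setdiff(c(edges$from, edges$to), nodes)
  if (length(missing) > 0) abort("edge endpoints outside the node universe")
  i <- match(edges$from, nodes)
  j <- match(edges$to, nodes)
  n <- length(nodes)
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(n, n), use.last.ij = TRUE)
  W@x[] <- 1
  Matrix::diag(W) <- 0
  new_gene_network("PPI", nodes, Matrix::drop0(W))
}

#' Logistic filtering of a phenotype similarity matrix
#'
#' Replaces every off-diagonal similarity s with L(s) = 1 / (1 + exp(c s + d))
#' and zeroes entries with L(s) < 0.5, so only confidently similar phenotype
#' pairs survive. With the default constants c = -15, d = log(9999), a
#' similarity of 0 maps to 1e-4 (filtered) and a similarity of 1 is retained.
#' The diagonal stays 1.
#'
#' @param sims a `pheno_sim`.
#' @param c,d logistic constants.
#' @return a `pheno_sim` holding the filtered values.
#' @export
filter_phenotype_network <- function(sims, c = -15, d = log(9999)) {
  L <- 1 / (1 + exp(c * sims$sims + d))
  L[L < 0.5] <- 0
  diag(L) <- 1
  new_pheno_sim(sims$phenotypes, L)
}

#' Transition matrix for the random walk
#'
#' Divides each row of W by its weighted degree and transposes, giving the
#' column-oriented transition form used by [rwr()]. For networks with
#' negative weights (co-expression), absolute values are used for both the
#' degree and the propagated weight when `use_abs` is `TRUE` (the default),
#' since a probability flow is ill-defined with mixed signs. Zero-degree
#' nodes map to all-zero columns.
#'
#' @param net a `gene_network`.
#' @param use_abs use absolute edge weights (default `TRUE`).
#' @return a `transition_matrix`: list with `nodes` and the sparse `Wt`.
#' @export
to_transition <- function(net, use_abs = TRUE) {
  W <- if (use_abs) abs(net$W) else net$W
  d <- Matrix::rowSums(if (use_abs) W else abs(W))
  inv <- ifelse(d > 0, 1 / d, 0)
  Wt <- Matrix::t(Matrix::Diagonal(x = inv) %*% W)
  dimnames(Wt) <- list(net$nodes, net$nodes)
  structure(list(nodes = net$nodes, Wt = Wt), class = "transition_matrix")
}
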