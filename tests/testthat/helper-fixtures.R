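# Shared fixtures and small independent oracles used across test files.

# Write an OBO file from a parent table and read it back through the package
# parser, so tests exercise the real IO path.
make_dag <- function(edges, namespace = "MF", obsolete = character()) {
  terms <- unique(c(edges$child, edges$parent))
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  con <- file(path, "w")
  writeLines("format-version: 1.2\n", con)
  for (tm in terms) {
    writeLines(c("[Term]", paste0("id: ", tm),
                 paste0("namespace: ", namespace)), con)
    e <- edges[edges$child == tm, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      if (e$type[i] == "is_a") writeLines(paste0("is_a: ", e$parent[i]), con)
      else writeLines(paste0("relationship: part_of ", e$parent[i]), con)
    }
    if (tm %in% obsolete) writeLines("is_obsolete: true", con)
    writeLines("", con)
  }
  close(con)
  read_ontology(path)[[namespace]]
}

# rank-based AUC: probability a positive outscores a negative
auc_score <- function(scores_pos, scores_neg) {
  r <- rank(c(scores_pos, scores_neg))
  n1 <- length(scores_pos); n2 <- length(scores_neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# small feature matrix around plain numeric data
fake_features <- function(X, kind = NULL) {
  genes <- rownames(X)
  kind <- kind %||% rep("MF", ncol(X))
  epulearn:::new_gene_feature_matrix(genes, kind,
                                     colnames(X) %||% paste0("f", seq_len(ncol(X))),
                                     X)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small synthetic bundle shared by the harness tests (built once per run)
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_genes = 90, n_disease = 14, n_tissues = 8,
                              n_phenotypes = 20, n_pheno_groups = 4,
                              n_decoys = 20, seed = 11)
      cache <<- generate_bundle(cfg)
    }
    cache
  }
})

# random sparse nonnegative symmetric network on n nodes
random_network <- function(n, p = 0.15, name = "PPI") {
  nodes <- sprintf("n%03d", seq_len(n))
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  hit <- ut & matrix(runif(n * n) < p, n, n)
  W[hit] <- runif(sum(hit))
  W <- W + t(W)
  epulearn:::new_gene_network(name, nodes, methods::as(W, "CsparseMatrix"))
}
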