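# Gene feature vectors: GO semantic-similarity features (Wang measure),
# binary protein-domain indicators and min-max scaled PPI topology
# statistics; plus discriminative GO feature selection and the positive
# representative vector.

# --- Wang semantic similarity -------------------------------------------

# Per-term semantic contributions: S-values over the term's ancestor closure
# (including itself). S(A) = 1; walking upward, S(t) = max over child edges
# c -> t inside the closure of w_edge * S(c), with w_edge 0.8 for is_a and
# 0.6 for part_of. Computed by fixed-point relaxation (cheap on small DAGs).
term_svalues <- function(term, dag, w_is_a = 0.8, w_part_of = 0.6) {
  if (!(term %in% dag$terms)) abort(sprintf("term %s not in namespace %s", term, dag$namespace))
  wmap <- c(is_a = w_is_a, part_of = w_part_of)
  sv <- c(1)
  names(sv) <- term
  edges <- dag$edges
  repeat {
    changed <- FALSE
    hit <- edges$child %in% names(sv)
    if (any(hit)) {
      e <- edges[hit, , drop = FALSE]
      cand <- wmap[e$type] * sv[e$child]
      upd <- tapply(cand, e$parent, max)
      for (p in names(upd)) {
        if (is.na(sv[p]) || upd[[p]] > sv[[p]] + 1e-15) {
          sv[p] <- upd[[p]]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  sv
}

#' Wang similarity between two ontology terms
#'
#' DAG-based semantic similarity: each term contributes S-values to its
#' ancestors, discounted along edges by 0.8 (is_a) or 0.6 (part_of); the
#' similarity is the summed S-values over the shared ancestors divided by the
#' two terms' total semantic values. Always in \[0, 1\], 1 on the diagonal.
#'
#' @param a,b term ids in the same namespace.
#' @param dag an `ontology_dag`.
#' @param w_is_a,w_part_of edge contribution factors.
#' @return a number in \[0, 1\].
#' @export
wang_term_similarity <- function(a, b, dag, w_is_a = 0.8, w_part_of = 0.6) {
  sa <- term_svalues(a, dag, w_is_a, w_part_of)
  sb <- term_svalues(b, dag, w_is_a, w_part_of)
  shared <- intersect(names(sa), names(sb))
  if (length(shared) == 0) return(0)
  sum(sa[shared] + sb[shared]) / (sum(sa) + sum(sb))
}

# All-pairs Wang similarity over a term set (one S-value computation per term)
term_similarity_matrix <- function(terms, dag, w_is_a = 0.8, w_part_of = 0.6) {
  svs <- lapply(terms, term_svalues, dag = dag,
                w_is_a = w_is_a, w_part_of = w_part_of)
  tot <- vapply(svs, sum, 0)
  n <- length(terms)
  M <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        shared <- intersect(names(svs[[i]]), names(svs[[j]]))
        M[i, j] <- M[j, i] <- if (length(shared) == 0) 0 else
          sum(svs[[i]][shared] + svs[[j]][shared]) / (tot[i] + tot[j])
      }
    }
  }
  dimnames(M) <- list(terms, terms)
  M
}

#' Similarity of a gene to a GO feature term
#'
#' The maximum Wang similarity between the feature term and any of the gene's
#' annotated terms in the same namespace; 0 for an unannotated gene.
#'
#' @param gene a gene id.
#' @param feature_term a term id in `dag`.
#' @param annots an `annotation_table` (gene -> terms).
#' @param dag the `ontology_dag` of the feature term's namespace.
#' @inheritParams wang_term_similarity
#' @return a number in \[0, 1\].
#' @export
gene_feature_value <- function(gene, feature_term, annots, dag,
                               w_is_a = 0.8, w_part_of = 0.6) {
  terms <- intersect(annots[[gene]] %||% character(), dag$terms)
  if (length(terms) == 0) return(0)
  max(vapply(terms, wang_term_similarity, 0, b = feature_term, dag = dag,
             w_is_a = w_is_a, w_part_of = w_part_of))
}

# genes x feature-terms block of Wang similarities, vectorized through a
# precomputed term-term similarity matrix over the union of feature terms and
# annotated terms.
go_feature_block <- function(genes, feature_terms, annots, dag,
                             w_is_a = 0.8, w_part_of = 0.6) {
  used <- sort(unique(intersect(
    unlist(annots[intersect(genes, names(annots))], use.names = FALSE),
    dag$terms)))
  all_terms <- sort(unique(c(feature_terms, used)))
  TS <- term_similarity_matrix(all_terms, dag, w_is_a, w_part_of)
  V <- matrix(0, length(genes), length(feature_terms),
              dimnames = list(genes, feature_terms))
  for (gi in seq_along(genes)) {
    terms <- intersect(annots[[genes[gi]]] %||% character(), dag$terms)
    if (length(terms) > 0) {
      block <- TS[terms, feature_terms, drop = FALSE]
      V[gi, ] <- apply(block, 2, max)
    }
  }
  V
}

#' Select the most discriminative GO feature terms
#'
#' Scores each candidate term by the absolute difference between its mean
#' gene-feature value over the positive genes and over the unlabeled genes,
#' and keeps the top `n` per namespace (all candidates when fewer). Ties are
#' broken by ascending term id.
#'
#' @param P,U disjoint, non-empty gene sets.
#' @param candidates candidate term ids (within `dag`).
#' @param annots an `annotation_table`.
#' @param dag an `ontology_dag`.
#' @param n number of features to keep (default 1000).
#' @inheritParams wang_term_similarity
#' @return character vector of selected terms, highest score first.
#' @export
select_go_features <- function(P, U, candidates, annots, dag, n = 1000,
                               w_is_a = 0.8, w_part_of = 0.6) {
  if (length(P) == 0 || length(U) == 0) abort("P and U must be non-empty")
  if (length(intersect(P, U)) > 0) abort("P and U must be disjoint")
  candidates <- sort(unique(candidates))
  VP <- go_feature_block(sort(unique(P)), candidates, annots, dag, w_is_a, w_part_of)
  VU <- go_feature_block(sort(unique(U)), candidates, annots, dag, w_is_a, w_part_of)
  score <- abs(colMeans(VP) - colMeans(VU))
  ord <- order_desc_ties_asc(score, candidates)
  candidates[ord[seq_len(min(n, length(candidates)))]]
}

#' PPI topology features
#'
#' Four statistics per gene on the PPI network: degree, mean neighbour
#' degree, local clustering coefficient, and an isolation indicator; each
#' column min-max scaled to \[0, 1\] over the gene universe.
#'
#' @param genes gene ids (rows of the result).
#' @param ppi a `gene_network`.
#' @return a genes x 4 matrix with columns `degree`, `mean_nbr_degree`,
#'   `clustering`, `isolated`.
#' @export
topology_features <- function(genes, ppi) {
  g <- igraph::graph_from_adjacency_matrix(ppi$W, mode = "undirected",
                                           weighted = NULL, diag = FALSE)
  deg <- igraph::degree(g)
  knn <- igraph::knn(g)$knn
  knn[is.na(knn) | is.nan(knn)] <- 0
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(cc) <- igraph::V(g)$name
  iso <- as.numeric(deg == 0)
  M <- cbind(degree = deg, mean_nbr_degree = knn, clustering = cc, isolated = iso)
  M <- apply(M, 2, function(col) {
    rng <- range(col)
    if (diff(rng) == 0) rep(0, length(col)) else (col - rng[1]) / diff(rng)
  })
  rownames(M) <- ppi$nodes
  out <- matrix(0, length(genes), 4,
                dimnames = list(genes, colnames(M)))
  present <- intersect(genes, ppi$nodes)
  out[present, ] <- M[present, , drop = FALSE]
  # genes absent from the PPI are isolated by definition
  absent <- setdiff(genes, ppi$nodes)
  if (length(absent) > 0 && any(iso == 1)) out[absent, "isolated"] <- max(M[, "isolated"])
  out
}

#' Build the full gene feature matrix
#'
#' Assembles the feature blocks in the fixed column order MF, BP, CC, DOMAIN,
#' TOPO. GO features are selected per namespace with [select_go_features()]
#' against the supplied P and U sets; domain features are binary indicators;
#' topology features come from [topology_features()].
#'
#' @param genes gene universe (rows).
#' @param go_annots gene -> GO term `annotation_table`.
#' @param ontology an `ontology_set` with namespaces `MF`, `BP`, `CC` (any
#'   subset present is used).
#' @param domain_annots gene -> domain `annotation_table` (may be `NULL`).
#' @param ppi `gene_network` for topology features (may be `NULL`).
#' @param P,U gene sets driving GO feature selection.
#' @param config an [epu_config()] list.
#' @return a `gene_feature_matrix`: list with `genes`, `kind` (per-column
#'   block label), `anchor` (per-column term/statistic name) and the dense
#'   matrix `V`.
#' @export
build_feature_matrix <- function(genes, go_annots, ontology, domain_annots,
                                 ppi, P, U, config = epu_config()) {
  w1 <- config$features$wang$w_is_a
  w2 <- config$features$wang$w_part_of
  n_go <- config$features$n_go_features
  blocks <- list(); kinds <- character(); anchors <- character()
  for (ns in c("MF", "BP", "CC")) {
    dag <- ontology[[ns]]
    if (is.null(dag)) next
    annotated <- unlist(go_annots, use.names = FALSE)
    candidates <- intersect(dag$terms, annotated)
    if (length(candidates) == 0) next
    sel <- select_go_features(P, U, candidates, go_annots, dag, n = n_go,
                              w_is_a = w1, w_part_of = w2)
    B <- go_feature_block(genes, sel, go_annots, dag, w1, w2)
    blocks <- c(blocks, list(B))
    kinds <- c(kinds, rep(ns, ncol(B)))
    anchors <- c(anchors, sel)
  }
  if (!is.null(domain_annots)) {
    doms <- sort(unique(unlist(domain_annots, use.names = FALSE)))
    if (length(doms) > 0) {
      D <- matrix(0, length(genes), length(doms), dimnames = list(genes, doms))
      for (gi in seq_along(genes)) {
        has <- intersect(domain_annots[[genes[gi]]] %||% character(), doms)
        D[gi, has] <- 1
      }
      blocks <- c(blocks, list(D))
      kinds <- c(kinds, rep("DOMAIN", length(doms)))
      anchors <- c(anchors, doms)
    }
  }
  if (!is.null(ppi)) {
    Tp <- topology_features(genes, ppi)
    blocks <- c(blocks, list(Tp))
    kinds <- c(kinds, rep("TOPO", ncol(Tp)))
    anchors <- c(anchors, colnames(Tp))
  }
  if (length(blocks) == 0) abort("no feature blocks could be built")
  V <- do.call(cbind, blocks)
  rownames(V) <- genes
  new_gene_feature_matrix(genes, kinds, anchors, V)
}

new_gene_feature_matrix <- function(genes, kind, anchor, V) {
  colnames(V) <- make.unique(paste(kind, anchor, sep = ":"))
  structure(list(genes = genes, kind = kind, anchor = anchor, V = V),
            class = "gene_feature_matrix")
}

#' @exportS3Method base::print
print.gene_feature_matrix <- function(x, ...) {
  tab <- table(factor(x$kind, levels = unique(x$kind)))
  cat(sprintf("<gene_feature_matrix> %d genes x %d features (%s)\n",
              length(x$genes), ncol(x$V),
              paste(sprintf("%s:%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Positive representative vector
#'
#' The mean feature vector of the positive genes; reliable negatives are the
#' unlabeled genes whose Euclidean distance to this vector exceeds the
#' unlabeled-set average.
#'
#' @param P non-empty positive gene set.
#' @param V a `gene_feature_matrix`.
#' @return numeric vector of length `ncol(V$V)`.
#' @export
positive_representative <- function(P, V) {
  if (length(P) == 0) abort("P must be non-empty")
  missing <- setdiff(P, V$genes)
  if (length(missing) > 0) abort("positive gene(s) missing from the feature matrix")
  colMeans(V$V[P, , drop = FALSE])
}
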