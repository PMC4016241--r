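# Seeding of the positive-unlabeled split: phenotype-derived candidate
# positives, distance-derived reliable negatives, and flow-balanced initial
# scores for the random walk.

#' Extract candidate positive genes from phenotype similarity
#'
#' A gene from the known-disease universe (outside P and `exclude`) becomes a
#' candidate positive when one of its phenotypes survives the logistic filter
#' against a phenotype of the query positives; its confidence score is the
#' maximal such filtered similarity (in (0, 1\]).
#'
#' @param P query positive genes.
#' @param assoc a `phenotype_assoc`.
#' @param sims a logistic-filtered `pheno_sim` (zeros mean "not similar").
#' @param exclude genes never eligible as candidates (defaults to `P`; pass
#'   the full declared positive set plus any held-out test genes to avoid
#'   information leaking through the seeds).
#' @return a tibble with columns `gene`, `cp_score`.
#' @export
extract_candidate_positives <- function(P, assoc, sims, exclude = P) {
  empty <- tibble::tibble(gene = character(), cp_score = double())
  ph_p <- unique(unlist(assoc$g2ph[intersect(P, names(assoc$g2ph))],
                        use.names = FALSE))
  if (length(ph_p) == 0) {
    warn("query positives have no phenotype associations; CP is empty")
    return(empty)
  }
  ph_p <- intersect(ph_p, sims$phenotypes)
  universe <- setdiff(names(assoc$g2ph), union(P, exclude))
  if (length(universe) == 0 || length(ph_p) == 0) return(empty)
  S <- sims$sims[, ph_p, drop = FALSE]
  scores <- vapply(universe, function(g) {
    ph_g <- intersect(assoc$g2ph[[g]], sims$phenotypes)
    if (length(ph_g) == 0) return(0)
    max(S[ph_g, , drop = FALSE])
  }, 0.0)
  scores <- unname(scores)
  keep <- scores > 0
  tibble::tibble(gene = universe[keep],
                 cp_score = pmin(scores[keep], 1)) |>
    dplyr::arrange(.data$gene)
}

#' Extract reliable negatives
#'
#' Unlabeled genes whose Euclidean distance to the positive representative
#' vector strictly exceeds the average distance of all unlabeled genes.
#'
#' @param U unlabeled gene set (non-empty).
#' @param pr positive representative vector (from
#'   [positive_representative()]).
#' @param V a `gene_feature_matrix`.
#' @return character vector of reliable-negative gene ids, with attributes
#'   `d_avg` and `distances` (named numeric over `U`).
#' @export
extract_reliable_negatives <- function(U, pr, V) {
  if (length(U) == 0) abort("U must be non-empty")
  X <- V$V[U, , drop = FALSE]
  d <- sqrt(rowSums((X - matrix(pr, nrow(X), ncol(X), byrow = TRUE))^2))
  d_avg <- mean(d)
  rn <- U[d > d_avg]
  structure(rn, d_avg = d_avg, distances = setNames(d, U))
}

#' Flow-balanced initial seed scores
#'
#' Positives get +1, candidate positives their phenotype-similarity score,
#' and every reliable negative the shared value -(total positive mass)/|RN|,
#' so the seed vector sums to zero and positive and negative flow are
#' balanced during propagation. Other genes start at 0.
#'
#' @param P positive genes.
#' @param cp tibble `gene`/`cp_score` (from
#'   [extract_candidate_positives()]), or `NULL` for none.
#' @param rn reliable-negative gene ids.
#' @param nodes optional gene universe over which to define the vector;
#'   defaults to the union of the seed sets.
#' @param balance_include_cp include the CP mass in the balanced total
#'   (default `TRUE`); with `FALSE` only |P| is balanced.
#' @return a named numeric vector of class `seed_scores`.
#' @export
init_seed_scores <- function(P, cp = NULL, rn = character(), nodes = NULL,
                             balance_include_cp = TRUE) {
  cp_genes <- if (is.null(cp)) character() else cp$gene
  cp_scores <- if (is.null(cp)) numeric() else cp$cp_score
  nodes <- nodes %||% sort(unique(c(P, cp_genes, rn)))
  r0 <- setNames(numeric(length(nodes)), nodes)
  r0[P] <- 1
  r0[cp_genes] <- cp_scores
  pos_mass <- length(P) + if (balance_include_cp) sum(cp_scores) else 0
  if (length(rn) == 0) {
    warn("no reliable negatives: seed scores are unbalanced")
  } else {
    r0[rn] <- -pos_mass / length(rn)
  }
  structure(r0, class = "seed_scores")
}
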