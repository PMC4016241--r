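# Synthetic data bundle with planted structure: a disease module that is
# densely wired in the PPI graph, co-expressed across tissues, annotated
# from a compact GO clade and a shared domain pool, and linked to one
# phenotype group. Half of the true module (by default) is withheld from the
# positive list: these hidden positives sit in the unlabeled universe and
# are the currency for testing PU behaviour.

#' Synthetic study configuration
#'
#' @param n_genes gene universe size (default 600).
#' @param n_disease true disease-module size (default one tenth of the
#'   genes).
#' @param n_tissues expression conditions (default 16, a whole-body tissue
#'   panel design).
#' @param n_phenotypes,n_pheno_groups phenotype universe and its group
#'   structure (default 100 phenotypes in 5 groups; group 1 is the disease
#'   group).
#' @param p_in,p_out within-module / background PPI edge probabilities
#'   (defaults 0.2 / 0.01; `p_out < p_in` required).
#' @param expr_corr_in target within-module expression correlation
#'   (default 0.7).
#' @param go_depth,go_branching per-namespace ontology tree shape
#'   (default depth 3, branching 3: 40 terms per namespace).
#' @param n_domains protein-domain universe size (default 30).
#' @param n_decoys background genes given phenotype associations to
#'   non-disease groups (default 100); a handful also touch the disease
#'   group so candidate-positive extraction is exercised.
#' @param feature_noise_sd probability that a module gene draws an
#'   annotation (GO term or domain) from the background pool instead of the
#'   module pool (default 0.1).
#' @param hidden_frac fraction of true positives withheld from the positive
#'   list (default 0.5; strictly inside (0, 1)).
#' @param seed RNG seed (default 42).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 600L, n_disease = round(n_genes / 10),
                             n_tissues = 16L, n_phenotypes = 100L,
                             n_pheno_groups = 5L, p_in = 0.2, p_out = 0.01,
                             expr_corr_in = 0.7, go_depth = 3L,
                             go_branching = 3L, n_domains = 30L,
                             n_decoys = 100L, feature_noise_sd = 0.1,
                             hidden_frac = 0.5, seed = 42L) {
  cfg <- list(n_genes = as.integer(n_genes), n_disease = as.integer(n_disease),
              n_tissues = as.integer(n_tissues),
              n_phenotypes = as.integer(n_phenotypes),
              n_pheno_groups = as.integer(n_pheno_groups),
              p_in = p_in, p_out = p_out, expr_corr_in = expr_corr_in,
              go_depth = as.integer(go_depth),
              go_branching = as.integer(go_branching),
              n_domains = as.integer(n_domains), n_decoys = as.integer(n_decoys),
              feature_noise_sd = feature_noise_sd, hidden_frac = hidden_frac,
              seed = as.integer(seed))
  if (!(cfg$p_out >= 0 && cfg$p_out < cfg$p_in && cfg$p_in <= 1))
    abort("need 0 <= p_out < p_in <= 1")
  if (!(cfg$hidden_frac > 0 && cfg$hidden_frac < 1))
    abort("hidden_frac must be in (0, 1)")
  if (cfg$n_disease >= cfg$n_genes) abort("disease module larger than universe")
  if (any(c(cfg$n_genes, cfg$n_disease, cfg$n_tissues, cfg$n_phenotypes,
            cfg$n_pheno_groups) <= 0)) abort("all counts must be positive")
  structure(cfg, class = "synthetic_config")
}

# one random tree-plus-part_of ontology namespace
make_namespace <- function(ns, depth, branching, part_of_frac = 0.1) {
  terms <- sprintf("%s:%04d", ns, 1L)
  level <- 0L
  parent <- NA_character_
  levels_list <- list(terms)
  edges <- tibble::tibble(child = character(), parent = character(),
                          type = character())
  idx <- 1L
  for (d in seq_len(depth)) {
    prev <- levels_list[[d]]
    cur <- character()
    for (p in prev) {
      kids <- sprintf("%s:%04d", ns, idx + seq_len(branching))
      idx <- idx + branching
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        child = kids, parent = p, type = "is_a"))
      cur <- c(cur, kids)
    }
    levels_list[[d + 1L]] <- cur
  }
  all_terms <- unlist(levels_list, use.names = FALSE)
  # extra part_of edges from deeper terms to strictly shallower non-ancestors
  deep <- unlist(levels_list[-1], use.names = FALSE)
  extra <- deep[runif(length(deep)) < part_of_frac]
  for (tm in extra) {
    lev <- which(vapply(levels_list, function(l) tm %in% l, TRUE))
    shallow <- unlist(levels_list[seq_len(lev - 1L)], use.names = FALSE)
    tgt <- sample(shallow, 1L)
    if (!any(edges$child == tm & edges$parent == tgt)) {
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        child = tm, parent = tgt, type = "part_of"))
    }
  }
  list(dag = new_ontology_dag(ns, all_terms, edges),
       levels = levels_list)
}

#' Generate a synthetic data bundle
#'
#' Pure function of its configuration (seeded): produces the complete input
#' set the pipeline consumes (PPI edges, expression table, ontology, GO and
#' domain annotations, phenotype associations and similarities, declared
#' positive list) plus the ground truth, with a planted disease module whose
#' members interact, co-express, share a GO clade and a domain pool, and
#' whose declared members link to the disease phenotype group.
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_bundle` list; `truth` is a tibble
#'   (`gene`, `is_disease`, `is_hidden`) kept outside the pipeline inputs.
#' @export
generate_bundle <- function(config = synthetic_config()) {
  with_seed_(config$seed, generate_bundle_impl(config))
}

generate_bundle_impl <- function(cfg) {
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  module <- sort(sample(genes, cfg$n_disease))
  n_declared <- max(1L, round((1 - cfg$hidden_frac) * cfg$n_disease))
  declared <- sort(sample(module, n_declared))
  hidden <- setdiff(module, declared)
  background <- setdiff(genes, module)

  # --- PPI: planted partition -------------------------------------------
  idx <- seq_len(cfg$n_genes)
  in_module <- genes %in% module
  pairs <- utils::combn(idx, 2)
  p_edge <- ifelse(in_module[pairs[1, ]] & in_module[pairs[2, ]],
                   cfg$p_in, cfg$p_out)
  keep <- runif(ncol(pairs)) < p_edge
  ppi_edges <- tibble::tibble(from = genes[pairs[1, keep]],
                              to = genes[pairs[2, keep]],
                              weight = 1)

  # --- expression: shared module factor + noise -------------------------
  rho <- cfg$expr_corr_in
  z <- rnorm(cfg$n_tissues)
  X <- matrix(rnorm(cfg$n_genes * cfg$n_tissues), cfg$n_genes, cfg$n_tissues)
  X[in_module, ] <- sqrt(rho) * matrix(z, sum(in_module), cfg$n_tissues,
                                       byrow = TRUE) +
    sqrt(1 - rho) * X[in_module, ]
  expr <- new_expression_table(genes, sprintf("tissue%02d", seq_len(cfg$n_tissues)), X)

  # --- ontology + GO annotations ----------------------------------------
  noise_p <- min(0.5, cfg$feature_noise_sd)
  nss <- lapply(c(MF = "MF", BP = "BP", CC = "CC"), make_namespace,
                depth = cfg$go_depth, branching = cfg$go_branching)
  ontology <- structure(lapply(nss, `[[`, "dag"), class = "ontology_set")
  go_annots <- setNames(vector("list", cfg$n_genes), genes)
  for (ns in names(nss)) {
    levels_list <- nss[[ns]]$levels
    all_terms <- setdiff(unlist(levels_list, use.names = FALSE), levels_list[[1]])
    # module clade: first child of the root and its descendants
    clade_root <- levels_list[[2]][1]
    clade <- clade_root
    repeat {
      kids <- nss[[ns]]$dag$edges$child[
        nss[[ns]]$dag$edges$parent %in% clade & nss[[ns]]$dag$edges$type == "is_a"]
      new <- setdiff(kids, clade)
      if (length(new) == 0) break
      clade <- c(clade, new)
    }
    for (g in genes) {
      pool <- if (g %in% module && runif(1) >= noise_p) clade else all_terms
      go_annots[[g]] <- c(go_annots[[g]], sample(pool, 1L))
    }
  }
  go_annots <- lapply(go_annots, unique)
  go_annots <- structure(go_annots, class = "annotation_table")

  # --- domains -----------------------------------------------------------
  domains <- sprintf("DOM%03d", seq_len(cfg$n_domains))
  module_doms <- domains[seq_len(min(6L, cfg$n_domains))]
  domain_annots <- lapply(setNames(genes, genes), function(g) {
    if (g %in% module && runif(1) >= noise_p) {
      sample(module_doms, min(2L, length(module_doms)))
    } else {
      sample(domains, 2L)
    }
  })
  domain_annots <- structure(domain_annots, class = "annotation_table")

  # --- phenotypes --------------------------------------------------------
  phenos <- sprintf("ph%03d", seq_len(cfg$n_phenotypes))
  group <- rep_len(seq_len(cfg$n_pheno_groups), cfg$n_phenotypes)
  group <- sort(group)
  S <- matrix(0, cfg$n_phenotypes, cfg$n_phenotypes)
  same <- outer(group, group, "==")
  ut <- upper.tri(S)
  S[ut & same] <- runif(sum(ut & same), 0.7, 1)
  S[ut & !same] <- runif(sum(ut & !same), 0, 0.3)
  S <- S + t(S)
  diag(S) <- 1
  pheno_sim <- new_pheno_sim(phenos, S)

  disease_phenos <- phenos[group == 1L]
  other_phenos <- phenos[group != 1L]
  assoc_ph <- character(); assoc_g <- character()
  for (g in declared) {
    k <- sample(1:2, 1L)
    assoc_ph <- c(assoc_ph, sample(disease_phenos, k))
    assoc_g <- c(assoc_g, rep(g, k))
  }
  decoys <- sort(sample(background, min(cfg$n_decoys, length(background))))
  for (i in seq_along(decoys)) {
    k <- sample(1:2, 1L)
    assoc_ph <- c(assoc_ph, sample(other_phenos, k))
    assoc_g <- c(assoc_g, rep(decoys[i], k))
    if (i <= 5L) {  # a few decoys touch the disease group
      assoc_ph <- c(assoc_ph, sample(disease_phenos, 1L))
      assoc_g <- c(assoc_g, decoys[i])
    }
  }
  ph2g <- lapply(split(assoc_g, assoc_ph), unique)
  g2ph <- lapply(split(assoc_ph, assoc_g), unique)
  phenotype_assoc <- structure(
    list(ph2g = ph2g[order(names(ph2g), method = "radix")],
         g2ph = g2ph[order(names(g2ph), method = "radix")]),
    class = "phenotype_assoc")

  truth <- tibble::tibble(gene = genes,
                          is_disease = as.integer(genes %in% module),
                          is_hidden = as.integer(genes %in% hidden))

  structure(list(
    genes = genes,
    ppi_edges = ppi_edges,
    expression = expr,
    ontology = ontology,
    go_annotations = go_annots,
    domain_annotations = domain_annots,
    phenotype_assoc = phenotype_assoc,
    phenotype_sim = pheno_sim,
    positives = declared,
    truth = truth,
    config = cfg
  ), class = "synthetic_bundle")
}

#' @exportS3Method base::print
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_bundle> %d genes, %d true disease genes ",
                     "(%d declared, %d hidden), %d PPI edges, %d phenotypes\n"),
              length(x$genes), sum(x$truth$is_disease), length(x$positives),
              sum(x$truth$is_hidden), nrow(x$ppi_edges),
              length(x$phenotype_sim$phenotypes)))
  invisible(x)
}

#' Write a bundle to disk in the pipeline's file formats
#'
#' Every file is loadable with the package readers; the ground truth goes to
#' a separate `truth.tsv` that the pipeline never reads.
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) abort(sprintf("cannot create directory %s", dir))
  write_edge_list(bundle$ppi_edges, file.path(dir, "ppi_edges.tsv"))
  write_expression(bundle$expression, file.path(dir, "expression.tsv"))
  write_ontology(bundle$ontology, file.path(dir, "ontology.obo"))
  write_annotations(bundle$go_annotations, file.path(dir, "go_annotations.tsv"))
  write_annotations(bundle$domain_annotations, file.path(dir, "domain_annotations.tsv"))
  write_phenotype_assoc(bundle$phenotype_assoc, file.path(dir, "phenotype_genes.tsv"))
  write_pheno_sim(bundle$phenotype_sim, file.path(dir, "phenotype_sim.tsv"))
  write_gene_list(bundle$positives, file.path(dir, "positives.txt"))
  write_gene_list(bundle$genes, file.path(dir, "genes.txt"))
  truth <- bundle$truth
  writeLines(c("gene\tis_disease\tis_hidden",
               sprintf("%s\t%d\t%d", truth$gene, truth$is_disease,
                       truth$is_hidden)),
             file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a bundle directory written by [write_bundle()]
#'
#' @param dir bundle directory.
#' @param with_truth also load `truth.tsv` (default `FALSE`: the pipeline's
#'   view of the data has no ground truth).
#' @return a `synthetic_bundle` (with `truth = NULL` unless requested).
#' @export
read_bundle <- function(dir, with_truth = FALSE) {
  truth <- NULL
  if (with_truth) {
    tt <- utils::read.delim(file.path(dir, "truth.tsv"), sep = "\t",
                            stringsAsFactors = FALSE)
    truth <- tibble::as_tibble(tt)
  }
  structure(list(
    genes = read_gene_list(file.path(dir, "genes.txt")),
    ppi_edges = read_edge_list(file.path(dir, "ppi_edges.tsv")),
    expression = read_expression(file.path(dir, "expression.tsv")),
    ontology = read_ontology(file.path(dir, "ontology.obo")),
    go_annotations = read_annotations(file.path(dir, "go_annotations.tsv")),
    domain_annotations = read_annotations(file.path(dir, "domain_annotations.tsv")),
    phenotype_assoc = read_phenotype_assoc(file.path(dir, "phenotype_genes.tsv")),
    phenotype_sim = read_pheno_sim(file.path(dir, "phenotype_sim.tsv")),
    positives = read_gene_list(file.path(dir, "positives.txt")),
    truth = truth,
    config = NULL
  ), class = "synthetic_bundle")
}
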