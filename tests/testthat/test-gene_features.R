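# three-term DAG: A and B are is_a children of root R
three_term_dag <- function() {
  make_dag(data.frame(child = c("A", "B"), parent = "R", type = "is_a"))
}

test_that("Wang similarity matches hand recursion on small DAGs", {
  dag <- three_term_dag()
  expect_equal(wang_term_similarity("A", "A", dag), 1.0)
  # S_A = {A: 1, R: 0.8}; shared {R}: (0.8 + 0.8) / (1.8 + 1.8)
  expect_equal(wang_term_similarity("A", "B", dag), 1.6 / 3.6)
  # part_of edge discounts by 0.6 instead of 0.8
  dagp <- make_dag(data.frame(child = c("A", "B"), parent = "R",
                              type = c("is_a", "part_of")))
  expect_equal(wang_term_similarity("A", "B", dagp),
               (0.8 + 0.6) / (1.8 + 1.6))
})

test_that("terms with disjoint ancestor sets have similarity zero", {
  dag <- make_dag(data.frame(child = c("A", "B"), parent = c("R1", "R2"),
                             type = "is_a"))
  expect_equal(wang_term_similarity("A", "B", dag), 0.0)
})

test_that("Wang similarity is symmetric and bounded on random DAGs", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      # random layered DAG
      n_mid <- sample(3:5, 1); n_leaf <- sample(4:8, 1)
      mids <- sprintf("M%d", seq_len(n_mid))
      leaves <- sprintf("L%d", seq_len(n_leaf))
      edges <- rbind(
        data.frame(child = mids, parent = "R", type = "is_a"),
        data.frame(child = leaves, parent = sample(mids, n_leaf, TRUE),
                   type = sample(c("is_a", "part_of"), n_leaf, TRUE)))
      # some leaves get a second parent
      extra <- leaves[runif(n_leaf) < 0.4]
      if (length(extra) > 0) {
        edges <- rbind(edges, data.frame(child = extra,
                                         parent = sample(mids, length(extra), TRUE),
                                         type = "part_of"))
        edges <- unique(edges)
      }
      dag <- make_dag(edges)
      terms <- dag$terms
      for (i in 1:8) {
        ab <- sample(terms, 2)
        s1 <- wang_term_similarity(ab[1], ab[2], dag)
        s2 <- wang_term_similarity(ab[2], ab[1], dag)
        expect_equal(s1, s2)
        expect_gte(s1, 0); expect_lte(s1, 1)
        expect_equal(wang_term_similarity(ab[1], ab[1], dag), 1.0)
      }
    }
  })
})

test_that("gene-to-feature similarity is the max over annotated terms", {
  dag <- three_term_dag()
  annots <- structure(list(g1 = "A", g2 = c("A", "B"), g3 = character()),
                      class = "annotation_table")
  expect_equal(gene_feature_value("g1", "A", annots, dag), 1.0)
  expect_equal(gene_feature_value("g3", "A", annots, dag), 0.0)
  expect_equal(gene_feature_value("gX", "A", annots, dag), 0.0)  # unannotated
  # exhaustive check: max over {sim(A, B), sim(B, B)}
  expected <- max(wang_term_similarity("A", "B", dag),
                  wang_term_similarity("B", "B", dag))
  expect_equal(gene_feature_value("g2", "B", annots, dag), expected)
})

test_that("GO feature selection ranks by class-mean separation", {
  dag <- make_dag(data.frame(child = sprintf("T%d", 1:6), parent = "R",
                             type = "is_a"))
  P <- sprintf("p%d", 1:3)
  U <- sprintf("u%d", 1:3)
  annots <- structure(c(
    setNames(rep(list("T1"), 3), P),   # T1 annotates every P gene
    setNames(rep(list("T2"), 3), U)),  # T2 annotates every U gene
    class = "annotation_table")
  sel <- select_go_features(P, U, sprintf("T%d", 1:6), annots, dag, n = 6)
  # perfect separators first (tie between T1 and T2 broken by term id)
  expect_equal(sel[1:2], c("T1", "T2"))

  # ranking equals a brute-force score sort
  oracle_score <- vapply(sprintf("T%d", 1:6), function(tau) {
    vp <- vapply(P, gene_feature_value, 0, feature_term = tau,
                 annots = annots, dag = dag)
    vu <- vapply(U, gene_feature_value, 0, feature_term = tau,
                 annots = annots, dag = dag)
    abs(mean(vp) - mean(vu))
  }, 0.0)
  oracle <- names(sort(-oracle_score))
  ord <- order(-oracle_score, names(oracle_score))
  expect_equal(sel, names(oracle_score)[ord])
  # order of P and U must not matter
  expect_equal(select_go_features(rev(P), rev(U), sprintf("T%d", 1:6),
                                  annots, dag, n = 6), sel)
  expect_error(select_go_features(character(), U, "T1", annots, dag), "non-empty")
  expect_error(select_go_features(P, P, "T1", annots, dag), "disjoint")
})

test_that("topology features match hand counts on small graphs", {
  # triangle A-B-C plus pendant D-A plus isolated E
  ed <- tibble::tibble(from = c("A", "B", "A", "A"), to = c("B", "C", "C", "D"),
                       weight = 1)
  net <- build_ppi_network(ed, nodes = c("A", "B", "C", "D", "E"))
  M <- topology_features(c("A", "B", "C", "D", "E"), net)
  raw_deg <- c(A = 3, B = 2, C = 2, D = 1, E = 0)
  expect_equal(M[, "degree"], (raw_deg - 0) / 3)   # min-max over universe
  expect_equal(unname(M["E", ]), c(0, 0, 0, 1))    # isolated gene
  # triangle member clustering: B has neighbours {A, C} which are connected
  expect_equal(M["B", "clustering"], 1.0)
  # degree column equals adjacency row sums (up to scaling)
  expect_equal(M[, "degree"] * 3, Matrix::rowSums(net$W)[rownames(M)])
})

test_that("positive representative is the mean vector", {
  X <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  V <- fake_features(X)
  expect_equal(unname(positive_representative(c("a", "b"), V)), c(0.5, 0.5))
  expect_equal(unname(positive_representative("a", V)), c(1, 0))
  expect_equal(positive_representative(c("b", "a"), V),
               positive_representative(c("a", "b"), V))
  expect_error(positive_representative(character(), V), "non-empty")
})

test_that("feature matrix blocks have the declared order and ranges", {
  b <- small_bundle()
  P <- b$positives
  U <- setdiff(b$genes, union(P, names(b$phenotype_assoc$g2ph)))[1:10]
  ppi <- build_ppi_network(b$ppi_edges, nodes = b$genes)
  V <- build_feature_matrix(b$genes, b$go_annotations, b$ontology,
                            b$domain_annotations, ppi, P, U,
                            epu_config(features = list(n_go_features = 5)))
  expect_equal(unique(V$kind), c("MF", "BP", "CC", "DOMAIN", "TOPO"))
  expect_equal(sum(V$kind == "MF"), 5)
  expect_true(all(V$V >= 0 & V$V <= 1))
  expect_equal(V$genes, b$genes)
  # deterministic given identical inputs
  V2 <- build_feature_matrix(b$genes, b$go_annotations, b$ontology,
                             b$domain_annotations, ppi, P, U,
                             epu_config(features = list(n_go_features = 5)))
  expect_identical(V$V, V2$V)
})
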