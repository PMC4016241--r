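test_that("pearson similarity matches hand values and flags zero variance", {
  expect_equal(as.numeric(pearson_similarity(c(1, 2, 3), c(2, 4, 6))), 1.0)
  expect_equal(as.numeric(pearson_similarity(c(1, 2, 3), c(3, 2, 1))), -1.0)
  expect_equal(as.numeric(pearson_similarity(c(1, 2, 3), c(1, 3, 2))), 0.5)
  flat <- pearson_similarity(c(1, 1, 1), c(1, 2, 3))
  expect_equal(as.numeric(flat), 0)
  expect_true(attr(flat, "zero_variance"))
  expect_error(pearson_similarity(1:3, 1:4), "mismatch")
})

test_that("pearson similarity is shift/scale invariant up to sign", {
  withr::with_seed(5, {
    for (i in 1:20) {
      x <- rnorm(10); y <- rnorm(10); a <- runif(1, -3, 3)
      if (a == 0) next
      expect_equal(as.numeric(pearson_similarity(x, a * y + 2)),
                   sign(a) * as.numeric(pearson_similarity(x, y)),
                   tolerance = 1e-12)
    }
  })
})

expression_fixture <- function(n = 10, tissues = 6, seed = 3) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * tissues), n)
    rownames(X) <- sprintf("g%02d", seq_len(n))
    X
  })
}

test_that("expression network keeps planted co-expressed pairs and caps k", {
  X <- expression_fixture()
  X[2, ] <- X[1, ] * 2 + 0.01 * rnorm(ncol(X))  # planted r ~ 1 pair
  et <- epulearn:::new_expression_table(rownames(X), colnames(X) <-
                                          sprintf("t%d", 1:ncol(X)), X)
  net <- build_expression_network(et, k = 3)
  expect_gt(net$W["g01", "g02"], 0.99)
  expect_true(Matrix::isSymmetric(net$W))
  expect_equal(Matrix::diag(net$W), setNames(rep(0, 10), rownames(X)))

  # 3 genes with k larger than n-1: complete graph
  et3 <- epulearn:::new_expression_table(c("a", "b", "c"), c("t1", "t2", "t3"),
                                         matrix(rnorm(9), 3))
  net3 <- build_expression_network(et3, k = 5)
  expect_equal(Matrix::nnzero(net3$W), 6)
  expect_error(build_expression_network(et3, k = 0), "k must be positive")
})

test_that("constant expression profiles are flagged and harmless", {
  X <- expression_fixture()
  X[4, ] <- 7
  et <- epulearn:::new_expression_table(rownames(X), sprintf("t%d", 1:ncol(X)), X)
  net <- build_expression_network(et, k = 3)
  expect_equal(attr(net, "zero_variance_genes"), "g04")
  expect_equal(Matrix::rowSums(abs(net$W))[["g04"]], 0)  # all its sims are 0
})

test_that("expression kNN edges match a brute-force all-pairs oracle", {
  X <- expression_fixture(n = 12, seed = 9)
  et <- epulearn:::new_expression_table(rownames(X), sprintf("t%d", 1:ncol(X)), X)
  k <- 4
  net <- build_expression_network(et, k = k)
  S <- cor(t(X))
  nodes <- rownames(X)
  # oracle: union of per-gene top-k by descending r, ties by ascending id
  in_topk <- matrix(FALSE, 12, 12, dimnames = list(nodes, nodes))
  for (i in seq_len(12)) {
    s <- S[i, ]; s[i] <- -Inf
    top <- nodes[order(-s, nodes)][seq_len(k)]
    in_topk[i, top] <- TRUE
  }
  expected <- in_topk | t(in_topk)
  actual <- as.matrix(net$W != 0)
  expect_equal(actual, expected)
  # weights are the raw similarities
  expect_equal(as.matrix(net$W)[expected], S[expected])
})

test_that("GO network weights follow w = 1/(1 + distance)", {
  X <- matrix(c(0, 0, 0, 0, 1, 0, 3, 4, 0), 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  V <- fake_features(X)
  net <- build_go_network(V, k = 2)
  expect_equal(net$W["a", "b"], 0.5)          # distance 1
  expect_equal(net$W["a", "c"], 1 / 6)        # distance 5
  Vsame <- fake_features(X[c(1, 1), , drop = FALSE] * 0)
  # identical rows: distance 0 -> weight 1
  rownames(Vsame$V) <- Vsame$genes <- c("x", "y")
  net2 <- build_go_network(Vsame, k = 1)
  expect_equal(net2$W["x", "y"], 1.0)
  expect_error(build_go_network(fake_features(X, kind = rep("TOPO", 3))),
               "empty GO block")
})

test_that("GO kNN sets equal the exhaustive distance oracle", {
  withr::with_seed(21, {
    X <- matrix(runif(6 * 4), 6, dimnames = list(sprintf("g%d", 1:6), NULL))
  })
  V <- fake_features(X)
  net <- build_go_network(V, k = 2)
  D <- as.matrix(dist(X))
  nodes <- rownames(X)
  in_topk <- matrix(FALSE, 6, 6, dimnames = list(nodes, nodes))
  for (i in 1:6) {
    d <- D[i, ]; d[i] <- Inf
    top <- nodes[order(d, nodes)][1:2]
    in_topk[i, top] <- TRUE
  }
  expected <- in_topk | t(in_topk)
  expect_equal(as.matrix(net$W != 0), expected)
})

test_that("PPI network is binary, symmetric, honours isolated nodes", {
  ed <- tibble::tibble(from = c("A", "B", "A"), to = c("B", "C", "C"),
                       weight = 1)
  net <- build_ppi_network(ed, nodes = c("A", "B", "C", "D"))
  expect_equal(net$W["A", "B"], 1)
  expect_equal(net$W["B", "A"], 1)
  expect_equal(Matrix::rowSums(net$W)[["D"]], 0)
  # triangle: degree vector (2, 2, 2)
  expect_equal(unname(Matrix::rowSums(net$W)[c("A", "B", "C")]), c(2, 2, 2))
})

test_that("logistic filtering keeps high similarities and zeroes low ones", {
  S <- matrix(c(1, 0.9, 0, 0.9, 1, 0.2, 0, 0.2, 1), 3,
              dimnames = list(sprintf("p%d", 1:3), sprintf("p%d", 1:3)))
  ps <- epulearn:::new_pheno_sim(rownames(S), S)
  f <- filter_phenotype_network(ps)
  L <- function(s) 1 / (1 + exp(-15 * s + log(9999)))
  expect_equal(f$sims["p1", "p2"], L(0.9))      # retained (> 0.5)
  expect_equal(f$sims["p1", "p3"], 0)           # L(0) = 1e-4, filtered
  expect_equal(f$sims["p2", "p3"], 0)           # L(0.2) < 0.5, filtered
  expect_equal(diag(f$sims), setNames(rep(1, 3), rownames(S)))
  expect_true(isSymmetric(f$sims))
  expect_gt(L(1), 0.5)                          # s = 1 always survives
})

test_that("transition matrices are column-normalized with zero-degree safety", {
  ed <- tibble::tibble(from = c("A", "B"), to = c("B", "C"), weight = 1)
  net <- build_ppi_network(ed, nodes = c("A", "B", "C", "D"))
  tm <- to_transition(net)
  expect_equal(as.numeric(tm$Wt[, "B"]), c(0.5, 0, 0.5, 0))  # path centre
  expect_equal(sum(abs(tm$Wt[, "D"])), 0)                    # zero-degree
  cs <- Matrix::colSums(tm$Wt)
  expect_equal(unname(cs[c("A", "B", "C")]), c(1, 1, 1))
  # degree conservation: total column mass = number of nonzero-degree nodes
  expect_equal(sum(cs), 3)
})

test_that("built networks are symmetric with zero diagonal (property)", {
  withr::with_seed(31, {
    for (i in 1:5) {
      n <- sample(8:20, 1)
      X <- matrix(rnorm(n * 5), n, dimnames = list(sprintf("g%02d", 1:n), NULL))
      et <- epulearn:::new_expression_table(rownames(X), sprintf("t%d", 1:5), X)
      net <- build_expression_network(et, k = 3)
      expect_true(Matrix::isSymmetric(net$W))
      expect_equal(max(abs(Matrix::diag(net$W))), 0)
      gn <- build_go_network(fake_features(abs(X)), k = 3)
      expect_true(Matrix::isSymmetric(gn$W))
      expect_equal(max(abs(Matrix::diag(gn$W))), 0)
    }
  })
})
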