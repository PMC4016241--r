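test_that("WKNN accumulates signed score mass over the k neighbours", {
  # geometry: query q at origin; neighbours at increasing distance
  X <- rbind(q = c(0, 0), a = c(1, 0), b = c(0, 1.1), c = c(1.2, 0),
             d = c(5, 5))
  V <- fake_features(X)
  int <- c(a = 0.6, b = 0.2, c = -0.2, d = -9)
  post <- wknn_posterior("q", c("a", "b", "c", "d"), int, V, k = 3)
  expect_equal(post$p_pos, 0.8 / 1.0)       # (0.6 + 0.2) / (0.8 + 0.2)
  expect_equal(post$p_pos + post$p_neg, 1)
  # all-positive neighbourhood
  post2 <- wknn_posterior("q", c("a", "b", "c"), c(a = 1, b = 1, c = 1), V, k = 3)
  expect_equal(post2$p_pos, 1.0)
  # all-zero neighbour scores -> (0.5, 0.5)
  post3 <- wknn_posterior("q", c("a", "b", "c"), c(a = 0, b = 0, c = 0), V, k = 3)
  expect_equal(post3$p_pos, 0.5)
  expect_error(wknn_posterior("q", c("a", "b"), int, V, k = 0), "positive")
  expect_error(wknn_posterior("q", c("a", "b"), int, V, k = 5), "exceeds")
})

test_that("WKNN equals the exhaustive nearest-neighbour oracle", {
  withr::with_seed(71, {
    n <- 100
    X <- matrix(rnorm(n * 6), n, dimnames = list(sprintf("g%03d", 1:n), NULL))
    V <- fake_features(X)
    int <- setNames(rnorm(n), rownames(X))
    train <- rownames(X)[1:80]
    queries <- rownames(X)[81:100]
    for (k in c(1, 3, 5)) {
      post <- wknn_posterior(queries, train, int, V, k = k)
      for (qi in seq_along(queries)) {
        q <- queries[qi]
        d <- sqrt(colSums((t(X[train, ]) - X[q, ])^2))
        nb <- train[order(d, train)][1:k]
        s <- int[nb]
        pos <- sum(s[s >= 0]); neg <- sum(abs(s[s < 0]))
        expected <- if (pos + neg == 0) 0.5 else pos / (pos + neg)
        expect_equal(post$p_pos[qi], expected)
      }
    }
  })
})

test_that("weighted naive Bayes matches a hand-computed log-space oracle", {
  X <- rbind(p1 = c(1, 0, 0.5), n1 = c(0, 1, 0.2),
             u1 = c(0.8, 0.1, 0), u2 = c(0.1, 0.9, 0.3),
             t1 = c(0.6, 0.2, 0.1))
  V <- fake_features(X)
  int <- c(u1 = 0.5, u2 = -0.25)
  model <- wnb_fit("p1", "n1", c("u1", "u2"), int, V, laplace = 1)
  post <- wnb_posterior(model, "t1", V)
  # oracle: weighted multinomial counts with Laplace 1, priors 0.5
  s_pos <- 1 * X["p1", ] + 0.5 * X["u1", ]
  s_neg <- 1 * X["n1", ] + 0.25 * X["u2", ]
  lp_pos <- log((1 + s_pos) / (3 + sum(s_pos)))
  lp_neg <- log((1 + s_neg) / (3 + sum(s_neg)))
  lp <- log(0.5) + sum(X["t1", ] * lp_pos)
  ln <- log(0.5) + sum(X["t1", ] * lp_neg)
  expect_equal(post$p_pos, exp(lp) / (exp(lp) + exp(ln)), tolerance = 1e-9)
  expect_equal(post$p_pos + post$p_neg, 1)
})

test_that("naive Bayes is symmetric and directionally sound", {
  # perfectly symmetric pools: a symmetric test gene scores (0.5, 0.5)
  X <- rbind(p = c(1, 0), n = c(0, 1), t = c(0.5, 0.5))
  V <- fake_features(X)
  model <- wnb_fit("p", "n", character(), numeric(), V)
  post <- wnb_posterior(model, "t", V)
  expect_equal(post$p_pos, 0.5, tolerance = 1e-12)
  # a feature present only in the positive pool pushes p_pos above 0.5
  X2 <- rbind(p = c(1, 0.2), n = c(0, 0.2), t = c(1, 0))
  model2 <- wnb_fit("p", "n", character(), numeric(), fake_features(X2))
  post2 <- wnb_posterior(model2, "t", fake_features(X2))
  expect_gt(post2$p_pos, 0.5)
  expect_error(wnb_fit(character(), "n", character(), numeric(), V),
               "positive pool")
  expect_error(wnb_fit("p", character(), character(), numeric(), V),
               "negative pool")
})

test_that("level partition uses class-conditional mean thresholds", {
  u <- sprintf("u%d", 1:4)
  int <- setNames(c(0.9, 0.1, -0.1, -0.9), u)
  lv <- partition_levels(u, int)
  expect_equal(lv$LP, "u1")
  expect_equal(lv$LN, "u4")
  expect_setequal(lv$WN, c("u2", "u3"))
  # all equal and positive: everything is LP
  int2 <- setNames(rep(0.4, 4), u)
  lv2 <- partition_levels(u, int2)
  expect_equal(lv2$LP, u)
  expect_length(lv2$LN, 0)
  # invariant under positive rescaling
  lv3 <- partition_levels(u, int * 17)
  expect_equal(lv3, lv)
})

separable_fixture <- function() {
  withr::with_seed(91, {
    pos <- matrix(rnorm(20, mean = 2, sd = 0.3), 10)
    neg <- matrix(rnorm(20, mean = -2, sd = 0.3), 10)
    X <- rbind(pos, neg)
    rownames(X) <- c(sprintf("p%d", 1:10), sprintf("n%d", 1:10))
    X
  })
}

test_that("multi-level SVM separates a separable fixture at large cost", {
  X <- separable_fixture()
  V <- fake_features(X)
  P <- sprintf("p%d", 1:10)
  RN <- sprintf("n%d", 1:10)
  lv <- structure(list(LP = character(), LN = character(), WN = character()),
                  class = "level_partition")
  costs <- c(P = 100, RN = 100, LP = 50, LN = 50, WN = 25)
  model <- msvm_fit(P, RN, lv, V, costs = costs)
  dec <- msvm_decision_values(model, c(P, RN), V)
  expect_true(all(dec[P] > 0))
  expect_true(all(dec[RN] < 0))
  post <- msvm_posterior(model, c(P, RN), V)
  expect_true(all(post$p_pos >= 0 & post$p_pos <= 1))
  expect_equal(post$p_pos + post$p_neg, rep(1, 20))
  expect_true(all(post$p_pos[1:10] > 0.5))
  expect_error(msvm_fit(P, character(), lv, V, costs = costs), "single-class")
})

test_that("zero-cost weak negatives drop out of the SVM fit", {
  X <- separable_fixture()
  # move two negatives near the boundary and call them WN
  X[c("n9", "n10"), ] <- matrix(rnorm(4, 0, 0.1), 2)
  V <- fake_features(X)
  P <- sprintf("p%d", 1:10)
  RN <- sprintf("n%d", 1:8)
  lv_with <- structure(list(LP = character(), LN = character(),
                            WN = c("n9", "n10")), class = "level_partition")
  lv_without <- structure(list(LP = character(), LN = character(),
                               WN = character()), class = "level_partition")
  m1 <- msvm_fit(P, RN, lv_with, V,
                 costs = c(P = 5, RN = 5, LP = 5, LN = 5, WN = 0))
  m2 <- msvm_fit(P, RN, lv_without, V,
                 costs = c(P = 5, RN = 5, LP = 5, LN = 5, WN = 0))
  expect_equal(m1$fit$w, m2$fit$w, tolerance = 1e-5)
  expect_equal(m1$fit$b, m2$fit$b, tolerance = 1e-5)
})

test_that("duplicating a training point equals doubling its cost", {
  X <- rbind(p1 = c(1, 1), p2 = c(1.5, 0.8), n1 = c(-1, -1), n2 = c(-0.8, -1.2))
  lv0 <- structure(list(LP = character(), LN = character(), WN = character()),
                   class = "level_partition")
  # duplicate n2 as an extra negative with the same cost
  Xdup <- rbind(X, n2b = X["n2", ])
  m_dup <- msvm_fit(c("p1", "p2"), c("n1", "n2", "n2b"), lv0,
                    fake_features(Xdup),
                    costs = c(P = 2, RN = 2, LP = 2, LN = 2, WN = 2))
  # single point with doubled cost via per-set costs: put n2 in LN at 2x
  lv_ln <- structure(list(LP = character(), LN = "n2", WN = character()),
                     class = "level_partition")
  m_2c <- msvm_fit(c("p1", "p2"), "n1", lv_ln, fake_features(X),
                   costs = c(P = 2, RN = 2, LP = 2, LN = 4, WN = 2))
  expect_equal(m_dup$fit$w, m_2c$fit$w, tolerance = 1e-5)
  expect_equal(m_dup$fit$b, m_2c$fit$b, tolerance = 1e-5)
})

test_that("all three models emit valid posteriors on random fixtures", {
  withr::with_seed(47, {
    n <- 40
    X <- matrix(runif(n * 5), n, dimnames = list(sprintf("g%02d", 1:n), NULL))
    V <- fake_features(X)
    int <- setNames(rnorm(n, sd = 0.5), rownames(X))
    P <- rownames(X)[1:6]; RN <- rownames(X)[7:14]
    up <- rownames(X)[15:30]
    lv <- partition_levels(up, int)
    q <- rownames(X)[31:40]
    posts <- list(
      wknn_posterior(q, c(P, RN, up), int, V, k = 3),
      wnb_posterior(wnb_fit(P, RN, up, int, V), q, V),
      msvm_posterior(msvm_fit(P, RN, lv, V), q, V)
    )
    for (p in posts) {
      expect_true(all(p$p_pos >= 0 & p$p_neg >= 0))
      expect_equal(p$p_pos + p$p_neg, rep(1, 10))
    }
  })
})

test_that("models rank hidden positives above negatives on separated data", {
  # integrated score perfectly separates the hidden classes
  withr::with_seed(83, {
    n <- 60
    lab <- rep(c(1, -1), each = n / 2)
    # classes differ in feature composition (first two vs last two features)
    X <- matrix(rnorm(n * 4, mean = c(lab, lab, -lab, -lab)), n,
                dimnames = list(sprintf("g%02d", 1:n), NULL))
    X <- pmin(pmax((X + 4) / 8, 0), 1)  # keep features nonnegative
    V <- fake_features(X)
    int <- setNames(lab * runif(n, 0.2, 1), rownames(X))
    P <- rownames(X)[1:6]; RN <- rownames(X)[31:36]
    held_pos <- rownames(X)[7:16]; held_neg <- rownames(X)[37:46]
    up <- setdiff(rownames(X), c(P, RN, held_pos, held_neg))
    lv <- partition_levels(up, int)
    pool <- c(P, RN, up)
    q <- c(held_pos, held_neg)
    posts <- list(
      WKNN = wknn_posterior(q, pool, int, V, k = 3),
      WNB = wnb_posterior(wnb_fit(P, RN, up, int, V), q, V),
      MSVM = msvm_posterior(msvm_fit(P, RN, lv, V), q, V)
    )
    for (nm in names(posts)) {
      s <- posts[[nm]]$p_pos
      expect_gt(auc_score(s[1:10], s[11:20]), 0.8)
    }
  })
})
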