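test_that("fern models have the promised structure", {
  d <- planted_dataset(n = 30, p = 20, seed = 2)$dataset
  m <- train_ferns(d, depth = 3, n_ferns = 50, seed = 1)
  expect_equal(dim(m$feat), c(50L, 3L))
  expect_equal(length(m$logp), 50 * 2^3 * 2)
  # every leaf's probabilities exponentiate-and-sum to 1
  lp <- array(m$logp, c(2, 2^3, 50)) # class fastest, then leaf, then fern
  sums <- apply(exp(lp), c(2, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # bag and oob cover the training samples for every fern
  expect_true(all(vapply(m$oob, function(o) all(o %in% 1:30), logical(1))))

  m1 <- train_ferns(d, depth = 1, n_ferns = 1, seed = 1)
  expect_equal(length(m1$logp), 1 * 2 * 2) # a single two-leaf stump
  m7 <- train_ferns(d, depth = 7, n_ferns = 2, seed = 1)
  expect_equal(length(m7$logp), 2 * 2^7 * 2) # 128-row leaf tables
})

test_that("training is deterministic under a fixed seed", {
  d <- planted_dataset(n = 30, p = 20, seed = 2)$dataset
  m1 <- train_ferns(d, depth = 4, n_ferns = 100, seed = 9)
  m2 <- train_ferns(d, depth = 4, n_ferns = 100, seed = 9)
  expect_identical(m1[c("feat", "thr", "logp")], m2[c("feat", "thr", "logp")])
  i1 <- ferns_importance(m1, d, seed = 3)$scores
  i2 <- ferns_importance(m2, d, seed = 3)$scores
  expect_identical(i1, i2)
})

test_that("MAP voting returns the arg-max class, ties to the lowest index", {
  d <- planted_dataset(n = 30, p = 20, seed = 2)$dataset
  m <- train_ferns(d, depth = 2, n_ferns = 30, seed = 5)
  pr <- predict(m, d)
  sc <- selstab:::cpp_ferns_scores(m$feat, m$thr, m$logp, m$depth, 2,
                                   d$expression)
  expect_equal(as.integer(pr), max.col(sc, ties.method = "first"))
  # constructed tie: two ferns with identical splits but class-swapped leaf
  # tables cancel exactly
  mt <- m
  mt$feat <- m$feat[c(1, 1), , drop = FALSE]
  mt$thr <- m$thr[c(1, 1), , drop = FALSE]
  lp1 <- log(matrix(c(0.9, 0.1, 0.8, 0.2, 0.3, 0.7, 0.4, 0.6), 2, 4))
  mt$logp <- c(lp1, lp1[2:1, ]) # fern 2 swaps the class rows of fern 1
  mt$n_ferns <- 2L
  expect_true(all(predict(mt, d) == mt$classes[1]))
  expect_error(predict(m, d$expression[, 1:5]), "expects")
})

test_that("a perfectly separating gene yields perfect training accuracy", {
  # the only gene is a label copy: any in-range threshold separates classes
  set.seed(4)
  y <- factor(rep(c("a", "b"), each = 15))
  X <- cbind(copy = as.numeric(y == "b") + rnorm(30, sd = 1e-6))
  d <- expression_dataset(X, y)
  m <- train_ferns(d, depth = 1, n_ferns = 500, seed = 8)
  expect_equal(mean(predict(m, d) == y), 1)
})

test_that("importance is 0 for unused genes and constant genes", {
  d <- planted_dataset(n = 30, p = 40, seed = 3)$dataset
  m <- train_ferns(d, depth = 2, n_ferns = 3, seed = 1) # uses <= 6 genes
  sc <- ferns_importance(m, d, seed = 2)$scores
  used <- unique(as.vector(m$feat)) + 1L
  expect_true(all(sc[-used] == 0))
  expect_true(any(sc[used] != 0))

  # permuting a constant gene changes nothing, so its contribution is 0
  Xc <- d$expression
  Xc[, 1] <- 5
  dc <- expression_dataset(Xc, d$labels)
  mc <- train_ferns(dc, depth = 2, n_ferns = 300, seed = 2)
  scc <- ferns_importance(mc, dc, seed = 3)$scores
  expect_equal(unname(scc[1]), 0)
})

test_that("noise genes have importance centred on 0", {
  scores <- vapply(1:15, function(s) {
    d <- planted_dataset(n = 40, p = 30, k_rel = 0, seed = s)$dataset
    mean(ferns_importance(train_ferns(d, 3, 200, seed = s), d,
                          seed = s + 100)$scores)
  }, numeric(1))
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores)), 4 * se + 1e-4)
})

test_that("larger ensembles stabilise the importance of a planted gene", {
  g <- planted_dataset(n = 50, p = 30, k_rel = 1, delta = 2, seed = 6)
  d <- g$dataset
  one <- function(K, s)
    ferns_importance(train_ferns(d, 3, K, seed = s), d,
                     seed = s + 1)$scores[g$truth$relevant_ids]
  v_small <- var(vapply(1:12, function(s) one(100, s), numeric(1)))
  v_large <- var(vapply(1:12, function(s) one(1500, s), numeric(1)))
  expect_lt(v_large, v_small)
})
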