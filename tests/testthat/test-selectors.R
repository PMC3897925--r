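test_that("shadows double the gene count and permute per column", {
  d <- planted_dataset(n = 30, p = 7, seed = 1)$dataset
  sh <- add_shadows(d, seed = 2)
  expect_equal(length(sh$data$gene_ids), 14)
  X <- sh$data$expression
  for (j in 1:7) # each shadow is a permutation of exactly its parent
    expect_equal(sort(unname(X[, 7 + j])), sort(unname(X[, j])))
  # a 1-gene dataset gets exactly 2 columns; a constant gene's shadow is
  # identical to it
  y <- factor(rep(c("a", "b"), each = 5))
  d1 <- expression_dataset(matrix(3, 10, 1), y)
  sh1 <- add_shadows(d1, seed = 1)
  expect_equal(ncol(sh1$data$expression), 2L)
  expect_equal(sh1$data$expression[, 1], sh1$data$expression[, 2],
               ignore_attr = TRUE)
})

test_that("a shadow of a strongly informative gene is null-associated", {
  g <- planted_dataset(n = 40, p = 5, k_rel = 1, delta = 5, seed = 3)
  d <- g$dataset
  y <- d$labels
  pv <- vapply(1:1000, function(s) {
    sh <- add_shadows(d, seed = s)
    t_p(sh$data$expression[, 5 + 1], y) # shadow of rel1
  }, numeric(1))
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.02)
})

test_that("Boruta state machine: statuses partition, one-iteration run is empty", {
  d <- planted_dataset(n = 40, p = 30, seed = 4)$dataset
  prov <- importance_ferns(3, 300)
  b1 <- boruta_select(d, prov, max_iterations = 1, seed = 1)
  expect_false(any(b1$selected)) # nothing reaches significance in 1 round
  expect_true(all(b1$state$status == "undecided"))

  b <- boruta_select(d, prov, max_iterations = 30, seed = 1)
  st <- table(b$state$status)
  expect_equal(sum(st), 30)
  expect_equal(sum(b$selected), unname(st["confirmed"]))
  expect_true(all(b$state$hits <= b$state$iterations))
})

test_that("Boruta confirms a label-copy gene and survives added noise", {
  hits <- vapply(1:8, function(s) {
    d <- label_copy_dataset(n = 40, p_noise = 80, seed = s)
    b <- boruta_select(d, importance_ferns(3, 500), max_iterations = 40,
                       seed = s)
    b$selected["copy"]
  }, logical(1))
  expect_gte(sum(hits), 7)
  # monotonicity: tripling the noise dimension keeps the power high
  hits_wide <- vapply(1:8, function(s) {
    d <- label_copy_dataset(n = 40, p_noise = 240, seed = s)
    b <- boruta_select(d, importance_ferns(3, 500), max_iterations = 40,
                       seed = s)
    b$selected["copy"]
  }, logical(1))
  expect_gte(sum(hits_wide), 7)
})

test_that("shadow t-test selection has working alpha edges", {
  d <- planted_dataset(n = 40, p = 20, seed = 5)$dataset
  prov <- importance_ferns(3, 300)
  expect_false(any(ace_select(d, prov, n_iterations = 5, alpha = 0,
                              seed = 1)$selected))
  a1 <- ace_select(d, prov, n_iterations = 5, alpha = 1, seed = 1)
  expect_true(all(a1$selected[is.finite(a1$p_values) & a1$p_values < 1]))
  expect_error(ace_select(d, prov, n_iterations = 1), "n_iterations >= 2")
})

test_that("shadow t-test finds a label-copy gene", {
  found <- vapply(1:8, function(s) {
    d <- label_copy_dataset(n = 40, p_noise = 60, seed = s)
    ace_select(d, importance_ferns(3, 500), n_iterations = 10,
               seed = s)$selected["copy"]
  }, logical(1))
  expect_gte(sum(found), 7)
})

test_that("degenerate equal-score genes get p-value 1, never selected", {
  d <- planted_dataset(n = 20, p = 6, seed = 6)$dataset
  # provider scoring every gene and shadow identically
  flat <- function(data, seed) setNames(rep(1, length(data$gene_ids)),
                                        data$gene_ids)
  a <- ace_select(d, flat, n_iterations = 5, seed = 1)
  expect_true(all(a$p_values == 1))
  expect_false(any(a$selected))
})

test_that("RFE schedule follows the power-of-two contraction", {
  expect_identical(rfe_schedule(8), c(8L, 4L))
  expect_identical(rfe_schedule(2000),
                   c(2000L, 1024L, 512L, 256L, 128L, 64L, 32L, 16L, 8L, 4L))
  # property: every step lands on the largest power of 2 strictly below
  set.seed(7)
  for (p in sample(5:5000, 25)) {
    s <- rfe_schedule(p)
    expect_equal(s[1], p)
    expect_equal(s[length(s)], 4L)
    for (i in seq_along(s)[-1]) {
      expect_true(bitwAnd(s[i], s[i] - 1L) == 0L) # power of two
      expect_lt(s[i], s[i - 1])
      expect_gte(2L * s[i], s[i - 1]) # largest such power
    }
  }
})

test_that("RFE keeps a perfectly separating gene and sizes its trace", {
  d <- label_copy_dataset(n = 40, p_noise = 63, seed = 8)
  r <- rfe_select(d, importance_ferns(3, 500), n_boot = 5,
                  n_trees_eval = 100, seed = 2)
  expect_identical(r$trace$size, c(64L, 32L, 16L, 8L, 4L))
  expect_true(r$selected["copy"])
  expect_lte(r$trace$error[r$trace$size == 4],
             r$trace$error[r$trace$size == 64] + 0.05)
  # ties at the cut keep lower column indices
  tied <- function(data, seed) setNames(rep(1, length(data$gene_ids)),
                                        data$gene_ids)
  r2 <- rfe_select(d, tied, n_boot = 2, n_trees_eval = 50, seed = 3)
  expect_identical(which(unname(r2$selected)), seq_len(sum(r2$selected)))
})
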