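test_that("train and test indices are disjoint in every iteration", {
  g <- planted_dataset(n = 30, p = 20, seed = 1)
  plan <- make_bootstrap_plan(30, 8, seed = 2, labels = g$dataset$labels)
  for (i in 1:8)
    expect_length(intersect(unique(plan$resamples[[i]]),
                            plan$oob_sets[[i]]), 0)
  sel <- selection_matrix(matrix(TRUE, 8, 20), "all",
                          g$dataset$gene_ids)
  ev <- post_selection_error(g$dataset, plan, sel, n_trees = 50, seed = 3)
  expect_length(ev$rates, 8)
  expect_true(all(ev$rates >= 0 & ev$rates <= 1, na.rm = TRUE))
})

test_that("an empty selection predicts the training majority class", {
  labels <- factor(c("a", "a", "a", "a", "b", "b"))
  X <- matrix(rnorm(12), 6, 2)
  d <- expression_dataset(X, labels)
  plan <- structure(
    list(n_iterations = 1L, resamples = list(c(1L, 2L, 3L, 1L, 5L, 6L)),
         oob_sets = list(4L), n_samples = 6L, seed = 1L),
    class = "BootstrapPlan")
  sel <- selection_matrix(matrix(FALSE, 1, 2), "empty", d$gene_ids)
  # training majority is "a"; the only oob sample is labelled "a" -> error 0
  ev <- post_selection_error(d, plan, sel, n_trees = 10, seed = 1)
  expect_equal(ev$rates, 0)
  # same plan but oob sample of class "b" -> error 1
  plan$resamples <- list(c(1L, 2L, 3L, 4L, 5L, 1L))
  plan$oob_sets <- list(6L)
  ev2 <- post_selection_error(d, plan, sel, n_trees = 10, seed = 1)
  expect_equal(ev2$rates, 1)
})

test_that("a selection holding a label-copy gene yields near-zero error", {
  oks <- vapply(1:8, function(s) {
    d <- label_copy_dataset(n = 30, p_noise = 10, seed = s)
    plan <- make_bootstrap_plan(30, 5, seed = s, labels = d$labels)
    ind <- matrix(FALSE, 5, 11); ind[, 1] <- TRUE
    ev <- post_selection_error(d, plan,
                               selection_matrix(ind, "copy", d$gene_ids),
                               n_trees = 100, seed = s + 50)
    all(ev$rates == 0, na.rm = TRUE)
  }, logical(1))
  expect_gte(sum(oks), 7)
})

test_that("signed-rank p-values match the classical test", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    ours <- selstab:::signed_rank_p(x, y)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE,
                         alternative = "greater"))$p.value
    expect_equal(ours, ref, tolerance = 1e-10)
  }
  # tied magnitudes take the corrected normal path, like the classical test
  x <- c(1, 2, 3, 4, 5, 6); y <- x - c(1, 1, 2, 2, 3, 3)
  expect_equal(selstab:::signed_rank_p(x, y),
               suppressWarnings(stats::wilcox.test(
                 x, y, paired = TRUE, alternative = "greater"))$p.value,
               tolerance = 1e-10)
})

test_that("method comparison flags only genuinely worse methods", {
  mk <- function(id, rates) structure(
    list(method_id = id, rates = rates, test_sizes = rep(10, length(rates))),
    class = "ErrorVector")
  base <- runif(30, 0.05, 0.2)
  # identical errors: never significantly worse
  r <- compare_methods(list(mk("a", base), mk("b", base)))
  expect_equal(r$table$p_value[r$table$method == "b"], 1)
  expect_false(any(r$table$worse_than_best))
  # everywhere-worse by distinct amounts: significant after Holm
  worse <- base + seq(0.01, 0.3, length.out = 30)
  r2 <- compare_methods(list(mk("good", base), mk("bad", worse)))
  expect_equal(r2$best_method, "good")
  expect_true(r2$table$worse_than_best[r2$table$method == "bad"])
  # symmetric wins and losses of equal magnitude: p near 0.5
  d <- rep(c(0.01, -0.01, 0.02, -0.02, 0.03, -0.03), 5)
  r3 <- compare_methods(list(mk("a", base), mk("b", base + d)))
  pb <- r3$table$p_value[!is.na(r3$table$p_value)]
  expect_gt(pb, 0.3)
  expect_lt(pb, 0.7)
})

test_that("identical per-iteration selections cannot differ significantly", {
  d <- planted_dataset(n = 30, p = 15, seed = 5)$dataset
  plan <- make_bootstrap_plan(30, 6, seed = 6, labels = d$labels)
  ind <- matrix(runif(6 * 15) < 0.4, 6, 15)
  e1 <- post_selection_error(d, plan, selection_matrix(ind, "m1", d$gene_ids),
                             n_trees = 50, seed = 7)
  e2 <- post_selection_error(d, plan, selection_matrix(ind, "m2", d$gene_ids),
                             n_trees = 50, seed = 7)
  r <- compare_methods(list(e1, e2))
  expect_false(any(r$table$worse_than_best))
})
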