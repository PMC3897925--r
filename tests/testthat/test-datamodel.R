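test_that("expression_dataset enforces its invariants", {
  X <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
  y <- c("a", "a", "b", "b")
  d <- expression_dataset(X, y)
  expect_s3_class(d, "ExpressionDataset")
  expect_equal(dim(d), c(4L, 3L))
  expect_equal(d$gene_ids, c("g1", "g2", "g3"))

  Xna <- X; Xna[2, 3] <- NA
  expect_error(expression_dataset(Xna, y), "sample 2, gene 3")
  expect_error(expression_dataset(X, c("a", "a", "a", "a")), ">=2 classes")
  expect_error(expression_dataset(X, c("a", "a", "a", "b")), ">=2 samples")
  colnames(X) <- c("g1", "g1", "g3")
  expect_error(expression_dataset(X, y), "duplicate gene id")
})

test_that("read_expression parses TSV and CSV with both label specs", {
  dir <- withr::local_tempdir()
  X <- matrix(c(1.5, 2, 3, 4, 5, 6, 7, 8), 4, 2)
  tsv <- file.path(dir, "expr.tsv")
  writeLines(c("g1\tg2", apply(X, 1, paste, collapse = "\t")), tsv)
  labf <- file.path(dir, "labels.txt")
  writeLines(c("a", "a", "a", "b"), labf)
  expect_error(read_expression(tsv, labf), ">=2 samples")
  writeLines(c("a", "a", "b", "b"), labf)
  d <- read_expression(tsv, labf)
  expect_equal(dim(d), c(4L, 2L))
  expect_equal(unname(d$expression[, 1]), c(1.5, 2, 3, 4))

  # combined CSV with a label column, delimiter auto-detected
  csv <- file.path(dir, "expr.csv")
  writeLines(c("g1,g2,cls", "1,5,a", "2,6,a", "3,7,b", "4,8,b"), csv)
  d2 <- read_expression(csv, "cls")
  expect_equal(d2$gene_ids, c("g1", "g2"))
  expect_equal(unname(d2$expression[, 2]), c(5, 6, 7, 8))
  expect_equal(as.character(d2$labels), c("a", "a", "b", "b"))

  # transposed orientation: genes are rows, first column holds gene ids
  gtsv <- file.path(dir, "genes_rows.tsv")
  writeLines(c("id\ts1\ts2\ts3\ts4", "g1\t1\t2\t3\t4", "g2\t5\t6\t7\t8"),
             gtsv)
  d3 <- read_expression(gtsv, labf, orientation = "genes-as-rows")
  expect_equal(d3$gene_ids, c("g1", "g2"))
  expect_equal(unname(d3$expression["s2", ]), c(2, 6))

  # NA cell is rejected with its location
  bad <- file.path(dir, "bad.tsv")
  writeLines(c("g1\tg2", "1\tNA", "2\t5", "3\t6", "4\t7"), bad)
  expect_error(read_expression(bad, labf), "row 1, column g2")
})

test_that("bootstrap plans are complementary, deterministic, seed-sensitive", {
  plan <- make_bootstrap_plan(25, 12, seed = 42)
  expect_equal(plan$n_iterations, 12L)
  for (i in 1:12) {
    r <- plan$resamples[[i]]
    expect_length(r, 25)
    expect_setequal(c(unique(r), plan$oob_sets[[i]]), 1:25)
    expect_length(intersect(unique(r), plan$oob_sets[[i]]), 0)
  }
  expect_identical(plan$resamples,
                   make_bootstrap_plan(25, 12, seed = 42)$resamples)
  expect_false(identical(plan$resamples,
                         make_bootstrap_plan(25, 12, seed = 43)$resamples))
  expect_error(make_bootstrap_plan(25, 0), "n_iterations")

  # single sample: every resample is that sample, oob always empty
  p1 <- make_bootstrap_plan(1, 5, seed = 1)
  expect_true(all(vapply(p1$resamples, identical, logical(1), 1L)))
  expect_true(all(lengths(p1$oob_sets) == 0))
})

test_that("mean oob fraction matches the (1 - 1/n)^n closed form", {
  plan <- make_bootstrap_plan(100, 1000, seed = 7)
  frac <- mean(lengths(plan$oob_sets)) / 100
  expect_lt(abs(frac - (1 - 1 / 100)^100), 0.01)
})

test_that("degenerate single-class resamples are redrawn when labels given", {
  # 2 samples of class b among 10: single-class resamples are common
  labels <- factor(c(rep("a", 8), rep("b", 2)))
  suppressWarnings(
    plan <- make_bootstrap_plan(10, 50, seed = 3, labels = labels))
  ok <- vapply(plan$resamples,
               function(r) length(unique(labels[r])) >= 2, logical(1))
  expect_true(all(ok))
})

test_that("selection matrices round-trip losslessly and write byte-stably", {
  set.seed(5)
  ind <- matrix(runif(30 * 200) < 0.2, 30, 200)
  sel <- selection_matrix(ind, "boruta_ferns5", paste0("gene", 1:200))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_selection_matrix(sel, f1)
  back <- read_selection_matrix(f1)
  expect_identical(back$indicator, sel$indicator)
  expect_identical(back$method_id, "boruta_ferns5")
  expect_identical(back$gene_ids, sel$gene_ids)
  write_selection_matrix(sel, f2)
  expect_same_file(f1, f2)

  # all-false matrix round-trips too
  z <- selection_matrix(matrix(FALSE, 2, 3), "empty")
  fz <- withr::local_tempfile()
  write_selection_matrix(z, fz)
  expect_identical(read_selection_matrix(fz)$indicator, z$indicator)

  # ragged rows are a format error
  fr <- withr::local_tempfile()
  writeLines(c("#method=x", "g1\tg2", "0\t1", "1"), fr)
  expect_error(read_selection_matrix(fr), "ragged row")
})
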