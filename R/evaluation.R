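#' Post-selection classification error over bootstrap iterations
#'
#' For every bootstrap iteration, a random-forest validation model is trained
#' on the resampled samples restricted to the genes that iteration selected,
#' and its misclassification rate is measured on the out-of-bag samples —
#' which took no part in either the gene selection or the model training (the
#' no-leakage contract; train and test indices are asserted disjoint). An
#' empty selection degrades to predicting the training resample's majority
#' class; an iteration with an empty out-of-bag set yields `NA` and is
#' excluded from downstream tests.
#'
#' @param data an [expression_dataset()].
#' @param plan a [make_bootstrap_plan()] for the same samples.
#' @param sel a [selection_matrix()] with one row per plan iteration.
#' @param n_trees validation-forest size (default 1000; the full-fidelity
#'   setting is 50000).
#' @param seed integer seed.
#' @return object of class `ErrorVector`: list with `method_id`, `rates`
#'   (length B, in [0,1] or NA), `test_sizes`.
#' @export
post_selection_error <- function(data, plan, sel, n_trees = 1000L,
                                 seed = 1L) {
  stopifnot(inherits(data, "ExpressionDataset"),
            inherits(plan, "BootstrapPlan"),
            inherits(sel, "SelectionMatrix"))
  B <- plan$n_iterations
  if (nrow(sel$indicator) != B)
    stop("selection matrix rows do not match the plan's iterations")
  if (plan$n_samples != length(data$sample_ids))
    stop("plan was built for a different number of samples")
  rates <- rep(NA_real_, B)
  sizes <- integer(B)
  for (i in seq_len(B)) {
    tr <- plan$resamples[[i]]
    te <- plan$oob_sets[[i]]
    stopifnot(length(intersect(unique(tr), te)) == 0L) # no leakage
    sizes[i] <- length(te)
    if (length(te) == 0L) next
    genes <- which(sel$indicator[i, ])
    truth <- as.character(data$labels[te])
    if (length(genes) == 0L) {
      tab <- table(data$labels[tr])
      pred <- rep(names(tab)[which.max(tab)], length(te))
    } else {
      set.seed(derive_seed(seed, i))
      fit <- randomForest::randomForest(
        x = data$expression[tr, genes, drop = FALSE],
        y = droplevels(data$labels[tr]), ntree = n_trees)
      pred <- as.character(predict(
        fit, data$expression[te, genes, drop = FALSE]))
    }
    rates[i] <- mean(pred != truth)
  }
  structure(
    list(method_id = sel$method_id, rates = rates, test_sizes = sizes),
    class = "ErrorVector"
  )
}

# paired one-sided signed-rank p-value for H1: mean(x) > mean(y).
# Zero differences are dropped; exact null when there are no ties in |d| and
# n <= 50, otherwise normal approximation with tie and continuity correction
# (the behaviour of the classical test).
signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (!ties && n <= 50L)
    return(psignrank(W - 1, n, lower.tail = FALSE))
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (W - mu - 0.5) / sqrt(sigma2)
  pnorm(z, lower.tail = FALSE)
}

#' Compare per-iteration errors of several methods against the best
#'
#' Identifies the method with the lowest mean error and tests every other
#' method for being significantly worse with a paired one-sided signed-rank
#' test on the per-iteration error differences (errors are paired because all
#' methods share one bootstrap plan), Holm–Bonferroni corrected across the
#' compared methods.
#'
#' @param errors list of [post_selection_error()] `ErrorVector`s sharing B
#'   and iteration alignment.
#' @param alpha family-wise level for the worse-than-best flags (default
#'   0.01).
#' @return object of class `ComparisonReport`: list with `best_method` and
#'   `table`, a data.frame of `method`, `mean_error`, `p_value` (unadjusted),
#'   `p_adjusted` (Holm), `worse_than_best` flag (`FALSE`, with `NA`
#'   p-values, for the best method itself).
#' @export
compare_methods <- function(errors, alpha = 0.01) {
  stopifnot(length(errors) >= 1,
            all(vapply(errors, inherits, logical(1), "ErrorVector")))
  B <- unique(vapply(errors, function(e) length(e$rates), integer(1)))
  if (length(B) != 1L) stop("error vectors have differing lengths")
  ids <- vapply(errors, `[[`, character(1), "method_id")
  means <- vapply(errors, function(e) mean(e$rates, na.rm = TRUE),
                  numeric(1))
  best <- which.min(means)
  others <- setdiff(seq_along(errors), best)
  pv <- vapply(others, function(j)
    signed_rank_p(errors[[j]]$rates, errors[[best]]$rates), numeric(1))
  flags <- holm_bonferroni(pv, alpha)
  adj <- pmin(1, stats::p.adjust(pv, method = "holm"))
  tab <- data.frame(
    method = ids, mean_error = means,
    p_value = NA_real_, p_adjusted = NA_real_,
    worse_than_best = FALSE, stringsAsFactors = FALSE)
  tab$p_value[others] <- pv
  tab$p_adjusted[others] <- adj
  tab$worse_than_best[others] <- flags
  structure(
    list(best_method = ids[best], alpha = alpha, table = tab),
    class = "ComparisonReport"
  )
}

#' @export
print.ComparisonReport <- function(x, ...) {
  cat(sprintf("ComparisonReport: best method '%s' (alpha = %g)\n",
              x$best_method, x$alpha))
  print(x$table, row.names = FALSE)
  invisible(x)
}
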