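#' Grow a bagged CART forest (optionally regularised)
#'
#' Classification forest with Gini splits, full-size bootstrap bags and
#' `mtry`-gene subsampling at each split. With `lambda = 1` this is an
#' ordinary random forest; with `lambda < 1` the Gini gain of any gene not
#' yet present in the ensemble-wide used-gene set F is multiplied by
#' `lambda`, so a new gene enters only when its information is not redundant
#' with genes already used (the regularised-forest selection principle; see
#' [rrf_select()]). Per-tree structures are retained so out-of-bag
#' bookkeeping and permutation importance can be computed exactly.
#'
#' @param data an [expression_dataset()].
#' @param n_trees number of trees.
#' @param mtry genes tried per split; default `floor(sqrt(p))`.
#' @param lambda new-gene gain multiplier in (0, 1]; 1 disables
#'   regularisation.
#' @param penalty_scope `"forest"` (F shared by the whole ensemble, the
#'   regularised-forest default) or `"tree"` (F reset for each tree).
#' @param min_node minimal node size to attempt a split.
#' @param seed integer seed.
#' @return object of class `CartForest`: per-tree node arrays, in-bag count
#'   matrix, per-gene summed Gini decrease, the forest's total impurity
#'   decrease, and the logical `used` vector (genes appearing in >= 1 split).
#' @export
grow_forest <- function(data, n_trees = 500L, mtry = NULL, lambda = 1,
                        penalty_scope = c("forest", "tree"),
                        min_node = 2L, seed = 1L) {
  stopifnot(inherits(data, "ExpressionDataset"), n_trees >= 1,
            lambda > 0, lambda <= 1)
  penalty_scope <- match.arg(penalty_scope)
  p <- length(data$gene_ids)
  mtry <- as.integer(mtry %||% max(1L, floor(sqrt(p))))
  set.seed(seed)
  f <- cpp_grow_forest(data$expression, as.integer(data$labels) - 1L,
                       nlevels(data$labels), as.integer(n_trees), mtry,
                       lambda, penalty_scope == "forest",
                       as.integer(min_node))
  structure(
    list(trees = f$trees, inbag = f$inbag,
         gini_sum = setNames(as.numeric(f$gini_sum), data$gene_ids),
         total_decrease = f$total_decrease,
         used = setNames(as.logical(f$used), data$gene_ids),
         n_trees = as.integer(n_trees), mtry = mtry, lambda = lambda,
         penalty_scope = penalty_scope, classes = levels(data$labels),
         gene_ids = data$gene_ids, seed = as.integer(seed)),
    class = "CartForest"
  )
}

#' @export
print.CartForest <- function(x, ...) {
  cat(sprintf(
    "CartForest: %d trees, mtry %d, lambda %g (%s scope), %d/%d genes used\n",
    x$n_trees, x$mtry, x$lambda, x$penalty_scope, sum(x$used),
    length(x$used)))
  invisible(x)
}

# raw and normalised permutation importance from per-tree difference moments;
# zeros of unused trees are part of the moments already
perm_importance_from_moments <- function(sum, sumsq, n_trees,
                                         measure = c("raw", "normalised"),
                                         norm_denominator = c("se", "sd")) {
  measure <- match.arg(measure)
  norm_denominator <- match.arg(norm_denominator)
  raw <- sum / n_trees
  if (measure == "raw") return(raw)
  if (n_trees < 2) return(ifelse(raw == 0, 0, raw))
  v <- pmax(0, (sumsq - sum^2 / n_trees) / (n_trees - 1))
  s <- sqrt(v)
  den <- if (norm_denominator == "se") s / sqrt(n_trees) else s
  ifelse(den == 0, 0, raw / den)
}

#' Random-forest gene importance
#'
#' The three classical forest importance measures, computed from the per-tree
#' structures of a [grow_forest()] ensemble:
#'
#' * `gini` — total Gini impurity decrease attributed to splits on the gene,
#'   summed over all trees and divided by `n_trees`. Non-negative; summed
#'   over genes (times `n_trees`) it equals the forest's total impurity
#'   decrease exactly.
#' * `raw` — mean over trees of (OOB accuracy − OOB accuracy after permuting
#'   the gene within that tree's OOB set); one permutation per tree-gene
#'   pair, trees not using the gene contribute 0, so a gene used in no tree
#'   scores exactly 0.
#' * `normalised` — the raw measure divided by the standard error of the
#'   per-tree differences (`sd / sqrt(n_trees)`; set `norm_denominator =
#'   "sd"` for the plain-sd variant), with 0 wherever the sd is 0.
#'
#' @param data an [expression_dataset()].
#' @param measure `"gini"`, `"raw"` or `"normalised"`.
#' @param n_trees forest size (default 5000 for stable scores).
#' @param mtry genes tried per split; default `floor(sqrt(p))`.
#' @param norm_denominator `"se"` (default) or `"sd"`.
#' @param seed integer seed.
#' @return named numeric vector of per-gene importances.
#' @export
forest_importance <- function(data, measure = c("raw", "gini", "normalised"),
                              n_trees = 5000L, mtry = NULL,
                              norm_denominator = c("se", "sd"), seed = 1L) {
  measure <- match.arg(measure)
  forest <- grow_forest(data, n_trees = n_trees, mtry = mtry, lambda = 1,
                        seed = seed)
  if (measure == "gini")
    return(forest$gini_sum / forest$n_trees)
  set.seed(derive_seed(seed, 31L))
  mom <- cpp_forest_perm_importance(forest$trees, forest$inbag,
                                    data$expression,
                                    as.integer(data$labels) - 1L)
  setNames(
    perm_importance_from_moments(mom$sum, mom$sumsq, mom$n_trees, measure,
                                 norm_denominator),
    data$gene_ids)
}

#' Forest-based importance provider
#'
#' Provider-contract wrapper around [forest_importance()]; see
#' [importance_ferns()] for the contract.
#'
#' @param measure `"gini"`, `"raw"` or `"normalised"`.
#' @param n_trees forest size.
#' @param norm_denominator see [forest_importance()].
#' @return a provider function with an `id` attribute (e.g. `"rf-raw"`).
#' @export
importance_forest <- function(measure = c("raw", "gini", "normalised"),
                              n_trees = 5000L,
                              norm_denominator = c("se", "sd")) {
  measure <- match.arg(measure)
  norm_denominator <- match.arg(norm_denominator)
  force(n_trees)
  f <- function(data, seed) {
    forest_importance(data, measure = measure, n_trees = n_trees,
                      norm_denominator = norm_denominator, seed = seed)
  }
  attr(f, "id") <- paste0("rf-", c(raw = "raw", gini = "gini",
                                   normalised = "norm")[measure])
  f
}
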