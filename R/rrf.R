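#' Regularised random forest gene selection
#'
#' Grows a forest whose tree grower penalises the Gini gain of genes not yet
#' used anywhere in the ensemble (gain multiplied by `lambda` < 1), so a new
#' gene enters the model only when its information is not redundant with the
#' genes already used. The selection is simply the set of genes used in at
#' least one split of the resulting ensemble — a minimal-optimal style
#' selector that typically returns very few genes.
#'
#' @param data an [expression_dataset()].
#' @param lambda penalty multiplier in (0, 1]; `1` reduces to an ordinary
#'   forest (every used gene selected). Default 0.8.
#' @param n_trees ensemble size.
#' @param mtry genes tried per split; default `floor(sqrt(p))`.
#' @param penalty_scope `"forest"` (used-gene set shared across trees,
#'   default) or `"tree"`.
#' @param seed integer seed.
#' @return list with `selected` (named logical vector over genes) and
#'   `forest` (the [grow_forest()] object).
#' @export
rrf_select <- function(data, lambda = 0.8, n_trees = 500L, mtry = NULL,
                       penalty_scope = c("forest", "tree"), seed = 1L) {
  penalty_scope <- match.arg(penalty_scope)
  forest <- grow_forest(data, n_trees = n_trees, mtry = mtry,
                        lambda = lambda, penalty_scope = penalty_scope,
                        seed = seed)
  if (!any(forest$used))
    warning("no tree performed any split; selection is empty")
  list(selected = forest$used, forest = forest)
}
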