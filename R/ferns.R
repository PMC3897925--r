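#' Train a Random Ferns ensemble
#'
#' A fern is a fixed-depth tree that applies the same split rule to every node
#' of a level, so a depth-D fern partitions samples into 2^D leaves by D
#' (gene, threshold) tests. Splits are drawn completely at random: the gene
#' uniformly over all genes and the threshold uniformly between the in-bag
#' minimum and maximum of that gene. Each fern is grown on its own full-size
#' bootstrap bag; leaves store additively smoothed (Laplace +1) log class
#' probabilities of the in-bag samples routed to them. The out-of-bag samples
#' of each fern drive the permutation importance (see [ferns_importance()]).
#'
#' @param data an [expression_dataset()].
#' @param depth fern depth D (1..7 typical; leaves number 2^D).
#' @param n_ferns ensemble size K. Large ensembles are needed for stable
#'   importance scores (default 5000 when used as an importance source).
#' @param seed integer seed.
#' @return object of class `FernModel`.
#' @export
train_ferns <- function(data, depth = 5L, n_ferns = 1000L, seed = 1L) {
  stopifnot(inherits(data, "ExpressionDataset"), depth >= 1, n_ferns >= 1)
  if (depth > 8) stop("depth > 8 not supported")
  X <- data$expression
  if (all(apply(X, 2L, function(v) max(v) == min(v))))
    warning("all genes are constant; every split threshold is degenerate")
  y <- as.integer(data$labels) - 1L
  set.seed(seed)
  m <- cpp_train_ferns(X, y, nlevels(data$labels), as.integer(depth),
                       as.integer(n_ferns))
  structure(
    list(feat = m$feat, thr = m$thr, logp = m$logp, oob = m$oob,
         depth = as.integer(depth), n_ferns = as.integer(n_ferns),
         classes = levels(data$labels), gene_ids = data$gene_ids,
         n_train = nrow(X), seed = as.integer(seed)),
    class = "FernModel"
  )
}

#' @export
print.FernModel <- function(x, ...) {
  cat(sprintf("FernModel: %d ferns of depth %d (%d leaves), %d genes, %d classes\n",
              x$n_ferns, x$depth, 2^x$depth, length(x$gene_ids),
              length(x$classes)))
  invisible(x)
}

#' Predict classes with a fern ensemble
#'
#' Maximum-a-posteriori voting: per sample, the leaf log class probabilities
#' are summed over all ferns and the arg-max class is returned; ties go to the
#' lowest class index.
#'
#' @param object a [train_ferns()] model.
#' @param newdata numeric matrix (or `ExpressionDataset`) with the training
#'   gene columns.
#' @param ... unused.
#' @return factor of predicted classes with the training levels.
#' @export
predict.FernModel <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "ExpressionDataset")) newdata$expression
       else newdata
  if (ncol(X) != length(object$gene_ids))
    stop(sprintf("newdata has %d genes, model expects %d", ncol(X),
                 length(object$gene_ids)))
  sc <- cpp_ferns_scores(object$feat, object$thr, object$logp, object$depth,
                         length(object$classes), X)
  factor(object$classes[max.col(sc, ties.method = "first")],
         levels = object$classes)
}

#' Fern OOB permutation importance
#'
#' For each fern and each distinct gene used in its splits, the mean
#' out-of-bag probability of the correct class is compared with the same
#' quantity after permuting that gene's values among the fern's OOB samples
#' (one permutation per fern-gene pair). A gene's importance is the mean of
#' these differences over all ferns that use it; a gene used in no fern
#' scores exactly 0. The measure differs from forest permutation importance
#' in using class probabilities rather than vote counts, which extracts more
#' information per fern and lets a cheap, fully random ensemble stand in for
#' a much more expensive forest.
#'
#' @param model a [train_ferns()] model.
#' @param data the `ExpressionDataset` the model was trained on.
#' @param seed integer seed for the permutations.
#' @return object of class `FernsImportance`: list with `scores` (named
#'   numeric, length n_genes), `depth`, `n_ferns`.
#' @export
ferns_importance <- function(model, data, seed = 1L) {
  stopifnot(inherits(model, "FernModel"), inherits(data, "ExpressionDataset"))
  if (!identical(model$gene_ids, data$gene_ids))
    stop("model and data gene ids disagree")
  if (nrow(data$expression) != model$n_train)
    stop("data does not match the training set")
  set.seed(seed)
  sc <- cpp_ferns_importance(model$feat, model$thr, model$logp, model$oob,
                             model$depth, length(model$classes),
                             data$expression,
                             as.integer(data$labels) - 1L)
  structure(
    list(scores = setNames(as.numeric(sc), data$gene_ids),
         depth = model$depth, n_ferns = model$n_ferns),
    class = "FernsImportance"
  )
}

#' Fern-based importance provider
#'
#' Returns a function satisfying the package-wide importance-provider
#' contract: `f(dataset, seed)` giving one finite score per gene, higher
#' meaning more important. Trains a fresh depth-`depth` ensemble of `n_ferns`
#' ferns and returns its OOB permutation importance.
#'
#' @param depth fern depth.
#' @param n_ferns ensemble size.
#' @return a provider function with an `id` attribute (e.g. `"ferns5"`).
#' @export
importance_ferns <- function(depth = 5L, n_ferns = 5000L) {
  force(depth); force(n_ferns)
  f <- function(data, seed) {
    model <- train_ferns(data, depth = depth, n_ferns = n_ferns, seed = seed)
    ferns_importance(model, data, seed = derive_seed(seed, 97L))$scores
  }
  attr(f, "id") <- paste0("ferns", depth)
  f
}
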