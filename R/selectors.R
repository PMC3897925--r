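#' Append shadow (contrast) genes to a dataset
#'
#' A shadow is a copy of a real gene whose values are independently permuted
#' across samples, destroying any class association while preserving the
#' marginal distribution. Shadow importance scores form an empirical null
#' against which real genes are judged; shadows are re-shuffled on every call
#' (fresh seed-derived permutations), matching the behaviour of iterative
#' shadow-based selectors.
#'
#' @param data an [expression_dataset()].
#' @param seed integer seed.
#' @return object of class `ShadowedDataset`: list with `data` (the combined
#'   `ExpressionDataset`, real genes first, shadows named
#'   `shadow_<gene id>`), `real` and `shadow` (column index vectors).
#' @export
add_shadows <- function(data, seed = 1L) {
  stopifnot(inherits(data, "ExpressionDataset"))
  X <- data$expression
  p <- ncol(X)
  set.seed(seed)
  S <- apply(X, 2L, function(v) v[sample.int(length(v))])
  colnames(S) <- paste0("shadow_", data$gene_ids)
  combined <- expression_dataset(cbind(X, S), data$labels)
  structure(
    list(data = combined, real = seq_len(p), shadow = p + seq_len(p),
         seed = as.integer(seed)),
    class = "ShadowedDataset"
  )
}

#' Boruta all-relevant gene selection
#'
#' Iterative shadow-feature testing. Each iteration appends freshly permuted
#' shadows of all genes still in play (undecided and confirmed), scores the
#' combined data with the importance provider, and credits a *hit* to every
#' undecided gene whose importance strictly exceeds the best shadow's. Hit
#' counts are then tested against Binomial(iterations, 1/2): two one-sided
#' exact tests per undecided gene, Bonferroni-corrected across the currently
#' undecided genes. Genes significant in the upper tail are confirmed; genes
#' significant in the lower tail are rejected and removed from the system
#' together with their shadows. The loop ends when no gene is undecided or
#' after `max_iterations`; genes still undecided are returned as not
#' selected.
#'
#' @param data an [expression_dataset()].
#' @param importance provider function `f(dataset, seed)` (see
#'   [importance_ferns()]).
#' @param alpha significance cut-off for the binomial tests (default 0.01).
#' @param max_iterations iteration limit (default 100).
#' @param seed integer seed.
#' @return list with `selected` (named logical, TRUE = confirmed), `state`
#'   (a `BorutaState`: per-gene `status` factor
#'   undecided/confirmed/rejected, `hits`, `iterations`, `alpha`).
#' @export
boruta_select <- function(data, importance, alpha = 0.01,
                          max_iterations = 100L, seed = 1L) {
  stopifnot(inherits(data, "ExpressionDataset"), max_iterations >= 1,
            alpha > 0, alpha < 1)
  p <- length(data$gene_ids)
  status <- rep("undecided", p)
  hits <- integer(p)
  names(hits) <- data$gene_ids
  iter <- 0L
  while (any(status == "undecided") && iter < max_iterations) {
    iter <- iter + 1L
    active <- which(status != "rejected")
    sub <- subset_dataset(data, genes = active)
    sh <- add_shadows(sub, seed = derive_seed(seed, 2L * iter))
    imp <- importance(sh$data, derive_seed(seed, 2L * iter + 1L))
    best_shadow <- max(imp[sh$shadow])
    und_local <- which(status[active] == "undecided")
    hit <- imp[sh$real][und_local] > best_shadow # strict: ties are not hits
    und <- active[und_local]
    hits[und] <- hits[und] + as.integer(hit)

    m <- length(und)
    p_up <- pbinom(hits[und] - 1L, iter, 0.5, lower.tail = FALSE)
    p_down <- pbinom(hits[und], iter, 0.5)
    status[und[p_up <= alpha / m]] <- "confirmed"
    status[und[p_down <= alpha / m & p_up > alpha / m]] <- "rejected"
  }
  status <- factor(status, levels = c("undecided", "confirmed", "rejected"))
  names(status) <- data$gene_ids
  list(
    selected = setNames(status == "confirmed", data$gene_ids),
    state = structure(
      list(status = status, hits = hits, iterations = iter, alpha = alpha,
           max_iterations = as.integer(max_iterations)),
      class = "BorutaState")
  )
}

#' Shadow t-test ("artificial contrasts") gene selection
#'
#' Runs a fixed number of iterations; each iteration re-shuffles the shadows,
#' scores the combined data and records every real gene's importance together
#' with the mean importance of all shadows. Per gene, a one-sided two-sample
#' t-test (Welch by default) asks whether the gene's mean importance over the
#' iterations significantly exceeds the mean shadow importance; genes with
#' p < `alpha` are selected. No multiplicity correction is applied — the
#' procedure's nominal per-gene level is `alpha`, which on all-noise data
#' yields an `alpha` fraction of false positives by construction.
#'
#' @param data an [expression_dataset()].
#' @param importance provider function `f(dataset, seed)`.
#' @param n_iterations number of shadow iterations (default 20).
#' @param alpha per-gene significance level (default 0.05).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @param seed integer seed.
#' @return list with `selected` (named logical) and `p_values` (named
#'   numeric).
#' @export
ace_select <- function(data, importance, n_iterations = 20L, alpha = 0.05,
                       var_equal = FALSE, seed = 1L) {
  stopifnot(inherits(data, "ExpressionDataset"), n_iterations >= 2)
  p <- length(data$gene_ids)
  scores <- matrix(NA_real_, n_iterations, p)
  shadow_means <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    sh <- add_shadows(data, seed = derive_seed(seed, 2L * it))
    imp <- importance(sh$data, derive_seed(seed, 2L * it + 1L))
    scores[it, ] <- imp[sh$real]
    shadow_means[it] <- mean(imp[sh$shadow])
  }
  pv <- vapply(seq_len(p), function(g) {
    x <- scores[, g]
    if (sd(x) == 0 && sd(shadow_means) == 0) {
      # degenerate: no sampling variability on either side
      if (mean(x) > mean(shadow_means)) return(0)
      return(1)
    }
    t.test(x, shadow_means, alternative = "greater",
           var.equal = var_equal)$p.value
  }, numeric(1))
  names(pv) <- data$gene_ids
  list(selected = !is.na(pv) & pv < alpha, p_values = pv)
}

#' Subset-size schedule of recursive feature elimination
#'
#' Starting from `p` genes, each step keeps the highest power of 2 strictly
#' below the current count, stopping once the count reaches 4.
#'
#' @param p starting number of genes (>= 4).
#' @return integer vector of evaluated subset sizes, e.g. `c(2000, 1024,
#'   512, ..., 8, 4)`.
#' @export
rfe_schedule <- function(p) {
  stopifnot(p >= 4)
  sizes <- as.integer(p)
  while (sizes[length(sizes)] > 4L) {
    k <- 2L^floor(log2(sizes[length(sizes)] - 1e-9))
    if (k >= sizes[length(sizes)]) k <- k %/% 2L
    sizes <- c(sizes, max(4L, as.integer(k)))
  }
  sizes
}

#' Recursive feature elimination with bootstrap-validated error
#'
#' Minimal-optimal selection: at each subset size of the power-of-two
#' schedule ([rfe_schedule()]), the misclassification error of a random
#' forest restricted to the current genes is estimated by `n_boot` bootstrap
#' rounds (train on a resample, test on its out-of-bag complement) and
#' recorded; the importance provider then ranks the current genes and only
#' the scheduled number of top genes is kept. After the size-4 subset is
#' evaluated, the recorded subset with the lowest error is returned (ties go
#' to the smallest subset). Importance ties at the cut boundary keep the
#' gene with the lower column index.
#'
#' @param data an [expression_dataset()].
#' @param importance provider function `f(dataset, seed)`.
#' @param n_boot bootstrap rounds per error estimate (default 10).
#' @param n_trees_eval trees in each validation forest (default 1000; the
#'   full-fidelity setting is 50000).
#' @param seed integer seed.
#' @return list with `selected` (named logical) and `trace` (an `RfeTrace`:
#'   data.frame of `size`, `error`, plus `feature_sets`, the evaluated gene
#'   sets).
#' @export
rfe_select <- function(data, importance, n_boot = 10L, n_trees_eval = 1000L,
                       seed = 1L) {
  stopifnot(inherits(data, "ExpressionDataset"),
            length(data$gene_ids) >= 4L, n_boot >= 1)
  current <- seq_along(data$gene_ids)
  sizes <- rfe_schedule(length(current))
  errors <- numeric(length(sizes))
  sets <- vector("list", length(sizes))
  for (s in seq_along(sizes)) {
    sub <- subset_dataset(data, genes = current)
    errors[s] <- bootstrap_forest_error(sub, n_boot = n_boot,
                                        n_trees = n_trees_eval,
                                        seed = derive_seed(seed, 3L * s))
    sets[[s]] <- data$gene_ids[current]
    if (sizes[s] == 4L) break
    imp <- importance(sub, derive_seed(seed, 3L * s + 1L))
    keep <- order(-imp, seq_along(imp))[seq_len(sizes[s + 1L])]
    current <- current[sort(keep)]
  }
  best <- which(errors == min(errors))
  best <- best[length(best)] # sizes strictly decrease: last minimum = smallest set
  list(
    selected = setNames(data$gene_ids %in% sets[[best]], data$gene_ids),
    trace = structure(
      list(size = sizes, error = errors, feature_sets = sets,
           best = best),
      class = "RfeTrace")
  )
}

# bootstrap error of a randomForest classifier: train on a with-replacement
# resample, test on its out-of-bag complement, average over rounds
bootstrap_forest_error <- function(data, n_boot, n_trees, seed) {
  n <- length(data$sample_ids)
  errs <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    s <- derive_seed(seed, b)
    repeat {
      set.seed(s)
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(data$labels[idx])) >= 2L) break
      s <- derive_seed(s, 1L)
    }
    oob <- setdiff(seq_len(n), idx)
    if (length(oob) == 0L) next
    fit <- randomForest::randomForest(
      x = data$expression[idx, , drop = FALSE],
      y = droplevels(data$labels[idx]), ntree = n_trees)
    pred <- predict(fit, data$expression[oob, , drop = FALSE])
    errs[b] <- mean(as.character(pred) != as.character(data$labels[oob]))
  }
  mean(errs, na.rm = TRUE)
}
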