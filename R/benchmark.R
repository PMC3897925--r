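#' Run one selector over every iteration of a bootstrap plan
#'
#' Applies a selection method to the dataset restricted to each resample of
#' the plan and stacks the per-iteration selections into a
#' [selection_matrix()]. This is the unit of the benchmark: every method sees
#' exactly the same resamples, which is what makes per-iteration results
#' comparable (and the downstream error comparison paired).
#'
#' @param data an [expression_dataset()].
#' @param plan a [make_bootstrap_plan()] for the same samples.
#' @param method one of `"boruta"`, `"ace"`, `"rfe"`, `"rrf"`.
#' @param importance provider function (ignored by `"rrf"`).
#' @param method_id identifier stored in the result; defaults to
#'   `<method>_<provider id>`.
#' @param seed integer seed.
#' @param ... further arguments passed to the selector (e.g.
#'   `max_iterations`, `alpha`, `n_trees_eval`, `lambda`).
#' @return a [selection_matrix()] with `plan$n_iterations` rows.
#' @export
run_selection <- function(data, plan, method = c("boruta", "ace", "rfe",
                                                 "rrf"),
                          importance = NULL, method_id = NULL, seed = 1L,
                          ...) {
  method <- match.arg(method)
  stopifnot(inherits(data, "ExpressionDataset"),
            inherits(plan, "BootstrapPlan"))
  if (method != "rrf" && is.null(importance))
    stop("method '", method, "' needs an importance provider")
  method_id <- method_id %||%
    if (method == "rrf") "rrf"
    else paste0(method, "_", attr(importance, "id") %||% "imp")
  B <- plan$n_iterations
  ind <- matrix(FALSE, B, length(data$gene_ids))
  for (i in seq_len(B)) {
    sub <- subset_dataset(data, samples = plan$resamples[[i]])
    s <- derive_seed(seed, i)
    sel <- switch(method,
      boruta = boruta_select(sub, importance, seed = s, ...)$selected,
      ace = ace_select(sub, importance, seed = s, ...)$selected,
      rfe = rfe_select(sub, importance, seed = s, ...)$selected,
      rrf = rrf_select(sub, seed = s, ...)$selected)
    ind[i, ] <- as.logical(sel)
  }
  selection_matrix(ind, method_id, data$gene_ids)
}

#' Run the full selection-stability benchmark
#'
#' End-to-end experimental design on one dataset: draw a shared bootstrap
#' plan, run every configured (method, importance source) cell on all
#' resamples, compute each cell's self-consistency report, estimate each
#' cell's post-selection error vector, and compare all cells against the best
#' one. All artifacts are written under `out_dir` as plain text (selection
#' matrices as TSV, reports as JSON) together with a manifest from which the
#' run can be reproduced.
#'
#' @param data an [expression_dataset()].
#' @param grid list of cells; each cell is a list with `method` and optional
#'   `importance` (a provider function), `id`, and further selector
#'   arguments, e.g. `list(method = "boruta", importance =
#'   importance_ferns(5), max_iterations = 50)`.
#' @param B bootstrap iterations (default 30).
#' @param seed global run seed.
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @param n_trees_validation trees of the post-selection validation forests.
#' @param scs_alpha level of the self-consistency tests (default 0.01).
#' @param compare_alpha level of the error comparison (default 0.01).
#' @return list with `plan`, `selections` (list of `SelectionMatrix`),
#'   `scs` (list of `SCSReport`), `errors` (list of `ErrorVector`),
#'   `comparison` (`ComparisonReport`), `manifest`.
#' @export
run_benchmark <- function(data, grid, B = 30L, seed = 1L, out_dir = NULL,
                          n_trees_validation = 1000L, scs_alpha = 0.01,
                          compare_alpha = 0.01) {
  stopifnot(inherits(data, "ExpressionDataset"), length(grid) >= 1)
  known <- c("boruta", "ace", "rfe", "rrf")
  for (cell in grid) {
    if (is.null(cell$method) || !cell$method %in% known)
      stop("unknown method in grid: ",
           if (is.null(cell$method)) "<missing>" else cell$method)
  }
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  plan <- make_bootstrap_plan(length(data$sample_ids), B,
                              seed = derive_seed(seed, 1L),
                              labels = data$labels)
  selections <- list()
  scs <- list()
  errors <- list()
  for (k in seq_along(grid)) {
    cell <- grid[[k]]
    extra <- cell[setdiff(names(cell), c("method", "importance", "id"))]
    id <- cell$id %||%
      if (cell$method == "rrf") "rrf"
      else paste0(cell$method, "_", attr(cell$importance, "id") %||% "imp")
    message(sprintf("[%s] selecting over %d iterations ...", id, B))
    selmat <- tryCatch(
      do.call(run_selection,
              c(list(data = data, plan = plan, method = cell$method,
                     importance = cell$importance, method_id = id,
                     seed = derive_seed(seed, 100L + k)),
                extra)),
      error = function(e) {
        warning(sprintf("grid cell '%s' failed: %s", id,
                        conditionMessage(e)))
        NULL
      })
    if (is.null(selmat)) next
    selections[[id]] <- selmat
    scs[[id]] <- compute_scs(selmat, alpha = scs_alpha)
    errors[[id]] <- post_selection_error(
      data, plan, selmat, n_trees = n_trees_validation,
      seed = derive_seed(seed, 200L + k))
    if (!is.null(out_dir)) {
      write_selection_matrix(selmat,
                             file.path(out_dir, paste0("selection_", id,
                                                       ".tsv")))
      jsonlite::write_json(
        scs_report_json(scs[[id]]),
        file.path(out_dir, paste0("scs_", id, ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      jsonlite::write_json(
        list(method_id = id, rates = errors[[id]]$rates,
             test_sizes = errors[[id]]$test_sizes),
        file.path(out_dir, paste0("errors_", id, ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  comparison <- if (length(errors) >= 1)
    compare_methods(errors, alpha = compare_alpha) else NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("selstab")),
    r_version = as.character(getRversion()),
    seed = seed, B = B,
    n_samples = length(data$sample_ids), n_genes = length(data$gene_ids),
    n_trees_validation = n_trees_validation,
    scs_alpha = scs_alpha, compare_alpha = compare_alpha,
    grid = lapply(seq_along(grid), function(k) {
      cell <- grid[[k]]
      c(list(method = cell$method,
             importance = attr(cell$importance, "id")),
        cell[setdiff(names(cell), c("method", "importance", "id"))])
    })
  )
  if (!is.null(out_dir)) {
    if (!is.null(comparison))
      jsonlite::write_json(
        list(best_method = comparison$best_method,
             alpha = comparison$alpha, table = comparison$table),
        file.path(out_dir, "comparison.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(plan = plan, selections = selections, scs = scs, errors = errors,
       comparison = comparison, manifest = manifest)
}

scs_report_json <- function(r) {
  list(method_id = r$method_id, c = r$c, f = r$f, ratio = r$ratio,
       p_hat = r$p_hat, alpha = r$alpha, n_iterations = r$n_iterations,
       n_scs = length(r$scs_gene_ids), scs_gene_ids = r$scs_gene_ids)
}
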