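#' Holm–Bonferroni step-down rejection
#'
#' Classical step-down procedure controlling the family-wise error rate:
#' p-values are sorted ascending and the i-th smallest is rejected while
#' `p_(i) <= alpha / (m - i + 1)`; the first failure stops the procedure.
#'
#' @param pvalues numeric vector in [0, 1].
#' @param alpha family-wise error level.
#' @return logical rejection flags in the input order (empty input gives an
#'   empty vector).
#' @export
holm_bonferroni <- function(pvalues, alpha = 0.01) {
  m <- length(pvalues)
  if (m == 0L) return(logical(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must be in [0, 1]")
  ord <- order(pvalues)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (pvalues[ord[i]] <= alpha / (m - i + 1)) reject[ord[i]] <- TRUE
    else break
  }
  reject
}

#' Self-consistency of a selection across bootstrap iterations
#'
#' A method applied to B bootstrap resamples yields a B x p selection
#' indicator. Under the null that the method selects genes interchangeably,
#' each gene's selection count is Binomial(B, p_hat), with p_hat estimated as
#' the mean fraction of genes selected (the grand mean of the indicator).
#' Genes selected significantly more often than this null allows — upper-tail
#' exact binomial test, Holm–Bonferroni corrected across all genes at `alpha`
#' — are the *significantly self-consistent selections* (SCS). The summary
#' mirrors the stability report of a selection benchmark:
#'
#' * `c` — mean over iterations of the number of selected genes that are SCS;
#' * `f` — mean over iterations of the number of selected genes;
#' * `ratio` — `c / f` (0 when `f` is 0), the fraction of a typical
#'   iteration's selection that is reproducible.
#'
#' @param sel a [selection_matrix()].
#' @param alpha family-wise level of the Holm-corrected binomial tests
#'   (default 0.01).
#' @return object of class `SCSReport`: list with `method_id`,
#'   `scs_gene_ids`, `c`, `f`, `ratio`, `p_hat`, `alpha`, `n_iterations`,
#'   `counts` (per-gene selection counts) and `p_values` (per-gene unadjusted
#'   upper-tail p-values).
#' @export
compute_scs <- function(sel, alpha = 0.01) {
  stopifnot(inherits(sel, "SelectionMatrix"))
  ind <- sel$indicator
  B <- nrow(ind)
  counts <- colSums(ind)
  p_hat <- mean(ind)
  pv <- pbinom(counts - 1L, B, p_hat, lower.tail = FALSE) # P(X >= count)
  scs <- holm_bonferroni(pv, alpha)
  c_i <- if (any(scs)) rowSums(ind[, scs, drop = FALSE]) else rep(0, B)
  f_i <- rowSums(ind)
  cbar <- mean(c_i)
  fbar <- mean(f_i)
  structure(
    list(method_id = sel$method_id, scs_gene_ids = sel$gene_ids[scs],
         c = cbar, f = fbar, ratio = if (fbar > 0) cbar / fbar else 0,
         p_hat = p_hat, alpha = alpha, n_iterations = B,
         counts = setNames(counts, sel$gene_ids),
         p_values = setNames(pv, sel$gene_ids)),
    class = "SCSReport"
  )
}

#' @export
print.SCSReport <- function(x, ...) {
  cat(sprintf(
    "SCSReport [%s]: c = %.1f, f = %.1f, c/f = %.0f%% (%d SCS genes, B = %d, p_hat = %.4f)\n",
    x$method_id, x$c, x$f, 100 * x$ratio, length(x$scs_gene_ids),
    x$n_iterations, x$p_hat))
  invisible(x)
}
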