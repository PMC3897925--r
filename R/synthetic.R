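#' Specification of a synthetic p >> n expression dataset
#'
#' Describes a dataset with a planted ground truth: `n_relevant` genes whose
#' class-conditional means are separated by `effect_size` noise-SD units,
#' `n_redundant_per_relevant` correlated copies of each relevant gene, and
#' pure-noise genes filling the rest. Defaults emulate the shape of a classic
#' two-class colon-tumour microarray set: 62 samples, 2000 genes, unbalanced
#' classes 40:22.
#'
#' Class-mean shifts are applied on the latent Gaussian scale for both noise
#' distributions, so `effect_size` has a single interpretation; the lognormal
#' option exponentiates the latent values afterwards. A redundant copy is
#' `rho * parent + sqrt(1 - rho^2) * fresh_noise` on the latent scale, which
#' produces blocks of correlated, class-informative-but-redundant genes.
#'
#' @param n_samples,n_genes dataset shape (p >> n expected but not required).
#' @param n_classes number of classes (>= 2).
#' @param class_proportions simplex vector of length `n_classes`.
#' @param n_relevant number of independently informative planted genes.
#' @param effect_size class-mean separation delta, in noise-SD units.
#' @param n_redundant_per_relevant correlated copies per relevant gene.
#' @param redundancy_correlation latent correlation rho in [0, 1).
#' @param noise_distribution `"gaussian"` or `"lognormal"`.
#' @param seed integer seed.
#' @return an object of class `SyntheticSpec` (a validated list).
#' @export
synthetic_spec <- function(n_samples = 62L, n_genes = 2000L, n_classes = 2L,
                           class_proportions = c(40, 22) / 62,
                           n_relevant = 20L, effect_size = 1,
                           n_redundant_per_relevant = 2L,
                           redundancy_correlation = 0.8,
                           noise_distribution = c("gaussian", "lognormal"),
                           seed = 1L) {
  noise_distribution <- match.arg(noise_distribution)
  stopifnot(n_samples >= 2, n_genes >= 1, n_classes >= 2,
            n_relevant >= 0, effect_size >= 0,
            n_redundant_per_relevant >= 0,
            redundancy_correlation >= 0, redundancy_correlation < 1)
  if (length(class_proportions) != n_classes)
    stop("class_proportions must have length n_classes")
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("class_proportions must sum to 1")
  if (n_relevant * (1 + n_redundant_per_relevant) > n_genes)
    stop("planted genes (relevant + redundant) exceed n_genes")
  structure(
    list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
         n_classes = as.integer(n_classes),
         class_proportions = class_proportions,
         n_relevant = as.integer(n_relevant), effect_size = effect_size,
         n_redundant_per_relevant = as.integer(n_redundant_per_relevant),
         redundancy_correlation = redundancy_correlation,
         noise_distribution = noise_distribution, seed = as.integer(seed)),
    class = "SyntheticSpec"
  )
}

#' Generate a synthetic expression dataset with known ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (an [expression_dataset()]) and `truth`, a
#'   `GroundTruth` list of disjoint id sets `relevant_ids`, `redundant_ids`,
#'   `noise_ids` partitioning all gene ids.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  p <- spec$n_genes
  K <- spec$n_classes

  # deterministic class sizes from proportions (largest-remainder rounding),
  # each class forced to >=2 samples
  counts <- floor(spec$class_proportions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(spec$class_proportions * n - counts, decreasing = TRUE)
    counts[extra[seq_len(rem)]] <- counts[extra[seq_len(rem)]] + 1
  }
  while (any(counts < 2)) {
    counts[which.min(counts)] <- counts[which.min(counts)] + 1
    counts[which.max(counts)] <- counts[which.max(counts)] - 1
  }
  labels <- factor(rep(paste0("class", seq_len(K)), counts))

  # class centres equally spaced effect_size apart, centred on 0
  centres <- spec$effect_size * (seq_len(K) - (K + 1) / 2)
  shift <- centres[as.integer(labels)]

  nr <- spec$n_relevant
  nred <- spec$n_relevant * spec$n_redundant_per_relevant
  nnoise <- p - nr - nred

  latent <- matrix(rnorm(n * p), n, p)
  rel_idx <- seq_len(nr)
  for (j in rel_idx) latent[, j] <- latent[, j] + shift

  red_idx <- if (nred > 0) nr + seq_len(nred) else integer(0)
  rho <- spec$redundancy_correlation
  if (nred > 0) {
    parent_of <- rep(rel_idx, each = spec$n_redundant_per_relevant)
    for (k in seq_along(red_idx)) {
      j <- red_idx[k]
      latent[, j] <- rho * latent[, parent_of[k]] +
        sqrt(1 - rho^2) * latent[, j]
    }
  }

  expr <- if (spec$noise_distribution == "lognormal") exp(latent) else latent

  gene_ids <- c(
    if (nr > 0) paste0("rel", seq_len(nr)) else character(0),
    if (nred > 0) paste0("red", rep(seq_len(nr),
                                    each = spec$n_redundant_per_relevant),
                         "_", seq_len(spec$n_redundant_per_relevant))
    else character(0),
    if (nnoise > 0) paste0("noise", seq_len(nnoise)) else character(0)
  )
  colnames(expr) <- gene_ids
  rownames(expr) <- paste0("s", seq_len(n))

  list(
    dataset = expression_dataset(expr, labels),
    truth = structure(
      list(relevant_ids = gene_ids[rel_idx],
           redundant_ids = gene_ids[red_idx],
           noise_ids = if (nnoise > 0) gene_ids[nr + nred + seq_len(nnoise)]
                       else character(0)),
      class = "GroundTruth")
  )
}

#' Generate an i.i.d. Bernoulli null selection matrix
#'
#' Oracle input for calibrating the self-consistency statistic: every entry is
#' an independent Bernoulli(q) draw, so no gene is genuinely more consistent
#' than any other.
#'
#' @param B number of iterations (rows).
#' @param n_genes number of genes (columns).
#' @param q selection probability in [0, 1].
#' @param seed integer seed.
#' @param method_id identifier stored in the matrix.
#' @return a [selection_matrix()].
#' @export
generate_null_selection_matrix <- function(B, n_genes, q, seed = 1L,
                                           method_id = "null") {
  if (q < 0 || q > 1) stop("q must be in [0, 1]")
  set.seed(seed)
  ind <- matrix(runif(B * n_genes) < q, B, n_genes)
  selection_matrix(ind, method_id, paste0("g", seq_len(n_genes)))
}
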