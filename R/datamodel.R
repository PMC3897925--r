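#' Expression dataset container
#'
#' The universal input of the package: a numeric sample-by-gene expression
#' matrix (already pre-processed, arbitrary units) plus a categorical class
#' label per sample. Validation enforces the contracts every downstream stage
#' relies on: no missing values, at least two classes with at least two
#' samples each, and unique gene / sample identifiers.
#'
#' @param expression numeric matrix, samples in rows, genes in columns.
#' @param labels vector (coerced to factor) of length `nrow(expression)`.
#' @param gene_ids,sample_ids optional identifier vectors; default to the
#'   matrix dimnames or to `g1..gp` / `s1..sn`.
#' @return an object of class `ExpressionDataset`: a list with elements
#'   `expression` (matrix with dimnames set), `labels` (factor), `gene_ids`,
#'   `sample_ids`.
#' @export
expression_dataset <- function(expression, labels, gene_ids = NULL,
                               sample_ids = NULL) {
  if (!is.matrix(expression) || !is.numeric(expression))
    stop("`expression` must be a numeric matrix")
  n <- nrow(expression)
  p <- ncol(expression)
  if (p < 1L || n < 2L)
    stop("need at least 2 samples and 1 gene")
  if (anyNA(expression) || any(!is.finite(expression))) {
    bad <- which(!is.finite(expression), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing/non-finite expression value at sample %d, gene %d",
                 bad[1L], bad[2L]))
  }
  gene_ids <- as.character(gene_ids %||% colnames(expression) %||%
                             paste0("g", seq_len(p)))
  sample_ids <- as.character(sample_ids %||% rownames(expression) %||%
                               paste0("s", seq_len(n)))
  if (length(gene_ids) != p) stop("gene_ids length mismatch")
  if (length(sample_ids) != n) stop("sample_ids length mismatch")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ", gene_ids[anyDuplicated(gene_ids)])
  if (anyDuplicated(sample_ids)) stop("duplicate sample id")
  labels <- factor(labels)
  if (length(labels) != n) stop("labels length must equal number of samples")
  if (anyNA(labels)) stop("missing label for at least one sample")
  tab <- table(labels)
  if (length(tab) < 2L) stop("need >=2 classes in the labels")
  if (any(tab < 2L))
    stop("every class needs >=2 samples; class '",
         names(tab)[which.min(tab)], "' has ", min(tab))
  dimnames(expression) <- list(sample_ids, gene_ids)
  structure(
    list(expression = expression, labels = labels,
         gene_ids = gene_ids, sample_ids = sample_ids),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d samples x %d genes, %d classes (%s)\n",
              length(x$sample_ids), length(x$gene_ids),
              nlevels(x$labels),
              paste(table(x$labels), collapse = ":")))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$expression)

#' Subset an expression dataset
#'
#' Row subsetting allows repeated indices (bootstrap resamples); duplicated
#' sample ids are made unique. Class validity (>=2 classes, >=2 samples each)
#' is NOT re-enforced here because resamples may legitimately be degenerate;
#' callers that need validity must check `nlevels(droplevels(labels))`.
#'
#' @param data an `ExpressionDataset`.
#' @param samples integer indices of samples (may repeat).
#' @param genes logical or integer index of genes.
#' @return a new `ExpressionDataset`-classed list (not re-validated).
#' @export
subset_dataset <- function(data, samples = NULL, genes = NULL) {
  samples <- samples %||% seq_along(data$sample_ids)
  genes <- genes %||% seq_along(data$gene_ids)
  ex <- data$expression[samples, genes, drop = FALSE]
  sid <- make.unique(data$sample_ids[samples])
  rownames(ex) <- sid
  structure(
    list(expression = ex, labels = data$labels[samples],
         gene_ids = colnames(ex), sample_ids = sid),
    class = "ExpressionDataset"
  )
}

#' Read an expression table with class labels
#'
#' Reads a delimited text table (tab or comma, auto-detected from the header
#' line) with one header row of gene identifiers. By default samples are rows;
#' many microarray sets are distributed transposed, so
#' `orientation = "genes-as-rows"` transposes on load (the header then holds
#' sample identifiers and the first column gene identifiers).
#'
#' @param path path to the expression table.
#' @param label_spec either the name of a label column inside the table or the
#'   path of a companion file with one label per line (no header).
#' @param orientation `"samples-as-rows"` (default) or `"genes-as-rows"`.
#' @return a validated [expression_dataset()].
#' @export
read_expression <- function(path,
                            label_spec,
                            orientation = c("samples-as-rows",
                                            "genes-as-rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, colClasses = NULL)
  label_col <- NULL
  if (label_spec %in% names(dt)) {
    label_col <- dt[[label_spec]]
    dt <- dt[setdiff(names(dt), label_spec)]
  }

  if (orientation == "genes-as-rows") {
    gene_ids <- as.character(dt[[1L]])
    m <- t(as.matrix(dt[-1L]))
    colnames(m) <- gene_ids
  } else {
    first_chr <- !is.numeric(dt[[1L]])
    rn <- if (first_chr) as.character(dt[[1L]]) else NULL
    if (first_chr) dt <- dt[-1L]
    m <- as.matrix(dt)
    if (!is.null(rn)) rownames(m) <- rn
  }
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) &
                   !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop(sprintf("non-numeric expression cell at row %d, column %s",
                   bad[1L, 1L], colnames(m)[bad[1L, 2L]]))
    storage.mode(m) <- "double"
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value (NA) at row %d, column %s",
                 bad[1L], colnames(m)[bad[2L]]))
  }

  if (is.null(label_col)) {
    if (!file.exists(label_spec))
      stop("label_spec '", label_spec,
           "' is neither a column of the table nor an existing file")
    label_col <- readLines(label_spec)
    label_col <- label_col[nzchar(label_col)]
  }
  if (length(label_col) != nrow(m))
    stop(sprintf("got %d labels for %d samples", length(label_col), nrow(m)))
  expression_dataset(m, label_col)
}

#' Bootstrap resampling plan
#'
#' Draws `n_iterations` resamples of `n_samples` indices with replacement
#' (plain uniform, not class-stratified) and records, for each, the
#' out-of-sample complement (the "out-of-bag" set). All selection methods and
#' the post-selection error assessment share one plan so that per-iteration
#' results are paired across methods.
#'
#' If `labels` is supplied, any resample containing fewer than 2 distinct
#' classes is redrawn with an incremented derived seed (with a warning); the
#' plain procedure can produce such degenerate resamples when a class is
#' small.
#'
#' @param n_samples number of samples in the dataset.
#' @param n_iterations number of bootstrap iterations B (default 30).
#' @param seed integer seed.
#' @param labels optional factor used only for the degenerate-resample redraw.
#' @return object of class `BootstrapPlan`: list with `n_iterations`,
#'   `resamples` (list of length-B integer vectors, each of length
#'   `n_samples`), `oob_sets` (their complements), `n_samples`, `seed`.
#' @export
make_bootstrap_plan <- function(n_samples, n_iterations = 30L, seed = 1L,
                                labels = NULL) {
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  resamples <- vector("list", n_iterations)
  oob_sets <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    s <- derive_seed(seed, i)
    repeat {
      set.seed(s)
      idx <- sample.int(n_samples, n_samples, replace = TRUE)
      if (is.null(labels) ||
          length(unique(labels[idx])) >= min(2L, length(unique(labels)))) break
      warning(sprintf(
        "iteration %d: resample contained <2 classes; redrawing", i))
      s <- derive_seed(s, 1L)
    }
    resamples[[i]] <- idx
    oob_sets[[i]] <- setdiff(seq_len(n_samples), idx)
  }
  structure(
    list(n_iterations = as.integer(n_iterations), resamples = resamples,
         oob_sets = oob_sets, n_samples = as.integer(n_samples),
         seed = as.integer(seed)),
    class = "BootstrapPlan"
  )
}

#' Selection matrix
#'
#' Boolean B x p record of which genes each bootstrap iteration selected.
#'
#' @param indicator logical matrix, one row per bootstrap iteration.
#' @param method_id identifier of the producing method (e.g.
#'   `"boruta_ferns5"`).
#' @param gene_ids gene identifiers, one per column.
#' @return object of class `SelectionMatrix`.
#' @export
selection_matrix <- function(indicator, method_id, gene_ids = NULL) {
  if (!is.matrix(indicator) || !is.logical(indicator))
    stop("`indicator` must be a logical matrix")
  gene_ids <- as.character(gene_ids %||% colnames(indicator) %||%
                             paste0("g", seq_len(ncol(indicator))))
  if (length(gene_ids) != ncol(indicator)) stop("gene_ids length mismatch")
  colnames(indicator) <- gene_ids
  structure(
    list(indicator = indicator, method_id = as.character(method_id),
         gene_ids = gene_ids),
    class = "SelectionMatrix"
  )
}

#' @export
print.SelectionMatrix <- function(x, ...) {
  cat(sprintf("SelectionMatrix [%s]: %d iterations x %d genes, %.1f%% selected\n",
              x$method_id, nrow(x$indicator), ncol(x$indicator),
              100 * mean(x$indicator)))
  invisible(x)
}

#' Write / read a selection matrix as TSV
#'
#' The file holds a `#method=<id>` comment line, a header of gene ids and one
#' 0/1 row per bootstrap iteration. The round trip is lossless.
#'
#' @param sel a [selection_matrix()].
#' @param path output path.
#' @return `write_selection_matrix` returns `path` invisibly;
#'   `read_selection_matrix` returns the `SelectionMatrix`.
#' @export
write_selection_matrix <- function(sel, path) {
  stopifnot(inherits(sel, "SelectionMatrix"))
  con <- file(path, "wb") # binary mode: fixed '\n', byte-stable output
  on.exit(close(con))
  writeLines(c(paste0("#method=", sel$method_id),
               paste(sel$gene_ids, collapse = "\t")), con, sep = "\n")
  apply(sel$indicator, 1L, function(r)
    writeLines(paste(as.integer(r), collapse = "\t"), con, sep = "\n"))
  invisible(path)
}

#' @rdname write_selection_matrix
#' @export
read_selection_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1L], "#method="))
    stop("not a selection matrix file (missing #method= header): ", path)
  method_id <- sub("^#method=", "", lines[1L])
  gene_ids <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  rows <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  if (length(rows) == 0L) stop("selection matrix has no rows: ", path)
  widths <- lengths(rows)
  if (any(widths != length(gene_ids)))
    stop(sprintf("ragged row %d: %d fields, expected %d",
                 which(widths != length(gene_ids))[1L],
                 widths[widths != length(gene_ids)][1L], length(gene_ids)))
  ind <- do.call(rbind, lapply(rows, function(r) as.integer(r) != 0L))
  selection_matrix(ind, method_id, gene_ids)
}
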