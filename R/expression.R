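#' Construct an expression matrix object
#'
#' Container for a genes x samples expression matrix with a designated set
#' of normal (non-tumor) samples. Expression may be on the log2 scale (the
#' usual microarray representation) or linear; fold changes are computed
#' accordingly by [fold_changes()].
#'
#' @param values numeric matrix, genes in rows, samples in columns; must
#'   carry unique rownames (gene ids) and colnames (sample ids).
#' @param normal_samples character vector of sample ids regarded as normal
#'   tissue; must be a subset of `colnames(values)`.
#' @param scale `"log2"` or `"linear"`.
#' @return an object of class `expr_matrix` with fields `values`, `scale`,
#'   `normal_samples`.
#' @export
expression_matrix <- function(values, normal_samples, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  assert_that(is.matrix(values) && is.numeric(values), "values must be a numeric matrix")
  assert_that(!is.null(rownames(values)) && !is.null(colnames(values)),
              "values must have gene rownames and sample colnames")
  assert_that(!anyDuplicated(rownames(values)), "duplicate gene ids")
  assert_that(!anyDuplicated(colnames(values)), "duplicate sample ids")
  assert_that(all(normal_samples %in% colnames(values)),
              "normal_samples must be a subset of sample ids")
  assert_that(all(is.finite(values)), "expression values must be finite")
  structure(
    list(values = values, scale = scale,
         normal_samples = as.character(normal_samples)),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d normal), scale=%s\n",
              nrow(x$values), ncol(x$values), length(x$normal_samples), x$scale))
  invisible(x)
}

#' Gene ids of an expression matrix
#' @param expr an `expr_matrix`.
#' @return character vector of gene ids.
#' @export
expr_genes <- function(expr) rownames(expr$values)

#' Tumor (non-normal) sample ids of an expression matrix
#' @param expr an `expr_matrix`.
#' @return character vector of sample ids.
#' @export
tumor_samples <- function(expr) {
  setdiff(colnames(expr$values), expr$normal_samples)
}

#' Read an expression matrix from TSV
#'
#' First column holds gene ids, remaining columns are samples.
#'
#' @param path TSV file path.
#' @param normal_samples character vector of normal sample ids, or a path to
#'   a one-id-per-line file.
#' @param scale `"log2"` (default) or `"linear"`.
#' @return an `expr_matrix`.
#' @export
read_expression <- function(path, normal_samples, scale = "log2") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (length(normal_samples) == 1 && file.exists(normal_samples)) {
    normal_samples <- readLines(normal_samples)
    normal_samples <- normal_samples[nzchar(normal_samples)]
  }
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  expression_matrix(m, normal_samples = normal_samples, scale = scale)
}

#' Write an expression matrix to TSV
#' @param expr an `expr_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  dt <- data.table::data.table(gene_id = rownames(expr$values))
  for (s in colnames(expr$values)) dt[[s]] <- expr$values[, s]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Per-individual log2 fold changes against the mean of normals
#'
#' Each individual's expression is compared with the mean expression of the
#' normal samples, gene by gene. On the log2 scale the fold change is the
#' difference from the normal mean; on the linear scale it is
#' `log2((x + eps) / (mean_normal + eps))` with `eps = 1e-9` guarding zeros.
#'
#' @param expr an `expr_matrix` with at least 2 normal samples.
#' @param individual a tumor sample id present in `expr`.
#' @return named numeric vector of class fold changes (genes with a
#'   non-finite result are dropped with a warning).
#' @export
fold_changes <- function(expr, individual) {
  assert_that(individual %in% colnames(expr$values),
              sprintf("individual '%s' not found in expression matrix", individual))
  assert_that(length(expr$normal_samples) >= 2,
              "at least 2 normal samples required for fold changes")
  normals <- expr$values[, expr$normal_samples, drop = FALSE]
  mu <- rowMeans(normals)
  x <- expr$values[, individual]
  fc <- if (expr$scale == "log2") {
    x - mu
  } else {
    eps <- 1e-9
    log2((x + eps) / (mu + eps))
  }
  bad <- !is.finite(fc)
  if (any(bad)) {
    warning(sprintf("%d genes with non-finite fold change dropped", sum(bad)))
    fc <- fc[!bad]
  }
  fc
}
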