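# Per-individual genetic alterations: GISTIC-style thresholded copy-number
# calls plus a MAF-lite mutation table.

#' Read a GISTIC-style thresholded copy-number call matrix
#'
#' TSV with gene rows and sample columns; entries are integer calls in
#' {-2, -1, 0, 1, 2}.
#'
#' @param path TSV file.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_cna <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  mode(m) <- "integer"
  rownames(m) <- as.character(dt[[1]])
  m
}

#' Read a MAF-lite mutation table
#'
#' TSV with a header; the columns `sample_id` and `gene_id` (or the first
#' two columns) identify one mutation per row.
#'
#' @param path TSV file.
#' @return data.frame with columns `sample_id`, `gene_id`.
#' @export
read_maf <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  cols <- intersect(c("sample_id", "gene_id"), names(dt))
  if (length(cols) == 2) {
    data.frame(sample_id = as.character(dt$sample_id),
               gene_id = as.character(dt$gene_id), stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = as.character(dt[[1]]),
               gene_id = as.character(dt[[2]]), stringsAsFactors = FALSE)
  }
}

#' Genetic alteration profile of one individual
#'
#' Collects the genes altered in an individual: genes with a high-level
#' copy-number call (thresholded call of -2, homozygous deletion, or +2,
#' high-level amplification) and genes with at least one somatic mutation.
#' Low-level calls (+/-1) do not qualify.
#'
#' @param cna_matrix integer gene x sample matrix of thresholded calls in
#'   {-2,...,2} (or NULL if unavailable).
#' @param maf data.frame with columns `sample_id`, `gene_id` (or NULL).
#' @param individual sample id; must appear in at least one of the inputs.
#' @return object of class `alteration_profile`: list with `individual`,
#'   `cna_genes`, `mutated_genes`, `altered` (the union, deduplicated and
#'   sorted).
#' @export
load_alterations <- function(cna_matrix, maf, individual) {
  has_cna <- !is.null(cna_matrix) && individual %in% colnames(cna_matrix)
  has_maf <- !is.null(maf) && individual %in% maf$sample_id
  assert_that(has_cna || has_maf,
              sprintf("individual '%s' absent from both CNA and mutation inputs",
                      individual))
  cna_genes <- character(0)
  if (has_cna) {
    calls <- cna_matrix[, individual]
    bad <- which(!calls %in% -2:2)
    if (length(bad) > 0) {
      stop(sprintf("malformed CNA call %s for gene '%s', sample '%s'",
                   calls[bad[1]], rownames(cna_matrix)[bad[1]], individual),
           call. = FALSE)
    }
    cna_genes <- sort(unique(rownames(cna_matrix)[abs(calls) == 2]))
  }
  mutated <- character(0)
  if (has_maf) {
    mutated <- sort(unique(maf$gene_id[maf$sample_id == individual]))
  }
  structure(list(individual = individual,
                 cna_genes = cna_genes,
                 mutated_genes = mutated,
                 altered = sort(unique(c(cna_genes, mutated)))),
            class = "alteration_profile")
}

#' @export
print.alteration_profile <- function(x, ...) {
  cat(sprintf("alteration_profile '%s': %d CNA, %d mutated, %d altered\n",
              x$individual, length(x$cna_genes), length(x$mutated_genes),
              length(x$altered)))
  invisible(x)
}

#' Jaccard coefficient of two gene sets
#'
#' `|a intersect b| / |a union b|`; 0 if both sets are empty.
#'
#' @param a,b character vectors (treated as sets).
#' @return numeric in [0, 1].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}
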