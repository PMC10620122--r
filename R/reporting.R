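# Per-individual driver-gene -> hallmark networks and cumulative
# contribution curves.

#' Personalized driver gene - hallmark network
#'
#' For each driver gene alone, a single-seed RWR profile is tested by GSEA
#' against each of the individual's dysfunctional hallmarks; an edge
#' gene -> hallmark is emitted iff `p <= p_threshold` and NES > 0 (the
#' hallmark is significantly and positively driven by the gene). Each edge
#' carries the "core enrichment genes": the intersection of the hallmark's
#' expression-side leading edge and the propagation-side leading edge.
#'
#' @param result a `driver_set_result` with at least one driver gene.
#' @param tm a `transfer_matrix`.
#' @param dysf data.frame from [dysfunctional_hallmarks()] (its
#'   `leading_edges` attribute supplies the expression-side leading edges).
#' @param hallmarks named list of hallmark gene sets.
#' @param params an `rwr_params`.
#' @param n_perm permutations per GSEA; default 1000.
#' @param rng_seed integer seed.
#' @param p_threshold edge significance threshold; default 0.05.
#' @return data.frame with columns `gene`, `hallmark`, `nes`, `p`,
#'   `core_genes` (comma-separated); attribute `core_gene_sets` holds them
#'   as character vectors.
#' @export
driver_hallmark_network <- function(result, tm, dysf, hallmarks,
                                    params = rwr_params(), n_perm = 1000L,
                                    rng_seed = 1L, p_threshold = 0.05) {
  assert_that(length(result$driver_genes) >= 1, "no driver genes in result")
  expr_ledges <- attr(dysf, "leading_edges")
  dysf_sets <- hallmarks[dysf$set]
  rows <- list()
  cores <- list()
  for (gi in seq_along(result$driver_genes)) {
    g <- result$driver_genes[gi]
    ranking <- run_rwr(tm, g, params)$p
    res <- gsea_collection(ranking, dysf_sets, n_perm = n_perm,
                           rng_seed = derive_seed(rng_seed, gi))
    prop_ledges <- attr(res, "leading_edges")
    hit <- res$p <= p_threshold & !is.na(res$nes) & res$nes > 0
    for (s in res$set[hit]) {
      core <- intersect(expr_ledges[[s]] %||% character(0),
                        prop_ledges[[s]] %||% character(0))
      key <- paste(g, s, sep = "\r")
      cores[[key]] <- core
      rows[[key]] <- data.frame(
        gene = g, hallmark = s,
        nes = res$nes[res$set == s], p = res$p[res$set == s],
        core_genes = paste(core, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), hallmark = character(0),
                      nes = numeric(0), p = numeric(0),
                      core_genes = character(0))
  }
  rownames(out) <- NULL
  # every emitted edge must satisfy both constraints
  stopifnot(all(out$p <= p_threshold), all(out$nes > 0))
  attr(out, "core_gene_sets") <- cores
  out
}

#' Cumulative contribution curve of a driver gene set
#'
#' Fitness (PCC between Dscores and Escores) of the growing prefixes
#' {g1}, {g1, g2}, ..., of the driver genes in the given order. The last
#' value equals the full driver set's PCC exactly. The default order adds
#' genes by decreasing single-gene fitness.
#'
#' @param result a `driver_set_result`.
#' @param ctx the `fitness_context` used to obtain `result`.
#' @param order optional permutation (character vector) of
#'   `result$driver_genes`.
#' @return named numeric vector of prefix PCCs (names: the gene added at
#'   each step).
#' @export
cumulative_contribution <- function(result, ctx, order = NULL) {
  genes <- result$driver_genes
  assert_that(length(genes) >= 1, "no driver genes in result")
  if (is.null(order)) {
    single <- vapply(genes, function(g) {
      evaluate_fitness(as.integer(ctx$genes == g), ctx)
    }, numeric(1))
    order <- genes[base::order(-single, genes)]
  }
  assert_that(setequal(order, genes) && length(order) == length(genes),
              "order must be a permutation of the driver genes")
  out <- vapply(seq_along(order), function(i) {
    bits <- as.integer(ctx$genes %in% order[seq_len(i)])
    evaluate_fitness(bits, ctx)
  }, numeric(1))
  names(out) <- order
  out
}

#' Write a driver-hallmark edge list to TSV
#' @param edges data.frame from [driver_hallmark_network()] (optionally
#'   with an `individual` column prepended by the pipeline).
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  data.table::fwrite(edges, path, sep = "\t")
  invisible(path)
}
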