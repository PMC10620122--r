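# Candidate driver screening: an altered gene is a candidate driver if the
# GSEA of its single-seed RWR stationary profile is significant for at
# least one cancer hallmark.

#' Screen altered genes for candidate driver ability
#'
#' For each altered gene present in the network, a single-seed random walk
#' with restart is run and all network genes are ranked by their stationary
#' probability; every hallmark gene set is then tested by permutation GSEA
#' against that ranking. The gene is retained as a candidate driver iff at
#' least one hallmark reaches `p <= p_threshold` (either ES sign; the sign
#' is recorded). Altered genes absent from the network are skipped with a
#' message.
#'
#' @param profile an `alteration_profile`.
#' @param tm a `transfer_matrix`.
#' @param hallmarks named list of hallmark gene sets.
#' @param params an `rwr_params`.
#' @param n_perm permutations per GSEA; default 1000.
#' @param rng_seed integer seed.
#' @param p_threshold significance threshold; default 0.05.
#' @param drop_seed_from_ranking if TRUE, the seed gene itself is removed
#'   from the ranked list before GSEA; default FALSE.
#' @return object of class `candidate_set`: list with `individual`, `genes`
#'   (candidates in lexicographic order), `hallmark_table` (data.frame
#'   gene, set, es, nes, p over the significant gene-hallmark pairs), and
#'   `skipped` (altered genes not in the network).
#' @export
select_candidates <- function(profile, tm, hallmarks, params = rwr_params(),
                              n_perm = 1000L, rng_seed = 1L,
                              p_threshold = 0.05,
                              drop_seed_from_ranking = FALSE) {
  assert_that(length(profile$altered) > 0, "alteration profile is empty")
  in_net <- profile$altered %in% tm$nodes
  skipped <- profile$altered[!in_net]
  if (length(skipped) > 0) {
    message(sprintf("%d altered gene(s) not in network, skipped: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  }
  genes <- profile$altered[in_net]
  if (length(genes) == 0) stop("no mappable alterations", call. = FALSE)
  rows <- list()
  keep <- logical(length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    ranking <- run_rwr(tm, g, params)$p
    if (drop_seed_from_ranking) ranking <- ranking[names(ranking) != g]
    res <- gsea_collection(ranking, hallmarks, n_perm = n_perm,
                           rng_seed = derive_seed(rng_seed, gi))
    sig <- res[res$p <= p_threshold, , drop = FALSE]
    if (nrow(sig) > 0) {
      keep[gi] <- TRUE
      rows[[g]] <- data.frame(gene = g, set = sig$set, es = sig$es,
                              nes = sig$nes, p = sig$p,
                              stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(gene = character(0), set = character(0),
                      es = numeric(0), nes = numeric(0), p = numeric(0))
  }
  rownames(tab) <- NULL
  structure(list(individual = profile$individual,
                 genes = sort(genes[keep]),
                 hallmark_table = tab,
                 skipped = skipped),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set '%s': %d candidate(s); %d altered gene(s) not in network\n",
              x$individual, length(x$genes), length(x$skipped)))
  invisible(x)
}

#' Write the per-gene significant-hallmark audit table
#' @param cands a `candidate_set`.
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(cands, path) {
  data.table::fwrite(cands$hallmark_table, path, sep = "\t")
  invisible(path)
}
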