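# End-to-end per-individual pipeline: fold changes -> dysfunctional
# hallmarks -> alterations -> candidate screen -> genetic algorithm ->
# driver set + driver-hallmark network.

#' Pipeline configuration
#'
#' Bundles every tunable parameter of the method with its default:
#' restart probability 0.3, RWR tolerance 1e-10, 1000 GSEA permutations,
#' significance threshold 0.05, ssGSEA exponent 0.25, GSEA weight exponent
#' 1, crossover 0.9, mutation 0.01, tournament size 3.
#'
#' @param restart RWR restart probability.
#' @param tol RWR convergence tolerance.
#' @param max_iter RWR iteration cap.
#' @param n_perm GSEA permutations.
#' @param p_threshold significance threshold for dysfunctional hallmarks,
#'   candidate screening, and driver-hallmark edges.
#' @param alpha ssGSEA rank-weight exponent.
#' @param weight_exp GSEA hit-weight exponent.
#' @param crossover_prob,mutation_prob,tournament_k genetic operators.
#' @param exhaustive_max_L exhaustive search is considered feasible up to
#'   this many candidates (used by tests/cross-checks; the pipeline itself
#'   always runs the genetic algorithm unless `method = "exhaustive"`).
#' @param method `"ga"` or `"exhaustive"`.
#' @param seed root seed; all per-individual and per-stage seeds derive
#'   from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(restart = 0.3, tol = 1e-10, max_iter = 10000L,
                            n_perm = 1000L, p_threshold = 0.05,
                            alpha = 0.25, weight_exp = 1,
                            crossover_prob = 0.9, mutation_prob = 0.01,
                            tournament_k = 3L, exhaustive_max_L = 12L,
                            method = "ga", seed = 1L) {
  structure(list(restart = restart, tol = tol, max_iter = as.integer(max_iter),
                 n_perm = as.integer(n_perm), p_threshold = p_threshold,
                 alpha = alpha, weight_exp = weight_exp,
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 tournament_k = as.integer(tournament_k),
                 exhaustive_max_L = as.integer(exhaustive_max_L),
                 method = method, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Identify the driver gene set of one individual
#'
#' Runs the whole per-individual chain against a prebuilt transfer matrix:
#' fold changes, dysfunctional hallmarks (>= 3 required), Escores,
#' alteration profile, candidate screening, genetic algorithm search, and
#' the driver-hallmark network with the cumulative contribution curve.
#'
#' @param individual tumor sample id.
#' @param expr an `expr_matrix`.
#' @param tm a `transfer_matrix` (largest component, column-normalized).
#' @param hallmarks named list of hallmark gene sets.
#' @param cna integer gene x sample CNA call matrix (or NULL).
#' @param maf mutation data.frame (or NULL).
#' @param config a `pipeline_config`.
#' @param individual_index integer used to derive this individual's seeds.
#' @return a `driver_set_result` with additional fields `dysfunctional`
#'   (the hallmark table), `edges` (driver-hallmark network),
#'   `cumulative` (contribution curve), `candidates`.
#' @export
identify_drivers <- function(individual, expr, tm, hallmarks, cna, maf,
                             config = pipeline_config(),
                             individual_index = 1L) {
  seed_i <- derive_seed(config$seed, individual_index)
  rp <- rwr_params(config$restart, config$tol, config$max_iter)
  fc <- fold_changes(expr, individual)
  dysf <- dysfunctional_hallmarks(fc, hallmarks,
                                  p_threshold = config$p_threshold,
                                  n_perm = config$n_perm,
                                  rng_seed = derive_seed(seed_i, 1),
                                  weight_exp = config$weight_exp)
  if (nrow(dysf) < 3) {
    stop(sprintf("individual '%s' has %d dysfunctional hallmarks (< 3)",
                 individual, nrow(dysf)), call. = FALSE)
  }
  dysf_sets <- hallmarks[dysf$set]
  escores <- ssgsea_collection(fc, dysf_sets, alpha = config$alpha)
  profile <- load_alterations(cna, maf, individual)
  cands <- select_candidates(profile, tm, hallmarks, params = rp,
                             n_perm = config$n_perm,
                             rng_seed = derive_seed(seed_i, 2),
                             p_threshold = config$p_threshold)
  if (length(cands$genes) == 0) {
    stop(sprintf("individual '%s' has no candidate driver genes", individual),
         call. = FALSE)
  }
  ctx <- build_fitness_context(cands, tm, dysf_sets, escores,
                               params = rp, alpha = config$alpha)
  result <- optimize_drivers(
    ctx,
    ga_config(crossover_prob = config$crossover_prob,
              mutation_prob = config$mutation_prob,
              tournament_k = config$tournament_k,
              rng_seed = derive_seed(seed_i, 3)),
    method = config$method)
  result$individual <- individual
  result$dysfunctional <- dysf
  result$candidates <- cands$genes
  result$edges <- driver_hallmark_network(result, tm, dysf, hallmarks,
                                          params = rp,
                                          n_perm = config$n_perm,
                                          rng_seed = derive_seed(seed_i, 4),
                                          p_threshold = config$p_threshold)
  result$cumulative <- cumulative_contribution(result, ctx)
  result
}

#' Run the pipeline over a cohort
#'
#' Individuals are the intersection of the tumor expression samples, the
#' CNA matrix columns, and the mutation table samples. Individuals with
#' fewer than 3 dysfunctional hallmarks, no mappable alterations, or no
#' candidates are skipped with a recorded reason rather than failing the
#' run. Optionally writes per-individual JSON results, a cohort TSV, the
#' assembled driver-hallmark edge TSV, and a run manifest.
#'
#' @param expr an `expr_matrix`.
#' @param edges interaction edge list data.frame (gene_a, gene_b).
#' @param hallmarks named list of hallmark gene sets.
#' @param cna integer CNA call matrix.
#' @param maf mutation data.frame.
#' @param config a `pipeline_config`.
#' @param outdir output directory, or NULL to skip writing.
#' @return list of class `cohort_result`: `results` (named list of
#'   `driver_set_result`), `skipped` (named character of reasons),
#'   `tm` (the transfer matrix used), `config`.
#' @export
run_pipeline <- function(expr, edges, hallmarks, cna, maf,
                         config = pipeline_config(), outdir = NULL) {
  net <- build_weighted_network(edges, expr)
  tm <- column_normalize(largest_component(net))
  individuals <- Reduce(intersect, list(tumor_samples(expr),
                                        colnames(cna),
                                        unique(maf$sample_id)))
  individuals <- sort(individuals)
  assert_that(length(individuals) > 0,
              "no individual present in expression, CNA and mutation data")
  results <- list()
  skipped <- character(0)
  for (i in seq_along(individuals)) {
    ind <- individuals[i]
    res <- tryCatch(
      identify_drivers(ind, expr, tm, hallmarks, cna, maf, config,
                       individual_index = i),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      message(sprintf("skipping '%s': %s", ind, res))
      skipped[ind] <- res
    } else {
      results[[ind]] <- res
    }
  }
  out <- structure(list(results = results, skipped = skipped, tm = tm,
                        config = config),
                   class = "cohort_result")
  if (!is.null(outdir)) write_cohort(out, outdir)
  out
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("cohort_result: %d individuals analysed, %d skipped\n",
              length(x$results), length(x$skipped)))
  invisible(x)
}

#' Cohort summary table
#' @param cohort a `cohort_result`.
#' @return data.frame, one row per analysed individual.
#' @export
cohort_summary <- function(cohort) {
  rows <- lapply(cohort$results, function(r) {
    data.frame(individual = r$individual,
               n_candidates = r$n_candidates,
               n_drivers = length(r$driver_genes),
               driver_genes = paste(r$driver_genes, collapse = ","),
               pcc = r$pcc, p_value = r$p_value,
               significant = r$significant,
               n_dysfunctional = nrow(r$dysfunctional),
               generations = r$generations_run,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write cohort results to disk
#'
#' Writes `cohort.tsv` (summary), `driver_hallmark_edges.tsv` (assembled
#' edge list with an `individual` column), one `result_<id>.json` per
#' individual, and `manifest.json` (parameters, seed, skip reasons,
#' package and R versions).
#'
#' @param cohort a `cohort_result`.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(cohort_summary(cohort),
                     file.path(outdir, "cohort.tsv"), sep = "\t")
  all_edges <- do.call(rbind, lapply(cohort$results, function(r) {
    if (nrow(r$edges) == 0) return(NULL)
    cbind(individual = r$individual, r$edges)
  }))
  if (is.null(all_edges)) {
    all_edges <- data.frame(individual = character(0), gene = character(0),
                            hallmark = character(0), nes = numeric(0),
                            p = numeric(0), core_genes = character(0))
  }
  write_edge_list(all_edges, file.path(outdir, "driver_hallmark_edges.tsv"))
  for (r in cohort$results) {
    jsonlite::write_json(
      list(individual = r$individual,
           driver_genes = r$driver_genes,
           pcc = r$pcc, p_value = r$p_value,
           significant = r$significant,
           n_candidates = r$n_candidates,
           generations = r$generations_run,
           dscores = as.list(r$dscores),
           escores = as.list(r$escores),
           cumulative = as.list(r$cumulative)),
      file.path(outdir, sprintf("result_%s.json", r$individual)),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    list(parameters = unclass(cohort$config),
         skipped = as.list(cohort$skipped),
         n_individuals = length(cohort$results),
         package_version = as.character(utils::packageVersion("gadriver")),
         r_version = R.version.string),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
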