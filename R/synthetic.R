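# Self-contained synthetic cohorts with planted per-individual driver
# genes. The generative model deliberately matches the method's own
# assumption -- drivers act through network propagation onto hallmark
# genes -- so that recovering the planted drivers tests the implementation,
# not the biological model.

#' Generate a synthetic cohort fixture with planted drivers
#'
#' Builds (1) a connected scale-free interaction graph (preferential
#' attachment); (2) hallmark gene sets as unions of one-hop neighborhoods
#' of randomly chosen center genes; (3) per-individual tumor expression:
#' a shared log2 baseline plus `effect_size` times the planted drivers'
#' multi-seed RWR stationary profile (max-normalized and quarter-power
#' flattened so the diffusion signature spans the network) plus Gaussian
#' noise smoothed one step over the graph (interacting genes co-vary, the
#' co-expression the pipeline's edge weights estimate); normal samples are
#' baseline plus noise only; (4) alteration calls:
#' each planted driver and each random passenger is assigned either a
#' high-level copy-number call (+/-2) or a mutation row, and low-level
#' (+/-1) background calls are sprinkled in. The planted truth is recorded.
#'
#' @param n_genes number of genes (>= 200); default 500.
#' @param attach_m edges added per vertex during preferential attachment
#'   (total edges ~ `attach_m * n_genes`); default 4 (~2000 edges).
#' @param n_individuals tumor samples; default 20.
#' @param n_normals normal samples; default 10.
#' @param n_hallmarks number of hallmark gene sets; default 30.
#' @param centers_per_hallmark neighborhood centers unioned per hallmark;
#'   default 3.
#' @param drivers_per_individual planted drivers, 1..7; default 3.
#' @param passenger_alterations additional altered non-driver genes per
#'   individual (>= drivers); default 10.
#' @param effect_size log2 expression shift at the driver itself; default 6
#'   (a strong lesion, e.g. a high-level amplification).
#' @param noise_sd Gaussian noise sd on log2 expression; default 0.15.
#' @param baseline_mean,baseline_sd per-gene baseline log2 expression
#'   distribution; defaults 8 and 1.5.
#' @param restart RWR restart probability used to diffuse the planted
#'   signal; default 0.3.
#' @param seed integer seed; the fixture is deterministic given it.
#' @return object of class `driver_fixture`: list with `expr`
#'   (`expr_matrix`), `edges` (data.frame), `hallmarks` (named list),
#'   `cna` (integer matrix), `maf` (data.frame), `truth` (named list of
#'   planted driver sets), `gen_params`.
#' @export
generate_fixture <- function(n_genes = 500L, attach_m = 4L,
                             n_individuals = 20L, n_normals = 10L,
                             n_hallmarks = 30L, centers_per_hallmark = 3L,
                             drivers_per_individual = 3L,
                             passenger_alterations = 10L,
                             effect_size = 6, noise_sd = 0.15,
                             baseline_mean = 8, baseline_sd = 1.5,
                             restart = 0.3, seed = 1L) {
  assert_that(n_genes >= 200, "n_genes must be >= 200")
  assert_that(drivers_per_individual >= 1 && drivers_per_individual <= 7,
              "drivers_per_individual must be in 1..7")
  assert_that(passenger_alterations >= drivers_per_individual,
              "passenger_alterations must be >= drivers_per_individual")
  assert_that(n_hallmarks >= drivers_per_individual,
              "need at least as many hallmarks as planted drivers")
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  withr::with_seed(seed, {
    g <- igraph::sample_pa(n_genes, m = attach_m, directed = FALSE)
    igraph::V(g)$name <- gene_ids
    el <- igraph::as_edgelist(g)
    edges <- unique(data.frame(gene_a = pmin(el[, 1], el[, 2]),
                               gene_b = pmax(el[, 1], el[, 2]),
                               stringsAsFactors = FALSE))
    edges <- edges[edges$gene_a != edges$gene_b, ]
    rownames(edges) <- NULL

    # structural transfer matrix (unit weights) used to diffuse signal
    net <- structure(list(nodes = gene_ids,
                          edges = cbind(edges, weight = 1)),
                     class = "weighted_network")
    tm <- column_normalize(net)

    # hallmarks: unions of closed one-hop neighborhoods of random centers
    hallmarks <- list()
    centers <- list()
    for (h in seq_len(n_hallmarks)) {
      cs <- sample(gene_ids, centers_per_hallmark)
      members <- unique(unlist(lapply(
        igraph::ego(g, order = 1, nodes = cs), names)))
      while (length(members) < 10) {
        extra <- sample(setdiff(gene_ids, c(cs, members)), 1)
        cs <- c(cs, extra)
        members <- unique(c(members, names(igraph::ego(g, 1, extra)[[1]])))
      }
      nm <- sprintf("HALLMARK_%02d", h)
      hallmarks[[nm]] <- sort(members)
      centers[[nm]] <- cs
    }
    tumor_ids <- sprintf("ind%02d", seq_len(n_individuals))
    normal_ids <- sprintf("norm%02d", seq_len(n_normals))
    baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    names(baseline) <- gene_ids

    # per-sample noise, smoothed one step over the interaction graph so
    # that interacting genes co-vary across the cohort (the co-expression
    # the pipeline's edge weights are estimated from)
    sample_noise <- function() {
      e <- stats::rnorm(n_genes)
      z <- e + 2 * as.vector(tm$W %*% e)
      z * (noise_sd / stats::sd(z))
    }

    vals <- matrix(NA_real_, n_genes, n_individuals + n_normals,
                   dimnames = list(gene_ids, c(tumor_ids, normal_ids)))
    truth <- list()
    altered <- list()
    rp <- rwr_params(r = restart)
    for (i in seq_len(n_individuals)) {
      hs <- sample(names(hallmarks), drivers_per_individual)
      drivers <- vapply(hs, function(h) sample(centers[[h]], 1), character(1))
      drivers <- unique(unname(drivers))
      while (length(drivers) < drivers_per_individual) {
        h <- sample(names(hallmarks), 1)
        drivers <- unique(c(drivers, sample(centers[[h]], 1)))
      }
      p <- run_rwr(tm, drivers, rp)$p
      s <- (p / max(p))^0.25                      # flatten the sharp diffusion decay
      # signal spans the whole network (see vignette)
      s[drivers] <- 1                             # the lesion itself
      vals[, tumor_ids[i]] <- baseline + effect_size * s + sample_noise()
      passengers <- sample(setdiff(gene_ids, drivers), passenger_alterations)
      truth[[tumor_ids[i]]] <- sort(drivers)
      altered[[tumor_ids[i]]] <- list(drivers = drivers, passengers = passengers)
    }
    for (j in seq_len(n_normals)) {
      vals[, normal_ids[j]] <- baseline + sample_noise()
    }

    # alteration calls: each altered gene is either CNA(+/-2) or mutated
    cna <- matrix(0L, n_genes, n_individuals,
                  dimnames = list(gene_ids, tumor_ids))
    maf_rows <- list()
    for (i in seq_len(n_individuals)) {
      al <- altered[[tumor_ids[i]]]
      for (gx in c(al$drivers, al$passengers)) {
        if (stats::runif(1) < 0.5) {
          cna[gx, i] <- sample(c(-2L, 2L), 1)
        } else {
          maf_rows[[length(maf_rows) + 1L]] <-
            data.frame(sample_id = tumor_ids[i], gene_id = gx,
                       variant_class = "Missense_Mutation",
                       stringsAsFactors = FALSE)
        }
      }
      # low-level background calls that must not qualify as alterations
      bg <- sample(setdiff(gene_ids, c(al$drivers, al$passengers)), 5)
      cna[bg, i] <- sample(c(-1L, 1L), 5, replace = TRUE)
    }
    maf <- do.call(rbind, maf_rows)
    if (is.null(maf)) {
      maf <- data.frame(sample_id = character(0), gene_id = character(0),
                        variant_class = character(0))
    }

    expr <- expression_matrix(round(vals, 6), normal_samples = normal_ids,
                              scale = "log2")
    structure(list(expr = expr, edges = edges, hallmarks = hallmarks,
                   cna = cna, maf = maf, truth = truth,
                   gen_params = list(n_genes = n_genes, attach_m = attach_m,
                                     n_individuals = n_individuals,
                                     n_normals = n_normals,
                                     n_hallmarks = n_hallmarks,
                                     centers_per_hallmark = centers_per_hallmark,
                                     drivers_per_individual = drivers_per_individual,
                                     passenger_alterations = passenger_alterations,
                                     effect_size = effect_size,
                                     noise_sd = noise_sd,
                                     baseline_mean = baseline_mean,
                                     baseline_sd = baseline_sd,
                                     restart = restart, seed = seed)),
              class = "driver_fixture")
  })
}

#' @export
print.driver_fixture <- function(x, ...) {
  gp <- x$gen_params
  cat(sprintf(paste0("driver_fixture: %d genes, %d edges, %d tumors + %d ",
                     "normals, %d hallmarks, %d planted drivers each (seed %d)\n"),
              gp$n_genes, nrow(x$edges), gp$n_individuals, gp$n_normals,
              gp$n_hallmarks, gp$drivers_per_individual, gp$seed))
  invisible(x)
}

#' Write a fixture to disk in the dialects the pipeline reads
#'
#' Writes expression.tsv, normals.txt, edges.tsv, hallmarks.gmt, cna.tsv,
#' maf.tsv and truth.json under `dir`.
#'
#' @param fixture a `driver_fixture`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(fixture$expr, file.path(dir, "expression.tsv"))
  writeLines(fixture$expr$normal_samples, file.path(dir, "normals.txt"))
  data.table::fwrite(fixture$edges, file.path(dir, "edges.tsv"), sep = "\t")
  write_gmt(fixture$hallmarks, file.path(dir, "hallmarks.gmt"))
  cna_dt <- data.table::data.table(gene_id = rownames(fixture$cna))
  for (s in colnames(fixture$cna)) cna_dt[[s]] <- fixture$cna[, s]
  data.table::fwrite(cna_dt, file.path(dir, "cna.tsv"), sep = "\t")
  data.table::fwrite(fixture$maf, file.path(dir, "maf.tsv"), sep = "\t")
  jsonlite::write_json(fixture$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
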