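# Small in-code fixtures shared across test files.

# Expression matrix with given dimensions filled with seeded noise.
random_expr <- function(n_genes, samples, normals = character(0), seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * length(samples), 8, 2),
                nrow = n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)), samples))
    expression_matrix(m, normal_samples = normals)
  })
}

# Transfer matrix of a tiny named weighted graph given as a data.frame.
toy_tm <- function(edges_df) {
  nodes <- sort(unique(c(edges_df$gene_a, edges_df$gene_b)))
  net <- structure(list(nodes = nodes, edges = edges_df),
                   class = "weighted_network")
  column_normalize(net)
}

# Random connected weighted graph on n nodes (spanning tree + extra edges).
random_tm <- function(n, extra = n, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("n%02d", seq_len(n))
    a <- ids[unlist(lapply(2:n, function(i) sample(i - 1, 1)))]
    b <- ids[2:n]
    if (extra > 0) {
      i <- sample(n, extra, replace = TRUE)
      j <- sample(n, extra, replace = TRUE)
      keep <- i != j
      a <- c(a, ids[pmin(i, j)[keep]])
      b <- c(b, ids[pmax(i, j)[keep]])
    }
    df <- unique(data.frame(gene_a = pmin(a, b), gene_b = pmax(a, b),
                            stringsAsFactors = FALSE))
    df$weight <- runif(nrow(df), 0.05, 1)
    toy_tm(df)
  })
}

# Brute-force GSEA running sum: walks all n positions explicitly.
brute_gsea_es <- function(ranking, gene_set, weight_exp = 1) {
  s <- ranking[order(-ranking, names(ranking))]
  hit <- names(s) %in% gene_set
  n <- length(s)
  k <- sum(hit)
  w <- abs(s)^weight_exp
  tw <- sum(w[hit])
  inc <- if (tw > 0) w / tw else rep(1 / k, n)
  run <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- if (hit[i]) cur + inc[i] else cur - 1 / (n - k)
    run[i] <- cur
  }
  # extremum of largest magnitude; exact ties resolve to the positive side
  if (max(run, 0) >= -min(run, 0)) max(run, 0) else min(run, 0)
}

# Brute-force ssGSEA: explicit weighted in-set ECDF minus out-set ECDF,
# rank weights (n - i + 1)^alpha.
brute_ssgsea_es <- function(scores, gene_set, alpha = 0.25) {
  s <- scores[order(-scores, names(scores))]
  n <- length(s)
  hit <- names(s) %in% gene_set
  u <- ifelse(hit, (n - seq_len(n) + 1)^alpha, 0)
  p_in <- cumsum(u) / sum(u)
  p_out <- cumsum(!hit) / sum(!hit)
  sum(p_in - p_out)
}
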