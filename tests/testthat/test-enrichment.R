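test_that("fold changes follow the definitional formula on both scales", {
  m <- matrix(c(3, 1, 8,    2, 2, 2,   2, 2, 2), nrow = 3,
              dimnames = list(c("ga", "gb", "gc"), c("t1", "n1", "n2")))
  expr <- expression_matrix(m, normal_samples = c("n1", "n2"), scale = "log2")
  fc <- fold_changes(expr, "t1")
  expect_equal(unname(fc["ga"]), 1)     # 3 - mean(2,2)
  expect_equal(unname(fc["gb"]), -1)
  expect_equal(unname(fc["gc"]), 6)

  lin <- expression_matrix(matrix(c(8, 4, 2, 2, 2, 2), nrow = 2,
                                  dimnames = list(c("ga", "gb"),
                                                  c("t1", "n1", "n2"))),
                           normal_samples = c("n1", "n2"), scale = "linear")
  fcl <- fold_changes(lin, "t1")
  expect_equal(unname(fcl["ga"]), 2, tolerance = 1e-6)   # log2(8/2)
  expect_equal(unname(fcl["gb"]), 1, tolerance = 1e-6)   # log2(4/2)

  # random fixture vs elementwise oracle
  expr <- random_expr(20, c("t1", "t2", "n1", "n2", "n3"),
                      normals = c("n1", "n2", "n3"), seed = 8)
  fc <- fold_changes(expr, "t2")
  mu <- rowMeans(expr$values[, c("n1", "n2", "n3")])
  expect_equal(fc, expr$values[, "t2"] - mu)
  expect_error(fold_changes(expr, "nope"), "not found")
})

test_that("GSEA extreme sets reach ES of +1 and -1", {
  ranking <- c(a = 4, b = 3, c = 2, d = 1)
  top <- gsea(ranking, "a", n_perm = 50, rng_seed = 1)
  expect_equal(top$es, 1.0)
  expect_equal(top$leading_edge, "a")
  bottom <- gsea(ranking, "d", n_perm = 50, rng_seed = 1)
  expect_equal(bottom$es, -1.0)
  expect_equal(bottom$leading_edge, "d")
})

test_that("GSEA ES equals the brute-force running-sum oracle exactly", {
  for (seed in 1:25) {
    withr::with_seed(seed, {
      n <- sample(4:10, 1)
      ranking <- setNames(rnorm(n), sprintf("x%02d", sample(n)))
      k <- sample(1:(n - 1), 1)
      set <- sample(names(ranking), k)
    })
    res <- gsea(ranking, set, n_perm = 10, rng_seed = seed)
    expect_equal(res$es, brute_gsea_es(ranking, set), tolerance = 1e-12)
    expect_true(res$es >= -1 && res$es <= 1)
    expect_true(all(res$leading_edge %in% set))
    if (abs(res$es) > 0) expect_gt(length(res$leading_edge), 0)
  }
})

test_that("GSEA p-values are reproducible given the seed and lie in (0, 1]", {
  withr::with_seed(42, {
    ranking <- setNames(rnorm(200), sprintf("g%03d", 1:200))
    set <- sample(names(ranking), 15)
  })
  r1 <- gsea(ranking, set, n_perm = 500, rng_seed = 99)
  r2 <- gsea(ranking, set, n_perm = 500, rng_seed = 99)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$nes, r2$nes)
  expect_true(r1$p > 0 && r1$p <= 1)
  r3 <- gsea(ranking, set, n_perm = 500, rng_seed = 100)
  expect_true(is.numeric(r3$p))  # different seed still valid
})

test_that("reversing a ranking negates the unweighted ES", {
  withr::with_seed(7, {
    ranking <- setNames(sample(seq(1, 3, length.out = 12)), letters[1:12])
    set <- sample(names(ranking), 4)
  })
  es_fwd <- gsea(ranking, set, n_perm = 10, rng_seed = 1, weight_exp = 0)$es
  es_rev <- gsea(-ranking, set, n_perm = 10, rng_seed = 1, weight_exp = 0)$es
  expect_equal(es_fwd, -es_rev, tolerance = 1e-12)
  # order-preserving shift leaves the unweighted ES unchanged
  es_shift <- gsea(ranking + 100, set, n_perm = 10, rng_seed = 1,
                   weight_exp = 0)$es
  expect_equal(es_fwd, es_shift, tolerance = 1e-12)
})

test_that("gsea errors on unrepresented or all-covering sets", {
  ranking <- c(a = 2, b = 1)
  expect_error(gsea(ranking, "zz"), "not represented")
  expect_error(gsea(ranking, c("a", "b")), "entire ranking")
})

test_that("ssGSEA matches the hand-enumerated ECDF oracle", {
  # alpha = 0, set = top half of a 4-gene ranking
  scores <- c(w = 4, x = 3, y = 2, z = 1)
  set <- c("w", "x")
  expect_equal(ssgsea(scores, set, alpha = 0)$es,
               brute_ssgsea_es(scores, set, alpha = 0), tolerance = 1e-12)
  # positions 1,2 of 4: unweighted P_in = 1/2,1,1,1; P_out = 0,0,1/2,1
  expect_equal(ssgsea(scores, set, alpha = 0)$es, 0.5 + 1 + 0.5 + 0)

  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- sample(5:10, 1)
      scores <- setNames(rnorm(n), sprintf("s%02d", sample(n)))
      set <- sample(names(scores), sample(1:(n - 1), 1))
      alpha <- sample(c(0, 0.25, 1), 1)
    })
    expect_equal(ssgsea(scores, set, alpha = alpha)$es,
                 brute_ssgsea_es(scores, set, alpha = alpha),
                 tolerance = 1e-12)
  }
})

test_that("moving an in-set gene up in rank never decreases the ssGSEA score", {
  withr::with_seed(3, {
    scores <- setNames(sort(runif(12), decreasing = TRUE), letters[1:12])
    set <- c("h", "k")
  })
  base <- ssgsea(scores, set)$es
  # swap in-set gene "h" (rank 8) with out-of-set gene "d" (rank 4)
  swapped <- scores
  swapped[c("h", "d")] <- swapped[c("d", "h")]
  expect_gte(ssgsea(swapped, set)$es, base)
  expect_error(ssgsea(scores, names(scores)), "entire ranking")
})

test_that("dysfunctional hallmark calling retains truly enriched sets", {
  withr::with_seed(21, {
    fc <- setNames(rnorm(500), sprintf("g%03d", 1:500))
  })
  top20 <- names(sort(fc, decreasing = TRUE))[1:20]
  hallmarks <- list(TOP = top20,
                    RAND = sprintf("g%03d", seq(5, 480, by = 16)))
  res <- dysfunctional_hallmarks(fc, hallmarks, n_perm = 1000, rng_seed = 5)
  expect_true("TOP" %in% res$set)
  expect_true(all(res$p <= 0.05))
  le <- attr(res, "leading_edges")
  expect_true(all(le$TOP %in% top20))
})

test_that("null hallmarks are retained at about the nominal 5% rate", {
  withr::with_seed(100, {
    fc <- setNames(rnorm(300), sprintf("g%03d", 1:300))
  })
  n_trials <- 1000
  hits <- 0
  for (i in seq_len(n_trials)) {
    set <- withr::with_seed(2000 + i, sample(names(fc), 15))
    p <- gsea(fc, set, n_perm = 200, rng_seed = 3000 + i)$p
    if (p <= 0.05) hits <- hits + 1
  }
  rate <- hits / n_trials
  # binomial 99.9% envelope around 0.05 for 1000 trials is ~ +/- 0.023
  expect_gt(rate, 0.05 - 0.025)
  expect_lt(rate, 0.05 + 0.025)
})

test_that("a p-value exactly at the threshold is retained", {
  df <- data.frame(set = c("A", "B"), size = c(5L, 5L), es = c(0.9, 0.2),
                   nes = c(2, 0.5), p = c(0.05, 0.051))
  attr(df, "leading_edges") <- list(A = "g1", B = "g2")
  # filter logic mirrors dysfunctional_hallmarks: boundary inclusive
  keep <- df[df$p <= 0.05, ]
  expect_equal(keep$set, "A")
})

test_that("GMT round trip preserves the collection", {
  sets <- list(S1 = c("a", "b", "c"), S2 = c("d", "e"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back[["S1"]], sets$S1)
  expect_equal(back[["S2"]], sets$S2)
  if (requireNamespace("fgsea", quietly = TRUE)) {
    ref <- fgsea::gmtPathways(path)
    expect_equal(ref[["S1"]], sets$S1)
    expect_equal(ref[["S2"]], sets$S2)
  }
})

test_that("GSEA ES agrees with the fgsea statistic", {
  skip_if_not_installed("fgsea")
  withr::with_seed(17, {
    ranking <- setNames(rnorm(100), sprintf("g%03d", 1:100))
    set <- sample(names(ranking), 12)
  })
  ours <- gsea(ranking, set, n_perm = 10, rng_seed = 1)$es
  ord <- order(-ranking, names(ranking))
  ref <- fgsea::calcGseaStat(ranking[ord],
                             selectedStats = which(names(ranking)[ord] %in% set),
                             gseaParam = 1, scoreType = "std")
  expect_equal(ours, unname(ref), tolerance = 1e-6)
})
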