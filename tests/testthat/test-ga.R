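# Fitness contexts for GA tests are built on a small random graph with
# hallmarks taken from node neighborhoods, so Dscores are real ssGSEA
# values rather than canned numbers.
make_ctx <- function(n = 60, n_cand = 6, n_sets = 5, seed = 1,
                     escores = NULL) {
  tm <- random_tm(n, extra = 2 * n, seed = seed)
  withr::with_seed(seed + 1000, {
    cand <- sort(sample(tm$nodes, n_cand))
    sets <- lapply(seq_len(n_sets), function(i) sample(tm$nodes, 12))
    names(sets) <- sprintf("S%02d", seq_len(n_sets))
  })
  if (is.null(escores)) {
    withr::with_seed(seed + 2000, {
      escores <- setNames(rnorm(n_sets), names(sets))
    })
  }
  build_fitness_context(cand, tm, sets, escores)
}

test_that("fitness is the Pearson correlation of Dscores with Escores", {
  ctx <- make_ctx(seed = 3)
  bits <- c(1L, 0L, 1L, 0L, 0L, 1L)
  d <- subset_dscores(bits, ctx)
  oracle <- sum((d - mean(d)) * (ctx$escores - mean(ctx$escores))) /
    (sqrt(sum((d - mean(d))^2)) * sqrt(sum((ctx$escores - mean(ctx$escores))^2)))
  expect_equal(evaluate_fitness(bits, ctx), oracle, tolerance = 1e-12)
})

test_that("a subset whose Dscores equal the Escores has fitness 1", {
  ctx <- make_ctx(seed = 5)
  bits <- c(1L, 1L, 0L, 0L, 0L, 0L)
  d <- subset_dscores(bits, ctx)
  # reuse the precomputed profiles, replace the Escores with that subset's
  # own Dscores: the correlation must then be exactly 1
  ctx$escores <- d
  ctx$memo <- new.env(parent = emptyenv())
  expect_equal(evaluate_fitness(bits, ctx), 1, tolerance = 1e-12)
})

test_that("degenerate chromosomes get the sentinel fitness", {
  ctx <- make_ctx(seed = 7)
  expect_equal(evaluate_fitness(rep(0L, 6), ctx), -2)
})

test_that("fitness evaluations are memoized and deterministic", {
  ctx <- make_ctx(seed = 9)
  bits <- c(0L, 1L, 1L, 0L, 1L, 0L)
  f1 <- evaluate_fitness(bits, ctx)
  f2 <- evaluate_fitness(bits, ctx)
  expect_identical(f1, f2)
  expect_true(paste(bits, collapse = "") %in% ls(ctx$memo))
})

test_that("fewer than 3 dysfunctional hallmarks is not evaluable", {
  tm <- random_tm(30, seed = 2)
  sets <- list(A = tm$nodes[1:5], B = tm$nodes[6:10])
  expect_error(
    build_fitness_context(tm$nodes[1:3], tm, sets,
                          setNames(c(1, 2), c("A", "B"))),
    "not evaluable")
})

test_that("tournament selection returns the best of the drawn sample", {
  pop <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L))
  fitness <- c(0.2, 0.9, 0.5)
  withr::with_seed(1, {
    for (i in 1:30) {
      sel <- tournament_select(pop, fitness, k = 3)
      # with k = N = 3 and replacement, the winner always has fitness >=
      # the minimum of the sample; across many draws the best must appear
      expect_true(any(apply(pop, 1, function(r) all(r == sel))))
    }
    # identical population: that chromosome comes back
    pop2 <- rbind(c(1L, 0L), c(1L, 0L))
    expect_equal(tournament_select(pop2, c(0.5, 0.5), k = 2), c(1L, 0L))
  })
  # exhaustive property: best chromosome returned whenever it is sampled
  withr::with_seed(4, {
    wins <- replicate(200, tournament_select(pop, fitness, k = 3)[2])
    expect_gt(mean(wins), 0.6)  # best (0,1) dominates
  })
})

test_that("equal-fitness tournament ties prefer smaller then lexicographic subsets", {
  # (0,1) beats (1,1) on size whenever both are sampled; a k = 3 draw with
  # replacement misses row 1 with probability (1/2)^3, so the big
  # chromosome can only win ~12.5% of draws
  pop <- rbind(c(1L, 1L), c(0L, 1L))
  fit <- c(0.5, 0.5)
  withr::with_seed(2, {
    sel <- replicate(400, tournament_select(pop, fit, k = 3))
  })
  expect_gt(mean(colSums(sel) == 1), 0.75)
  # (0,1) beats (1,0) lexicographically under the same sampling logic
  pop2 <- rbind(c(1L, 0L), c(0L, 1L))
  withr::with_seed(3, {
    sel2 <- replicate(400, tournament_select(pop2, fit, k = 3))
  })
  expect_gt(mean(sel2[1, ] == 0), 0.75)
})

test_that("uniform crossover conserves the per-locus bit multiset", {
  withr::with_seed(11, {
    for (i in 1:200) {
      L <- sample(2:12, 1)
      a <- as.integer(runif(L) < 0.5)
      b <- as.integer(runif(L) < 0.5)
      off <- uniform_crossover(a, b)
      expect_equal(off[[1]] + off[[2]], a + b)
    }
    # identical parents reproduce themselves
    a <- c(1L, 0L, 1L)
    off <- uniform_crossover(a, a)
    expect_equal(off[[1]], a)
    expect_equal(off[[2]], a)
    # complementary parents give complementary offspring
    off <- uniform_crossover(c(0L, 0L, 0L, 0L), c(1L, 1L, 1L, 1L))
    expect_equal(off[[1]] + off[[2]], rep(1L, 4))
  })
  expect_error(uniform_crossover(c(1L), c(1L, 0L)), "length mismatch")
})

test_that("mutation flips bits at the binomial rate", {
  bits <- rep(0L, 100)
  withr::with_seed(13, {
    expect_equal(mutate_bits(bits, p = 0), bits)
    expect_equal(mutate_bits(bits, p = 1), rep(1L, 100))
    flips <- replicate(10000, sum(mutate_bits(bits, p = 0.01)))
  })
  # mean flips ~ Binomial(100, 0.01): mean 1, se of the mean ~ 0.00995
  expect_lt(abs(mean(flips) - 1), 3 * sqrt(100 * 0.01 * 0.99 / 10000))
})

test_that("a single candidate gene is returned directly", {
  ctx <- make_ctx(n_cand = 1, seed = 15)
  res <- optimize_drivers(ctx, ga_config(rng_seed = 1))
  expect_equal(res$driver_genes, ctx$genes)
  expect_equal(res$pcc, evaluate_fitness(1L, ctx))
})

test_that("GA optimum equals the exhaustive optimum for L = 8 across seeds", {
  # planted structure: the Escores are generated by a true 2-gene subset,
  # as in the end-to-end use of the optimizer
  ctx <- make_ctx(n = 80, n_cand = 8, n_sets = 6, seed = 21)
  bits <- integer(8); bits[c(2, 5)] <- 1L
  ctx$escores <- subset_dscores(bits, ctx)
  ctx$memo <- new.env(parent = emptyenv())
  ex <- exhaustive_search(ctx)
  for (ga_seed in 1:10) {
    res <- optimize_drivers(ctx, ga_config(rng_seed = ga_seed,
                                           max_generations = 200,
                                           stagnation_limit = 60))
    expect_equal(res$pcc, ex$fitness, tolerance = 1e-12)
  }
})

test_that("the GA recovers a planted subset whose Dscores generate the Escores", {
  ctx <- make_ctx(n = 80, n_cand = 8, n_sets = 8, seed = 31)
  planted <- c(2L, 5L)
  bits <- integer(8); bits[planted] <- 1L
  ctx$escores <- subset_dscores(bits, ctx)
  ctx$memo <- new.env(parent = emptyenv())
  ex <- exhaustive_search(ctx)
  res <- optimize_drivers(ctx, ga_config(rng_seed = 3))
  expect_equal(res$pcc, ex$fitness, tolerance = 1e-12)
  expect_equal(res$pcc, 1, tolerance = 1e-9)
  expect_equal(res$driver_genes, ctx$genes[planted])
})

test_that("optimization is deterministic given its seed", {
  ctx <- make_ctx(n = 60, n_cand = 7, seed = 41)
  r1 <- optimize_drivers(ctx, ga_config(rng_seed = 17))
  r2 <- optimize_drivers(ctx, ga_config(rng_seed = 17))
  expect_identical(r1$driver_genes, r2$driver_genes)
  expect_identical(r1$pcc, r2$pcc)
})

test_that("pcc_test matches the t-distribution oracle", {
  expect_equal(pcc_test(1:5, 2 * (1:5) + 1)$pcc, 1)
  expect_lt(pcc_test(1:5, 2 * (1:5) + 1)$p, 1e-10)
  expect_equal(pcc_test(1:4, -(1:4))$pcc, -1)
  withr::with_seed(51, {
    x <- rnorm(10); y <- rnorm(10)
  })
  res <- pcc_test(x, y)
  r <- cor(x, y)
  tstat <- r * sqrt((10 - 2) / (1 - r^2))
  p_oracle <- 2 * pt(-abs(tstat), df = 8)
  expect_equal(res$pcc, r, tolerance = 1e-12)
  expect_equal(res$p, p_oracle, tolerance = 1e-10)
  expect_error(pcc_test(rep(1, 5), 1:5), "zero variance")
})
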