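# Genetic algorithm over binary subsets of candidate driver genes.
# Fitness of a subset = Pearson correlation between its Dscores (ssGSEA of
# the subset's multi-seed RWR stationary profile over the individual's
# dysfunctional hallmarks) and the individual's Escores (ssGSEA of fold
# changes over the same hallmarks).

FITNESS_SENTINEL <- -2

#' Genetic algorithm configuration
#'
#' Defaults follow the standard subset-search setup: uniform crossover
#' applied to a fraction 0.9 of the selected population, per-bit mutation
#' at 0.01, tournament selection of 3, elitism on. Population size and
#' generation count scale with the number of candidate genes L:
#' `N = clamp(2L, 40, 200)` and `G = clamp(5L, 50, 500)` with early stop
#' after 30 stagnant generations.
#'
#' @param crossover_prob probability a selected pair undergoes uniform
#'   crossover; default 0.9.
#' @param mutation_prob per-bit flip probability; default 0.01.
#' @param tournament_k tournament size; default 3.
#' @param pop_size explicit population size N, or NULL for the rule above.
#' @param max_generations explicit generation count G, or NULL for the rule.
#' @param stagnation_limit early-stop after this many generations without
#'   improvement of the best-ever fitness; default 30.
#' @param elitism keep a copy of the best-ever chromosome in the population
#'   each generation; default TRUE.
#' @param rng_seed integer seed for all GA randomness.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(crossover_prob = 0.9, mutation_prob = 0.01,
                      tournament_k = 3L, pop_size = NULL,
                      max_generations = NULL, stagnation_limit = 30L,
                      elitism = TRUE, rng_seed = 1L) {
  assert_that(crossover_prob >= 0 && crossover_prob <= 1, "crossover_prob in [0,1]")
  assert_that(mutation_prob >= 0 && mutation_prob <= 1, "mutation_prob in [0,1]")
  assert_that(tournament_k >= 1, "tournament_k >= 1")
  structure(list(crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 tournament_k = as.integer(tournament_k),
                 pop_size = pop_size, max_generations = max_generations,
                 stagnation_limit = as.integer(stagnation_limit),
                 elitism = elitism, rng_seed = as.integer(rng_seed)),
            class = "ga_config")
}

#' Precompute the fitness-evaluation context for one individual
#'
#' Runs a single-seed RWR for every candidate gene once and stores the
#' stationary vectors column-wise. The stationary vector of any candidate
#' subset is then the mean of its members' columns — exact by linearity of
#' the fixed-point equation `p = (1-r) W p + r p0` in `p0` — so each GA
#' fitness evaluation costs one ranking plus one ssGSEA pass per hallmark
#' instead of a fresh power iteration.
#'
#' @param candidates a `candidate_set` (or character vector of genes).
#' @param tm a `transfer_matrix`.
#' @param dysf_sets named list: the individual's dysfunctional hallmark
#'   gene sets (at least 3; Pearson correlation needs 3 points).
#' @param escores named numeric: ssGSEA Escores over the same hallmarks.
#' @param params an `rwr_params`.
#' @param alpha ssGSEA rank-weight exponent; default 0.25.
#' @return list of class `fitness_context`.
#' @export
build_fitness_context <- function(candidates, tm, dysf_sets, escores,
                                  params = rwr_params(), alpha = 0.25) {
  genes <- if (inherits(candidates, "candidate_set")) candidates$genes else
    sort(unique(as.character(candidates)))
  assert_that(length(genes) >= 1, "no candidate genes")
  assert_that(all(genes %in% tm$nodes), "all candidates must be network nodes")
  if (length(dysf_sets) < 3) stop("individual not evaluable", call. = FALSE)
  assert_that(identical(sort(names(dysf_sets)), sort(names(escores))),
              "dysf_sets and escores must cover the same hallmarks")
  escores <- escores[names(dysf_sets)]
  if (stats::sd(escores) == 0) stop("Escores have zero variance", call. = FALSE)
  profiles <- vapply(genes, function(g) run_rwr(tm, g, params)$p,
                     numeric(length(tm$nodes)))
  rownames(profiles) <- tm$nodes
  structure(list(genes = genes, profiles = profiles, dysf_sets = dysf_sets,
                 escores = escores, alpha = alpha,
                 memo = new.env(parent = emptyenv())),
            class = "fitness_context")
}

#' Dscores of a candidate subset
#'
#' ssGSEA scores of each dysfunctional hallmark on the subset's multi-seed
#' RWR stationary probability vector.
#'
#' @param bits integer/logical vector of length L selecting candidates.
#' @param ctx a `fitness_context`.
#' @return named numeric vector of Dscores (NULL for the empty subset).
#' @export
subset_dscores <- function(bits, ctx) {
  sel <- which(as.logical(bits))
  if (length(sel) == 0) return(NULL)
  p <- rowMeans(ctx$profiles[, sel, drop = FALSE])
  ssgsea_collection(p, ctx$dysf_sets, alpha = ctx$alpha)
}

#' Fitness of a candidate subset
#'
#' Pearson correlation between the subset's Dscores and the individual's
#' Escores over the dysfunctional hallmarks. The empty subset and subsets
#' with zero-variance Dscores receive the sentinel fitness -2 (below any
#' attainable correlation). Evaluations are memoized by bit pattern in the
#' context.
#'
#' @inheritParams subset_dscores
#' @return numeric fitness in [-1, 1] or the sentinel -2.
#' @export
evaluate_fitness <- function(bits, ctx) {
  bits <- as.integer(as.logical(bits))
  assert_that(length(bits) == length(ctx$genes), "chromosome length mismatch")
  key <- paste(bits, collapse = "")
  hit <- ctx$memo[[key]]
  if (!is.null(hit)) return(hit)
  d <- subset_dscores(bits, ctx)
  fit <- if (is.null(d) || stats::sd(d) == 0) {
    FITNESS_SENTINEL
  } else {
    stats::cor(d, ctx$escores[names(d)])
  }
  ctx$memo[[key]] <- fit
  fit
}

# Chromosome comparison used everywhere a tie must break deterministically:
# higher fitness wins; at equal fitness the smaller subset wins; at equal
# size the lexicographically smaller bit string wins.
#' @keywords internal
chromosome_better <- function(fit_a, bits_a, fit_b, bits_b, tol = 0) {
  if (fit_a > fit_b + tol) return(TRUE)
  if (fit_b > fit_a + tol) return(FALSE)
  sa <- sum(bits_a); sb <- sum(bits_b)
  if (sa != sb) return(sa < sb)
  ka <- paste(bits_a, collapse = ""); kb <- paste(bits_b, collapse = "")
  ka < kb
}

#' Tournament selection
#'
#' Samples `k` chromosomes uniformly with replacement and returns a copy of
#' the fittest (ties: fewer set bits, then lexicographic bit string).
#'
#' @param pop 0/1 matrix, one chromosome per row.
#' @param fitness numeric vector, one value per row.
#' @param k tournament size; default 3.
#' @return integer 0/1 vector (the selected chromosome).
#' @export
tournament_select <- function(pop, fitness, k = 3L) {
  assert_that(nrow(pop) >= 1, "empty population")
  idx <- sample.int(nrow(pop), k, replace = TRUE)
  best <- idx[1]
  for (i in idx[-1]) {
    if (chromosome_better(fitness[i], pop[i, ], fitness[best], pop[best, ])) {
      best <- i
    }
  }
  pop[best, ]
}

#' Uniform crossover of two chromosomes
#'
#' At each locus, with probability 0.5 the two offspring swap the parental
#' bits; the multiset of bits at every locus is conserved across the pair.
#'
#' @param a,b integer 0/1 vectors of equal length.
#' @return list of two offspring chromosomes.
#' @export
uniform_crossover <- function(a, b) {
  if (length(a) != length(b)) stop("chromosome length mismatch", call. = FALSE)
  swap <- stats::runif(length(a)) < 0.5
  o1 <- a; o2 <- b
  o1[swap] <- b[swap]
  o2[swap] <- a[swap]
  list(o1, o2)
}

#' Bit mutation
#'
#' Flips each bit independently with probability `p`.
#'
#' @param bits integer 0/1 vector.
#' @param p per-bit flip probability; default 0.01.
#' @return mutated chromosome.
#' @export
mutate_bits <- function(bits, p = 0.01) {
  flip <- stats::runif(length(bits)) < p
  bits[flip] <- 1L - bits[flip]
  bits
}

#' @keywords internal
pop_size_rule <- function(L) as.integer(min(max(2L * L, 40L), 200L))

#' @keywords internal
generations_rule <- function(L) as.integer(min(max(5L * L, 50L), 500L))

#' Exhaustive search over all nonempty candidate subsets
#'
#' Enumerates all `2^L - 1` nonempty subsets; feasible for small L (<= ~15).
#' Used as the exact optimizer for few candidates and as the oracle that
#' the genetic algorithm must match.
#'
#' @param ctx a `fitness_context`.
#' @return list with `bits`, `fitness`.
#' @export
exhaustive_search <- function(ctx) {
  L <- length(ctx$genes)
  assert_that(L <= 20, "exhaustive search limited to L <= 20")
  best_bits <- NULL
  best_fit <- -Inf
  for (mask in seq_len(2^L - 1)) {
    bits <- as.integer(bitwAnd(bitwShiftR(mask, 0:(L - 1)), 1L))
    fit <- evaluate_fitness(bits, ctx)
    if (is.null(best_bits) ||
        chromosome_better(fit, bits, best_fit, best_bits)) {
      best_bits <- bits
      best_fit <- fit
    }
  }
  list(bits = best_bits, fitness = best_fit)
}

#' Search the optimal driver gene set by genetic algorithm
#'
#' Runs the full evolutionary loop: random 0/1 initialization (density 0.5
#' per bit), fitness evaluation, tournament selection, uniform crossover of
#' shuffled consecutive pairs at the crossover probability, per-bit
#' mutation, and an elitist copy of the best-ever chromosome replacing the
#' worst of the new generation. Stops after the generation budget or after
#' `stagnation_limit` generations without improvement. The best-ever
#' chromosome decoded to genes is the driver gene set; its correlation
#' p-value comes from [pcc_test()].
#'
#' @param ctx a `fitness_context` from [build_fitness_context()].
#' @param cfg a `ga_config`.
#' @param method `"ga"` (default) or `"exhaustive"` (exact; small L only).
#' @return object of class `driver_set_result`: list with `individual`
#'   (filled by the pipeline), `driver_genes`, `bits`, `pcc`, `p_value`,
#'   `significant` (p <= 0.05), `dscores`, `escores`, `generations_run`,
#'   `n_candidates`, `method`.
#' @export
optimize_drivers <- function(ctx, cfg = ga_config(), method = c("ga", "exhaustive")) {
  method <- match.arg(method)
  L <- length(ctx$genes)
  if (method == "exhaustive" || L == 1) {
    res <- exhaustive_search(ctx)
    best_bits <- res$bits
    best_fit <- res$fitness
    gens <- 0L
  } else {
    N <- cfg$pop_size %||% pop_size_rule(L)
    G <- cfg$max_generations %||% generations_rule(L)
    run <- withr::with_seed(cfg$rng_seed, {
      pop <- matrix(as.integer(stats::runif(N * L) < 0.5), nrow = N, ncol = L)
      fitness <- apply(pop, 1, evaluate_fitness, ctx = ctx)
      bi <- which.max(fitness)
      best_bits <- pop[bi, ]
      best_fit <- fitness[bi]
      stagnant <- 0L
      gen <- 0L
      while (gen < G && stagnant < cfg$stagnation_limit) {
        gen <- gen + 1L
        selected <- t(vapply(seq_len(N),
                             function(i) tournament_select(pop, fitness, cfg$tournament_k),
                             integer(L)))
        # crossover on shuffled consecutive pairs; odd leftover passes through
        ord <- sample.int(N)
        newpop <- selected
        pair_starts <- seq(1, N - 1, by = 2)
        for (s in pair_starts) {
          i <- ord[s]; j <- ord[s + 1]
          if (stats::runif(1) < cfg$crossover_prob) {
            off <- uniform_crossover(selected[i, ], selected[j, ])
            newpop[i, ] <- off[[1]]
            newpop[j, ] <- off[[2]]
          }
        }
        for (i in seq_len(N)) {
          newpop[i, ] <- mutate_bits(newpop[i, ], cfg$mutation_prob)
        }
        pop <- newpop
        fitness <- apply(pop, 1, evaluate_fitness, ctx = ctx)
        gi <- which.max(fitness)
        if (chromosome_better(fitness[gi], pop[gi, ], best_fit, best_bits)) {
          best_fit <- fitness[gi]
          best_bits <- pop[gi, ]
          stagnant <- 0L
        } else {
          stagnant <- stagnant + 1L
        }
        if (cfg$elitism) {
          wi <- which.min(fitness)
          pop[wi, ] <- best_bits
          fitness[wi] <- best_fit
        }
      }
      list(best_bits = best_bits, best_fit = best_fit, gen = gen)
    })
    best_bits <- run$best_bits
    best_fit <- run$best_fit
    gens <- run$gen
  }
  dscores <- subset_dscores(best_bits, ctx)
  pval <- if (!is.null(dscores) && best_fit > FITNESS_SENTINEL) {
    pcc_test(dscores, ctx$escores[names(dscores)])$p
  } else {
    NA_real_
  }
  structure(list(individual = NA_character_,
                 driver_genes = ctx$genes[as.logical(best_bits)],
                 bits = as.integer(best_bits),
                 pcc = best_fit,
                 p_value = pval,
                 significant = isTRUE(pval <= 0.05),
                 dscores = dscores,
                 escores = ctx$escores,
                 generations_run = gens,
                 n_candidates = L,
                 method = method),
            class = "driver_set_result")
}

#' @export
print.driver_set_result <- function(x, ...) {
  cat(sprintf("driver_set_result%s: {%s}, PCC=%.3f, p=%.3g (%s, %d candidates)\n",
              if (is.na(x$individual)) "" else paste0(" '", x$individual, "'"),
              paste(x$driver_genes, collapse = ", "),
              x$pcc, x$p_value, x$method, x$n_candidates))
  invisible(x)
}

#' Pearson correlation with significance test
#'
#' Two-sided test of zero correlation via the t statistic
#' `r * sqrt((n - 2) / (1 - r^2))` on n-2 degrees of freedom, as computed
#' by `stats::cor.test`.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `pcc`, `p`.
#' @export
pcc_test <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 3,
              "need >= 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(pcc = unname(ct$estimate), p = ct$p.value)
}
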