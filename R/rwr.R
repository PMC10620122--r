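# Random walk with restart over the transfer matrix.

#' Random-walk-with-restart parameters
#'
#' @param r restart probability in (0, 1]; default 0.3.
#' @param tol convergence threshold on the maximum absolute change of the
#'   probability vector between iterations; default 1e-10.
#' @param max_iter iteration cap; default 10000.
#' @return list of class `rwr_params`.
#' @export
rwr_params <- function(r = 0.3, tol = 1e-10, max_iter = 10000L) {
  assert_that(is.numeric(r) && length(r) == 1 && r > 0 && r <= 1,
              "restart probability r must be in (0, 1]")
  assert_that(tol > 0, "tol must be positive")
  assert_that(max_iter >= 1, "max_iter must be >= 1")
  structure(list(r = r, tol = tol, max_iter = as.integer(max_iter)),
            class = "rwr_params")
}

#' Run random walk with restart
#'
#' Iterates `P_{t+1} = (1 - r) W P_t + r P_0` from the initial vector P_0
#' placing uniform mass `1/|seeds|` on the seed genes, until the maximum
#' absolute elementwise change drops below `params$tol` or `params$max_iter`
#' is reached. The stationary vector quantifies how strongly the
#' perturbation started at the seeds reaches every network gene.
#'
#' Seeds absent from the network are dropped with a message as long as at
#' least one remains. Total probability mass 1 is preserved at every
#' iteration because W is column-stochastic.
#'
#' @param tm a `transfer_matrix`.
#' @param seeds character vector of seed genes.
#' @param params an `rwr_params` object.
#' @return object of class `stable_prob`: list with `p` (named probability
#'   vector over `tm$nodes`), `seeds` (the seeds used), `iterations`,
#'   `converged`.
#' @export
run_rwr <- function(tm, seeds, params = rwr_params()) {
  seeds <- unique(as.character(seeds))
  in_net <- seeds %in% tm$nodes
  if (!all(in_net)) {
    message(sprintf("%d seed gene(s) not in network, dropped: %s",
                    sum(!in_net), paste(seeds[!in_net], collapse = ", ")))
  }
  seeds <- seeds[in_net]
  if (length(seeds) == 0) stop("no seeds in component", call. = FALSE)
  n <- length(tm$nodes)
  p0 <- numeric(n)
  p0[match(seeds, tm$nodes)] <- 1 / length(seeds)
  r <- params$r
  W <- tm$W
  p <- p0
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iter) {
    iter <- iter + 1L
    p_next <- as.vector((1 - r) * (W %*% p)) + r * p0
    delta <- max(abs(p_next - p))
    p <- p_next
    if (delta < params$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("RWR did not converge within %d iterations", params$max_iter))
  }
  names(p) <- tm$nodes
  structure(list(p = p, seeds = seeds, iterations = iter, converged = converged),
            class = "stable_prob")
}

#' @export
print.stable_prob <- function(x, ...) {
  cat(sprintf("stable_prob: %d genes, %d seed(s), %d iterations, converged=%s\n",
              length(x$p), length(x$seeds), x$iterations, x$converged))
  invisible(x)
}

#' Closed-form RWR stationary vector by direct linear solve
#'
#' Solves `p = r (I - (1 - r) W)^{-1} P_0` densely. Intended for small
#' networks, as an exact cross-check of the iterative [run_rwr()].
#'
#' @inheritParams run_rwr
#' @return named numeric stationary vector.
#' @export
rwr_linear_solve <- function(tm, seeds, params = rwr_params()) {
  seeds <- intersect(unique(as.character(seeds)), tm$nodes)
  if (length(seeds) == 0) stop("no seeds in component", call. = FALSE)
  n <- length(tm$nodes)
  p0 <- numeric(n)
  p0[match(seeds, tm$nodes)] <- 1 / length(seeds)
  r <- params$r
  A <- diag(n) - (1 - r) * as.matrix(tm$W)
  p <- solve(A, r * p0)
  names(p) <- tm$nodes
  p
}
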