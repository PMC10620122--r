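# Co-expression-weighted protein interaction network and its
# column-stochastic transfer matrix.

#' Read a protein interaction edge list from TSV
#'
#' Expects at least two columns (gene_a, gene_b); any further columns (e.g.
#' an interaction confidence score) are ignored. A header row is
#' auto-detected: if the first row repeats no gene id elsewhere and the
#' file parses identically either way, `data.table::fread`'s heuristic is
#' used.
#'
#' @param path TSV file.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
read_edge_list <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = "auto", data.table = FALSE)
  assert_that(ncol(dt) >= 2, "edge list needs at least two columns")
  data.frame(gene_a = as.character(dt[[1]]), gene_b = as.character(dt[[2]]),
             stringsAsFactors = FALSE)
}

#' Build the co-expression-weighted interaction network
#'
#' Each interaction between two genes measured in the expression matrix is
#' weighted by the absolute Pearson correlation of the two genes' expression
#' across the cancer cohort samples. Edges with an endpoint missing from the
#' expression matrix, self-loops, duplicate pairs, edges where either gene
#' has zero expression variance (correlation undefined), and edges whose
#' absolute correlation does not exceed 1e-12 are dropped; counts of dropped
#' edges are recorded in the `dropped` attribute.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b` (or any first two
#'   columns holding the pair).
#' @param expr an `expr_matrix`.
#' @param cohort_samples sample ids over which to correlate (default: all
#'   tumor samples of `expr`); at least 3 required.
#' @return object of class `weighted_network`: list with `nodes` (character)
#'   and `edges` (data.frame gene_a, gene_b, weight).
#' @export
build_weighted_network <- function(edges, expr,
                                   cohort_samples = tumor_samples(expr)) {
  if (length(cohort_samples) < 3) {
    stop("insufficient samples for correlation", call. = FALSE)
  }
  ga <- as.character(edges[[1]])
  gb <- as.character(edges[[2]])
  # canonical unordered pairs; drop self-loops and duplicates
  a <- pmin(ga, gb)
  b <- pmax(ga, gb)
  self <- a == b
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  keep <- !self & !dup
  a <- a[keep]; b <- b[keep]
  genes <- rownames(expr$values)
  present <- a %in% genes & b %in% genes
  n_missing <- sum(!present)
  a <- a[present]; b <- b[present]
  x <- expr$values[a, cohort_samples, drop = FALSE]
  y <- expr$values[b, cohort_samples, drop = FALSE]
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  sx <- rowSums(xc * xc)
  sy <- rowSums(yc * yc)
  denom <- sqrt(sx * sy)
  zero_var <- denom == 0
  w <- rep(NA_real_, length(a))
  w[!zero_var] <- abs(rowSums(xc * yc)[!zero_var] / denom[!zero_var])
  w <- pmin(w, 1)  # guard rounding just above 1
  retained <- !zero_var & w > 1e-12
  net <- structure(
    list(nodes = sort(unique(c(a[retained], b[retained]))),
         edges = data.frame(gene_a = a[retained], gene_b = b[retained],
                            weight = w[retained], stringsAsFactors = FALSE)),
    class = "weighted_network"
  )
  attr(net, "dropped") <- c(
    self_or_duplicate = sum(!keep),
    missing_from_expression = n_missing,
    zero_variance = sum(zero_var),
    near_zero_weight = sum(!zero_var & w <= 1e-12)
  )
  net
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @keywords internal
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("gene_a", "gene_b", "weight")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes)
  )
}

#' Extract the maximum connected component
#'
#' Returns the component with the most nodes. Ties are broken
#' deterministically in favor of the component containing the
#' lexicographically smallest gene id.
#'
#' @param net a `weighted_network`.
#' @return a `weighted_network` restricted to the chosen component.
#' @export
largest_component <- function(net) {
  assert_that(length(net$nodes) > 0, "empty network")
  g <- as_igraph(net)
  comp <- igraph::components(g)
  sizes <- comp$csize
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1) {
    # component of the lexicographically smallest node among tied components
    first_node <- vapply(biggest, function(ci) {
      min(names(comp$membership)[comp$membership == ci])
    }, character(1))
    biggest <- biggest[order(first_node)[1]]
  }
  keep_nodes <- names(comp$membership)[comp$membership == biggest]
  e <- net$edges
  e <- e[e$gene_a %in% keep_nodes & e$gene_b %in% keep_nodes, , drop = FALSE]
  rownames(e) <- NULL
  structure(list(nodes = sort(keep_nodes), edges = e),
            class = "weighted_network")
}

#' Column-normalized transfer matrix
#'
#' Builds the square transfer matrix W of the random walk: the probability
#' of stepping from gene j to gene i is the edge weight w(j, i) divided by
#' the total weight incident to j, so every column sums to 1 and transfer
#' probabilities are proportional to the absolute co-expression
#' correlations.
#'
#' @param net a connected `weighted_network` in which every node has at
#'   least one incident edge of positive weight.
#' @return object of class `transfer_matrix`: list with `nodes` (ordered
#'   node index) and `W` (sparse column-stochastic dgCMatrix).
#' @export
column_normalize <- function(net) {
  nodes <- sort(net$nodes)
  n <- length(nodes)
  i <- match(net$edges$gene_a, nodes)
  j <- match(net$edges$gene_b, nodes)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = rep(net$edges$weight, 2),
                            dims = c(n, n), dimnames = list(nodes, nodes))
  cs <- Matrix::colSums(A)
  if (any(cs <= 0)) {
    stop(sprintf("dangling node: '%s' has no positive incident weight",
                 nodes[which(cs <= 0)[1]]), call. = FALSE)
  }
  W <- A %*% Matrix::Diagonal(n, 1 / cs)
  dimnames(W) <- list(nodes, nodes)
  structure(list(nodes = nodes, W = W), class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("transfer_matrix: %d x %d, column-stochastic\n",
              length(x$nodes), length(x$nodes)))
  invisible(x)
}
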