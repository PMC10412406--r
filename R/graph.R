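#' Pairwise squared Euclidean distances
#'
#' @param x samples-by-features numeric matrix without missing values.
#' @return symmetric n-by-n matrix of squared Euclidean distances with zero
#'   diagonal.
#' @export
pairwiseSqDistances <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("input contains missing values")
  rs <- rowSums(x^2)
  d2 <- outer(rs, rs, "+") - 2 * tcrossprod(x)
  d2 <- pmax(d2, 0)
  diag(d2) <- 0
  d2
}

#' Exponential-kernel k-nn affinity graph
#'
#' Builds the patient-similarity graph of one omics view: with squared
#' Euclidean distances \eqn{\rho^2(x_i, x_j)} and scale \eqn{\delta^2} set to
#' the median off-diagonal pairwise squared distance, the directed affinity is
#' \deqn{A(i,j) = \exp(-\rho^2(x_i, x_j) / (\mu \delta^2))}
#' for the `k` nearest neighbours j of i (self excluded, distance ties broken
#' by ascending sample index) and 0 otherwise. Since the neighbour relation is
#' directional, the matrix is then symmetrized; the default averages
#' \eqn{(A + A^T)/2}, `"mutual"` keeps only reciprocal edges, `"max"` takes
#' the elementwise maximum. The bandwidth defaults in practice are
#' `mu = 0.3` for the gene graph and `mu = 0.2` for the microRNA graph.
#'
#' @param x samples-by-features matrix (one omics view, preprocessed).
#' @param k neighbourhood size, `1 <= k <= n-1`.
#' @param mu positive kernel bandwidth hyperparameter.
#' @param symmetrize one of `"average"`, `"mutual"`, `"max"`.
#' @param label label stored on the graph.
#' @return an [AffinityGraph-class].
#' @export
knnAffinity <- function(x, k, mu, symmetrize = c("average", "mutual", "max"),
                        label = "omics") {
  symmetrize <- match.arg(symmetrize)
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1 || k > n - 1)
    stop("k must satisfy 1 <= k <= n-1 (n = ", n, ")")
  if (mu <= 0) stop("mu must be positive")
  d2 <- pairwiseSqDistances(x)
  deltaSq <- stats::median(d2[upper.tri(d2)])
  if (deltaSq == 0)
    stop("all points are identical (median pairwise distance is zero); ",
         "add jitter to the features")
  kern <- exp(-d2 / (mu * deltaSq))
  mask <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ], seq_len(n))
    ord <- ord[ord != i]
    mask[i, ord[seq_len(k)]] <- TRUE
  }
  a <- kern * mask
  a <- switch(symmetrize,
              average = (a + t(a)) / 2,
              mutual = kern * (mask & t(mask)),
              max = pmax(a, t(a)))
  diag(a) <- 0
  new("AffinityGraph", weights = a, label = label, k = as.numeric(k),
      mu = mu, deltaSq = deltaSq)
}

#' Average several affinity graphs
#'
#' Elementwise arithmetic mean of the weight matrices; the result is labelled
#' `"fused"`.
#'
#' @param graphs list of [AffinityGraph-class] objects on the same samples.
#' @return the fused [AffinityGraph-class].
#' @export
fuseGraphs <- function(graphs) {
  if (!length(graphs)) stop("need at least one graph")
  dims <- vapply(graphs, function(g) nrow(g@weights), integer(1))
  if (length(unique(dims)) != 1L)
    stop("graphs have mismatched sizes: ", paste(dims, collapse = ", "))
  w <- Reduce(`+`, lapply(graphs, graphWeights)) / length(graphs)
  new("AffinityGraph", weights = w, label = "fused",
      k = NA_real_, mu = NA_real_, deltaSq = NA_real_)
}

#' Normalized graph-convolution matrix
#'
#' Adds self-loops and symmetrically normalizes:
#' \eqn{\tilde{A} = A + I}, \eqn{\tilde{d}_i = \sum_j \tilde{A}_{ij}},
#' \eqn{\hat{A} = \tilde{D}^{-1/2} \tilde{A} \tilde{D}^{-1/2}}. For the empty
#' graph this is the identity; in general the spectrum lies in \eqn{[-1, 1]}.
#'
#' @param graph an [AffinityGraph-class] (symmetric, nonnegative).
#' @return a [ConvolutionMatrix-class].
#' @export
normalizeAdjacency <- function(graph) {
  a <- if (is(graph, "AffinityGraph")) graph@weights else as.matrix(graph)
  at <- a + diag(nrow(a))
  d <- rowSums(at)
  stopifnot(all(d > 0))
  inv <- 1 / sqrt(d)
  aHat <- at * tcrossprod(inv)
  aHat <- (aHat + t(aHat)) / 2  # kill round-off asymmetry
  new("ConvolutionMatrix", aHat = aHat, degree = d)
}

#' Build the fused convolution matrix of a cohort
#'
#' Convenience wrapper: per-omics k-nn graphs (gene and microRNA bandwidths
#' `muGene`, `muMirna`), averaged into a fused graph, then normalized.
#'
#' @param dataset a [MultiOmicsSurvival-class].
#' @param k neighbourhood size.
#' @param muGene,muMirna kernel bandwidths for the two views.
#' @param symmetrize symmetrization rule, see [knnAffinity()].
#' @param rows optional integer subset of samples to build the graph on.
#' @return a [ConvolutionMatrix-class].
#' @export
fusedConvolution <- function(dataset, k = 10, muGene = 0.3, muMirna = 0.2,
                             symmetrize = "average", rows = NULL) {
  x1 <- geneExpr(dataset)
  x2 <- mirnaExpr(dataset)
  if (!is.null(rows)) {
    x1 <- x1[rows, , drop = FALSE]
    x2 <- x2[rows, , drop = FALSE]
  }
  g1 <- knnAffinity(x1, k, muGene, symmetrize, label = "gene")
  g2 <- knnAffinity(x2, k, muMirna, symmetrize, label = "microRNA")
  normalizeAdjacency(fuseGraphs(list(g1, g2)))
}

#' Export a graph as an edge list
#'
#' Writes the upper-triangle nonzero edges as a TSV with columns `i`, `j`,
#' `weight` (1-based sample indices).
#'
#' @param graph an [AffinityGraph-class].
#' @param path output path.
#' @return `invisible(path)`.
#' @export
writeEdgeList <- function(graph, path) {
  w <- graph@weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  out <- data.frame(i = idx[, 1], j = idx[, 2], weight = w[idx])
  data.table::fwrite(out[order(out$i, out$j), ], path, sep = "\t")
  invisible(path)
}
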