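#' Preprocessing configuration
#'
#' Bundles the knobs of the raw-to-model-ready pipeline. Defaults follow the
#' standard practice for paired gene/microRNA expression cohorts: drop
#' features missing in more than 10% of samples, impute the rest by weighted
#' 10-nearest-neighbour averaging, log-transform after adding a pseudocount of
#' 1, keep the 6000 most variable genes and 600 most variable microRNAs, and
#' standardize each feature to zero mean and unit (population) variance.
#' Quantile discretization into `nBins` categories is available but off by
#' default, since the downstream encoders operate on continuous features.
#'
#' @param maxMissingFrac maximum tolerated per-feature missing fraction.
#' @param imputeNeighbors neighbourhood size for weighted k-nn imputation.
#' @param pseudocount added before the log transform.
#' @param logBase base of the log transform (natural log by default).
#' @param topKGene,topKMirna number of top-variance features kept per omics.
#' @param discretize whether to apply quantile discretization after
#'   standardization.
#' @param nBins number of quantile bins when `discretize = TRUE`.
#' @return a list of class `PreprocessConfig`.
#' @export
preprocessConfig <- function(maxMissingFrac = 0.10, imputeNeighbors = 10L,
                             pseudocount = 1, logBase = exp(1),
                             topKGene = 6000L, topKMirna = 600L,
                             discretize = FALSE, nBins = 4L) {
  stopifnot(maxMissingFrac >= 0, maxMissingFrac <= 1,
            imputeNeighbors >= 1, topKGene >= 1, topKMirna >= 1,
            nBins >= 2, logBase > 0, logBase != 1)
  structure(list(maxMissingFrac = maxMissingFrac,
                 imputeNeighbors = as.integer(imputeNeighbors),
                 pseudocount = pseudocount, logBase = logBase,
                 topKGene = as.integer(topKGene),
                 topKMirna = as.integer(topKMirna),
                 discretize = isTRUE(discretize), nBins = as.integer(nBins)),
            class = "PreprocessConfig")
}

.values <- function(x) if (is(x, "OmicsMatrix")) x@values else as.matrix(x)

.rewrap <- function(x, values) {
  if (is(x, "OmicsMatrix"))
    OmicsMatrix(values, x@omicsLabel)
  else
    OmicsMatrix(values, "unlabelled")
}

#' Drop features with excess missingness
#'
#' Keeps exactly the features whose fraction of missing samples is at most
#' `maxMissingFrac`; column order is preserved.
#'
#' @param x an [OmicsMatrix-class] (or matrix), possibly with `NA` entries.
#' @param maxMissingFrac threshold on the per-feature missing fraction.
#' @return the filtered [OmicsMatrix-class].
#' @export
filterMissingFeatures <- function(x, maxMissingFrac = 0.10) {
  v <- .values(x)
  frac <- colMeans(is.na(v))
  keep <- frac <= maxMissingFrac
  if (!any(keep))
    stop("all features exceed the missingness threshold of ", maxMissingFrac)
  .rewrap(x, v[, keep, drop = FALSE])
}

# Squared Euclidean distances between all sample pairs over mutually observed
# features, as three matrix products (no O(n^2 p) loop).
.maskedSqDist <- function(v) {
  obs <- !is.na(v)
  v0 <- v
  v0[!obs] <- 0
  sq <- v0^2
  storage.mode(obs) <- "double"
  t1 <- obs %*% t(sq)
  d2 <- t1 + t(t1) - 2 * tcrossprod(v0)
  pmax(d2, 0)
}

#' Weighted k-nearest-neighbour imputation
#'
#' Replaces every missing entry by the inverse-distance-weighted mean of that
#' feature's values among the `k` nearest samples, using Euclidean distance
#' over mutually observed features. Distance ties are broken by ascending
#' sample order; a neighbour at (numerically) zero distance receives the
#' largest finite weight. If fewer than `k` samples observe the feature, all
#' of them are used.
#'
#' @param x an [OmicsMatrix-class] after missingness filtering.
#' @param k number of neighbours.
#' @return the imputed [OmicsMatrix-class] with no `NA` left.
#' @export
imputeWeightedKNN <- function(x, k = 10L) {
  v <- .values(x)
  if (!anyNA(v)) return(.rewrap(x, v))
  allMissing <- colSums(!is.na(v)) == 0L
  if (any(allMissing))
    stop("feature(s) missing in all samples: ",
         paste(colnames(v)[allMissing], collapse = ", "))
  d2 <- .maskedSqDist(v)
  n <- nrow(v)
  for (f in which(colSums(is.na(v)) > 0L)) {
    obsSamples <- which(!is.na(v[, f]))
    for (i in which(is.na(v[, f]))) {
      cand <- setdiff(obsSamples, i)
      ord <- cand[order(d2[i, cand], cand)]
      nb <- ord[seq_len(min(k, length(ord)))]
      d <- sqrt(d2[i, nb])
      w <- 1 / pmax(d, .Machine$double.eps)
      v[i, f] <- sum(w * v[nb, f]) / sum(w)
    }
  }
  .rewrap(x, v)
}

#' Log-transform expression values
#'
#' Elementwise `log(value + pseudocount)` in the requested base (natural log
#' by default).
#'
#' @param x an [OmicsMatrix-class] with no missing values.
#' @param pseudocount offset added before the log.
#' @param base log base.
#' @return the transformed [OmicsMatrix-class].
#' @export
logTransform <- function(x, pseudocount = 1, base = exp(1)) {
  v <- .values(x)
  bad <- which(v + pseudocount <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("value + pseudocount <= 0 at sample %s, feature %s",
                 rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]))
  .rewrap(x, log(v + pseudocount, base = base))
}

.colVarsPop <- function(v) colMeans(v^2) - colMeans(v)^2

#' Keep the most variable features
#'
#' Retains the `topK` features with largest across-sample variance (the
#' low-information features whose values barely change are dropped). Variance
#' ties are broken in favour of the earlier column; the retained features keep
#' their original column order.
#'
#' @param x an [OmicsMatrix-class], typically log-transformed.
#' @param topK number of features to keep; must not exceed the feature count.
#' @return the filtered [OmicsMatrix-class].
#' @export
selectTopVarianceFeatures <- function(x, topK) {
  v <- .values(x)
  if (topK > ncol(v))
    stop("topK (", topK, ") exceeds the number of features (", ncol(v), ")")
  vars <- .colVarsPop(v)
  keep <- sort(order(-vars, seq_along(vars))[seq_len(topK)])
  .rewrap(x, v[, keep, drop = FALSE])
}

#' Standardize features to zero mean, unit variance
#'
#' Uses the population (1/n) variance convention, so that a standardized
#' feature satisfies `mean == 0` and `mean(x^2) == 1` exactly.
#'
#' @param x an [OmicsMatrix-class] with no constant feature.
#' @return the standardized [OmicsMatrix-class].
#' @export
standardizeFeatures <- function(x) {
  v <- .values(x)
  mu <- colMeans(v)
  s2 <- colMeans(v^2) - mu^2
  if (any(s2 <= 0))
    stop("constant feature(s) cannot be standardized: ",
         paste(utils::head(colnames(v)[s2 <= 0], 5), collapse = ", "))
  .rewrap(x, sweep(sweep(v, 2, mu), 2, sqrt(s2), "/"))
}

#' Quantile discretization
#'
#' Maps each feature to integer categories `0..nBins-1` by per-feature
#' quantile bins and re-centres each feature to zero mean. Duplicate quantile
#' breaks (heavy ties) collapse the affected bins. Off by default in the
#' pipeline: the downstream encoders consume continuous features.
#'
#' @param x an [OmicsMatrix-class], typically standardized.
#' @param nBins number of quantile bins, at least 2.
#' @return the discretized, re-centred [OmicsMatrix-class].
#' @export
discretizeFeatures <- function(x, nBins = 4L) {
  if (nBins < 2) stop("nBins must be at least 2")
  v <- .values(x)
  out <- apply(v, 2, function(col) {
    br <- unique(stats::quantile(col, probs = seq(0, 1, length.out = nBins + 1),
                                 names = FALSE))
    if (length(br) < 2L) return(rep(0, length(col)))
    cats <- findInterval(col, br, rightmost.closed = TRUE,
                         all.inside = TRUE) - 1
    cats - mean(cats)
  })
  dimnames(out) <- dimnames(v)
  .rewrap(x, out)
}

#' Full preprocessing pipeline
#'
#' Aligns the raw gene and microRNA matrices with the survival table (sample
#' intersection, ordered as in the survival table), then per omics applies, in
#' order: missingness filtering, weighted k-nn imputation, log transform,
#' top-variance feature selection, standardization, and (optionally) quantile
#' discretization. Deterministic given input and configuration.
#'
#' @param geneRaw,mirnaRaw raw [OmicsMatrix-class] objects (or matrices with
#'   sample ids in rownames), possibly containing missing values.
#' @param outcome a [SurvivalOutcome-class] covering (at least) the shared
#'   samples.
#' @param config a [preprocessConfig()] list.
#' @return a model-ready [MultiOmicsSurvival-class].
#' @export
preprocessOmics <- function(geneRaw, mirnaRaw, outcome,
                            config = preprocessConfig()) {
  if (!is(geneRaw, "OmicsMatrix")) geneRaw <- OmicsMatrix(geneRaw, "gene")
  if (!is(mirnaRaw, "OmicsMatrix")) mirnaRaw <- OmicsMatrix(mirnaRaw, "microRNA")
  ids <- outcome@sampleIDs
  shared <- ids[ids %in% rownames(geneRaw@values) &
                ids %in% rownames(mirnaRaw@values)]
  if (!length(shared))
    stop("no samples shared between the omics matrices and the survival table")
  keep <- match(shared, ids)
  out <- SurvivalOutcome(outcome@time[keep], outcome@event[keep], shared)

  onePipe <- function(x, topK) {
    x <- OmicsMatrix(x@values[shared, , drop = FALSE], x@omicsLabel)
    x <- filterMissingFeatures(x, config$maxMissingFrac)
    x <- imputeWeightedKNN(x, config$imputeNeighbors)
    x <- logTransform(x, config$pseudocount, config$logBase)
    x <- selectTopVarianceFeatures(x, topK)
    x <- standardizeFeatures(x)
    if (config$discretize) x <- discretizeFeatures(x, config$nBins)
    x
  }
  gene <- onePipe(geneRaw, config$topKGene)
  mirna <- onePipe(mirnaRaw, config$topKMirna)
  MultiOmicsSurvival(gene, mirna, out)
}
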