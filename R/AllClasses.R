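#' @import methods
NULL

#' Single-omics expression matrix
#'
#' Thin S4 container for a samples-by-features expression matrix with unique
#' sample and feature identifiers held in the dimnames. Missing entries are
#' represented as `NA` and survive until the imputation stage of the
#' preprocessing pipeline.
#'
#' @slot values numeric matrix, samples in rows, features in columns; dimnames
#'   carry the sample and feature identifiers.
#' @slot omicsLabel single string naming the omics layer, e.g. `"gene"` or
#'   `"microRNA"`.
#'
#' @seealso [OmicsMatrix()] for the constructor,
#'   [preprocessOmics()] for the full raw-to-model-ready pipeline.
#' @exportClass OmicsMatrix
setClass("OmicsMatrix",
  representation(values = "matrix", omicsLabel = "character"))

setValidity("OmicsMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v))
    msg <- c(msg, "'values' must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "'values' must carry sample (row) and feature (column) names")
  else {
    dup <- unique(rownames(v)[duplicated(rownames(v))])
    if (length(dup))
      msg <- c(msg, paste0("duplicated sample ids: ",
                           paste(dup, collapse = ", ")))
    dup <- unique(colnames(v)[duplicated(colnames(v))])
    if (length(dup))
      msg <- c(msg, paste0("duplicated feature ids: ",
                           paste(dup, collapse = ", ")))
  }
  if (length(object@omicsLabel) != 1L)
    msg <- c(msg, "'omicsLabel' must be a single string")
  if (length(msg)) msg else TRUE
})

#' Right-censored survival outcome
#'
#' Observed follow-up times and event indicators for a cohort, in a fixed
#' sample order. The observed time is the minimum of the latent event and
#' censoring times; the indicator is 1 when the event was observed.
#'
#' @slot time nonnegative numeric vector of observed times.
#' @slot event integer vector in \{0, 1\}; 1 = event observed, 0 = censored.
#' @slot sampleIDs character vector of unique sample identifiers.
#'
#' @exportClass SurvivalOutcome
setClass("SurvivalOutcome",
  representation(time = "numeric", event = "integer", sampleIDs = "character"))

setValidity("SurvivalOutcome", function(object) {
  msg <- character()
  n <- length(object@time)
  if (length(object@event) != n || length(object@sampleIDs) != n)
    msg <- c(msg, "time, event and sampleIDs must have equal length")
  if (any(!is.finite(object@time)) || any(object@time < 0))
    msg <- c(msg, "observed times must be finite and nonnegative")
  if (!all(object@event %in% c(0L, 1L)))
    msg <- c(msg, "event indicators must be 0 or 1")
  if (anyDuplicated(object@sampleIDs))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Aligned multi-omics survival cohort
#'
#' The central data container: a gene-expression matrix, a microRNA matrix and
#' a right-censored outcome, all carrying the same samples in the same order,
#' with no missing values (i.e. model-ready, after preprocessing).
#'
#' @slot gene an [OmicsMatrix-class] of gene expression.
#' @slot mirna an [OmicsMatrix-class] of microRNA expression.
#' @slot outcome a [SurvivalOutcome-class].
#'
#' @seealso [MultiOmicsSurvival()], [preprocessOmics()], [simulateCohort()]
#' @exportClass MultiOmicsSurvival
setClass("MultiOmicsSurvival",
  representation(gene = "OmicsMatrix", mirna = "OmicsMatrix",
                 outcome = "SurvivalOutcome"))

setValidity("MultiOmicsSurvival", function(object) {
  msg <- character()
  ids <- object@outcome@sampleIDs
  if (!identical(rownames(object@gene@values), ids))
    msg <- c(msg, "gene sample ids do not match the outcome sample order")
  if (!identical(rownames(object@mirna@values), ids))
    msg <- c(msg, "microRNA sample ids do not match the outcome sample order")
  if (anyNA(object@gene@values) || anyNA(object@mirna@values))
    msg <- c(msg, "a model-ready cohort must not contain missing values")
  if (length(msg)) msg else TRUE
})

#' Patient-similarity affinity graph
#'
#' Symmetric nonnegative affinity weights among patients, built from one omics
#' layer by an exponential-kernel k-nn rule (or by averaging several such
#' graphs). The diagonal is zero; self-affinity only enters later through the
#' self-loop added during adjacency normalization.
#'
#' @slot weights n-by-n symmetric nonnegative matrix with zero diagonal.
#' @slot label omics label, or `"fused"` for an averaged graph.
#' @slot k neighbourhood size used in construction (NA for fused graphs).
#' @slot mu kernel bandwidth hyperparameter (NA for fused graphs).
#' @slot deltaSq median pairwise squared distance used as the kernel scale.
#'
#' @seealso [knnAffinity()], [fuseGraphs()], [normalizeAdjacency()]
#' @exportClass AffinityGraph
setClass("AffinityGraph",
  representation(weights = "matrix", label = "character",
                 k = "numeric", mu = "numeric", deltaSq = "numeric"))

setValidity("AffinityGraph", function(object) {
  w <- object@weights
  msg <- character()
  if (nrow(w) != ncol(w))
    msg <- c(msg, "weights must be square")
  if (any(w < 0))
    msg <- c(msg, "weights must be nonnegative")
  if (any(abs(diag(w)) > 0))
    msg <- c(msg, "diagonal must be zero")
  if (max(abs(w - t(w))) > 1e-8)
    msg <- c(msg, "weights must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Normalized graph-convolution matrix
#'
#' The symmetric normalized adjacency with self-loops,
#' \eqn{\hat{A} = \tilde{D}^{-1/2} \tilde{A} \tilde{D}^{-1/2}} with
#' \eqn{\tilde{A} = A + I}, used as the propagation operator of the graph
#' convolutional layers. Its spectrum lies in \eqn{[-1, 1]}.
#'
#' @slot aHat the n-by-n symmetric convolution matrix.
#' @slot degree the self-loop-augmented degree vector \eqn{\tilde{d}}.
#'
#' @exportClass ConvolutionMatrix
setClass("ConvolutionMatrix",
  representation(aHat = "matrix", degree = "numeric"))

setValidity("ConvolutionMatrix", function(object) {
  msg <- character()
  if (nrow(object@aHat) != ncol(object@aHat))
    msg <- c(msg, "aHat must be square")
  if (max(abs(object@aHat - t(object@aHat))) > 1e-8)
    msg <- c(msg, "aHat must be symmetric")
  if (length(object@degree) != nrow(object@aHat))
    msg <- c(msg, "degree length must match aHat dimension")
  if (any(object@degree <= 0))
    msg <- c(msg, "augmented degrees must be positive")
  if (length(msg)) msg else TRUE
})

#' Fused feature set
#'
#' Per-omics encoder outputs together with their low-level sum, the factorized
#' bilinear cross-omics features, and the final concatenation fed to the graph
#' convolutional network.
#'
#' @slot z1 n-by-l encoded gene features.
#' @slot z2 n-by-l encoded microRNA features.
#' @slot zLow n-by-l low-level fusion, `z1 + z2`.
#' @slot zCross n-by-m cross-omics bilinear features.
#' @slot z n-by-(l+m) concatenation `cbind(zLow, zCross)`.
#'
#' @seealso [fuseFeatures()], [fbmForward()]
#' @exportClass FusedFeatures
setClass("FusedFeatures",
  representation(z1 = "matrix", z2 = "matrix", zLow = "matrix",
                 zCross = "matrix", z = "matrix"))

setValidity("FusedFeatures", function(object) {
  msg <- character()
  if (!identical(dim(object@z1), dim(object@z2)))
    msg <- c(msg, "z1 and z2 must have identical shape")
  if (!identical(dim(object@zLow), dim(object@z1)))
    msg <- c(msg, "zLow must match z1's shape")
  if (nrow(object@zCross) != nrow(object@z1))
    msg <- c(msg, "zCross must be row-aligned with z1")
  if (!identical(object@z, cbind(object@zLow, object@zCross)))
    msg <- c(msg, "z must equal cbind(zLow, zCross)")
  if (length(msg)) msg else TRUE
})

#' Breslow baseline cumulative hazard
#'
#' Step-function estimate of the cumulative baseline hazard
#' \eqn{H_0(t) = \sum_{t_k \le t} d_k / \sum_{j \in R(t_k)} \exp(r_j)} given
#' fitted risks, where \eqn{d_k} counts events at the k-th distinct event time
#' and \eqn{R(t_k)} is the risk set. Zero before the first event time.
#'
#' @slot time sorted distinct uncensored event times.
#' @slot cumhaz nondecreasing cumulative hazard at those times.
#'
#' @seealso [breslowBaseline()]
#' @exportClass BaselineHazard
setClass("BaselineHazard",
  representation(time = "numeric", cumhaz = "numeric"))

setValidity("BaselineHazard", function(object) {
  msg <- character()
  if (length(object@time) != length(object@cumhaz))
    msg <- c(msg, "time and cumhaz must have equal length")
  if (is.unsorted(object@time, strictly = TRUE))
    msg <- c(msg, "event times must be strictly increasing")
  if (length(object@cumhaz) && (object@cumhaz[1] < 0 ||
      is.unsorted(object@cumhaz)))
    msg <- c(msg, "cumulative hazard must be nonnegative and nondecreasing")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated cohort
#'
#' The planted quantities behind a simulated multi-omics cohort: the per-sample
#' log-hazard the survival times were generated from, the cluster assignment
#' that induces the shared neighbourhood structure, and the latent factors both
#' omics views load on.
#'
#' @slot trueRisk numeric per-sample planted log-hazard (mean-centred at
#'   generation time).
#' @slot clusterID integer cluster assignment per sample.
#' @slot latent samples-by-latent-dim matrix of latent factors.
#'
#' @seealso [simulateCohort()]
#' @exportClass SimTruth
setClass("SimTruth",
  representation(trueRisk = "numeric", clusterID = "integer",
                 latent = "matrix"))

setValidity("SimTruth", function(object) {
  msg <- character()
  if (any(!is.finite(object@trueRisk)))
    msg <- c(msg, "trueRisk must be finite")
  if (length(object@clusterID) != length(object@trueRisk))
    msg <- c(msg, "clusterID length must match trueRisk")
  if (length(msg)) msg else TRUE
})

#' Fitted survival network
#'
#' Result of [trainModel()]: the fitted parameters of the requested model
#' variant, per-sample risk scores, the train/test partition used, the
#' per-epoch loss trace, and the Breslow baseline hazard estimated from the
#' training risks.
#'
#' @slot variant model variant name (see [buildModel()]).
#' @slot params nested list of fitted weight arrays.
#' @slot config the training configuration list used.
#' @slot risk named numeric vector of risk scores for every sample that
#'   entered the forward pass.
#' @slot trainIdx integer indices of training samples.
#' @slot testIdx integer indices of held-out samples.
#' @slot history data.frame with columns `epoch` and `loss`.
#' @slot baseline a [BaselineHazard-class] estimated on the training samples.
#'
#' @exportClass SurvFit
setClass("SurvFit",
  representation(variant = "character", params = "list", config = "list",
                 risk = "numeric", trainIdx = "integer", testIdx = "integer",
                 history = "data.frame", baseline = "BaselineHazard"))

#' Repeated-holdout evaluation report
#'
#' Per-repeat test-set concordance and cumulative AUC for a model variant
#' under the repeated random 80/20 holdout protocol, with the split seeds that
#' make the report reproducible.
#'
#' @slot metrics data.frame with one row per repeat: `seed`, `cindex`, `auc`.
#' @slot variant model variant evaluated.
#' @slot trainFrac fraction of samples used for training in each split.
#'
#' @seealso [repeatedHoldout()]
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(metrics = "data.frame", variant = "character",
                 trainFrac = "numeric"))

setValidity("EvaluationReport", function(object) {
  m <- object@metrics
  msg <- character()
  if (!all(c("seed", "cindex", "auc") %in% names(m)))
    msg <- c(msg, "metrics must have columns seed, cindex, auc")
  else if (nrow(m) && (any(m$cindex < 0 | m$cindex > 1) ||
                       any(m$auc < 0 | m$auc > 1)))
    msg <- c(msg, "metrics must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
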