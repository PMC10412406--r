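#' Construct an OmicsMatrix
#'
#' @param values numeric samples-by-features matrix. Row/column names are used
#'   as sample/feature ids unless `sampleIDs` / `featureIDs` are given.
#' @param omicsLabel single string naming the omics layer.
#' @param sampleIDs,featureIDs optional id vectors overriding the dimnames.
#' @return an [OmicsMatrix-class].
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("S", 1:4), paste0("g", 1:3)))
#' OmicsMatrix(m, "gene")
#' @export
OmicsMatrix <- function(values, omicsLabel,
                        sampleIDs = rownames(values),
                        featureIDs = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(sampleIDs))
    sampleIDs <- paste0("S", seq_len(nrow(values)))
  if (is.null(featureIDs))
    featureIDs <- paste0("f", seq_len(ncol(values)))
  dimnames(values) <- list(as.character(sampleIDs), as.character(featureIDs))
  new("OmicsMatrix", values = values, omicsLabel = as.character(omicsLabel))
}

#' Construct a SurvivalOutcome
#'
#' @param time nonnegative observed times.
#' @param event event indicators, coercible to 0/1 integers.
#' @param sampleIDs unique sample identifiers (defaults to names of `time`,
#'   else `S1..Sn`).
#' @return a [SurvivalOutcome-class].
#' @export
SurvivalOutcome <- function(time, event, sampleIDs = names(time)) {
  if (is.null(sampleIDs))
    sampleIDs <- paste0("S", seq_along(time))
  ev <- as.integer(event)
  if (any(is.na(ev)) || any(!(event == ev)))
    stop("'event' must contain only 0/1 values")
  new("SurvivalOutcome", time = as.numeric(time), event = ev,
      sampleIDs = as.character(sampleIDs))
}

#' Assemble an aligned multi-omics survival cohort
#'
#' Accepts either [OmicsMatrix-class] objects or plain matrices (with sample
#' ids in rownames). All three parts must carry identical samples in identical
#' order; use [preprocessOmics()] to align and clean raw inputs first.
#'
#' @param gene gene expression, samples in rows.
#' @param mirna microRNA expression, samples in rows.
#' @param outcome a [SurvivalOutcome-class], or a data.frame with columns
#'   `sample_id`, `observed_time`, `event`.
#' @return a [MultiOmicsSurvival-class].
#' @export
MultiOmicsSurvival <- function(gene, mirna, outcome) {
  if (!is(gene, "OmicsMatrix")) gene <- OmicsMatrix(gene, "gene")
  if (!is(mirna, "OmicsMatrix")) mirna <- OmicsMatrix(mirna, "microRNA")
  if (is.data.frame(outcome))
    outcome <- SurvivalOutcome(outcome$observed_time, outcome$event,
                               outcome$sample_id)
  new("MultiOmicsSurvival", gene = gene, mirna = mirna, outcome = outcome)
}

#' Accessors for the core data classes
#'
#' `geneExpr`/`mirnaExpr` return the raw numeric matrices of a cohort;
#' `survTime`/`survEvent` the outcome vectors; `sampleIDs`, `featureIDs`,
#' `nSamples` the obvious identifiers and counts; `omicsValues`/`omicsLabel`
#' the matrix and label of a single [OmicsMatrix-class].
#'
#' @param x the object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
setMethod("omicsValues", "OmicsMatrix", function(x) x@values)
#' @rdname accessors
setMethod("omicsLabel", "OmicsMatrix", function(x) x@omicsLabel)
#' @rdname accessors
setMethod("sampleIDs", "OmicsMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("featureIDs", "OmicsMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("nSamples", "OmicsMatrix", function(x) nrow(x@values))

#' @rdname accessors
setMethod("sampleIDs", "SurvivalOutcome", function(x) x@sampleIDs)
#' @rdname accessors
setMethod("survTime", "SurvivalOutcome", function(x) x@time)
#' @rdname accessors
setMethod("survEvent", "SurvivalOutcome", function(x) x@event)
#' @rdname accessors
setMethod("nSamples", "SurvivalOutcome", function(x) length(x@time))

#' @rdname accessors
setMethod("geneExpr", "MultiOmicsSurvival", function(x) x@gene@values)
#' @rdname accessors
setMethod("mirnaExpr", "MultiOmicsSurvival", function(x) x@mirna@values)
#' @rdname accessors
setMethod("survTime", "MultiOmicsSurvival", function(x) x@outcome@time)
#' @rdname accessors
setMethod("survEvent", "MultiOmicsSurvival", function(x) x@outcome@event)
#' @rdname accessors
setMethod("sampleIDs", "MultiOmicsSurvival", function(x) x@outcome@sampleIDs)
#' @rdname accessors
setMethod("nSamples", "MultiOmicsSurvival", function(x) length(x@outcome@time))

#' Graph accessors
#'
#' `graphWeights` returns the affinity matrix of an [AffinityGraph-class];
#' `convMatrix` the normalized adjacency of a [ConvolutionMatrix-class].
#'
#' @param x the object.
#' @return a numeric matrix.
#' @name graph-accessors
NULL

#' @rdname graph-accessors
setMethod("graphWeights", "AffinityGraph", function(x) x@weights)
#' @rdname graph-accessors
setMethod("convMatrix", "ConvolutionMatrix", function(x) x@aHat)

#' Fitted-model accessors
#'
#' `riskScores` returns the per-sample risk scores of a [SurvFit-class]
#' (optionally restricted to `which = "train"` or `"test"`); `lossHistory`
#' the per-epoch training-loss data.frame.
#'
#' @param x a [SurvFit-class].
#' @param which one of `"all"`, `"train"`, `"test"`.
#' @param ... unused.
#' @return a named numeric vector, or a data.frame for `lossHistory`.
#' @name fit-accessors
NULL

#' @rdname fit-accessors
setMethod("riskScores", "SurvFit", function(x, which = c("all", "train", "test"), ...) {
  which <- match.arg(which)
  switch(which,
         all = x@risk,
         train = x@risk[x@trainIdx],
         test = x@risk[x@testIdx])
})

#' @rdname fit-accessors
setMethod("lossHistory", "SurvFit", function(x) x@history)

setMethod("show", "OmicsMatrix", function(object) {
  cat(sprintf("OmicsMatrix [%s]: %d samples x %d features (%d missing)\n",
              object@omicsLabel, nrow(object@values), ncol(object@values),
              sum(is.na(object@values))))
})

setMethod("show", "SurvivalOutcome", function(object) {
  cat(sprintf("SurvivalOutcome: %d samples, %d events (%.1f%% censored)\n",
              length(object@time), sum(object@event),
              100 * mean(object@event == 0)))
})

setMethod("show", "MultiOmicsSurvival", function(object) {
  cat(sprintf(paste0("MultiOmicsSurvival: %d samples\n",
                     "  gene:     %d features\n",
                     "  microRNA: %d features\n",
                     "  outcome:  %d events (%.1f%% censored)\n"),
              nSamples(object), ncol(object@gene@values),
              ncol(object@mirna@values), sum(object@outcome@event),
              100 * mean(object@outcome@event == 0)))
})

setMethod("show", "AffinityGraph", function(object) {
  nz <- sum(object@weights > 0)
  cat(sprintf("AffinityGraph [%s]: %d nodes, %d nonzero edges (k=%s, mu=%s)\n",
              object@label, nrow(object@weights), nz / 2,
              format(object@k), format(object@mu)))
})

setMethod("show", "ConvolutionMatrix", function(object) {
  cat(sprintf("ConvolutionMatrix: %d x %d normalized adjacency\n",
              nrow(object@aHat), ncol(object@aHat)))
})

setMethod("show", "FusedFeatures", function(object) {
  cat(sprintf("FusedFeatures: n=%d, l=%d, m=%d (fused width %d)\n",
              nrow(object@z1), ncol(object@z1), ncol(object@zCross),
              ncol(object@z)))
})

setMethod("show", "SurvFit", function(object) {
  cat(sprintf(paste0("SurvFit [%s]: %d train / %d test samples, ",
                     "%d epochs, final loss %.6g\n"),
              object@variant, length(object@trainIdx), length(object@testIdx),
              nrow(object@history), utils::tail(object@history$loss, 1)))
})

setMethod("show", "EvaluationReport", function(object) {
  m <- object@metrics
  cat(sprintf(paste0("EvaluationReport [%s]: %d repeats (train fraction ",
                     "%.2f)\n  C-index: %.3f +/- %.3f\n  AUC:     ",
                     "%.3f +/- %.3f\n"),
              object@variant, nrow(m), object@trainFrac,
              mean(m$cindex), stats::sd(m$cindex),
              mean(m$auc), stats::sd(m$auc)))
})

#' Summarize a repeated-holdout report
#'
#' @param object an [EvaluationReport-class].
#' @param ... unused.
#' @return a data.frame with one row: variant, repeats, mean/sd of C-index
#'   and cumulative AUC.
#' @export
setMethod("summary", "EvaluationReport", function(object, ...) {
  m <- object@metrics
  data.frame(variant = object@variant, repeats = nrow(m),
             cindex_mean = mean(m$cindex), cindex_sd = stats::sd(m$cindex),
             auc_mean = mean(m$auc), auc_sd = stats::sd(m$auc))
})
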