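#' Negative Cox log partial likelihood
#'
#' The training loss: \eqn{\sum_{i: \Delta_i = 1} [\log \sum_{j \in R(i)}
#' \exp(r_j) - r_i]} with risk set \eqn{R(i) = \{j : O_j \ge O_i\}} (the
#' patient's own time is included; tied event times are handled in the
#' Breslow manner). The log-sum-exp is stabilized by max subtraction. The
#' partial likelihood depends only on differences of risk scores, so adding a
#' constant to every risk leaves the loss unchanged.
#'
#' @param risk numeric vector of risk scores (the linear predictor).
#' @param time observed times.
#' @param event 0/1 event indicators; at least one event is required.
#' @return the scalar loss.
#' @export
coxPartialLoss <- function(risk, time, event) {
  event <- as.integer(event)
  if (!any(event == 1L)) stop("at least one event is required")
  if (any(!is.finite(risk))) stop("non-finite risk scores")
  ord <- order(time)
  tt <- time[ord]
  rr <- risk[ord]
  ee <- event[ord]
  mx <- max(rr)
  ex <- exp(rr - mx)
  s <- rev(cumsum(rev(ex)))
  denom <- s[match(tt, tt)]  # first index of each tie block: sum over O_j >= O_i
  sum(ee * (log(denom) + mx - rr))
}

#' Gradient of the Cox partial-likelihood loss
#'
#' Analytic gradient of [coxPartialLoss()] with respect to the risk vector:
#' \eqn{\partial L / \partial r_k = -\Delta_k + e^{r_k} \sum_{i \in E, O_i
#' \le O_k} 1 / \sum_{j \in R(i)} e^{r_j}}.
#'
#' @inheritParams coxPartialLoss
#' @return numeric gradient vector of the same length as `risk`.
#' @export
coxPartialGradient <- function(risk, time, event) {
  event <- as.integer(event)
  ord <- order(time)
  tt <- time[ord]
  rr <- risk[ord]
  ee <- event[ord]
  mx <- max(rr)
  ex <- exp(rr - mx)
  s <- rev(cumsum(rev(ex)))
  denom <- s[match(tt, tt)]
  cum <- cumsum(ee / denom)
  gs <- -ee + ex * cum[findInterval(tt, tt)]  # last index of tie block
  g <- numeric(length(risk))
  g[ord] <- gs
  g
}

#' Graph-convolution forward pass
#'
#' The two-layer graph convolutional embedding
#' \deqn{Z_h = f_2(f_1(\hat{A} Z W_1) W_2)}
#' with \eqn{f_1 = \tanh}, \eqn{f_2 = sigmoid}. Note that graph mixing is
#' applied in the first layer only; `twoHop = TRUE` switches to the
#' conventional variant that multiplies by \eqn{\hat{A}} in both layers.
#'
#' @param aHat a [ConvolutionMatrix-class], a plain n-by-n matrix, or `NULL`
#'   for the identity (no neighbour mixing).
#' @param z n-by-(feature width) fused feature matrix.
#' @param params list with weight matrices `W1`, `W2`.
#' @param twoHop apply \eqn{\hat{A}} in the second layer too.
#' @param cache if `TRUE`, return intermediates for the backward pass.
#' @return n-by-h2 embedding, or `list(out, cache)`.
#' @export
gcnForward <- function(aHat, z, params, twoHop = FALSE, cache = FALSE) {
  a <- if (is(aHat, "ConvolutionMatrix")) aHat@aHat else aHat
  if (!is.null(a) && (nrow(a) != nrow(z)))
    stop("aHat dimension does not match the number of samples")
  if (ncol(z) != nrow(params$W1))
    stop("feature width ", ncol(z), " does not match W1 input dim ",
         nrow(params$W1))
  az <- if (is.null(a)) z else a %*% z
  h1 <- tanh(az %*% params$W1)
  mid <- if (twoHop && !is.null(a)) a %*% h1 else h1
  zh <- .sigmoid(mid %*% params$W2)
  if (cache)
    list(out = zh, cache = list(az = az, h1 = h1, mid = mid, zh = zh))
  else zh
}

.gcnBackward <- function(dzh, z, params, cc, a, twoHop) {
  dP2 <- dzh * cc$zh * (1 - cc$zh)
  dW2 <- crossprod(cc$mid, dP2)
  dMid <- tcrossprod(dP2, params$W2)
  dH1 <- if (twoHop && !is.null(a)) a %*% dMid else dMid
  dP1 <- dH1 * (1 - cc$h1^2)
  dW1 <- crossprod(cc$az, dP1)
  dz <- tcrossprod(dP1, params$W1)
  if (!is.null(a)) dz <- a %*% dz  # a is symmetric
  list(W1 = dW1, W2 = dW2, dz = dz)
}

#' Linear Cox risk scores
#'
#' @param zh n-by-h embedding (or feature) matrix.
#' @param beta length-h weight vector (no intercept).
#' @return numeric vector of risk scores.
#' @export
riskScore <- function(zh, beta) {
  if (ncol(zh) != length(beta))
    stop("embedding width ", ncol(zh), " does not match beta length ",
         length(beta))
  drop(zh %*% beta)
}

#' Breslow estimate of the cumulative baseline hazard
#'
#' \eqn{H_0(t) = \sum_{t_k \le t} d_k / \sum_{j : O_j \ge t_k} \exp(r_j)}
#' over the distinct uncensored event times \eqn{t_k} with event counts
#' \eqn{d_k}. With all risks zero this reduces to the Nelson-Aalen estimator.
#'
#' @inheritParams coxPartialLoss
#' @return a [BaselineHazard-class].
#' @export
breslowBaseline <- function(risk, time, event) {
  event <- as.integer(event)
  if (!any(event == 1L)) stop("at least one event is required")
  evTimes <- sort(unique(time[event == 1L]))
  ex <- exp(risk)
  jumps <- vapply(evTimes, function(tk)
    sum(event == 1L & time == tk) / sum(ex[time >= tk]), numeric(1))
  new("BaselineHazard", time = evTimes, cumhaz = cumsum(jumps))
}

.variantNames <- c("FULL", "GCN_SINGLE", "LOW_FF", "FBM_FF", "HIGH_FF",
                   "NO_GRAPH", "NO_FBM")

.variantFlags <- function(variant, singleOmics = "gene") {
  switch(variant,
    FULL = list(useGCN = TRUE, useFBM = TRUE, featureSource = "fused",
                identityGraph = FALSE, omics = "both"),
    GCN_SINGLE = list(useGCN = TRUE, useFBM = FALSE, featureSource = "single",
                      identityGraph = FALSE, omics = singleOmics),
    LOW_FF = list(useGCN = FALSE, useFBM = FALSE, featureSource = "low",
                  identityGraph = TRUE, omics = "both"),
    FBM_FF = list(useGCN = FALSE, useFBM = TRUE, featureSource = "cross",
                  identityGraph = TRUE, omics = "both"),
    HIGH_FF = list(useGCN = FALSE, useFBM = TRUE, featureSource = "fused",
                   identityGraph = TRUE, omics = "both"),
    NO_GRAPH = list(useGCN = TRUE, useFBM = TRUE, featureSource = "fused",
                    identityGraph = TRUE, omics = "both"),
    NO_FBM = list(useGCN = TRUE, useFBM = FALSE, featureSource = "low",
                  identityGraph = FALSE, omics = "both"),
    stop("unknown variant: ", variant))
}

#' Assemble a model variant
#'
#' Wires one of the network configurations and initializes its parameters
#' (Glorot-uniform, from the current RNG stream):
#' \describe{
#'   \item{FULL}{highway encoders, FBM, fused features (width l+m), fused
#'     graph, GCN, Cox head.}
#'   \item{GCN_SINGLE}{one omics only: its highway features (width l), its
#'     own graph, GCN, Cox head.}
#'   \item{LOW_FF}{Cox head directly on the low-level sum `z1 + z2`
#'     (no FBM, no GCN).}
#'   \item{FBM_FF}{Cox head directly on the cross-omics FBM features
#'     (no GCN).}
#'   \item{HIGH_FF}{Cox head directly on the full concatenation
#'     `cbind(zLow, zCross)` (no GCN).}
#'   \item{NO_GRAPH}{FULL with the convolution matrix replaced by the
#'     identity (GCN layers become dense layers).}
#'   \item{NO_FBM}{FULL with the fused features replaced by the low-level
#'     features `zLow` (width l).}
#' }
#'
#' @param variant one of the names above.
#' @param pGene,pMirna input feature counts of the two views.
#' @param l encoder width. @param d FBM factor rank. @param m number of
#'   cross-omics features. @param h1,h2 GCN hidden widths.
#' @param nLayers highway blocks per encoder.
#' @param singleOmics which view `GCN_SINGLE` uses, `"gene"` or `"mirna"`.
#' @return a list with elements `variant`, `flags`, `params`, `dims`.
#' @export
buildModel <- function(variant, pGene, pMirna, l = 50L, d = 16L, m = 10L,
                       h1 = 30L, h2 = 15L, nLayers = 3L,
                       singleOmics = "gene") {
  variant <- match.arg(variant, .variantNames)
  l <- as.integer(l); d <- as.integer(d); m <- as.integer(m)
  h1 <- as.integer(h1); h2 <- as.integer(h2)
  flags <- .variantFlags(variant, singleOmics)
  params <- list()
  if (flags$omics %in% c("both", "gene"))
    params$enc1 <- initHighwayParams(pGene, l, nLayers)
  if (flags$omics %in% c("both", "mirna"))
    params$enc2 <- initHighwayParams(pMirna, l, nLayers)
  if (flags$useFBM)
    params$fbm <- initFBMParams(l, d, m)
  featWidth <- switch(flags$featureSource,
                      fused = l + m, low = l, cross = m, single = l)
  if (flags$useGCN) {
    params$gcn <- list(W1 = .glorot(featWidth, h1), W2 = .glorot(h1, h2))
    params$beta <- drop(.glorot(h2, 1))
  } else {
    params$beta <- drop(.glorot(featWidth, 1))
  }
  list(variant = variant, flags = flags, params = params,
       dims = list(pGene = pGene, pMirna = pMirna, l = l, d = d, m = m,
                   h1 = h1, h2 = h2, featWidth = featWidth))
}

# Forward pass of an assembled model. Returns risk plus caches when cache=TRUE.
.modelForward <- function(model, x1, x2, aHat, twoHop = FALSE,
                          cache = FALSE) {
  flags <- model$flags
  p <- model$params
  cc <- list()
  z1 <- z2 <- NULL
  if (!is.null(p$enc1)) {
    f <- highwayForward(x1, p$enc1, cache = cache)
    if (cache) { z1 <- f$out; cc$enc1 <- f$cache } else z1 <- f
  }
  if (!is.null(p$enc2)) {
    f <- highwayForward(x2, p$enc2, cache = cache)
    if (cache) { z2 <- f$out; cc$enc2 <- f$cache } else z2 <- f
  }
  zCross <- NULL
  if (flags$useFBM) {
    f <- fbmForward(z1, z2, p$fbm, cache = cache)
    if (cache) { zCross <- f$out; cc$fbm <- f$cache } else zCross <- f
  }
  feat <- switch(flags$featureSource,
                 fused = cbind(z1 + z2, zCross),
                 low = z1 + z2,
                 cross = zCross,
                 single = if (!is.null(z1)) z1 else z2)
  a <- if (flags$identityGraph) NULL else aHat
  if (flags$useGCN) {
    f <- gcnForward(a, feat, p$gcn, twoHop = twoHop, cache = cache)
    if (cache) { zh <- f$out; cc$gcn <- f$cache } else zh <- f
  } else {
    zh <- feat
  }
  risk <- riskScore(zh, p$beta)
  if (cache)
    list(risk = risk, z1 = z1, z2 = z2, zCross = zCross, feat = feat,
         zh = zh, cache = cc)
  else
    list(risk = risk)
}

# Backward pass: returns gradients mirroring model$params exactly.
.modelBackward <- function(model, fw, drisk, x1, x2, aHat, twoHop = FALSE) {
  flags <- model$flags
  p <- model$params
  g <- list()
  dzh <- drisk %o% p$beta
  gBeta <- drop(crossprod(fw$zh, drisk))
  a <- if (flags$identityGraph) NULL else aHat
  if (flags$useGCN) {
    gb <- .gcnBackward(dzh, fw$feat, p$gcn, fw$cache$gcn, a, twoHop)
    g$gcn <- list(W1 = gb$W1, W2 = gb$W2)
    dFeat <- gb$dz
  } else {
    dFeat <- dzh
  }
  l <- model$dims$l
  m <- model$dims$m
  dz1 <- dz2 <- dzCross <- NULL
  if (flags$featureSource == "fused") {
    dLow <- dFeat[, seq_len(l), drop = FALSE]
    dzCross <- dFeat[, l + seq_len(m), drop = FALSE]
    dz1 <- dLow
    dz2 <- dLow
  } else if (flags$featureSource == "low") {
    dz1 <- dFeat
    dz2 <- dFeat
  } else if (flags$featureSource == "cross") {
    dzCross <- dFeat
  } else {  # single
    if (!is.null(p$enc1)) dz1 <- dFeat else dz2 <- dFeat
  }
  if (flags$useFBM) {
    fb <- .fbmBackward(dzCross, fw$z1, fw$z2, p$fbm, fw$cache$fbm)
    g$fbm <- list(U = fb$U, V = fb$V)
    dz1 <- if (is.null(dz1)) fb$dz1 else dz1 + fb$dz1
    dz2 <- if (is.null(dz2)) fb$dz2 else dz2 + fb$dz2
  }
  if (!is.null(p$enc1))
    g$enc1 <- .highwayBackward(dz1, x1, p$enc1, fw$cache$enc1)
  if (!is.null(p$enc2))
    g$enc2 <- .highwayBackward(dz2, x2, p$enc2, fw$cache$enc2)
  g$beta <- gBeta
  # reorder to mirror params
  g[names(p)]
}

.zeroLike <- function(p) {
  if (is.list(p)) lapply(p, .zeroLike) else p * 0
}

.adamStep <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(p)) {
    out <- mapply(.adamStep, p, g, m, v,
                  MoreArgs = list(lr = lr, t = t, b1 = b1, b2 = b2, eps = eps),
                  SIMPLIFY = FALSE)
    list(p = lapply(out, `[[`, "p"),
         m = lapply(out, `[[`, "m"),
         v = lapply(out, `[[`, "v"))
  } else {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    list(p = p - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps),
         m = m, v = v)
  }
}

#' Training configuration
#'
#' Defaults: Adam with learning rate 2e-4, full-batch gradients (cohorts of a
#' few hundred samples make this exact and deterministic), at most 3000
#' epochs with early stopping once the training loss improves by less than
#' `tol` (relative) over `patience` consecutive epochs. Graph construction
#' uses neighbourhood size `k` with kernel bandwidths `muGene = 0.3` and
#' `muMirna = 0.2`. In the default transductive mode the graph and the
#' forward pass cover train and test samples while the loss sums over
#' training samples only; `graphMode = "train_graph"` trains strictly on the
#' training subgraph and only embeds the test samples once, after training.
#'
#' @param learningRate Adam learning rate.
#' @param maxEpochs maximum number of full-batch epochs.
#' @param tol relative improvement threshold for early stopping.
#' @param patience epochs without sufficient improvement before stopping.
#' @param seed RNG seed controlling initialization.
#' @param k graph neighbourhood size.
#' @param muGene,muMirna kernel bandwidths of the two per-omics graphs.
#' @param symmetrize graph symmetrization rule (see [knnAffinity()]).
#' @param graphMode `"transductive"` or `"train_graph"`.
#' @param l,m,d,h1,h2 architecture widths (encoder width, cross-feature
#'   count, FBM rank, GCN hidden widths).
#' @param nLayers highway blocks per encoder.
#' @param twoHop apply the convolution matrix in both GCN layers.
#' @param singleOmics omics used by the `GCN_SINGLE` variant.
#' @return a list of class `TrainConfig`.
#' @export
trainConfig <- function(learningRate = 2e-4, maxEpochs = 3000L, tol = 1e-6,
                        patience = 20L, seed = 1L, k = 10L, muGene = 0.3,
                        muMirna = 0.2, symmetrize = "average",
                        graphMode = c("transductive", "train_graph"),
                        l = 50L, m = 10L, d = 16L, h1 = 30L, h2 = 15L,
                        nLayers = 3L, twoHop = FALSE, singleOmics = "gene") {
  stopifnot(learningRate >= 0, maxEpochs >= 1)
  graphMode <- match.arg(graphMode)
  structure(list(learningRate = learningRate,
                 maxEpochs = as.integer(maxEpochs), tol = tol,
                 patience = as.integer(patience), seed = as.integer(seed),
                 k = as.integer(k), muGene = muGene, muMirna = muMirna,
                 symmetrize = symmetrize, graphMode = graphMode,
                 l = as.integer(l), m = as.integer(m), d = as.integer(d),
                 h1 = as.integer(h1), h2 = as.integer(h2),
                 nLayers = as.integer(nLayers), twoHop = twoHop,
                 singleOmics = singleOmics),
            class = "TrainConfig")
}

.buildAHat <- function(dataset, flags, config, rows) {
  if (flags$identityGraph || !flags$useGCN) return(NULL)
  if (flags$omics == "both")
    fusedConvolution(dataset, config$k, config$muGene, config$muMirna,
                     config$symmetrize, rows = rows)@aHat
  else if (flags$omics == "gene")
    normalizeAdjacency(knnAffinity(geneExpr(dataset)[rows, , drop = FALSE],
                                   config$k, config$muGene,
                                   config$symmetrize, "gene"))@aHat
  else
    normalizeAdjacency(knnAffinity(mirnaExpr(dataset)[rows, , drop = FALSE],
                                   config$k, config$muMirna,
                                   config$symmetrize, "microRNA"))@aHat
}

#' Train a survival network
#'
#' Full-batch Adam on the negative Cox log partial likelihood. In the
#' default transductive mode the patient graph and the forward pass include
#' the training and held-out samples, but the loss (and its gradient) is
#' restricted to the training samples; held-out outcomes never influence the
#' fit. Training is deterministic given `config$seed`.
#'
#' @param dataset a [MultiOmicsSurvival-class].
#' @param variant model variant, see [buildModel()].
#' @param trainIdx integer indices of the training samples (at least one
#'   event required).
#' @param testIdx integer indices of held-out samples (may be empty).
#' @param config a [trainConfig()] list.
#' @param aHat optional precomputed convolution matrix over
#'   `sort(c(trainIdx, testIdx))`, to amortize graph construction across
#'   repeated fits.
#' @return a [SurvFit-class]; `riskScores(fit)` is named by sample id and
#'   covers `union(trainIdx, testIdx)` (in dataset order).
#' @export
trainModel <- function(dataset, variant = "FULL", trainIdx,
                       testIdx = integer(0), config = trainConfig(),
                       aHat = NULL) {
  variant <- match.arg(variant, .variantNames)
  trainIdx <- sort(as.integer(trainIdx))
  testIdx <- sort(as.integer(testIdx))
  if (!length(trainIdx)) stop("trainIdx must be nonempty")
  if (length(intersect(trainIdx, testIdx)))
    stop("trainIdx and testIdx overlap")
  time <- survTime(dataset)
  event <- survEvent(dataset)
  if (!any(event[trainIdx] == 1L))
    stop("training set contains no events")

  flags <- .variantFlags(variant, config$singleOmics)
  scope <- sort(c(trainIdx, testIdx))
  withr::local_seed(config$seed)
  model <- buildModel(variant, ncol(geneExpr(dataset)),
                      ncol(mirnaExpr(dataset)), l = config$l, d = config$d,
                      m = config$m, h1 = config$h1, h2 = config$h2,
                      nLayers = config$nLayers,
                      singleOmics = config$singleOmics)

  fitRows <- if (config$graphMode == "transductive") scope else trainIdx
  x1 <- geneExpr(dataset)[fitRows, , drop = FALSE]
  x2 <- mirnaExpr(dataset)[fitRows, , drop = FALSE]
  aFit <- if (config$graphMode == "transductive" && !is.null(aHat)) {
    if (is(aHat, "ConvolutionMatrix")) aHat@aHat else aHat
  } else {
    .buildAHat(dataset, flags, config, fitRows)
  }
  trainPos <- match(trainIdx, fitRows)
  tTr <- time[trainIdx]
  eTr <- event[trainIdx]

  params <- model$params
  mSt <- .zeroLike(params)
  vSt <- .zeroLike(params)
  history <- numeric(config$maxEpochs)
  best <- Inf
  stall <- 0L
  nEpoch <- 0L
  for (epoch in seq_len(config$maxEpochs)) {
    model$params <- params
    fw <- .modelForward(model, x1, x2, aFit, twoHop = config$twoHop,
                        cache = TRUE)
    loss <- coxPartialLoss(fw$risk[trainPos], tTr, eTr)
    if (!is.finite(loss))
      stop("training diverged (non-finite loss) at epoch ", epoch)
    history[epoch] <- loss
    nEpoch <- epoch
    if (!is.finite(best) || loss < best - config$tol * max(1, abs(best))) {
      best <- loss
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
    drisk <- numeric(length(fw$risk))
    drisk[trainPos] <- coxPartialGradient(fw$risk[trainPos], tTr, eTr)
    grads <- .modelBackward(model, fw, drisk, x1, x2, aFit,
                            twoHop = config$twoHop)
    upd <- .adamStep(params, grads, mSt, vSt, config$learningRate, epoch)
    params <- upd$p
    mSt <- upd$m
    vSt <- upd$v
  }
  model$params <- params

  # final risks over the full scope (rebuild graph over scope when training
  # used only the training subgraph)
  if (config$graphMode == "transductive") {
    xs1 <- x1
    xs2 <- x2
    aScope <- aFit
  } else {
    xs1 <- geneExpr(dataset)[scope, , drop = FALSE]
    xs2 <- mirnaExpr(dataset)[scope, , drop = FALSE]
    aScope <- .buildAHat(dataset, flags, config, scope)
  }
  risk <- .modelForward(model, xs1, xs2, aScope, twoHop = config$twoHop)$risk
  names(risk) <- sampleIDs(dataset)[scope]
  scopePos <- match(trainIdx, scope)
  baseline <- breslowBaseline(risk[scopePos], tTr, eTr)
  new("SurvFit", variant = variant, params = params,
      config = unclass(config), risk = risk,
      trainIdx = match(trainIdx, scope), testIdx = match(testIdx, scope),
      history = data.frame(epoch = seq_len(nEpoch),
                           loss = history[seq_len(nEpoch)]),
      baseline = baseline)
}
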