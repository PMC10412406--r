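#' Simulation configuration
#'
#' Conditions for the synthetic multi-omics cohort generator. The defaults
#' describe a mid-sized cancer cohort at desk scale: 300 patients, 120 gene
#' and 40 microRNA features loading on a shared 8-dimensional latent space
#' organized in 3 clusters, additive and cross-omics risk components of equal
#' strength, exponential baseline hazard, and 50% censoring (real cohorts of
#' this kind range from roughly 40% to 85% censored).
#'
#' @param nSamples number of patients (at least 10).
#' @param pGene,pMirna feature counts of the two omics views.
#' @param nClusters number of latent clusters shared by both views.
#' @param latentDim dimension of the shared latent factors.
#' @param clusterSep standard deviation of the cluster centres in latent
#'   space; large relative to the unit within-cluster spread, so that the
#'   planted partition is geometrically unambiguous (exactly so at
#'   `noiseSD = 0`).
#' @param betaAdditive scale of the additive (single-omics, linear) risk
#'   component, in units of risk standard deviations.
#' @param betaCross scale of the multiplicative cross-omics risk component.
#' @param baselineScale exponential baseline hazard rate.
#' @param targetCensoring desired censoring proportion, strictly in (0, 1).
#' @param noiseSD standard deviation of the additive observation noise on
#'   both omics views.
#' @param weibullShape shape of the event/censoring time distributions; 1
#'   (default) gives exponential, i.e. constant hazards.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return a list of class `SimConfig`.
#' @export
simConfig <- function(nSamples = 300L, pGene = 120L, pMirna = 40L,
                      nClusters = 3L, latentDim = 8L, clusterSep = 6,
                      betaAdditive = 1, betaCross = 1,
                      baselineScale = 0.1, targetCensoring = 0.5,
                      noiseSD = 1, weibullShape = 1, seed = 1L) {
  stopifnot(nSamples >= 10, pGene >= 1, pMirna >= 1, nClusters >= 1,
            latentDim >= 1, targetCensoring > 0, targetCensoring < 1,
            noiseSD >= 0, baselineScale > 0, weibullShape > 0, clusterSep >= 0)
  structure(list(nSamples = as.integer(nSamples), pGene = as.integer(pGene),
                 pMirna = as.integer(pMirna), nClusters = as.integer(nClusters),
                 latentDim = as.integer(latentDim), clusterSep = clusterSep,
                 betaAdditive = betaAdditive, betaCross = betaCross,
                 baselineScale = baselineScale,
                 targetCensoring = targetCensoring, noiseSD = noiseSD,
                 weibullShape = weibullShape, seed = as.integer(seed)),
            class = "SimConfig")
}

.unitScale <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x * 0)
  (x - mean(x)) / s
}

#' Calibrate the censoring rate
#'
#' Finds the rate of an independent censoring distribution (exponential, or
#' Weibull sharing the event-time shape) such that the expected censoring
#' proportion of the cohort equals `targetCensoring`. For same-shape
#' competing Weibull times the censoring probability of patient i is
#' `c / (lambda_i + c)` with `lambda_i` the patient's event rate, so the
#' expectation is a monotone function of `c` and the rate is solved by
#' root-finding on the cohort average.
#'
#' @param trueRisk per-sample planted log-hazard.
#' @param baselineScale baseline hazard rate.
#' @param targetCensoring desired censoring proportion in (0, 1).
#' @return the censoring rate (scalar).
#' @export
calibrateCensoringRate <- function(trueRisk, baselineScale, targetCensoring) {
  stopifnot(targetCensoring > 0, targetCensoring < 1)
  lambda <- baselineScale * exp(trueRisk - mean(trueRisk))
  f <- function(logc) mean(exp(logc) / (lambda + exp(logc))) - targetCensoring
  lo <- log(min(lambda)) - 40
  hi <- log(max(lambda)) + 40
  if (f(lo) > 0 || f(hi) < 0)
    stop("failed to bracket a censoring rate for target ", targetCensoring)
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
}

#' Simulate a multi-omics right-censored cohort
#'
#' Generative recipe: (1) patients are assigned to clusters with
#' well-separated latent centres and per-patient latent factors
#' `h = centre + N(0, I)`; (2) both omics views are random linear loadings of
#' the latent factors plus independent Gaussian noise, so they share
#' neighbourhood structure; (3) the planted log-hazard combines an additive
#' part (sparse linear weights on both views) and a multiplicative
#' cross-omics part (a low-rank bilinear form between the views), each
#' standardized to unit variance before scaling by `betaAdditive` /
#' `betaCross`; (4) event times are proportional-hazards Weibull
#' (exponential by default) with rate proportional to `exp(trueRisk)`;
#' (5) independent censoring times use the rate returned by
#' [calibrateCensoringRate()], and only `min(T, C)` plus the indicator are
#' kept. All randomness flows from `config$seed`; the caller's RNG state is
#' untouched.
#'
#' @param config a [simConfig()] list.
#' @return a list with elements `dataset` (a [MultiOmicsSurvival-class]) and
#'   `truth` (a [SimTruth-class]).
#' @export
simulateCohort <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  withr::local_seed(config$seed)
  n <- config$nSamples
  q <- config$latentDim

  cluster <- sample(rep_len(seq_len(config$nClusters), n))
  centres <- matrix(stats::rnorm(config$nClusters * q, sd = config$clusterSep),
                    config$nClusters, q)
  h <- centres[cluster, , drop = FALSE] +
    matrix(stats::rnorm(n * q), n, q)

  loading <- function(p) matrix(stats::rnorm(q * p), q, p) / sqrt(q)
  # features are emitted cohort-centred (as model-ready expression features
  # are); centring is a per-feature translation, so it changes neither the
  # pairwise-distance geometry nor the cluster margins, but it removes the
  # large mean offsets around which a bilinear form would linearize
  centreCols <- function(x) sweep(x, 2, colMeans(x))
  x1 <- centreCols(h %*% loading(config$pGene) +
    config$noiseSD * matrix(stats::rnorm(n * config$pGene), n))
  x2 <- centreCols(h %*% loading(config$pMirna) +
    config$noiseSD * matrix(stats::rnorm(n * config$pMirna), n))

  sparseWeights <- function(p) {
    w <- numeric(p)
    nz <- sample(p, max(1L, ceiling(0.1 * p)))
    w[nz] <- stats::rnorm(length(nz))
    w
  }
  additive <- drop(x1 %*% sparseWeights(config$pGene) +
                   x2 %*% sparseWeights(config$pMirna))
  rank2 <- function(p) matrix(stats::rnorm(p * 2), p, 2) / sqrt(p)
  cross <- rowSums((x1 %*% rank2(config$pGene)) *
                   (x2 %*% rank2(config$pMirna)))
  trueRisk <- config$betaAdditive * .unitScale(additive) +
    config$betaCross * .unitScale(cross)
  trueRisk <- trueRisk - mean(trueRisk)

  lambda <- config$baselineScale * exp(trueRisk)
  shape <- config$weibullShape
  tEvent <- (stats::rexp(n) / lambda)^(1 / shape)
  cRate <- calibrateCensoringRate(trueRisk, config$baselineScale,
                                  config$targetCensoring)
  tCens <- (stats::rexp(n) / cRate)^(1 / shape)
  obs <- pmin(tEvent, tCens)
  delta <- as.integer(tEvent <= tCens)

  ids <- sprintf("P%04d", seq_len(n))
  gene <- OmicsMatrix(`dimnames<-`(x1, list(ids, sprintf("g%04d",
           seq_len(config$pGene)))), "gene")
  mirna <- OmicsMatrix(`dimnames<-`(x2, list(ids, sprintf("mir%03d",
            seq_len(config$pMirna)))), "microRNA")
  outcome <- SurvivalOutcome(obs, delta, ids)
  dimnames(h) <- list(ids, paste0("latent", seq_len(q)))
  list(dataset = MultiOmicsSurvival(gene, mirna, outcome),
       truth = new("SimTruth", trueRisk = stats::setNames(trueRisk, ids),
                   clusterID = as.integer(cluster), latent = h))
}

#' Write a simulated cohort to disk
#'
#' Writes `gene.tsv`, `mirna.tsv`, `survival.tsv` in the formats the readers
#' consume, plus `truth.tsv` (sample_id, true_risk, cluster_id).
#'
#' @param cohort the list returned by [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return `invisible(dir)`.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpressionMatrix(cohort$dataset@gene, file.path(dir, "gene.tsv"))
  writeExpressionMatrix(cohort$dataset@mirna, file.path(dir, "mirna.tsv"))
  writeSurvivalTable(cohort$dataset@outcome, file.path(dir, "survival.tsv"))
  truth <- data.frame(sample_id = names(cohort$truth@trueRisk),
                      true_risk = as.numeric(cohort$truth@trueRisk),
                      cluster_id = cohort$truth@clusterID)
  data.table::fwrite(truth, file.path(dir, "truth.tsv"), sep = "\t")
  invisible(dir)
}
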