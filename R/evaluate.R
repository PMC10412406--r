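#' Harrell concordance index
#'
#' Over all comparable pairs — pairs (i, j) with \eqn{O_i < O_j} where the
#' earlier patient experienced the event (\eqn{\Delta_i = 1}); pairs whose
#' earlier time is censored, or with tied times, are not compared — the
#' C-index is the fraction in which the shorter-lived patient has the higher
#' predicted risk, counting tied risks as 1/2.
#'
#' @param risk numeric risk scores (higher = shorter predicted survival).
#' @param time observed times.
#' @param event 0/1 event indicators.
#' @return the concordance in [0, 1].
#' @export
concordanceIndex <- function(risk, time, event) {
  cmp <- outer(time, time, "<") & (as.integer(event) == 1L)
  n <- sum(cmp)
  if (n == 0) stop("no comparable pairs")
  conc <- outer(risk, risk, ">") + 0.5 * outer(risk, risk, "==")
  sum(conc[cmp]) / n
}

#' Cumulative dynamic AUC
#'
#' Ranking quality at event-time level: for every distinct uncensored event
#' time t, cases are patients with an observed event strictly before t and
#' controls are patients still at risk strictly after t; each case/control
#' pair contributes 1 when the case has the higher risk (1/2 on ties). The
#' returned value is the total over all event times divided by the total
#' number of comparable (case, control, t) triples.
#'
#' @inheritParams concordanceIndex
#' @return the cumulative AUC in [0, 1].
#' @export
cumulativeAUC <- function(risk, time, event) {
  event <- as.integer(event)
  tot <- 0
  num <- 0
  for (t in sort(unique(time[event == 1L]))) {
    cases <- which(time < t & event == 1L)
    controls <- which(time > t)
    if (!length(cases) || !length(controls)) next
    num <- num + length(cases) * length(controls)
    tot <- tot + sum(outer(risk[cases], risk[controls], ">")) +
      0.5 * sum(outer(risk[cases], risk[controls], "=="))
  }
  if (num == 0) stop("no comparable (case, control, time) triples")
  tot / num
}

#' Median-risk stratification
#'
#' Splits patients at the median risk: strictly above the median is
#' `"high"`, at or below is `"low"` (boundary samples deterministically go
#' low).
#'
#' @param risk numeric risk scores, at least 2, not all equal.
#' @return factor with levels `low`, `high`.
#' @export
stratifyByMedian <- function(risk) {
  if (length(risk) < 2) stop("need at least two samples")
  if (length(unique(risk)) == 1L)
    stop("constant risk scores cannot be stratified")
  g <- factor(ifelse(risk > stats::median(risk), "high", "low"),
              levels = c("low", "high"))
  if (any(table(g) == 0))
    stop("median split produced an empty group (heavy risk ties)")
  g
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of the survival curves of two groups:
#' observed versus expected events in each group under the hypergeometric
#' null at every distinct event time, chi-square statistic with 1 degree of
#' freedom (computed via [survival::survdiff()]).
#'
#' @param groups two-level factor (or vector coercible to one).
#' @param time observed times.
#' @param event 0/1 event indicators.
#' @return list with `chisq` and `p` (upper-tail of the 1-df chi-square).
#' @export
logrankTest <- function(groups, time, event) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) != 2L)
    stop("need exactly two nonempty groups, got ", nlevels(groups))
  if (!any(as.integer(event) == 1L)) stop("at least one event is required")
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Kaplan-Meier curves
#'
#' Product-limit survival estimate, overall or per group, via
#' [survival::survfit()].
#'
#' @param time observed times.
#' @param event 0/1 event indicators.
#' @param groups optional grouping factor.
#' @return data.frame with columns `group`, `time`, `surv`, `nRisk`,
#'   `nEvent` (group is `"all"` when no grouping is given).
#' @export
kmCurve <- function(time, event, groups = NULL) {
  if (is.null(groups)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    data.frame(group = "all", time = fit$time, surv = fit$surv,
               nRisk = fit$n.risk, nEvent = fit$n.event)
  } else {
    groups <- if (is.factor(groups)) groups else factor(groups)
    if (any(table(groups) == 0)) stop("empty group")
    fit <- survival::survfit(survival::Surv(time, event) ~ groups)
    gl <- rep(sub("^groups=", "", names(fit$strata)), fit$strata)
    data.frame(group = gl, time = fit$time, surv = fit$surv,
               nRisk = fit$n.risk, nEvent = fit$n.event)
  }
}

#' Repeated-holdout split scheme
#'
#' @param trainFrac fraction of samples in each training split.
#' @param nRepeats number of random splits.
#' @param seeds integer seed per repeat (defaults to `1:nRepeats`).
#' @return a list of class `SplitScheme`.
#' @export
splitScheme <- function(trainFrac = 0.8, nRepeats = 20L, seeds = NULL) {
  stopifnot(trainFrac > 0, trainFrac < 1, nRepeats >= 1)
  if (is.null(seeds)) seeds <- seq_len(nRepeats)
  if (length(seeds) != nRepeats)
    stop("length(seeds) must equal nRepeats")
  structure(list(trainFrac = trainFrac, nRepeats = as.integer(nRepeats),
                 seeds = as.integer(seeds)), class = "SplitScheme")
}

# One random split with >=1 event on both sides; resamples (with a warning)
# up to 50 times if a side has no event.
.drawSplit <- function(n, event, trainFrac, seed) {
  withr::local_seed(seed)
  nTrain <- round(trainFrac * n)
  for (attempt in 1:50) {
    perm <- sample.int(n)
    tr <- sort(perm[seq_len(nTrain)])
    te <- sort(perm[-seq_len(nTrain)])
    if (any(event[tr] == 1L) && any(event[te] == 1L))
      return(list(train = tr, test = te))
    warning("split seed ", seed, " produced an event-free side; resampling")
  }
  stop("could not draw a split with events on both sides")
}

#' Repeated random-holdout evaluation
#'
#' The evaluation protocol: repeatedly partition the cohort at random into
#' training and test sets (80/20 by default), train the requested variant on
#' the training part, score the held-out part, and report per-repeat test-set
#' C-index and cumulative AUC. Reproducible from the scheme's seed list. In
#' transductive graph mode the fused graph over all samples is built once and
#' shared across repeats.
#'
#' @param dataset a [MultiOmicsSurvival-class].
#' @param variant model variant, see [buildModel()].
#' @param scheme a [splitScheme()].
#' @param config a [trainConfig()].
#' @return an [EvaluationReport-class].
#' @export
repeatedHoldout <- function(dataset, variant = "FULL",
                            scheme = splitScheme(), config = trainConfig()) {
  n <- nSamples(dataset)
  event <- survEvent(dataset)
  time <- survTime(dataset)
  flags <- .variantFlags(variant, config$singleOmics)
  aHat <- NULL
  if (config$graphMode == "transductive")
    aHat <- .buildAHat(dataset, flags, config, seq_len(n))
  rows <- lapply(scheme$seeds, function(s) {
    sp <- .drawSplit(n, event, scheme$trainFrac, s)
    fit <- trainModel(dataset, variant, sp$train, sp$test, config,
                      aHat = aHat)
    rk <- riskScores(fit, "test")
    data.frame(seed = s,
               cindex = concordanceIndex(rk, time[sp$test], event[sp$test]),
               auc = cumulativeAUC(rk, time[sp$test], event[sp$test]))
  })
  new("EvaluationReport", metrics = do.call(rbind, rows), variant = variant,
      trainFrac = scheme$trainFrac)
}

#' Select the graph neighbourhood size by cross-validation
#'
#' Inner 5-fold cross-validation on the training data only (folds stratified
#' by event status): for each candidate k the variant is trained on four
#' folds and scored (C-index) on the fifth; the k with the highest mean
#' validation C-index wins, ties going to the smallest k.
#'
#' @param dataset a [MultiOmicsSurvival-class].
#' @param candidateKs integer candidates (default 2..15).
#' @param config a [trainConfig()]; its `k` is overridden per candidate.
#' @param variant model variant.
#' @param trainIdx samples available for the inner CV (default: all).
#' @param nFolds number of folds.
#' @return the selected k (integer).
#' @export
selectKCV <- function(dataset, candidateKs = 2:15, config = trainConfig(),
                      variant = "FULL", trainIdx = NULL, nFolds = 5L) {
  if (!length(candidateKs)) stop("no candidate k values")
  if (is.null(trainIdx)) trainIdx <- seq_len(nSamples(dataset))
  event <- survEvent(dataset)
  time <- survTime(dataset)
  withr::local_seed(config$seed)
  foldOf <- integer(length(trainIdx))
  for (cls in unique(event[trainIdx])) {
    pos <- which(event[trainIdx] == cls)
    foldOf[pos] <- sample(rep_len(seq_len(nFolds), length(pos)))
  }
  score <- vapply(candidateKs, function(k) {
    cfg <- config
    cfg$k <- as.integer(k)
    cv <- vapply(seq_len(nFolds), function(f) {
      tr <- trainIdx[foldOf != f]
      va <- trainIdx[foldOf == f]
      if (!any(event[tr] == 1L) || !any(event[va] == 1L)) return(NA_real_)
      fit <- trainModel(dataset, variant, tr, va, cfg)
      concordanceIndex(riskScores(fit, "test"), time[va], event[va])
    }, numeric(1))
    mean(cv, na.rm = TRUE)
  }, numeric(1))
  as.integer(candidateKs[order(-score, candidateKs)[1]])
}

#' Sweep the graph neighbourhood size
#'
#' Runs [repeatedHoldout()] for each candidate k and tabulates the mean and
#' standard deviation of the test C-index, for robustness plots. A failure at
#' one k is recorded as `NA` and does not abort the sweep.
#'
#' @param dataset a [MultiOmicsSurvival-class].
#' @param ks integer vector of neighbourhood sizes.
#' @param scheme a [splitScheme()].
#' @param config a [trainConfig()]; `k` overridden per entry.
#' @param variant model variant.
#' @return data.frame with columns `k`, `cindex_mean`, `cindex_sd`.
#' @export
kSensitivitySweep <- function(dataset, ks, scheme = splitScheme(),
                              config = trainConfig(), variant = "FULL") {
  if (!length(ks)) stop("no k values supplied")
  rows <- lapply(ks, function(k) {
    cfg <- config
    cfg$k <- as.integer(k)
    res <- tryCatch({
      rep <- repeatedHoldout(dataset, variant, scheme, cfg)
      c(mean(rep@metrics$cindex), stats::sd(rep@metrics$cindex))
    }, error = function(e) {
      warning("k = ", k, " failed: ", conditionMessage(e))
      c(NA_real_, NA_real_)
    })
    data.frame(k = k, cindex_mean = res[1], cindex_sd = res[2])
  })
  do.call(rbind, rows)
}
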