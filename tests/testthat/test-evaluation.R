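test_that("concordance follows the comparable-pair rule", {
  expect_equal(concordanceIndex(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  # pairs with a censored earlier member are skipped
  expect_equal(concordanceIndex(c(3, 1, 2), c(1, 2, 3), c(1, 0, 1)), 1)
  for (seed in 1:10) {
    co <- rand_cohort(50, seed + 200)
    if (!any(co$event == 1)) next
    expect_equal(concordanceIndex(co$risk, co$time, co$event),
                 oracle_cindex(co$risk, co$time, co$event))
  }
  expect_error(concordanceIndex(1, 5, 0), "comparable")
})

test_that("concordance agrees with the survival package on tie-free data", {
  set.seed(6)
  n <- 60
  risk <- rnorm(n)
  time <- rexp(n)
  event <- rbinom(n, 1, 0.6)
  ours <- concordanceIndex(risk, time, event)
  # survival treats larger x as longer survival, hence the complement
  theirs <- survival::concordance(survival::Surv(time, event) ~ risk)$concordance
  expect_equal(ours, 1 - theirs, tolerance = 1e-12)
})

test_that("concordance flips under negation and survives monotone maps", {
  set.seed(7)
  risk <- rnorm(40)
  time <- rexp(40)
  event <- rbinom(40, 1, 0.7)
  c1 <- concordanceIndex(risk, time, event)
  expect_equal(concordanceIndex(-risk, time, event), 1 - c1)
  expect_equal(concordanceIndex(exp(2 * risk) + 5, time, event), c1)
  expect_equal(cumulativeAUC(exp(2 * risk) + 5, time, event),
               cumulativeAUC(risk, time, event))
})

test_that("cumulative AUC matches the literal triple sum", {
  # risk anti-monotone in time, no censoring: perfect ranking
  expect_equal(cumulativeAUC(5:1, 1:5, rep(1, 5)), 1)
  # constant risk scores rank at chance under the tie rule
  expect_equal(cumulativeAUC(rep(2, 6), 1:6, rep(1, 6)), 0.5)
  for (seed in 1:8) {
    co <- rand_cohort(20, seed + 300)
    ok <- tryCatch({
      ours <- cumulativeAUC(co$risk, co$time, co$event)
      expect_equal(ours, oracle_cumulative_auc(co$risk, co$time, co$event))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) expect_error(cumulativeAUC(co$risk, co$time, co$event))
  }
})

test_that("median stratification puts boundary samples in the low group", {
  g <- stratifyByMedian(c(1, 2, 3, 4))
  expect_identical(as.character(g), c("low", "low", "high", "high"))
  g3 <- stratifyByMedian(c(1, 2, 3))
  expect_identical(as.character(g3), c("low", "low", "high"))
  expect_error(stratifyByMedian(rep(1, 5)), "constant")
  set.seed(8)
  r <- rnorm(101)
  tab <- table(stratifyByMedian(r))
  expect_lte(abs(diff(tab)), 1 + sum(r == stats::median(r)))
})

test_that("log-rank test matches a hand-computed fixture and the null", {
  # identical outcome vectors in both groups: no separation at all
  time <- c(2, 4, 6, 2, 4, 6)
  event <- c(1, 1, 0, 1, 1, 0)
  grp <- rep(c("a", "b"), each = 3)
  res <- logrankTest(grp, time, event)
  expect_lt(res$chisq, 1e-10)
  expect_gt(res$p, 0.999)

  # 6-sample worked example: O-E and hypergeometric variance by hand
  time2 <- c(1, 2, 3, 4, 5, 6)
  event2 <- c(1, 1, 1, 1, 0, 1)
  grp2 <- factor(c("a", "b", "a", "b", "a", "b"))
  oe <- 0; v <- 0
  for (tk in time2[event2 == 1]) {
    atRisk <- time2 >= tk
    n1 <- sum(atRisk & grp2 == "a")
    nAll <- sum(atRisk)
    d <- sum(time2 == tk & event2 == 1)
    oe <- oe + sum(time2 == tk & event2 == 1 & grp2 == "a") - d * n1 / nAll
    if (nAll > 1)
      v <- v + d * (n1 / nAll) * (1 - n1 / nAll) * (nAll - d) / (nAll - 1)
  }
  expect_equal(logrankTest(grp2, time2, event2)$chisq, oe^2 / v,
               tolerance = 1e-10)

  # strongly separated exponential groups are detected decisively
  set.seed(9)
  n <- 100
  tA <- rexp(n, 1); tB <- rexp(n, 3)
  res2 <- logrankTest(rep(c("a", "b"), each = n), c(tA, tB), rep(1, 2 * n))
  expect_lt(res2$p, 0.001)
  expect_error(logrankTest(rep("a", 6), time2, event2), "two")
})

test_that("Kaplan-Meier curves reproduce the product-limit table", {
  km <- kmCurve(1:4, rep(1, 4))
  expect_equal(km$surv, c(3, 2, 1, 0) / 4)
  flat <- kmCurve(1:5, rep(0, 5))
  expect_true(all(flat$surv == 1))
  # 8-sample mixed fixture, hand-computed:
  # t=1 (d=1,n=8) S=7/8; t=2 censored; t=3 (d=2,n=6) S=7/8*4/6; t=5 (d=1,n=4)
  # S=7/8*4/6*3/4; t=6 censored x2; t=9 (d=1,n=1) S=0
  time <- c(1, 2, 3, 3, 5, 6, 6, 9)
  event <- c(1, 0, 1, 1, 1, 0, 0, 1)
  km8 <- kmCurve(time, event)
  sAt <- function(t) km8$surv[km8$time == t][1]
  expect_equal(sAt(1), 7 / 8)
  expect_equal(sAt(3), 7 / 8 * 4 / 6)
  expect_equal(sAt(5), 7 / 8 * 4 / 6 * 3 / 4)
  expect_equal(sAt(9), 0)
  # grouped curves carry the group label
  kmg <- kmCurve(time, event, rep(c("hi", "lo"), 4))
  expect_setequal(unique(kmg$group), c("hi", "lo"))
  expect_error(kmCurve(time, event, factor(rep("a", 8), levels = c("a", "b"))),
               "empty")
})

test_that("repeated holdout produces disjoint deterministic splits", {
  co <- small_sim(31, n = 100)
  ds <- co$dataset
  cfg <- trainConfig(maxEpochs = 40, l = 5, m = 2, d = 2, h1 = 4, h2 = 3,
                     k = 5, seed = 4)
  sch <- splitScheme(0.8, 3, seeds = c(11, 12, 13))
  rep1 <- repeatedHoldout(ds, "LOW_FF", sch, cfg)
  expect_s4_class(rep1, "EvaluationReport")
  expect_identical(nrow(rep1@metrics), 3L)
  expect_true(all(rep1@metrics$cindex >= 0 & rep1@metrics$cindex <= 1))
  # identical seed list, identical report
  rep2 <- repeatedHoldout(ds, "LOW_FF", sch, cfg)
  expect_identical(rep1@metrics, rep2@metrics)
  # the split itself: 20 test samples, disjoint, union is everything
  sp <- FuseSurv:::.drawSplit(100, survEvent(ds), 0.8, 11)
  expect_length(sp$test, 20)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:100)
  s <- summary(rep1)
  expect_identical(s$repeats, 3L)
})

test_that("neighbourhood-size selection returns single candidates and breaks ties low", {
  co <- small_sim(32, n = 60)
  ds <- co$dataset
  cfg <- trainConfig(maxEpochs = 25, l = 4, m = 2, d = 2, h1 = 3, h2 = 2,
                     seed = 5)
  expect_identical(selectKCV(ds, 7, cfg, variant = "FULL"), 7L)
  # LOW_FF ignores the graph entirely, so all candidates tie -> smallest wins
  expect_identical(selectKCV(ds, c(9, 3, 6), cfg, variant = "LOW_FF"), 3L)
})

test_that("the k sweep is consistent with repeated holdout", {
  co <- small_sim(33, n = 60)
  ds <- co$dataset
  cfg <- trainConfig(maxEpochs = 30, l = 4, m = 2, d = 2, h1 = 3, h2 = 2,
                     k = 99, seed = 6)
  sch <- splitScheme(0.8, 2, seeds = c(5, 6))
  sw <- kSensitivitySweep(ds, ks = 5, sch, cfg)
  cfg5 <- cfg; cfg5$k <- 5L
  rh <- repeatedHoldout(ds, "FULL", sch, cfg5)
  expect_equal(sw$cindex_mean, mean(rh@metrics$cindex))
  expect_equal(sw$cindex_sd, sd(rh@metrics$cindex))
  sw2 <- kSensitivitySweep(ds, ks = c(3, 8), sch, cfg)
  expect_true(all(is.finite(sw2$cindex_mean)))
  expect_true(all(sw2$cindex_mean >= 0 & sw2$cindex_mean <= 1))
})
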