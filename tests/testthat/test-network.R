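test_that("partial-likelihood loss matches the term-by-term definition", {
  # singleton with an event: log over a one-element risk set cancels the risk
  expect_equal(coxPartialLoss(3.7, 1, 1), 0)
  # two events at zero risk: risk sets of sizes 2 and 1
  expect_equal(coxPartialLoss(c(0, 0), c(1, 2), c(1, 1)), log(2))
  # mixed censoring against the independent sum
  expect_equal(coxPartialLoss(c(0.5, -0.2, 0.1), c(1, 2, 3), c(1, 0, 1)),
               oracle_cox_loss(c(0.5, -0.2, 0.1), c(1, 2, 3), c(1, 0, 1)))
  for (seed in 1:20) {
    co <- rand_cohort(sample(3:40, 1), seed)
    if (!any(co$event == 1)) next
    expect_equal(coxPartialLoss(co$risk, co$time, co$event),
                 oracle_cox_loss(co$risk, co$time, co$event),
                 tolerance = 1e-10)
  }
  expect_error(coxPartialLoss(c(0, 0), c(1, 2), c(0, 0)), "event")
  expect_error(coxPartialLoss(c(NA, 0), c(1, 2), c(1, 1)), "finite")
})

test_that("the loss is invariant to constant risk shifts", {
  co <- rand_cohort(30, 77)
  base <- coxPartialLoss(co$risk, co$time, co$event)
  for (c0 in c(-5, 1e-3, 2, 100)) {
    expect_equal(coxPartialLoss(co$risk + c0, co$time, co$event), base,
                 tolerance = 1e-8)
  }
})

test_that("the analytic risk gradient matches central finite differences", {
  for (seed in 1:5) {
    co <- rand_cohort(25, seed + 50)
    if (!any(co$event == 1)) next
    g <- coxPartialGradient(co$risk, co$time, co$event)
    fd <- vapply(seq_along(co$risk), function(i) {
      e <- numeric(length(co$risk)); e[i] <- 1e-5
      (coxPartialLoss(co$risk + e, co$time, co$event) -
       coxPartialLoss(co$risk - e, co$time, co$event)) / 2e-5
    }, numeric(1))
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-4)), 1e-4)
  }
})

test_that("graph convolution follows Zh = sigmoid(tanh(A Z W1) W2)", {
  set.seed(1)
  n <- 6; pw <- 5; h1 <- 4; h2 <- 3
  z <- matrix(rnorm(n * pw), n)
  params <- list(W1 = matrix(rnorm(pw * h1), pw), W2 = matrix(rnorm(h1 * h2), h1))
  a <- matrix(runif(n * n), n); a <- (a + t(a)) / 2
  # loop-based oracle
  oracle <- matrix(0, n, h2)
  az <- matrix(0, n, pw)
  for (i in 1:n) for (j in 1:pw) az[i, j] <- sum(a[i, ] * z[, j])
  t1 <- tanh(az %*% params$W1)
  for (i in 1:n) for (j in 1:h2)
    oracle[i, j] <- 1 / (1 + exp(-sum(t1[i, ] * params$W2[, j])))
  expect_equal(gcnForward(a, z, params), oracle, tolerance = 1e-6)

  # identity convolution reduces to a dense two-layer network
  expect_equal(gcnForward(NULL, z, params), gcnForward(diag(n), z, params))
  # zero first layer saturates the sigmoid at one half
  expect_equal(gcnForward(a, z, list(W1 = params$W1 * 0, W2 = params$W2)),
               matrix(0.5, n, h2))
  expect_error(gcnForward(a, z, list(W1 = matrix(0, pw + 1, h1),
                                     W2 = params$W2)), "width")
})

test_that("risk scores are plain inner products", {
  set.seed(2)
  zh <- matrix(rnorm(12), 4, 3)
  expect_equal(riskScore(zh, c(0, 0, 0)), rep(0, 4))
  beta <- rnorm(3)
  expect_equal(riskScore(zh, beta),
               vapply(1:4, function(i) sum(zh[i, ] * beta), numeric(1)))
  expect_error(riskScore(zh, c(1, 2)), "width")
})

test_that("Breslow baseline reduces to Nelson-Aalen at zero risk", {
  n <- 6
  bh <- breslowBaseline(rep(0, n), 1:n, rep(1L, n))
  expect_equal(bh@cumhaz, cumsum(1 / (n:1)))
  # against survfit's Nelson-Aalen estimator
  sf <- survival::survfit(survival::Surv(c(2, 4, 4, 7, 9), c(1, 1, 0, 1, 0)) ~ 1,
                          ctype = 1)
  bh2 <- breslowBaseline(rep(0, 5), c(2, 4, 4, 7, 9), c(1L, 1L, 0L, 1L, 0L))
  expect_equal(bh2@cumhaz, sf$cumhaz[sf$n.event > 0], tolerance = 1e-12)
  # random risks against the term-by-term oracle
  co <- rand_cohort(6, 12)
  co$event[1] <- 1L
  bh3 <- breslowBaseline(co$risk, co$time, co$event)
  or <- oracle_breslow(co$risk, co$time, co$event)
  expect_equal(bh3@time, or$time)
  expect_equal(bh3@cumhaz, or$cumhaz, tolerance = 1e-12)
  expect_true(all(diff(bh3@cumhaz) >= 0))
})

test_that("model variants wire the stated configurations", {
  set.seed(3)
  full <- buildModel("FULL", 20, 8, l = 6, d = 2, m = 3, h1 = 5, h2 = 4)
  expect_identical(full$dims$featWidth, 9L)       # l + m
  nofbm <- buildModel("NO_FBM", 20, 8, l = 6, d = 2, m = 3, h1 = 5, h2 = 4)
  expect_identical(nofbm$dims$featWidth, 6L)      # low-level features only
  expect_null(nofbm$params$fbm)
  lowff <- buildModel("LOW_FF", 20, 8, l = 6, d = 2, m = 3)
  expect_identical(length(lowff$params$beta), 6L) # Cox head on zLow
  expect_null(lowff$params$gcn)
  fbmff <- buildModel("FBM_FF", 20, 8, l = 6, d = 2, m = 3)
  expect_identical(length(fbmff$params$beta), 3L) # Cox head on zCross
  highff <- buildModel("HIGH_FF", 20, 8, l = 6, d = 2, m = 3)
  expect_identical(length(highff$params$beta), 9L)
  single <- buildModel("GCN_SINGLE", 20, 8, l = 6, d = 2, m = 3)
  expect_null(single$params$enc2)
  expect_error(buildModel("WAT", 20, 8), "variant|arg")

  # the no-graph ablation is definitionally the full model at A-hat = I
  set.seed(9)
  x1 <- matrix(rnorm(5 * 20), 5); x2 <- matrix(rnorm(5 * 8), 5)
  set.seed(11)
  mFull <- buildModel("FULL", 20, 8, l = 6, d = 2, m = 3, h1 = 5, h2 = 4)
  set.seed(11)
  mNoG <- buildModel("NO_GRAPH", 20, 8, l = 6, d = 2, m = 3, h1 = 5, h2 = 4)
  rFull <- FuseSurv:::.modelForward(mFull, x1, x2, diag(5))$risk
  rNoG <- FuseSurv:::.modelForward(mNoG, x1, x2, NULL)$risk
  expect_equal(rFull, rNoG, tolerance = 1e-12)
})

test_that("training is deterministic, inert at zero learning rate, and descends", {
  co <- small_sim(21, n = 60)
  ds <- co$dataset
  tr <- 1:48; te <- 49:60
  cfg0 <- trainConfig(learningRate = 0, maxEpochs = 5, k = 5,
                      l = 6, m = 3, d = 2, h1 = 5, h2 = 4, seed = 2)
  fit0 <- trainModel(ds, "FULL", tr, te, cfg0)
  expect_equal(diff(range(lossHistory(fit0)$loss)), 0)

  cfg <- trainConfig(maxEpochs = 120, k = 5, l = 6, m = 3, d = 2,
                     h1 = 5, h2 = 4, seed = 2)
  fitA <- trainModel(ds, "FULL", tr, te, cfg)
  fitB <- trainModel(ds, "FULL", tr, te, cfg)
  expect_identical(riskScores(fitA), riskScores(fitB))
  expect_identical(lossHistory(fitA)$loss, lossHistory(fitB)$loss)

  # near-monotone descent at a small learning rate
  h <- lossHistory(fitA)$loss
  expect_lt(mean(diff(h) > 0), 0.01)
  expect_lt(h[length(h)], h[1])
})

test_that("training errors on degenerate inputs", {
  co <- small_sim(22, n = 40)
  ds <- co$dataset
  expect_error(trainModel(ds, "FULL", integer(0)), "nonempty")
  expect_error(trainModel(ds, "FULL", 1:10, 5:20), "overlap")
  noEv <- which(survEvent(ds) == 0)[1:5]
  expect_error(trainModel(ds, "FULL", noEv), "events")
})

test_that("the strict train-graph mode embeds test samples only after fitting", {
  co <- small_sim(23, n = 50)
  ds <- co$dataset
  cfg <- trainConfig(maxEpochs = 60, k = 4, l = 5, m = 2, d = 2,
                     h1 = 4, h2 = 3, seed = 3, graphMode = "train_graph")
  fit <- trainModel(ds, "FULL", 1:40, 41:50, cfg)
  expect_length(riskScores(fit), 50)
  expect_length(riskScores(fit, "test"), 10)
  expect_true(all(is.finite(riskScores(fit))))
})
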