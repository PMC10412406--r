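mk <- function(m, label = "gene") {
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  OmicsMatrix(m, label)
}

test_that("missingness filter keeps exactly the features at or under threshold", {
  set.seed(1)
  m <- matrix(rnorm(50), 10, 5)
  # missing counts per feature: 0, 1, 1, 2, 3 of 10 samples
  m[1, 2] <- NA
  m[2, 3] <- NA
  m[c(1, 5), 4] <- NA
  m[c(2, 6, 9), 5] <- NA
  x <- mk(m)
  kept <- filterMissingFeatures(x, 0.10)
  expect_identical(featureIDs(kept), c("f1", "f2", "f3"))

  # a 20%-missing feature is dropped at the 10% threshold
  expect_false("f4" %in% featureIDs(kept))
  # no missing values: identity
  clean <- mk(matrix(rnorm(20), 5, 4))
  expect_equal(omicsValues(filterMissingFeatures(clean, 0.10)),
               omicsValues(clean))
  expect_error(filterMissingFeatures(mk(matrix(NA_real_, 4, 2)), 0.1), "all")
})

test_that("weighted k-nn imputation follows the inverse-distance formula", {
  # neighbours at distances 1 and 3 carrying values 10 and 2:
  # (10/1 + 2/3) / (1 + 1/3) = 8
  m <- matrix(c(0, 1, 3,
                NA, 10, 2), 3, 2,
              dimnames = list(paste0("S", 1:3), c("a", "b")))
  out <- imputeWeightedKNN(mk(m), k = 2)
  expect_equal(omicsValues(out)["S1", "b"], 8.0)

  # constant neighbourhood imputes the constant
  m2 <- matrix(c(0, 1, 2, 3,
                 NA, 7, 7, 7), 4, 2,
               dimnames = list(paste0("S", 1:4), c("a", "b")))
  expect_equal(omicsValues(imputeWeightedKNN(mk(m2), k = 3))["S1", "b"], 7.0)

  # complete matrix is returned unchanged
  clean <- mk(matrix(rnorm(20), 5, 4))
  expect_equal(omicsValues(imputeWeightedKNN(clean, 3)), omicsValues(clean))

  allNA <- mk(cbind(a = c(1, 2, 3), b = NA_real_))
  expect_error(imputeWeightedKNN(allNA, 2), "all samples")
})

test_that("log transform matches elementwise log1p and validates domain", {
  set.seed(2)
  m <- mk(matrix(rexp(12), 4, 3))
  expect_equal(omicsValues(logTransform(m, 1)), log1p(omicsValues(m)))
  expect_equal(omicsValues(logTransform(mk(matrix(0, 2, 2)), 1)),
               matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(omicsValues(logTransform(mk(matrix(exp(1) - 1, 2, 2)), 1)),
               matrix(1, 2, 2), ignore_attr = TRUE)
  expect_error(logTransform(mk(matrix(-2, 2, 2)), 1), "pseudocount")
  # base-2 option
  expect_equal(omicsValues(logTransform(mk(matrix(3, 1, 1)), 1, base = 2)),
               matrix(2, 1, 1), ignore_attr = TRUE)
})

test_that("variance filter keeps the top-k features in original order", {
  m <- mk(cbind(flat = rep(1, 6), mid = c(1, 2, 1, 2, 1, 2) * 2,
                wide = c(-4, 4, -4, 4, -4, 4)))
  kept <- selectTopVarianceFeatures(m, 2)
  expect_identical(featureIDs(kept), c("mid", "wide"))
  expect_identical(featureIDs(selectTopVarianceFeatures(m, 3)),
                   c("flat", "mid", "wide"))
  expect_error(selectTopVarianceFeatures(m, 4), "exceeds")
})

test_that("standardization achieves zero mean, unit population variance", {
  set.seed(3)
  x <- mk(matrix(rnorm(100, 5, 3), 20, 5))
  z <- omicsValues(standardizeFeatures(x))
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(colMeans(z^2) - 1)), 1e-10)
  # idempotence
  z2 <- omicsValues(standardizeFeatures(standardizeFeatures(x)))
  expect_equal(z2, z, tolerance = 1e-12)
  expect_error(standardizeFeatures(mk(cbind(a = rep(2, 4)))), "constant")
})

test_that("quantile discretization bins evenly and re-centres", {
  x <- mk(cbind(a = c(-1, -0.5, 0.5, 1)))
  d <- omicsValues(discretizeFeatures(x, 2))[, 1]
  expect_equal(d, c(-0.5, -0.5, 0.5, 0.5), ignore_attr = TRUE)
  set.seed(4)
  z <- mk(cbind(a = rnorm(100)))
  d4 <- omicsValues(discretizeFeatures(z, 4))[, 1]
  expect_equal(as.vector(table(d4)), rep(25, 4))
  expect_equal(mean(d4), 0)
  expect_error(discretizeFeatures(z, 1), "nBins")
})

test_that("full pipeline aligns samples and reduces to log-select-standardize on complete data", {
  set.seed(5)
  n <- 12
  gene <- matrix(rexp(n * 8), n, 8,
                 dimnames = list(paste0("S", 1:n), paste0("g", 1:8)))
  mirna <- matrix(rexp(n * 5), n, 5,
                  dimnames = list(paste0("S", 1:n), paste0("m", 1:5)))
  # 3 gene features exceed 10% missingness (2 of 12 missing)
  geneNA <- gene
  geneNA[1:2, c(2, 5, 7)] <- NA
  outcome <- SurvivalOutcome(rexp(n), rbinom(n, 1, 0.7), paste0("S", 1:n))
  cfg <- preprocessConfig(topKGene = 4, topKMirna = 3)
  ds <- preprocessOmics(geneNA, mirna, outcome, cfg)
  expect_identical(dim(geneExpr(ds)), c(12L, 4L))
  expect_identical(dim(mirnaExpr(ds)), c(12L, 3L))
  expect_false(any(c("g2", "g5", "g7") %in% colnames(geneExpr(ds))))

  # complete matrix: filter+impute are identities, so the pipeline equals
  # log -> select -> standardize applied directly
  ds2 <- preprocessOmics(gene, mirna, outcome, cfg)
  direct <- standardizeFeatures(selectTopVarianceFeatures(
    logTransform(OmicsMatrix(gene, "gene"), 1), 4))
  expect_equal(geneExpr(ds2), omicsValues(direct))

  # sample intersection ordered by the survival table
  sub <- outcome@sampleIDs[c(4, 2, 9, 11, 1, 6, 8, 3)]
  out2 <- SurvivalOutcome(outcome@time[match(sub, outcome@sampleIDs)],
                          outcome@event[match(sub, outcome@sampleIDs)], sub)
  ds3 <- preprocessOmics(gene, mirna, out2, cfg)
  expect_identical(sampleIDs(ds3), sub)
  expect_identical(rownames(geneExpr(ds3)), sub)
  outNone <- SurvivalOutcome(c(1, 2), c(1L, 0L), c("Q1", "Q2"))
  expect_error(preprocessOmics(gene, mirna, outNone, cfg), "shared")
})
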