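# LDA staging, evaluation schemes, trajectories, permutation tests.

gaussFeatures <- function(centers, n, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
      matrix(rnorm(n * 4, rep(centers[k, ], each = n), sd), n, 4)))
    colnames(x) <- c("lambda1Apical", "lambda1Basal", "cab", "shallowRatio")
    list(x = as.data.frame(x),
         labels = rep(rownames(centers), each = n))
  })
}

wellSeparated <- function(n = 15, seed = 1) {
  centers <- rbind(cleavage = c(0, 0, 0, 0), syncytial = c(10, 10, 10, 10),
                   cc14 = c(-10, 10, -10, 10))
  gaussFeatures(centers, n, sd = 1, seed = seed)
}

test_that("LDA separates well-separated classes and their means", {
  d <- wellSeparated()
  clf <- fitStageClassifier(d$x, d$labels)
  pred <- predictStage(clf, data.frame(lambda1Apical = c(0, 10),
                                       lambda1Basal = c(0, 10),
                                       cab = c(0, 10),
                                       shallowRatio = c(0, 10)))
  expect_equal(pred$label, c("cleavage", "syncytial"))
  expect_equal(clf@labels, c("cleavage", "syncytial", "cc14"))
  expect_equal(sum(clf@priors), 1)
})

test_that("predictions are invariant under invertible affine feature maps", {
  d <- wellSeparated(n = 20, seed = 3)
  A <- matrix(c(2, 0.3, 0, 0.1,
                0.5, 1.5, 0.2, 0,
                0, 0.4, 3, 0.6,
                0.1, 0, 0.2, 1.2), 4, 4)
  b <- c(5, -3, 2, 7)
  xt <- as.data.frame(sweep(as.matrix(d$x) %*% A, 2, -b))
  colnames(xt) <- colnames(d$x)
  p1 <- predictStage(fitStageClassifier(d$x, d$labels), d$x)$label
  p2 <- predictStage(fitStageClassifier(xt, d$labels), xt)$label
  expect_identical(p1, p2)
})

test_that("well-separated Gaussian clusters give near-perfect LOO accuracy", {
  accs <- vapply(1:12, function(s) {
    centers <- rbind(cleavage = c(0, 0, 0, 0), syncytial = c(4, 0, 0, 0),
                     cc14 = c(0, 4, 0, 0))     # 4 sd apart
    d <- gaussFeatures(centers, n = 25, sd = 1, seed = 100 + s)
    evaluateClassifier(d$x, d$labels, "loo")@accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.95)
  expect_true(all(accs > 0.85))
})

test_that("perfectly separable data yields per-class fractions of 1", {
  d <- wellSeparated(n = 10, seed = 5)
  cm <- evaluateClassifier(d$x, d$labels, "loo")
  expect_equal(unname(cm@perClass), c(1, 1, 1))
  expect_equal(cm@n, 30L)
  expect_equal(rowSums(cm@counts), c(cleavage = 10, syncytial = 10,
                                     cc14 = 10))
})

test_that("permuted labels drop accuracy to chance", {
  d <- wellSeparated(n = 20, seed = 7)
  perm <- withr::with_seed(8, sample(d$labels))
  cm <- evaluateClassifier(d$x, perm, "loo")
  # binomial error around 1/3 for n = 60
  expect_lt(abs(cm@accuracy - 1 / 3), 4 * sqrt((1 / 3) * (2 / 3) / 60))
})

test_that("missing shallow ratios are excluded, not imputed", {
  d <- wellSeparated(n = 10, seed = 9)
  d$x$shallowRatio[c(1, 15)] <- NA
  expect_message(clf <- fitStageClassifier(d$x, d$labels), "excluded")
  expect_equal(clf@nExcluded, 2L)
  expect_error(predictStage(clf, transform(d$x[1, ], cab = NA)), "missing")
})

test_that("exact posterior ties go to the earlier label in fixed order", {
  base <- data.frame(lambda1Apical = c(-1, -2, 1, 2, -1, -2, 1, 2),
                     lambda1Basal = c(1, -1, 1, -1, 2, -2, 2, -2),
                     cab = c(1, -1, 1, -1, 2, -2, 2, -2) * 0.5,
                     shallowRatio = c(-1, 1, -1, 1, -2, 2, -2, 2))
  x <- rbind(base, base + 0.25, base - 0.25)  # zero-mean classes, n = 12
  labels <- rep(rep(c("cleavage", "syncytial"), each = 4), 3)
  clf <- suppressWarnings(fitStageClassifier(x, labels))
  # the origin is equidistant from both class means by construction
  p <- predictStage(clf, c(lambda1Apical = 0, lambda1Basal = 0, cab = 0,
                           shallowRatio = 0))
  expect_equal(unname(p$scores[1, 1]), unname(p$scores[1, 2]),
               tolerance = 1e-9)
  expect_identical(p$label, "cleavage")
})

test_that("resubstitution is optimistic relative to LOO on average", {
  diffs <- vapply(1:50, function(s) {
    centers <- rbind(cleavage = c(0, 0, 0, 0), syncytial = c(1.5, 0, 0, 0),
                     cc14 = c(0, 1.5, 0, 0))   # overlapping clusters
    d <- gaussFeatures(centers, n = 8, sd = 1, seed = 300 + s)
    rs <- evaluateClassifier(d$x, d$labels, "resubstitution")@accuracy
    lo <- evaluateClassifier(d$x, d$labels, "loo")@accuracy
    rs - lo
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("the subgroup trajectory is ordered and reflects its inputs", {
  feats <- do.call(rbind, lapply(seq_along(subgroupLevels()), function(i)
    data.frame(lambda1Apical = 0.8 + i / 100, lambda1Basal = 0.85,
               cab = 0.5 - i / 10, shallowRatio = 1,
               subgroup = subgroupLevels()[i])))
  tr <- subgroupTrajectory(feats)
  expect_equal(tr$subgroup, subgroupLevels())
  expect_equal(tr$lambda1Apical, 0.8 + seq_len(9) / 100)

  # single record per sub-group: the trajectory is those records
  expect_equal(tr$n, rep(1L, 9))
  expect_message(subgroupTrajectory(feats[-3, ]), "omitted")
  expect_error(subgroupTrajectory(transform(feats, subgroup = "cc99")),
               "unknown")
})

test_that("cohort trajectories increase lambda1 apical through cc13", {
  rec <- generateCohort(subgroupLevels()[1:6], nPerPreset = 10, seed = 31,
                        noise = noiseSpec(additiveSd = 2))
  truthFeats <- do.call(rbind, lapply(rec, function(r) {
    data.frame(lambda1Apical = exp(r@truth$apical@alpha[1]),
               lambda1Basal = exp(r@truth$basal@alpha[1]),
               cab = log(r@truth$apical@C0[1] / r@truth$basal@C0[1]),
               shallowRatio = 1, subgroup = r@subgroup)
  }))
  tr <- subgroupTrajectory(truthFeats)
  expect_equal(tr$subgroup, subgroupLevels()[1:6])
  expect_true(all(diff(tr$lambda1Apical) > 0))
})

test_that("permutation tests detect separation and respect the null", {
  d0 <- data.frame(lambda1Apical = rep(c(1, 2, 3), 4),
                   lambda1Basal = rep(c(1, 2, 3), 4),
                   cab = rep(c(1, 2, 3), 4),
                   shallowRatio = rep(c(1, 2, 3), 4))
  same <- testGroupDifference(d0, rep(c("a", "b"), each = 6), nPerm = 200,
                              seed = 2)
  expect_gte(same$omnibus, 0.5)       # identical groups

  centers <- rbind(a = c(0, 0, 0, 0), b = c(5, 5, 5, 5))
  d1 <- gaussFeatures(centers, n = 30, sd = 1, seed = 11)
  far <- testGroupDifference(d1$x, d1$labels, nPerm = 10000, seed = 3)
  expect_lte(far$omnibus, 0.001)
  expect_true(all(far$perFeature <= 0.001))

  again <- testGroupDifference(d1$x, d1$labels, nPerm = 10000, seed = 3)
  expect_identical(far$perFeature, again$perFeature)
  expect_warning(testGroupDifference(d1$x, d1$labels, nPerm = 50, seed = 1),
                 "100")
})

test_that("the permutation test holds its type-I error on null cohorts", {
  alpha <- 0.05
  rejections <- vapply(1:120, function(s) {
    d <- gaussFeatures(rbind(a = rep(0, 4), b = rep(0, 4)), n = 10, sd = 1,
                       seed = 600 + s)
    testGroupDifference(d$x, d$labels, nPerm = 199, seed = s)$omnibus <= alpha
  }, logical(1))
  rate <- mean(rejections)
  expect_lte(rate, alpha + 2.5 * sqrt(alpha * (1 - alpha) / 120))
})
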