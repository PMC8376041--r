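# Multi-exponential model evaluation, fitting, ordering and features.

mkFit <- function(C0, alpha, kind = "2exp", B = 0, window = c(10, 90),
                  roles = NULL) {
  if (is.null(roles)) roles <- rep("unordered", length(C0))
  new("MultiExpFit", kind = kind, C0 = C0, alpha = alpha,
      lambda = exp(alpha), background = B, roles = roles,
      window = window, sse = 0, nPoints = 10L, converged = TRUE)
}

test_that("model evaluation matches the closed form", {
  f <- mkFit(c(100, 10), c(-0.2, -0.01))
  expect_equal(evalModel(f, 0), 110)
  fB <- mkFit(0, -0.1, kind = "1expB", B = 7)
  expect_equal(evalModel(fB, c(0, 33, 90)), rep(7, 3))
  # window midpoint against a direct re-evaluation
  x <- 50
  expect_equal(evalModel(f, x), 100 * exp(-0.2 * x) + 10 * exp(-0.01 * x),
               tolerance = 1e-14)
})

test_that("noiseless profiles are recovered within tight tolerances", {
  prof1 <- generateProfile(multiExpParams(100, -0.1), 0:100)
  f1 <- fitProfile(prof1, "1expB")
  expect_lt(abs(f1@C0[1] - 100) / 100, 1e-6)
  expect_lt(abs(f1@alpha[1] + 0.1), 1e-8)
  expect_lt(abs(f1@background), 1e-6)

  prof2 <- generateProfile(multiExpParams(c(200, 20), c(-0.2, -0.01)), 0:100)
  f2 <- fitProfile(prof2, "2exp", window = c(10, 90))
  expect_equal(f2@C0, c(200, 20), tolerance = 1e-4)
  expect_equal(f2@alpha, c(-0.2, -0.01), tolerance = 1e-4)
  expect_true(f2@converged)

  # brute-force grid oracle cannot beat the returned optimum
  sel <- prof2@positions >= 10 & prof2@positions <= 90
  g <- gridSearch2exp(prof2@positions[sel], prof2@intensities[sel])
  expect_lte(f2@sse, g$sse + 1e-9)
})

test_that("a posterior rise needs and gets the third component", {
  pars <- multiExpParams(c(150, 15, 0.4), c(-0.15, -0.01, 0.045))
  prof <- generateProfile(pars, 0:100, noiseSpec(additiveSd = 0.8, seed = 5))
  f3 <- fitProfile(prof, "3exp", window = c(10, 90))
  f2 <- fitProfile(prof, "2exp", window = c(10, 90))
  rising <- f3@roles == "rising"
  expect_true(any(rising))
  expect_gt(f3@alpha[rising][1], 0)
  expect_lt(f3@sse, f2@sse)
  expect_identical(as.character(selectModel(prof, c(10, 90))), "3exp")

  # pure two-component data keeps the simpler model
  prof2 <- generateProfile(multiExpParams(c(150, 15), c(-0.15, -0.01)),
                           0:100, noiseSpec(additiveSd = 0.8, seed = 6))
  expect_identical(as.character(selectModel(prof2, c(10, 90))), "2exp")

  flat <- AxisProfile(0:100, rep(0, 101))
  expect_error(selectModel(flat, c(10, 90)), "all-zero")
})

test_that("fitting rejects unusable inputs", {
  short <- AxisProfile(seq(20, 40, by = 5), c(9, 7, 6, 5, 4))
  expect_error(fitProfile(short, "2exp"), "too few")
  gap <- AxisProfile(0:100, c(rep(NA, 95), 6:1))
  expect_error(fitProfile(gap, "2exp"), "too few")
})

test_that("components are ordered anterior, shallow, rising", {
  # given as (shallow, anterior): must be swapped
  f <- orderComponents(mkFit(c(10, 200), c(-0.01, -0.2)))
  expect_equal(f@C0, c(200, 10))
  expect_equal(f@roles, c("anterior", "shallow"))

  # equal window-start contributions: steeper alpha ranks anterior
  lo <- 10
  C2 <- 5; C1 <- C2 * exp((-0.01 - (-0.2)) * lo)
  f2 <- orderComponents(mkFit(c(C2, C1), c(-0.01, -0.2)))
  expect_equal(f2@alpha[1], -0.2)

  # a rising component is always third, whatever its size
  f3 <- orderComponents(mkFit(c(5, 1000, 80), c(-0.1, 0.05, -0.02),
                              kind = "3exp"))
  expect_equal(f3@roles, c("anterior", "shallow", "rising"))
  expect_equal(f3@alpha[3], 0.05)
})

test_that("lambda equals exp(alpha) exactly in every stored fit", {
  prof <- generateProfile(multiExpParams(c(120, 18), c(-0.12, -0.015)),
                          0:100, noiseSpec(additiveSd = 2, seed = 9))
  for (kind in c("1expB", "2exp", "3exp")) {
    f <- fitProfile(prof, kind, window = c(10, 90))
    expect_identical(f@lambda, exp(f@alpha))
  }
})

test_that("SSE nesting holds across the model hierarchy", {
  pars <- list(multiExpParams(c(200, 20), c(-0.2, -0.01)),
               multiExpParams(c(90, 25), c(-0.09, -0.02)),
               multiExpParams(c(150, 15, 0.4), c(-0.15, -0.01, 0.04)))
  for (i in seq_along(pars)) for (sd in c(0, 3)) {
    prof <- generateProfile(pars[[i]], 0:100,
                            noiseSpec(additiveSd = sd, seed = 50 + i))
    f1 <- fitProfile(prof, "1expB", c(10, 90))
    f2 <- fitProfile(prof, "2exp", c(10, 90))
    f3 <- fitProfile(prof, "3exp", c(10, 90))
    expect_lte(f2@sse, f1@sse * (1 + 1e-9))
    expect_lte(f3@sse, f2@sse * (1 + 1e-9) + 1e-12)
  }
})

test_that("features take their defining values and flag missing parts", {
  fa <- orderComponents(mkFit(c(2, 0.5), c(-0.1, -0.01)))
  fb <- orderComponents(mkFit(c(1, 0.25), c(-0.1, -0.01)))
  feat <- computeFeatures(fa, fb)
  expect_equal(unname(feat["cab"]), log(2), tolerance = 1e-12)
  expect_equal(unname(feat["shallowRatio"]), 2, tolerance = 1e-12)

  featSame <- computeFeatures(fa, fa)
  expect_equal(unname(featSame["cab"]), 0)
  expect_equal(unname(featSame["shallowRatio"]), 1)

  f1 <- orderComponents(mkFit(5, -0.1, kind = "1expB", B = 1))
  expect_true(is.na(computeFeatures(f1, fb)["shallowRatio"]))
})

test_that("Cab and shallow ratio are invariant under common rescaling", {
  pars <- list(apical = multiExpParams(c(150, 18), c(-0.12, -0.012)),
               basal = multiExpParams(c(100, 14), c(-0.10, -0.011)))
  profs <- lapply(names(pars), function(l)
    generateProfile(pars[[l]], 0:100, noiseSpec(additiveSd = 2, seed = 77),
                    layer = l))
  names(profs) <- names(pars)
  k <- 3.7
  scaled <- lapply(profs, function(p)
    AxisProfile(positions(p), k * intensities(p), layer = p@layer))
  f <- lapply(profs, fitProfile, kind = "2exp", window = c(10, 90))
  fk <- lapply(scaled, fitProfile, kind = "2exp", window = c(10, 90))
  a <- computeFeatures(f$apical, f$basal)
  b <- computeFeatures(fk$apical, fk$basal)
  expect_lt(abs(a["cab"] - b["cab"]), 1e-8)
  expect_lt(abs(a["shallowRatio"] - b["shallowRatio"]), 1e-8)
  # every C0 scales by k, every alpha is unchanged
  expect_equal(fk$apical@C0, k * f$apical@C0, tolerance = 1e-7)
  expect_equal(fk$apical@alpha, f$apical@alpha, tolerance = 1e-8)
})

test_that("two-exponential parameter recovery meets the error bands", {
  truth <- multiExpParams(c(200, 20), c(-0.1, -0.01))
  n <- 100
  errs <- vapply(seq_len(n), function(i) {
    prof <- generateProfile(truth, 0:100,
                            noiseSpec(additiveSd = 4, seed = 1000 + i))
    f <- fitProfile(prof, "2exp", c(10, 90), restarts = 6)
    c(abs(f@lambda[1] - exp(-0.1)), abs(log(f@C0[1]) - log(200)))
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.01)
  expect_lt(median(errs[2, ]), 0.1)
})
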