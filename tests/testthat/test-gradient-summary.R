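# Prototypical profiles, background subtraction, cumulative curves.

protoFit <- function(C0, alpha, kind = "2exp") {
  orderComponents(new("MultiExpFit", kind = kind, C0 = C0, alpha = alpha,
                      lambda = exp(alpha), background = 0,
                      roles = rep("unordered", length(C0)),
                      window = c(10, 90), sse = 1, nPoints = 81L,
                      converged = TRUE))
}

test_that("prototypes average parameters and are idempotent", {
  f1 <- protoFit(c(100, 10), c(-0.1, -0.01))
  f2 <- protoFit(c(200, 10), c(-0.1, -0.01))
  pp <- prototypicalProfile(list(f1, f2), stage = "cleavage",
                            layer = "apical")
  expect_equal(pp@params@C0[1], 150)
  expect_equal(pp@params@alpha, c(-0.1, -0.01))

  solo <- prototypicalProfile(list(f1, f1))
  expect_equal(solo@curve, evalModel(f1, solo@grid), tolerance = 1e-12)

  # mixed kinds reduce to the shared two-exponential part
  f3 <- protoFit(c(100, 10, 0.5), c(-0.1, -0.01, 0.04), kind = "3exp")
  expect_message(mix <- prototypicalProfile(list(f1, f3)), "common 2-exp")
  expect_length(mix@params@C0, 2)
})

test_that("cohort prototypes recover the preset means", {
  rec <- generateCohort("syncytial", 25, seed = 17)
  feats <- cohortFeatures(rec, restarts = 6)
  fits <- lapply(attr(feats, "fits"), `[[`, "apical")
  pp <- prototypicalProfile(fits, stage = "syncytial", layer = "apical")
  truth <- stagePreset("syncytial")@apical
  # between-embryo spread is sdLogC0 = 0.15 / sdAlphaFrac = 0.08; the
  # mean over 25 embryos should land within a few standard errors
  expect_lt(abs(pp@params@alpha[1] - truth@alpha[1]) /
              abs(truth@alpha[1]), 0.1)
  expect_lt(abs(log(pp@params@C0[1] / truth@C0[1])), 0.15)
})

test_that("flat background subtraction behaves like the closed form", {
  const <- AxisProfile(0:100, rep(5, 101))
  sub <- subtractBackground(const, anchor = 95)
  expect_true(all(intensities(sub) == 0))
  expect_equal(attr(sub, "backgroundValue"), 5)

  x <- 0:100
  y <- 100 * exp(-x / 15) + 8
  prof <- AxisProfile(x, y)
  sub2 <- subtractBackground(prof, anchor = 95)
  pure <- 100 * exp(-x / 15)
  tailBound <- 100 * exp(-95 / 15)
  expect_lt(max(abs(intensities(sub2) - pure)), tailBound + 1e-9)
  expect_error(subtractBackground(prof, anchor = 150), "outside")
})

test_that("cumulative curves integrate mass correctly", {
  unif <- AxisProfile(0:100, rep(3, 101))
  cc <- cumulativeDistribution(unif)
  expect_equal(cc@ecdf, (0:100) / 100, tolerance = 1e-12)

  x <- seq(0, 100, by = 1)
  expProf <- AxisProfile(x, 50 * exp(-x / 20))
  ce <- cumulativeDistribution(expProf)
  # closed form at 20 %EL: (1 - e^-1) / (1 - e^-5)
  expect_equal(ce@ecdf[x == 20], (1 - exp(-1)) / (1 - exp(-5)),
               tolerance = 1e-3)
  expect_equal(ce@ecdf, exactExpEcdf(x, 20), tolerance = 1e-3)

  # invariant under positive rescaling
  ce2 <- cumulativeDistribution(AxisProfile(x, 17 * 50 * exp(-x / 20)))
  expect_equal(ce@ecdf, ce2@ecdf, tolerance = 1e-12)

  expect_error(cumulativeDistribution(AxisProfile(0:10, rep(0, 11))),
               "zero total mass")
})

test_that("length constants invert decay rates", {
  expect_equal(lengthConstant(-0.05)[1], 20)
  expect_equal(lengthConstant(-0.01)[1], 100)
  expect_equal(lengthConstant(-0.025)[1], 2 * lengthConstant(-0.05)[1])
  expect_warning(lc <- lengthConstant(0.1), "undefined")
  expect_true(is.na(lc[1]))
  expect_equal(attr(lengthConstant(-0.05), "fractionOfEL")[1], 0.2)
  # identity: alpha = -1/L maps back to L
  for (L in c(5, 15, 20, 25, 60))
    expect_equal(lengthConstant(-1 / L)[1], L, tolerance = 1e-12)
})

test_that("comparison to the reference gradient matches analytic curves", {
  x <- seq(0, 100, by = 1)
  curve <- cumulativeDistribution(AxisProfile(x, 30 * exp(-x / 20)))
  self <- compareToReference(curve, 20)
  expect_lt(self$maxDeviation, 1e-6)

  curve15 <- cumulativeDistribution(AxisProfile(x, 30 * exp(-x / 15)))
  cmp <- compareToReference(curve15, 20)
  analytic <- max(abs(exactExpEcdf(x, 15) - exactExpEcdf(x, 20)))
  expect_equal(cmp$maxDeviation, analytic, tolerance = 1e-6)

  # background contamination: deviation shrinks after subtraction
  contaminated <- AxisProfile(x, 40 * exp(-x / 20) + 6)
  before <- compareToReference(cumulativeDistribution(contaminated), 20)
  after <- compareToReference(
    cumulativeDistribution(subtractBackground(contaminated, 95)), 20)
  expect_lt(after$maxDeviation, before$maxDeviation)
})

test_that("cohorts built in the 0.15-0.25 EL band report it back", {
  # RNA-like regime constructed inside the band comparable to the ~20 %EL
  # protein gradient; fitted anterior length constants must land there too
  lcs <- vapply(1:15, function(i) {
    L <- withr::with_seed(900 + i, runif(1, 16, 24))
    prof <- generateProfile(multiExpParams(c(120, 15), c(-1 / L, -0.01)),
                            0:100, noiseSpec(additiveSd = 2.4,
                                             seed = 910 + i))
    f <- fitProfile(prof, "2exp", c(10, 90), restarts = 6)
    attr(lengthConstant(f), "fractionOfEL")[1]
  }, numeric(1))
  expect_gt(mean(lcs >= 0.15 & lcs <= 0.25), 0.7)
  expect_true(median(lcs) >= 0.15 && median(lcs) <= 0.25)
})
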