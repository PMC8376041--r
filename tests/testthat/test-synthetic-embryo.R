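# Synthetic profile, cohort and image generation.

test_that("noiseless profiles equal the model formula exactly", {
  p <- multiExpParams(C0 = 100, alpha = -0.05)
  prof <- generateProfile(p, positions = c(0, 20))
  expect_equal(intensities(prof), c(100, 100 * exp(-1)), tolerance = 1e-12)

  # length constant 20 %EL corresponds to lambda = exp(-1/20)
  expect_equal(exp(-1 / 20), 0.9512, tolerance = 1e-4)
  expect_equal(lengthConstant(-0.05)[1], 20)

  p3 <- multiExpParams(C0 = c(50, 10, 1), alpha = c(-0.2, -0.01, 0.03))
  x <- seq(0, 100, by = 7)
  prof3 <- generateProfile(p3, x)
  manual <- 50 * exp(-0.2 * x) + 10 * exp(-0.01 * x) + 1 * exp(0.03 * x)
  expect_equal(intensities(prof3), manual, tolerance = 1e-12)
})

test_that("generation is seed-reproducible and validates its inputs", {
  p <- multiExpParams(c(100, 10), c(-0.1, -0.01))
  ns <- noiseSpec(additiveSd = 3, multiplicativeCv = 0.1, seed = 42)
  a <- generateProfile(p, 0:50, ns)
  b <- generateProfile(p, 0:50, ns)
  expect_identical(intensities(a), intensities(b))
  c <- generateProfile(p, 0:50, noiseSpec(additiveSd = 3,
                                          multiplicativeCv = 0.1, seed = 43))
  expect_false(identical(intensities(a), intensities(c)))

  expect_error(multiExpParams(C0 = -5, alpha = -0.1), "C0")
  expect_error(multiExpParams(C0 = c(1, 1), alpha = c(0.1, -0.1)), "rising")
  expect_error(generateProfile(p, numeric(0)), "non-empty")
  expect_error(generateProfile(p, c(5, 5, 10)), "strictly increasing")
})

test_that("all-decaying noiseless profiles are strictly decreasing", {
  for (s in 1:10) {
    k <- 1 + s %% 3
    pars <- withr::with_seed(s, multiExpParams(
      C0 = runif(min(k, 2), 10, 200),
      alpha = sort(-runif(min(k, 2), 0.005, 0.3))))
    prof <- generateProfile(pars, seq(0, 100, by = 2))
    expect_true(all(diff(intensities(prof)) < 0))
  }
})

test_that("cohorts have the requested size, labels and ground truth", {
  rec <- generateCohort(c("cleavage", "syncytial", "cc14"), nPerPreset = 20,
                        seed = 7)
  expect_length(rec, 60)
  stages <- vapply(rec, function(r) r@stage, character(1))
  expect_equal(as.vector(table(factor(stages, stageLevels()))), c(20, 20, 20))
  expect_true(all(vapply(rec, function(r)
    is(r@truth$apical, "MultiExpParams"), logical(1))))
  # identical seed, identical cohort
  rec2 <- generateCohort(c("cleavage", "syncytial", "cc14"), 20, seed = 7)
  expect_identical(intensities(rec[[5]]@apical), intensities(rec2[[5]]@apical))
  expect_error(generateCohort("gastrula", 5), "unknown preset")
})

test_that("zero between-embryo variation collapses to the preset means", {
  ps <- stagePreset("cleavage", sdLogC0 = 0, sdAlphaFrac = 0)
  rec <- generateCohort(list(ps), nPerPreset = 4, seed = 1,
                        noise = noiseSpec())
  truths <- lapply(rec, function(r) r@truth$apical@C0)
  expect_true(all(vapply(truths, identical, logical(1), truths[[1]])))
  expect_equal(rec[[1]]@truth$apical@C0, ps@apical@C0, tolerance = 1e-12)
})

test_that("stage presets reproduce the developmental ordering relations", {
  cab <- function(p) log(p@apical@C0[1] / p@basal@C0[1])
  l1 <- function(p) exp(p@apical@alpha[1])
  cl <- stagePreset("cleavage"); sy <- stagePreset("syncytial")
  cc <- stagePreset("cc14")
  expect_lt(l1(cl), l1(sy))          # sharpest gradient pre-blastoderm
  expect_lt(l1(sy), l1(cc))
  expect_gt(cab(cl), 0)              # apical brighter before blastoderm
  expect_lt(cab(sy), 0)              # basal brighter in syncytial stages
  expect_gt(cab(cc), 0)              # flip back at cellularization
  # fitted cohorts inherit the lambda1 ordering
  recCl <- generateCohort("cleavage", 8, seed = 21)
  recSy <- generateCohort("syncytial", 8, seed = 22)
  fCl <- cohortFeatures(recCl, restarts = 6)
  fSy <- cohortFeatures(recSy, restarts = 6)
  expect_lt(mean(fCl$lambda1Apical), mean(fSy$lambda1Apical))
})

test_that("rendered images decompose exactly and respect geometry limits", {
  sc <- embryoScene(nucleiCount = 25L, nucleiIntensity = 30,
                    textureAmplitude = 3,
                    noise = noiseSpec(additiveSd = 2, seed = 3))
  si <- renderEmbryoImage(sc)
  expect_true(all(si@pixels - si@trend - si@texture - si@noise == 0))
  expect_true(all(si@pixels >= 0))
  si2 <- renderEmbryoImage(sc)
  expect_identical(si2@pixels, si@pixels)   # same scene + seed

  expect_error(embryoScene(dim = c(100, 150), center = c(50, 75),
                           semiAxes = c(90, 40)), "frame")
  expect_error(embryoScene(apicalDepth = 20, basalDepth = 10), "Depth|depth")
})

test_that("uniform scenes extract to constant profiles", {
  lvl <- 40
  sc <- embryoScene(apicalParams = multiExpParams(lvl, -1e-12),
                    basalParams = multiExpParams(lvl, -1e-12),
                    interiorLevel = lvl)
  si <- renderEmbryoImage(sc, seed = 1L)
  ct <- offsetContour(si@mask, 8, "dorsal")
  ch <- buildRoiChain(ct, radius = 4, spacing = 6, layer = "apical")
  prof <- extractProfile(si@pixels, ch, si@mask)
  vals <- intensities(prof)
  expect_lt(max(abs(vals - lvl), na.rm = TRUE), 1e-6)
})
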