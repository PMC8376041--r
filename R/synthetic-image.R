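## Rendering synthetic sagittal embryo images with exact ground truth.

#' Construct an EmbryoScene
#'
#' Defaults draw a mid-sized sagittal section: a 160 x 260 px frame with an
#' axis-aligned ellipse (AP semi-axis 110 px, minor 60 px), an apical band
#' down to 14 px depth carrying the apical gradient, a basal band from 14
#' to 28 px depth carrying the basal gradient, nominal ROI-chain depths of
#' 8 px (apical) and 20 px (basal), and a dim uniform core plasm.  Cortical
#' intensity is a function of AP position in \%EL (anterior pole = smallest
#' column); the dorsal (top) and ventral (bottom) halves may carry
#' different parameters.
#'
#' @param apicalParams,basalParams a [MultiExpParams-class], or a list with
#'   elements `dorsal` and `ventral` for asymmetric scenes.
#' @param dim image (rows, cols) px.
#' @param center ellipse center (row, col) px; integer centers keep the
#'   mask's AP chord exactly at center +/- the AP semi-axis.
#' @param semiAxes (AP semi-axis a, minor semi-axis b) px.
#' @param apicalDepth,basalDepth nominal ROI-chain depths (px).
#' @param nuclearDepth depth separating the apical from the basal band.
#' @param cortexDepth outer edge of the basal band.
#' @param interiorLevel core-plasm intensity (a.u.).
#' @param nucleiCount,nucleiRadius,nucleiIntensity nuclei blobs at the
#'   nuclear-layer depth.
#' @param textureAmplitude,texturePeriod sinusoidal cytoplasmic texture.
#' @param noise a [NoiseSpec-class].
#' @return An [EmbryoScene-class].
#' @export
embryoScene <- function(apicalParams = multiExpParams(c(150, 16),
                                                      c(-0.15, -0.012)),
                        basalParams = multiExpParams(c(95, 14),
                                                     c(-0.13, -0.012)),
                        dim = c(160, 260), center = c(80, 130),
                        semiAxes = c(110, 60),
                        apicalDepth = 8, basalDepth = 20,
                        nuclearDepth = 14, cortexDepth = 28,
                        interiorLevel = 5,
                        nucleiCount = 0L, nucleiRadius = 3,
                        nucleiIntensity = 0,
                        textureAmplitude = 0, texturePeriod = 12,
                        noise = noiseSpec()) {
  asSides <- function(p) {
    if (is(p, "MultiExpParams")) list(dorsal = p, ventral = p) else p
  }
  new("EmbryoScene", dim = as.integer(dim), center = as.numeric(center),
      semiAxes = as.numeric(semiAxes), apicalDepth = apicalDepth,
      basalDepth = basalDepth, nuclearDepth = nuclearDepth,
      cortexDepth = cortexDepth, apicalParams = asSides(apicalParams),
      basalParams = asSides(basalParams), interiorLevel = interiorLevel,
      nucleiCount = as.integer(nucleiCount), nucleiRadius = nucleiRadius,
      nucleiIntensity = nucleiIntensity,
      textureAmplitude = textureAmplitude, texturePeriod = texturePeriod,
      noise = noise)
}

#' Render a synthetic embryo image
#'
#' Renders the scene's cortical gradients, nuclei, texture and noise onto a
#' pixel grid.  The deterministic cortical/interior structure is the trend
#' component; nuclei and sinusoidal texture form the texture component; the
#' noise component is defined as the residual `pixels - trend - texture`,
#' so the three ground-truth components sum to the rendered image exactly.
#' Noiseless per-layer gradients (dorsal side) are stored on a 1 \%EL grid.
#'
#' @param scene an [EmbryoScene-class].
#' @param seed integer seed; defaults to the scene's noise seed.
#' @return A [SyntheticImage-class].
#' @export
renderEmbryoImage <- function(scene, seed = NULL) {
  stopifnot(is(scene, "EmbryoScene"))
  validObject(scene)
  if (is.null(seed)) seed <- scene@noise@seed
  nr <- scene@dim[1]; nc <- scene@dim[2]
  cr <- scene@center[1]; cc <- scene@center[2]
  a <- scene@semiAxes[1]; b <- scene@semiAxes[2]

  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  mask <- ((row - cr) / b)^2 + ((col - cc) / a)^2 <= 1
  depth <- .depthMap(mask)
  xpct <- pmin(pmax((col - (cc - a)) / (2 * a) * 100, 0), 100)
  dorsal <- row < cr

  trend <- matrix(0, nr, nc)
  fillBand <- function(trend, sel, paramsBySide) {
    for (s in c("dorsal", "ventral")) {
      pick <- sel & (if (s == "dorsal") dorsal else !dorsal)
      if (any(pick))
        trend[pick] <- evalModel(paramsBySide[[s]], xpct[pick])
      trend
    }
    trend
  }
  apicalSel <- mask & depth > 0 & depth <= scene@nuclearDepth
  basalSel <- mask & depth > scene@nuclearDepth & depth <= scene@cortexDepth
  interiorSel <- mask & depth > scene@cortexDepth
  trend <- fillBand(trend, apicalSel, scene@apicalParams)
  trend <- fillBand(trend, basalSel, scene@basalParams)
  trend[interiorSel] <- scene@interiorLevel

  render <- function() {
    texture <- matrix(0, nr, nc)
    if (scene@textureAmplitude > 0)
      texture[mask] <- scene@textureAmplitude *
        sin(2 * pi * row[mask] / scene@texturePeriod) *
        sin(2 * pi * col[mask] / scene@texturePeriod)
    if (scene@nucleiCount > 0) {
      theta <- stats::runif(scene@nucleiCount, 0, 2 * pi)
      d <- scene@nuclearDepth
      nucRow <- cr + (b - d) * sin(theta)
      nucCol <- cc + (a - d) * cos(theta)
      s2 <- (scene@nucleiRadius / 2)^2
      for (i in seq_len(scene@nucleiCount)) {
        d2 <- (row - nucRow[i])^2 + (col - nucCol[i])^2
        blob <- d2 <= (2 * scene@nucleiRadius)^2
        texture[blob] <- texture[blob] +
          scene@nucleiIntensity * exp(-d2[blob] / (2 * s2))
      }
      texture[!mask] <- 0
    }
    noiseless <- trend + texture
    noisy <- noiseless
    ns <- scene@noise
    if (ns@multiplicativeCv > 0)
      noisy <- noisy * exp(matrix(stats::rnorm(nr * nc, 0,
                                               ns@multiplicativeCv), nr, nc))
    if (ns@additiveSd > 0)
      noisy <- noisy + matrix(stats::rnorm(nr * nc, 0, ns@additiveSd), nr, nc)
    pixels <- pmax(noisy + ns@baselineOffset, 0)
    list(texture = texture, pixels = pixels)
  }
  parts <- if (!is.na(seed)) withr::with_seed(as.integer(seed), render())
           else render()

  grid <- seq(0, 100, by = 1)
  new("SyntheticImage", pixels = parts$pixels, mask = mask, trend = trend,
      texture = parts$texture,
      noise = parts$pixels - trend - parts$texture,
      truthApical = AxisProfile(grid,
                                evalModel(scene@apicalParams$dorsal, grid),
                                layer = "apical", embryoId = "truth"),
      truthBasal = AxisProfile(grid,
                               evalModel(scene@basalParams$dorsal, grid),
                               layer = "basal", embryoId = "truth"),
      scene = scene, seed = as.integer(seed))
}

#' Analytic disc-averaged gradient value
#'
#' The continuous average of a multi-exponential AP gradient over a
#' circular ROI of radius `radiusPct` (\%EL units) centered at `x0`:
#' the independent oracle for extraction-fidelity checks.
#'
#' @param params [MultiExpParams-class].
#' @param x0 disc center position (\%EL).
#' @param radiusPct disc radius in \%EL.
#' @return numeric disc-averaged intensities.
#' @export
discAveragedModel <- function(params, x0, radiusPct) {
  vapply(x0, function(x) {
    f <- function(u) evalModel(params, x + u) * 2 *
      sqrt(pmax(radiusPct^2 - u^2, 0)) / (pi * radiusPct^2)
    stats::integrate(f, -radiusPct, radiusPct, rel.tol = 1e-10)$value
  }, numeric(1))
}

#' Write a synthetic image with its ground truth to disk
#'
#' The rendered pixels and each ground-truth component are written as
#' 32-bit float single-channel TIFFs, with a JSON sidecar recording the
#' scene parameters and seed.
#'
#' @param simg a [SyntheticImage-class].
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return Invisibly, the sidecar path.
#' @export
writeSyntheticImage <- function(simg, dir, name = "embryo") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, what) {
    tiff::writeTIFF(m / max(max(m), 1e-12),
                    file.path(dir, sprintf("%s_%s.tif", name, what)),
                    bits.per.sample = 32L)
  }
  wr(simg@pixels, "pixels"); wr(simg@trend, "trend")
  wr(simg@texture + max(0, -min(simg@texture)), "texture")
  wr(simg@noise + max(0, -min(simg@noise)), "noise")
  wr(simg@mask * 1, "mask")
  scene <- simg@scene
  sidecar <- list(
    seed = simg@seed, dim = scene@dim, center = scene@center,
    semiAxes = scene@semiAxes,
    depths = c(apical = scene@apicalDepth, nuclear = scene@nuclearDepth,
               basal = scene@basalDepth, cortex = scene@cortexDepth),
    apical = lapply(scene@apicalParams, function(p)
      list(C0 = p@C0, alpha = p@alpha)),
    basal = lapply(scene@basalParams, function(p)
      list(C0 = p@C0, alpha = p@alpha)),
    noise = list(additiveSd = scene@noise@additiveSd,
                 multiplicativeCv = scene@noise@multiplicativeCv,
                 baselineOffset = scene@noise@baselineOffset),
    intensityScale = list(pixels = max(simg@pixels),
                          trend = max(simg@trend)))
  path <- file.path(dir, sprintf("%s_truth.json", name))
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
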