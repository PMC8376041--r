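## Seeded synthetic profiles and embryo cohorts with known ground truth.

.applyNoise <- function(signal, noise, seed = NULL) {
  stopifnot(is(noise, "NoiseSpec"))
  if (is.null(seed)) seed <- noise@seed
  realize <- function() {
    y <- signal
    if (noise@multiplicativeCv > 0)
      y <- y * exp(stats::rnorm(length(y), 0, noise@multiplicativeCv))
    if (noise@additiveSd > 0)
      y <- y + stats::rnorm(length(y), 0, noise@additiveSd)
    pmax(y + noise@baselineOffset, 0)
  }
  if (!is.na(seed)) withr::with_seed(as.integer(seed), realize()) else realize()
}

#' Generate a synthetic AP intensity profile
#'
#' Evaluates a multi-exponential gradient at the given positions and
#' perturbs it with the noise model (multiplicative lognormal x signal,
#' additive Gaussian, constant baseline; all default to zero).  Negative
#' noisy values are clipped at zero.  The noiseless ground truth is
#' attached as attribute `"groundTruth"` and the generating parameters as
#' `"trueParams"`.
#'
#' @param params a [MultiExpParams-class].
#' @param positions strictly increasing positions in [0, 100] \%EL.
#' @param noise a [NoiseSpec-class]; its seed (if not NA) makes the
#'   realization reproducible.
#' @param layer,channel,embryoId profile metadata.
#' @return An [AxisProfile-class] with ground-truth attributes.
#' @examples
#' p <- multiExpParams(C0 = 100, alpha = -0.05)
#' prof <- generateProfile(p, positions = c(0, 20))
#' intensities(prof)   # 100, 100 * exp(-1)
#' @export
generateProfile <- function(params, positions, noise = noiseSpec(),
                            layer = "apical", channel = "bcd",
                            embryoId = "synthetic") {
  stopifnot(is(params, "MultiExpParams"))
  validObject(params)
  positions <- as.numeric(positions)
  if (length(positions) == 0L)
    stop("positions must be non-empty")
  if (any(diff(positions) <= 0) || min(positions) < 0 || max(positions) > 100)
    stop("positions must be strictly increasing within [0, 100] %EL")
  truth <- evalModel(params, positions)
  noisy <- .applyNoise(truth, noise)
  out <- AxisProfile(positions, noisy, layer = layer, channel = channel,
                     embryoId = embryoId)
  attr(out, "groundTruth") <- AxisProfile(positions, truth, layer = layer,
                                          channel = channel,
                                          embryoId = embryoId)
  attr(out, "trueParams") <- params
  out
}

## Stage presets ---------------------------------------------------------------

# Preset means (a.u., per %EL).  Configuration of the generator, chosen to
# reproduce the qualitative stage ordering: cleavage lambda1 apical smallest
# with apical > basal (Cab > 0); syncytial blastoderm shallower with basal >
# apical (Cab < 0); cc14 apical >> basal again with lambda1 high and nearly
# fixed.  The nine sub-groups interpolate these regimes smoothly; lambda1
# apical increases monotonically from CleavageEarly through cc13.
.presetTable <- function() {
  tab <- rbind(
    # name            a1ap    C1ap  a1ba    C1ba  a2ap    C2ap a2ba    C2ba
    CleavageEarly = c(-0.240, 170, -0.200,  95, -0.012, 16, -0.012, 14),
    CleavageLate  = c(-0.160, 140, -0.140, 100, -0.012, 16, -0.012, 14),
    cc10          = c(-0.115,  85, -0.105, 105, -0.011, 15, -0.011, 14),
    cc11          = c(-0.100,  75, -0.095, 110, -0.011, 15, -0.011, 14),
    cc12          = c(-0.090,  68, -0.088, 115, -0.010, 15, -0.010, 14),
    cc13          = c(-0.080,  62, -0.082, 118, -0.010, 15, -0.010, 14),
    cc14early1    = c(-0.075, 150, -0.080, 100, -0.010, 18, -0.010, 14),
    cc14early2    = c(-0.072, 215, -0.078,  80, -0.010, 20, -0.010, 14),
    cc14late      = c(-0.070, 240, -0.076,  75, -0.010, 20, -0.010, 14),
    cleavage      = c(-0.200, 155, -0.170,  97, -0.012, 16, -0.012, 14),
    syncytial     = c(-0.095,  72, -0.092, 112, -0.011, 15, -0.011, 14),
    cc14          = c(-0.072, 200, -0.078,  85, -0.010, 19, -0.010, 14))
  colnames(tab) <- c("a1ap", "C1ap", "a1ba", "C1ba",
                     "a2ap", "C2ap", "a2ba", "C2ba")
  tab
}

#' Built-in developmental stage presets
#'
#' Returns the parameter regime for one of the three main stages
#' ("cleavage", "syncytial", "cc14") or the nine age sub-groups
#' (see [subgroupLevels()]).  Each preset holds mean apical and basal
#' two-exponential parameters plus between-embryo variability.
#'
#' @param name preset name.
#' @param sdLogC0 between-embryo sd of log C0 (default 0.15).
#' @param sdAlphaFrac between-embryo sd of alpha as a fraction of its
#'   magnitude (default 0.08).
#' @return A [StagePreset-class].
#' @export
stagePreset <- function(name, sdLogC0 = 0.15, sdAlphaFrac = 0.08) {
  tab <- .presetTable()
  if (!name %in% rownames(tab))
    stop("unknown preset name '", name, "'; known presets: ",
         paste(rownames(tab), collapse = ", "))
  p <- tab[name, ]
  stage <- if (name %in% stageLevels()) name else subgroupToStage(name)
  new("StagePreset", name = name, stage = stage,
      apical = multiExpParams(C0 = c(p["C1ap"], p["C2ap"]),
                              alpha = c(p["a1ap"], p["a2ap"])),
      basal = multiExpParams(C0 = c(p["C1ba"], p["C2ba"]),
                             alpha = c(p["a1ba"], p["a2ba"])),
      sdLogC0 = sdLogC0, sdAlphaFrac = sdAlphaFrac)
}

.drawParams <- function(mean, sdLogC0, sdAlphaFrac) {
  k <- length(mean@C0)
  C0 <- mean@C0 * exp(stats::rnorm(k, 0, sdLogC0))
  alpha <- mean@alpha * (1 + stats::rnorm(k, 0, sdAlphaFrac))
  # keep decaying components decaying (draws are mild; guard the tail)
  alpha <- ifelse(mean@alpha < 0, pmin(alpha, -1e-4), alpha)
  multiExpParams(C0 = C0, alpha = alpha, background = mean@background)
}

#' Generate a synthetic embryo cohort
#'
#' Draws `nPerPreset` embryos from each preset: per-embryo parameters are
#' sampled around the preset means (lognormal on C0, Gaussian relative on
#' alpha), paired apical and basal profiles are generated with the shared
#' noise model, and ground-truth parameters are stored on each record.
#'
#' @param presets list of [StagePreset-class] objects or preset names.
#' @param nPerPreset embryos per preset (>= 1).
#' @param seed integer seed for the whole cohort.
#' @param positions sampling grid in \%EL (default every 1 \%EL).
#' @param noise a [NoiseSpec-class] applied to every profile (its own seed
#'   slot is ignored; the cohort seed governs).
#' @param channel staining channel label for metadata.
#' @return list of [EmbryoRecord-class].
#' @export
generateCohort <- function(presets, nPerPreset, seed = 1L,
                           positions = seq(0, 100, by = 1),
                           noise = noiseSpec(additiveSd = 2),
                           channel = "bcd") {
  if (is.character(presets)) presets <- lapply(presets, stagePreset)
  stopifnot(all(vapply(presets, is, TRUE, "StagePreset")),
            nPerPreset >= 1)
  noise@seed <- NA_integer_   # realizations come from the cohort stream
  withr::with_seed(as.integer(seed), {
    records <- list()
    idx <- 0L
    for (preset in presets) {
      for (i in seq_len(nPerPreset)) {
        idx <- idx + 1L
        id <- sprintf("%s_%03d", preset@name, i)
        pa <- .drawParams(preset@apical, preset@sdLogC0, preset@sdAlphaFrac)
        pb <- .drawParams(preset@basal, preset@sdLogC0, preset@sdAlphaFrac)
        ap <- generateProfile(pa, positions, noise, layer = "apical",
                              channel = channel, embryoId = id)
        ba <- generateProfile(pb, positions, noise, layer = "basal",
                              channel = channel, embryoId = id)
        records[[idx]] <- new("EmbryoRecord", apical = ap, basal = ba,
                              channel = channel, stage = preset@stage,
                              subgroup = if (preset@name %in% subgroupLevels())
                                preset@name else "",
                              embryoId = id,
                              truth = list(apical = pa, basal = pb))
      }
    }
    records
  })
}
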