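#' @import methods
NULL

## Canonical developmental stage vocabulary ----------------------------------

#' Developmental stage labels
#'
#' Canonical label sets for the three main early-embryo stages
#' (pre-blastoderm cleavage, syncytial blastoderm, cellularization) and the
#' nine finer age sub-groups, in developmental order.
#'
#' @return Character vector of labels.
#' @export
stageLevels <- function() c("cleavage", "syncytial", "cc14")

#' @rdname stageLevels
#' @export
subgroupLevels <- function() {
  c("CleavageEarly", "CleavageLate", "cc10", "cc11", "cc12", "cc13",
    "cc14early1", "cc14early2", "cc14late")
}

#' @rdname stageLevels
#' @param subgroup character vector of sub-group labels.
#' @export
subgroupToStage <- function(subgroup) {
  map <- c(CleavageEarly = "cleavage", CleavageLate = "cleavage",
           cc10 = "syncytial", cc11 = "syncytial", cc12 = "syncytial",
           cc13 = "syncytial",
           cc14early1 = "cc14", cc14early2 = "cc14", cc14late = "cc14")
  out <- unname(map[subgroup])
  if (anyNA(out)) stop("unknown sub-group label(s): ",
                       paste(setdiff(subgroup, names(map)), collapse = ", "))
  out
}

## AxisProfile ----------------------------------------------------------------

#' AxisProfile: a 1D intensity profile along the embryo axis
#'
#' Ordered (position, intensity) samples for one embryo, cortical layer and
#' staining channel.  Positions are percent egg length (\%EL, 0 = anterior
#' pole) for standard apical/basal profiles, or arc-length fraction in [0,1]
#' for profiles taken along arbitrary contours.  Missing samples (e.g. an ROI
#' falling entirely outside the embryo mask) are `NA` intensities and are
#' skipped, never imputed, by downstream fitting.
#'
#' @slot positions numeric, strictly increasing.
#' @slot intensities numeric, same length; `NA` marks a missing sample.
#' @slot layer one of "apical", "basal", "custom".
#' @slot channel staining channel, e.g. "bcd" or "stau".
#' @slot embryoId identifier.
#' @slot unit "pctEL" or "arcFraction".
#' @export
setClass("AxisProfile",
         representation(positions = "numeric", intensities = "numeric",
                        layer = "character", channel = "character",
                        embryoId = "character", unit = "character"))

setValidity("AxisProfile", function(object) {
  msg <- NULL
  if (length(object@positions) != length(object@intensities))
    msg <- c(msg, "positions and intensities must have equal length")
  if (length(object@positions) == 0L)
    msg <- c(msg, "profile must contain at least one sample")
  if (anyNA(object@positions))
    msg <- c(msg, "positions must not contain NA")
  if (length(object@positions) > 1L && any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (!object@unit %in% c("pctEL", "arcFraction"))
    msg <- c(msg, "unit must be 'pctEL' or 'arcFraction'")
  if (object@unit == "pctEL" &&
      (min(object@positions) < 0 || max(object@positions) > 100))
    msg <- c(msg, "pctEL positions must lie in [0, 100]")
  if (object@unit == "arcFraction" &&
      (min(object@positions) < 0 || max(object@positions) > 1))
    msg <- c(msg, "arcFraction positions must lie in [0, 1]")
  if (!object@layer %in% c("apical", "basal", "custom"))
    msg <- c(msg, "layer must be 'apical', 'basal' or 'custom'")
  if (is.null(msg)) TRUE else msg
})

#' Construct an AxisProfile
#'
#' @param positions numeric vector of positions (strictly increasing).
#' @param intensities numeric vector of intensities (NA = missing sample).
#' @param layer "apical", "basal" or "custom".
#' @param channel staining channel label.
#' @param embryoId embryo identifier.
#' @param unit "pctEL" (default) or "arcFraction".
#' @return An [AxisProfile-class] object.
#' @export
AxisProfile <- function(positions, intensities, layer = "apical",
                        channel = "bcd", embryoId = "embryo",
                        unit = "pctEL") {
  new("AxisProfile", positions = as.numeric(positions),
      intensities = as.numeric(intensities), layer = layer,
      channel = channel, embryoId = embryoId, unit = unit)
}

## Multi-exponential parameter set --------------------------------------------

#' MultiExpParams: parameters of a multi-exponential gradient model
#'
#' The model is \eqn{I(x) = \sum_i C_{0i} \exp(\alpha_i x) (+ B)} with x in
#' \%EL.  One to three components; decaying components have \eqn{\alpha < 0};
#' a posteriorly rising component (\eqn{\alpha > 0}) is permitted only as the
#' third component.  The exponential base is \eqn{\lambda = \exp(\alpha)} per
#' \%EL.
#'
#' @slot C0 positive pre-exponential factors (a.u., at x = 0).
#' @slot alpha decay rates per \%EL.
#' @slot background non-negative flat background B (used by the
#'   one-exponential-plus-background model).
#' @export
setClass("MultiExpParams",
         representation(C0 = "numeric", alpha = "numeric",
                        background = "numeric"))

setValidity("MultiExpParams", function(object) {
  msg <- NULL
  k <- length(object@C0)
  if (k < 1L || k > 3L) msg <- c(msg, "1 to 3 components required")
  if (length(object@alpha) != k)
    msg <- c(msg, "C0 and alpha must have equal length")
  if (any(!is.finite(object@C0)) || any(object@C0 <= 0))
    msg <- c(msg, "all C0 must be finite and > 0")
  if (any(!is.finite(object@alpha)))
    msg <- c(msg, "all alpha must be finite")
  rising <- which(object@alpha > 0)
  if (length(rising) > 1L || (length(rising) == 1L && rising != 3L))
    msg <- c(msg, "a rising component (alpha > 0) is only permitted third")
  if (length(object@background) != 1L || !is.finite(object@background) ||
      object@background < 0)
    msg <- c(msg, "background must be a single non-negative number")
  if (is.null(msg)) TRUE else msg
})

#' Construct a MultiExpParams
#'
#' @param C0 numeric vector (length 1-3) of positive amplitudes.
#' @param alpha numeric vector of decay rates per \%EL.
#' @param background optional flat background (default 0).
#' @return A [MultiExpParams-class] object.
#' @export
multiExpParams <- function(C0, alpha, background = 0) {
  new("MultiExpParams", C0 = as.numeric(C0), alpha = as.numeric(alpha),
      background = as.numeric(background))
}

## Noise specification ---------------------------------------------------------

#' NoiseSpec: noise model for the synthetic generator
#'
#' A generated signal s is perturbed to
#' `s * exp(rnorm(sdlog = multiplicativeCv)) + rnorm(sd = additiveSd)
#'  + baselineOffset`, then clipped at zero.  The default is additive-only.
#' Identical seed implies an identical realization.
#'
#' @slot additiveSd additive Gaussian sd (a.u.).
#' @slot multiplicativeCv sdlog of the multiplicative lognormal term.
#' @slot baselineOffset constant offset (a.u.).
#' @slot seed integer seed (NA = use the current RNG state).
#' @export
setClass("NoiseSpec",
         representation(additiveSd = "numeric", multiplicativeCv = "numeric",
                        baselineOffset = "numeric", seed = "integer"))

setValidity("NoiseSpec", function(object) {
  v <- c(object@additiveSd, object@multiplicativeCv, object@baselineOffset)
  if (length(v) != 3L || any(!is.finite(v)) || any(v < 0))
    return("additiveSd, multiplicativeCv and baselineOffset must be single non-negative numbers")
  TRUE
})

#' Construct a NoiseSpec
#'
#' @param additiveSd additive Gaussian sd in a.u. (default 0).
#' @param multiplicativeCv lognormal sdlog of the multiplicative term.
#' @param baselineOffset constant baseline in a.u.
#' @param seed integer seed, or NA to use the ambient RNG state.
#' @return A [NoiseSpec-class] object.
#' @export
noiseSpec <- function(additiveSd = 0, multiplicativeCv = 0,
                      baselineOffset = 0, seed = NA_integer_) {
  new("NoiseSpec", additiveSd = as.numeric(additiveSd),
      multiplicativeCv = as.numeric(multiplicativeCv),
      baselineOffset = as.numeric(baselineOffset),
      seed = as.integer(seed))
}

## Stage presets ---------------------------------------------------------------

#' StagePreset: parameter regime of one developmental stage
#'
#' Mean apical and basal two-exponential parameters plus between-embryo
#' variability for one of the three main stages or nine age sub-groups.  The
#' shipped presets reproduce the qualitative stage ordering: cleavage has the
#' smallest apical anterior base \eqn{\lambda_1} and apical brighter than
#' basal (Cab > 0); the syncytial blastoderm has larger \eqn{\lambda_1} with
#' basal brighter (Cab < 0); cellularization (cc14) flips back to Cab > 0
#' with \eqn{\lambda_1} high.
#'
#' @slot name preset name (main stage or sub-group).
#' @slot stage the main stage the preset belongs to.
#' @slot apical,basal mean [MultiExpParams-class] per layer.
#' @slot sdLogC0 between-embryo sd of log C0.
#' @slot sdAlphaFrac between-embryo sd of alpha, as a fraction of |alpha|.
#' @export
setClass("StagePreset",
         representation(name = "character", stage = "character",
                        apical = "MultiExpParams", basal = "MultiExpParams",
                        sdLogC0 = "numeric", sdAlphaFrac = "numeric"))

setValidity("StagePreset", function(object) {
  msg <- NULL
  if (!object@stage %in% stageLevels())
    msg <- c(msg, "stage must be one of the main stage labels")
  if (object@sdLogC0 < 0 || object@sdAlphaFrac < 0)
    msg <- c(msg, "variability sds must be non-negative")
  if (is.null(msg)) TRUE else msg
})

## Embryo records --------------------------------------------------------------

#' EmbryoRecord: paired apical and basal profiles for one embryo
#'
#' @slot apical,basal [AxisProfile-class] for the two cortical layers.
#' @slot channel staining channel.
#' @slot stage main stage label (may be "" when unknown).
#' @slot subgroup nine-level age sub-group label (may be "").
#' @slot embryoId identifier.
#' @slot truth list of ground-truth generator parameters (empty for real
#'   data): elements `apical`, `basal` ([MultiExpParams-class]).
#' @export
setClass("EmbryoRecord",
         representation(apical = "AxisProfile", basal = "AxisProfile",
                        channel = "character", stage = "character",
                        subgroup = "character", embryoId = "character",
                        truth = "list"))

## Multi-exponential fits ------------------------------------------------------

#' MultiExpFit: a fitted multi-exponential model
#'
#' Components are stored in canonical order after [orderComponents()]:
#' "anterior" (largest contribution at the window start among decaying
#' components), "shallow" (remaining decaying), and "rising" (alpha > 0,
#' always third).  `lambda` is `exp(alpha)` exactly.
#'
#' @slot kind "1expB", "2exp" or "3exp".
#' @slot C0,alpha,lambda per-component parameters.
#' @slot background flat background B (0 unless kind is "1expB").
#' @slot roles per-component canonical role.
#' @slot window fit window (lo, hi) in \%EL.
#' @slot sse residual sum of squares at the optimum.
#' @slot nPoints number of non-missing samples used.
#' @slot converged optimizer convergence flag.
#' @export
setClass("MultiExpFit",
         representation(kind = "character", C0 = "numeric", alpha = "numeric",
                        lambda = "numeric", background = "numeric",
                        roles = "character", window = "numeric",
                        sse = "numeric", nPoints = "integer",
                        converged = "logical"))

setValidity("MultiExpFit", function(object) {
  msg <- NULL
  if (!object@kind %in% c("1expB", "2exp", "3exp"))
    msg <- c(msg, "kind must be '1expB', '2exp' or '3exp'")
  k <- length(object@C0)
  if (length(object@alpha) != k || length(object@lambda) != k ||
      length(object@roles) != k)
    msg <- c(msg, "C0, alpha, lambda, roles must have equal length")
  if (any(object@lambda != exp(object@alpha)))
    msg <- c(msg, "lambda must equal exp(alpha) exactly")
  if (length(object@window) != 2L || object@window[1] >= object@window[2])
    msg <- c(msg, "window must be (lo, hi) with lo < hi")
  if (object@sse < 0) msg <- c(msg, "SSE must be non-negative")
  if (is.null(msg)) TRUE else msg
})

## Staging ---------------------------------------------------------------------

#' StageClassifier: linear discriminant stage classifier
#'
#' Wraps a standard LDA fit on the four staging features.  If the pooled
#' within-class covariance is singular the fit falls back to a ridge-
#' regularized Gaussian discriminant (method "rlda"), which is logged.
#'
#' @slot fit the underlying `MASS::lda` object, or NULL for "rlda".
#' @slot method "lda" or "rlda".
#' @slot labels class labels in fixed prediction/tie-break order.
#' @slot featureNames the feature columns used.
#' @slot priors class priors (sum to 1).
#' @slot means per-class feature means (classes x features).
#' @slot pooledCov pooled within-class covariance.
#' @slot nExcluded number of rows dropped for missing features.
#' @export
setClass("StageClassifier",
         representation(fit = "ANY", method = "character",
                        labels = "character", featureNames = "character",
                        priors = "numeric", means = "matrix",
                        pooledCov = "matrix", nExcluded = "integer"))

setValidity("StageClassifier", function(object) {
  msg <- NULL
  if (abs(sum(object@priors) - 1) > 1e-8)
    msg <- c(msg, "priors must sum to 1")
  pc <- object@pooledCov
  if (nrow(pc) && any(abs(pc - t(pc)) > 1e-8 * max(1, max(abs(pc)))))
    msg <- c(msg, "pooled covariance must be symmetric")
  if (is.null(msg)) TRUE else msg
})

#' ConfusionMatrix: staging evaluation result
#'
#' @slot counts integer matrix, rows = true class, cols = predicted.
#' @slot perClass per-class correct fraction.
#' @slot accuracy overall correct fraction.
#' @slot n number of evaluated embryos.
#' @slot scheme "loo", "kfold" or "resubstitution".
#' @slot permutationP permutation p-value for accuracy above chance
#'   (NA unless requested).
#' @export
setClass("ConfusionMatrix",
         representation(counts = "matrix", perClass = "numeric",
                        accuracy = "numeric", n = "integer",
                        scheme = "character", permutationP = "numeric"))

setValidity("ConfusionMatrix", function(object) {
  msg <- NULL
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  pc <- object@perClass[!is.na(object@perClass)]
  if (any(pc < 0 | pc > 1))
    msg <- c(msg, "per-class fractions must lie in [0, 1]")
  if (sum(object@counts) != object@n)
    msg <- c(msg, "counts must sum to n")
  if (is.null(msg)) TRUE else msg
})

## Synthetic scenes ------------------------------------------------------------

#' EmbryoScene: geometry and signal model of a synthetic sagittal section
#'
#' The embryo is an axis-aligned ellipse; the anterior pole is at the left
#' (smallest column).  Cortical intensity is organised in two bands by depth
#' from the surface: the apical band (depth up to `nuclearDepth`) and the
#' basal band (from `nuclearDepth` to `cortexDepth`), each carrying a
#' multi-exponential gradient in AP position; the dorsal (top) and ventral
#' (bottom) halves may carry different parameters.  Nuclei sit at the
#' nuclear-layer depth between the bands.
#'
#' @slot dim image (rows, cols) in px.
#' @slot center ellipse center (row, col) in px.
#' @slot semiAxes (a = AP semi-axis along columns, b = minor semi-axis along
#'   rows) in px.
#' @slot apicalDepth,basalDepth nominal ROI-chain depths (px).
#' @slot nuclearDepth depth separating apical from basal band (px).
#' @slot cortexDepth outer edge of the basal band (px).
#' @slot apicalParams,basalParams lists with `dorsal` and `ventral`
#'   [MultiExpParams-class].
#' @slot interiorLevel constant intensity of the core plasm (a.u.).
#' @slot nucleiCount,nucleiRadius,nucleiIntensity nuclei blob parameters.
#' @slot textureAmplitude,texturePeriod sinusoidal cytoplasmic texture.
#' @slot noise [NoiseSpec-class].
#' @export
setClass("EmbryoScene",
         representation(dim = "integer", center = "numeric",
                        semiAxes = "numeric",
                        apicalDepth = "numeric", basalDepth = "numeric",
                        nuclearDepth = "numeric", cortexDepth = "numeric",
                        apicalParams = "list", basalParams = "list",
                        interiorLevel = "numeric",
                        nucleiCount = "integer", nucleiRadius = "numeric",
                        nucleiIntensity = "numeric",
                        textureAmplitude = "numeric",
                        texturePeriod = "numeric",
                        noise = "NoiseSpec"))

setValidity("EmbryoScene", function(object) {
  msg <- NULL
  a <- object@semiAxes[1]; b <- object@semiAxes[2]
  if (!(object@apicalDepth < object@nuclearDepth &&
        object@nuclearDepth <= object@basalDepth &&
        object@basalDepth < object@cortexDepth))
    msg <- c(msg, "need apicalDepth < nuclearDepth <= basalDepth < cortexDepth")
  if (object@cortexDepth >= b)
    msg <- c(msg, "cortex depth must be smaller than the minor semi-axis")
  if (object@center[2] - a < 1 || object@center[2] + a > object@dim[2] ||
      object@center[1] - b < 1 || object@center[1] + b > object@dim[1])
    msg <- c(msg, "embryo ellipse exceeds the image frame")
  if (object@interiorLevel < 0 || object@nucleiIntensity < 0)
    msg <- c(msg, "intensities must be non-negative")
  for (s in c("dorsal", "ventral")) {
    if (!is(object@apicalParams[[s]], "MultiExpParams") ||
        !is(object@basalParams[[s]], "MultiExpParams"))
      msg <- c(msg, "apicalParams/basalParams need dorsal and ventral MultiExpParams")
  }
  if (is.null(msg)) TRUE else msg
})

#' SyntheticImage: a rendered scene with exact ground truth
#'
#' The decomposition `trend + texture + noise` equals `pixels` exactly
#' (the noise component is defined as the residual after clipping at zero,
#' so the identity holds bit-for-bit).
#'
#' @slot pixels rendered image matrix (a.u.).
#' @slot mask logical embryo-interior mask.
#' @slot trend deterministic cortical-gradient + interior component.
#' @slot texture nuclei + sinusoidal texture component.
#' @slot noise realized noise component (pixels - trend - texture).
#' @slot truthApical,truthBasal noiseless ground-truth gradients on a 1 \%EL
#'   grid (dorsal side).
#' @slot scene the generating [EmbryoScene-class].
#' @slot seed seed used for the stochastic parts.
#' @export
setClass("SyntheticImage",
         representation(pixels = "matrix", mask = "matrix", trend = "matrix",
                        texture = "matrix", noise = "matrix",
                        truthApical = "AxisProfile",
                        truthBasal = "AxisProfile",
                        scene = "EmbryoScene", seed = "integer"))

setValidity("SyntheticImage", function(object) {
  if (!identical(dim(object@pixels), dim(object@trend)) ||
      !identical(dim(object@pixels), dim(object@texture)) ||
      !identical(dim(object@pixels), dim(object@noise)))
    return("component images must share the pixel grid's dimensions")
  # same association used at construction time, so the identity is exact
  resid <- object@pixels - object@trend - object@texture - object@noise
  if (max(abs(resid)) != 0)
    return("trend + texture + noise must equal pixels exactly")
  TRUE
})

## ROI chains ------------------------------------------------------------------

#' ROIChain: a chain of circular ROIs along a contour
#'
#' @slot centers n x 2 matrix of (row, col) centers in px.
#' @slot radius disc radius in px (pixel membership: center distance <=
#'   radius, pixel centers at integers).
#' @slot layer "apical", "basal" or "custom".
#' @slot arcLengths cumulative arc length of each center along the source
#'   contour (px).
#' @export
setClass("ROIChain",
         representation(centers = "matrix", radius = "numeric",
                        layer = "character", arcLengths = "numeric"))

setValidity("ROIChain", function(object) {
  msg <- NULL
  if (ncol(object@centers) != 2L)
    msg <- c(msg, "centers must be an n x 2 (row, col) matrix")
  if (object@radius <= 0) msg <- c(msg, "radius must be positive")
  if (is.null(msg)) TRUE else msg
})

## SSA -------------------------------------------------------------------------

#' SSADecomposition: a (shaped) 2D SSA decomposition of an image region
#'
#' Holds the eigentriples of the Hankel-block-Hankel trajectory matrix: the
#' singular values, the left factors (window space) and the sigma-scaled
#' right factors (placement space, zero outside valid placements for the
#' shaped variant).  Reconstruction is by diagonal averaging over all patch
#' placements covering each pixel.
#'
#' @slot sigma singular values, non-increasing.
#' @slot U (Lx*Ly) x rank left factor matrix.
#' @slot SV (Kx*Ky) x rank sigma-scaled right factors (sigma_k * v_k),
#'   embedded on the full placement grid.
#' @slot window (Lx, Ly) window in px.
#' @slot imageDim analyzed image dimensions.
#' @slot mask logical analysis mask (all TRUE for plain 2D SSA).
#' @slot placements logical Kx x Ky valid-placement indicator.
#' @slot coverage per-pixel placement coverage counts.
#' @slot trajNormSq squared Frobenius norm of the trajectory matrix.
#' @slot rank retained rank.
#' @slot shaped TRUE for the shaped (masked) variant.
#' @slot image the analyzed image (masked pixels as given).
#' @export
setClass("SSADecomposition",
         representation(sigma = "numeric", U = "matrix", SV = "matrix",
                        window = "integer", imageDim = "integer",
                        mask = "matrix", placements = "matrix",
                        coverage = "matrix", trajNormSq = "numeric",
                        rank = "integer", shaped = "logical",
                        image = "matrix"))

setValidity("SSADecomposition", function(object) {
  msg <- NULL
  if (is.unsorted(rev(object@sigma), strictly = FALSE))
    msg <- c(msg, "singular values must be non-increasing")
  if (any(object@sigma < -1e-12))
    msg <- c(msg, "singular values must be non-negative")
  if (is.null(msg)) TRUE else msg
})

## Gradient summaries ----------------------------------------------------------

#' PrototypicalProfile: stage-level mean-parameter profile
#'
#' @slot stage,layer group identity.
#' @slot params mean [MultiExpParams-class] over the group (canonical order).
#' @slot grid evaluation grid (\%EL).
#' @slot curve model curve on the grid.
#' @slot n group size.
#' @export
setClass("PrototypicalProfile",
         representation(stage = "character", layer = "character",
                        params = "MultiExpParams", grid = "numeric",
                        curve = "numeric", n = "integer"))

#' CumulativeCurve: cumulative intensity distribution along the AP axis
#'
#' The ECDF of intensity mass: trapezoid-integrated intensity from the
#' profile start, normalized by the total.  Monotone non-decreasing, ends
#' at 1.
#'
#' @slot positions \%EL grid.
#' @slot ecdf cumulative values in [0, 1].
#' @slot backgroundValue flat background that was subtracted (0 if none).
#' @slot anchor background anchor position in \%EL (NA if none).
#' @export
setClass("CumulativeCurve",
         representation(positions = "numeric", ecdf = "numeric",
                        backgroundValue = "numeric", anchor = "numeric"))

setValidity("CumulativeCurve", function(object) {
  msg <- NULL
  if (length(object@positions) != length(object@ecdf))
    msg <- c(msg, "positions and ecdf must have equal length")
  if (any(diff(object@ecdf) < -1e-12))
    msg <- c(msg, "ecdf must be monotone non-decreasing")
  n <- length(object@ecdf)
  if (n && abs(object@ecdf[n] - 1) > 1e-9)
    msg <- c(msg, "ecdf must end at 1")
  if (is.null(msg)) TRUE else msg
})
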