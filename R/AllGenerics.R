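## Accessor generics and show methods.

#' @rdname AxisProfile-class
#' @param object,x an object.
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname AxisProfile-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname AxisProfile-class
#' @export
setGeneric("profileLayer", function(x) standardGeneric("profileLayer"))

#' @rdname AxisProfile-class
#' @export
setGeneric("profileChannel", function(x) standardGeneric("profileChannel"))

#' @rdname AxisProfile-class
#' @export
setMethod("positions", "AxisProfile", function(x) x@positions)

#' @rdname AxisProfile-class
#' @export
setMethod("intensities", "AxisProfile", function(x) x@intensities)

#' @rdname AxisProfile-class
#' @export
setMethod("profileLayer", "AxisProfile", function(x) x@layer)

#' @rdname AxisProfile-class
#' @export
setMethod("profileChannel", "AxisProfile", function(x) x@channel)

#' @rdname AxisProfile-class
#' @export
setMethod("length", "AxisProfile", function(x) length(x@positions))

setMethod("show", "AxisProfile", function(object) {
  cat(sprintf("AxisProfile '%s' [%s/%s]: %d samples, %s in [%g, %g]%s\n",
              object@embryoId, object@layer, object@channel,
              length(object@positions), object@unit,
              min(object@positions), max(object@positions),
              if (anyNA(object@intensities))
                sprintf(", %d missing", sum(is.na(object@intensities)))
              else ""))
})

setMethod("show", "MultiExpParams", function(object) {
  cat(sprintf("MultiExpParams: %d component(s)\n", length(object@C0)))
  for (i in seq_along(object@C0))
    cat(sprintf("  C0 = %8.3f  alpha = %+.5f /%%EL  lambda = %.5f\n",
                object@C0[i], object@alpha[i], exp(object@alpha[i])))
  if (object@background > 0)
    cat(sprintf("  background B = %.3f\n", object@background))
})

setMethod("show", "MultiExpFit", function(object) {
  cat(sprintf("MultiExpFit [%s] on window (%g, %g) %%EL: SSE = %.4g, n = %d%s\n",
              object@kind, object@window[1], object@window[2], object@sse,
              object@nPoints,
              if (object@converged) "" else " (NOT converged)"))
  for (i in seq_along(object@C0))
    cat(sprintf("  %-8s C0 = %9.3f  alpha = %+.5f  lambda = %.5f\n",
                object@roles[i], object@C0[i], object@alpha[i],
                object@lambda[i]))
  if (object@kind == "1expB")
    cat(sprintf("  background B = %.3f\n", object@background))
})

setMethod("show", "EmbryoRecord", function(object) {
  cat(sprintf("EmbryoRecord '%s' [%s] stage = %s%s\n", object@embryoId,
              object@channel,
              if (nzchar(object@stage)) object@stage else "<unknown>",
              if (nzchar(object@subgroup))
                sprintf(" (%s)", object@subgroup) else ""))
  cat(sprintf("  apical: %d samples; basal: %d samples; ground truth: %s\n",
              length(object@apical@positions),
              length(object@basal@positions),
              if (length(object@truth)) "yes" else "no"))
})

setMethod("show", "StagePreset", function(object) {
  cab <- log(object@apical@C0[1] / object@basal@C0[1])
  cat(sprintf("StagePreset '%s' (stage %s): lambda1 apical = %.4f, Cab = %+.3f\n",
              object@name, object@stage, exp(object@apical@alpha[1]), cab))
})

setMethod("show", "StageClassifier", function(object) {
  cat(sprintf("StageClassifier (%s) on %s\n", object@method,
              paste(object@featureNames, collapse = ", ")))
  cat(sprintf("  classes: %s; priors: %s; %d row(s) excluded for missing features\n",
              paste(object@labels, collapse = " < "),
              paste(sprintf("%.3f", object@priors), collapse = ", "),
              object@nExcluded))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix (%s), n = %d, accuracy = %.3f",
              object@scheme, object@n, object@accuracy))
  if (!is.na(object@permutationP))
    cat(sprintf(", permutation p = %.4g", object@permutationP))
  cat("\n")
  print(object@counts)
  cat("per-class correct fraction:\n")
  print(round(object@perClass, 3))
})

setMethod("show", "SSADecomposition", function(object) {
  cat(sprintf("%s2D SSA decomposition: %dx%d image, %dx%d window, rank %d\n",
              if (object@shaped) "shaped " else "",
              object@imageDim[1], object@imageDim[2],
              object@window[1], object@window[2], object@rank))
  k <- min(5L, object@rank)
  cat(sprintf("  leading sigma: %s\n",
              paste(sprintf("%.4g", object@sigma[seq_len(k)]), collapse = ", ")))
  cat(sprintf("  energy retained: %.4f\n",
              sum(object@sigma^2) / object@trajNormSq))
})

setMethod("show", "EmbryoScene", function(object) {
  cat(sprintf("EmbryoScene %dx%d px, ellipse a = %g, b = %g px, depths %g/%g px\n",
              object@dim[1], object@dim[2], object@semiAxes[1],
              object@semiAxes[2], object@apicalDepth, object@basalDepth))
})

setMethod("show", "SyntheticImage", function(object) {
  cat(sprintf("SyntheticImage %dx%d px (seed %s): intensity range [%.3g, %.3g]\n",
              nrow(object@pixels), ncol(object@pixels),
              ifelse(is.na(object@seed), "ambient", object@seed),
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "ROIChain", function(object) {
  cat(sprintf("ROIChain [%s]: %d ROIs, radius %g px, span %.1f px of arc\n",
              object@layer, nrow(object@centers), object@radius,
              diff(range(object@arcLengths))))
})

setMethod("show", "PrototypicalProfile", function(object) {
  cat(sprintf("PrototypicalProfile %s/%s (n = %d)\n",
              object@stage, object@layer, object@n))
  show(object@params)
})

setMethod("show", "CumulativeCurve", function(object) {
  cat(sprintf("CumulativeCurve on [%g, %g] %%EL (%d points)",
              min(object@positions), max(object@positions),
              length(object@positions)))
  if (!is.na(object@anchor))
    cat(sprintf(", background %.3f a.u. anchored at %g %%EL",
                object@backgroundValue, object@anchor))
  cat("\n")
})

#' Extract the ground-truth (noiseless) profile stored with a generated one
#'
#' @param x an [AxisProfile-class] produced by [generateProfile()].
#' @return An AxisProfile of the noiseless model values, or NULL.
#' @export
groundTruth <- function(x) attr(x, "groundTruth")
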