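## Multi-exponential model evaluation, shared by the generator and the fitter.

#' Evaluate a multi-exponential gradient model
#'
#' Computes \eqn{I(x) = \sum_i C_{0i}\exp(\alpha_i x) + B} at the given
#' AP positions.  Accepts either a [MultiExpParams-class] (generator side) or
#' a [MultiExpFit-class] (fitting side); for fits, B contributes only for the
#' "1expB" kind.
#'
#' @param object a [MultiExpParams-class] or [MultiExpFit-class].
#' @param x numeric positions in \%EL.
#' @return numeric vector of model intensities.
#' @export
setGeneric("evalModel", function(object, x) standardGeneric("evalModel"))

.evalMultiExp <- function(C0, alpha, background, x) {
  y <- rep(background, length(x))
  for (i in seq_along(C0)) y <- y + C0[i] * exp(alpha[i] * x)
  y
}

#' @rdname evalModel
#' @export
setMethod("evalModel", "MultiExpParams", function(object, x) {
  .evalMultiExp(object@C0, object@alpha, object@background, as.numeric(x))
})

#' @rdname evalModel
#' @export
setMethod("evalModel", "MultiExpFit", function(object, x) {
  .evalMultiExp(object@C0, object@alpha,
                if (object@kind == "1expB") object@background else 0,
                as.numeric(x))
})

#' Length constant of an exponential component
#'
#' The length constant is \eqn{-1/\alpha}: the AP distance over which an
#' exponential gradient decays by a factor of e.  Defined only for decaying
#' components (\eqn{\alpha < 0}); for a rising or flat component the result
#' is NA with a warning.
#'
#' @param alpha decay rate(s) per \%EL, or a [MultiExpFit-class] /
#'   [MultiExpParams-class] whose component rates are used.
#' @return numeric length constants in \%EL, with attribute
#'   `"fractionOfEL"` giving the same values divided by 100.
#' @examples
#' lengthConstant(-0.05)   # 20 %EL
#' @export
lengthConstant <- function(alpha) {
  if (is(alpha, "MultiExpFit") || is(alpha, "MultiExpParams"))
    alpha <- alpha@alpha
  alpha <- as.numeric(alpha)
  out <- ifelse(alpha < 0, -1 / alpha, NA_real_)
  if (anyNA(out))
    warning("length constant undefined for non-decaying component(s)")
  attr(out, "fractionOfEL") <- out / 100
  out
}
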