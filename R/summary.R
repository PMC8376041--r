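## Prototypical profiles, background subtraction, cumulative distributions
## and length-constant comparison against the reference protein gradient.

#' Prototypical profile from the mean model parameters of a group
#'
#' Averages the fitted parameters (C0 and alpha component-wise, after
#' canonical ordering) over all converged fits of one stage and layer, and
#' evaluates the mean model on a standard grid.  Groups mixing model kinds
#' are reduced to the common two-exponential part (anterior + shallow),
#' with a message.
#'
#' @param fits list of [MultiExpFit-class] objects for one stage + layer.
#' @param stage,layer labels recorded on the result.
#' @param grid evaluation grid in \%EL (default 0..100 by 1).
#' @return A [PrototypicalProfile-class].
#' @export
prototypicalProfile <- function(fits, stage = "", layer = "",
                                grid = seq(0, 100, by = 1)) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, is, TRUE, "MultiExpFit")))
  conv <- vapply(fits, function(f) f@converged, logical(1))
  if (!any(conv)) stop("no converged fit in the group")
  fits <- lapply(fits[conv], orderComponents)
  kinds <- unique(vapply(fits, function(f) f@kind, character(1)))
  roleSets <- lapply(fits, function(f) f@roles)
  common <- Reduce(intersect, roleSets)
  common <- intersect(c("anterior", "shallow", "rising"), common)
  if (length(kinds) > 1L) {
    common <- intersect(common, c("anterior", "shallow"))
    message("mixed model kinds in group: reduced to the common 2-exp part")
  }
  if (!length(common)) stop("fits share no common component")
  C0 <- vapply(common, function(r) mean(vapply(fits, function(f)
    f@C0[match(r, f@roles)], numeric(1))), numeric(1))
  alpha <- vapply(common, function(r) mean(vapply(fits, function(f)
    f@alpha[match(r, f@roles)], numeric(1))), numeric(1))
  B <- mean(vapply(fits, function(f)
    if (f@kind == "1expB") f@background else 0, numeric(1)))
  params <- multiExpParams(C0 = C0, alpha = alpha, background = B)
  new("PrototypicalProfile", stage = stage, layer = layer, params = params,
      grid = as.numeric(grid), curve = evalModel(params, grid),
      n = length(fits))
}

#' Subtract a flat background anchored at a posterior position
#'
#' The simplest background hypothesis: a constant equal to the intensity
#' at the anchor position (default 95 \%EL, the convention for bcd) is
#' subtracted everywhere; negative values are clipped to zero and the
#' clipped fraction is reported as attribute `"clipFraction"`.
#'
#' @param profile an [AxisProfile-class].
#' @param anchor anchor position in the profile's units (default 95 \%EL).
#' @return The background-subtracted [AxisProfile-class] with attributes
#'   `"backgroundValue"`, `"anchor"`, `"clipFraction"`.
#' @export
subtractBackground <- function(profile, anchor = 95) {
  stopifnot(is(profile, "AxisProfile"))
  pos <- profile@positions
  if (anchor < min(pos) || anchor > max(pos))
    stop("anchor lies outside the profile support")
  ok <- !is.na(profile@intensities)
  bg <- stats::approx(pos[ok], profile@intensities[ok], xout = anchor)$y
  shifted <- profile@intensities - bg
  clipped <- !is.na(shifted) & shifted < 0
  shifted[clipped] <- 0
  out <- initialize(profile, intensities = shifted)
  attr(out, "backgroundValue") <- bg
  attr(out, "anchor") <- anchor
  attr(out, "clipFraction") <- mean(clipped[ok])
  out
}

#' Cumulative distribution of intensity mass along the AP axis
#'
#' The ECDF of (background-subtracted) intensity: trapezoid-integrated
#' intensity from the profile start, normalized by the total over the
#' observed support.  Missing samples are dropped.  Degenerate profiles
#' (zero total mass after subtraction) are rejected.
#'
#' @param profile an [AxisProfile-class], typically the output of
#'   [subtractBackground()].
#' @return A [CumulativeCurve-class].
#' @export
cumulativeDistribution <- function(profile) {
  stopifnot(is(profile, "AxisProfile"))
  ok <- !is.na(profile@intensities)
  x <- profile@positions[ok]; y <- profile@intensities[ok]
  if (length(x) < 2L) stop("need at least two non-missing samples")
  if (any(y < 0)) stop("intensities must be non-negative for an ECDF")
  steps <- diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2
  total <- sum(steps)
  if (total <= 0) stop("zero total mass: degenerate after subtraction")
  ec <- c(0, cumsum(steps)) / total
  bg <- attr(profile, "backgroundValue")
  anc <- attr(profile, "anchor")
  new("CumulativeCurve", positions = x, ecdf = pmin(ec, 1),
      backgroundValue = if (is.null(bg)) 0 else bg,
      anchor = if (is.null(anc)) NA_real_ else anc)
}

#' Closed-form cumulative curve of a pure exponential gradient
#'
#' The reference against which measured cumulative curves are compared:
#' for a gradient with length constant L on the observed support,
#' \eqn{ECDF(x) = (e^{-x_0/L} - e^{-x/L}) / (e^{-x_0/L} - e^{-x_N/L})}.
#'
#' @param lengthConstant reference length constant in \%EL (20 \%EL is the
#'   usual protein-gradient approximation).
#' @param positions evaluation grid in \%EL.
#' @return numeric ECDF values.
#' @export
referenceEcdf <- function(lengthConstant, positions) {
  stopifnot(lengthConstant > 0)
  x0 <- positions[1]; xn <- positions[length(positions)]
  (exp(-x0 / lengthConstant) - exp(-positions / lengthConstant)) /
    (exp(-x0 / lengthConstant) - exp(-xn / lengthConstant))
}

#' Compare a cumulative curve to the reference exponential gradient
#'
#' Sup-norm distance between the measured curve and the closed-form ECDF
#' of an exponential with the given length constant, on the curve's grid.
#'
#' @param curve a [CumulativeCurve-class].
#' @param referenceLengthConstant reference length constant in \%EL
#'   (default 20).
#' @return list with `maxDeviation` and `position` (\%EL of the maximum
#'   deviation).
#' @export
compareToReference <- function(curve, referenceLengthConstant = 20) {
  stopifnot(is(curve, "CumulativeCurve"))
  ref <- referenceEcdf(referenceLengthConstant, curve@positions)
  dev <- abs(curve@ecdf - ref)
  i <- which.max(dev)
  list(maxDeviation = dev[i], position = curve@positions[i])
}
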