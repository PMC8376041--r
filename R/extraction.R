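## Profile extraction: offset contours, ROI chains, disc-averaged profiles.
##
## Pixel convention: matrices are [row, col], 1-based, pixel centers at
## integer coordinates; a pixel belongs to an ROI disc when its center lies
## within `radius` of the disc center.  The anterior pole is the mask's
## smallest-column extreme; "dorsal" is the top (small-row) half.

#' Segment the embryo interior from a grayscale image
#'
#' A simple threshold plus largest-connected-component mask with hole
#' filling.  Sufficient for synthetic scenes; it is not a general embryo
#' segmenter.
#'
#' @param image numeric matrix.
#' @param method "otsu" (default) or "threshold".
#' @param threshold absolute intensity threshold for method "threshold".
#' @return logical matrix, TRUE inside the embryo.
#' @export
embryoMask <- function(image, method = c("otsu", "threshold"),
                       threshold = NULL) {
  method <- match.arg(method)
  rng <- range(image)
  th <- if (method == "otsu") {
    scaled <- (image - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
    EBImage::otsu(EBImage::Image(scaled)) * (rng[2] - rng[1]) + rng[1]
  } else {
    if (is.null(threshold)) stop("method 'threshold' needs a threshold")
    threshold
  }
  bw <- image > th
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
  if (max(lab) == 0) stop("no foreground found at the chosen threshold")
  counts <- tabulate(lab[lab > 0])
  keep <- lab == which.max(counts)
  EBImage::imageData(EBImage::fillHull(EBImage::Image(keep * 1))) > 0
}

# Euclidean distance-to-background for foreground pixels
.depthMap <- function(mask) {
  EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
}

#' Inward offset contour of the embryo boundary
#'
#' Returns the embryo boundary eroded inward by `depth` pixels (the level
#' set of the Euclidean distance transform), restricted to the requested
#' side and ordered from the anterior pole posteriorly.  With
#' `side = "full"` the polyline runs ventral -> anterior pole -> dorsal,
#' the convention for profiles taken through the pole.
#'
#' @param mask logical embryo-interior matrix (single connected region).
#' @param depth inward offset in px (0 = the boundary itself).
#' @param side "dorsal" (default), "ventral" or "full".
#' @return n x 2 matrix of (row, col) polyline vertices with attribute
#'   `"side"`.
#' @export
offsetContour <- function(mask, depth = 0, side = c("dorsal", "ventral",
                                                    "full")) {
  side <- match.arg(side)
  stopifnot(is.matrix(mask), depth >= 0)
  z <- if (depth == 0) mask * 1 else .depthMap(mask)
  level <- if (depth == 0) 0.5 else depth
  cl <- grDevices::contourLines(x = seq_len(nrow(mask)),
                                y = seq_len(ncol(mask)), z = z,
                                levels = level)
  if (length(cl) == 0)
    stop("offset depth erodes the mask to nothing")
  cl <- cl[[which.max(lengths(lapply(cl, `[[`, "x")))]]
  pts <- cbind(row = cl$x, col = cl$y)
  # drop the duplicated closing vertex of a closed contour
  n <- nrow(pts)
  if (n > 1 && all(abs(pts[1, ] - pts[n, ]) < 1e-9)) pts <- pts[-n, , drop = FALSE]
  n <- nrow(pts)
  if (n < 4) stop("offset contour degenerate")

  iA <- which.min(pts[, "col"])   # anterior pole
  ord <- c(iA:n, seq_len(iA - 1)) # rotate so the walk starts at the pole
  pts <- pts[ord, , drop = FALSE]
  iP <- which.max(pts[, "col"])   # posterior extreme along the walk
  arc1 <- pts[seq_len(iP), , drop = FALSE]           # pole -> posterior
  arc2 <- pts[c(1L, n:iP), , drop = FALSE]           # pole -> posterior, other way
  if (mean(arc1[, "row"]) <= mean(arc2[, "row"])) {
    dorsal <- arc1; ventral <- arc2
  } else {
    dorsal <- arc2; ventral <- arc1
  }
  out <- switch(side,
                dorsal = dorsal,
                ventral = ventral,
                full = rbind(ventral[rev(seq_len(nrow(ventral))), ,
                                     drop = FALSE],
                             dorsal[-1, , drop = FALSE]))
  attr(out, "side") <- side
  out
}

.cumArc <- function(pts) {
  seg <- sqrt(rowSums(diff(pts)^2))
  c(0, cumsum(seg))
}

#' Build a chain of circular ROIs along a contour
#'
#' ROI centers are placed at uniform arc-length spacing along the polyline
#' (linear interpolation between vertices).  A spacing larger than the ROI
#' diameter leaves coverage gaps and triggers a warning; a contour shorter
#' than one spacing is rejected.  For a closed contour the duplicated wrap
#' point is dropped, so the first and last centers are distinct.
#'
#' @param contour n x 2 (row, col) polyline.
#' @param radius ROI radius in px.
#' @param spacing arc-length distance between consecutive centers in px.
#' @param layer layer tag for the chain ("apical", "basal", "custom").
#' @return An [ROIChain-class].
#' @export
buildRoiChain <- function(contour, radius, spacing, layer = "custom") {
  stopifnot(radius > 0, spacing > 0)
  contour <- as.matrix(contour)
  n <- nrow(contour)
  closed <- n > 1 && all(abs(contour[1, ] - contour[n, ]) < 1e-9)
  arc <- .cumArc(contour)
  total <- arc[n]
  if (total < spacing) stop("contour shorter than one ROI spacing")
  if (spacing > 2 * radius)
    warning("spacing exceeds the ROI diameter: coverage gaps along the chain")
  s <- seq(0, total, by = spacing)
  if (closed && total - s[length(s)] < spacing / 2)
    s <- s[-length(s)]                     # no duplicated wrap point
  rows <- stats::approx(arc, contour[, 1], xout = s)$y
  cols <- stats::approx(arc, contour[, 2], xout = s)$y
  new("ROIChain", centers = cbind(row = rows, col = cols), radius = radius,
      layer = layer, arcLengths = s)
}

.roiMean <- function(image, mask, r0, c0, radius) {
  nr <- nrow(image); nc <- ncol(image)
  rr <- max(1L, ceiling(r0 - radius)):min(nr, floor(r0 + radius))
  cc <- max(1L, ceiling(c0 - radius)):min(nc, floor(c0 + radius))
  if (length(rr) == 0 || length(cc) == 0) return(NA_real_)
  d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
  inside <- d2 <= radius^2
  if (!is.null(mask)) inside <- inside & mask[rr, cc, drop = FALSE]
  if (!any(inside)) return(NA_real_)
  mean(image[rr, cc, drop = FALSE][inside])
}

#' Extract an intensity profile from an ROI chain
#'
#' Each sample is the mean intensity of the pixels inside the ROI disc
#' intersected with the embryo mask.  An ROI with no pixel inside the mask
#' yields an `NA` sample (flagged missing, never zero).  For apical/basal
#' chains the position is the AP projection of the ROI center onto the
#' mask's anterior-posterior chord, in \%EL, so both layers share one
#' coordinate system; for "custom" chains the position is the arc-length
#' fraction along the chain.
#'
#' @param image numeric matrix.
#' @param chain an [ROIChain-class].
#' @param mask logical embryo mask (required for \%EL positions; optional
#'   for custom chains).
#' @param channel,embryoId metadata for the returned profile.
#' @return An [AxisProfile-class].
#' @export
extractProfile <- function(image, chain, mask = NULL, channel = "bcd",
                           embryoId = "embryo") {
  stopifnot(is(chain, "ROIChain"))
  ctr <- chain@centers
  if (any(ctr[, 1] < 1 - chain@radius | ctr[, 1] > nrow(image) + chain@radius |
          ctr[, 2] < 1 - chain@radius | ctr[, 2] > ncol(image) + chain@radius))
    stop("ROI chain extends beyond the image frame")
  vals <- vapply(seq_len(nrow(ctr)), function(i)
    .roiMean(image, mask, ctr[i, 1], ctr[i, 2], chain@radius), numeric(1))

  if (chain@layer %in% c("apical", "basal")) {
    if (is.null(mask)) stop("%EL projection requires the embryo mask")
    colsIn <- which(apply(mask, 2, any))
    antCol <- min(colsIn); postCol <- max(colsIn)
    pos <- (ctr[, 2] - antCol) / (postCol - antCol) * 100
    pos <- pmin(pmax(pos, 0), 100)
    unit <- "pctEL"
  } else {
    total <- max(chain@arcLengths)
    pos <- chain@arcLengths / max(total, .Machine$double.eps)
    unit <- "arcFraction"
  }
  ord <- order(pos)
  pos <- pos[ord]; vals <- vals[ord]
  keep <- c(TRUE, diff(pos) > 1e-9)
  if (!all(keep))
    message(sum(!keep), " ROI(s) dropped: duplicate axis positions")
  AxisProfile(pos[keep], vals[keep], layer = chain@layer, channel = channel,
              embryoId = embryoId, unit = unit)
}
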