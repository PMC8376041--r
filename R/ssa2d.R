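## 2D and shaped 2D singular spectrum analysis.
##
## The trajectory matrix stacks every Lx x Ly sliding window of the image
## (Hankel-block-Hankel structure) as a column; the shaped variant keeps
## only window placements lying fully inside an arbitrary mask.  The SVD is
## computed from the small Gram matrix of window space; reconstruction is
## diagonal averaging (each pixel averages the rank-restricted trajectory
## entries of every placement covering it), performed by direct
## accumulation so the full-rank completeness identity holds to machine
## precision.

#' Hankel-block-Hankel embedding of an image region
#'
#' Returns the trajectory matrix whose columns are the vectorized Lx x Ly
#' sliding patches of the image (column-major within the patch; placements
#' in column-major order of their top-left corner).
#'
#' @param image numeric matrix.
#' @param window integer (Lx, Ly).
#' @return (Lx*Ly) x (Kx*Ky) matrix, Kx = nrow - Lx + 1, Ky = ncol - Ly + 1.
#' @export
ssaEmbed <- function(image, window) {
  window <- as.integer(rep(window, length.out = 2))
  .ssaTrajectory(image, matrix(TRUE, nrow(image), ncol(image)), window)$A
}

.ssaTrajectory <- function(image, mask, window) {
  nr <- nrow(image); nc <- ncol(image)
  Lx <- window[1]; Ly <- window[2]
  if (Lx < 1 || Ly < 1 || Lx > nr || Ly > nc)
    stop("window must fit inside the image region")
  Kx <- nr - Lx + 1L; Ky <- nc - Ly + 1L
  # valid placements: window fully inside the mask (integral-image test)
  S <- rbind(0, apply(rbind(0, apply(mask * 1, 2, cumsum)), 1, cumsum))
  S <- t(S)  # (nr+1) x (nc+1) summed-area table
  i <- matrix(seq_len(Kx), Kx, Ky)
  j <- matrix(seq_len(Ky), Kx, Ky, byrow = TRUE)
  winSum <- S[cbind(as.vector(i + Lx), as.vector(j + Ly))] -
    S[cbind(as.vector(i), as.vector(j + Ly))] -
    S[cbind(as.vector(i + Lx), as.vector(j))] +
    S[cbind(as.vector(i), as.vector(j))]
  placements <- matrix(winSum == Lx * Ly, Kx, Ky)
  valid <- which(placements)
  if (length(valid) == 0)
    stop("no window placement fits inside the mask")
  pi0 <- (i[valid] - 1L) + (j[valid] - 1L) * nr   # 0-based pixel offset
  L <- Lx * Ly
  A <- matrix(0, L, length(valid))
  rowIdx <- 0L
  for (v in seq_len(Ly)) for (u in seq_len(Lx)) {
    rowIdx <- rowIdx + 1L
    A[rowIdx, ] <- image[pi0 + (u - 1L) + (v - 1L) * nr + 1L]
  }
  list(A = A, placements = placements, valid = valid, Kx = Kx, Ky = Ky)
}

.ssaCore <- function(image, mask, window, maxRank, shaped) {
  window <- as.integer(rep(window, length.out = 2))
  tr <- .ssaTrajectory(image, mask, window)
  A <- tr$A
  L <- nrow(A); nP <- ncol(A)
  # direct SVD of the trajectory matrix: small singular values are accurate
  # to eps * sigma_1, which the rank-1 limit checks rely on
  sv <- svd(A, nu = min(L, nP), nv = 0)
  sigma <- sv$d
  rank <- min(maxRank, L, nP)
  U <- sv$u[, seq_len(rank), drop = FALSE]
  SVvalid <- crossprod(A, U)                     # nP x rank = sigma * V
  SV <- matrix(0, tr$Kx * tr$Ky, rank)
  SV[tr$valid, ] <- SVvalid

  # coverage: number of valid placements covering each pixel
  cov <- .accumulate(matrix(1, L, nP), tr$placements, window,
                     nrow(image), ncol(image))

  new("SSADecomposition", sigma = sigma, U = U, SV = SV, window = window,
      imageDim = c(nrow(image), ncol(image)), mask = mask,
      placements = tr$placements, coverage = cov,
      trajNormSq = sum(A^2), rank = as.integer(rank), shaped = shaped,
      image = image)
}

# diagonal-averaging numerator: accumulate the rank-restricted trajectory
# matrix M (L x nPlacements) onto the pixel grid; row order matches the
# (u, v) patch order used when the trajectory matrix was built
.accumulate <- function(M, placements, window, nr, nc) {
  Kx <- nrow(placements)
  out <- numeric(nr * nc)
  p0 <- which(placements) - 1L
  i <- p0 %% Kx; j <- p0 %/% Kx
  base <- i + j * nr                     # 0-based pixel offset of top-left
  rowIdx <- 0L
  for (v in seq_len(window[2])) for (u in seq_len(window[1])) {
    rowIdx <- rowIdx + 1L
    idx <- base + (u - 1L) + (v - 1L) * nr + 1L
    out[idx] <- out[idx] + M[rowIdx, ]   # idx unique within one row
  }
  matrix(out, nr, nc)
}

#' Decompose an image by plain 2D SSA
#'
#' @param image numeric matrix.
#' @param window (Lx, Ly) window in px; default about a quarter of each
#'   image extent.
#' @param maxRank number of eigentriples to retain (left/right factors);
#'   all singular values are always kept for energy accounting.
#' @return An [SSADecomposition-class].
#' @export
ssa2d <- function(image, window = NULL, maxRank = 16L) {
  if (is.null(window)) window <- pmax(2L, floor(dim(image) / 4))
  .ssaCore(image, matrix(TRUE, nrow(image), ncol(image)), window,
           maxRank, shaped = FALSE)
}

#' Decompose an image region by shaped 2D SSA
#'
#' Identical to [ssa2d()] except that only window placements lying fully
#' inside `mask` enter the trajectory matrix, and the reconstruction is
#' defined only on pixels covered by at least one placement (uncovered
#' pixels are `NA`, never zero-filled).  On a full mask this reduces
#' exactly to plain 2D SSA.
#'
#' @param image numeric matrix.
#' @param mask logical matrix of analyzed pixels.
#' @param window (Lx, Ly) window; default a quarter of the mask bounding
#'   box.
#' @param maxRank eigentriples to retain.
#' @return An [SSADecomposition-class].
#' @export
shapedSsa2d <- function(image, mask, window = NULL, maxRank = 16L) {
  stopifnot(identical(dim(image), dim(mask)))
  if (is.null(window)) {
    rows <- range(which(apply(mask, 1, any)))
    cols <- range(which(apply(mask, 2, any)))
    window <- pmax(2L, floor(c(diff(rows) + 1, diff(cols) + 1) / 4))
  }
  .ssaCore(image, mask, window, maxRank, shaped = TRUE)
}

#' Reconstruct a grouped SSA component image
#'
#' Projects the rank-restricted trajectory matrix of the chosen eigentriple
#' group back to image space by diagonal averaging: each pixel is the mean
#' of the corresponding entries over every placement covering it.  An empty
#' group yields the zero image.  Pixels covered by no placement (shaped
#' variant) are `NA`.
#'
#' @param decomposition an [SSADecomposition-class].
#' @param group integer vector of eigentriple indices (within the retained
#'   rank).
#' @return numeric matrix of the component image.
#' @export
ssaReconstruct <- function(decomposition, group) {
  d <- decomposition
  stopifnot(is(d, "SSADecomposition"))
  nr <- d@imageDim[1]; nc <- d@imageDim[2]
  out <- matrix(0, nr, nc)
  cov <- d@coverage
  if (length(group)) {
    if (any(group < 1 | group > d@rank))
      stop("group indices must lie within the retained rank")
    M <- d@U[, group, drop = FALSE] %*% t(d@SV[, group, drop = FALSE])
    M <- M[, as.vector(d@placements), drop = FALSE]     # valid placements only
    out <- .accumulate(M, d@placements, d@window, nr, nc)
    out <- out / ifelse(cov > 0, cov, 1)
  }
  out[cov == 0] <- NA_real_
  out
}

#' Split an image into trend, mid-frequency and noise components
#'
#' The default grouping used for cortical-signal images: F1 (the first
#' eigentriple) is the smooth trend; F2-F4 (eigentriples 2-4) carry
#' mid-frequency inhomogeneities; the residual `image - F1 - (F2-F4)` on
#' the analyzed region is noise.  If fewer than four eigentriples are
#' available the mid-frequency group is truncated (with a message).
#'
#' @param image numeric matrix.
#' @param window SSA window; see [ssa2d()].
#' @param mask optional logical mask; when supplied the shaped variant is
#'   used.
#' @param maxRank eigentriples to retain (>= 4 recommended).
#' @return list with `F1`, `F24`, `residual` matrices and the underlying
#'   `decomposition`.
#' @export
splitSignalNoise <- function(image, window = NULL, mask = NULL,
                             maxRank = 8L) {
  d <- if (is.null(mask)) ssa2d(image, window, maxRank)
       else shapedSsa2d(image, mask, window, maxRank)
  g2 <- seq(2L, min(4L, d@rank))
  if (d@rank < 4L)
    message("only ", d@rank, " eigentriples available; F2-F4 truncated")
  F1 <- ssaReconstruct(d, 1L)
  F24 <- if (d@rank >= 2L) ssaReconstruct(d, g2) else F1 * 0
  residual <- image - F1 - F24
  residual[d@coverage == 0] <- NA_real_
  list(F1 = F1, F24 = F24, residual = residual, decomposition = d)
}

#' Weighted correlation matrix of elementary SSA components
#'
#' The w-correlation between reconstructed elementary components, weighted
#' by each pixel's placement coverage; near-zero off-diagonal blocks
#' justify a grouping.
#'
#' @param decomposition an [SSADecomposition-class].
#' @param components indices of elementary components to compare.
#' @return symmetric correlation matrix.
#' @export
wCorMatrix <- function(decomposition, components = seq_len(
  min(decomposition@rank, 10L))) {
  recs <- lapply(components, function(k)
    ssaReconstruct(decomposition, k))
  w <- decomposition@coverage
  ok <- w > 0
  inner <- function(a, b) sum(w[ok] * a[ok] * b[ok])
  m <- length(recs)
  out <- matrix(0, m, m, dimnames = list(paste0("F", components),
                                         paste0("F", components)))
  for (i in seq_len(m)) for (j in i:m) {
    v <- inner(recs[[i]], recs[[j]]) /
      sqrt(inner(recs[[i]], recs[[i]]) * inner(recs[[j]], recs[[j]]))
    out[i, j] <- v; out[j, i] <- v
  }
  out
}
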