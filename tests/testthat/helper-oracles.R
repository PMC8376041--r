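# Independent oracles used across the suite.

# trajectory matrix by explicit loops (independent of ssaEmbed)
naiveTrajectory <- function(image, Lx, Ly) {
  Kx <- nrow(image) - Lx + 1
  Ky <- ncol(image) - Ly + 1
  A <- matrix(0, Lx * Ly, Kx * Ky)
  colIdx <- 0
  for (j in seq_len(Ky)) for (i in seq_len(Kx)) {
    colIdx <- colIdx + 1
    A[, colIdx] <- as.vector(image[i:(i + Lx - 1), j:(j + Ly - 1)])
  }
  A
}

# dense grid search over decay-rate pairs with linear amplitude solve:
# a brute-force reference optimum for the two-exponential fit
gridSearch2exp <- function(x, y, n1 = 60, n2 = 60) {
  a1s <- -exp(seq(log(0.01), log(0.6), length.out = n1))
  a2s <- -exp(seq(log(0.001), log(0.1), length.out = n2))
  best <- list(sse = Inf)
  for (a1 in a1s) for (a2 in a2s) {
    if (a1 >= a2) next
    basis <- cbind(exp(a1 * x), exp(a2 * x))
    cf <- tryCatch(qr.solve(crossprod(basis), crossprod(basis, y)),
                   error = function(e) NULL)
    if (is.null(cf) || any(cf < 0)) next
    sse <- sum((basis %*% cf - y)^2)
    if (sse < best$sse)
      best <- list(sse = sse, C0 = as.numeric(cf), alpha = c(a1, a2))
  }
  best
}

# closed-form ECDF of C * exp(-x / L) on [x0, xn]
exactExpEcdf <- function(x, L, x0 = min(x), xn = max(x)) {
  (exp(-x0 / L) - exp(-x / L)) / (exp(-x0 / L) - exp(-xn / L))
}

# brute-force Euclidean distance from points to the mask background
naiveBoundaryDistance <- function(mask, pts) {
  bg <- which(!mask, arr.ind = TRUE)
  apply(pts, 1, function(p)
    sqrt(min((bg[, 1] - p[1])^2 + (bg[, 2] - p[2])^2)))
}

# standard synthetic image for SSA checks: separable exponential trend +
# sinusoid texture + seeded Gaussian noise at a given SNR (sd ratio)
ssaTestImage <- function(n = 96, snr = 5, textureAmp = 2, seed = 11) {
  trend <- 100 * outer(exp(-0.02 * seq_len(n)), exp(-0.015 * seq_len(n)))
  texture <- textureAmp * outer(sin(seq_len(n) / 4), sin(seq_len(n) / 5))
  noise <- withr::with_seed(seed,
    matrix(rnorm(n * n, 0, stats::sd(trend) / snr), n, n))
  list(image = trend + texture + noise, trend = trend,
       texture = texture, noise = noise)
}

relErr <- function(est, truth) {
  sqrt(sum((est - truth)^2) / sum(truth^2))
}
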