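## Bounded multi-start nonlinear least squares for multi-exponential models.
##
## Multi-exponential fitting is notoriously ill-conditioned, so the fitter
## combines (i) separable starts: a grid of decay rates with amplitudes
## solved linearly, (ii) a log-linear regression start, (iii) boundary
## starts embedding the best lower-order model (which also enforces the
## SSE nesting 3exp <= 2exp <= 1expB at the returned optima), and
## (iv) bounded Levenberg-Marquardt refinement with an analytic Jacobian.

.ALPHA_MIN <- -1          # steepest admissible decay, per %EL
.ALPHA_MAX <- -1e-12      # decaying components stay strictly negative
.RISE_MIN <- 1e-12        # rising third component, per %EL
.RISE_MAX <- 0.2

# residual and Jacobian for nls.lm; par = c(C[1..k], alpha[1..k], B?)
.meResid <- function(par, x, y, k, hasB) {
  C0 <- par[seq_len(k)]; al <- par[k + seq_len(k)]
  B <- if (hasB) par[2 * k + 1] else 0
  .evalMultiExp(C0, al, B, x) - y
}

.meJac <- function(par, x, y, k, hasB) {
  C0 <- par[seq_len(k)]; al <- par[k + seq_len(k)]
  J <- matrix(0, length(x), length(par))
  for (i in seq_len(k)) {
    e <- exp(al[i] * x)
    J[, i] <- e
    J[, k + i] <- C0[i] * x * e
  }
  if (hasB) J[, 2 * k + 1] <- 1
  J
}

# amplitudes (and B) solved linearly for fixed decay rates; clamped >= 0
.linearAmplitudes <- function(x, y, alpha, hasB) {
  basis <- vapply(alpha, function(a) exp(a * x), numeric(length(x)))
  if (hasB) basis <- cbind(basis, 1)
  cf <- tryCatch(stats::lm.fit(basis, y)$coefficients,
                 error = function(e) rep(NA_real_, ncol(basis)))
  cf[!is.finite(cf)] <- 0
  unname(pmax(cf, 1e-9))
}

.sseOf <- function(par, x, y, k, hasB) sum(.meResid(par, x, y, k, hasB)^2)

.refine <- function(par, lower, upper, x, y, k, hasB) {
  par <- pmin(pmax(par, lower), upper)
  # iteration-cap warnings are recorded in the convergence flag instead
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = par, lower = lower, upper = upper,
                         fn = .meResid, jac = .meJac, x = x, y = y, k = k,
                         hasB = hasB,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 400, ftol = 1e-15, ptol = 1e-13))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  list(par = fit$par, sse = sum(fit$fvec^2),
       converged = fit$info %in% 1:4)
}

.alphaStarts <- function(x, y, kind, restarts) {
  # log-linear regression on the positive part anchors one start
  pos <- y > 0
  aHat <- if (sum(pos) >= 3) {
    cf <- stats::coef(stats::lm(log(y[pos]) ~ x[pos]))[2]
    max(min(cf, -0.005), -0.9)
  } else -0.1
  if (kind == "1expB") {
    unique(c(aHat, -exp(seq(log(0.005), log(0.5), length.out = restarts))))
  } else {
    steep <- -exp(seq(log(0.03), log(0.5), length.out = max(3L, ceiling(sqrt(restarts)))))
    shallow <- -exp(seq(log(0.002), log(0.08), length.out = max(3L, ceiling(sqrt(restarts)))))
    g <- expand.grid(a1 = unique(c(aHat, steep)), a2 = shallow)
    g <- g[g$a1 < g$a2, , drop = FALSE]
    g
  }
}

.asFit <- function(kind, C0, alpha, B, window, sse, n, converged) {
  C0 <- unname(C0); alpha <- unname(alpha); B <- unname(B)
  fit <- new("MultiExpFit", kind = kind, C0 = C0, alpha = alpha,
             lambda = exp(alpha), background = B,
             roles = rep("unordered", length(C0)),
             window = as.numeric(window), sse = sse, nPoints = as.integer(n),
             converged = converged)
  orderComponents(fit)
}

#' Fit a multi-exponential model to an AP profile
#'
#' Least-squares fit of the one-exponential-plus-background ("1expB"),
#' two-exponential ("2exp") or three-exponential ("3exp") model over a
#' stated \%EL window.  Decaying rates are bounded to [-1, 0); the third
#' component of "3exp" is the posteriorly rising one, bounded to (0, 0.2].
#' Multi-start: log-spaced decay-rate initializations with amplitudes
#' solved linearly, plus a boundary start from the best lower-order model,
#' refined by bounded Levenberg-Marquardt; the best-of-restarts fit is
#' returned with components in canonical order.  Missing (NA) samples
#' inside the window are skipped, never interpolated.
#'
#' @param profile an [AxisProfile-class] (positions in \%EL).
#' @param kind "2exp" (default), "1expB" or "3exp".
#' @param window fit window (lo, hi) in \%EL; defaults to (10, 90), the
#'   bcd convention (use (10, 80) for Stau).
#' @param restarts number of multi-start initializations (default 8).
#' @param seed unused for the deterministic start grid; kept for interface
#'   stability.
#' @return A [MultiExpFit-class].
#' @export
fitProfile <- function(profile, kind = c("2exp", "1expB", "3exp"),
                       window = c(10, 90), restarts = 8L, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(is(profile, "AxisProfile"))
  if (profile@unit != "pctEL")
    stop("fitting requires a %EL profile")
  sel <- profile@positions >= window[1] & profile@positions <= window[2] &
    !is.na(profile@intensities)
  x <- profile@positions[sel]
  y <- profile@intensities[sel]
  nFree <- switch(kind, "1expB" = 3L, "2exp" = 4L, "3exp" = 6L)
  if (length(x) < 2L * nFree)
    stop("too few non-missing samples inside the window (need >= ",
         2L * nFree, ", have ", length(x), ")")
  if (all(y == 0))
    stop("all-zero intensities: log-linear initialization undefined")

  # fit on unit-scale intensities, quantized to 7 significant digits
  # (beyond any 8/16-bit acquisition): the optimizer then sees bit-identical
  # inputs under a common positive rescaling, so fitted alphas and C ratios
  # are exactly scale-invariant rather than merely close
  yScale <- max(y)
  y <- signif(y / yScale, 7)

  best <- NULL
  keepBest <- function(cand) {
    if (!is.null(cand) && (is.null(best) || cand$sse < best$sse)) best <<- cand
  }

  if (kind == "1expB") {
    lower <- c(0, .ALPHA_MIN, 0); upper <- c(Inf, .ALPHA_MAX, Inf)
    for (a in .alphaStarts(x, y, kind, restarts)) {
      cf <- .linearAmplitudes(x, y, a, hasB = TRUE)
      keepBest(.refine(c(cf[1], a, cf[2]), lower, upper, x, y, 1L, TRUE))
    }
    if (is.null(best)) stop("1expB fit failed from every start")
    return(.asFit("1expB", best$par[1] * yScale, best$par[2],
                  best$par[3] * yScale, window, best$sse * yScale^2,
                  length(x), best$converged))
  }

  ## the 1expB optimum seeds the 2exp boundary start (alpha2 -> 0-, C2 = B)
  base1 <- tryCatch(fitProfile(profile, "1expB", window, restarts),
                    error = function(e) NULL)

  lower2 <- c(0, 0, .ALPHA_MIN, .ALPHA_MIN)
  upper2 <- c(Inf, Inf, .ALPHA_MAX, .ALPHA_MAX)
  grid <- .alphaStarts(x, y, "2exp", restarts)
  for (r in seq_len(nrow(grid))) {
    al <- c(grid$a1[r], grid$a2[r])
    cf <- .linearAmplitudes(x, y, al, hasB = FALSE)
    keepBest(.refine(c(cf, al), lower2, upper2, x, y, 2L, FALSE))
  }
  if (!is.null(base1)) {
    bpar <- c(base1@C0[1] / yScale, max(base1@background / yScale, 1e-9),
              base1@alpha[1], .ALPHA_MAX)
    keepBest(.refine(bpar, lower2, upper2, x, y, 2L, FALSE))
    # direct boundary candidate: guarantees SSE(2exp) <= SSE(1expB) even if
    # LM stalls at the first iteration
    keepBest(list(par = bpar, sse = .sseOf(bpar, x, y, 2L, FALSE),
                  converged = base1@converged))
  }
  if (is.null(best)) stop("2exp fit failed from every start")
  fit2 <- .asFit("2exp", best$par[1:2] * yScale, best$par[3:4], 0,
                 window, best$sse * yScale^2, length(x), best$converged)
  if (kind == "2exp") return(fit2)

  ## 3exp: decaying pair + rising third; seeded from the 2exp optimum
  best <- NULL
  lower3 <- c(0, 0, 0, .ALPHA_MIN, .ALPHA_MIN, .RISE_MIN)
  upper3 <- c(Inf, Inf, Inf, .ALPHA_MAX, .ALPHA_MAX, .RISE_MAX)
  dec <- which(fit2@alpha < 0)[1:2]
  for (a3 in c(0.005, 0.02, 0.05, 0.1)) {
    al <- c(fit2@alpha[dec], a3)
    cf <- .linearAmplitudes(x, y, al, hasB = FALSE)
    keepBest(.refine(c(cf, al), lower3, upper3, x, y, 3L, FALSE))
  }
  # exact boundary embed (C3 = 0): SSE(3exp) can never exceed SSE(2exp)
  zpar <- c(fit2@C0[dec] / yScale, 0, fit2@alpha[dec], 0.05)
  keepBest(.refine(zpar, lower3, upper3, x, y, 3L, FALSE))
  keepBest(list(par = zpar, sse = .sseOf(zpar, x, y, 3L, FALSE),
                converged = fit2@converged))
  if (is.null(best)) stop("3exp fit failed from every start")
  .asFit("3exp", best$par[1:3] * yScale, best$par[4:6], 0,
         window, best$sse * yScale^2, length(x), best$converged)
}

#' Put fitted components into canonical order
#'
#' Component 1 ("anterior") is the decaying component with the largest
#' contribution \eqn{C_0 \exp(\alpha \cdot lo)} at the window start;
#' component 2 ("shallow") is the remaining decaying component; a rising
#' component (\eqn{\alpha > 0}) is always ranked third regardless of
#' magnitude.  Ties in the window-start contribution are broken by the
#' steeper (more negative) alpha first.
#'
#' @param fit a [MultiExpFit-class].
#' @return The fit with components reordered and roles assigned.
#' @export
orderComponents <- function(fit) {
  stopifnot(is(fit, "MultiExpFit"))
  lo <- fit@window[1]
  dec <- which(fit@alpha <= 0)
  ris <- which(fit@alpha > 0)
  contrib <- fit@C0[dec] * exp(fit@alpha[dec] * lo)
  # primary key: contribution at the window start; near-ties (within 1e-9
  # relative) broken by the steeper (more negative) alpha
  key <- -contrib
  if (length(contrib) > 1) {
    scale <- max(contrib, .Machine$double.eps)
    key <- -round(contrib / scale / 1e-9) * 1e-9
  }
  ord <- dec[order(key, fit@alpha[dec])]
  idx <- c(ord, ris)
  roles <- c(c("anterior", "shallow")[seq_along(ord)], rep("rising",
                                                           length(ris)))
  initialize(fit, C0 = fit@C0[idx], alpha = fit@alpha[idx],
             lambda = exp(fit@alpha[idx]), roles = roles)
}

#' Choose between the two- and three-exponential models
#'
#' Fits both models and returns "3exp" only when the three-exponential fit
#' converges, its third component genuinely rises (alpha > 0 with a
#' non-negligible amplitude), and it reduces the SSE by more than
#' `threshold` relative to the two-exponential fit.  Otherwise "2exp".
#' The one-exponential-plus-background model is available via
#' [fitProfile()] for diagnostics only.
#'
#' @param profile an [AxisProfile-class].
#' @param window fit window in \%EL.
#' @param threshold relative SSE reduction required to prefer "3exp"
#'   (default 0.1).
#' @param restarts multi-start count passed to [fitProfile()].
#' @return "2exp" or "3exp", with both candidate fits attached as
#'   attribute `"fits"`.
#' @export
selectModel <- function(profile, window = c(10, 90), threshold = 0.1,
                        restarts = 8L) {
  f2 <- fitProfile(profile, "2exp", window, restarts)
  f3 <- tryCatch(fitProfile(profile, "3exp", window, restarts),
                 error = function(e) NULL)
  kind <- "2exp"
  if (!is.null(f3) && f3@converged) {
    rising <- f3@roles == "rising"
    material <- any(rising) && f3@C0[rising][1] * exp(f3@alpha[rising][1] *
                                                      window[2]) >
      1e-3 * max(evalModel(f2, window[1]), 1e-12)
    if (material && f2@sse > 0 && (f2@sse - f3@sse) / f2@sse > threshold)
      kind <- "3exp"
  }
  structure(kind, fits = list(`2exp` = f2, `3exp` = f3))
}

#' Compute the four staging features from an apical/basal fit pair
#'
#' The features that separate the three main developmental stages:
#' the anterior exponential bases \eqn{\lambda_1} of the apical and basal
#' profiles, the apical:basal log amplitude ratio
#' \eqn{C^{ab} = \ln(C_1^{apical}/C_1^{basal})}, and the shallow-component
#' ratio \eqn{(C_2^{ap}\alpha_2^{ap})/(C_2^{ba}\alpha_2^{ba})}.  Cab and the
#' shallow ratio are invariant under a common positive rescaling of both
#' layers' intensities (robustness to microscope intensity scale).
#'
#' @param fitApical,fitBasal converged [MultiExpFit-class] objects with at
#'   least an anterior component each.
#' @return named numeric vector `lambda1Apical`, `lambda1Basal`, `cab`,
#'   `shallowRatio` (NA when a shallow component is absent).
#' @export
computeFeatures <- function(fitApical, fitBasal) {
  stopifnot(is(fitApical, "MultiExpFit"), is(fitBasal, "MultiExpFit"))
  if (!fitApical@converged || !fitBasal@converged)
    warning("computing features from a non-converged fit")
  aA <- which(fitApical@roles == "anterior")[1]
  aB <- which(fitBasal@roles == "anterior")[1]
  if (is.na(aA) || is.na(aB))
    stop("both fits must contain an anterior (decaying) component")
  sA <- which(fitApical@roles == "shallow")[1]
  sB <- which(fitBasal@roles == "shallow")[1]
  shallow <- if (is.na(sA) || is.na(sB)) NA_real_ else
    (fitApical@C0[sA] * fitApical@alpha[sA]) /
    (fitBasal@C0[sB] * fitBasal@alpha[sB])
  c(lambda1Apical = fitApical@lambda[aA],
    lambda1Basal = fitBasal@lambda[aB],
    cab = log(fitApical@C0[aA] / fitBasal@C0[aB]),
    shallowRatio = shallow)
}

#' Fit every record of a cohort and tabulate staging features
#'
#' Convenience wrapper: fits the chosen model to the apical and basal
#' profile of each [EmbryoRecord-class] and returns one feature row per
#' embryo together with the stage labels.
#'
#' @param records list of [EmbryoRecord-class].
#' @param kind,window,restarts passed to [fitProfile()].
#' @return data.frame with columns embryoId, stage, subgroup and the four
#'   features; the per-record fits are attached as attribute `"fits"`.
#' @export
cohortFeatures <- function(records, kind = "2exp", window = c(10, 90),
                           restarts = 8L) {
  fits <- lapply(records, function(rec) {
    list(apical = fitProfile(rec@apical, kind, window, restarts),
         basal = fitProfile(rec@basal, kind, window, restarts))
  })
  feats <- t(vapply(fits, function(f) computeFeatures(f$apical, f$basal),
                    c(lambda1Apical = 0, lambda1Basal = 0, cab = 0,
                      shallowRatio = 0)))
  colnames(feats) <- c("lambda1Apical", "lambda1Basal", "cab",
                       "shallowRatio")
  out <- data.frame(
    embryoId = vapply(records, function(r) r@embryoId, character(1)),
    stage = vapply(records, function(r) r@stage, character(1)),
    subgroup = vapply(records, function(r) r@subgroup, character(1)),
    feats, stringsAsFactors = FALSE)
  attr(out, "fits") <- fits
  out
}
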