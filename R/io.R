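## Plain-text interchange: profile/cohort CSV, fit tables, TIFF images.

#' Convert between cohorts and long-format data frames
#'
#' The long format has one row per sample: `embryo_id`, `channel`,
#' `layer`, `stage`, `subgroup`, `position_pct_el`, `intensity`.
#'
#' @param records list of [EmbryoRecord-class].
#' @return data.frame in long format.
#' @export
cohortToDataFrame <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    do.call(rbind, lapply(list(r@apical, r@basal), function(p) {
      data.frame(embryo_id = r@embryoId, channel = r@channel,
                 layer = p@layer, stage = r@stage, subgroup = r@subgroup,
                 position_pct_el = p@positions, intensity = p@intensities,
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' @rdname cohortToDataFrame
#' @param df data.frame in the long format above.
#' @return list of [EmbryoRecord-class] (ground truth is not round-tripped).
#' @export
cohortFromDataFrame <- function(df) {
  need <- c("embryo_id", "channel", "layer", "position_pct_el", "intensity")
  if (!all(need %in% colnames(df)))
    stop("missing column(s): ", paste(setdiff(need, colnames(df)),
                                      collapse = ", "))
  blank <- function(v) {
    v <- as.character(v); v[is.na(v)] <- ""; v
  }
  df$stage <- if (is.null(df$stage)) "" else blank(df$stage)
  df$subgroup <- if (is.null(df$subgroup)) "" else blank(df$subgroup)
  lapply(split(df, df$embryo_id), function(d) {
    prof <- function(layer) {
      di <- d[d$layer == layer, ]
      di <- di[order(di$position_pct_el), ]
      AxisProfile(di$position_pct_el, di$intensity, layer = layer,
                  channel = di$channel[1], embryoId = di$embryo_id[1])
    }
    new("EmbryoRecord", apical = prof("apical"), basal = prof("basal"),
        channel = d$channel[1], stage = d$stage[1],
        subgroup = d$subgroup[1], embryoId = d$embryo_id[1], truth = list())
  })
}

#' Read and write cohort CSV files
#'
#' @param records list of [EmbryoRecord-class].
#' @param path CSV path.
#' @export
writeCohortCsv <- function(records, path) {
  utils::write.csv(cohortToDataFrame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortCsv
#' @export
readCohortCsv <- function(path) {
  cohortFromDataFrame(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Tabulate multi-exponential fits
#'
#' One row per fit: kind, per-component C0/alpha/lambda, background,
#' window, SSE, number of points, convergence.
#'
#' @param fits list of [MultiExpFit-class] (optionally named).
#' @return data.frame.
#' @export
fitsToDataFrame <- function(fits) {
  do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    pad <- function(v) c(v, rep(NA_real_, 3 - length(v)))
    d <- data.frame(id = if (!is.null(names(fits))) names(fits)[i] else i,
                    kind = f@kind, t(pad(f@C0)), t(pad(f@alpha)),
                    t(pad(f@lambda)), background = f@background,
                    window_lo = f@window[1], window_hi = f@window[2],
                    sse = f@sse, n_points = f@nPoints,
                    converged = f@converged, stringsAsFactors = FALSE)
    colnames(d)[3:11] <- c(paste0("C0_", 1:3), paste0("alpha_", 1:3),
                           paste0("lambda_", 1:3))
    d
  }))
}

#' Read and write grayscale images as TIFF
#'
#' Images are single-channel matrices; intensities are stored normalized
#' to [0, 1] with the original maximum in the return attribute / argument.
#'
#' @param image numeric matrix.
#' @param path TIFF path.
#' @param bits 8, 16 or 32 bits per sample.
#' @export
writeImageTiff <- function(image, path, bits = 16L) {
  m <- max(image)
  tiff::writeTIFF(image / max(m, 1e-12), path,
                  bits.per.sample = as.integer(bits))
  invisible(path)
}

#' @rdname writeImageTiff
#' @param scale intensity value that 1.0 maps back to (default 1).
#' @export
readImageTiff <- function(path, scale = 1) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m * scale
}
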