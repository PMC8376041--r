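## Developmental staging: LDA on the four profile features, evaluation,
## sub-group trajectories, and permutation tests for group differences.

.featureCols <- c("lambda1Apical", "lambda1Basal", "cab", "shallowRatio")

.asFeatureMatrix <- function(features, featureNames = .featureCols) {
  if (is.data.frame(features)) {
    missing <- setdiff(featureNames, colnames(features))
    if (length(missing))
      stop("missing feature column(s): ", paste(missing, collapse = ", "))
    features <- as.matrix(features[, featureNames, drop = FALSE])
  } else if (is.numeric(features) && is.null(dim(features))) {
    features <- matrix(features, nrow = 1,
                       dimnames = list(NULL, names(features)))
    features <- features[, featureNames, drop = FALSE]
  }
  as.matrix(features)
}

.labelOrder <- function(labels) {
  u <- unique(as.character(labels))
  if (all(u %in% stageLevels())) intersect(stageLevels(), u) else sort(u)
}

#' Fit the linear discriminant stage classifier
#'
#' Standard LDA on the four staging features with empirical class priors.
#' Rows with any missing feature (typically a missing shallow component)
#' are excluded, not imputed, and their count is reported.  If the pooled
#' within-class covariance is singular, a ridge-regularized Gaussian
#' discriminant is used instead (logged).
#'
#' @param features data.frame or matrix with the columns
#'   `lambda1Apical`, `lambda1Basal`, `cab`, `shallowRatio`.
#' @param labels stage labels, one per row.
#' @param priors "empirical" (default) or "uniform".
#' @return A [StageClassifier-class].
#' @export
fitStageClassifier <- function(features, labels,
                               priors = c("empirical", "uniform")) {
  priors <- match.arg(priors)
  x <- .asFeatureMatrix(features)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(x))
  keep <- stats::complete.cases(x)
  nExcluded <- sum(!keep)
  if (nExcluded)
    message(nExcluded, " row(s) excluded for missing feature values")
  x <- x[keep, , drop = FALSE]; labels <- labels[keep]
  lev <- .labelOrder(labels)
  if (length(lev) < 2L) stop("need at least two classes")
  counts <- table(factor(labels, lev))
  if (any(counts <= ncol(x)))
    stop("every class needs more members than features")
  grouping <- factor(labels, levels = lev)
  prior <- if (priors == "empirical") as.numeric(counts) / sum(counts)
           else rep(1 / length(lev), length(lev))

  means <- do.call(rbind, lapply(lev, function(l)
    colMeans(x[labels == l, , drop = FALSE])))
  rownames(means) <- lev
  pooled <- Reduce(`+`, lapply(lev, function(l) {
    xi <- x[labels == l, , drop = FALSE]
    crossprod(scale(xi, center = TRUE, scale = FALSE))
  })) / (nrow(x) - length(lev))

  fit <- tryCatch(MASS::lda(x, grouping = grouping, prior = prior),
                  error = function(e) NULL)
  if (is.null(fit)) {
    message("pooled covariance singular: using ridge-regularized discriminant")
    method <- "rlda"
  } else method <- "lda"
  new("StageClassifier", fit = fit, method = method, labels = lev,
      featureNames = colnames(x), priors = prior, means = means,
      pooledCov = (pooled + t(pooled)) / 2, nExcluded = as.integer(nExcluded))
}

.rldaScores <- function(clf, x) {
  W <- clf@pooledCov
  gamma <- 1e-6 * mean(diag(W))
  Winv <- solve(W + diag(gamma, nrow(W)))
  t(apply(x, 1, function(v)
    vapply(seq_along(clf@labels), function(k) {
      mu <- clf@means[k, ]
      drop(v %*% Winv %*% mu - 0.5 * mu %*% Winv %*% mu +
             log(clf@priors[k]))
    }, numeric(1))))
}

#' Predict developmental stage from features
#'
#' Argmax of the class posterior under the equal-covariance Gaussian model.
#' Exact posterior ties are broken by the classifier's fixed label order
#' (cleavage < syncytial < cc14).
#'
#' @param classifier a [StageClassifier-class].
#' @param features a feature row (named numeric), matrix or data.frame.
#' @return list with `label` (character vector) and `scores` (posterior
#'   matrix, columns in label order).
#' @export
predictStage <- function(classifier, features) {
  x <- .asFeatureMatrix(features, classifier@featureNames)
  if (anyNA(x)) stop("missing feature values; cannot predict")
  if (classifier@method == "lda") {
    p <- stats::predict(classifier@fit, x)$posterior
    p <- p[, classifier@labels, drop = FALSE]
  } else {
    s <- .rldaScores(classifier, x)
    s <- s - apply(s, 1, max)
    p <- exp(s) / rowSums(exp(s))
    colnames(p) <- classifier@labels
  }
  lab <- classifier@labels[max.col(p, ties.method = "first")]
  list(label = lab, scores = p)
}

.accuracyOf <- function(x, labels, scheme, k, lev) {
  n <- nrow(x)
  pred <- rep(NA_character_, n)
  if (scheme == "resubstitution") {
    clf <- suppressMessages(fitStageClassifier(x, labels))
    pred <- predictStage(clf, x)$label
  } else {
    folds <- if (scheme == "loo") as.list(seq_len(n))
             else split(seq_len(n), rep_len(seq_len(k), n))
    for (f in folds) {
      train <- setdiff(seq_len(n), f)
      if (length(unique(labels[train])) < length(lev)) {
        message("fold skipped: a class is absent from its training set")
        next
      }
      clf <- try(suppressMessages(fitStageClassifier(
        x[train, , drop = FALSE], labels[train])), silent = TRUE)
      if (inherits(clf, "try-error")) {
        message("fold skipped: classifier could not be fitted")
        next
      }
      pred[f] <- predictStage(clf, x[f, , drop = FALSE])$label
    }
  }
  list(pred = pred, accuracy = mean(pred == labels, na.rm = TRUE))
}

#' Evaluate staging accuracy by confusion matrix
#'
#' Leave-one-out (default), k-fold or resubstitution evaluation of the
#' stage classifier, with per-class correct fractions and, optionally, a
#' permutation p-value for overall accuracy above chance (labels shuffled,
#' same evaluation scheme).
#'
#' @param features feature data.frame/matrix (rows with missing values are
#'   excluded up front).
#' @param labels stage labels.
#' @param scheme "loo", "kfold" or "resubstitution".
#' @param k folds for "kfold".
#' @param nPerm permutations for the accuracy p-value (0 = skip).
#' @param seed seed for fold assignment and permutations.
#' @return A [ConfusionMatrix-class].
#' @export
evaluateClassifier <- function(features, labels,
                               scheme = c("loo", "kfold", "resubstitution"),
                               k = 5L, nPerm = 0L, seed = 1L) {
  scheme <- match.arg(scheme)
  x <- .asFeatureMatrix(features)
  labels <- as.character(labels)
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]; labels <- labels[keep]
  lev <- .labelOrder(labels)
  if (any(table(factor(labels, lev)) < 2L))
    stop("every class needs at least two members")

  run <- function(lab) .accuracyOf(x, lab, scheme, k, lev)
  res <- withr::with_seed(as.integer(seed), run(labels))
  counts <- table(factor(labels, lev),
                  factor(res$pred, lev), useNA = "no")
  counts <- matrix(as.integer(counts), nrow = length(lev),
                   dimnames = dimnames(counts))
  perClass <- diag(counts) / pmax(rowSums(counts), 1L)

  pval <- NA_real_
  if (nPerm > 0) {
    permAcc <- withr::with_seed(as.integer(seed) + 1L,
      vapply(seq_len(nPerm), function(i)
        suppressMessages(run(sample(labels))$accuracy), numeric(1)))
    pval <- (1 + sum(permAcc >= res$accuracy)) / (nPerm + 1)
  }
  new("ConfusionMatrix", counts = counts, perClass = perClass,
      accuracy = res$accuracy, n = sum(counts), scheme = scheme,
      permutationP = pval)
}

#' Mean-feature trajectory over the nine age sub-groups
#'
#' Per-sub-group mean of each staging feature, in fixed developmental
#' order CleavageEarly -> cc14late.  Empty sub-groups are omitted with a
#' message.
#'
#' @param features data.frame containing the feature columns and a
#'   `subgroup` column (or pass `subgroups` explicitly).
#' @param subgroups optional sub-group label vector.
#' @return data.frame: subgroup, n, and the mean of each feature.
#' @export
subgroupTrajectory <- function(features, subgroups = features$subgroup) {
  x <- .asFeatureMatrix(features)
  subgroups <- as.character(subgroups)
  lev <- subgroupLevels()
  unknown <- setdiff(unique(subgroups), c(lev, ""))
  if (length(unknown))
    stop("unknown sub-group label(s): ", paste(unknown, collapse = ", "))
  present <- lev[lev %in% subgroups]
  absent <- setdiff(lev, present)
  if (length(absent))
    message("empty sub-group(s) omitted: ", paste(absent, collapse = ", "))
  rows <- lapply(present, function(g) {
    xi <- x[subgroups == g, , drop = FALSE]
    data.frame(subgroup = g, n = nrow(xi),
               t(colMeans(xi, na.rm = TRUE)))
  })
  do.call(rbind, rows)
}

#' Permutation test for feature differences between stage groups
#'
#' Per-feature statistic: the between-group sum of squares of group means
#' standardized by the pooled within-group variance; omnibus statistic:
#' the sum over features.  P-values are computed by label shuffling with
#' the add-one correction, so identical groups give p = 1.
#'
#' @param features feature data.frame/matrix.
#' @param labels group labels (two or more groups).
#' @param nPerm number of permutations (default 1000; a warning below 100).
#' @param seed permutation seed (same seed, same p-values).
#' @return list with `perFeature` (named p-values), `omnibus` p-value, and
#'   the observed statistics.
#' @export
testGroupDifference <- function(features, labels, nPerm = 1000L, seed = 1L) {
  x <- .asFeatureMatrix(features)
  labels <- as.character(labels)
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]; labels <- labels[keep]
  if (length(unique(labels)) < 2L) stop("need two or more groups")
  if (nPerm < 100L) warning("fewer than 100 permutations: p-values are coarse")

  stat <- function(lab) {
    vapply(seq_len(ncol(x)), function(j) {
      v <- x[, j]
      grand <- mean(v)
      groups <- split(v, lab)
      between <- sum(vapply(groups, function(g)
        length(g) * (mean(g) - grand)^2, numeric(1)))
      within <- sum(vapply(groups, function(g)
        sum((g - mean(g))^2), numeric(1))) /
        max(length(v) - length(groups), 1L)
      between / max(within, .Machine$double.eps)
    }, numeric(1))
  }
  obs <- stat(labels)
  names(obs) <- colnames(x)
  perms <- withr::with_seed(as.integer(seed),
    vapply(seq_len(nPerm), function(i) stat(sample(labels)),
           numeric(ncol(x))))
  perms <- matrix(perms, nrow = ncol(x))
  perFeature <- vapply(seq_len(ncol(x)), function(j)
    (1 + sum(perms[j, ] >= obs[j])) / (nPerm + 1), numeric(1))
  names(perFeature) <- colnames(x)
  omnibus <- (1 + sum(colSums(perms) >= sum(obs))) / (nPerm + 1)
  list(perFeature = perFeature, omnibus = omnibus, statistics = obs)
}
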