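# Confusion-matrix metrics, balanced subsampling and stratified k-fold
# cross-validation. The positive class is "coding" throughout: TPR (recall /
# sensitivity), PPV (precision), ACC (accuracy) and F1 (harmonic mean of PPV
# and TPR).

#' Confusion-matrix metrics for coding/noncoding predictions
#'
#' Computes TP/FP/TN/FN and the derived rates
#' `TPR = TP / (TP + FN)`, `PPV = TP / (TP + FP)`,
#' `ACC = (TP + TN) / (TP + TN + FP + FN)`, and
#' `F1 = 2 * PPV * TPR / (PPV + TPR)`. A rate whose denominator is zero is
#' reported as `NA` with the `undefined` field naming it, never silently as
#' zero.
#'
#' @param predicted Predicted labels.
#' @param truth True labels, same length.
#' @param positiveClass The positive class (default `"coding"`).
#' @return A list of class `dsnMetrics`: counts `TP`, `FP`, `TN`, `FN`,
#'   rates `TPR`, `PPV`, `ACC`, `F1`, and `undefined` (character vector of
#'   rates with zero denominators).
#' @examples
#' computeMetrics(rep(c("coding", "noncoding"), c(10, 10)),
#'                rep(c("coding", "noncoding"), c(9, 11)))
#' @export
computeMetrics <- function(predicted, truth, positiveClass = "coding") {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have the same length")
  }
  predPos <- as.character(predicted) == positiveClass
  truePos <- as.character(truth) == positiveClass
  TP <- sum(predPos & truePos)
  FP <- sum(predPos & !truePos)
  FN <- sum(!predPos & truePos)
  TN <- sum(!predPos & !truePos)
  undefined <- character(0)
  rate <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      return(NA_real_)
    }
    num / den
  }
  TPR <- rate(TP, TP + FN, "TPR")
  PPV <- rate(TP, TP + FP, "PPV")
  ACC <- rate(TP + TN, TP + TN + FP + FN, "ACC")
  F1 <- if (is.na(TPR) || is.na(PPV) || (PPV + TPR) == 0) {
    undefined <- c(undefined, "F1")
    NA_real_
  } else {
    2 * PPV * TPR / (PPV + TPR)
  }
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 TPR = TPR, PPV = PPV, ACC = ACC, F1 = F1,
                 undefined = undefined),
            class = "dsnMetrics")
}

#' @export
print.dsnMetrics <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("TPR=%.4f PPV=%.4f ACC=%.4f F1=%.4f\n",
              x$TPR, x$PPV, x$ACC, x$F1))
  if (length(x$undefined)) {
    cat("undefined (zero denominator):", paste(x$undefined, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Harmonic-mean F1 score from precision and sensitivity
#'
#' @param ppv Precision (positive predictive value), in `[0, 1]` or percent.
#' @param tpr Sensitivity (true positive rate), same scale as `ppv`.
#' @return `2 * ppv * tpr / (ppv + tpr)`, on the input scale.
#' @export
f1Score <- function(ppv, tpr) 2 * ppv * tpr / (ppv + tpr)

#' Column-wise average of a table of per-run metric summaries
#'
#' Summary tables of repeated cross-validation runs report one
#' `mean +/- sd` pair per metric and run; the overall row of such a table is
#' the column-wise mean of every numeric column (both the means and the
#' deviations).
#'
#' @param tbl A data.frame of per-run summaries; non-numeric columns are
#'   dropped.
#' @return Named numeric vector of column means.
#' @export
averageMetricRows <- function(tbl) {
  num <- vapply(tbl, is.numeric, logical(1))
  colMeans(as.data.frame(tbl)[, num, drop = FALSE])
}

#' Balanced subsample of labeled candidates
#'
#' Draws exactly `nPerClass` members of each class uniformly at random
#' without replacement, as used to build balanced training sets.
#'
#' @param labels Class label vector, or an ORF table / data.frame with a
#'   `label` column.
#' @param nPerClass Number of samples to keep per class.
#' @param seed Optional integer seed.
#' @return Integer vector of selected indices (rows), sorted.
#' @export
sampleBalanced <- function(labels, nPerClass, seed = NULL) {
  if (!is.null(dim(labels)) || methods::is(labels, "DataFrame")) {
    labels <- labels$label
  }
  labels <- as.character(labels)
  idxByClass <- split(seq_along(labels), labels)
  small <- names(idxByClass)[lengths(idxByClass) < nPerClass]
  if (length(small)) {
    stop("class '", small[1L], "' has only ",
         length(idxByClass[[small[1L]]]), " members; ", nPerClass,
         " requested")
  }
  withSeed(seed, {
    sel <- lapply(idxByClass, sample, size = nPerClass)
  })
  sort(unlist(sel, use.names = FALSE))
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin into k folds, so fold sizes differ by at most 1 per class.
.stratifiedFolds <- function(labels, k, seed = NULL) {
  folds <- integer(length(labels))
  withSeed(seed, {
    for (idx in split(seq_along(labels), labels)) {
      folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Stratified k-fold cross-validation of the DSN classifier
#'
#' Splits the samples into `k` stratified, disjoint folds covering all data,
#' retrains the model on each training split and evaluates on the held-out
#' fold. Reports per-fold metrics and their mean and sample standard
#' deviation (the `mean +/- sd` convention; `sd` uses the n-1 denominator).
#'
#' @param x `D x N` feature matrix or a `SummarizedExperiment` (see
#'   [trainDsn()]).
#' @param y Labels (ignored for a `SummarizedExperiment`).
#' @param k Number of folds (default 10).
#' @param config A [dsnTrainConfig()]; its seed is offset per fold so folds
#'   are independent but reproducible.
#' @param seed Seed for the fold assignment.
#' @param positiveClass Positive class label.
#' @return A list: `perFold` (data.frame of fold, TPR, PPV, ACC, F1),
#'   `summary` (data.frame with `mean` and `sd` per metric), and `folds`
#'   (the fold assignment vector).
#' @export
kfoldCv <- function(x, y = NULL, k = 10L, config = dsnTrainConfig(),
                    seed = 1L, positiveClass = "coding") {
  if (methods::is(x, "SummarizedExperiment")) {
    y <- SummarizedExperiment::colData(x)$label
    x <- SummarizedExperiment::assay(x)
  }
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(k >= 2L, length(y) == ncol(x))
  folds <- .stratifiedFolds(y, k, seed = seed)
  perFold <- vector("list", k)
  for (fold in seq_len(k)) {
    trainIdx <- which(folds != fold)
    testIdx <- which(folds == fold)
    if (length(unique(y[trainIdx])) < 2L) {
      stop("fold ", fold, ": a class is absent from the training split")
    }
    cfg <- config
    cfg$seed <- config$seed + fold
    fit <- trainDsn(x[, trainIdx, drop = FALSE], y[trainIdx], cfg,
                    positiveClass = positiveClass)
    pred <- predictDsn(fit, x[, testIdx, drop = FALSE])
    met <- computeMetrics(pred$label, y[testIdx],
                          positiveClass = positiveClass)
    perFold[[fold]] <- data.frame(fold = fold, TPR = met$TPR, PPV = met$PPV,
                                  ACC = met$ACC, F1 = met$F1)
  }
  perFold <- do.call(rbind, perFold)
  metricCols <- c("TPR", "PPV", "ACC", "F1")
  summary <- data.frame(
    metric = metricCols,
    mean = vapply(perFold[metricCols], mean, numeric(1)),
    sd = vapply(perFold[metricCols], sd, numeric(1)),
    row.names = NULL
  )
  list(perFold = perFold, summary = summary, folds = folds)
}

#' Write a metrics object or CV summary as JSON
#'
#' @param x A `dsnMetrics` object or the result of [kfoldCv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMetricsJson <- function(x, path) {
  if (inherits(x, "dsnMetrics")) {
    x <- unclass(x)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
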