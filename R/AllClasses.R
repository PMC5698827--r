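#' DsnModel: a trained deep stacking network
#'
#' Container for the ordered list of DSN modules (each a lower weight matrix
#' `W`, bias row included, and an upper weight matrix `U`), together with the
#' per-feature input scaling fitted on the training data, the class labels,
#' and an echo of the training configuration. Module `m` takes as input the
#' standardized raw features concatenated with the outputs of all previous
#' modules plus a constant bias row, so its `W` has
#' `dRaw + (m - 1) * C + 1` rows.
#'
#' @slot modules List of modules; each is `list(W =, U =)`.
#' @slot scalerCenter,scalerScale Per-feature affine standardization (z-score)
#'   applied to raw inputs before the network.
#' @slot minmaxMin,minmaxRange Per-feature min-max scaling to `[0, 1]` used
#'   for the Bernoulli RBM pretraining of the bottom module.
#' @slot dRaw Raw feature dimension (119 for the full fused descriptor).
#' @slot classes Class labels in output order (positive class first).
#' @slot featureNames Names of the raw features the model expects, in order.
#' @slot config Training configuration echo (see [dsnTrainConfig()]).
#' @slot trainError Per-module total squared error on the training data.
#' @slot version Model container format version.
#' @seealso [trainDsn()], [predictDsn()], [writeDsnModel()], [readDsnModel()]
#' @export
setClass("DsnModel", representation(
  modules = "list",
  scalerCenter = "numeric",
  scalerScale = "numeric",
  minmaxMin = "numeric",
  minmaxRange = "numeric",
  dRaw = "integer",
  classes = "character",
  featureNames = "character",
  config = "list",
  trainError = "numeric",
  version = "character"
))

setValidity("DsnModel", function(object) {
  msgs <- character(0)
  C <- length(object@classes)
  if (C < 2L) msgs <- c(msgs, "model must have at least 2 classes")
  if (length(object@scalerCenter) != object@dRaw ||
      length(object@scalerScale) != object@dRaw) {
    msgs <- c(msgs, "scaler length must equal dRaw")
  }
  for (m in seq_along(object@modules)) {
    mod <- object@modules[[m]]
    if (!all(c("W", "U") %in% names(mod))) {
      msgs <- c(msgs, sprintf("module %d lacks W/U", m))
      next
    }
    expectedD <- object@dRaw + (m - 1L) * C + 1L
    if (nrow(mod$W) != expectedD) {
      msgs <- c(msgs, sprintf(
        "module %d: W has %d rows, expected dRaw + (m-1)*C + 1 = %d",
        m, nrow(mod$W), expectedD))
    }
    if (ncol(mod$W) != nrow(mod$U)) {
      msgs <- c(msgs, sprintf("module %d: ncol(W) != nrow(U)", m))
    }
    if (ncol(mod$U) != C) {
      msgs <- c(msgs, sprintf("module %d: ncol(U) != number of classes", m))
    }
    if (!all(is.finite(mod$W)) || !all(is.finite(mod$U))) {
      msgs <- c(msgs, sprintf("module %d: non-finite weights", m))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn DsnModel compact description of the stacked architecture
#' @param object A `DsnModel`.
#' @export
setMethod("show", "DsnModel", function(object) {
  C <- length(object@classes)
  L <- if (length(object@modules)) ncol(object@modules[[1L]]$W) else 0L
  cat("DsnModel (deep stacking network)\n",
      "  modules:      ", length(object@modules), "\n",
      "  hidden units: ", L, "\n",
      "  raw features: ", object@dRaw, "\n",
      "  classes:      ", paste(object@classes, collapse = ", "), "\n",
      sep = "")
  if (length(object@trainError)) {
    cat("  training squared error by module: ",
        paste(signif(object@trainError, 6), collapse = " -> "), "\n",
        sep = "")
  }
})

#' Number of stacked modules in a DsnModel
#' @param model A [DsnModel-class] object.
#' @return Integer count of modules.
#' @export
nModules <- function(model) length(model@modules)

#' Class labels of a DsnModel
#' @param model A [DsnModel-class] object.
#' @return Character vector of class labels, positive class first.
#' @export
modelClasses <- function(model) model@classes
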