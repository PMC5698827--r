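# Deep stacking network.
#
# Each module is a single-hidden-layer perceptron: H = sigma(W' X_m),
# Y = U' H, with squared error E = ||Y - T||^2. For fixed W the optimal
# upper weights have the closed form U = (H H')^{-1} H T' (a small ridge
# keeps the solve well-posed). Modules are stacked by concatenating each
# module's output with the raw input; the bottom module's W is pretrained
# as a Bernoulli restricted Boltzmann machine, upper modules start from
# fan-in-scaled random weights, and every module's W can be fine-tuned by
# batch gradient descent on E with U eliminated through its closed form.

#' Training configuration for a deep stacking network
#'
#' Collects every hyperparameter of [trainDsn()] with the package defaults:
#' 3 stacked modules of 128 hidden units; Bernoulli RBM pretraining by CD-1
#' for 10 epochs at learning rate 0.1 with minibatches of 100; fine tuning
#' for 20 epochs at learning rate `eta = 1e-3` with step halving whenever a
#' step would increase the squared error; ridge `1e-8` in the closed-form
#' solve.
#'
#' @param nModules Number of stacked modules.
#' @param hiddenUnits Hidden units per module (`L`).
#' @param rbm List of RBM settings: `cdSteps` (contrastive divergence steps),
#'   `epochs`, `learningRate`, `batchSize`.
#' @param fineTune List: `enabled`, `eta` (gradient step size), `epochs`.
#' @param ridgeEps Ridge added to `H H'` in the closed-form solve.
#' @param seed Integer seed controlling all randomness in training.
#' @return A list of class `dsnTrainConfig`.
#' @export
dsnTrainConfig <- function(nModules = 3L, hiddenUnits = 128L,
                           rbm = list(), fineTune = list(),
                           ridgeEps = 1e-8, seed = 1L) {
  rbm <- modifyList(list(cdSteps = 1L, epochs = 10L, learningRate = 0.1,
                         batchSize = 100L), rbm)
  fineTune <- modifyList(list(enabled = TRUE, eta = 1e-3, epochs = 20L),
                         fineTune)
  stopifnot(nModules >= 1L, hiddenUnits >= 1L, ridgeEps >= 0,
            rbm$cdSteps >= 1L, rbm$epochs >= 1L, rbm$learningRate > 0,
            rbm$batchSize >= 1L, fineTune$epochs >= 0L)
  if (isTRUE(fineTune$enabled) && fineTune$eta <= 0) {
    stop("fine-tune learning rate eta must be > 0 when fine tuning is enabled")
  }
  structure(list(nModules = as.integer(nModules),
                 hiddenUnits = as.integer(hiddenUnits),
                 rbm = rbm, fineTune = fineTune,
                 ridgeEps = ridgeEps, seed = as.integer(seed)),
            class = "dsnTrainConfig")
}

#' Pretrain a Bernoulli RBM by contrastive divergence
#'
#' Trains a Bernoulli--Bernoulli restricted Boltzmann machine on inputs
#' scaled to `[0, 1]` (treated as visible-unit probabilities) with CD-k, and
#' returns the learned weights with the hidden bias folded in as a final
#' bias row, ready to serve as the bottom DSN module's lower weight matrix.
#'
#' @param X `D x N` matrix with entries in `[0, 1]`.
#' @param hiddenUnits Number of hidden units (`L > 0`).
#' @param cdSteps Contrastive divergence steps (default 1).
#' @param epochs Training epochs.
#' @param learningRate Learning rate.
#' @param batchSize Minibatch size (columns).
#' @param seed Integer seed; the same seed gives identical weights.
#' @return A list: `W` (`(D+1) x L` weights, bias row last), `vbias`,
#'   and `reconError` (mean squared reconstruction error per epoch, with the
#'   error at initialization first).
#' @export
trainRbm <- function(X, hiddenUnits, cdSteps = 1L, epochs = 10L,
                     learningRate = 0.1, batchSize = 100L, seed = 1L) {
  if (hiddenUnits < 1L) stop("hiddenUnits must be >= 1")
  if (!all(is.finite(X))) stop("RBM input contains non-finite values")
  if (min(X) < 0 || max(X) > 1) {
    stop("RBM input must be scaled to [0, 1]")
  }
  D <- nrow(X); N <- ncol(X); L <- as.integer(hiddenUnits)
  withSeed(seed, {
    W <- matrix(rnorm(D * L, sd = 0.01), D, L)
    hbias <- numeric(L)
    vbias <- numeric(D)
    reconOf <- function() {
      hp <- sigmoid(crossprod(W, X) + hbias)
      vp <- sigmoid(W %*% hp + vbias)
      mean((X - vp)^2)
    }
    recon <- reconOf()
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      for (b in split(ord, ceiling(seq_along(ord) / batchSize))) {
        v0 <- X[, b, drop = FALSE]
        nb <- length(b)
        h0p <- sigmoid(crossprod(W, v0) + hbias)
        hs <- matrix(as.numeric(runif(L * nb) < h0p), L, nb)
        for (k in seq_len(cdSteps)) {
          vp <- sigmoid(W %*% hs + vbias)
          hp <- sigmoid(crossprod(W, vp) + hbias)
          if (k < cdSteps) {
            hs <- matrix(as.numeric(runif(L * nb) < hp), L, nb)
          }
        }
        W <- W + learningRate * (tcrossprod(v0, h0p) - tcrossprod(vp, hp)) / nb
        vbias <- vbias + learningRate * rowMeans(v0 - vp)
        hbias <- hbias + learningRate * rowMeans(h0p - hp)
      }
      recon <- c(recon, reconOf())
    }
  })
  list(W = rbind(W, bias = hbias), vbias = vbias, reconError = recon)
}

#' Closed-form upper (output) weights of a DSN module
#'
#' For fixed hidden activations `H` the upper weights minimizing
#' `||U' H - T||^2` are `U = (H H' + ridgeEps I)^{-1} H T'`.
#'
#' @param H `L x N` hidden-layer output matrix.
#' @param T `C x N` target matrix (one-hot class coding).
#' @param ridgeEps Ridge term guaranteeing solvability (default 1e-8; 0 gives
#'   the plain normal equations).
#' @return The `L x C` weight matrix `U`.
#' @export
fitUpperWeights <- function(H, T, ridgeEps = 1e-8) {
  if (ncol(H) != ncol(T)) stop("H and T must have the same number of columns")
  A <- tcrossprod(H)
  if (ridgeEps > 0) {
    A <- A + diag(ridgeEps, nrow(H))
  }
  solve(A, H %*% t(T))
}

# Squared-error objective of one module with U refit in closed form.
.moduleObjective <- function(W, X, T, ridgeEps) {
  H <- sigmoid(crossprod(W, X))
  U <- fitUpperWeights(H, T, ridgeEps)
  R <- crossprod(U, H) - T
  list(E = sum(R^2), H = H, U = U, R = R)
}

# Gradient of E(W) = ||U*(W)' sigma(W'X) - T||^2 with U*(W) the closed-form
# minimizer. Because U* is optimal, the envelope theorem reduces dE/dW to the
# partial derivative through H with U held fixed:
#   dE/dW = X [ (2 U (U'H - T)) o H o (1 - H) ]'
.moduleGradient <- function(W, X, T, ridgeEps) {
  obj <- .moduleObjective(W, X, T, ridgeEps)
  G <- 2 * (obj$U %*% obj$R)           # L x N back-propagated error
  grad <- X %*% t(G * obj$H * (1 - obj$H))
  if (!all(is.finite(grad))) {
    stop("non-finite gradient in fine tuning (||W|| = ",
         signif(sqrt(sum(W^2)), 6), ", E = ", signif(obj$E, 6), ")")
  }
  list(grad = grad, E = obj$E)
}

#' Fine-tune a module's lower weights by batch gradient descent
#'
#' Minimizes the module's squared error as a function of `W` alone, with the
#' upper weights eliminated through their closed-form solution (refit after
#' every step). Steps that would increase the error are halved until they
#' descend, so the error never increases across accepted steps.
#'
#' @param W Initial `D_m x L` lower weight matrix.
#' @param X `D_m x N` module input (bias row included).
#' @param T `C x N` targets.
#' @param eta Learning rate (> 0).
#' @param epochs Number of gradient steps.
#' @param ridgeEps Ridge for the embedded closed-form solve.
#' @param maxHalvings Step halvings tried per epoch before stopping early.
#' @return A list: `W` (updated weights), `E` (squared-error trace, starting
#'   value first).
#' @export
fineTuneWeights <- function(W, X, T, eta, epochs, ridgeEps = 1e-8,
                            maxHalvings = 30L) {
  stopifnot(eta > 0, epochs >= 0)
  Etrace <- .moduleObjective(W, X, T, ridgeEps)$E
  for (ep in seq_len(epochs)) {
    g <- .moduleGradient(W, X, T, ridgeEps)
    step <- eta
    accepted <- FALSE
    for (h in seq_len(maxHalvings)) {
      Wnew <- W - step * g$grad
      Enew <- .moduleObjective(Wnew, X, T, ridgeEps)$E
      if (Enew <= g$E) {
        W <- Wnew
        Etrace <- c(Etrace, Enew)
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break  # at (numerical) stationarity; keep current W
  }
  list(W = W, E = Etrace)
}

#' Stack the input for DSN module m
#'
#' Concatenates the raw (standardized) input with the outputs of all previous
#' modules and appends a constant bias row.
#'
#' @param Xraw `D x N` raw input matrix.
#' @param previousOutputs List of `C x N` output matrices of modules
#'   `1 .. m-1`, in module order.
#' @return `(D + (m-1) C + 1) x N` input matrix for module `m`.
#' @export
stackInput <- function(Xraw, previousOutputs = list()) {
  for (Y in previousOutputs) {
    if (ncol(Y) != ncol(Xraw)) {
      stop("previous module output has ", ncol(Y),
           " columns; expected ", ncol(Xraw))
    }
  }
  rows <- c(list(Xraw), previousOutputs,
            list(bias = matrix(1, 1L, ncol(Xraw))))
  do.call(rbind, rows)
}

# One-hot target matrix, positive class in row 1.
.oneHot <- function(y, classes) {
  T <- matrix(0, length(classes), length(y),
              dimnames = list(classes, NULL))
  T[cbind(match(y, classes), seq_along(y))] <- 1
  T
}

.orderClasses <- function(y, positiveClass) {
  cls <- sort(unique(as.character(y)))
  if (!is.null(positiveClass) && positiveClass %in% cls) {
    cls <- c(positiveClass, setdiff(cls, positiveClass))
  }
  cls
}

#' Train a deep stacking network classifier
#'
#' Fits per-feature scaling on the training data, pretrains the bottom
#' module's lower weights as a Bernoulli RBM on min-max scaled inputs, and
#' warm-starts each upper module from its predecessor (shared input rows
#' copied, the rows for the newly stacked output initialized with small
#' seeded random values). Each module is then trained in turn: closed-form
#' upper weights, optional gradient fine tuning of the lower weights (with
#' the upper weights refit afterwards), and stacking of the module output
#' into the next module's input. Fully deterministic given `config$seed`.
#'
#' @param x `D x N` numeric feature matrix (features in rows, e.g. from
#'   [featureMatrix()]), or a [SummarizedExperiment::SummarizedExperiment]
#'   whose first assay is the feature matrix and whose `colData` has a
#'   `label` column.
#' @param y Class labels, one per column of `x` (ignored when `x` is a
#'   `SummarizedExperiment`). Exactly the two-class case is supported well;
#'   the positive class is put first in the output ordering.
#' @param config A [dsnTrainConfig()].
#' @param positiveClass Label treated as the positive class (default
#'   `"coding"` when present).
#' @return A [DsnModel-class] object.
#' @examples
#' set.seed(1)
#' x <- cbind(matrix(rnorm(10 * 200), 10), matrix(rnorm(10 * 200, 2), 10))
#' y <- rep(c("coding", "noncoding"), each = 200)
#' fit <- trainDsn(x, y, dsnTrainConfig(nModules = 1, hiddenUnits = 16))
#' mean(predictDsn(fit, x)$label == y)
#' @export
trainDsn <- function(x, y = NULL, config = dsnTrainConfig(),
                     positiveClass = "coding") {
  if (methods::is(x, "SummarizedExperiment")) {
    y <- SummarizedExperiment::colData(x)$label
    x <- SummarizedExperiment::assay(x)
  }
  x <- as.matrix(x)
  y <- as.character(y)
  if (length(y) != ncol(x)) {
    stop("length(y) must equal ncol(x)")
  }
  classes <- .orderClasses(y, positiveClass)
  if (length(classes) < 2L) {
    stop("training data must contain at least 2 classes; found: ",
         paste(classes, collapse = ", "))
  }
  D <- nrow(x); N <- ncol(x); C <- length(classes)
  L <- config$hiddenUnits

  center <- rowMeans(x)
  scale <- apply(x, 1L, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  Z <- (x - center) / scale

  mmMin <- apply(x, 1L, min)
  mmRange <- apply(x, 1L, max) - mmMin
  mmRange[mmRange == 0] <- 1
  X01 <- (x - mmMin) / mmRange

  T <- .oneHot(y, classes)
  modules <- vector("list", config$nModules)
  trainError <- numeric(config$nModules)
  outputs <- list()
  for (m in seq_len(config$nModules)) {
    Xm <- stackInput(Z, outputs)
    Dm <- nrow(Xm)
    if (m == 1L) {
      rbm <- trainRbm(X01, hiddenUnits = L,
                      cdSteps = config$rbm$cdSteps,
                      epochs = config$rbm$epochs,
                      learningRate = config$rbm$learningRate,
                      batchSize = config$rbm$batchSize,
                      seed = config$seed)
      W <- rbm$W  # (D+1) x L: RBM weights with hidden bias as bias row
    } else {
      # warm start: copy the previous module's weights for the shared input
      # rows and give the new rows (previous output + bias shift) small
      # seeded random values, so the module begins where its predecessor
      # ended and fine tuning can only improve on it
      Wprev <- modules[[m - 1L]]$W
      shared <- nrow(Wprev) - 1L
      Wnew <- withSeed(config$seed + m,
                       matrix(rnorm(C * L, sd = 0.01), C, L))
      W <- rbind(Wprev[seq_len(shared), , drop = FALSE],
                 Wnew,
                 Wprev[shared + 1L, , drop = FALSE])
    }
    if (isTRUE(config$fineTune$enabled) && config$fineTune$epochs > 0L) {
      ft <- fineTuneWeights(W, Xm, T, eta = config$fineTune$eta,
                            epochs = config$fineTune$epochs,
                            ridgeEps = config$ridgeEps)
      W <- ft$W
    }
    H <- sigmoid(crossprod(W, Xm))
    U <- fitUpperWeights(H, T, config$ridgeEps)
    Y <- crossprod(U, H)
    trainError[m] <- sum((Y - T)^2)
    modules[[m]] <- list(W = unname(W), U = unname(U))
    outputs[[m]] <- Y
  }
  methods::new("DsnModel",
               modules = modules,
               scalerCenter = unname(center),
               scalerScale = unname(scale),
               minmaxMin = unname(mmMin),
               minmaxRange = unname(mmRange),
               dRaw = D,
               classes = classes,
               featureNames = rownames(x) %||% character(0),
               config = unclass(config),
               trainError = trainError,
               version = "1.0")
}

#' Predict coding/noncoding labels with a trained DSN
#'
#' Propagates raw feature vectors through the stacked modules (standardizing
#' with the scaler stored in the model) and reads scores off the final
#' module's output. The predicted label is the argmax class; softmax-
#' normalized scores are reported for ranking.
#'
#' @param model A [DsnModel-class] object.
#' @param x `D x N` raw feature matrix (same feature order as in training),
#'   or a `SummarizedExperiment` with the feature assay.
#' @return A `data.frame` with one row per sample: `label`, one
#'   `score_<class>` column per class (softmax), and `raw_<class>` columns
#'   with the unnormalized network outputs.
#' @export
predictDsn <- function(model, x) {
  if (methods::is(x, "SummarizedExperiment")) {
    x <- SummarizedExperiment::assay(x)
  }
  x <- as.matrix(x)
  if (nrow(x) != model@dRaw) {
    stop("feature dimension ", nrow(x), " does not match the model's ",
         model@dRaw)
  }
  Z <- (x - model@scalerCenter) / model@scalerScale
  outputs <- list()
  Y <- NULL
  for (m in seq_along(model@modules)) {
    Xm <- stackInput(Z, outputs)
    H <- sigmoid(crossprod(model@modules[[m]]$W, Xm))
    Y <- crossprod(model@modules[[m]]$U, H)
    outputs[[m]] <- Y
  }
  sm <- exp(Y - rep(apply(Y, 2L, max), each = nrow(Y)))
  sm <- sm / rep(colSums(sm), each = nrow(sm))
  lab <- model@classes[apply(Y, 2L, which.max)]
  out <- data.frame(label = lab, stringsAsFactors = FALSE)
  for (i in seq_along(model@classes)) {
    out[[paste0("score_", model@classes[i])]] <- sm[i, ]
  }
  for (i in seq_along(model@classes)) {
    out[[paste0("raw_", model@classes[i])]] <- Y[i, ]
  }
  rownames(out) <- colnames(x)
  out
}

#' @describeIn predictDsn S4 `predict` method delegating to `predictDsn()`
#' @param object A `DsnModel`.
#' @param newdata Feature matrix.
#' @param ... Ignored.
#' @export
setMethod("predict", "DsnModel", function(object, newdata, ...) {
  predictDsn(object, newdata)
})
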