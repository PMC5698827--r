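test_that("RBM pretraining is seeded, contract-checked, and learns", {
  set.seed(5)
  # two-cluster binary data
  X <- cbind(matrix(rbinom(12 * 60, 1, 0.9), 12),
             matrix(rbinom(12 * 60, 1, 0.1), 12))
  a <- trainRbm(X, hiddenUnits = 8, seed = 42)
  b <- trainRbm(X, hiddenUnits = 8, seed = 42)
  expect_identical(a$W, b$W)
  expect_identical(dim(a$W), c(13L, 8L))  # bias row appended
  # mean reconstruction error after training below the value at init
  expect_lt(tail(a$reconError, 1), a$reconError[1])
  expect_error(trainRbm(X, hiddenUnits = 0), "hiddenUnits")
  expect_error(trainRbm(X * 2, hiddenUnits = 4), "\\[0, 1\\]")
  expect_error(trainRbm(X * NA, hiddenUnits = 4), "non-finite")
})

test_that("closed-form upper weights solve the least-squares problem", {
  set.seed(6)
  # square invertible H: zero residual without ridge
  H <- matrix(rnorm(25), 5)
  T <- matrix(rnorm(10), 2)
  U <- fitUpperWeights(H, T, ridgeEps = 0)
  expect_equal(crossprod(U, H), T, tolerance = 1e-9)

  # overdetermined case against an independent QR least-squares solve
  H <- abs(matrix(rnorm(6 * 40), 6))
  T <- matrix(rnorm(2 * 40), 2)
  U <- fitUpperWeights(H, T, ridgeEps = 0)
  Uo <- qr.solve(t(H), t(T))
  expect_lt(max(abs(U - Uo)), 1e-8)

  # optimality: no random perturbation does better
  E <- sum((crossprod(U, H) - T)^2)
  for (i in 1:200) {
    dU <- matrix(rnorm(length(U), sd = 0.1), nrow(U))
    expect_gte(sum((crossprod(U + dU, H) - T)^2), E)
  }
  expect_error(fitUpperWeights(H, T[, 1:10]), "same number of columns")
})

test_that("the analytic fine-tuning gradient matches finite differences", {
  set.seed(7)
  D <- 5L; L <- 4L; N <- 8L; C <- 2L
  X <- rbind(matrix(rnorm((D - 1) * N), D - 1), 1)
  T <- matrix(0, C, N); T[cbind(sample(1:C, N, TRUE), 1:N)] <- 1
  W <- matrix(rnorm(D * L, sd = 0.5), D, L)
  eps <- 1e-6
  ridge <- 1e-8
  objective <- function(W) {
    H <- 1 / (1 + exp(-crossprod(W, X)))
    U <- fitUpperWeights(H, T, ridge)
    sum((crossprod(U, H) - T)^2)
  }
  g <- MetaGeneDSN:::.moduleGradient(W, X, T, ridge)$grad
  fd <- matrix(0, D, L)
  for (i in seq_len(D)) for (j in seq_len(L)) {
    Wp <- W; Wp[i, j] <- W[i, j] + eps
    Wm <- W; Wm[i, j] <- W[i, j] - eps
    fd[i, j] <- (objective(Wp) - objective(Wm)) / (2 * eps)
  }
  relErr <- max(abs(g - fd)) / max(abs(fd))
  expect_lt(relErr, 1e-5)
})

test_that("fine tuning never increases the module error", {
  set.seed(8)
  D <- 10L; L <- 6L; N <- 80L
  X <- rbind(matrix(rnorm((D - 1) * N), D - 1), 1)
  y <- sample(c("coding", "noncoding"), N, TRUE)
  T <- rbind(as.numeric(y == "coding"), as.numeric(y == "noncoding"))
  W <- matrix(rnorm(D * L, sd = 0.3), D, L)
  ft <- fineTuneWeights(W, X, T, eta = 1e-3, epochs = 25)
  expect_true(all(diff(ft$E) <= 1e-12))
  expect_lt(tail(ft$E, 1), ft$E[1])
  # zero epochs is a no-op
  expect_identical(fineTuneWeights(W, X, T, eta = 1e-3, epochs = 0)$W, W)
})

test_that("stacked inputs concatenate raw features, outputs, and a bias row", {
  X <- matrix(rnorm(119 * 10), 119)
  X1 <- stackInput(X)
  expect_identical(dim(X1), c(120L, 10L))
  expect_equal(X1[1:119, ], X)
  expect_true(all(X1[120, ] == 1))
  Y1 <- matrix(rnorm(20), 2); Y2 <- matrix(rnorm(20), 2)
  X3 <- stackInput(X, list(Y1, Y2))
  expect_identical(nrow(X3), 119L + 4L + 1L)  # 124 for module 3
  expect_equal(X3[120:121, ], Y1)
  expect_error(stackInput(X, list(matrix(0, 2, 9))), "columns")
})

test_that("training separates linearly separable classes and is seeded", {
  set.seed(9)
  x <- cbind(matrix(rnorm(10 * 200), 10), matrix(rnorm(10 * 200, mean = 2), 10))
  y <- rep(c("coding", "noncoding"), each = 200)
  cfg <- tinyConfig(seed = 4, nModules = 1L)
  fit <- trainDsn(x, y, cfg)
  pred <- predictDsn(fit, x)
  expect_gte(mean(pred$label == y), 0.95)

  # bit-identical model files from identical config + seed
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  writeDsnModel(fit, f1)
  writeDsnModel(trainDsn(x, y, cfg), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(trainDsn(x, rep("coding", 400), cfg), "2 classes")
})

test_that("stacking never worsens training error and deepens the fit", {
  set.seed(10)
  x <- cbind(matrix(rnorm(20 * 150), 20),
             matrix(rnorm(20 * 150, mean = 1), 20))
  y <- rep(c("coding", "noncoding"), each = 150)
  fit <- trainDsn(x, y, tinyConfig(seed = 2, nModules = 3L))
  err <- fit@trainError
  expect_length(err, 3L)
  # monotone within 1% tolerance (empirical property of the stack)
  expect_true(all(diff(err) <= 0.01 * err[-length(err)]))
})

test_that("prediction validates dimensions and is deterministic", {
  set.seed(12)
  x <- cbind(matrix(rnorm(8 * 100), 8), matrix(rnorm(8 * 100, 1.5), 8))
  y <- rep(c("coding", "noncoding"), each = 100)
  fit <- trainDsn(x, y, tinyConfig(seed = 1, nModules = 2L))
  expect_error(predictDsn(fit, x[1:5, ]), "does not match")
  two <- predictDsn(fit, cbind(x[, 1], x[, 1]))
  expect_equal(two$score_coding[1], two$score_coding[2])
  expect_equal(rowSums(as.matrix(two[, c("score_coding", "score_noncoding")])),
               c(1, 1))
  # S4 predict delegates
  expect_identical(predict(fit, x[, 1:5]), predictDsn(fit, x[, 1:5]))
})

test_that("a permutation null gives chance-level cross-validated accuracy", {
  set.seed(13)
  n <- 300
  x <- matrix(rnorm(15 * n), 15)
  y <- sample(rep(c("coding", "noncoding"), each = n / 2))
  cv <- kfoldCv(x, y, k = 10, config = tinyConfig(seed = 3, nModules = 1L),
                seed = 21)
  acc <- cv$summary$mean[cv$summary$metric == "ACC"]
  expect_gt(acc, 0.40)
  expect_lt(acc, 0.60)
})

test_that("model JSON round-trips exactly and rejects foreign files", {
  set.seed(14)
  x <- cbind(matrix(rnorm(6 * 60), 6), matrix(rnorm(6 * 60, 2), 6))
  y <- rep(c("coding", "noncoding"), each = 60)
  fit <- trainDsn(x, y, tinyConfig(seed = 8, nModules = 2L))
  f <- withr::local_tempfile(fileext = ".json")
  writeDsnModel(fit, f)
  back <- readDsnModel(f)
  expect_equal(back@modules, fit@modules)
  expect_equal(back@scalerCenter, fit@scalerCenter)
  expect_identical(back@classes, fit@classes)
  expect_identical(predictDsn(back, x), predictDsn(fit, x))

  writeLines('{"format": "something-else"}', f)
  expect_error(readDsnModel(f), "not a MetaGeneDSN model")
})
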