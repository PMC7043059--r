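test_that("unit-interval scaling uses train statistics and clips", {
  m <- matrix(c(2, 3, 4, 7, 7, 7), 3, 2,
              dimnames = list(paste0("M", 1:3), c("D1", "D2")))
  sc <- fitUnitScaler(m)
  out <- applyUnitScaler(sc, m)
  expect_equal(out[, "D1"], c(M1 = 0, M2 = 0.5, M3 = 1))
  expect_true(all(out[, "D2"] == 0))  # constant feature maps to 0
  test <- matrix(c(-5, 10, 7, 7), 2, 2,
                 dimnames = list(c("T1", "T2"), c("D1", "D2")))
  outT <- applyUnitScaler(sc, test)
  expect_equal(unname(outT[, "D1"]), c(0, 1))  # clipped to [0,1]
  expect_equal(attr(scaleUnitInterval(m), "scaler")$min, sc$min)
})

test_that("zero-parameter RBM activates every unit with probability 1/2", {
  rbm <- rbmSpec(3, 2, seed = 1)
  rbm@weights[] <- 0
  v <- matrix(runif(6), 2, 3)
  expect_true(all(hiddenProbability(rbm, v) == 0.5))
  expect_true(all(visibleProbability(rbm, matrix(c(0, 1, 1, 0), 2, 2)) ==
                    0.5))
})

test_that("CD-1 gradient matches the enumerable-state expectation", {
  # 2 visible x 2 hidden: all conditionals recomputed by enumerating the
  # joint energy table, independent of the sigmoid shortcut
  rbm <- rbmSpec(2, 2, seed = 5)
  rbm@weights <- matrix(c(0.4, -0.3, 0.2, 0.7), 2, 2)
  rbm@visibleBias <- c(0.1, -0.2)
  rbm@hiddenBias <- c(-0.1, 0.3)
  v <- matrix(c(0.8, 0.3), 1, 2)
  hSample <- matrix(c(1, 0), 1, 2)

  energy <- function(vv, hh)
    -sum(vv * (rbm@weights %*% hh)) - sum(rbm@visibleBias * vv) -
      sum(rbm@hiddenBias * hh)
  hStates <- as.matrix(expand.grid(0:1, 0:1))
  # P(h_j = 1 | v) by enumeration over hidden configurations
  w <- apply(hStates, 1, function(h) exp(-energy(drop(v), h)))
  pH <- colSums(hStates * w) / sum(w)
  # P(v_i = 1 | hSample) by enumeration over visible configurations
  vStates <- as.matrix(expand.grid(0:1, 0:1))
  wv <- apply(vStates, 1, function(vv) exp(-energy(vv, drop(hSample))))
  pV <- colSums(vStates * wv) / sum(wv)
  # and P(h_j = 1 | reconstruction)
  wh2 <- apply(hStates, 1, function(h) exp(-energy(pV, h)))
  pH2 <- colSums(hStates * wh2) / sum(wh2)

  expDW <- outer(drop(v), pH) - outer(pV, pH2)
  g <- cdGradient(rbm, v, hSample = hSample)
  expect_lt(max(abs(g$dW - expDW)), 1e-6)
  expect_lt(max(abs(g$dVisibleBias - (drop(v) - pV))), 1e-6)
  expect_lt(max(abs(g$dHiddenBias - (pH - pH2))), 1e-6)
})

test_that("CD training reduces reconstruction error on binary prototypes", {
  set.seed(3)
  proto <- rbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1))
  data <- proto[rep(1:2, each = 10), ] +
    matrix(runif(120, 0, 0.1), 20, 6)
  data <- pmin(data, 1)
  rbm <- trainRbm(data, rbmSpec(6, 3, learningRate = 0.2, epochs = 50,
                                batchSize = 5, seed = 2))
  expect_lt(tail(rbm@reconstructionError, 1), rbm@reconstructionError[1])
  # non-finite updates are reported with the epoch
  expect_error(trainRbm(data, rbmSpec(6, 3, learningRate = 1e6,
                                      epochs = 5, seed = 2)),
               "non-finite RBM update at epoch")
})

test_that("training free energy broadly decreases across epochs", {
  proto <- rbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1))
  traces <- sapply(1:5, function(s) {
    set.seed(s)
    data <- pmin(proto[rep(1:2, each = 8), ] +
                   matrix(runif(96, 0, 0.1), 16, 6), 1)
    rbm <- rbmSpec(6, 3, learningRate = 0.1, epochs = 1, batchSize = 8,
                   seed = s)
    vapply(1:25, function(ep) {
      rbm <<- trainRbm(data, rbm)
      mean(freeEnergy(rbm, data))
    }, 1)
  })
  avg <- rowMeans(traces)
  expect_lt(tail(avg, 1), avg[1])
  expect_lte(mean(diff(avg) > 0), 0.10)
})

test_that("greedy stacking chains layers and preserves the presets", {
  arch <- dbnArchitectures(5270)
  expect_identical(arch$one, c(5270L, 500L))
  expect_identical(arch$two, c(5270L, 2000L, 500L))
  expect_identical(arch$three, c(5270L, 2000L, 1000L, 500L))

  set.seed(9)
  data <- matrix(runif(30 * 8), 30, 8)
  dbn1 <- pretrainStack(data, c(8, 4), epochs = 3, seed = 21)
  # degenerate one-RBM stack equals a directly trained RBM
  direct <- trainRbm(data, rbmSpec(8, 4, epochs = 3,
                                   seed = chemPercept:::deriveSeed(21,
                                     "layer", 1)))
  expect_identical(dbn1@rbms[[1]]@weights, direct@weights)

  dbn3 <- pretrainStack(data, c(8, 6, 5, 3), epochs = 2, seed = 1)
  expect_length(dbn3@rbms, 3)
  top <- chemPercept:::dbnForward(
    fineTune(dbn3, data, factor(rep(c("u", "w"), 15)), epochs = 0,
             seed = 1), data)[[4]]
  expect_equal(ncol(top), 3)
  expect_error(pretrainStack(data, c(7, 4)), "must equal ncol")
})

test_that("backprop gradients match central finite differences", {
  set.seed(42)
  X <- matrix(runif(8 * 6), 8, 6)
  y <- factor(sample(c("a", "b", "c"), 8, TRUE))
  dbn <- pretrainStack(X, c(6, 4), epochs = 2, seed = 1)
  dbn <- fineTune(dbn, X, y, epochs = 0, seed = 2)
  Y <- chemPercept:::oneHot(y)
  g <- chemPercept:::dbnLossGrad(dbn, X, Y)
  eps <- 1e-6
  relErr <- function(analytic, bump) {
    num <- analytic * 0
    for (i in seq_len(nrow(num))) for (j in seq_len(ncol(num))) {
      d1 <- bump(dbn, i, j, eps)
      d2 <- bump(dbn, i, j, -eps)
      num[i, j] <- (chemPercept:::dbnLossGrad(d1, X, Y)$loss -
                      chemPercept:::dbnLossGrad(d2, X, Y)$loss) / (2 * eps)
    }
    max(abs(num - analytic)) / max(abs(num))
  }
  errW <- relErr(g$W[[1]], function(d, i, j, e) {
    d@rbms[[1]]@weights[i, j] <- d@rbms[[1]]@weights[i, j] + e; d
  })
  errH <- relErr(g$headW, function(d, i, j, e) {
    d@headWeights[i, j] <- d@headWeights[i, j] + e; d
  })
  expect_lt(errW, 1e-4)
  expect_lt(errH, 1e-4)
})

test_that("fine-tuned DBN separates a planted 4-class problem", {
  ds <- imputeZero(cleanDataset(n = 240, p = 60, k = 4, ipc = 3, effect = 3,
                                seed = 12))
  X <- descriptorMatrix(ds); y <- perceptLabels(ds)
  tr <- 1:180; te <- 181:240
  sc <- fitUnitScaler(X[tr, ])
  dbn <- pretrainStack(applyUnitScaler(sc, X[tr, ]), c(60, 20), epochs = 10,
                       seed = 3)
  dbn <- fineTune(dbn, applyUnitScaler(sc, X[tr, ]), y[tr], epochs = 60,
                  learningRate = 0.3, seed = 4)
  acc <- mean(predictLabels(dbn, applyUnitScaler(sc, X[te, ])) == y[te])
  expect_gt(acc, 0.9)
})

test_that("the hyperparameter surface behaves like a maximum", {
  ds <- imputeZero(cleanDataset(n = 90, p = 20, k = 3, ipc = 2, effect = 3,
                                seed = 30))
  folds <- makeFolds(ds, 3, seed = 1)
  gs <- dbnGridSearch(ds, folds, lrGrid = 0.2, momentumGrid = 0.5,
                      hiddenSizes = 10L, pretrainEpochs = 4L,
                      fineTuneEpochs = 25L, seed = 2)
  expect_equal(nrow(gs$summary), 1)  # 1x1 grid is a single CV run
  expect_equal(gs$best$accuracy, gs$summary$accuracy)

  gs2 <- dbnGridSearch(ds, folds, lrGrid = c(0.05, 0.2),
                       momentumGrid = c(0, 0.5), hiddenSizes = 10L,
                       pretrainEpochs = 4L, fineTuneEpochs = 25L, seed = 2)
  expect_true(all(gs2$best$accuracy >= gs2$summary$accuracy))
  # an absurd learning rate never beats the best grid point
  gsBad <- suppressWarnings(
    dbnGridSearch(ds, folds, lrGrid = 10, momentumGrid = 0.5,
                  hiddenSizes = 10L, pretrainEpochs = 4L,
                  fineTuneEpochs = 25L, seed = 2))
  bad <- gsBad$summary$accuracy
  expect_true(is.na(bad) || bad <= gs2$best$accuracy)
})

test_that("the shallow architecture tends to beat the deep one at this scale", {
  wins <- vapply(1:10, function(s) {
    ds <- imputeZero(cleanDataset(n = 140, p = 50, k = 4, ipc = 2,
                                  effect = 3, seed = 200 + s))
    X <- descriptorMatrix(ds); y <- perceptLabels(ds)
    tr <- 1:100; te <- 101:140
    sc <- fitUnitScaler(X[tr, ])
    Xtr <- applyUnitScaler(sc, X[tr, ]); Xte <- applyUnitScaler(sc, X[te, ])
    accOf <- function(layers) {
      dbn <- pretrainStack(Xtr, layers, epochs = 6, seed = s)
      dbn <- fineTune(dbn, Xtr, y[tr], epochs = 40, learningRate = 0.3,
                      seed = s)
      mean(predictLabels(dbn, Xte) == y[te])
    }
    accOf(c(50, 12)) >= accOf(c(50, 30, 20, 12))
  }, logical(1))
  expect_gte(sum(wins), 6)
})
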