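#' Min-max scaling to the unit interval
#'
#' RBM visible units expect inputs in \[0,1\]; descriptors are unbounded
#' reals, so each descriptor is scaled by its training-set minimum and
#' range. Constant descriptors map to 0. When a stored scaler is applied to
#' new data, values outside the training range are clipped into \[0,1\].
#'
#' @param x molecules-by-descriptors matrix (or [DescriptorSet-class],
#'   already imputed).
#' @param scaler a scaler from [fitUnitScaler()]; `NULL` fits one on `x`.
#' @return matrix in \[0,1\] with the scaler attached as
#'   `attr(, "scaler")`.
#' @export
scaleUnitInterval <- function(x, scaler = NULL) {
  m <- dsToXy(x, requireLabels = FALSE)$X
  if (is.null(scaler)) scaler <- fitUnitScaler(m)
  out <- applyUnitScaler(scaler, m)
  attr(out, "scaler") <- scaler
  out
}

#' @rdname scaleUnitInterval
#' @export
fitUnitScaler <- function(x) {
  m <- dsToXy(x, requireLabels = FALSE)$X
  mins <- apply(m, 2L, min)
  rng <- apply(m, 2L, max) - mins
  list(min = mins, range = rng, features = colnames(m))
}

#' @rdname scaleUnitInterval
#' @export
applyUnitScaler <- function(scaler, x) {
  m <- dsToXy(x, requireLabels = FALSE)$X
  m <- m[, scaler$features, drop = FALSE]
  rng <- ifelse(scaler$range == 0, 1, scaler$range)
  out <- sweep(sweep(m, 2L, scaler$min), 2L, rng, "/")
  out[, scaler$range == 0] <- 0
  pmin(pmax(out, 0), 1)
}

#' Construct an untrained RBM
#'
#' Weights are initialized from a zero-mean Gaussian with SD 0.01 (seeded);
#' biases start at zero.
#'
#' @param nVisible,nHidden layer sizes.
#' @param learningRate CD step size (default 0.05).
#' @param momentum velocity coefficient in \[0,1) (default 0.5).
#' @param cdSteps Gibbs steps per update (default 1, i.e. CD-1).
#' @param epochs,batchSize minibatch schedule.
#' @param seed RNG seed for initialization, shuffling and hidden sampling.
#' @return An [RBM-class].
#' @export
rbmSpec <- function(nVisible, nHidden, learningRate = 0.05, momentum = 0.5,
                    cdSteps = 1L, epochs = 50L, batchSize = 32L, seed = 1L) {
  set.seed(deriveSeed(seed, "rbminit"))
  w <- matrix(rnorm(nVisible * nHidden, 0, 0.01), nVisible, nHidden)
  obj <- new("RBM", weights = w, visibleBias = numeric(nVisible),
             hiddenBias = numeric(nHidden),
             learningRate = as.numeric(learningRate),
             momentum = as.numeric(momentum), cdSteps = as.integer(cdSteps),
             epochs = as.integer(epochs), batchSize = as.integer(batchSize),
             seed = as.integer(seed), reconstructionError = numeric())
  validObject(obj)
  obj
}

#' Conditional unit activation probabilities
#'
#' `hiddenProbability` gives P(h_j = 1 | v) = sigmoid(v W + b_h) for each
#' hidden unit; `visibleProbability` gives P(v_i = 1 | h). With zero weights
#' and biases every probability is exactly 0.5.
#'
#' @param rbm an [RBM-class].
#' @param v,h batch matrices (rows = samples).
#' @return matrix of probabilities.
#' @export
hiddenProbability <- function(rbm, v) {
  sigmoid(sweep(v %*% rbm@weights, 2L, rbm@hiddenBias, "+"))
}

#' @rdname hiddenProbability
#' @export
visibleProbability <- function(rbm, h) {
  sigmoid(sweep(h %*% t(rbm@weights), 2L, rbm@visibleBias, "+"))
}

#' Free energy of visible configurations
#'
#' F(v) = -v.b_v - sum_j log(1 + exp(v W_j + b_hj)); averaged training free
#' energy should broadly decrease over CD epochs.
#'
#' @param rbm an [RBM-class].
#' @param v batch matrix.
#' @return numeric vector, one free energy per row.
#' @export
freeEnergy <- function(rbm, v) {
  act <- sweep(v %*% rbm@weights, 2L, rbm@hiddenBias, "+")
  -drop(v %*% rbm@visibleBias) - rowSums(log1p(exp(act)))
}

#' One contrastive-divergence gradient
#'
#' Computes the CD-1 gradient for a batch: positive statistics use
#' P(h | v); the reconstruction uses a binary hidden sample (drawn here if
#' `hSample` is `NULL`), visible probabilities P(v | h), and negative
#' statistics P(h | v'). Returned gradients are averaged over the batch and
#' are what [trainRbm()] adds (times the learning rate) to the parameters.
#'
#' @param rbm an [RBM-class].
#' @param v batch matrix in \[0,1\].
#' @param hSample optional binary hidden matrix to use instead of sampling.
#' @return list with `dW`, `dVisibleBias`, `dHiddenBias`, `hSample`,
#'   `vRecon`.
#' @export
cdGradient <- function(rbm, v, hSample = NULL) {
  v <- matrix(v, ncol = nrow(rbm@weights))
  hp <- hiddenProbability(rbm, v)
  if (is.null(hSample))
    hSample <- matrix(runif(length(hp)) < hp, nrow(hp), ncol(hp)) * 1
  vn <- v
  hs <- hSample
  for (step in seq_len(rbm@cdSteps)) {
    vn <- visibleProbability(rbm, hs)
    hn <- hiddenProbability(rbm, vn)
    if (step < rbm@cdSteps)
      hs <- matrix(runif(length(hn)) < hn, nrow(hn), ncol(hn)) * 1
  }
  nb <- nrow(v)
  list(dW = (crossprod(v, hp) - crossprod(vn, hn)) / nb,
       dVisibleBias = colMeans(v) - colMeans(vn),
       dHiddenBias = colMeans(hp) - colMeans(hn),
       hSample = hSample, vRecon = vn)
}

#' Train an RBM by contrastive divergence
#'
#' Momentum-accelerated minibatch CD with `cdSteps` Gibbs steps; rows are
#' shuffled each epoch and the per-epoch mean squared reconstruction error
#' is logged in `@reconstructionError`. Deterministic under the RBM seed.
#'
#' @param data matrix in \[0,1\], rows = samples.
#' @param rbm an [RBM-class] whose visible size matches `ncol(data)`.
#' @return The fitted [RBM-class].
#' @export
trainRbm <- function(data, rbm) {
  data <- as.matrix(data)
  if (ncol(data) != nrow(rbm@weights))
    stop("data has ", ncol(data), " columns but RBM expects ",
         nrow(rbm@weights))
  set.seed(deriveSeed(rbm@seed, "rbmtrain"))
  vW <- rbm@weights * 0; vVb <- rbm@visibleBias * 0; vHb <- rbm@hiddenBias * 0
  lr <- rbm@learningRate; mom <- rbm@momentum
  recon <- numeric(rbm@epochs)
  n <- nrow(data)
  for (ep in seq_len(rbm@epochs)) {
    ord <- sample(n)
    starts <- seq(1L, n, by = rbm@batchSize)
    se <- 0
    for (s in starts) {
      rows <- ord[s:min(s + rbm@batchSize - 1L, n)]
      g <- cdGradient(rbm, data[rows, , drop = FALSE])
      vW <- mom * vW + lr * g$dW
      vVb <- mom * vVb + lr * g$dVisibleBias
      vHb <- mom * vHb + lr * g$dHiddenBias
      rbm@weights <- rbm@weights + vW
      rbm@visibleBias <- rbm@visibleBias + vVb
      rbm@hiddenBias <- rbm@hiddenBias + vHb
      if (!all(is.finite(rbm@weights)) || max(abs(rbm@weights)) > 1e4)
        stop("non-finite RBM update at epoch ", ep,
             "; lower the learning rate")
      se <- se + sum((data[rows, , drop = FALSE] - g$vRecon)^2)
    }
    recon[ep] <- se / length(data)
  }
  rbm@reconstructionError <- recon
  rbm
}

#' Preset DBN architectures
#'
#' The three layer layouts compared for 5,270-descriptor perception tables:
#' one RBM (p-500), two RBMs (p-2000-500), three RBMs (p-2000-1000-500).
#'
#' @param p input dimension (default 5270).
#' @return named list of layer-size vectors `one`, `two`, `three`.
#' @examples
#' dbnArchitectures(5270)$one  # c(5270, 500)
#' @export
dbnArchitectures <- function(p = 5270L) {
  p <- as.integer(p)
  list(one = c(p, 500L), two = c(p, 2000L, 500L),
       three = c(p, 2000L, 1000L, 500L))
}

#' Greedy layerwise pretraining of a DBN
#'
#' Trains a stack of RBMs bottom-up: the first on the data, each subsequent
#' RBM on the hidden activation probabilities of the layer below.
#'
#' @param data matrix in \[0,1\].
#' @param layerSizes chain of layer sizes; `layerSizes[1]` must equal
#'   `ncol(data)`.
#' @param learningRate,momentum,cdSteps,epochs,batchSize,seed shared RBM
#'   hyperparameters (see [rbmSpec()]).
#' @return A pretrained [DBN-class] (no classification head yet).
#' @export
pretrainStack <- function(data, layerSizes, learningRate = 0.05,
                          momentum = 0.5, cdSteps = 1L, epochs = 50L,
                          batchSize = 32L, seed = 1L) {
  layerSizes <- as.integer(layerSizes)
  if (layerSizes[1] != ncol(data))
    stop("layerSizes[1] must equal ncol(data)")
  input <- as.matrix(data)
  rbms <- vector("list", length(layerSizes) - 1L)
  for (i in seq_along(rbms)) {
    rbm <- rbmSpec(layerSizes[i], layerSizes[i + 1L], learningRate,
                   momentum, cdSteps, epochs, batchSize,
                   seed = deriveSeed(seed, "layer", i))
    rbm <- trainRbm(input, rbm)
    rbms[[i]] <- rbm
    input <- hiddenProbability(rbm, input)
  }
  new("DBN", layerSizes = layerSizes, rbms = rbms,
      headWeights = matrix(numeric(), 0, 0), headBias = numeric(),
      vocabulary = character(), trainAccuracy = numeric())
}

# Forward pass: list of activations per layer (sigmoid), then softmax head.
dbnForward <- function(dbn, X) {
  acts <- list(X)
  h <- X
  for (r in dbn@rbms) {
    h <- hiddenProbability(r, h)
    acts[[length(acts) + 1L]] <- h
  }
  z <- sweep(h %*% dbn@headWeights, 2L, dbn@headBias, "+")
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  acts$prob <- ez / rowSums(ez)
  acts
}

# Cross-entropy loss and full backprop gradients for all layers + head.
dbnLossGrad <- function(dbn, X, Yonehot) {
  acts <- dbnForward(dbn, X)
  n <- nrow(X)
  prob <- acts$prob
  loss <- -sum(Yonehot * log(pmax(prob, 1e-12))) / n
  nl <- length(dbn@rbms)
  top <- acts[[nl + 1L]]
  dz <- (prob - Yonehot) / n
  gHeadW <- crossprod(top, dz)
  gHeadB <- colSums(dz)
  gW <- vector("list", nl); gB <- vector("list", nl)
  delta <- dz %*% t(dbn@headWeights)
  for (i in rev(seq_len(nl))) {
    a <- acts[[i + 1L]]
    dpre <- delta * a * (1 - a)
    gW[[i]] <- crossprod(acts[[i]], dpre)
    gB[[i]] <- colSums(dpre)
    if (i > 1L) delta <- dpre %*% t(dbn@rbms[[i]]@weights)
  }
  list(loss = loss, headW = gHeadW, headB = gHeadB, W = gW, b = gB)
}

oneHot <- function(y) {
  Y <- matrix(0, length(y), nlevels(y))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  colnames(Y) <- levels(y)
  Y
}

#' Supervised fine-tuning of a pretrained DBN
#'
#' Appends a softmax head after the last RBM and trains the whole network
#' end-to-end by backpropagation on the cross-entropy, with momentum
#' minibatch SGD. Per-epoch training accuracy is logged. With
#' `epochs = 0` the network keeps its pretrained features and a freshly
#' initialized head (the contractual baseline).
#'
#' @param dbn a pretrained [DBN-class].
#' @param X training matrix in \[0,1\] (rows = molecules).
#' @param y factor of class labels.
#' @param epochs fine-tuning epochs (default 100).
#' @param learningRate,momentum,batchSize SGD hyperparameters.
#' @param seed RNG seed (head init and shuffling).
#' @return The fitted [DBN-class].
#' @export
fineTune <- function(dbn, X, y, epochs = 100L, learningRate = 0.1,
                     momentum = 0.5, batchSize = 32L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.factor(y)
  nh <- dbn@layerSizes[length(dbn@layerSizes)]
  set.seed(deriveSeed(seed, "head"))
  dbn@headWeights <- matrix(rnorm(nh * nlevels(y), 0, 0.01), nh, nlevels(y))
  dbn@headBias <- numeric(nlevels(y))
  dbn@vocabulary <- levels(y)
  if (epochs == 0L) return(dbn)
  Y <- oneHot(y)
  nl <- length(dbn@rbms)
  vel <- list(headW = dbn@headWeights * 0, headB = dbn@headBias * 0,
              W = lapply(dbn@rbms, function(r) r@weights * 0),
              b = lapply(dbn@rbms, function(r) r@hiddenBias * 0))
  set.seed(deriveSeed(seed, "finetune"))
  accLog <- numeric(epochs)
  n <- nrow(X)
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    for (s in seq(1L, n, by = batchSize)) {
      rows <- ord[s:min(s + batchSize - 1L, n)]
      g <- dbnLossGrad(dbn, X[rows, , drop = FALSE],
                       Y[rows, , drop = FALSE])
      if (!is.finite(g$loss))
        stop("fine-tuning diverged at epoch ", ep)
      vel$headW <- momentum * vel$headW - learningRate * g$headW
      vel$headB <- momentum * vel$headB - learningRate * g$headB
      dbn@headWeights <- dbn@headWeights + vel$headW
      dbn@headBias <- dbn@headBias + vel$headB
      for (i in seq_len(nl)) {
        vel$W[[i]] <- momentum * vel$W[[i]] - learningRate * g$W[[i]]
        vel$b[[i]] <- momentum * vel$b[[i]] - learningRate * g$b[[i]]
        dbn@rbms[[i]]@weights <- dbn@rbms[[i]]@weights + vel$W[[i]]
        dbn@rbms[[i]]@hiddenBias <- dbn@rbms[[i]]@hiddenBias + vel$b[[i]]
      }
    }
    pred <- dbn@vocabulary[max.col(dbnForward(dbn, X)$prob,
                                   ties.method = "first")]
    accLog[ep] <- mean(pred == as.character(y))
  }
  dbn@trainAccuracy <- accLog
  dbn
}

#' @describeIn fineTune class predictions from a fine-tuned DBN (softmax
#'   argmax; ties toward the lowest vocabulary index).
#' @param object a fine-tuned [DBN-class].
#' @param newdata matrix in \[0,1\] over the training descriptors.
#' @param ... unused.
#' @export
setMethod("predictLabels", "DBN", function(object, newdata, ...) {
  if (length(object@vocabulary) == 0L)
    stop("DBN has no classification head; run fineTune() first")
  prob <- dbnForward(object, as.matrix(newdata))$prob
  factor(object@vocabulary[max.col(prob, ties.method = "first")],
         levels = object@vocabulary)
})

setMethod("show", "DBN", function(object) {
  cat("DBN: layers", paste(object@layerSizes, collapse = "-"),
      if (length(object@vocabulary)) paste0("-> softmax(",
        length(object@vocabulary), ")") else "(no head)", "\n")
})

setMethod("show", "RBM", function(object) {
  cat("RBM:", nrow(object@weights), "visible x", ncol(object@weights),
      "hidden; CD-", object@cdSteps, "\n", sep = "")
  if (length(object@reconstructionError))
    cat("  final reconstruction MSE:",
        signif(tail(object@reconstructionError, 1), 4), "\n")
})

#' DBN learner for cross-validation
#'
#' Wraps min-max scaling, pretraining and fine-tuning into the learner
#' interface used by [crossValidate()].
#'
#' @param hiddenSizes hidden-layer sizes appended after the input layer.
#' @param pretrainEpochs,fineTuneEpochs,learningRate,momentum,batchSize
#'   training hyperparameters.
#' @param seed RNG seed.
#' @return learner list with `fit` and `predict`.
#' @export
dbnLearner <- function(hiddenSizes = 500L, pretrainEpochs = 20L,
                       fineTuneEpochs = 60L, learningRate = 0.1,
                       momentum = 0.5, batchSize = 32L, seed = 1L) {
  list(
    fit = function(ds) {
      d <- dsToXy(ds)
      sc <- fitUnitScaler(d$X)
      Xs <- applyUnitScaler(sc, d$X)
      dbn <- pretrainStack(Xs, c(ncol(Xs), hiddenSizes),
                           learningRate = learningRate, momentum = momentum,
                           epochs = pretrainEpochs, batchSize = batchSize,
                           seed = seed)
      dbn <- fineTune(dbn, Xs, d$y, epochs = fineTuneEpochs,
                      learningRate = learningRate * 2, momentum = momentum,
                      batchSize = batchSize, seed = seed)
      list(dbn = dbn, scaler = sc, vocabulary = levels(d$y))
    },
    predict = function(model, ds) {
      d <- dsToXy(ds, requireLabels = FALSE)
      pred <- predictLabels(model$dbn, applyUnitScaler(model$scaler, d$X))
      factor(as.character(pred), levels = model$vocabulary)
    })
}

#' Grid search over learning rate and momentum
#'
#' Evaluates DBN cross-validation accuracy on every (learning rate,
#' momentum) pair — the accuracy surface whose axes are the two training
#' hyperparameters — and reports the best pair.
#'
#' @param x a labeled, imputed [DescriptorSet-class].
#' @param folds a [FoldAssignment-class].
#' @param lrGrid,momentumGrid hyperparameter grids.
#' @param hiddenSizes hidden-layer sizes.
#' @param pretrainEpochs,fineTuneEpochs,batchSize,seed passed to
#'   [dbnLearner()].
#' @return list with `surface` (long data.frame: learningRate, momentum,
#'   fold, accuracy), `summary` (mean accuracy per pair) and `best` (row of
#'   `summary`).
#' @export
dbnGridSearch <- function(x, folds, lrGrid = c(0.001, 0.01, 0.05, 0.1),
                          momentumGrid = c(0, 0.5, 0.9), hiddenSizes = 500L,
                          pretrainEpochs = 20L, fineTuneEpochs = 60L,
                          batchSize = 32L, seed = 1L) {
  if (!length(lrGrid) || !length(momentumGrid)) stop("empty grid")
  rows <- list()
  for (lr in lrGrid) for (mom in momentumGrid) {
    # a diverging hyperparameter pair scores NA instead of aborting the grid
    acc <- tryCatch({
      cv <- crossValidate(x, folds,
                          dbnLearner(hiddenSizes, pretrainEpochs,
                                     fineTuneEpochs, lr, mom, batchSize,
                                     seed))
      cv@foldAccuracy
    }, error = function(e) {
      warning("grid point (lr = ", lr, ", momentum = ", mom, ") failed: ",
              conditionMessage(e))
      NA_real_
    })
    rows[[length(rows) + 1L]] <- data.frame(
      learningRate = lr, momentum = mom,
      fold = seq_along(acc), accuracy = acc)
  }
  surface <- do.call(rbind, rows)
  summary <- stats::aggregate(accuracy ~ learningRate + momentum, surface,
                              mean, na.action = stats::na.pass)
  list(surface = surface, summary = summary,
       best = summary[which.max(summary$accuracy), ])
}
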