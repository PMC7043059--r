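#' GA wrapper-selection configuration
#'
#' Defaults are sized for desk-scale problems (p up to about a thousand
#' descriptors): population 30, 25 generations, tournament selection of
#' size 3, uniform crossover at rate 0.9, per-bit mutation at 1/p, elitism
#' of 1, 40-tree forests on a `fitnessFolds`-fold internal CV as fitness.
#' Fitness values are cached by chromosome, so the GA optimizes a
#' deterministic landscape within a run.
#'
#' @param populationSize,generations GA budget.
#' @param crossoverRate probability a child is produced by uniform
#'   crossover.
#' @param mutationRate per-bit flip probability; `NULL` means 1/p.
#' @param fitnessFolds internal CV folds for the fitness (default 4).
#' @param nTrees trees per fitness forest (default 40).
#' @param tournamentSize,elitism selection controls.
#' @param initProb probability a bit starts active (default 0.5).
#' @param seed run seed.
#' @return A [GAConfig-class].
#' @export
gaConfig <- function(populationSize = 30L, generations = 25L,
                     crossoverRate = 0.9, mutationRate = NULL,
                     fitnessFolds = 4L, nTrees = 40L, tournamentSize = 3L,
                     elitism = 1L, initProb = 0.5, seed = 1L) {
  cfg <- new("GAConfig", populationSize = as.integer(populationSize),
             generations = as.integer(generations),
             crossoverRate = as.numeric(crossoverRate),
             mutationRate = if (is.null(mutationRate)) NA_real_ else
               as.numeric(mutationRate),
             fitnessFolds = as.integer(fitnessFolds),
             nTrees = as.integer(nTrees),
             tournamentSize = as.integer(tournamentSize),
             elitism = as.integer(elitism), initProb = as.numeric(initProb),
             seed = as.integer(seed))
  validObject(cfg)
  cfg
}

# Fitness of a chromosome: CV accuracy of a forest restricted to its active
# descriptors, on pre-built stratified folds. Seeded per fold so the value
# is a pure function of (mask, folds, config).
maskFitness <- function(X, y, mask, foldIdx, nTrees, seed) {
  Xa <- X[, mask, drop = FALSE]
  correct <- 0L
  for (f in sort(unique(foldIdx))) {
    tr <- foldIdx != f
    fit <- ranger::ranger(x = Xa[tr, , drop = FALSE], y = droplevels(y[tr]),
                          num.trees = nTrees,
                          mtry = max(1L, defaultMtry(ncol(Xa))),
                          num.threads = 1L, seed = deriveSeed(seed, "fit", f))
    pr <- predict(fit, data = Xa[!tr, , drop = FALSE],
                  num.threads = 1L)$predictions
    correct <- correct + sum(as.character(pr) == as.character(y[!tr]))
  }
  correct / length(y)
}

repairMask <- function(mask) {
  if (!any(mask)) mask[sample(length(mask), 1L)] <- TRUE
  mask
}

#' Genetic-algorithm wrapper feature selection
#'
#' Evolves binary chromosomes of length p (one bit per descriptor); the
#' fitness of a chromosome is the cross-validated accuracy of a random
#' forest restricted to its active descriptors. Tournament selection,
#' uniform crossover, per-bit mutation, elitism. Chromosomes that collapse
#' to all-zero are repaired by switching one random bit on (counted in
#' `@repairs`). Deterministic under the config seed.
#'
#' @param x a labeled, imputed [DescriptorSet-class].
#' @param config a [GAConfig-class].
#' @param folds optional [FoldAssignment-class] for the fitness CV;
#'   defaults to stratified `fitnessFolds` folds built from the config seed.
#' @return A [GASelection-class]: best chromosome of the final generation
#'   plus the per-generation best/mean fitness trace.
#' @export
gaSelect <- function(x, config = gaConfig(), folds = NULL) {
  d <- dsToXy(x)
  X <- d$X; y <- d$y
  p <- ncol(X)
  if (is.null(folds))
    folds <- makeFolds(x, k = config@fitnessFolds,
                       seed = deriveSeed(config@seed, "gafolds"))
  foldIdx <- folds@foldIndex[rownames(X)]
  mut <- if (is.na(config@mutationRate)) 1 / p else config@mutationRate
  cache <- new.env(hash = TRUE, parent = emptyenv())
  evals <- 0L
  evalMask <- function(m) {
    key <- paste(which(m), collapse = ",")
    v <- cache[[key]]
    if (is.null(v)) {
      v <- maskFitness(X, y, m, foldIdx, config@nTrees, config@seed)
      cache[[key]] <- v
      evals <<- evals + 1L
    }
    v
  }
  set.seed(deriveSeed(config@seed, "ga"))
  pop <- config@populationSize
  P <- matrix(runif(pop * p) < config@initProb, pop, p)
  repairs <- 0L
  for (i in seq_len(pop)) {
    if (!any(P[i, ])) { P[i, ] <- repairMask(P[i, ]); repairs <- repairs + 1L }
  }
  fit <- apply(P, 1L, evalMask)
  trace <- data.frame(generation = 0L, best = max(fit), mean = mean(fit))
  for (g in seq_len(config@generations)) {
    ord <- order(fit, decreasing = TRUE)
    newP <- matrix(FALSE, pop, p)
    nE <- min(config@elitism, pop)
    if (nE > 0L) newP[seq_len(nE), ] <- P[ord[seq_len(nE)], , drop = FALSE]
    for (i in seq(nE + 1L, length.out = pop - nE)) {
      t1 <- sample(pop, config@tournamentSize)
      p1 <- P[t1[which.max(fit[t1])], ]
      if (runif(1) < config@crossoverRate) {
        t2 <- sample(pop, config@tournamentSize)
        p2 <- P[t2[which.max(fit[t2])], ]
        child <- ifelse(runif(p) < 0.5, p1, p2)
      } else child <- p1
      flip <- runif(p) < mut
      child[flip] <- !child[flip]
      if (!any(child)) { child <- repairMask(child); repairs <- repairs + 1L }
      newP[i, ] <- child
    }
    P <- newP
    fit <- apply(P, 1L, evalMask)
    trace <- rbind(trace,
                   data.frame(generation = g, best = max(fit),
                              mean = mean(fit)))
  }
  best <- which.max(fit)
  new("GASelection", mask = P[best, ], featureNames = colnames(X),
      trace = trace, fitness = fit[best], repairs = as.integer(repairs))
}

#' Repeated GA runs for consensus selection
#'
#' Runs [gaSelect()] `runs` times with independent seeds derived from the
#' config seed and returns the list of best chromosomes.
#'
#' @param x a labeled, imputed [DescriptorSet-class].
#' @param config a [GAConfig-class] (its seed is the master seed).
#' @param runs number of repeats (default 20).
#' @param folds optional shared [FoldAssignment-class].
#' @return list of [GASelection-class] objects.
#' @export
runGaConsensus <- function(x, config = gaConfig(), runs = 20L,
                           folds = NULL) {
  lapply(seq_len(runs), function(r) {
    cfg <- config
    cfg@seed <- deriveSeed(config@seed, "garun", r)
    gaSelect(x, cfg, folds)
  })
}

#' Consensus over repeated selection runs
#'
#' Counts, per descriptor, in how many runs it appeared in the best
#' chromosome; the consensus set is every descriptor selected at least
#' `minCount` times. Raising `minCount` never grows the set.
#'
#' @param runMasks list of logical masks (or [GASelection-class] objects)
#'   of identical length.
#' @param minCount consensus threshold (e.g. 18 of 20 runs for color, 16 of
#'   20 for odor).
#' @return A [ConsensusSelection-class].
#' @export
consensus <- function(runMasks, minCount) {
  if (!length(runMasks)) stop("empty run list")
  masks <- lapply(runMasks, function(m)
    if (is(m, "GASelection")) stats::setNames(m@mask, m@featureNames) else m)
  lens <- vapply(masks, length, 1L)
  if (length(unique(lens)) != 1L) stop("masks must all have the same length")
  counts <- Reduce(`+`, lapply(masks, as.integer))
  nms <- names(masks[[1]])
  if (is.null(nms)) nms <- paste0("D", seq_along(counts))
  counts <- as.integer(counts)
  names(counts) <- nms
  obj <- new("ConsensusSelection", runs = length(masks),
             selectionCount = counts,
             minCount = as.integer(minCount),
             consensusFeatures = nms[counts >= minCount])
  validObject(obj)
  obj
}

#' @describeIn consensus the consensus descriptor names.
#' @param x a [ConsensusSelection-class].
#' @export
setMethod("consensusFeatures", "ConsensusSelection",
          function(x) x@consensusFeatures)

#' @describeIn consensus named per-descriptor selection counts.
#' @export
setMethod("selectionCounts", "ConsensusSelection",
          function(x) x@selectionCount)

setMethod("show", "ConsensusSelection", function(object) {
  cat("ConsensusSelection:", length(object@consensusFeatures),
      "descriptors selected >=", object@minCount, "of", object@runs,
      "runs\n")
})

#' Export selection counts and consensus as CSV
#'
#' @param x a [ConsensusSelection-class].
#' @param featureNames descriptor names, parallel to the counts.
#' @param path output file (columns `descriptor`, `count`, `in_consensus`).
#' @return `path`, invisibly.
#' @export
writeConsensus <- function(x, featureNames, path) {
  data.table::fwrite(data.frame(
    descriptor = featureNames, count = x@selectionCount,
    in_consensus = featureNames %in% x@consensusFeatures), path)
  invisible(path)
}

#' Permutation-based feature ranking
#'
#' For each descriptor A_i, the validation column of A_i is randomly
#' permuted across molecules and the validation accuracy recomputed; the
#' importance indicator is |acc2 - acc1| averaged over `repetitions`. With
#' `refit = TRUE` (default) a fresh forest is trained per repetition,
#' reflecting that the forest itself is random; with `refit = FALSE` one
#' model is reused and only the permutations vary.
#'
#' @param train labeled, imputed training [DescriptorSet-class].
#' @param validation labeled validation set, disjoint from `train`.
#' @param config a [ForestConfig-class] for the forests.
#' @param features descriptors to rank (default: all).
#' @param repetitions number of repetitions (default 20).
#' @param refit refit the forest each repetition (default TRUE).
#' @param seed RNG seed.
#' @return A [RankingResult-class].
#' @export
permutationRank <- function(train, validation, config = forestConfig(),
                            features = NULL, repetitions = 20L,
                            refit = TRUE, seed = 1L) {
  if (ncol(validation) == 0L) stop("validation set is empty")
  if (is.null(features)) features <- descriptorNames(train)
  dV <- dsToXy(validation)
  XV <- dV$X; yV <- as.character(dV$y)
  ind <- matrix(0, length(features), repetitions,
                dimnames = list(features, NULL))
  acc1 <- numeric(repetitions)
  model <- NULL
  for (r in seq_len(repetitions)) {
    if (refit || is.null(model)) {
      cfg <- config
      cfg@seed <- deriveSeed(seed, "rankfit", r)
      model <- fitForest(train, cfg)
    }
    base <- as.character(predictLabels(model, XV))
    acc1[r] <- mean(base == yV)
    set.seed(deriveSeed(seed, "rankperm", r))
    for (f in features) {
      Xp <- XV
      Xp[, f] <- XV[sample(nrow(XV)), f]
      acc2 <- mean(as.character(predictLabels(model, Xp)) == yV)
      ind[f, r] <- abs(acc2 - acc1[r])
    }
  }
  indicator <- rowMeans(ind)
  new("RankingResult", indicator = indicator,
      rank = names(sort(indicator, decreasing = TRUE)),
      acc1 = acc1, repetitions = as.integer(repetitions))
}

setMethod("show", "RankingResult", function(object) {
  cat("RankingResult:", length(object@indicator), "descriptors,",
      object@repetitions, "repetitions; top:",
      paste(head(object@rank, 5), collapse = ", "), "\n")
})

#' Export a ranking as CSV
#'
#' @param x a [RankingResult-class].
#' @param path output file (columns `descriptor`, `mean_indicator`,
#'   `rank`).
#' @return `path`, invisibly.
#' @export
writeRanking <- function(x, path) {
  ord <- match(x@rank, names(x@indicator))
  data.table::fwrite(data.frame(
    descriptor = x@rank, mean_indicator = unname(x@indicator[ord]),
    rank = seq_along(x@rank)), path)
  invisible(path)
}
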