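test_that("GA converges to the full mask when every descriptor is needed", {
  # 16 classes = the binary patterns of 4 descriptors, so dropping any
  # descriptor merges class pairs; only the full mask of p = 4 classifies
  # everything, confirmed by exhaustive enumeration over all 2^4 - 1 masks
  set.seed(6)
  patterns <- as.matrix(expand.grid(rep(list(c(0, 6)), 4)))
  y <- rep(sprintf("cls%02d", 1:16), each = 8)
  X <- patterns[rep(1:16, each = 8), ] + matrix(rnorm(128 * 4, 0, 0.15), 128)
  dimnames(X) <- list(sprintf("M%03d", 1:128), paste0("D", 1:4))
  ds <- handDataset(X, labels = y)
  folds <- makeFolds(ds, 2, seed = 3)
  cfg <- gaConfig(populationSize = 10, generations = 8, fitnessFolds = 2,
                  nTrees = 50, seed = 5)
  foldIdx <- folds@foldIndex[moleculeIds(ds)]
  allMasks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 4)))[-1, ]
  fits <- apply(allMasks, 1, function(m)
    chemPercept:::maskFitness(descriptorMatrix(ds), perceptLabels(ds),
                              m, foldIdx, 50, 5))
  expect_true(all(allMasks[which.max(fits), ]))  # exhaustive optimum
  sel <- gaSelect(ds, cfg, folds)
  expect_true(all(sel@mask))
  expect_equal(sel@fitness, max(fits))
})

test_that("GA retains jointly necessary descriptors across seeded runs", {
  ds <- jointCodedDataset(nPerClass = 15, pNoise = 8, seed = 2)
  folds <- makeFolds(ds, 2, seed = 1)
  hits <- vapply(1:20, function(r) {
    sel <- gaSelect(ds, gaConfig(populationSize = 10, generations = 8,
                                 fitnessFolds = 2, nTrees = 25,
                                 seed = 1000 + r), folds)
    all(sel@mask[match(c("g1", "g2"), sel@featureNames)])
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("degenerate and elitist GA behaviour", {
  ds <- jointCodedDataset(nPerClass = 10, pNoise = 4, seed = 3)
  sel1 <- gaSelect(ds, gaConfig(populationSize = 1, generations = 1,
                                fitnessFolds = 2, nTrees = 15, seed = 2))
  expect_equal(nrow(sel1@trace), 2)  # initial + one generation
  selE <- gaSelect(ds, gaConfig(populationSize = 8, generations = 10,
                                fitnessFolds = 2, nTrees = 15, seed = 4))
  expect_true(all(diff(selE@trace$best) >= 0))  # elitism
  # all-zero chromosomes are repaired to one active bit
  m <- rep(FALSE, 10)
  set.seed(1)
  expect_equal(sum(chemPercept:::repairMask(m)), 1)
  selZ <- gaSelect(ds, gaConfig(populationSize = 6, generations = 2,
                                fitnessFolds = 2, nTrees = 15,
                                initProb = 0, seed = 9))
  expect_gte(selZ@repairs, 6)
  expect_gte(sum(selZ@mask), 1)
})

test_that("consensus counts selections and is monotone in the threshold", {
  masks <- list(c(a = TRUE, b = TRUE, c = FALSE),
                c(a = TRUE, b = FALSE, c = FALSE),
                c(a = TRUE, b = TRUE, c = FALSE))
  cons <- consensus(masks, minCount = 3)
  expect_identical(consensusFeatures(cons), "a")
  expect_identical(unname(selectionCounts(cons)), c(3L, 2L, 0L))
  expect_identical(consensusFeatures(consensus(masks, 0)), c("a", "b", "c"))
  sizes <- vapply(0:3, function(mc)
    length(consensusFeatures(consensus(masks, mc))), 1L)
  expect_true(all(diff(sizes) <= 0))
  expect_error(consensus(list(), 1), "empty run list")
  expect_error(consensus(list(c(TRUE), c(TRUE, FALSE)), 1), "same length")
})

test_that("permutation ranking: baseline, unused features, planted ordering", {
  ds <- imputeZero(cleanDataset(n = 150, p = 20, k = 3, ipc = 2, effect = 3,
                                seed = 22))
  tr <- ds[, 1:110]; va <- ds[, 111:150]
  # with refit = FALSE acc1 equals the plain validation accuracy
  rk <- permutationRank(tr, va, forestConfig(nTrees = 60, seed = 2),
                        repetitions = 3, refit = FALSE, seed = 3)
  model <- fitForest(tr, forestConfig(nTrees = 60,
                                      seed = chemPercept:::deriveSeed(3,
                                        "rankfit", 1)))
  plain <- mean(predictLabels(model, va) == perceptLabels(va))
  expect_true(all(rk@acc1 == plain))
  # a constant descriptor the model cannot split on scores exactly 0
  vals <- cbind(descriptorMatrix(ds), CONST = 1)
  dsC <- DescriptorSet(vals, labels = perceptLabels(ds),
                       vocabulary = labelVocabulary(ds))
  rkC <- permutationRank(dsC[, 1:110], dsC[, 111:150],
                         forestConfig(nTrees = 60, seed = 2),
                         repetitions = 2, seed = 4)
  expect_equal(unname(rkC@indicator["CONST"]), 0)
  # planted descriptors occupy the top ranks in most seeded runs
  dsR <- imputeZero(cleanDataset(n = 160, p = 20, k = 3, ipc = 1,
                                 effect = 3, seed = 23))
  trR <- dsR[, 1:110]; vaR <- dsR[, 111:160]
  planted <- plantedFeatures(dsR)$allPlanted
  wins <- vapply(1:10, function(s) {
    r <- permutationRank(trR, vaR, forestConfig(nTrees = 60, seed = s),
                         repetitions = 3, seed = 60 + s)
    all(planted %in% head(r@rank, length(planted) + 2))
  }, logical(1))
  expect_gte(sum(wins), 6)
  expect_error(permutationRank(tr, va[, integer(0)]), "empty")
})

test_that("a duplicated descriptor masks/dilutes its permutation importance", {
  # with a perfectly correlated copy in the table, trees split between the
  # two and the majority vote compensates for permuting either one, so each
  # copy's indicator can only shrink relative to the unduplicated run
  splitOk <- vapply(1:10, function(s) {
    ds <- imputeZero(cleanDataset(n = 120, p = 8, k = 2, ipc = 1,
                                  effect = 3, seed = 300 + s))
    target <- plantedFeatures(ds)$allPlanted[1]
    vals <- descriptorMatrix(ds)
    valsDup <- cbind(vals, DUP = vals[, target])
    dsDup <- DescriptorSet(valsDup, labels = perceptLabels(ds),
                           vocabulary = labelVocabulary(ds))
    rk1 <- permutationRank(ds[, 1:90], ds[, 91:120],
                           forestConfig(nTrees = 60, seed = s),
                           features = target, repetitions = 4, seed = s)
    rk2 <- permutationRank(dsDup[, 1:90], dsDup[, 91:120],
                           forestConfig(nTrees = 60, seed = s),
                           features = c(target, "DUP"), repetitions = 4,
                           seed = s)
    rk1@indicator[target] > 0 &&
      max(rk2@indicator) <= rk1@indicator[target] + 0.02
  }, logical(1))
  expect_gte(sum(splitOk), 6)
})
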