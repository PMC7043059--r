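test_that("kappa is exactly 1 for any diagonal-only confusion matrix", {
  expect_equal(cohenKappa(diag(c(3, 5))), 1)
  expect_equal(cohenKappa(diag(c(560, 301, 257, 31, 24, 20, 17, 16, 15, 11,
                                 9, 6))), 1)
  expect_equal(cohenKappa(diag(rep(1, 30))), 1)
  expect_equal(cohenKappa(matrix(c(7, 0, 0, 0), 2, 2)), 1)  # degenerate
})

test_that("kappa agrees with the direct-formula oracle and its invariances", {
  expect_equal(cohenKappa(matrix(25, 2, 2)), 0)  # agreement equals chance
  cm3 <- rbind(c(10, 2, 0), c(1, 12, 1), c(0, 3, 11))
  expect_equal(cohenKappa(cm3), kappaOracle(cm3))
  expect_equal(cohenKappa(cm3), (33 / 40 - 538 / 1600) / (1 - 538 / 1600))
  set.seed(8)
  for (i in 1:10) {
    cm <- matrix(rpois(25, 6), 5, 5)
    expect_equal(cohenKappa(cm), kappaOracle(cm), tolerance = 1e-12)
    perm <- sample(5)
    expect_equal(cohenKappa(cm[perm, perm]), cohenKappa(cm))
    expect_identical(cohenKappa(cm) == 1, sum(cm) == sum(diag(cm)))
  }
  expect_error(cohenKappa(matrix(0, 3, 3)), "empty")
})

test_that("cross-validation pools folds coherently", {
  ds <- imputeZero(cleanDataset(n = 80, p = 10, k = 2, ipc = 1, effect = 6,
                                seed = 2))
  folds <- makeFolds(ds, 4, seed = 1)
  memorizer <- list(
    fit = function(tr) tr,
    predict = function(model, te) perceptLabels(te))
  cv <- crossValidate(ds, folds, memorizer)
  expect_equal(accuracyMean(cv), 1)
  expect_equal(accuracySd(cv), 0)
  expect_equal(kappaMean(cv), 1)
  expect_equal(sum(cv@confusion), 80)

  dummy <- list(
    fit = function(tr) names(which.max(table(perceptLabels(tr)))),
    predict = function(model, te)
      factor(rep(model, nMolecules(te)),
             levels = levels(perceptLabels(te))))
  ds2 <- handDataset(matrix(rnorm(120), 60, 2),
                     labels = rep(c("maj", "min"), c(45, 15)))
  cv2 <- crossValidate(ds2, makeFolds(ds2, 4, seed = 2), dummy)
  expect_equal(accuracyMean(cv2), 0.75)
  # pooled-confusion accuracy equals the molecule-weighted fold mean
  foldSizes <- tabulate(makeFolds(ds2, 4, seed = 2)@foldIndex, 4)
  expect_equal(sum(diag(cv2@confusion)) / sum(cv2@confusion),
               sum(cv2@foldAccuracy * foldSizes) / sum(foldSizes))
})

test_that("z-scores follow the sample-SD convention", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  z <- zscore(rnorm(50, 10, 4))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(zscore(z), z)
  expect_error(zscore(rep(2, 5), name = "D7"), "zero standard deviation.*D7")
  expect_error(zscore(3), "at least 2")
})

test_that("feature-class correlations behave like point-biserial values", {
  set.seed(5)
  y <- factor(rep(c("p", "q"), each = 30))
  ind <- as.numeric(y == "p")
  X <- cbind(IND = ind, matrix(rnorm(60 * 30), 60,
                               dimnames = list(NULL, paste0("N", 1:30))))
  rownames(X) <- sprintf("M%02d", 1:60)
  ds <- handDataset(X, labels = as.character(y))
  fcc <- featureClassCorrelation(ds)
  expect_equal(unname(fcc["IND", "p"]), 1)
  expect_equal(unname(fcc["IND", "q"]), -1)  # complementary two-class case
  expect_lt(max(abs(fcc[paste0("N", 1:30), ])), 4 / sqrt(60))
  # constant features log a message and get correlation 0
  Xc <- cbind(X, FLAT = 2)
  dsc <- handDataset(Xc, labels = as.character(y))
  expect_message(fcc2 <- featureClassCorrelation(dsc), "FLAT")
  expect_true(all(fcc2["FLAT", ] == 0))
})

test_that("hierarchical clustering groups identical and blocked rows", {
  m <- rbind(A = c(1, 1, 0), B = c(5, 5, 5), A2 = c(1, 1, 0),
             C = c(5.1, 5, 5))
  hc <- hierarchicalCluster(m)
  ord <- rownames(m)[hc$rowOrder]
  expect_equal(abs(which(ord == "A") - which(ord == "A2")), 1)
  expect_equal(abs(which(ord == "B") - which(ord == "C")), 1)
  expect_equal(as.matrix(dist(m))["A", "B"],
               sqrt(sum((m["A", ] - m["B", ])^2)))
  one <- hierarchicalCluster(m[1, , drop = FALSE])
  expect_equal(one$rowOrder, 1)
  expect_null(one$rowDendrogram)
  expect_error(hierarchicalCluster(matrix(c(1, NA), 1)), "finite")
})

test_that("cross-modal network tags shared features and respects the cutoff", {
  set.seed(7)
  shared <- rnorm(40)
  colorM <- cbind(K1 = shared, K2 = rnorm(40))
  odorM <- cbind(K1 = shared, K3 = rnorm(40))
  rownames(colorM) <- rownames(odorM) <- sprintf("M%02d", 1:40)
  net <- crossModalNetwork(colorM, odorM)
  e <- networkEdges(net)
  self <- e[e$colorFeature == "K1" & e$odorFeature == "K1", ]
  expect_equal(self$r, 1)
  nodes <- networkNodes(net)
  expect_equal(nodes$modality[nodes$feature == "K1"], "shared")
  expect_setequal(nodes$modality[nodes$feature %in% c("K2", "K3")],
                  c("color-key", "odor-key"))
  expect_equal(nrow(networkEdges(crossModalNetwork(colorM, odorM,
                                                   threshold = 1.01))), 0)
  # edge set is monotone non-increasing in the threshold
  sizes <- vapply(c(0, 0.2, 0.300552, 0.6, 1.01), function(th)
    nrow(networkEdges(crossModalNetwork(colorM, odorM, threshold = th))),
    1L)
  expect_true(all(diff(sizes) <= 0))
  expect_error(crossModalNetwork(colorM[1:2, ], odorM[1:2, ]),
               "at least 3")
})

test_that("dichotomized chi-square matches the closed form and chisq.test", {
  perfect <- matrix(c(10, 0, 0, 10), 2, 2)
  expect_equal(chiSquare2x2(perfect)@statistic, 20)
  expect_equal(chiSquare2x2(perfect)@statistic, chi2Oracle(perfect))
  indep <- matrix(c(10, 20, 5, 10), 2, 2)  # proportional margins
  expect_equal(chiSquare2x2(indep)@statistic, 0)
  set.seed(9)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 15) + 1, 2, 2)
    res <- chiSquare2x2(tab)
    expect_equal(res@statistic, chi2Oracle(tab), tolerance = 1e-9)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(res@statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(res@pValue, unname(ref$p.value), tolerance = 1e-9)
    refY <- suppressWarnings(chisq.test(tab, correct = TRUE))
    expect_equal(chiSquare2x2(tab, correct = TRUE)@statistic,
                 unname(refY$statistic), tolerance = 1e-9)
  }
  expect_error(chiSquare2x2(matrix(c(0, 0, 3, 4), 2, 2)), "empty margin")

  colors <- c("white", "colorless", "red", "red", "white", "colorless",
              "blue", "white")
  odors <- c("odorless", "odorless", "fruity", "spicy", "odorless",
             "fruity", "spicy", "odorless")
  res <- dichotomizeChi2(colors, odors)
  tab <- table(factor(colors %in% c("white", "colorless"),
                      levels = c(TRUE, FALSE)),
               factor(odors == "odorless", levels = c(TRUE, FALSE)))
  expect_equal(res@statistic,
               unname(suppressWarnings(
                 chisq.test(tab, correct = FALSE)$statistic)))
  expect_equal(res@dof, 1L)
})
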