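#' Pipeline configuration
#'
#' Describes one end-to-end run: where the data come from (exactly one of a
#' descriptor CSV or a synthetic spec), which perceptual task the labels
#' represent, which classifier(s) to cross-validate, and which descriptor
#' regime to use.
#'
#' @param csv path to a descriptor CSV (dialect of [writeDescriptorCsv()]).
#' @param labelColumn label column in the CSV (default "label").
#' @param spec a [SyntheticSpec-class] as the input source instead of a
#'   file.
#' @param task one of "color", "odor", "crossmodal".
#' @param model one of "forest", "dbn", "both".
#' @param featureSet one of "all", "rf_selected", "ga_selected", "union".
#' @param k cross-validation folds (default 4).
#' @param topM size of the importance-selected descriptor set (default 24).
#' @param maxMissing exclusion threshold for [filterHighMissing()].
#' @param ga a [GAConfig-class] for the GA regimes.
#' @param gaRuns,gaMinCount consensus schedule (default 20 runs, >= 18).
#' @param dbnHidden,dbnPretrainEpochs,dbnFineTuneEpochs,dbnLearningRate,
#'   dbnMomentum DBN settings.
#' @param colorPositive,odorPositive dichotomization sets for the
#'   cross-modal chi-square test.
#' @param threshold cross-modal network |r| cutoff.
#' @param seed master seed; stage seeds (folds, forest, GA, DBN,
#'   permutations) are independent streams derived from it.
#' @param outputDir directory for the JSON report and CSV tables (`NULL`
#'   disables writing).
#' @return a validated config (list with class "pipelineConfig").
#' @export
pipelineConfig <- function(csv = NULL, labelColumn = "label", spec = NULL,
                           task = c("color", "odor", "crossmodal"),
                           model = c("forest", "dbn", "both"),
                           featureSet = c("all", "rf_selected",
                                          "ga_selected", "union"),
                           k = 4L, topM = 24L, maxMissing = 2000L,
                           ga = gaConfig(), gaRuns = 20L, gaMinCount = 18L,
                           dbnHidden = 500L, dbnPretrainEpochs = 20L,
                           dbnFineTuneEpochs = 60L, dbnLearningRate = 0.05,
                           dbnMomentum = 0.5,
                           colorPositive = c("white", "colorless"),
                           odorPositive = "odorless", threshold = 0.300552,
                           seed = 1L, outputDir = NULL) {
  task <- match.arg(task)
  model <- match.arg(model)
  featureSet <- match.arg(featureSet)
  if (is.null(csv) == is.null(spec))
    stop("exactly one input source (csv or spec) must be given")
  if (task == "crossmodal" && is.null(spec))
    stop("crossmodal task requires a synthetic paired spec ",
         "(or use crossModalNetwork()/dichotomizeChi2() directly on files)")
  cfg <- list(csv = csv, labelColumn = labelColumn, spec = spec, task = task,
              model = model, featureSet = featureSet, k = as.integer(k),
              topM = as.integer(topM), maxMissing = as.integer(maxMissing),
              ga = ga, gaRuns = as.integer(gaRuns),
              gaMinCount = as.integer(gaMinCount),
              dbnHidden = as.integer(dbnHidden),
              dbnPretrainEpochs = as.integer(dbnPretrainEpochs),
              dbnFineTuneEpochs = as.integer(dbnFineTuneEpochs),
              dbnLearningRate = dbnLearningRate, dbnMomentum = dbnMomentum,
              colorPositive = colorPositive, odorPositive = odorPositive,
              threshold = threshold, seed = as.integer(seed),
              outputDir = outputDir)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipelineConfig()] arguments; a `spec:`
#' block is passed to [syntheticSpec()].
#'
#' @param path YAML file.
#' @return a pipeline config.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$spec)) y$spec <- do.call(syntheticSpec, y$spec)
  if (!is.null(y$ga)) y$ga <- do.call(gaConfig, y$ga)
  do.call(pipelineConfig, y)
}

loadInput <- function(config) {
  if (!is.null(config$csv))
    readDescriptorCsv(config$csv, labelColumn = config$labelColumn)
  else generateDataset(config$spec)
}

preprocess <- function(ds, config) {
  ds <- filterHighMissing(ds, config$maxMissing)
  imputeZero(ds)
}

# tiny stable hash of the config for provenance (no binary deps)
configHash <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "outputDir")]),
             collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %%
            .Machine$integer.max)
}

selectRegimeFeatures <- function(ds, folds, config) {
  out <- list()
  if (config$featureSet %in% c("rf_selected", "union") ||
      config$featureSet == "all") {
    # importance computed even under "all" so the report can list rankings
    fm <- fitForest(ds, forestConfig(seed = deriveSeed(config$seed,
                                                       "forest")))
    imp <- oobImportance(fm, seed = deriveSeed(config$seed, "importance"))
    out$importance <- imp
    out$rfSelected <- names(sort(imp, decreasing = TRUE))[
      seq_len(min(config$topM, length(imp)))]
  }
  if (config$featureSet %in% c("ga_selected", "union")) {
    ga <- config$ga
    ga@seed <- deriveSeed(config$seed, "ga")
    runs <- runGaConsensus(ds, ga, runs = config$gaRuns, folds = folds)
    cons <- consensus(runs, config$gaMinCount)
    out$gaConsensus <- cons
    out$gaSelected <- consensusFeatures(cons)
  }
  if (config$featureSet %in% c("ga_selected", "union") &&
      length(out$gaSelected) == 0L)
    stop("GA consensus is empty at minCount = ", config$gaMinCount,
         "; lower gaMinCount or increase gaRuns")
  out$features <- switch(config$featureSet,
    all = descriptorNames(ds),
    rf_selected = out$rfSelected,
    ga_selected = out$gaSelected,
    union = union(out$rfSelected, out$gaSelected))
  out
}

modelLearners <- function(config) {
  ls <- list()
  if (config$model %in% c("forest", "both"))
    ls$forest <- forestLearner(forestConfig(
      seed = deriveSeed(config$seed, "cvforest")))
  if (config$model %in% c("dbn", "both"))
    ls$dbn <- dbnLearner(hiddenSizes = config$dbnHidden,
                         pretrainEpochs = config$dbnPretrainEpochs,
                         fineTuneEpochs = config$dbnFineTuneEpochs,
                         learningRate = config$dbnLearningRate,
                         momentum = config$dbnMomentum,
                         seed = deriveSeed(config$seed, "cvdbn"))
  ls
}

cvToReport <- function(cv) {
  list(foldAccuracy = cv@foldAccuracy, accuracyMean = accuracyMean(cv),
       accuracySd = accuracySd(cv), foldKappa = cv@foldKappa,
       kappaMean = kappaMean(cv), kappaSd = kappaSd(cv),
       confusion = unclass(cv@confusion), vocabulary = cv@vocabulary,
       skippedFolds = cv@skippedFolds)
}

#' Run the full analysis pipeline
#'
#' Executes read -> exclusion filter -> zero imputation -> stratified folds
#' -> (feature selection if requested) -> model cross-validation -> metrics
#' -> association outputs, and writes a machine-readable JSON report plus
#' CSV tables when `outputDir` is set. For the crossmodal task it instead
#' generates the paired dataset, builds the Pearson network over the planted
#' key descriptors and runs the dichotomized chi-square test.
#'
#' @param config from [pipelineConfig()].
#' @return the report, invisibly a list (also written as
#'   `report.json`).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  if (config$task == "crossmodal") return(runCrossModal(config))
  ds <- loadInput(config)
  ds <- preprocess(ds, config)
  folds <- makeFolds(ds, k = config$k,
                     seed = deriveSeed(config$seed, "folds"))
  sel <- selectRegimeFeatures(ds, folds, config)
  dsUse <- if (identical(sel$features, descriptorNames(ds))) ds else
    selectFeatures(ds, sel$features)
  results <- lapply(modelLearners(config), function(l)
    crossValidate(dsUse, folds, l))
  fcc <- featureClassCorrelation(
    dsUse, head(sel$features, min(100L, length(sel$features))))
  clust <- hierarchicalCluster(fcc)
  report <- list(
    task = config$task, model = config$model,
    featureSet = config$featureSet,
    nMolecules = nMolecules(ds), nDescriptors = nDescriptors(ds),
    nFeaturesUsed = length(sel$features),
    removedMolecules = S4Vectors::metadata(ds)$removedMolecules$cid,
    selectedFeatures = if (config$featureSet == "all") NULL else
      sel$features,
    results = lapply(results, cvToReport),
    provenance = list(configHash = configHash(config), seed = config$seed,
                      k = config$k,
                      packageVersion = as.character(
                        utils::packageVersion("chemPercept"))))
  writeOutputs(report, config, extra = list(
    importance = sel$importance, gaConsensus = sel$gaConsensus,
    correlation = fcc, clustering = clust))
  invisible(report)
}

runCrossModal <- function(config) {
  pair <- generatePairedDataset(config$spec)
  dsC <- imputeZero(pair$color)
  dsO <- imputeZero(pair$odor)
  gt <- plantedFeatures(dsC)
  keyC <- unique(unlist(gt$plantedColor))
  keyO <- unique(unlist(gt$plantedOdor))
  valsC <- descriptorMatrix(dsC)[, keyC, drop = FALSE]
  valsO <- descriptorMatrix(dsO)[, keyO, drop = FALSE]
  zsafe <- function(m) apply(m, 2L, function(v)
    if (sd(v) == 0) v * 0 else zscore(v))
  net <- crossModalNetwork(zsafe(valsC), zsafe(valsO),
                           threshold = config$threshold)
  chi <- dichotomizeChi2(
    perceptLabels(dsC), perceptLabels(dsO),
    colorPositive = intersect(config$colorPositive,
                              labelVocabulary(dsC)) %0%
      labelVocabulary(dsC)[1],
    odorPositive = intersect(config$odorPositive,
                             labelVocabulary(dsO)) %0%
      labelVocabulary(dsO)[1])
  report <- list(
    task = "crossmodal",
    nSharedMolecules = nMolecules(dsC),
    threshold = config$threshold,
    nEdges = nrow(networkEdges(net)),
    sharedDescriptors = networkNodes(net)$feature[
      networkNodes(net)$modality == "shared"],
    chiSquare = list(statistic = chi@statistic, dof = chi@dof,
                     pValue = chi@pValue, table = unclass(chi@table)),
    provenance = list(configHash = configHash(config), seed = config$seed,
                      packageVersion = as.character(
                        utils::packageVersion("chemPercept"))))
  writeOutputs(report, config, extra = list(network = net))
  invisible(report)
}

`%0%` <- function(a, b) if (length(a)) a else b

writeOutputs <- function(report, config, extra = list()) {
  if (is.null(config$outputDir)) return(invisible(NULL))
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report,
                       file.path(config$outputDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  if (!is.null(extra$importance))
    writeImportance(extra$importance,
                    file.path(config$outputDir, "importance.csv"))
  if (!is.null(extra$gaConsensus))
    writeConsensus(extra$gaConsensus, names(extra$gaConsensus@selectionCount),
                   file.path(config$outputDir, "ga_consensus.csv"))
  if (!is.null(extra$network))
    writeEdgeList(extra$network, file.path(config$outputDir, "edges.csv"))
  if (!is.null(extra$correlation))
    data.table::fwrite(
      data.frame(descriptor = rownames(extra$correlation),
                 extra$correlation, check.names = FALSE),
      file.path(config$outputDir, "feature_class_correlation.csv"))
  invisible(NULL)
}

#' Structural validation of a pipeline report
#'
#' Checks a report against the bundled contract
#' (`inst/schema/report-schema.json`): required fields, types and ranges.
#'
#' @param report a report list from [runPipeline()].
#' @return `TRUE`, or an error describing the first violation.
#' @export
validateReport <- function(report) {
  need <- function(cond, msg) if (!cond) stop("invalid report: ", msg)
  need(is.list(report), "not a list")
  need(!is.null(report$task), "missing task")
  need(!is.null(report$provenance$configHash), "missing provenance hash")
  need(!is.null(report$provenance$seed), "missing seed")
  if (report$task == "crossmodal") {
    need(is.numeric(report$chiSquare$statistic) &&
           report$chiSquare$statistic >= 0, "bad chi-square statistic")
    need(report$nEdges >= 0, "bad edge count")
  } else {
    need(length(report$results) >= 1, "missing model results")
    for (res in report$results) {
      need(all(res$foldAccuracy >= 0 & res$foldAccuracy <= 1),
           "accuracy out of [0,1]")
      need(all(res$foldKappa >= -1 & res$foldKappa <= 1),
           "kappa out of [-1,1]")
      need(is.matrix(res$confusion) || is.list(res$confusion),
           "missing confusion matrix")
    }
  }
  TRUE
}

#' Compare descriptor regimes by cross-validated accuracy
#'
#' Reproduces the boxplot-style comparison of four regimes: all
#' descriptors, the top-m by forest importance, the GA-consensus set, and
#' their union. Returns a tidy per-fold accuracy table with one median per
#' regime.
#'
#' @param config from [pipelineConfig()] (its `model` picks the learner;
#'   "both" runs the forest).
#' @return list with `table` (regime, nFeatures, fold, accuracy) and
#'   `medians` (regime, nFeatures, median).
#' @export
compareFeatureSets <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  ds <- preprocess(loadInput(config), config)
  folds <- makeFolds(ds, k = config$k,
                     seed = deriveSeed(config$seed, "folds"))
  cfgU <- config; cfgU$featureSet <- "union"
  sel <- selectRegimeFeatures(ds, folds, cfgU)
  regimes <- list(all = descriptorNames(ds), rf_selected = sel$rfSelected,
                  ga_selected = sel$gaSelected,
                  union = union(sel$rfSelected, sel$gaSelected))
  regimes <- regimes[vapply(regimes, length, 1L) > 0]
  learner <- if (config$model == "dbn") modelLearners(config)$dbn else
    forestLearner(forestConfig(seed = deriveSeed(config$seed, "cvforest")))
  rows <- lapply(names(regimes), function(rg) {
    cv <- crossValidate(selectFeatures(ds, regimes[[rg]]), folds, learner)
    data.frame(regime = rg, nFeatures = length(regimes[[rg]]),
               fold = seq_along(cv@foldAccuracy),
               accuracy = cv@foldAccuracy)
  })
  tab <- do.call(rbind, rows)
  med <- stats::aggregate(accuracy ~ regime + nFeatures, tab, stats::median)
  names(med)[names(med) == "accuracy"] <- "median"
  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(tab, file.path(config$outputDir,
                                      "feature_set_comparison.csv"))
  }
  list(table = tab, medians = med)
}
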