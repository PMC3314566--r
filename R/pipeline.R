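# End-to-end orchestration: similarity -> embedding -> ensemble -> ranking
# -> stability report, reproducible from (config, seed), with artifacts
# echoed to an output directory.

#' Read a pipeline configuration file
#'
#' @param path YAML or JSON configuration file; fields mirror the arguments
#'   of [runPipeline()].
#' @return Named list.
#' @export
readPipelineConfig <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

.configDigest <- function(config) {
  # stable short fingerprint of the effective configuration
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  sprintf("%08x", sum(utf8ToInt(as.character(js)) *
                        seq_along(utf8ToInt(as.character(js)))) %%
            .Machine$integer.max)
}

#' Run the full stability-aware biomarker discovery pipeline
#'
#' Stages: (1) obtain expression data and a similarity matrix (from files,
#' from in-memory objects, or from the synthetic generators when
#' \code{config$preset == "standard"}); (2) align features; (3) tune the
#' embedding weight alpha over a grid by within-dataset list stability;
#' (4) rank features with the bootstrap perceptron ensemble at the tuned
#' alpha; (5) write artifacts (alpha report, global ranked list, a sample
#' of per-split lists, stability report JSON, effective config echo).
#'
#' @param config named list (or path to a YAML/JSON file) with fields:
#'   \code{expression} (path) and \code{labelColumn}, or \code{preset =
#'   "standard"} for the built-in synthetic fixture (optionally with
#'   \code{fidelity}); \code{similarity} (path to a similarity TSV, omitted
#'   for the synthetic preset); \code{alphaGrid}; \code{splits},
#'   \code{trainFraction}, \code{maxEpochs}, \code{pairBudget};
#'   \code{seed}; \code{outDir}.
#' @param dataset,similarity optional in-memory
#'   \linkS4class{ExpressionDataset} / \linkS4class{SimilarityMatrix}
#'   overriding the config's input stage.
#' @return The stability report: a list with \code{alphaStar},
#'   \code{report} (per-alpha table), \code{stability} and
#'   \code{meanAccuracy} at the tuned alpha, \code{oobAccuracy}, and the
#'   global \code{rankedList}.
#' @export
runPipeline <- function(config, dataset = NULL, similarity = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  cfg <- runConfig(
    T = if (is.null(config$splits)) 200L else as.integer(config$splits),
    trainFraction = if (is.null(config$trainFraction)) 0.7
                    else config$trainFraction,
    maxEpochs = if (is.null(config$maxEpochs)) 500L
                else as.integer(config$maxEpochs),
    seed = seed,
    pairBudget = if (is.null(config$pairBudget)) 10000L
                 else as.integer(config$pairBudget))
  alphaGrid <- if (is.null(config$alphaGrid)) cfg$alphaGrid
               else as.numeric(config$alphaGrid)

  # stage 1: inputs
  if (is.null(dataset)) {
    if (identical(config$preset, "standard")) {
      design <- blockDesign(seed = seed)
      dataset <- makeExpression(design)$dataset
      if (is.null(similarity)) {
        fidelity <- if (is.null(config$fidelity)) 1 else config$fidelity
        similarity <- makeSimilarity(design, fidelity = fidelity)
      }
    } else if (!is.null(config$expression)) {
      dataset <- readExpression(
        config$expression,
        labelColumn = if (is.null(config$labelColumn)) "label"
                      else config$labelColumn,
        labelsPath = config$labelsPath)
    } else stop("stage input: no expression data configured")
  }
  if (is.null(similarity)) {
    if (is.null(config$similarity))
      stop("stage input: no similarity matrix configured")
    similarity <- readSimilarity(config$similarity)
  }

  # stage 2: alignment
  al <- alignFeatures(dataset, similarity)
  dataset <- al$dataset
  similarity <- al$similarity

  # stage 3-4: alpha tuning + ranking at the tuned alpha
  tuned <- tuneAlpha(dataset, similarity, alphaGrid, cfg)
  globalList <- rankFeatures(tuned$best)
  embStar <- buildEmbedding(similarity, tuned$alphaStar)
  tdStar <- transformStandardize(dataset, embStar)
  oob <- oobAccuracy(tuned$best, tdStar)
  bestRow <- which(tuned$report$alpha == tuned$alphaStar)

  report <- list(alphaStar = tuned$alphaStar,
                 report = tuned$report,
                 stability = tuned$report$stability[bestRow],
                 meanAccuracy = tuned$report$meanAccuracy[bestRow],
                 meanEpochs = tuned$report$meanEpochs[bestRow],
                 oobAccuracy = oob,
                 rankedList = globalList)

  # stage 5: artifacts
  outDir <- config$outDir
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    digest <- .configDigest(config)
    utils::write.table(tuned$report,
                       file.path(outDir, "alpha_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeRankedList(globalList, file.path(outDir, "ranked_global.tsv"))
    nKeep <- min(20L, length(tuned$bestLists))
    dir.create(file.path(outDir, "split_lists"), showWarnings = FALSE)
    for (t in seq_len(nKeep))
      writeRankedList(tuned$bestLists[[t]],
                      file.path(outDir, "split_lists",
                                sprintf("split_%03d.tsv", t)))
    writeSimilarity(similarity, file.path(outDir, "similarity.tsv"))
    jsonlite::write_json(
      list(configHash = digest,
           alphaStar = report$alphaStar,
           stability = report$stability,
           meanAccuracy = report$meanAccuracy,
           meanEpochs = report$meanEpochs,
           oobAccuracy = report$oobAccuracy,
           report = tuned$report),
      file.path(outDir, "stability_report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    config$configHash <- digest
    jsonlite::write_json(config, file.path(outDir, "config_echo.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}
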