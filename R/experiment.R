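#' Configuration of an end-to-end segmentation experiment
#'
#' Bundles everything \code{\link{runExperiment}} needs to realise the
#' ablation grid \{variants\} x \{+-BEM\} x \{+-label correction\} on
#' synthetic data: dataset generation (or an existing manifest), network
#' and training settings, the sliding-window specification, confusion sets,
#' and the master seed from which every other seed is derived.
#'
#' @param outputDir results directory (created).
#' @param dataDir directory with an existing \code{manifest.csv}; if
#'   \code{NULL} a dataset is generated under \code{outputDir/data}.
#' @param nVolumes,split,volumeShape dataset size, split and grid shape
#'   passed to \code{\link{generateDataset}} when generating.
#' @param variants network variants to train and evaluate.
#' @param twoStagePred also evaluate BEM with a separately trained binary
#'   network guiding the baseline variant's probabilities.
#' @param twoStageGt also evaluate BEM with the ground-truth binary mask
#'   (upper bound) on the baseline variant's probabilities.
#' @param levels,channels architecture of all trained networks.
#' @param iterations,patchSize,learningRate training protocol.
#' @param inferPatch,overlap,pad sliding-window settings.
#' @param confusionSets a \code{\link{confusionSetConfig}} or NULL for
#'   \code{\link{defaultConfusionSets}} of the dataset's class count.
#' @param seed master seed; every training run, volume and noise field uses
#'   a seed derived from it.
#' @return A validated list of class \code{ExperimentConfig}.
#' @export
experimentConfig <- function(outputDir, dataDir = NULL, nVolumes = 8L,
                             split = c(train = 5L, val = 1L, test = 2L),
                             volumeShape = c(32L, 32L, 64L),
                             variants = c("baseline", "dual_d"),
                             twoStagePred = FALSE, twoStageGt = TRUE,
                             levels = 2L, channels = c(8L, 16L),
                             iterations = 200L, patchSize = 32L,
                             learningRate = 0.001, inferPatch = 32L,
                             overlap = 8L, pad = 0L, confusionSets = NULL,
                             seed = 1L) {
  variants <- match.arg(variants, c("baseline", "dual_a", "dual_b", "dual_c",
                                    "dual_d"), several.ok = TRUE)
  if ((twoStagePred || twoStageGt) && !("baseline" %in% variants))
    stop("two-stage evaluation guides the baseline variant's probabilities; add 'baseline' to variants")
  structure(list(outputDir = outputDir, dataDir = dataDir,
                 nVolumes = as.integer(nVolumes), split = split,
                 volumeShape = as.integer(volumeShape), variants = variants,
                 twoStagePred = twoStagePred, twoStageGt = twoStageGt,
                 levels = as.integer(levels), channels = as.integer(channels),
                 iterations = as.integer(iterations),
                 patchSize = as.integer(patchSize),
                 learningRate = learningRate,
                 inferPatch = as.integer(inferPatch),
                 overlap = as.integer(overlap), pad = as.integer(pad),
                 confusionSets = confusionSets, seed = as.integer(seed)),
            class = "ExperimentConfig")
}

#' Read an experiment configuration from a YAML file
#'
#' Top-level keys mirror the arguments of \code{\link{experimentConfig}};
#' \code{confusionSets} may be given as a list of integer lists plus a
#' \code{cap}.
#'
#' @param path YAML file.
#' @return An \code{ExperimentConfig}.
#' @export
readExperimentConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$confusionSets))
    y$confusionSets <- confusionSetConfig(y$confusionSets$sets,
                                          y$confusionSets$cap %||% 100L)
  if (!is.null(y$split)) y$split <- unlist(y$split)
  do.call(experimentConfig, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.eval_cell <- function(pred, gt) dscPerClass(pred, gt)

#' Run a reproducible end-to-end experiment
#'
#' Executes generate, train, infer, correct and evaluate stages and writes,
#' under \code{config$outputDir}: per-variant loss traces
#' (\code{trace_<variant>.csv}), per-class Dice scores of every test volume
#' and ablation cell (\code{scores.csv}), the ablation summary in the
#' four-cell layout baseline / +label correction / +BEM-inference / +both
#' (\code{summary.csv}), and a provenance log (\code{provenance.json}).
#' Every artefact is reproducible from the configuration and master seed.
#'
#' @param config an \code{\link{experimentConfig}}.
#' @return Invisibly, the summary data.frame.
#' @export
runExperiment <- function(config) {
  stopifnot(inherits(config, "ExperimentConfig"))
  stage <- "setup"
  runStage <- function(name, expr) {
    stage <<- name
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] done in %.1f s", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)

  manifest <- runStage("generate", {
    if (is.null(config$dataDir)) {
      generateDataset(file.path(config$outputDir, "data"),
                      nVolumes = config$nVolumes, split = config$split,
                      seed = config$seed,
                      params = anatomyParams(volumeShape = config$volumeShape))
    } else {
      utils::read.csv(file.path(config$dataDir, "manifest.csv"),
                      stringsAsFactors = FALSE)
    }
  })

  gts <- lapply(which(manifest$split == "test"), function(i)
    readVolume(manifest$seg[i], "labels"))
  nClasses <- max(vapply(gts, nClasses, 0L))
  cts <- lapply(which(manifest$split == "test"), function(i)
    readVolume(manifest$ct[i], "ct"))
  csets <- config$confusionSets %||% defaultConfusionSets(nClasses)

  models <- runStage("train", {
    out <- list()
    for (k in seq_along(config$variants)) {
      v <- config$variants[k]
      net <- buildNetwork(networkConfig(v, nClassesMulti = nClasses,
                                        levels = config$levels,
                                        channels = config$channels),
                          seed = .derive_seed(config$seed, 100L + k))
      tr <- trainNetwork(net, manifest,
                         trainConfig(learningRate = config$learningRate,
                                     iterations = config$iterations,
                                     patchSize = config$patchSize,
                                     seed = .derive_seed(config$seed, 200L + k)))
      utils::write.csv(tr$trace,
                       file.path(config$outputDir,
                                 sprintf("trace_%s.csv", v)),
                       row.names = FALSE)
      out[[v]] <- tr$model
    }
    if (config$twoStagePred) {
      net <- buildNetwork(networkConfig("baseline", nClassesMulti = 2L,
                                        levels = config$levels,
                                        channels = config$channels),
                          seed = .derive_seed(config$seed, 300L))
      tr <- trainNetwork(net, manifest,
                         trainConfig(learningRate = config$learningRate,
                                     iterations = config$iterations,
                                     patchSize = config$patchSize,
                                     seed = .derive_seed(config$seed, 301L)),
                         binarizeTargets = TRUE)
      utils::write.csv(tr$trace,
                       file.path(config$outputDir, "trace_binary.csv"),
                       row.names = FALSE)
      out[["binary"]] <- tr$model
    }
    out
  })

  spec <- patchSpec(config$inferPatch, config$overlap, config$pad)
  scores <- list()
  addScore <- function(row, cell, vol, df) {
    df$row <- row; df$cell <- cell; df$volume <- vol
    scores[[length(scores) + 1]] <<- df
  }

  runStage("evaluate", {
    for (ti in seq_along(cts)) {
      gt <- gts[[ti]]
      basePred <- NULL
      for (v in config$variants) {
        pr <- slidingWindowPredict(cts[[ti]], models[[v]], spec)
        dual <- !is.null(pr$binary)
        P <- if (dual) pr$multi else pr
        std <- standardArgmax(P)
        addScore(v, "baseline", ti, .eval_cell(std, gt))
        addScore(v, "label_correction", ti,
                 .eval_cell(correctLabels(std, csets), gt))
        if (dual) {
          bem <- bemCombine(P, maskToBinary(pr$binary))
          addScore(v, "bem", ti, .eval_cell(bem, gt))
          addScore(v, "both", ti, .eval_cell(correctLabels(bem, csets), gt))
        }
        if (v == "baseline") basePred <- P
      }
      if (config$twoStagePred) {
        prB <- slidingWindowPredict(cts[[ti]], models[["binary"]], spec)
        bem <- bemCombine(basePred, maskToBinary(prB))
        addScore("two_stage_pred", "bem", ti, .eval_cell(bem, gt))
        addScore("two_stage_pred", "both", ti,
                 .eval_cell(correctLabels(bem, csets), gt))
      }
      if (config$twoStageGt) {
        bem <- bemCombine(basePred, binarizeLabels(gt))
        addScore("two_stage_gt", "bem", ti, .eval_cell(bem, gt))
        addScore("two_stage_gt", "both", ti,
                 .eval_cell(correctLabels(bem, csets), gt))
      }
    }
  })

  runStage("summarise", {
    allScores <- do.call(rbind, scores)
    utils::write.csv(allScores, file.path(config$outputDir, "scores.csv"),
                     row.names = FALSE)
    rows <- unique(allScores$row)
    cells <- c("baseline", "label_correction", "bem", "both")
    # a cell without any true-positive voxel (conceivable in very short
    # smoke runs) reports NA rather than aborting the experiment
    safeSummary <- function(sub) {
      if (nrow(sub) == 0L) return(NULL)
      tryCatch(summarizeScores(sub), error = function(e) NULL)
    }
    summary <- do.call(rbind, lapply(rows, function(r) {
      vals <- vapply(cells, function(cl) {
        s <- safeSummary(allScores[allScores$row == r &
                                     allScores$cell == cl, , drop = FALSE])
        if (is.null(s)) NA_character_ else formatSummary(s)
      }, "")
      med <- vapply(cells, function(cl) {
        s <- safeSummary(allScores[allScores$row == r &
                                     allScores$cell == cl, , drop = FALSE])
        if (is.null(s)) NA_real_ else s$median
      }, 0)
      data.frame(model = r, cell = cells, summary = vals, medianDSC = med,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(summary, file.path(config$outputDir, "summary.csv"),
                     row.names = FALSE)
    prov <- list(seed = config$seed,
                 package = as.character(utils::packageVersion("BoneBEM")),
                 config = config[setdiff(names(config), "confusionSets")],
                 configHash = .config_hash(config),
                 rversion = R.version.string)
    jsonlite::write_json(prov, file.path(config$outputDir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(summary)
  })
}

.config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  # small stable polynomial hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%d", h)
}
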