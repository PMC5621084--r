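#' @include AllClasses.R synthetic.R selection.R classifier.R features-graphic.R
NULL

#' Default pipeline configuration
#'
#' All knobs of the end-to-end pipeline in one list: corpus size and
#' sampling, the occupancy-grid working resolution, the filter variant
#' feeding the wrapper, CV shape, network training length, and the master
#' seed from which every source of randomness is derived.
#'
#' @param outDir artifact directory (default "posture-out").
#' @param seed master seed.
#' @return named list of configuration values.
#' @export
defaultPipelineConfig <- function(outDir = "posture-out", seed = 1) {
  list(outDir = outDir, seed = seed, fs = 100, nPerSituation = 20,
       resolution = 990, filterVariant = "ttest2", nKeep = 20,
       folds = 10, repetitions = 10, tol = 0.001, maxit = 100, relieffK = 10)
}

.write_artifact <- function(object, path, config) {
  meta <- list(config = config, seed = config$seed)
  jsonlite::write_json(c(meta, list(result = object)), path,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

.report_as_list <- function(report) {
  list(mean_rate = report@meanRate,
       repetition_means = report@repetitionMeans,
       confusion = report@confusion, seed = report@seed)
}

#' Run the posture-classification pipeline
#'
#' Commands:
#' \describe{
#'   \item{simulate}{generate the synthetic corpus and write it (manifest +
#'     per-trial CSVs + layout JSON) under \code{outDir/trials}.}
#'   \item{extract}{read trials from \code{outDir/trials} (or generate them)
#'     and write the direct (60-column) and graphic feature tables as CSV.}
#'   \item{select}{run hybrid selection on the direct table and write the
#'     ranked trace CSV.}
#'   \item{train}{train the network on the hybrid-selected direct features of
#'     the whole corpus and write the JSON weight file.}
#'   \item{evaluate}{repeated stratified CV of the hybrid-selected direct
#'     features; writes an evaluation report.}
#'   \item{full}{the four benchmark comparisons: the filter-only top-20
#'     (dir_filter), the hybrid-selected direct subset (dir_hybride), the
#'     hybrid-selected graphic subset (graph_hybride), and their combination
#'     (integrate); writes one evaluation report per comparison plus a
#'     summary JSON, and returns the four \linkS4class{EvalReport}s.}
#' }
#' Every artifact embeds the generating configuration and seed.
#'
#' @param command one of simulate, extract, select, train, evaluate, full.
#' @param config a configuration list, see [defaultPipelineConfig()].
#' @return command-dependent, invisibly (the \code{full} report list is
#'   returned visibly).
#' @export
runPipeline <- function(command = c("full", "simulate", "extract", "select",
                                    "train", "evaluate"),
                        config = defaultPipelineConfig()) {
  command <- match.arg(command)
  cfg <- utils::modifyList(defaultPipelineConfig(), config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  layout <- defaultLayout()
  trialsDir <- file.path(cfg$outDir, "trials")

  corpus <- function() {
    if (dir.exists(trialsDir) && file.exists(file.path(trialsDir, "manifest.csv")))
      readTrials(trialsDir)
    else
      generateCorpus(cfg$nPerSituation, cfg$seed, layout = layout, fs = cfg$fs)
  }

  if (command == "simulate") {
    trials <- generateCorpus(cfg$nPerSituation, cfg$seed, layout = layout,
                             fs = cfg$fs)
    writeTrials(trials, trialsDir)
    writeLayout(layout, file.path(trialsDir, "layout.json"))
    .write_artifact(list(n_trials = length(trials)),
                    file.path(cfg$outDir, "simulate.json"), cfg)
    return(invisible(trials))
  }

  trials <- corpus()
  direct <- extractDirect(trials, layout)

  if (command == "extract") {
    graphic <- extractGraphic(trials, layout, cfg$resolution)
    writeFeatures(direct, file.path(cfg$outDir, "features_direct.csv"))
    writeFeatures(graphic, file.path(cfg$outDir, "features_graphic.csv"))
    return(invisible(list(direct = direct, graphic = graphic)))
  }

  selDirect <- function()
    hybridSelect(direct, variant = cfg$filterVariant, nKeep = cfg$nKeep,
                 folds = cfg$folds, seed = cfg$seed, tol = cfg$tol,
                 relieffK = cfg$relieffK, maxit = cfg$maxit)

  if (command == "select") {
    sel <- selDirect()
    writeSelection(sel, file.path(cfg$outDir, "selection_direct.csv"))
    return(invisible(sel))
  }

  if (command == "train") {
    sel <- selDirect()
    model <- mlpTrain(featureValues(direct)[, selectedFeatures(sel), drop = FALSE],
                      situations(direct), seed = cfg$seed, maxit = cfg$maxit)
    writeMlpModel(model, file.path(cfg$outDir, "model.json"))
    return(invisible(model))
  }

  if (command == "evaluate") {
    sel <- selDirect()
    report <- evaluateCv(direct, selectedFeatures(sel),
                         repetitions = cfg$repetitions, folds = cfg$folds,
                         seed = cfg$seed, maxit = cfg$maxit)
    writeEvalReport(report, file.path(cfg$outDir, "eval_direct.json"))
    return(invisible(report))
  }

  # full: the four benchmark comparisons
  graphic <- extractGraphic(trials, layout, cfg$resolution)
  filtScores <- aggregateFilter(direct, relieffK = cfg$relieffK)
  filt20 <- topFeatures(filtScores, cfg$filterVariant, cfg$nKeep)
  sel_dir <- sfsWrapper(direct, filt20, folds = cfg$folds, seed = cfg$seed,
                        tol = cfg$tol, maxit = cfg$maxit)
  sel_graph <- hybridSelect(graphic, variant = cfg$filterVariant,
                            nKeep = cfg$nKeep, folds = cfg$folds,
                            seed = cfg$seed, tol = cfg$tol,
                            relieffK = cfg$relieffK, maxit = cfg$maxit)
  combined <- combineFeatures(direct, graphic)
  subsets <- list(
    dir_filter = filt20,
    dir_hybride = selectedFeatures(sel_dir),
    graph_hybride = selectedFeatures(sel_graph),
    integrate = c(selectedFeatures(sel_dir), selectedFeatures(sel_graph)))
  reports <- lapply(names(subsets), function(nm) {
    tab <- if (nm == "graph_hybride") graphic else
           if (nm %in% c("dir_filter", "dir_hybride")) direct else combined
    rep <- evaluateCv(tab, subsets[[nm]], repetitions = cfg$repetitions,
                      folds = cfg$folds, seed = cfg$seed, maxit = cfg$maxit)
    writeEvalReport(rep, file.path(cfg$outDir, paste0("eval_", nm, ".json")))
    rep
  })
  names(reports) <- names(subsets)
  writeSelection(sel_dir, file.path(cfg$outDir, "selection_direct.csv"))
  writeSelection(sel_graph, file.path(cfg$outDir, "selection_graphic.csv"))
  .write_artifact(
    list(subsets = subsets,
         mean_rates = lapply(reports, function(r) meanRate(r))),
    file.path(cfg$outDir, "full_summary.json"), cfg)
  reports
}
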