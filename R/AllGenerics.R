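#' @include AllClasses.R
NULL

#' Sensor coordinates of a layout
#' @param object a \linkS4class{SensorLayout}.
#' @return numeric n x 2 matrix of sensor positions (mm).
#' @export
setGeneric("sensorCoords", function(object) standardGeneric("sensorCoords"))

#' @rdname sensorCoords
#' @export
setMethod("sensorCoords", "SensorLayout", function(object) object@coords)

#' Bounding rectangle of a layout or grid
#' @param object a \linkS4class{SensorLayout} or \linkS4class{OccupancyGrid}.
#' @return numeric length-2 (width, height) in mm.
#' @export
setGeneric("insoleBounds", function(object) standardGeneric("insoleBounds"))

#' @rdname insoleBounds
#' @export
setMethod("insoleBounds", "SensorLayout", function(object) object@bounds)

#' @rdname insoleBounds
#' @export
setMethod("insoleBounds", "OccupancyGrid", function(object) object@bounds)

#' COP samples of a trajectory
#' @param object a \linkS4class{CopTrajectory}.
#' @return numeric T x 2 matrix (mm).
#' @export
setGeneric("copSamples", function(object) standardGeneric("copSamples"))

#' @rdname copSamples
#' @export
setMethod("copSamples", "CopTrajectory", function(object) object@samples)

#' Sampling rate accessor
#' @param object a \linkS4class{CopTrajectory}.
#' @return sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "CopTrajectory", function(object) object@fs)

#' Occupancy cells of a grid
#' @param object an \linkS4class{OccupancyGrid}.
#' @return integer rows x cols 0/1 matrix.
#' @export
setGeneric("gridCells", function(object) standardGeneric("gridCells"))

#' @rdname gridCells
#' @export
setMethod("gridCells", "OccupancyGrid", function(object) object@cells)

#' Feature matrix of a feature table
#'
#' Returns the trials x features numeric matrix (the transpose of the stored
#' features x trials assay), which is the orientation the selection and
#' classification code consumes.
#'
#' @param object a \linkS4class{PostureFeatures}.
#' @return numeric trials x features matrix with feature column names.
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))

#' @rdname featureValues
#' @export
setMethod("featureValues", "PostureFeatures", function(object)
  t(SummarizedExperiment::assay(object, "features")))

#' Situation labels of a feature table
#' @param object a \linkS4class{PostureFeatures}.
#' @return integer vector of situation labels (1..6), one per trial.
#' @export
setGeneric("situations", function(object) standardGeneric("situations"))

#' @rdname situations
#' @export
setMethod("situations", "PostureFeatures", function(object)
  as.integer(SummarizedExperiment::colData(object)$situation))

#' Selected features of a selection result
#' @param object a \linkS4class{SelectionResult}.
#' @return character vector, the retained feature prefix.
#' @export
setGeneric("selectedFeatures", function(object) standardGeneric("selectedFeatures"))

#' @rdname selectedFeatures
#' @export
setMethod("selectedFeatures", "SelectionResult", function(object) object@selected)

#' Accuracy trace of a selection result
#' @param object a \linkS4class{SelectionResult}.
#' @return numeric vector of mean CV recognition rates, one per SFS addition.
#' @export
setGeneric("accuracyTrace", function(object) standardGeneric("accuracyTrace"))

#' @rdname accuracyTrace
#' @export
setMethod("accuracyTrace", "SelectionResult", function(object) object@accuracyTrace)

#' Ranked features of a selection result
#' @param object a \linkS4class{SelectionResult}.
#' @return character vector, the full greedy ordering.
#' @export
setGeneric("rankedFeatures", function(object) standardGeneric("rankedFeatures"))

#' @rdname rankedFeatures
#' @export
setMethod("rankedFeatures", "SelectionResult", function(object) object@rankedFeatures)

#' Mean recognition rate of an evaluation report
#' @param object an \linkS4class{EvalReport}.
#' @return numeric scalar in [0, 1].
#' @export
setGeneric("meanRate", function(object) standardGeneric("meanRate"))

#' @rdname meanRate
#' @export
setMethod("meanRate", "EvalReport", function(object) object@meanRate)

#' Confusion matrix of an evaluation report
#' @param object an \linkS4class{EvalReport}.
#' @return integer classes x classes matrix, rows = true situation.
#' @export
setGeneric("confusionMatrix", function(object) standardGeneric("confusionMatrix"))

#' @rdname confusionMatrix
#' @export
setMethod("confusionMatrix", "EvalReport", function(object) object@confusion)

setMethod("show", "SensorLayout", function(object) {
  cat("SensorLayout:", nrow(object@coords), "sensors over",
      paste(object@bounds, collapse = " x "), "mm\n")
})

setMethod("show", "PostureTrial", function(object) {
  cat(sprintf("PostureTrial %s | situation %d | insole %d x %d @ %g Hz | helmet %d x 3 @ %g Hz\n",
              object@trialId, object@situation,
              nrow(object@pressures), ncol(object@pressures), object@fsInsole,
              nrow(object@headAcc), object@fsHelmet))
})

setMethod("show", "CopTrajectory", function(object) {
  cat(sprintf("CopTrajectory: %d samples @ %g Hz (%.1f s)\n",
              nrow(object@samples), object@fs, nrow(object@samples) / object@fs))
})

setMethod("show", "OccupancyGrid", function(object) {
  cat(sprintf("OccupancyGrid: %d x %d (resolution %d), %d cells occupied\n",
              nrow(object@cells), ncol(object@cells), length(object@cells),
              sum(object@cells)))
})

setMethod("show", "FilterScores", function(object) {
  cat(sprintf("FilterScores: %d features x %d tests; top aggregate: %s\n",
              nrow(object@raw), ncol(object@raw),
              paste(head(object@ranking$aggregate, 5), collapse = ", ")))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d candidates, %d selected (best CV rate %.3f)\n",
              length(object@rankedFeatures), length(object@selected),
              max(object@accuracyTrace)))
  cat("  selected:", paste(object@selected, collapse = ", "), "\n")
})

setMethod("show", "MlpModel", function(object) {
  cat(sprintf("MlpModel: %d-%d-%d tanh/softmax network\n",
              nrow(object@W1), ncol(object@W1), ncol(object@W2)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d x %d-fold CV, mean recognition rate %.3f\n",
              nrow(object@foldRates), ncol(object@foldRates), object@meanRate))
})

setMethod("show", "SituationSpec", function(object) {
  cat(sprintf("SituationSpec %d: %s/%s, %gs, center (%g, %g) mm, dispersion %g mm\n",
              object@situation, object@kind, object@adequacy, object@duration,
              object@copCenter[1], object@copCenter[2], object@copDispersion))
})
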