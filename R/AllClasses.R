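#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats var sd fft qchisq runif rnorm optim setNames quantile dist cov
#' @importFrom utils read.csv write.csv head
NULL

#' SensorLayout: geometry of the insole force sensors
#'
#' Positions (mm) of the insole force sensors in the insole plane, together
#' with the bounding rectangle that encloses every center-of-pressure (COP)
#' position. The coordinate convention used throughout the package is
#' X = mediolateral, Y = anteroposterior, origin at the lower-left corner of
#' the bounding rectangle, units mm.
#'
#' @slot coords numeric matrix, one row per sensor, columns \code{x}, \code{y} (mm).
#' @slot bounds numeric length-2: width (X extent) and height (Y extent) of the
#'   rectangle enclosing all COP positions, in mm.
#'
#' @seealso [sensorLayout()], [defaultLayout()], [computeCop()]
#' @export
setClass("SensorLayout",
  representation(coords = "matrix", bounds = "numeric"))

setValidity("SensorLayout", function(object) {
  msg <- character()
  if (!is.numeric(object@coords) || ncol(object@coords) != 2L)
    msg <- c(msg, "coords must be a numeric matrix with 2 columns (x, y)")
  if (nrow(object@coords) < 3L)
    msg <- c(msg, "at least 3 sensors are required")
  if (length(object@bounds) != 2L || any(object@bounds <= 0))
    msg <- c(msg, "bounds must be two positive lengths (width, height) in mm")
  if (anyDuplicated(object@coords) > 0)
    msg <- c(msg, "sensor coordinates must be distinct")
  if (is.numeric(object@coords) && ncol(object@coords) == 2L &&
      length(object@bounds) == 2L) {
    inx <- object@coords[, 1] >= 0 & object@coords[, 1] <= object@bounds[1]
    iny <- object@coords[, 2] >= 0 & object@coords[, 2] <= object@bounds[2]
    if (!all(inx & iny))
      msg <- c(msg, "all sensor coordinates must lie inside the bounds rectangle")
  }
  if (length(msg)) msg else TRUE
})

#' PostureTrial: one synchronized insole + helmet recording
#'
#' A single trial: the insole pressure time series (one column per force
#' sensor, raw units -- only ratios of pressures are ever used) and the 3-axis
#' head acceleration time series (m/s^2; X mediolateral, Y anteroposterior,
#' Z vertical), each at its own sampling rate, plus the work-situation label.
#'
#' @slot pressures numeric T x n matrix of non-negative sensor pressures.
#' @slot headAcc numeric T' x 3 matrix of head accelerations (m/s^2).
#' @slot fsInsole,fsHelmet sampling rates in Hz.
#' @slot situation integer work-situation label in 1..6.
#' @slot trialId character identifier, unique within a corpus.
#'
#' @seealso [generateTrial()], [readTrials()], [computeCop()]
#' @export
setClass("PostureTrial",
  representation(pressures = "matrix", headAcc = "matrix",
                 fsInsole = "numeric", fsHelmet = "numeric",
                 situation = "integer", trialId = "character"))

setValidity("PostureTrial", function(object) {
  msg <- character()
  if (any(object@pressures < 0)) msg <- c(msg, "pressures must be non-negative")
  if (any(rowSums(object@pressures) <= 0))
    msg <- c(msg, "at least one sensor pressure must be > 0 at every sample")
  if (ncol(object@headAcc) != 3L) msg <- c(msg, "headAcc must have 3 columns (X, Y, Z)")
  if (!(object@situation %in% 1:6)) msg <- c(msg, "situation must be in 1..6")
  if (object@fsInsole <= 0 || object@fsHelmet <= 0)
    msg <- c(msg, "sampling rates must be positive")
  if (length(object@trialId) != 1L || !nzchar(object@trialId))
    msg <- c(msg, "trialId must be a non-empty string")
  if (length(msg)) msg else TRUE
})

#' CopTrajectory: the center-of-pressure path of one trial
#'
#' Per-sample COP coordinates (mm) in the insole plane. The trajectory
#' plotted in the plane is the statokinesigram; its per-axis time series are
#' the stabilograms.
#'
#' @slot samples numeric T x 2 matrix, columns \code{x} (mediolateral) and
#'   \code{y} (anteroposterior), mm.
#' @slot fs sampling rate, Hz.
#'
#' @seealso [computeCop()], [copVelocity()], [rasterize()]
#' @export
setClass("CopTrajectory",
  representation(samples = "matrix", fs = "numeric"))

setValidity("CopTrajectory", function(object) {
  msg <- character()
  if (ncol(object@samples) != 2L) msg <- c(msg, "samples must have 2 columns (x, y)")
  if (!all(is.finite(object@samples))) msg <- c(msg, "samples must be finite")
  if (length(object@fs) != 1L || object@fs <= 0) msg <- c(msg, "fs must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' CopVelocity: per-step COP velocities
#'
#' Forward-difference velocity estimates of a COP trajectory: mediolateral and
#' anteroposterior components and the resultant magnitude, mm/s, length T - 1.
#'
#' @slot vx,vy,v numeric vectors (mm/s); \code{v = sqrt(vx^2 + vy^2)} pointwise.
#' @seealso [copVelocity()]
#' @export
setClass("CopVelocity",
  representation(vx = "numeric", vy = "numeric", v = "numeric"))

setValidity("CopVelocity", function(object) {
  msg <- character()
  n <- length(object@vx)
  if (length(object@vy) != n || length(object@v) != n)
    msg <- c(msg, "vx, vy, v must have equal length")
  if (n > 0 && max(abs(object@v - sqrt(object@vx^2 + object@vy^2))) > 1e-8)
    msg <- c(msg, "v must equal sqrt(vx^2 + vy^2) pointwise")
  if (length(msg)) msg else TRUE
})

#' OccupancyGrid: binary discretization of a COP trajectory
#'
#' The insole bounding rectangle divided into a rows x cols grid; a cell is 1
#' iff at least one COP sample fell in it. Cell (1, 1) sits at the origin
#' corner; rows index the mediolateral (X) axis and columns the
#' anteroposterior (Y) axis, so a cell measures (width/rows) x (height/cols) mm.
#'
#' @slot cells integer rows x cols matrix of 0/1 occupancies.
#' @slot bounds numeric length-2 rectangle (width, height), mm.
#' @seealso [rasterize()], [gridDimensions()], [extractGraphic()]
#' @export
setClass("OccupancyGrid",
  representation(cells = "matrix", bounds = "numeric"))

setValidity("OccupancyGrid", function(object) {
  msg <- character()
  if (!all(object@cells %in% c(0L, 1L))) msg <- c(msg, "cells must be binary")
  if (sum(object@cells) < 1L) msg <- c(msg, "at least one cell must be occupied")
  if (length(object@bounds) != 2L || any(object@bounds <= 0))
    msg <- c(msg, "bounds must be two positive lengths")
  if (length(msg)) msg else TRUE
})

#' PostureFeatures: a features x trials table with situation labels
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one named feature
#' vector per trial: rows are features, columns are trials, and
#' \code{colData} carries \code{situation} (integer 1..6) and \code{trialId}.
#'
#' @seealso [extractDirect()], [extractGraphic()], [featureValues()],
#'   [situations()], [combineFeatures()]
#' @export
setClass("PostureFeatures", contains = "SummarizedExperiment")

setValidity("PostureFeatures", function(object) {
  msg <- character()
  if (anyDuplicated(rownames(object)) > 0) msg <- c(msg, "feature names must be unique")
  if (!all(c("situation", "trialId") %in% colnames(SummarizedExperiment::colData(object))))
    msg <- c(msg, "colData must contain situation and trialId")
  if (length(SummarizedExperiment::assays(object)) >= 1L &&
      anyNA(SummarizedExperiment::assay(object)))
    msg <- c(msg, "feature values must not contain missing values")
  if (length(msg)) msg else TRUE
})

#' FilterScores: per-feature relevance scores from the five filter tests
#'
#' Raw, min-max-normalized, and aggregated (mean of normalized) filter scores
#' for every feature, plus the descending ranking by aggregate score. Two-class
#' tests (Fisher, two-sample t, Pearson) are averaged over all unordered class
#' pairs before normalization.
#'
#' @slot raw,normalized numeric features x tests matrices; tests are
#'   \code{fisher}, \code{ttest2}, \code{pearson}, \code{anova}, \code{relieff}.
#' @slot aggregate named numeric vector in [0, 1].
#' @slot ranking list of character vectors: one descending feature ranking per
#'   test plus \code{aggregate}.
#' @seealso [aggregateFilter()]
#' @export
setClass("FilterScores",
  representation(raw = "matrix", normalized = "matrix",
                 aggregate = "numeric", ranking = "list"))

setValidity("FilterScores", function(object) {
  msg <- character()
  if (nrow(object@raw) != nrow(object@normalized) ||
      length(object@aggregate) != nrow(object@raw))
    msg <- c(msg, "raw, normalized and aggregate must agree in feature count")
  norm <- object@normalized[is.finite(object@normalized)]
  if (length(norm) && (min(norm) < -1e-12 || max(norm) > 1 + 1e-12))
    msg <- c(msg, "normalized scores must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' SelectionResult: outcome of sequential forward selection
#'
#' The full greedy ordering of the candidate features, the mean
#' cross-validated recognition rate after each addition, and the retained
#' prefix (shortest prefix whose accuracy is within a small tolerance of the
#' trace maximum).
#'
#' @slot rankedFeatures character, greedy SFS ordering (no duplicates).
#' @slot accuracyTrace numeric, mean CV recognition rate after each addition.
#' @slot selected character, the retained prefix of \code{rankedFeatures}.
#' @seealso [sfsWrapper()], [hybridSelect()]
#' @export
setClass("SelectionResult",
  representation(rankedFeatures = "character", accuracyTrace = "numeric",
                 selected = "character"))

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (anyDuplicated(object@rankedFeatures) > 0)
    msg <- c(msg, "rankedFeatures must not contain duplicates")
  if (length(object@accuracyTrace) != length(object@rankedFeatures))
    msg <- c(msg, "accuracyTrace length must match rankedFeatures")
  k <- length(object@selected)
  if (k > length(object@rankedFeatures) ||
      (k > 0 && !identical(object@selected, object@rankedFeatures[seq_len(k)])))
    msg <- c(msg, "selected must be a prefix of rankedFeatures")
  if (length(msg)) msg else TRUE
})

#' MlpModel: a trained single-hidden-layer tanh/softmax network
#'
#' Weights of the i-12-6 multilayer perceptron together with the
#' standardization (z-score) parameters fitted on the training data and the
#' class levels. Inputs are standardized before the hidden layer.
#'
#' @slot W1,b1 hidden-layer weights (i x 12) and biases.
#' @slot W2,b2 output-layer weights (12 x 6) and biases.
#' @slot center,scale per-feature standardization parameters.
#' @slot classes integer class labels in training order.
#' @slot featureNames character, the input features in column order.
#' @seealso [mlpTrain()], [mlpPredict()]
#' @export
setClass("MlpModel",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
                 center = "numeric", scale = "numeric",
                 classes = "integer", featureNames = "character"))

#' EvalReport: repeated stratified k-fold cross-validation summary
#'
#' Per-fold recognition rates for every repetition, their means, the overall
#' mean recognition rate, the pooled confusion matrix, and the seed used.
#'
#' @slot foldRates numeric repetitions x folds matrix of recognition rates.
#' @slot repetitionMeans numeric, mean rate per repetition.
#' @slot meanRate numeric scalar, mean over all fold rates.
#' @slot confusion integer classes x classes matrix (rows = truth), pooled
#'   over folds and repetitions.
#' @slot seed integer master seed of the evaluation.
#' @seealso [evaluateCv()]
#' @export
setClass("EvalReport",
  representation(foldRates = "matrix", repetitionMeans = "numeric",
                 meanRate = "numeric", confusion = "matrix", seed = "integer"))

setValidity("EvalReport", function(object) {
  msg <- character()
  if (abs(object@meanRate - mean(object@foldRates)) > 1e-9)
    msg <- c(msg, "meanRate must equal the mean of all fold rates")
  if (length(object@repetitionMeans) != nrow(object@foldRates))
    msg <- c(msg, "one repetition mean per repetition is required")
  if (length(msg)) msg else TRUE
})

#' SituationSpec: generative parameters of one work situation
#'
#' Parameters of the synthetic-trial generator for one of the six work
#' situations: static situations follow a mean-reverting AR(1) COP around a
#' situation-specific center; dynamic situations superimpose a sinusoidal
#' sweep. Head accelerations are means plus noise (static) or means plus
#' oscillation plus noise (dynamic).
#'
#' @slot situation integer 1..6.
#' @slot kind "static" or "dynamic".
#' @slot adequacy "adequate" or "inadequate".
#' @slot duration trial duration, s (20 static, 15 dynamic).
#' @slot copCenter numeric length-2 COP center (mm).
#' @slot copDispersion stationary COP dispersion scale (mm).
#' @slot arCoef AR(1) pull-back coefficient in [0, 1).
#' @slot sweepAmplitude,sweepFreq numeric length-2 amplitude (mm) and scalar
#'   frequency (Hz) of the dynamic sweep (zero for static situations).
#' @slot accMeans numeric length-3 head-acceleration means (m/s^2).
#' @slot accNoise head-acceleration noise s.d. (m/s^2).
#' @slot accOscAmplitude head-acceleration oscillation amplitude for dynamic
#'   situations (m/s^2).
#' @seealso [defaultSituationSpecs()], [generateTrial()]
#' @export
setClass("SituationSpec",
  representation(situation = "integer", kind = "character", adequacy = "character",
                 duration = "numeric", copCenter = "numeric",
                 copDispersion = "numeric", arCoef = "numeric",
                 sweepAmplitude = "numeric", sweepFreq = "numeric",
                 accMeans = "numeric", accNoise = "numeric",
                 accOscAmplitude = "numeric"))

setValidity("SituationSpec", function(object) {
  msg <- character()
  if (!(object@situation %in% 1:6)) msg <- c(msg, "situation must be in 1..6")
  if (!object@kind %in% c("static", "dynamic")) msg <- c(msg, "kind must be static/dynamic")
  if (!object@adequacy %in% c("adequate", "inadequate"))
    msg <- c(msg, "adequacy must be adequate/inadequate")
  if (object@duration <= 0) msg <- c(msg, "duration must be positive")
  if (object@arCoef < 0 || object@arCoef >= 1) msg <- c(msg, "arCoef must be in [0, 1)")
  if (length(object@copCenter) != 2L) msg <- c(msg, "copCenter must have length 2")
  if (length(object@accMeans) != 3L) msg <- c(msg, "accMeans must have length 3")
  if (length(msg)) msg else TRUE
})
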