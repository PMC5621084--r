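#' @include AllClasses.R
NULL

#' Compute the center-of-pressure trajectory of a trial
#'
#' The COP at each sample is the pressure-weighted barycenter of the sensor
#' positions:
#' \deqn{X_{COP} = \sum_i X_i P_i / \sum_i P_i, \qquad
#'       Y_{COP} = \sum_i Y_i P_i / \sum_i P_i.}
#' The formula is a ratio, so it is invariant to rescaling all pressures by a
#' positive constant, and with non-negative pressures the COP always lies in
#' the convex hull of the sensor positions.
#'
#' @param trial a \linkS4class{PostureTrial}.
#' @param layout a \linkS4class{SensorLayout} whose sensor count matches the
#'   trial's pressure columns.
#' @return a \linkS4class{CopTrajectory} (mm, at the insole sampling rate).
#' @examples
#' lay <- defaultLayout()
#' p <- matrix(1, nrow = 10, ncol = 4)   # equal load: COP at sensor centroid
#' tr <- postureTrial(p, matrix(0, 10, 3), situation = 1, trialId = "t1")
#' copSamples(computeCop(tr, lay))[1, ]
#' @export
computeCop <- function(trial, layout) {
  P <- pressures(trial)
  XY <- sensorCoords(layout)
  if (ncol(P) != nrow(XY))
    stop(sprintf("trial has %d pressure channels but layout has %d sensors",
                 ncol(P), nrow(XY)), call. = FALSE)
  tot <- rowSums(P)
  if (any(tot <= 0))
    stop(sprintf("all-zero pressure at sample %d", which(tot <= 0)[1]),
         call. = FALSE)
  samples <- cbind(x = (P %*% XY[, 1]) / tot,
                   y = (P %*% XY[, 2]) / tot)
  colnames(samples) <- c("x", "y")
  new("CopTrajectory", samples = samples, fs = trial@fsInsole)
}

#' Construct a COP trajectory directly
#'
#' @param samples numeric T x 2 matrix of (x, y) positions, mm.
#' @param fs sampling rate, Hz.
#' @return a \linkS4class{CopTrajectory}.
#' @export
copTrajectory <- function(samples, fs = 100) {
  samples <- as.matrix(samples); storage.mode(samples) <- "double"
  colnames(samples) <- c("x", "y")
  new("CopTrajectory", samples = samples, fs = as.numeric(fs))
}

#' Per-step COP velocity by forward differences
#'
#' Velocity components are forward differences of the stabilograms scaled by
#' the sampling rate, \eqn{v_x[t] = (x[t+1] - x[t]) f_s}, so a trajectory of T
#' samples yields T - 1 velocity samples; the magnitude is
#' \eqn{v = \sqrt{v_x^2 + v_y^2}}. No smoothing is applied: a smoothed
#' estimator changes the velocity feature bank and must be an explicit,
#' separate preprocessing step.
#'
#' @param cop a \linkS4class{CopTrajectory} with at least 2 samples.
#' @return a \linkS4class{CopVelocity} (mm/s).
#' @export
copVelocity <- function(cop) {
  s <- copSamples(cop)
  if (nrow(s) < 2L) stop("at least 2 samples are required", call. = FALSE)
  vx <- diff(s[, 1]) * samplingRate(cop)
  vy <- diff(s[, 2]) * samplingRate(cop)
  new("CopVelocity", vx = as.numeric(vx), vy = as.numeric(vy),
      v = sqrt(vx^2 + vy^2))
}

#' Export a COP trajectory as CSV
#'
#' Writes \code{t,xcop,ycop} (s, mm, mm).
#'
#' @param cop a \linkS4class{CopTrajectory}.
#' @param path output CSV file.
#' @return invisibly, \code{path}.
#' @export
writeCopTrajectory <- function(cop, path) {
  s <- copSamples(cop)
  write.csv(data.frame(t = (seq_len(nrow(s)) - 1) / samplingRate(cop),
                       xcop = s[, 1], ycop = s[, 2]),
            path, row.names = FALSE)
  invisible(path)
}
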