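#' @include AllClasses.R recordings-io.R cop.R
NULL

.situation_spec <- function(situation, kind, adequacy, duration, copCenter,
                            copDispersion, arCoef = 0.95,
                            sweepAmplitude = c(0, 0), sweepFreq = 0,
                            accMeans, accNoise, accOscAmplitude = 0) {
  new("SituationSpec", situation = as.integer(situation), kind = kind,
      adequacy = adequacy, duration = duration,
      copCenter = as.numeric(copCenter), copDispersion = copDispersion,
      arCoef = arCoef, sweepAmplitude = as.numeric(sweepAmplitude),
      sweepFreq = sweepFreq, accMeans = as.numeric(accMeans),
      accNoise = accNoise, accOscAmplitude = accOscAmplitude)
}

#' Default generative specifications of the six work situations
#'
#' The six situations mirror three workstation tasks, each performed in an
#' adequate and an inadequate variant:
#' \itemize{
#'   \item 1 (adequate) and 2 (inadequate): static load carriage, 20 s;
#'   \item 3 (adequate) and 4 (inadequate): dynamic handling movements, 15 s;
#'   \item 5 (adequate) and 6 (inadequate): static unloaded posture, 20 s.
#' }
#' Static situations use a mean-reverting AR(1) COP around a
#' situation-specific center -- adequate postures disperse a few mm
#' (stability), inadequate ones noticeably more -- while dynamic situations
#' sweep the COP sinusoidally across much of the insole. COP centers differ
#' by situation (forward trunk lean and load carriage shift the COP
#' anteriorly). Head-acceleration means are approximately
#' (X, Y) = (2, 0), (2, 2), (1, 0), (2, 0) m/s^2 for situations 1, 2, 5, 6,
#' with the vertical axis dominated by gravity (9.81 m/s^2); dynamic
#' situations add a synchronized oscillation on top of the means.
#'
#' @return list of six \linkS4class{SituationSpec} objects.
#' @export
defaultSituationSpecs <- function() {
  g <- 9.81
  list(
    .situation_spec(1, "static", "adequate", 20, copCenter = c(21, 75),
                    copDispersion = 2.0, accMeans = c(2, 0, g), accNoise = 0.3),
    .situation_spec(2, "static", "inadequate", 20, copCenter = c(25, 95),
                    copDispersion = 6.0, accMeans = c(2, 2, g), accNoise = 0.45),
    .situation_spec(3, "dynamic", "adequate", 15, copCenter = c(20, 65),
                    copDispersion = 3.0, sweepAmplitude = c(6, 35),
                    sweepFreq = 0.3, accMeans = c(1.5, 1, g), accNoise = 0.5,
                    accOscAmplitude = 1.5),
    .situation_spec(4, "dynamic", "inadequate", 15, copCenter = c(22, 70),
                    copDispersion = 5.0, sweepAmplitude = c(12, 50),
                    sweepFreq = 0.45, accMeans = c(1.5, 1.5, g), accNoise = 0.7,
                    accOscAmplitude = 2.5),
    .situation_spec(5, "static", "adequate", 20, copCenter = c(20, 60),
                    copDispersion = 1.5, accMeans = c(1, 0, g), accNoise = 0.25),
    .situation_spec(6, "static", "inadequate", 20, copCenter = c(24, 85),
                    copDispersion = 5.0, accMeans = c(2, 0, g), accNoise = 0.4))
}

.simulate_cop_path <- function(spec, n, fs, lim_lo, lim_hi) {
  # mean-reverting AR(1) around the center (stationary s.d. = copDispersion);
  # dynamic situations add a sinusoidal sweep to the center path
  phi <- spec@arCoef
  sigma_eps <- spec@copDispersion * sqrt(1 - phi^2)
  tt <- (seq_len(n) - 1) / fs
  center <- matrix(spec@copCenter, n, 2, byrow = TRUE)
  if (spec@kind == "dynamic") {
    phase <- runif(1, 0, 2 * pi)
    center[, 1] <- center[, 1] + spec@sweepAmplitude[1] *
      sin(2 * pi * spec@sweepFreq * tt + phase)
    center[, 2] <- center[, 2] + spec@sweepAmplitude[2] *
      sin(2 * pi * spec@sweepFreq * tt + phase + pi / 3)
  }
  dev <- matrix(0, n, 2)
  eps <- matrix(rnorm(2 * n, sd = sigma_eps), n, 2)
  dev[1, ] <- rnorm(2, sd = spec@copDispersion)
  for (t in 2:n) dev[t, ] <- phi * dev[t - 1, ] + eps[t, ]
  path <- center + dev
  # clip to the sensor rectangle with a small interior margin
  path[, 1] <- pmin(pmax(path[, 1], lim_lo[1]), lim_hi[1])
  path[, 2] <- pmin(pmax(path[, 2], lim_lo[2]), lim_hi[2])
  path
}

.is_rectangular_layout <- function(coords) {
  nrow(coords) == 4L &&
    length(unique(coords[, 1])) == 2L && length(unique(coords[, 2])) == 2L &&
    nrow(unique(coords)) == 4L
}

.allocate_pressures <- function(path, coords, load) {
  n <- nrow(path)
  if (.is_rectangular_layout(coords)) {
    xs <- sort(unique(coords[, 1])); ys <- sort(unique(coords[, 2]))
    u <- (path[, 1] - xs[1]) / (xs[2] - xs[1])
    v <- (path[, 2] - ys[1]) / (ys[2] - ys[1])
    W <- matrix(NA_real_, n, 4)
    for (j in 1:4) {
      wx <- if (coords[j, 1] == xs[1]) 1 - u else u
      wy <- if (coords[j, 2] == ys[1]) 1 - v else v
      W[, j] <- wx * wy          # bilinear: exactly inverted by the barycenter
    }
  } else {
    # general layouts: smallest non-negative weights reproducing the COP
    W <- matrix(NA_real_, n, nrow(coords))
    A <- rbind(t(coords), rep(1, nrow(coords)))
    for (t in seq_len(n)) {
      w <- pracma::lsqnonneg(A, c(path[t, ], 1))$x
      if (sum(w) <= 0 || max(abs(A %*% w - c(path[t, ], 1))) > 1e-6)
        stop(sprintf("COP target at sample %d lies outside the sensor hull", t),
             call. = FALSE)
      W[t, ] <- w
    }
  }
  if (any(W < -1e-9))
    stop("COP target path leaves the sensor hull", call. = FALSE)
  pmax(W, 0) * load
}

#' Generate one synthetic trial
#'
#' Simulates a COP target path from the situation's generative model, then
#' allocates non-negative sensor pressures whose barycenter reproduces that
#' path exactly (bilinear weights for a rectangular layout, non-negative
#' least squares otherwise), so [computeCop()] recovers the target to
#' floating-point precision. Head accelerations are the situation means plus
#' Gaussian noise, with an added oscillation for dynamic situations. The
#' total load carries a constant offset emulating a 9 kg carried piece in the
#' load-carriage and handling situations (cosmetic: the barycenter is
#' scale-invariant). Fully reproducible from \code{seed}.
#'
#' @param spec a \linkS4class{SituationSpec}.
#' @param layout a \linkS4class{SensorLayout}.
#' @param fs sampling rate for both streams, Hz (default 100).
#' @param seed integer seed.
#' @param trialId identifier (default derived from situation and seed).
#' @return a \linkS4class{PostureTrial}.
#' @export
generateTrial <- function(spec, layout = defaultLayout(), fs = 100, seed = 1,
                          trialId = sprintf("s%d_seed%d", spec@situation, seed)) {
  coords <- sensorCoords(layout)
  margin <- 0.5
  lim_lo <- apply(coords, 2, min) + margin
  lim_hi <- apply(coords, 2, max) - margin
  if (any(spec@copCenter < lim_lo | spec@copCenter > lim_hi))
    stop("spec COP center lies outside the sensor hull", call. = FALSE)
  n <- round(spec@duration * fs)
  .with_seed(seed, {
    # trial-level random effects: an operator does not reproduce identical
    # sway statistics across repetitions of the same situation
    tspec <- spec
    tspec@copCenter <- spec@copCenter + rnorm(2, sd = 2.5)
    tspec@copCenter <- pmin(pmax(tspec@copCenter, lim_lo + 1), lim_hi - 1)
    tspec@copDispersion <- spec@copDispersion * exp(rnorm(1, sd = 0.3))
    tspec@accNoise <- spec@accNoise * exp(rnorm(1, sd = 0.25))
    accMeans <- spec@accMeans + rnorm(3, sd = 0.35)
    if (spec@kind == "dynamic") {
      tspec@sweepAmplitude <- spec@sweepAmplitude * exp(rnorm(1, sd = 0.2))
      tspec@sweepFreq <- spec@sweepFreq * runif(1, 0.85, 1.15)
      tspec@accOscAmplitude <- spec@accOscAmplitude * exp(rnorm(1, sd = 0.2))
    }
    path <- .simulate_cop_path(tspec, n, fs, lim_lo, lim_hi)
    body_weight <- 700                       # N, order of magnitude only
    load <- body_weight + (if (spec@situation %in% 1:4) 9 * 9.81 else 0) +
      rnorm(n, sd = 5)
    P <- .allocate_pressures(path, coords, pmax(load, 1))
    tt <- (seq_len(n) - 1) / fs
    acc <- matrix(rnorm(3 * n, sd = tspec@accNoise), n, 3)
    acc <- sweep(acc, 2, accMeans, `+`)
    if (spec@kind == "dynamic") {
      phase <- runif(3, 0, 2 * pi)
      for (j in 1:3)
        acc[, j] <- acc[, j] + tspec@accOscAmplitude *
          sin(2 * pi * tspec@sweepFreq * tt + phase[j])
    }
    postureTrial(P, acc, situation = spec@situation, trialId = trialId,
                 fsInsole = fs, fsHelmet = fs)
  })
}

#' Generate the six-situation synthetic corpus
#'
#' Generates \code{nPerSituation} trials of each situation (default 20, i.e.
#' a 120-trial corpus) with per-trial seeds derived deterministically from
#' the master seed.
#'
#' @param nPerSituation trials per situation (default 20).
#' @param seed integer master seed.
#' @param specs list of \linkS4class{SituationSpec} (default
#'   [defaultSituationSpecs()]).
#' @param layout a \linkS4class{SensorLayout}.
#' @param fs sampling rate, Hz.
#' @return list of \code{6 * nPerSituation} \linkS4class{PostureTrial}
#'   objects, ordered by (situation, trial index).
#' @examples
#' corpus <- generateCorpus(nPerSituation = 2, seed = 42)
#' table(vapply(corpus, situation, integer(1)))
#' @export
generateCorpus <- function(nPerSituation = 20, seed = 1,
                           specs = defaultSituationSpecs(),
                           layout = defaultLayout(), fs = 100) {
  trials <- list()
  for (spec in specs) {
    for (i in seq_len(nPerSituation)) {
      tseed <- (seed * 1009 + spec@situation * 101 + i * 7) %% 2147483647
      trials[[length(trials) + 1L]] <-
        generateTrial(spec, layout, fs, seed = tseed,
                      trialId = sprintf("s%d_t%02d", spec@situation, i))
    }
  }
  trials
}
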