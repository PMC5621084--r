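#' @include AllClasses.R cop.R
NULL

# The six summary statistics applied to every signal, in registry order.
.STAT_SUFFIX <- c("m", "max", "std", "var", "rms", "kurt")

.six_stats <- function(x, warn_label = "signal") {
  m <- mean(x)
  v <- var(x)                      # sample variance
  mu2 <- mean((x - m)^2)           # population moments for kurtosis
  if (mu2 > 0) {
    kurt <- mean((x - m)^4) / mu2^2   # Pearson convention: normal -> 3
  } else {
    warning(sprintf("zero-variance %s: kurtosis set to 0", warn_label),
            call. = FALSE)
    kurt <- 0
  }
  c(m = m, max = max(x), std = sqrt(v), var = v,
    rms = sqrt(mean(x^2)), kurt = kurt)
}

#' Names of the 60-feature direct bank, in registry order
#'
#' The fixed ordering is: the six statistics (mean, max, std, var, rms,
#' kurtosis) of the mediolateral and anteroposterior stabilograms (Xm..Xkurt,
#' Ym..Ykurt), of the resultant and per-axis COP velocities (Vm..Vkurt,
#' VXm..VXkurt, VYm..VYkurt), then the eight statokinesigram features
#' (lg_tot, m_lg_seg, std_lg_seg, dist_prdr, Am_X, Am_Y, surf_ellip, lfs),
#' the four frequency features (mnfreqX, mnfreqY, mdfreqX, mdfreqY), and the
#' eighteen head-acceleration statistics (AccXm..AccZkurt).
#'
#' @return character vector of length 60.
#' @export
directFeatureNames <- function() {
  c(paste0("X", .STAT_SUFFIX), paste0("Y", .STAT_SUFFIX),
    paste0("V", .STAT_SUFFIX), paste0("VX", .STAT_SUFFIX),
    paste0("VY", .STAT_SUFFIX),
    "lg_tot", "m_lg_seg", "std_lg_seg", "dist_prdr",
    "Am_X", "Am_Y", "surf_ellip", "lfs",
    "mnfreqX", "mnfreqY", "mdfreqX", "mdfreqY",
    paste0("AccX", .STAT_SUFFIX), paste0("AccY", .STAT_SUFFIX),
    paste0("AccZ", .STAT_SUFFIX))
}

#' Head-acceleration features (18 values)
#'
#' Mean, maximum, standard deviation, variance, root-mean-square and kurtosis
#' (Pearson convention, so a normal signal scores about 3) of each
#' acceleration axis.
#'
#' @param headAcc numeric T' x 3 matrix of head accelerations (X, Y, Z), m/s^2,
#'   with at least 4 samples (kurtosis needs the fourth moment).
#' @return named numeric vector of length 18 (AccXm..AccZkurt).
#' @export
accFeatures <- function(headAcc) {
  headAcc <- as.matrix(headAcc)
  if (nrow(headAcc) < 4L) stop("at least 4 samples are required", call. = FALSE)
  if (ncol(headAcc) != 3L) stop("headAcc must have 3 columns", call. = FALSE)
  out <- unlist(lapply(1:3, function(j)
    .six_stats(headAcc[, j], warn_label = paste0("Acc", c("X", "Y", "Z")[j]))))
  names(out) <- c(paste0("AccX", .STAT_SUFFIX), paste0("AccY", .STAT_SUFFIX),
                  paste0("AccZ", .STAT_SUFFIX))
  out
}

#' Statokinesigram features (8 values)
#'
#' Planar sway-path features of the COP trajectory:
#' \describe{
#'   \item{lg_tot}{total path length, the sum of inter-sample segment lengths (mm).}
#'   \item{m_lg_seg, std_lg_seg}{mean and standard deviation of segment lengths (mm).}
#'   \item{dist_prdr}{distance between the first and last point (mm).}
#'   \item{Am_X, Am_Y}{per-axis displacement amplitude, max minus min (mm).}
#'   \item{surf_ellip}{area of the 90\% prediction ellipse (mm^2), computed
#'     from the eigen-decomposition of the sample covariance with semi-axes
#'     \eqn{\sqrt{\chi^2_2(0.90)\,\lambda_i}}, i.e. area
#'     \eqn{\pi\,\chi^2_2(0.90)\sqrt{\lambda_1\lambda_2}}.}
#'   \item{lfs}{length-over-surface ratio lg_tot / surf_ellip (1/mm), a proxy
#'     for the energy spent in postural control; defined as 0 (with a warning)
#'     for a degenerate zero-area trajectory.}
#' }
#'
#' @param cop a \linkS4class{CopTrajectory} with at least 3 samples.
#' @return named numeric vector of length 8.
#' @export
statokinesigramFeatures <- function(cop) {
  s <- copSamples(cop)
  if (nrow(s) < 3L) stop("at least 3 samples are required", call. = FALSE)
  seg <- sqrt(diff(s[, 1])^2 + diff(s[, 2])^2)
  lg_tot <- sum(seg)
  Sigma <- stats::cov(s)
  detS <- max(det(Sigma), 0)
  surf <- pi * qchisq(0.90, df = 2) * sqrt(detS)
  if (surf > 0) {
    lfs <- lg_tot / surf
  } else {
    warning("degenerate trajectory: surf_ellip = 0, lfs set to 0", call. = FALSE)
    lfs <- 0
  }
  c(lg_tot = lg_tot, m_lg_seg = mean(seg), std_lg_seg = sd(seg),
    dist_prdr = sqrt(sum((s[nrow(s), ] - s[1, ])^2)),
    Am_X = diff(range(s[, 1])), Am_Y = diff(range(s[, 2])),
    surf_ellip = surf, lfs = lfs)
}

#' Stabilogram features (30 values)
#'
#' The six summary statistics applied to the mediolateral and anteroposterior
#' COP time series (Xm..Ykurt, 12 values) and to the resultant velocity
#' magnitude and the signed per-axis velocity components (Vm..VYkurt,
#' 18 values).
#'
#' @param cop a \linkS4class{CopTrajectory} with at least 4 samples.
#' @param vel the matching \linkS4class{CopVelocity} (computed with
#'   [copVelocity()] if omitted).
#' @return named numeric vector of length 30.
#' @export
stabilogramFeatures <- function(cop, vel = copVelocity(cop)) {
  s <- copSamples(cop)
  if (nrow(s) < 4L) stop("at least 4 samples are required", call. = FALSE)
  out <- c(.six_stats(s[, 1], "X_COP"), .six_stats(s[, 2], "Y_COP"),
           .six_stats(vel@v, "V"), .six_stats(vel@vx, "V_X"),
           .six_stats(vel@vy, "V_Y"))
  names(out) <- c(paste0("X", .STAT_SUFFIX), paste0("Y", .STAT_SUFFIX),
                  paste0("V", .STAT_SUFFIX), paste0("VX", .STAT_SUFFIX),
                  paste0("VY", .STAT_SUFFIX))
  out
}

.spectral_freqs <- function(x, fs) {
  # single periodogram of the mean-removed, unwindowed signal
  x <- x - mean(x)
  n <- length(x)
  if (all(x == 0)) return(c(mn = 0, md = 0))
  k <- seq_len(floor(n / 2))            # positive frequencies only
  P <- Mod(fft(x))[k + 1]^2
  f <- k * fs / n
  mn <- sum(f * P) / sum(P)
  md <- f[which(cumsum(P) >= 0.5 * sum(P))[1]]
  c(mn = mn, md = md)
}

#' Frequency features (4 values)
#'
#' Mean frequency (first spectral moment, \eqn{\sum f P(f)/\sum P(f)}) and
#' median frequency (smallest frequency at which the cumulative power reaches
#' 50\%) of the mean-removed mediolateral and anteroposterior stabilograms,
#' from a single unwindowed periodogram. Resolution is one DFT bin,
#' \code{fs/T} Hz. A constant signal yields all-zero features.
#'
#' @param cop a \linkS4class{CopTrajectory} with at least 16 samples.
#' @return named numeric vector: mnfreqX, mnfreqY, mdfreqX, mdfreqY (Hz).
#' @export
frequencyFeatures <- function(cop) {
  s <- copSamples(cop)
  if (nrow(s) < 16L) stop("at least 16 samples are required", call. = FALSE)
  fs <- samplingRate(cop)
  fx <- .spectral_freqs(s[, 1], fs)
  fy <- .spectral_freqs(s[, 2], fs)
  c(mnfreqX = fx[["mn"]], mnfreqY = fy[["mn"]],
    mdfreqX = fx[["md"]], mdfreqY = fy[["md"]])
}

#' Assemble a PostureFeatures table
#'
#' @param values numeric trials x features matrix with feature column names.
#' @param situations integer vector of labels (1..6), one per trial.
#' @param trialIds character identifiers, one per trial.
#' @return a \linkS4class{PostureFeatures}.
#' @export
postureFeatures <- function(values, situations, trialIds) {
  values <- as.matrix(values)
  trialIds <- as.character(trialIds)
  assay <- t(values)
  colnames(assay) <- trialIds
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = assay),
    colData = S4Vectors::DataFrame(situation = as.integer(situations),
                                   trialId = trialIds,
                                   row.names = trialIds))
  new("PostureFeatures", se)
}

#' Direct-approach feature extraction (60 features per trial)
#'
#' Computes, for every trial, the COP trajectory and its velocity and then
#' the full direct bank: 12 stabilogram statistics, 18 velocity statistics,
#' 8 statokinesigram features, 4 frequency features, and 18 head-acceleration
#' statistics -- 60 features in the fixed [directFeatureNames()] order.
#'
#' @param trials list of \linkS4class{PostureTrial}.
#' @param layout a \linkS4class{SensorLayout}.
#' @return a \linkS4class{PostureFeatures} with 60 rows and one column per trial.
#' @examples
#' corpus <- generateCorpus(nPerSituation = 2, seed = 1)
#' ft <- extractDirect(corpus, defaultLayout())
#' dim(featureValues(ft))   # 12 trials x 60 features
#' @export
extractDirect <- function(trials, layout) {
  reg <- directFeatureNames()
  rows <- lapply(trials, function(tr) {
    feats <- tryCatch({
      cop <- computeCop(tr, layout)
      vel <- copVelocity(cop)
      c(stabilogramFeatures(cop, vel), statokinesigramFeatures(cop),
        frequencyFeatures(cop), accFeatures(headAcc(tr)))
    }, error = function(e)
      stop(sprintf("trial %s: %s", trialId(tr), conditionMessage(e)),
           call. = FALSE))
    feats[reg]
  })
  values <- do.call(rbind, rows)
  colnames(values) <- reg
  postureFeatures(values,
                  vapply(trials, situation, integer(1)),
                  vapply(trials, trialId, character(1)))
}

#' Export a feature table as CSV
#'
#' Header row of feature names, one row per trial, with a trailing
#' \code{situation} column.
#'
#' @param features a \linkS4class{PostureFeatures}.
#' @param path output CSV file.
#' @return invisibly, \code{path}.
#' @export
writeFeatures <- function(features, path) {
  df <- as.data.frame(featureValues(features))
  df$situation <- situations(features)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Combine feature tables column-wise
#'
#' Concatenates the feature banks of the same trials (e.g. 60 direct + 990
#' graphic = 1050 columns); trials must match in identity and order.
#'
#' @param ... two or more \linkS4class{PostureFeatures} over identical trials.
#' @return a \linkS4class{PostureFeatures}.
#' @export
combineFeatures <- function(...) {
  tabs <- list(...)
  ids <- lapply(tabs, function(tb) SummarizedExperiment::colData(tb)$trialId)
  if (!all(vapply(ids, identical, logical(1), y = ids[[1]])))
    stop("feature tables must cover identical trials in identical order",
         call. = FALSE)
  values <- do.call(cbind, lapply(tabs, featureValues))
  postureFeatures(values, situations(tabs[[1]]), ids[[1]])
}
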