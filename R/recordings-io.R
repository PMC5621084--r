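#' @include AllClasses.R
NULL

#' Construct a sensor layout
#'
#' @param coords numeric n x 2 matrix (or coercible) of sensor positions, mm,
#'   in the insole coordinate frame (X mediolateral, Y anteroposterior, origin
#'   at the lower-left corner of the bounding rectangle).
#' @param bounds numeric length-2 rectangle (width, height) enclosing all COP
#'   positions, mm. Defaults to the 43 x 134 mm insole area.
#' @return a \linkS4class{SensorLayout}.
#' @examples
#' sensorLayout(rbind(c(2, 2), c(41, 2), c(2, 132), c(41, 132)))
#' @export
sensorLayout <- function(coords, bounds = c(43, 134)) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y")
  new("SensorLayout", coords = coords, bounds = as.numeric(bounds))
}

#' Default four-sensor rectangular layout
#'
#' Four force sensors at the corners of a rectangle inset 2 mm from the
#' 43 x 134 mm insole bounding area. A rectangular layout makes the synthetic
#' generator's bilinear pressure allocation exactly invertible by the COP
#' barycenter formula.
#'
#' @return a \linkS4class{SensorLayout} with 4 sensors.
#' @export
defaultLayout <- function() {
  sensorLayout(rbind(c(2, 2), c(41, 2), c(2, 132), c(41, 132)))
}

#' Construct a posture trial
#'
#' @param pressures numeric T x n matrix of non-negative sensor pressures
#'   (raw units; only within-trial ratios are used).
#' @param headAcc numeric T' x 3 matrix of head accelerations, m/s^2.
#' @param fsInsole,fsHelmet sampling rates, Hz (default 100).
#' @param situation integer work-situation label in 1..6.
#' @param trialId character identifier.
#' @return a \linkS4class{PostureTrial}.
#' @export
postureTrial <- function(pressures, headAcc, situation, trialId,
                         fsInsole = 100, fsHelmet = 100) {
  pressures <- as.matrix(pressures); storage.mode(pressures) <- "double"
  headAcc <- as.matrix(headAcc); storage.mode(headAcc) <- "double"
  colnames(headAcc) <- c("ax", "ay", "az")
  new("PostureTrial", pressures = pressures, headAcc = headAcc,
      fsInsole = as.numeric(fsInsole), fsHelmet = as.numeric(fsHelmet),
      situation = as.integer(situation), trialId = as.character(trialId))
}

#' Situation label of a trial
#' @param object a \linkS4class{PostureTrial}.
#' @return integer in 1..6.
#' @export
setGeneric("situation", function(object) standardGeneric("situation"))

#' @rdname situation
#' @export
setMethod("situation", "PostureTrial", function(object) object@situation)

#' Trial identifier
#' @param object a \linkS4class{PostureTrial}.
#' @return character scalar.
#' @export
setGeneric("trialId", function(object) standardGeneric("trialId"))

#' @rdname trialId
#' @export
setMethod("trialId", "PostureTrial", function(object) object@trialId)

#' Head-acceleration matrix of a trial
#' @param object a \linkS4class{PostureTrial}.
#' @return numeric T' x 3 matrix (m/s^2).
#' @export
setGeneric("headAcc", function(object) standardGeneric("headAcc"))

#' @rdname headAcc
#' @export
setMethod("headAcc", "PostureTrial", function(object) object@headAcc)

#' Pressure matrix of a trial
#' @param object a \linkS4class{PostureTrial}.
#' @return numeric T x n matrix.
#' @export
setGeneric("pressures", function(object) standardGeneric("pressures"))

#' @rdname pressures
#' @export
setMethod("pressures", "PostureTrial", function(object) object@pressures)

.read_numeric_csv <- function(path, expected) {
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) stop(sprintf("%s: malformed CSV (%s)",
                                                  path, conditionMessage(e)), call. = FALSE))
  if (!identical(names(df), expected))
    stop(sprintf("%s: malformed header; expected '%s', found '%s'",
                 path, paste(expected, collapse = ","),
                 paste(names(df), collapse = ",")), call. = FALSE)
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(df[[nm]])))))[1]
      stop(sprintf("%s: non-numeric value in column '%s' at line %d",
                   path, nm, bad + 1L), call. = FALSE)
    }
  }
  df
}

#' Read trials from a manifest
#'
#' Reads a corpus written in the package's plain-text dialect: a manifest CSV
#' with columns \code{trial_id, situation, fs_insole, fs_helmet, insole_file,
#' helmet_file}, referencing per-trial insole CSVs (header \code{t,p1,...,pn})
#' and helmet CSVs (header \code{t,ax,ay,az}); file paths are resolved
#' relative to the manifest. Trials are returned sorted by (situation,
#' trial_id) so the result is independent of filesystem listing order.
#'
#' @param path a manifest CSV file, or a directory containing
#'   \code{manifest.csv}.
#' @return list of \linkS4class{PostureTrial} objects (possibly empty).
#' @seealso [writeTrials()]
#' @export
readTrials <- function(path) {
  if (dir.exists(path)) {
    manifest <- file.path(path, "manifest.csv")
    if (!file.exists(manifest)) return(list())
  } else manifest <- path
  if (!file.exists(manifest)) stop(sprintf("%s: no such file", manifest), call. = FALSE)
  man <- read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("trial_id", "situation", "fs_insole", "fs_helmet",
            "insole_file", "helmet_file")
  if (!all(need %in% names(man)))
    stop(sprintf("%s: malformed manifest header (need %s)", manifest,
                 paste(need, collapse = ", ")), call. = FALSE)
  if (nrow(man) == 0L) return(list())
  base <- dirname(manifest)
  trials <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    sit <- man$situation[i]
    if (!sit %in% 1:6)
      stop(sprintf("%s: unknown situation label '%s' at line %d",
                   manifest, sit, i + 1L), call. = FALSE)
    ifile <- file.path(base, man$insole_file[i])
    hfile <- file.path(base, man$helmet_file[i])
    idf <- read.csv(ifile, check.names = FALSE)
    if (names(idf)[1] != "t" || !all(grepl("^p[0-9]+$", names(idf)[-1])))
      stop(sprintf("%s: malformed header; expected 't,p1,...'", ifile), call. = FALSE)
    idf <- .read_numeric_csv(ifile, names(idf))
    hdf <- .read_numeric_csv(hfile, c("t", "ax", "ay", "az"))
    pmat <- as.matrix(idf[, -1, drop = FALSE])
    if (any(pmat < 0)) {
      bad <- which(rowSums(pmat < 0) > 0)[1]
      stop(sprintf("%s: negative pressure at line %d", ifile, bad + 1L),
           call. = FALSE)
    }
    trials[[i]] <- postureTrial(
      pressures = pmat,
      headAcc = as.matrix(hdf[, c("ax", "ay", "az")]),
      situation = sit, trialId = as.character(man$trial_id[i]),
      fsInsole = man$fs_insole[i], fsHelmet = man$fs_helmet[i])
  }
  ord <- order(vapply(trials, situation, integer(1)),
               vapply(trials, trialId, character(1)))
  trials[ord]
}

#' Write trials to a manifest directory
#'
#' Writes \code{manifest.csv} plus \code{<trial_id>_insole.csv} and
#' \code{<trial_id>_helmet.csv} per trial, the dialect [readTrials()] reads
#' back; the round trip reproduces every field to floating-point formatting
#' precision.
#'
#' @param trials list of \linkS4class{PostureTrial}.
#' @param path output directory (created if absent).
#' @return invisibly, the manifest path.
#' @export
writeTrials <- function(trials, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop(sprintf("%s: cannot create directory", path), call. = FALSE)
  rows <- lapply(trials, function(tr) {
    ifile <- paste0(trialId(tr), "_insole.csv")
    hfile <- paste0(trialId(tr), "_helmet.csv")
    p <- pressures(tr)
    idf <- data.frame(t = (seq_len(nrow(p)) - 1) / tr@fsInsole)
    for (j in seq_len(ncol(p))) idf[[paste0("p", j)]] <- p[, j]
    a <- headAcc(tr)
    hdf <- data.frame(t = (seq_len(nrow(a)) - 1) / tr@fsHelmet,
                      ax = a[, 1], ay = a[, 2], az = a[, 3])
    ok <- tryCatch({
      write.csv(idf, file.path(path, ifile), row.names = FALSE)
      write.csv(hdf, file.path(path, hfile), row.names = FALSE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop(sprintf("%s: not writable", path), call. = FALSE)
    data.frame(trial_id = trialId(tr), situation = situation(tr),
               fs_insole = tr@fsInsole, fs_helmet = tr@fsHelmet,
               insole_file = ifile, helmet_file = hfile)
  })
  man <- do.call(rbind, rows)
  manifest <- file.path(path, "manifest.csv")
  write.csv(man, manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read or write a sensor layout as JSON
#'
#' The on-disk form is \code{{"sensors": [[x, y], ...], "bounds": [w, h]}}
#' with all lengths in mm.
#'
#' @param path JSON file path.
#' @return \code{readLayout}: a \linkS4class{SensorLayout}.
#' @export
readLayout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$sensors) || is.null(obj$bounds))
    stop(sprintf("%s: layout JSON must contain 'sensors' and 'bounds'", path),
         call. = FALSE)
  sensorLayout(obj$sensors, obj$bounds)
}

#' @rdname readLayout
#' @param layout a \linkS4class{SensorLayout}.
#' @return \code{writeLayout}: invisibly, \code{path}.
#' @export
writeLayout <- function(layout, path) {
  jsonlite::write_json(list(sensors = unname(sensorCoords(layout)),
                            bounds = insoleBounds(layout)),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
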