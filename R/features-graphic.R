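#' @include AllClasses.R cop.R features-direct.R
NULL

# Fixed factorizations of the supported resolutions over the 43 x 134 mm area.
# Rows partition the mediolateral (43 mm) extent, columns the anteroposterior
# (134 mm) extent; these are the integer factorizations whose per-cell areas
# reproduce the documented cell sizes for each resolution.
.GRID_DIMS <- list(
  `420`  = c(12L, 35L),
  `574`  = c(14L, 41L),
  `768`  = c(16L, 48L),
  `990`  = c(18L, 55L),
  `1220` = c(20L, 61L),
  `1564` = c(23L, 68L),
  `2187` = c(27L, 81L))

#' Supported occupancy-grid resolutions
#' @return integer vector of supported cell counts.
#' @export
supportedResolutions <- function() as.integer(names(.GRID_DIMS))

#' Grid dimensions for a supported resolution
#'
#' Maps a total cell count to its (rows, cols) factorization over the
#' 43 x 134 mm insole area, e.g. 990 cells = 18 x 55, giving cells of about
#' 2.39 x 2.44 mm.
#'
#' @param resolution one of 420, 574, 768, 990, 1220, 1564, 2187.
#' @return integer length-2 vector (rows, cols) with rows * cols = resolution.
#' @export
gridDimensions <- function(resolution) {
  key <- as.character(as.integer(resolution))
  dims <- .GRID_DIMS[[key]]
  if (is.null(dims))
    stop(sprintf("unsupported resolution %s; supported: %s", resolution,
                 paste(names(.GRID_DIMS), collapse = ", ")), call. = FALSE)
  dims
}

#' Rasterize a COP trajectory into a binary occupancy grid
#'
#' Divides the bounding rectangle into rows x cols half-open cells (closed at
#' the far edge) indexed from the origin corner and sets a cell to 1 iff at
#' least one COP sample falls in it. Samples marginally outside the bounds
#' (within \code{clampTol} mm, from numeric noise) are clamped to the edge;
#' samples further out raise an error naming the sample.
#'
#' @param cop a \linkS4class{CopTrajectory}.
#' @param resolution a supported cell count (default 990, the
#'   best-performing working resolution).
#' @param bounds numeric length-2 rectangle (width, height), mm.
#' @param clampTol clamping tolerance in mm (default 0.5).
#' @return an \linkS4class{OccupancyGrid}.
#' @export
rasterize <- function(cop, resolution = 990, bounds = c(43, 134),
                      clampTol = 0.5) {
  dims <- gridDimensions(resolution)
  s <- copSamples(cop)
  for (j in 1:2) {
    lo <- s[, j] < -clampTol
    hi <- s[, j] > bounds[j] + clampTol
    if (any(lo | hi))
      stop(sprintf("sample %d lies outside the %g x %g mm bounds",
                   which(lo | hi)[1], bounds[1], bounds[2]), call. = FALSE)
  }
  x <- pmin(pmax(s[, 1], 0), bounds[1])
  y <- pmin(pmax(s[, 2], 0), bounds[2])
  # half-open cells [k*w, (k+1)*w); the far boundary belongs to the last cell
  ri <- pmin(floor(x / (bounds[1] / dims[1])) + 1L, dims[1])
  ci <- pmin(floor(y / (bounds[2] / dims[2])) + 1L, dims[2])
  cells <- matrix(0L, dims[1], dims[2])
  cells[cbind(ri, ci)] <- 1L
  new("OccupancyGrid", cells = cells, bounds = as.numeric(bounds))
}

#' Graphic-approach feature extraction (occupancy cells as binary features)
#'
#' Rasterizes every trial's COP trajectory at the requested resolution and
#' emits each grid cell as one binary feature named \code{g_r<row>_c<col>},
#' so a resolution-990 table has 990 columns.
#'
#' @param trials list of \linkS4class{PostureTrial}.
#' @param layout a \linkS4class{SensorLayout} (its bounds define the grid area).
#' @param resolution a supported cell count (default 990).
#' @return a \linkS4class{PostureFeatures} with \code{resolution} rows.
#' @export
extractGraphic <- function(trials, layout, resolution = 990) {
  dims <- gridDimensions(resolution)
  nm <- paste0("g_r", rep(seq_len(dims[1]), times = dims[2]),
               "_c", rep(seq_len(dims[2]), each = dims[1]))
  rows <- lapply(trials, function(tr) {
    g <- tryCatch(
      rasterize(computeCop(tr, layout), resolution, insoleBounds(layout)),
      error = function(e)
        stop(sprintf("trial %s: %s", trialId(tr), conditionMessage(e)),
             call. = FALSE))
    as.numeric(gridCells(g))      # column-major: matches nm construction
  })
  values <- do.call(rbind, rows)
  colnames(values) <- nm
  postureFeatures(values,
                  vapply(trials, situation, integer(1)),
                  vapply(trials, trialId, character(1)))
}

#' Dump an occupancy grid for visual inspection
#'
#' Writes the binary matrix as CSV (rows = mediolateral cells) or as a
#' plain-text PGM image.
#'
#' @param grid an \linkS4class{OccupancyGrid}.
#' @param path output file.
#' @param format "csv" or "pgm".
#' @return invisibly, \code{path}.
#' @export
writeGrid <- function(grid, path, format = c("csv", "pgm")) {
  format <- match.arg(format)
  cells <- gridCells(grid)
  if (format == "csv") {
    utils::write.table(cells, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(nrow(cells), ncol(cells)), "1"), con)
    # PGM scans row-by-row of the image: emit the grid transposed so the
    # anteroposterior axis runs down the image
    writeLines(apply(t(cells), 1, paste, collapse = " "), con)
  }
  invisible(path)
}
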