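# STDEV*COEFF contour maps: PLS coefficients back-mapped onto the grid,
# weighted by the training standard deviation of each descriptor column, and
# thresholded into favorable/unfavorable regions.

#' Per-grid-point coefficient values for one field
#'
#' The display value at a grid point is the PLS regression coefficient of
#' the corresponding descriptor column times that column's standard
#' deviation over the training compounds (the STDEV*COEFF convention, which
#' prevents high-variance columns from being read off the raw coefficient
#' scale). Dropped (constant) columns carry 0.
#'
#' @param model a \linkS4class{PlsModel} fitted with a column index.
#' @param fieldType "steric" or "electrostatic".
#' @param XTrain the training descriptor matrix (kept columns, same layout
#'   as at fit time).
#' @param grid the \linkS4class{GridSpec} of the field computation.
#' @return numeric vector, one value per grid point.
#' @export
coefficientGrid <- function(model, fieldType = c("steric", "electrostatic"),
                            XTrain, grid) {
  fieldType <- match.arg(fieldType)
  ci <- model@columnIndex
  if (nrow(ci) == 0) stop("model carries no column index")
  if (!any(ci$field == fieldType)) stop("field type absent from model")
  sds <- apply(XTrain, 2, stats::sd)
  vals <- numeric(prod(grid@dims))
  sel <- ci$field == fieldType
  vals[ci$point[sel]] <- model@coefficients[sel] * sds[sel]
  vals
}

#' Threshold coefficient values into contour regions
#'
#' Favorable points lie above the high percentile of the nonzero values,
#' unfavorable below the low percentile. All-zero input yields empty masks.
#'
#' @param values per-grid-point values from \code{\link{coefficientGrid}}.
#' @param lowPct,highPct percentiles in [0, 100], lowPct < highPct.
#' @return list with logical \code{favorable} and \code{unfavorable} masks.
#' @export
contourRegions <- function(values, lowPct = 20, highPct = 80) {
  if (!(lowPct >= 0 && lowPct < highPct && highPct <= 100))
    stop("need 0 <= lowPct < highPct <= 100")
  nz <- values[values != 0]
  if (!length(nz))
    return(list(favorable = rep(FALSE, length(values)),
                unfavorable = rep(FALSE, length(values))))
  qs <- stats::quantile(nz, c(lowPct, highPct) / 100, names = FALSE)
  list(favorable = values != 0 & values > qs[2],
       unfavorable = values != 0 & values < qs[1])
}

#' Build the contour set for one field
#'
#' @inheritParams coefficientGrid
#' @param lowPct,highPct percentile thresholds.
#' @return a \linkS4class{ContourSet}.
#' @export
buildContours <- function(model, fieldType, XTrain, grid, lowPct = 20,
                          highPct = 80) {
  vals <- coefficientGrid(model, fieldType, XTrain, grid)
  masks <- contourRegions(vals, lowPct, highPct)
  new("ContourSet", fieldType = fieldType, values = vals,
      favorable = masks$favorable, unfavorable = masks$unfavorable,
      thresholds = c(lowPct, highPct), grid = grid)
}

#' Export a contour set as grid files plus a JSON summary
#'
#' Writes the value grid and both masks (as 0/1 grids) in the requested
#' format, and a JSON summary with point counts and mask centroids.
#'
#' @param contours a \linkS4class{ContourSet}.
#' @param dir output directory (created if missing).
#' @param format "cube" or "dx".
#' @return invisibly, named vector of written paths.
#' @export
exportContours <- function(contours, dir, format = c("cube", "dx")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- format
  base <- file.path(dir, paste0(contours@fieldType, "_",
                                c("values", "favorable", "unfavorable")))
  paths <- paste0(base, ".", ext)
  writeGridField(contours@values, contours@grid, paths[1], format)
  writeGridField(as.numeric(contours@favorable), contours@grid, paths[2],
                 format)
  writeGridField(as.numeric(contours@unfavorable), contours@grid, paths[3],
                 format)
  pts <- gridPoints(contours@grid)
  centroid <- function(mask)
    if (any(mask)) colMeans(pts[mask, , drop = FALSE]) else c(NA, NA, NA)
  summary <- list(field = contours@fieldType,
                  thresholds = contours@thresholds,
                  n_favorable = sum(contours@favorable),
                  n_unfavorable = sum(contours@unfavorable),
                  favorable_centroid = centroid(contours@favorable),
                  unfavorable_centroid = centroid(contours@unfavorable))
  jsonPath <- file.path(dir, paste0(contours@fieldType, "_summary.json"))
  jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jsonPath))
}
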