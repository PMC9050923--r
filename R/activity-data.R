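# Screening and potency tables: active selection at the 10 uM viability
# screen and GI50 -> pGI50 transformation for the QSAR response.

#' Load the 10 uM viability screen
#'
#' @param path TSV with columns id, r1, r2 and one viability column per cell
#'   line; defaults to the packaged screen of the 126-compound library.
#' @return long data.frame with columns \code{compound_id}, \code{cell_line},
#'   \code{viability_pct}.
#' @export
loadViability <- function(path = system.file("extdata",
    "table1_viability.tsv", package = "fieldQSAR")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  lines <- setdiff(names(tab), c("id", "r1", "r2"))
  out <- do.call(rbind, lapply(lines, function(cl)
    data.frame(compound_id = as.integer(tab$id), cell_line = cl,
               viability_pct = as.numeric(tab[[cl]]),
               stringsAsFactors = FALSE)))
  if (any(is.na(out$viability_pct))) stop("malformed viability cell")
  if (any(out$viability_pct < 0 | out$viability_pct > 100))
    stop("viability must lie in [0, 100]")
  if (anyDuplicated(out[, c("compound_id", "cell_line")]))
    stop("duplicate (compound, cell line) viability record")
  out
}

#' Load the GI50 potency table
#'
#' Censored cells are written as ">N" in the fixture; they are preserved as
#' the bound with a \code{censored} flag, never imputed.
#'
#' @param path TSV with columns compound_id, cell_line, gi50, sem; defaults
#'   to the packaged potency table of the 25 selected compounds.
#' @return data.frame with columns \code{compound_id}, \code{cell_line},
#'   \code{gi50_uM}, \code{sem}, \code{censored}.
#' @export
loadPotency <- function(path = system.file("extdata",
    "table2_potency.tsv", package = "fieldQSAR")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", fill = TRUE)
  censored <- grepl("^>", tab$gi50)
  val <- suppressWarnings(as.numeric(sub("^>", "", tab$gi50)))
  if (any(is.na(val))) stop("malformed GI50 cell: ", tab$gi50[is.na(val)][1])
  if (any(val[!censored] <= 0)) stop("GI50 must be positive")
  out <- data.frame(compound_id = as.integer(tab$compound_id),
                    cell_line = tab$cell_line, gi50_uM = val,
                    sem = suppressWarnings(as.numeric(tab$sem)),
                    censored = censored, stringsAsFactors = FALSE)
  if (anyDuplicated(out[, c("compound_id", "cell_line")]))
    stop("duplicate (compound, cell line) potency record")
  out
}

#' Select active compounds from the viability screen
#'
#' Ids whose viability at 10 uM is at or below the threshold, optionally
#' unioned with an explicit override list (used to reproduce the published
#' 25-compound set, which includes one compound at 51 percent viability).
#'
#' @param viability long records from \code{\link{loadViability}}.
#' @param cellLine the screen cell line to filter on.
#' @param thresholdPct selection threshold in (0, 100]; a compound passes if
#'   viability_pct <= thresholdPct.
#' @param includeOverride integer ids force-included regardless of threshold.
#' @return sorted integer vector of selected ids.
#' @export
selectActives <- function(viability, cellLine = "MDA-MB231",
                          thresholdPct = 50, includeOverride = integer(0)) {
  if (thresholdPct < 0 || thresholdPct > 100)
    stop("threshold must lie in [0, 100]")
  v <- viability[viability$cell_line == cellLine, ]
  if (length(includeOverride)) {
    missing <- setdiff(includeOverride, v$compound_id)
    if (length(missing))
      stop("override id absent from table: ", missing[1])
  }
  sort(union(v$compound_id[v$viability_pct <= thresholdPct],
             as.integer(includeOverride)))
}

#' Convert GI50 (uM) to pGI50
#'
#' pGI50 is the negative decadic logarithm of the molar GI50; with GI50 in
#' micromolar units this is 6 - log10(GI50).
#'
#' @param gi50uM positive, uncensored GI50 values in uM.
#' @return pGI50 values.
#' @export
gi50ToPgi50 <- function(gi50uM) {
  if (any(!is.finite(gi50uM)) || any(gi50uM <= 0))
    stop("GI50 must be positive and uncensored")
  6 - log10(gi50uM)
}

#' Build the QSAR model dataset
#'
#' One pGI50 entry per requested compound on the response cell line. A
#' censored or missing GI50 for a requested id is an error.
#'
#' @param potency records from \code{\link{loadPotency}}.
#' @param ids compound ids to include; defaults to the published selection
#'   (viability <= 50 percent plus the explicit compound-110 override).
#' @param cellLine response cell line.
#' @return a \linkS4class{QsarDataset}.
#' @export
buildQsarDataset <- function(potency, ids = defaultQsarIds(),
                             cellLine = "MDA-MB231") {
  p <- potency[potency$cell_line == cellLine, ]
  idx <- match(ids, p$compound_id)
  if (any(is.na(idx)))
    stop("no ", cellLine, " GI50 for compound ", ids[is.na(idx)][1])
  if (any(p$censored[idx]))
    stop("censored GI50 for compound ", ids[which(p$censored[idx])[1]])
  new("QsarDataset",
      entries = data.frame(id = as.integer(ids),
                           pgi50 = gi50ToPgi50(p$gi50_uM[idx])),
      cellLine = cellLine)
}

#' Default ids of the 25-compound model dataset
#'
#' The screen selection at 50 percent viability on MDA-MB231 plus the
#' explicit override for compound 110 (printed viability 51 percent, yet
#' present in the published potency table).
#'
#' @return sorted integer vector of 25 ids.
#' @export
defaultQsarIds <- function() {
  selectActives(loadViability(), "MDA-MB231", 50, includeOverride = 110L)
}

#' Accessor: entries of a QsarDataset
#' @param x a \linkS4class{QsarDataset}.
#' @return data.frame with columns id, pgi50.
#' @export
datasetEntries <- function(x) {
  stopifnot(is(x, "QsarDataset"))
  x@entries
}

#' The packaged experimental/predicted pGI50 reference table
#'
#' Includes the printed row label alongside the resolved compound id: the row
#' printed as compound 71 is resolved to compound 81, whose potency matches
#' its experimental pGI50 and which is otherwise absent from the table.
#'
#' @return data.frame with columns \code{printed_id}, \code{compound_id},
#'   \code{experimental_pgi50}, \code{predicted_pgi50}, \code{residual},
#'   \code{test_set}.
#' @export
loadReferencePredictions <- function() {
  path <- system.file("extdata", "table3_predictions.tsv",
                      package = "fieldQSAR")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
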