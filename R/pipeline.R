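# End-to-end orchestration: library -> activities -> aligned conformers ->
# field grids -> PLS -> report -> contours, with a reproducibility manifest.

#' Pipeline configuration
#'
#' Defaults reproduce the published model run end to end: the packaged
#' 25-compound dataset, Gasteiger charges, alignment on compound 101, a
#' 2 Angstrom grid with 4 Angstrom margin, +1e/carbon probes truncated at
#' 30 kcal/mol with 50/50 field weights, the explicit 19/6 split, and
#' leave-one-out component selection capped at 5.
#'
#' @param seed RNG seed (used by maximin splitting and synthetic input).
#' @param gridSpacing,gridMargin grid geometry (Angstrom).
#' @param chargeScheme "gasteiger" or "mmff94".
#' @param truncation field clamp (kcal/mol).
#' @param stericWeight,electrostaticWeight field weights.
#' @param varianceFloor descriptor column sd floor.
#' @param referenceId alignment reference compound.
#' @param splitMode "explicit" or "diverse".
#' @param explicitTest test ids for explicit mode.
#' @param nTest test-set size for diverse mode.
#' @param maxComponents cap on PLS components.
#' @param contourLowPct,contourHighPct contour percentiles.
#' @param cellLine response cell line.
#' @return list of class "qsarConfig".
#' @export
qsarConfig <- function(seed = 2020, gridSpacing = 2, gridMargin = 4,
                       chargeScheme = "gasteiger", truncation = 30,
                       stericWeight = 0.5, electrostaticWeight = 0.5,
                       varianceFloor = 1e-6, referenceId = 101,
                       splitMode = c("explicit", "diverse"),
                       explicitTest = defaultTestIds(), nTest = 6,
                       maxComponents = 5, contourLowPct = 20,
                       contourHighPct = 80, cellLine = "MDA-MB231") {
  splitMode <- match.arg(splitMode)
  structure(as.list(environment()), class = "qsarConfig")
}

#' Run the full 3D-QSAR pipeline
#'
#' Executes every stage in order and (optionally) writes the artifacts:
#' structures (SMILES list), dataset TSV, descriptor matrix TSV with a JSON
#' sidecar, prediction report TSV with a JSON stats block, contour grids,
#' and a manifest recording the configuration and output digests. With a
#' fixed configuration the manifest digests are identical across runs on one
#' platform.
#'
#' @param config a \code{\link{qsarConfig}}.
#' @param outdir output directory, or NULL to skip writing artifacts.
#' @param synthetic optional \linkS4class{SyntheticQsar}: when supplied the
#'   structure and field stages are bypassed and the model runs on the
#'   synthetic descriptors (same report schema).
#' @param verbose log stage timing to stderr.
#' @return list with \code{library}, \code{dataset}, \code{conformers},
#'   \code{fields}, \code{descriptors}, \code{split}, \code{model},
#'   \code{report}, \code{contours}, \code{manifest} (synthetic runs omit
#'   the structure-stage members).
#' @export
runQsarPipeline <- function(config = qsarConfig(), outdir = NULL,
                            synthetic = NULL, verbose = FALSE) {
  t0 <- Sys.time()
  note <- function(stage) if (verbose)
    message(sprintf("[%s] %+.1fs", stage,
                    as.numeric(Sys.time() - t0, units = "secs")))
  fc <- fieldConfig(truncation = config$truncation,
                    stericWeight = config$stericWeight,
                    electrostaticWeight = config$electrostaticWeight)
  result <- list()

  if (is.null(synthetic)) {
    lib <- buildLibrary()
    note("build-library")
    dataset <- buildQsarDataset(loadPotency(), cellLine = config$cellLine)
    note("prepare-activities")
    ids <- datasetEntries(dataset)$id
    conformers <- libraryConformers(lib, ids = ids,
                                    reference = config$referenceId,
                                    chargeScheme = config$chargeScheme)
    note("align")
    grid <- makeGrid(conformers, spacing = config$gridSpacing,
                     margin = config$gridMargin)
    fields <- computeFields(conformers, grid, fc)
    note("fields")
    desc <- assembleDescriptorMatrix(fields, fc, config$varianceFloor)
    result[c("library", "conformers", "fields")] <-
      list(lib, conformers, fields)
  } else {
    sd <- syntheticData(synthetic)
    dataset <- new("QsarDataset",
                   entries = data.frame(id = seq_len(nrow(sd$X)),
                                        pgi50 = sd$y),
                   cellLine = "synthetic")
    np <- prod(synthetic@dims)
    desc <- list(X = sd$X,
                 columnIndex = data.frame(field = "steric",
                                          point = seq_len(np)),
                 keep = rep(TRUE, np),
                 grid = new("GridSpec", origin = c(0, 0, 0), spacing = 1,
                            dims = synthetic@dims))
  }

  split <- if (config$splitMode == "explicit" && is.null(synthetic))
    diverseSplit(dataset, explicitTest = config$explicitTest)
  else
    diverseSplit(dataset, X = desc$X, nTest = config$nTest,
                 seed = config$seed)
  ent <- datasetEntries(dataset)
  trIdx <- match(split$train, ent$id)
  Xtr <- desc$X[match(split$train, as.numeric(rownames(desc$X))), ,
                drop = FALSE]
  ytr <- ent$pgi50[trIdx]
  sel <- chooseComponents(Xtr, ytr, config$maxComponents)
  model <- fitPls(Xtr, ytr, sel$ncomp, columnIndex = desc$columnIndex)
  note("fit")
  report <- residualTable(dataset, split, model, desc$X)
  note("report")
  contours <- lapply(unique(desc$columnIndex$field), function(ft)
    buildContours(model, ft, Xtr, desc$grid, config$contourLowPct,
                  config$contourHighPct))
  names(contours) <- unique(desc$columnIndex$field)
  note("contours")

  result <- c(result, list(dataset = dataset, descriptors = desc,
                           split = split, model = model, report = report,
                           contours = contours, q2 = sel$q2))
  if (!is.null(outdir))
    result$manifest <- .writeArtifacts(result, config, outdir)
  result
}

# Write pipeline artifacts and the manifest; returns the manifest list.
.writeArtifacts <- function(result, config, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- character(0)
  p <- function(f) file.path(outdir, f)
  if (!is.null(result$library)) {
    writeStructures(result$library, p("structures.smi"), "smiles")
    paths <- c(paths, p("structures.smi"))
    writeConformers(result$conformers, p("conformers.sdf"),
                    p("alignment.tsv"))
    paths <- c(paths, p("conformers.sdf"), p("alignment.tsv"))
  }
  ds <- datasetEntries(result$dataset)
  ds$split <- ifelse(ds$id %in% result$split$test, "test", "train")
  utils::write.table(ds, p("dataset.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(
    data.frame(id = rownames(result$descriptors$X),
               round(result$descriptors$X, 6), check.names = FALSE),
    p("descriptors.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  g <- result$descriptors$grid
  jsonlite::write_json(
    list(grid = list(origin = g@origin, spacing = g@spacing, dims = g@dims),
         columns = result$descriptors$columnIndex),
    p("descriptors.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(reportTable(result$report), p("report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(reportStats(result$report), p("stats.json"),
                       auto_unbox = TRUE, digits = NA)
  m <- result$model
  jsonlite::write_json(
    list(ncomp = m@ncomp, yMean = m@yMean, xMean = m@xMean,
         coefficients = m@coefficients, columnIndex = m@columnIndex,
         grid = list(origin = g@origin, spacing = g@spacing, dims = g@dims)),
    p("model.json"), auto_unbox = TRUE, digits = NA)
  for (ct in result$contours)
    exportContours(ct, file.path(outdir, "contours"))
  paths <- c(paths, p("dataset.tsv"), p("descriptors.tsv"),
             p("descriptors.json"), p("report.tsv"), p("stats.json"),
             p("model.json"),
             list.files(file.path(outdir, "contours"), full.names = TRUE))
  manifest <- list(
    package = as.character(utils::packageVersion("fieldQSAR")),
    config = unclass(config),
    outputs = lapply(stats::setNames(paths, basename(paths)),
                     function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
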