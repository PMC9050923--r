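#' @import methods
NULL

#' CompoundLibrary: an enumerated congeneric series
#'
#' Holds one record per library member: the R1/R2 substituent tokens, the
#' assembled SMILES, its canonical form, the Hill-order molecular formula and
#' the molecular weight.
#'
#' @slot records data.frame with columns \code{id}, \code{r1}, \code{r2},
#'   \code{smiles}, \code{canonical}, \code{formula}, \code{mw}.
#' @exportClass CompoundLibrary
setClass("CompoundLibrary", representation(records = "data.frame"),
         validity = function(object) {
  rec <- object@records
  need <- c("id", "r1", "r2", "smiles", "canonical", "formula", "mw")
  if (!all(need %in% names(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(rec$id)) return("duplicate compound ids")
  TRUE
})

#' QsarDataset: compound ids with pGI50 responses
#'
#' @slot entries data.frame with columns \code{id}, \code{pgi50}.
#' @slot cellLine single character, the response cell line.
#' @exportClass QsarDataset
setClass("QsarDataset",
         representation(entries = "data.frame", cellLine = "character"),
         validity = function(object) {
  ent <- object@entries
  if (!all(c("id", "pgi50") %in% names(ent)))
    return("entries must have columns id, pgi50")
  if (anyDuplicated(ent$id)) return("one entry per compound required")
  if (any(!is.finite(ent$pgi50))) return("pGI50 must be finite")
  TRUE
})

#' ConformerSet: charged 3D conformers, optionally scaffold-aligned
#'
#' Each element of \code{conformers} is a list with \code{id},
#' \code{elements} (character), \code{xyz} (n x 3 matrix, Angstrom),
#' \code{charges} (partial charges, e), \code{energy} (force-field energy,
#' kcal/mol, may be NA) and \code{scaffold} (integer indices of the shared
#' scaffold atoms, or NULL).
#'
#' @slot conformers list of per-compound conformer lists.
#' @slot aligned logical flag.
#' @slot referenceId id of the alignment reference (NA before alignment).
#' @slot scaffoldRmsd named numeric, per-compound RMSD (Angstrom) of mapped
#'   scaffold atoms to the reference after superposition.
#' @exportClass ConformerSet
setClass("ConformerSet",
         representation(conformers = "list", aligned = "logical",
                        referenceId = "numeric", scaffoldRmsd = "numeric"),
         prototype(aligned = FALSE, referenceId = NA_real_,
                   scaffoldRmsd = numeric(0)),
         validity = function(object) {
  for (cf in object@conformers) {
    if (!all(c("id", "elements", "xyz", "charges") %in% names(cf)))
      return("each conformer needs id, elements, xyz, charges")
    if (nrow(cf$xyz) != length(cf$elements) ||
        length(cf$charges) != length(cf$elements))
      return("xyz/charges must align with the atom list")
    if (any(!is.finite(cf$xyz))) return("non-finite coordinates")
  }
  TRUE
})

#' GridSpec: a rectangular field grid
#'
#' Point order is x fastest, then y, then z (column-major over the box).
#'
#' @slot origin numeric(3), position of the first grid point (Angstrom).
#' @slot spacing positive numeric, lattice spacing (Angstrom).
#' @slot dims integer(3), number of points along x, y, z.
#' @exportClass GridSpec
setClass("GridSpec",
         representation(origin = "numeric", spacing = "numeric",
                        dims = "integer"),
         validity = function(object) {
  if (length(object@origin) != 3) return("origin must be length 3")
  if (object@spacing <= 0) return("spacing must be positive")
  if (length(object@dims) != 3 || any(object@dims < 1))
    return("dims must be 3 positive integers")
  TRUE
})

#' FieldSet: per-compound steric and electrostatic grid energies
#'
#' @slot ids compound ids (rows of the energy matrices).
#' @slot steric n x npts matrix of truncated Lennard-Jones probe energies.
#' @slot electrostatic n x npts matrix of truncated Coulomb probe energies.
#' @slot grid the GridSpec the energies were sampled on.
#' @slot truncation the clamp limit applied (kcal/mol).
#' @exportClass FieldSet
setClass("FieldSet",
         representation(ids = "numeric", steric = "matrix",
                        electrostatic = "matrix", grid = "GridSpec",
                        truncation = "numeric"),
         validity = function(object) {
  np <- prod(object@grid@dims)
  if (ncol(object@steric) != np || ncol(object@electrostatic) != np)
    return("energy matrices must have one column per grid point")
  if (nrow(object@steric) != length(object@ids) ||
      nrow(object@electrostatic) != length(object@ids))
    return("one row per compound required")
  lim <- object@truncation
  if (any(abs(object@steric) > lim + 1e-9) ||
      any(abs(object@electrostatic) > lim + 1e-9))
    return("energies exceed the truncation limit")
  TRUE
})

#' PlsModel: a fitted NIPALS PLS1 regression
#'
#' @slot ncomp number of latent components.
#' @slot xMean,yMean centering vectors used at fit time.
#' @slot weights,xLoadings p x ncomp matrices of NIPALS weights and loadings.
#' @slot yLoadings numeric(ncomp) inner regression coefficients.
#' @slot coefficients implied regression vector b so that
#'   yhat = (X - xMean) b + yMean.
#' @slot columnIndex data.frame mapping retained descriptor columns back to
#'   (field, point) on the grid, or a zero-row data.frame when not applicable.
#' @exportClass PlsModel
setClass("PlsModel",
         representation(ncomp = "integer", xMean = "numeric", yMean = "numeric",
                        weights = "matrix", xLoadings = "matrix",
                        yLoadings = "numeric", coefficients = "numeric",
                        columnIndex = "data.frame"),
         validity = function(object) {
  if (object@ncomp < 1) return("ncomp must be >= 1")
  if (length(object@coefficients) != length(object@xMean))
    return("coefficient length must match xMean")
  if (any(!is.finite(object@coefficients)))
    return("coefficients must be finite")
  TRUE
})

#' QsarReport: per-compound predictions and model statistics
#'
#' @slot table data.frame with columns \code{id}, \code{experimental},
#'   \code{predicted}, \code{residual}, \code{split}.
#' @slot r2Train,rmseTrain training-set squared Pearson correlation and
#'   root-mean-square residual.
#' @slot r2Det training-set coefficient of determination
#'   (1 - SSres/SStot), reported alongside the Pearson form.
#' @slot r2Pooled,rmsePooled same statistics over all rows.
#' @slot ncomp number of PLS components used.
#' @exportClass QsarReport
setClass("QsarReport",
         representation(table = "data.frame", r2Train = "numeric",
                        rmseTrain = "numeric", r2Det = "numeric",
                        r2Pooled = "numeric", rmsePooled = "numeric",
                        ncomp = "integer"),
         validity = function(object) {
  tb <- object@table
  need <- c("id", "experimental", "predicted", "residual", "split")
  if (!all(need %in% names(tb)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (max(abs(tb$experimental - tb$predicted - tb$residual)) > 1e-8)
    return("residual column inconsistent with experimental - predicted")
  TRUE
})

#' ContourSet: thresholded STDEV*COEFF values on the grid
#'
#' @slot fieldType "steric" or "electrostatic".
#' @slot values per-grid-point coefficient * training-stdev products
#'   (dropped columns carry 0).
#' @slot favorable,unfavorable disjoint logical masks over grid points.
#' @slot thresholds numeric(2), the (low, high) percentiles used.
#' @slot grid the GridSpec.
#' @exportClass ContourSet
setClass("ContourSet",
         representation(fieldType = "character", values = "numeric",
                        favorable = "logical", unfavorable = "logical",
                        thresholds = "numeric", grid = "GridSpec"),
         validity = function(object) {
  np <- prod(object@grid@dims)
  if (length(object@values) != np) return("values must cover the grid")
  if (length(object@favorable) != np || length(object@unfavorable) != np)
    return("masks must cover the grid")
  if (any(object@favorable & object@unfavorable))
    return("favorable and unfavorable masks must be disjoint")
  TRUE
})

#' SyntheticQsar: descriptor/activity pair with a planted linear signal
#'
#' @slot X n x p descriptor matrix mimicking truncated field energies.
#' @slot y activities, X w + Gaussian noise by construction.
#' @slot trueCoefficients the planted sparse coefficient vector w.
#' @slot noiseSd Gaussian noise standard deviation.
#' @slot seed RNG seed the object is reproducible from.
#' @slot dims grid dimensions the descriptor columns correspond to.
#' @exportClass SyntheticQsar
setClass("SyntheticQsar",
         representation(X = "matrix", y = "numeric",
                        trueCoefficients = "numeric", noiseSd = "numeric",
                        seed = "integer", dims = "integer"),
         validity = function(object) {
  if (length(object@y) != nrow(object@X)) return("y must match rows of X")
  if (length(object@trueCoefficients) != ncol(object@X))
    return("trueCoefficients must match columns of X")
  TRUE
})

setMethod("show", "CompoundLibrary", function(object) {
  cat("CompoundLibrary with", nrow(object@records), "compounds\n")
  cat("  substituent tokens:",
      length(unique(c(object@records$r1, object@records$r2))), "\n")
})

setMethod("show", "QsarDataset", function(object) {
  cat("QsarDataset:", nrow(object@entries), "compounds,",
      object@cellLine, "\n")
  cat("  pGI50 range:", sprintf("%.2f .. %.2f\n",
      min(object@entries$pgi50), max(object@entries$pgi50)))
})

setMethod("show", "ConformerSet", function(object) {
  cat("ConformerSet:", length(object@conformers), "conformers",
      if (object@aligned) sprintf("(aligned, reference %d)",
                                  as.integer(object@referenceId))
      else "(unaligned)", "\n")
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d x %d points, spacing %.2f A, origin (%.2f, %.2f, %.2f)\n",
              object@dims[1], object@dims[2], object@dims[3], object@spacing,
              object@origin[1], object@origin[2], object@origin[3]))
})

setMethod("show", "FieldSet", function(object) {
  cat("FieldSet:", length(object@ids), "compounds on",
      prod(object@grid@dims), "grid points (truncation",
      object@truncation, "kcal/mol)\n")
})

setMethod("show", "PlsModel", function(object) {
  cat("PlsModel:", object@ncomp, "components,",
      length(object@coefficients), "descriptors\n")
})

setMethod("show", "QsarReport", function(object) {
  cat("QsarReport:", nrow(object@table), "compounds (",
      sum(object@table$split == "train"), "train /",
      sum(object@table$split == "test"), "test )\n")
  cat(sprintf("  training r2 = %.3f, RMSE = %.3f (%d components)\n",
              object@r2Train, object@rmseTrain, object@ncomp))
})

setMethod("show", "ContourSet", function(object) {
  cat("ContourSet (", object@fieldType, "):",
      sum(object@favorable), "favorable /", sum(object@unfavorable),
      "unfavorable points\n")
})

setMethod("show", "SyntheticQsar", function(object) {
  cat("SyntheticQsar:", nrow(object@X), "x", ncol(object@X),
      "descriptors,", sum(object@trueCoefficients != 0),
      "planted coefficients, noise sd", object@noiseSd, "\n")
})
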