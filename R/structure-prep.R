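# One minimum-energy, partial-charge-assigned 3D conformer per compound,
# rigidly aligned on the shared triazine scaffold. Embedding and charge
# assignment go through OpenBabel (ChemmineOB); superposition is a Kabsch
# least-squares fit on the mapped scaffold atoms.

#' Embed and minimize 3D conformers with partial charges
#'
#' Each SMILES is built into a single 3D conformer by OpenBabel's structure
#' builder followed by MMFF94 minimization and a weighted rotor search (a
#' deterministic multi-start over rotatable torsions), then assigned partial
#' charges. The build is bit-reproducible across runs on one platform.
#'
#' @param smiles character vector of SMILES.
#' @param ids numeric compound ids, same length as \code{smiles}.
#' @param chargeScheme "gasteiger" (default) or "mmff94".
#' @param scaffoldIndices optional list (per compound) of integer indices of
#'   shared scaffold atoms, attached to each conformer for alignment.
#' @param computeEnergy if TRUE, attach the MMFF94 single-point energy of the
#'   built conformer via the obenergy tool (NA if unavailable).
#' @return an unaligned \linkS4class{ConformerSet}.
#' @export
embedMinimize <- function(smiles, ids = seq_along(smiles),
                          chargeScheme = c("gasteiger", "mmff94"),
                          scaffoldIndices = NULL, computeEnergy = FALSE) {
  chargeScheme <- match.arg(chargeScheme)
  stopifnot(length(smiles) == length(ids), length(smiles) >= 1)
  inp <- paste0(paste(smiles, ids), collapse = "\n")
  mol2 <- ChemmineOB::convertFormat("SMI", "MOL2", paste0(inp, "\n"),
    options = data.frame(names = c("gen3d", "partialcharge"),
                         args = c("", chargeScheme)))
  tf <- tempfile(fileext = ".mol2")
  on.exit(unlink(tf))
  writeLines(mol2, tf, sep = "")
  parsed <- bio3d::read.mol2(tf)
  if (inherits(parsed, "mol2")) parsed <- list(parsed)
  if (length(parsed) != length(smiles))
    stop("embedding failed: expected ", length(smiles), " conformers, got ",
         length(parsed))
  energies <- if (computeEnergy) .mmff94Energies(tf, length(smiles))
              else rep(NA_real_, length(smiles))
  confs <- lapply(seq_along(parsed), function(i) {
    a <- parsed[[i]]$atom
    list(id = ids[i],
         elements = sub("\\..*$", "", a$elety),
         xyz = unname(as.matrix(a[, c("x", "y", "z")])),
         charges = a$charge,
         energy = energies[i],
         scaffold = if (is.null(scaffoldIndices)) NULL
                    else as.integer(scaffoldIndices[[i]]))
  })
  new("ConformerSet", conformers = confs, aligned = FALSE)
}

# MMFF94 single-point energies (kcal/mol) via the obenergy CLI; returns NAs
# if the tool is unavailable or its output cannot be parsed.
.mmff94Energies <- function(mol2Path, n) {
  out <- tryCatch(
    suppressWarnings(system2("obenergy", c("-ff", "MMFF94", mol2Path),
                             stdout = TRUE, stderr = FALSE)),
    error = function(e) character(0))
  hits <- regmatches(out, regexpr("TOTAL ENERGY =\\s*-?[0-9.]+", out))
  vals <- as.numeric(sub("TOTAL ENERGY =\\s*", "", hits))
  if (length(vals) == n) vals else rep(NA_real_, n)
}

#' Build aligned conformers for a compound library subset
#'
#' Convenience wrapper: embeds the selected library members with scaffold
#' atom maps attached and aligns them on the shared triazine scaffold.
#'
#' @param library a \linkS4class{CompoundLibrary}.
#' @param ids compounds to build (default: all).
#' @param reference passed to \code{\link{alignToReference}}; by convention
#'   the most potent compound of the modelled set.
#' @param chargeScheme partial charge model.
#' @param computeEnergy attach MMFF94 energies (see
#'   \code{\link{embedMinimize}}).
#' @return an aligned \linkS4class{ConformerSet}.
#' @export
libraryConformers <- function(library, ids = libraryRecords(library)$id,
                              reference = 101, chargeScheme = "gasteiger",
                              computeEnergy = FALSE) {
  rec <- libraryRecords(library)
  idx <- match(ids, rec$id)
  if (any(is.na(idx))) stop("id not in library: ", ids[is.na(idx)][1])
  rec <- rec[idx, ]
  scafIdx <- mapply(scaffoldAtomIndices, rec$r1, rec$r2, SIMPLIFY = FALSE)
  confs <- embedMinimize(rec$smiles, rec$id, chargeScheme = chargeScheme,
                         scaffoldIndices = scafIdx,
                         computeEnergy = computeEnergy)
  for (cf in confs@conformers)
    if (!identical(cf$elements[cf$scaffold], .scaffoldElements))
      stop("scaffold atom map corrupted for compound ", cf$id)
  alignToReference(confs, reference = reference)
}

# Kabsch: optimal rotation R and translation moving P onto Q (both m x 3),
# minimizing the RMSD of corresponding rows.
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, centerP = cp, centerQ = cq)
}

# Apply a Kabsch fit to a full coordinate matrix.
.applyFit <- function(xyz, fit) {
  sweep(sweep(xyz, 2, fit$centerP) %*% t(fit$R), 2, fit$centerQ, "+")
}

#' Rigidly align conformers onto a reference by their scaffold atoms
#'
#' Least-squares (Kabsch) superposition of each conformer's mapped scaffold
#' atoms onto the reference's; the whole molecule is moved by the fitted
#' rigid transform. Alignment is invariant to arbitrary rigid motion of the
#' inputs.
#'
#' @param conformers a \linkS4class{ConformerSet} whose members carry a
#'   \code{scaffold} index vector.
#' @param reference "most_active" with \code{activities} supplied, or an
#'   explicit compound id present in the set.
#' @param activities optional named vector (names = ids) used to resolve
#'   \code{reference = "most_active"} (maximum activity wins).
#' @return an aligned \linkS4class{ConformerSet} with per-compound scaffold
#'   RMSDs (Angstrom) to the reference.
#' @export
alignToReference <- function(conformers, reference = "most_active",
                             activities = NULL) {
  confs <- conformers@conformers
  ids <- vapply(confs, function(cf) cf$id, numeric(1))
  if (identical(reference, "most_active")) {
    if (is.null(activities)) stop("activities required for 'most_active'")
    reference <- as.numeric(names(activities))[which.max(activities)]
  }
  refIdx <- match(reference, ids)
  if (is.na(refIdx)) stop("reference id not in conformer set")
  ref <- confs[[refIdx]]
  if (is.null(ref$scaffold)) stop("scaffold match not found")
  refScaf <- ref$xyz[ref$scaffold, , drop = FALSE]
  rmsd <- numeric(length(confs))
  for (i in seq_along(confs)) {
    cf <- confs[[i]]
    if (is.null(cf$scaffold)) stop("scaffold match not found for id ", cf$id)
    if (length(cf$scaffold) != nrow(refScaf))
      stop("scaffold size mismatch for id ", cf$id)
    fit <- .kabsch(cf$xyz[cf$scaffold, , drop = FALSE], refScaf)
    confs[[i]]$xyz <- .applyFit(cf$xyz, fit)
    rmsd[i] <- sqrt(mean(rowSums(
      (confs[[i]]$xyz[cf$scaffold, , drop = FALSE] - refScaf)^2)))
  }
  new("ConformerSet", conformers = confs, aligned = TRUE,
      referenceId = as.numeric(reference),
      scaffoldRmsd = stats::setNames(rmsd, ids))
}

#' Accessor: conformer list of a ConformerSet
#' @param x a \linkS4class{ConformerSet}.
#' @return list of conformers (id, elements, xyz, charges, energy, scaffold).
#' @export
conformerList <- function(x) {
  stopifnot(is(x, "ConformerSet"))
  x@conformers
}

#' Accessor: per-compound scaffold RMSD of an aligned ConformerSet
#' @param x an aligned \linkS4class{ConformerSet}.
#' @return named numeric vector (Angstrom).
#' @export
scaffoldRmsd <- function(x) {
  stopifnot(is(x, "ConformerSet"))
  x@scaffoldRmsd
}

#' Write aligned conformers to SDF with charges, plus an alignment report
#'
#' The SDF (V2000) stores one record per conformer with the compound id as
#' title and the per-atom partial charges as a data field; the report is a
#' TSV of compound_id and scaffold_rmsd.
#'
#' @param conformers an aligned \linkS4class{ConformerSet}.
#' @param sdfPath,reportPath output paths (either may be NULL to skip).
#' @return invisibly, a list of the written paths.
#' @export
writeConformers <- function(conformers, sdfPath = NULL, reportPath = NULL) {
  confs <- conformerList(conformers)
  if (!is.null(sdfPath)) {
    blocks <- vapply(confs, function(cf) {
      n <- nrow(cf$xyz)
      atoms <- paste(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                             cf$xyz[, 1], cf$xyz[, 2], cf$xyz[, 3],
                             cf$elements), collapse = "\n")
      paste0(cf$id, "\n  fieldQSAR\n\n",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000\n", n, 0L),
             atoms, "\nM  END\n> <PARTIAL_CHARGES>\n",
             paste(sprintf("%.4f", cf$charges), collapse = " "),
             "\n\n$$$$")
    }, character(1))
    writeLines(blocks, sdfPath)
  }
  if (!is.null(reportPath)) {
    utils::write.table(
      data.frame(compound_id = names(scaffoldRmsd(conformers)),
                 scaffold_rmsd = round(scaffoldRmsd(conformers), 4)),
      reportPath, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(list(sdf = sdfPath, report = reportPath))
}
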