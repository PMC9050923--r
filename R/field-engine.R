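# CoMFA-style molecular interaction fields: steric (Lennard-Jones carbon
# probe) and electrostatic (+1e point charge, distance-dependent dielectric)
# energies sampled on a common rectangular grid, truncated, and assembled
# into the PLS descriptor matrix.

# Per-element Lennard-Jones parameters (UFF-derived): rmin is the like-pair
# distance at the potential minimum (Angstrom), eps the well depth
# (kcal/mol). The probe combines by Lorentz-Berthelot: Rij = rmin/2 + probe
# radius, eps_ij = sqrt(eps * probe eps).
.vdwParams <- data.frame(
  element = c("H", "C", "N", "O", "F", "S", "Cl", "Br", "P", "I"),
  rmin = c(2.886, 3.851, 3.660, 3.500, 3.364, 4.035, 3.947, 4.189,
           4.147, 4.500),
  eps = c(0.044, 0.105, 0.069, 0.060, 0.050, 0.274, 0.227, 0.251,
          0.305, 0.339))

#' Field computation configuration
#'
#' Defaults follow the published protocol: a +1e point-charge electrostatic
#' probe under a distance-dependent dielectric (eps(r) = r), a carbon steric
#' probe of radius 1.5 Angstrom, truncation of both fields at 30 kcal/mol,
#' and equal 50/50 steric/electrostatic weighting at descriptor assembly.
#'
#' @param probeCharge electrostatic probe charge (e).
#' @param stericProbeRadius steric probe radius (Angstrom).
#' @param stericProbeEps steric probe well depth (kcal/mol; sp3 carbon).
#' @param truncation energy clamp limit (kcal/mol).
#' @param stericWeight,electrostaticWeight field weights, must sum to 1.
#' @param coulombConstant Coulomb constant in kcal A / (mol e^2).
#' @param distanceFloor minimum probe-atom distance (Angstrom) guarding the
#'   Coulomb singularity; truncation makes its exact value irrelevant.
#' @return a list of class "fieldConfig".
#' @export
fieldConfig <- function(probeCharge = 1, stericProbeRadius = 1.5,
                        stericProbeEps = 0.105, truncation = 30,
                        stericWeight = 0.5, electrostaticWeight = 0.5,
                        coulombConstant = 332.06, distanceFloor = 0.05) {
  if (truncation <= 0) stop("truncation must be positive")
  if (abs(stericWeight + electrostaticWeight - 1) > 1e-9)
    stop("field weights must sum to 1")
  structure(list(probeCharge = probeCharge,
                 stericProbeRadius = stericProbeRadius,
                 stericProbeEps = stericProbeEps, truncation = truncation,
                 stericWeight = stericWeight,
                 electrostaticWeight = electrostaticWeight,
                 coulombConstant = coulombConstant,
                 distanceFloor = distanceFloor),
            class = "fieldConfig")
}

#' Build the common grid over an aligned conformer set
#'
#' Axis-aligned box: the union bounding box of all atoms, padded by the
#' margin on every face and snapped outward to the spacing lattice.
#'
#' @param conformers an aligned \linkS4class{ConformerSet}.
#' @param spacing grid spacing (Angstrom).
#' @param margin padding beyond the bounding box on every face (Angstrom).
#' @return a \linkS4class{GridSpec}.
#' @export
makeGrid <- function(conformers, spacing = 2, margin = 4) {
  confs <- conformerList(conformers)
  if (!length(confs)) stop("empty conformer set")
  xyz <- do.call(rbind, lapply(confs, function(cf) cf$xyz))
  lo <- floor((apply(xyz, 2, min) - margin) / spacing) * spacing
  hi <- ceiling((apply(xyz, 2, max) + margin) / spacing) * spacing
  new("GridSpec", origin = unname(lo), spacing = spacing,
      dims = as.integer(round((hi - lo) / spacing)) + 1L)
}

#' Grid point coordinates
#'
#' @param grid a \linkS4class{GridSpec}.
#' @return npts x 3 matrix of point coordinates, x varying fastest.
#' @export
gridPoints <- function(grid) {
  ax <- lapply(1:3, function(k)
    grid@origin[k] + grid@spacing * (seq_len(grid@dims[k]) - 1))
  unname(as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])))
}

# Probe-to-atom distance matrix (npts x natoms), floored.
.distanceMatrix <- function(points, xyz, floor) {
  D2 <- outer(rowSums(points^2), rowSums(xyz^2), "+") -
    2 * points %*% t(xyz)
  D <- sqrt(pmax(D2, 0))
  D[D < floor] <- floor
  D
}

#' Electrostatic probe field of one conformer
#'
#' Coulomb energy of a unit positive point charge under a distance-dependent
#' dielectric eps(r) = r: E(p) = sum_i k q_i q_probe / r_ip^2, truncated to
#' the configured limit.
#'
#' @param conformer one conformer list (elements, xyz, charges).
#' @param grid a \linkS4class{GridSpec}.
#' @param config a \code{\link{fieldConfig}}.
#' @return numeric vector of energies (kcal/mol), one per grid point.
#' @export
electrostaticField <- function(conformer, grid, config = fieldConfig()) {
  if (is.null(conformer$charges) || any(is.na(conformer$charges)))
    stop("missing charges")
  D <- .distanceMatrix(gridPoints(grid), conformer$xyz, config$distanceFloor)
  e <- (1 / D^2) %*% (config$coulombConstant * config$probeCharge *
                        conformer$charges)
  truncateField(as.numeric(e), config$truncation)
}

#' Steric probe field of one conformer
#'
#' Lennard-Jones 12-6 energy of a carbon probe:
#' E(p) = sum_i eps_ij [ (R_ij/r_ip)^12 - 2 (R_ij/r_ip)^6 ], with
#' Lorentz-Berthelot combination of the probe with per-element parameters,
#' truncated to the configured limit.
#'
#' @inheritParams electrostaticField
#' @return numeric vector of energies (kcal/mol), one per grid point.
#' @export
stericField <- function(conformer, grid, config = fieldConfig()) {
  m <- match(conformer$elements, .vdwParams$element)
  if (any(is.na(m)))
    stop("unparameterized element: ", conformer$elements[is.na(m)][1])
  Rij <- .vdwParams$rmin[m] / 2 + config$stericProbeRadius
  epsij <- sqrt(.vdwParams$eps[m] * config$stericProbeEps)
  D <- .distanceMatrix(gridPoints(grid), conformer$xyz, config$distanceFloor)
  sr6 <- sweep(1 / D, 2, Rij, "*")^6
  e <- sweep(sr6^2 - 2 * sr6, 2, epsij, "*") %*% rep(1, length(m))
  truncateField(as.numeric(e), config$truncation)
}

#' Clamp field energies to a symmetric limit
#'
#' Elementwise clamp to [-limit, +limit]; idempotent.
#'
#' @param x numeric vector of energies.
#' @param limit positive clamp limit (kcal/mol).
#' @return clamped vector.
#' @export
truncateField <- function(x, limit = 30) {
  if (limit <= 0) stop("limit must be positive")
  pmin(pmax(x, -limit), limit)
}

#' Compute both fields for every conformer on a common grid
#'
#' @param conformers an aligned \linkS4class{ConformerSet}.
#' @param grid a \linkS4class{GridSpec}; defaults to
#'   \code{makeGrid(conformers)}.
#' @param config a \code{\link{fieldConfig}}.
#' @return a \linkS4class{FieldSet}.
#' @export
computeFields <- function(conformers, grid = makeGrid(conformers),
                          config = fieldConfig()) {
  confs <- conformerList(conformers)
  ids <- vapply(confs, function(cf) cf$id, numeric(1))
  ste <- t(vapply(confs, stericField, numeric(prod(grid@dims)),
                  grid = grid, config = config))
  ele <- t(vapply(confs, electrostaticField, numeric(prod(grid@dims)),
                  grid = grid, config = config))
  new("FieldSet", ids = ids, steric = ste, electrostatic = ele, grid = grid,
      truncation = config$truncation)
}

#' Assemble the PLS descriptor matrix from field blocks
#'
#' Row per compound: the weighted steric energies followed by the weighted
#' electrostatic energies. Columns whose standard deviation across compounds
#' falls below the variance floor (constant columns) are dropped; the column
#' index retains the (field, point) identity of every kept column for
#' contour back-mapping.
#'
#' @param fields a \linkS4class{FieldSet}.
#' @param config a \code{\link{fieldConfig}} (supplies the weights).
#' @param varianceFloor drop columns with sd below this (kcal/mol).
#' @return list with \code{X} (n x p kept descriptor matrix, rownames =
#'   compound ids), \code{columnIndex} (data.frame field/point for kept
#'   columns), \code{keep} (logical over all 2 npts columns) and \code{grid}.
#' @export
assembleDescriptorMatrix <- function(fields, config = fieldConfig(),
                                     varianceFloor = 1e-6) {
  X <- cbind(config$stericWeight * fields@steric,
             config$electrostaticWeight * fields@electrostatic)
  np <- prod(fields@grid@dims)
  columnIndex <- data.frame(
    field = rep(c("steric", "electrostatic"), each = np),
    point = rep(seq_len(np), 2))
  sds <- apply(X, 2, stats::sd)
  keep <- sds >= varianceFloor
  rownames(X) <- fields@ids
  list(X = X[, keep, drop = FALSE], columnIndex = columnIndex[keep, ],
       keep = keep, grid = fields@grid)
}

#' Export a grid scalar field for visualization
#'
#' Writes the values in the documented point order (x fastest) as a Gaussian
#' cube or OpenDX file; both formats encode identical values.
#'
#' @param values numeric vector, one value per grid point.
#' @param grid a \linkS4class{GridSpec}.
#' @param path output file path.
#' @param format "cube" or "dx".
#' @return invisibly, the path.
#' @export
writeGridField <- function(values, grid, path, format = c("cube", "dx")) {
  format <- match.arg(format)
  np <- prod(grid@dims)
  if (length(values) != np) stop("values must cover the grid")
  if (!dir.exists(dirname(path))) stop("unwritable path")
  bohr <- 1 / 0.529177210903  # cube headers are in bohr
  if (format == "cube") {
    # cube scans z fastest; reorder from our x-fastest layout
    arr <- array(values, dim = grid@dims)
    vals <- as.numeric(aperm(arr, c(3, 2, 1)))  # x slow ... z fast
    hdr <- c("fieldQSAR grid export",
             "scalar field, x fastest in source order",
             sprintf("%5d%12.6f%12.6f%12.6f", 1, grid@origin[1] * bohr,
                     grid@origin[2] * bohr, grid@origin[3] * bohr),
             sprintf("%5d%12.6f%12.6f%12.6f", grid@dims[1],
                     grid@spacing * bohr, 0, 0),
             sprintf("%5d%12.6f%12.6f%12.6f", grid@dims[2], 0,
                     grid@spacing * bohr, 0),
             sprintf("%5d%12.6f%12.6f%12.6f", grid@dims[3], 0, 0,
                     grid@spacing * bohr),
             sprintf("%5d%12.6f%12.6f%12.6f%12.6f", 1, 0, 0, 0, 0))
    body <- vapply(split(vals, ceiling(seq_along(vals) / 6)),
                   function(v) paste(sprintf("%13.5e", v), collapse = ""),
                   character(1))
    writeLines(c(hdr, unname(body)), path)
  } else {
    arr <- array(values, dim = grid@dims)
    vals <- as.numeric(aperm(arr, c(3, 2, 1)))  # dx also scans z fastest
    hdr <- c(sprintf(
      "object 1 class gridpositions counts %d %d %d",
      grid@dims[1], grid@dims[2], grid@dims[3]),
      sprintf("origin %.6f %.6f %.6f", grid@origin[1], grid@origin[2],
              grid@origin[3]),
      sprintf("delta %.6f 0 0", grid@spacing),
      sprintf("delta 0 %.6f 0", grid@spacing),
      sprintf("delta 0 0 %.6f", grid@spacing),
      sprintf("object 2 class gridconnections counts %d %d %d",
              grid@dims[1], grid@dims[2], grid@dims[3]),
      sprintf(
        "object 3 class array type double rank 0 items %d data follows", np))
    body <- vapply(split(vals, ceiling(seq_along(vals) / 3)),
                   function(v) paste(sprintf("%.6e", v), collapse = " "),
                   character(1))
    writeLines(c(hdr, unname(body),
                 'attribute "dep" string "positions"'), path)
  }
  invisible(path)
}

#' Read back a grid scalar field written by \code{\link{writeGridField}}
#'
#' @param path file path.
#' @param format "cube" or "dx".
#' @return list with \code{values} (x fastest), \code{origin}, \code{spacing},
#'   \code{dims}.
#' @export
readGridField <- function(path, format = c("cube", "dx")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "cube") {
    bohr <- 0.529177210903
    origin <- as.numeric(strsplit(trimws(lines[3]), "\\s+")[[1]][2:4]) * bohr
    dims <- vapply(4:6, function(i)
      as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]][1]), integer(1))
    spacing <- as.numeric(strsplit(trimws(lines[4]), "\\s+")[[1]][2]) * bohr
    vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:7)]), "\\s+")))
    arr <- array(vals, dim = rev(dims))  # z fastest on disk
    list(values = as.numeric(aperm(arr, c(3, 2, 1))), origin = origin,
         spacing = spacing, dims = dims)
  } else {
    cnt <- as.integer(strsplit(lines[1], "\\s+")[[1]][6:8])
    origin <- as.numeric(strsplit(lines[2], "\\s+")[[1]][2:4])
    spacing <- as.numeric(strsplit(lines[3], "\\s+")[[1]][2])
    dataStart <- grep("data follows", lines) + 1
    dataEnd <- grep("^attribute", lines) - 1
    vals <- as.numeric(unlist(strsplit(trimws(lines[dataStart:dataEnd]),
                                       "\\s+")))
    arr <- array(vals, dim = rev(cnt))
    list(values = as.numeric(aperm(arr, c(3, 2, 1))), origin = origin,
         spacing = spacing, dims = cnt)
  }
}
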