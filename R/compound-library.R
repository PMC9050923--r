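# Enumeration of the 6,N2-diaryl-1,3,5-triazine-2,4-diamine library from its
# R1/R2 substituent table. The scaffold is written with a fixed atom order so
# the nine shared scaffold heavy atoms (triazine ring, both exocyclic
# nitrogens, the C6-aryl ipso carbon) sit at known indices; substituent
# fragments always start at their attachment (ipso) atom.

# IUPAC standard atomic weights, abridged to >= 4 significant figures.
.atomicMasses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   F = 18.998403, S = 32.06, Cl = 35.45, Br = 79.904,
                   P = 30.973762, I = 126.90447)

#' Substituent vocabulary of the triazine library
#'
#' Returns the hand-built token-to-fragment map covering every code in the
#' library's R1/R2 columns. Each fragment SMILES starts at its single
#' attachment atom (the ipso ring carbon), so ring regiochemistry follows the
#' token: "2-FC6H4" is ortho-fluoro relative to the attachment, thiophene
#' attaches at ring position 2, pyridine at position 3.
#'
#' @return data.frame with columns \code{token}, \code{smiles},
#'   \code{n_atoms} (heavy-atom count of the fragment) and \code{ring_kind}.
#' @export
substituentTable <- function() {
  path <- system.file("extdata", "substituents.tsv", package = "fieldQSAR")
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Parse an (id, r1, r2) library table into compound stubs
#'
#' Validates every substituent token against the packaged vocabulary and
#' checks id uniqueness. Unknown tokens are an error naming the token and
#' row, never a silent skip.
#'
#' @param rows data.frame with columns \code{id}, \code{r1}, \code{r2}.
#' @return data.frame of stubs (id, r1, r2), ids preserved.
#' @export
parseLibraryTable <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0) stop("library table is empty")
  if (!all(c("id", "r1", "r2") %in% names(rows)))
    stop("library table needs columns id, r1, r2")
  vocab <- substituentTable()$token
  for (col in c("r1", "r2")) {
    bad <- which(!(rows[[col]] %in% vocab))
    if (length(bad))
      stop(sprintf("unknown substituent token '%s' in column %s, row %d",
                   rows[[col]][bad[1]], col, bad[1]))
  }
  if (anyDuplicated(rows$id))
    stop("duplicate compound id: ", rows$id[duplicated(rows$id)][1])
  data.frame(id = as.integer(rows$id), r1 = rows$r1, r2 = rows$r2,
             stringsAsFactors = FALSE)
}

#' Assemble the molecule for one (R1, R2) pair
#'
#' Builds the 2-amino-4-(N-arylamino)-6-aryl-1,3,5-triazine from the fixed
#' aromatic scaffold template, R1 on the C6-aryl ring and R2 on the N2-aryl
#' ring. The scaffold atoms are written first (NH2 nitrogen, then around the
#' triazine ring with the anilino NH in place), so atom indices of the shared
#' scaffold are known for downstream alignment.
#'
#' @param r1Token,r2Token substituent codes as printed in the library table.
#' @return SMILES string of the assembled molecule.
#' @export
assembleStructure <- function(r1Token, r2Token) {
  tab <- substituentTable()
  f1 <- tab$smiles[match(r1Token, tab$token)]
  f2 <- tab$smiles[match(r2Token, tab$token)]
  if (is.na(f1)) stop("unknown substituent token '", r1Token, "'")
  if (is.na(f2)) stop("unknown substituent token '", r2Token, "'")
  paste0("Nc1nc(N", f2, ")nc(", f1, ")n1")
}

#' Indices of the nine shared scaffold heavy atoms
#'
#' For a molecule assembled by \code{\link{assembleStructure}} the heavy-atom
#' order is: NH2 nitrogen (1), triazine C2 (2), ring N (3), triazine C4 (4),
#' anilino N (5), the R2 aryl fragment, ring N, triazine C6, the R1 aryl
#' fragment (ipso first), closing ring N. The scaffold set is the triazine
#' ring, both exocyclic nitrogens and the C6-aryl ipso carbon.
#'
#' @param r1Token,r2Token substituent codes.
#' @return integer(9) atom indices into the assembled molecule.
#' @export
scaffoldAtomIndices <- function(r1Token, r2Token) {
  tab <- substituentTable()
  n1 <- tab$n_atoms[match(r1Token, tab$token)]
  n2 <- tab$n_atoms[match(r2Token, tab$token)]
  if (is.na(n1) || is.na(n2)) stop("unknown substituent token")
  c(1L, 2L, 3L, 4L, 5L, 5L + n2 + 1L, 5L + n2 + 2L, 5L + n2 + 3L,
    8L + n2 + n1)
}

# Elements expected at the mapped scaffold positions, used as a sanity check
# after any toolkit round trip.
.scaffoldElements <- c("N", "C", "N", "C", "N", "N", "C", "C", "N")

#' Canonical SMILES via OpenBabel
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES, same length and order.
#' @export
canonicalSmiles <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  inp <- paste0(paste(smiles, seq_along(smiles)), collapse = "\n")
  out <- ChemmineOB::convertFormat("SMI", "CAN", paste0(inp, "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "[ \t]+"), `[`, character(1), 1L)
}

#' Molecular formula (Hill order) of one or more structures
#'
#' @param smiles character vector of SMILES.
#' @return character vector of Hill-order formulas.
#' @export
molecularFormula <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  inp <- paste0(paste(smiles, seq_along(smiles)), collapse = "\n")
  props <- ChemmineOB::forEachMol("SMI", paste0(inp, "\n"),
                                  function(m) ChemmineOB::prop_OB(m))
  vapply(props, function(p) p$formula, character(1))
}

# Parse a Hill formula into a named count vector ("C15H12FN5" -> c(C=15, ...)).
.parseFormula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (!length(toks) || paste(toks, collapse = "") != formula)
    stop("cannot parse formula '", formula, "'")
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(sub("^[A-Za-z]+", "", toks))
  n[is.na(n)] <- 1L
  counts <- tapply(n, el, sum)
  stats::setNames(as.integer(counts), names(counts))
}

#' Elemental mass composition of a molecular formula
#'
#' Mass percentages by element, for comparison with combustion-analysis
#' ("Anal. calcd") values. Percentages sum to 100 within 0.01.
#'
#' @param formula Hill-order formula string, e.g. "C15H12FN5".
#' @return named numeric vector of mass percent per element.
#' @export
elementalComposition <- function(formula) {
  counts <- .parseFormula(formula)
  unknown <- setdiff(names(counts), names(.atomicMasses))
  if (length(unknown)) stop("unknown element symbol: ", unknown[1])
  masses <- counts * .atomicMasses[names(counts)]
  100 * masses / sum(masses)
}

#' Build the full compound library
#'
#' Parses the table, assembles every structure, canonicalizes it and attaches
#' formula and molecular weight.
#'
#' @param table data.frame with columns id, r1, r2; defaults to the packaged
#'   126-compound library table.
#' @return a \linkS4class{CompoundLibrary}.
#' @export
buildLibrary <- function(table = loadLibraryTable()) {
  stubs <- parseLibraryTable(table)
  smiles <- mapply(assembleStructure, stubs$r1, stubs$r2, USE.NAMES = FALSE)
  inp <- paste0(paste(smiles, stubs$id), collapse = "\n")
  props <- ChemmineOB::forEachMol("SMI", paste0(inp, "\n"),
                                  function(m) ChemmineOB::prop_OB(m))
  rec <- data.frame(
    id = stubs$id, r1 = stubs$r1, r2 = stubs$r2, smiles = smiles,
    canonical = vapply(props, function(p) p$cansmi, character(1)),
    formula = vapply(props, function(p) p$formula, character(1)),
    mw = vapply(props, function(p) p$MW, numeric(1)),
    stringsAsFactors = FALSE)
  new("CompoundLibrary", records = rec)
}

#' The packaged library table (ids and substituent tokens)
#'
#' @return data.frame with columns id, r1, r2 for the 126 library members.
#' @export
loadLibraryTable <- function() {
  path <- system.file("extdata", "table1_viability.tsv", package = "fieldQSAR")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  tab[, c("id", "r1", "r2")]
}

#' Accessor: the record table of a CompoundLibrary
#' @param x a \linkS4class{CompoundLibrary}.
#' @return the records data.frame.
#' @export
libraryRecords <- function(x) {
  stopifnot(is(x, "CompoundLibrary"))
  x@records
}

#' Write library structures to a SMILES list or SDF file
#'
#' SMILES output is one record per line with the id after whitespace; SDF
#' output is V2000 with the id as the record title. Round-tripping through
#' \code{\link{readStructures}} recovers the same canonical structures.
#'
#' @param library a \linkS4class{CompoundLibrary}.
#' @param path output file path.
#' @param format "smiles" or "sdf".
#' @return invisibly, the path.
#' @export
writeStructures <- function(library, path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  rec <- libraryRecords(library)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: directory does not exist")
  if (format == "smiles") {
    writeLines(if (nrow(rec)) paste(rec$smiles, rec$id) else character(0),
               path)
  } else {
    if (nrow(rec) == 0) { writeLines(character(0), path); return(invisible(path)) }
    inp <- paste0(paste(rec$smiles, rec$id), collapse = "\n")
    sdf <- ChemmineOB::convertFormat("SMI", "SDF", paste0(inp, "\n"))
    writeLines(sdf, path, sep = "")
  }
  invisible(path)
}

#' Read structures back from a SMILES list or SDF file
#'
#' @param path input file path.
#' @param format "smiles" or "sdf".
#' @return data.frame with columns \code{id} and \code{canonical}.
#' @export
readStructures <- function(path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (format == "smiles") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
      return(data.frame(id = integer(0), canonical = character(0)))
    parts <- strsplit(lines, "[ \t]+")
    smi <- vapply(parts, `[`, character(1), 1L)
    id <- as.integer(vapply(parts, `[`, character(1), 2L))
    data.frame(id = id, canonical = canonicalSmiles(smi),
               stringsAsFactors = FALSE)
  } else {
    txt <- paste(readLines(path), collapse = "\n")
    if (!nzchar(trimws(txt)))
      return(data.frame(id = integer(0), canonical = character(0)))
    out <- ChemmineOB::convertFormat("SDF", "CAN", paste0(txt, "\n"))
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "[ \t]+")
    data.frame(id = as.integer(vapply(parts, `[`, character(1), 2L)),
               canonical = vapply(parts, `[`, character(1), 1L),
               stringsAsFactors = FALSE)
  }
}
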