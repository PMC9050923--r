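# Synthetic descriptor/activity data with a planted sparse linear signal,
# and tiny toy molecule sets, so the regression and contour stages are
# testable without any structure generation.

#' Generate a synthetic field-descriptor / activity dataset
#'
#' Descriptors mimic truncated field energies: per molecule, an i.i.d.
#' Gaussian field on the grid is smoothed with a 3x3x3 moving average (so
#' columns are spatially correlated, like real molecular fields), scaled and
#' clamped to +/- 30 kcal/mol. A contiguous block of k grid points carries
#' the planted coefficients; y = X w + Gaussian noise.
#'
#' @param nMol number of molecules (rows), >= 4.
#' @param gridDims integer(3) grid dimensions.
#' @param kSupport number of nonzero planted coefficients.
#' @param effectScale standard deviation of the planted nonzero
#'   coefficients.
#' @param noiseSd Gaussian noise standard deviation on y.
#' @param seed RNG seed; the object is fully reproducible from it.
#' @param fieldScale standard deviation (kcal/mol) of the smoothed
#'   descriptor values before clamping; order 1, matching the magnitude of
#'   the informative columns of a real truncated-field descriptor matrix
#'   (the clamp then engages only in rare tails, as it does on real grids).
#' @return a \linkS4class{SyntheticQsar}.
#' @export
generateSyntheticQsar <- function(nMol = 25, gridDims = c(5, 5, 5),
                                  kSupport = 10, effectScale = 1,
                                  noiseSd = 0.3, seed = 1, fieldScale = 1) {
  gridDims <- as.integer(gridDims)
  p <- prod(gridDims)
  if (nMol < 4) stop("need at least 4 molecules")
  if (kSupport > p) stop("kSupport exceeds the number of grid points")
  set.seed(seed)
  X <- t(vapply(seq_len(nMol), function(i) {
    raw <- array(stats::rnorm(p), dim = gridDims)
    sm <- .movingAverage3d(raw)
    v <- as.numeric(sm)
    v <- v / stats::sd(v) * fieldScale
    pmin(pmax(v, -30), 30)
  }, numeric(p)))
  rownames(X) <- seq_len(nMol)
  support <- .contiguousSupport(gridDims, kSupport)
  w <- numeric(p)
  w[support] <- stats::rnorm(kSupport, sd = effectScale)
  y <- as.numeric(X %*% w) + stats::rnorm(nMol, sd = noiseSd)
  new("SyntheticQsar", X = X, y = y, trueCoefficients = w,
      noiseSd = noiseSd, seed = as.integer(seed), dims = gridDims)
}

# 3D moving average with window 3 (edge-truncated), the spatial smoother
# that correlates neighbouring descriptor columns.
.movingAverage3d <- function(arr) {
  d <- dim(arr)
  out <- array(0, dim = d)
  cnt <- array(0, dim = d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    out[xs - dx, ys - dy, zs - dz] <- out[xs - dx, ys - dy, zs - dz] +
      arr[xs, ys, zs]
    cnt[xs - dx, ys - dy, zs - dz] <- cnt[xs - dx, ys - dy, zs - dz] + 1
  }
  out / cnt
}

# A contiguous support block in grid space: grow a neighbourhood around a
# random seed point until k points are collected (breadth-first over the
# 6-neighbour lattice graph).
.contiguousSupport <- function(dims, k) {
  idx <- function(x, y, z) x + dims[1] * (y - 1) + dims[1] * dims[2] * (z - 1)
  start <- c(sample.int(dims[1], 1), sample.int(dims[2], 1),
             sample.int(dims[3], 1))
  seen <- matrix(start, ncol = 3)
  queue <- list(start)
  while (nrow(seen) < k && length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (step in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                      c(0, 0, 1), c(0, 0, -1))) {
      nb <- cur + step
      if (any(nb < 1) || any(nb > dims)) next
      if (any(seen[, 1] == nb[1] & seen[, 2] == nb[2] & seen[, 3] == nb[3]))
        next
      seen <- rbind(seen, nb)
      queue <- c(queue, list(nb))
      if (nrow(seen) >= k) break
    }
  }
  sort(idx(seen[, 1], seen[, 2], seen[, 3]))[seq_len(k)]
}

#' Accessor: descriptor matrix and response of a SyntheticQsar
#' @param x a \linkS4class{SyntheticQsar}.
#' @return list with X, y, trueCoefficients.
#' @export
syntheticData <- function(x) {
  stopifnot(is(x, "SyntheticQsar"))
  list(X = x@X, y = x@y, trueCoefficients = x@trueCoefficients)
}

# Small rigid substituents for toy benzene derivatives.
.toyFragments <- c("F", "Cl", "Br", "C", "O", "N", "C#N", "OC")

#' Generate toy benzene-scaffold molecules
#'
#' Small rigid molecules sharing a benzene core with 1-2 substituents,
#' suitable for fast end-to-end smoke runs of the conformer, field and
#' regression stages. Deterministic per seed.
#'
#' @param n number of molecules, >= 1.
#' @param seed RNG seed.
#' @return data.frame with columns \code{id}, \code{smiles}, and
#'   \code{scaffold} (list column of the 6 benzene atom indices).
#' @export
generateToyMolecules <- function(n, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  fragAtoms <- c("F" = 1L, "Cl" = 1L, "Br" = 1L, "C" = 1L, "O" = 1L,
                 "N" = 1L, "C#N" = 2L, "OC" = 2L)
  smiles <- character(n)
  scaffold <- vector("list", n)
  for (i in seq_len(n)) {
    nsub <- sample(1:2, 1)
    subs <- sample(.toyFragments, nsub, replace = TRUE)
    if (nsub == 1) {
      smiles[i] <- paste0("c1ccccc1", subs[1])
      scaffold[[i]] <- 1:6
    } else {
      # para-disubstituted; the branch fragment shifts later ring indices
      smiles[i] <- paste0("c1ccc(", subs[2], ")cc1", subs[1])
      k <- fragAtoms[subs[2]]
      scaffold[[i]] <- c(1:4, 4L + k + 1L, 4L + k + 2L)
    }
  }
  out <- data.frame(id = seq_len(n), smiles = smiles,
                    stringsAsFactors = FALSE)
  out$scaffold <- scaffold
  out
}
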