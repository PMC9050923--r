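# Shared fixtures: hand-built conformers for field tests and a memoized run
# of the default pipeline (the expensive stages are computed once per suite).

.cache <- new.env(parent = emptyenv())

cachedDefaultRun <- function() {
  if (is.null(.cache$run))
    .cache$run <- runQsarPipeline(qsarConfig())
  .cache$run
}

cachedLibrary <- function() {
  if (is.null(.cache$lib)) .cache$lib <- buildLibrary()
  .cache$lib
}

# A minimal hand-built conformer (no toolkit involved): atoms at given
# coordinates with given elements and charges.
toyConformer <- function(xyz, elements, charges, id = 1) {
  list(id = id, elements = elements,
       xyz = matrix(xyz, ncol = 3, byrow = TRUE),
       charges = charges, energy = NA_real_, scaffold = NULL)
}

# A 3-point grid spec helper.
gridSpec <- function(origin, spacing, dims) {
  new("GridSpec", origin = origin, spacing = spacing, dims = as.integer(dims))
}

# Brute-force pairwise Coulomb oracle (distance-dependent dielectric
# eps(r) = r), no truncation: explicit double loop.
bruteCoulomb <- function(points, xyz, charges, k = 332.06, floor = 0.05) {
  out <- numeric(nrow(points))
  for (p in seq_len(nrow(points))) {
    e <- 0
    for (i in seq_len(nrow(xyz))) {
      r <- max(sqrt(sum((points[p, ] - xyz[i, ])^2)), floor)
      e <- e + k * charges[i] / r^2
    }
    out[p] <- e
  }
  out
}

# Random rigid motion (proper rotation + translation).
randomRigidMotion <- function(xyz, seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3)
  R <- qr.Q(qr(A))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(xyz %*% R, 2, runif(3, -10, 10), "+")
}
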