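# Grid construction, probe fields, truncation and descriptor assembly.

test_that("grid padding arithmetic and containment hold", {
  cf <- toyConformer(c(0, 0, 0), "C", 0)
  cs <- new("ConformerSet", conformers = list(cf), aligned = TRUE)
  g <- makeGrid(cs, spacing = 2, margin = 4)
  expect_equal(g@dims, c(5L, 5L, 5L))
  expect_equal(g@origin, c(-4, -4, -4))
  # every atom strictly inside the box, any geometry
  set.seed(3)
  cf2 <- toyConformer(rnorm(30, sd = 4), rep("C", 10), rep(0, 10))
  cs2 <- new("ConformerSet", conformers = list(cf2), aligned = TRUE)
  g2 <- makeGrid(cs2, 2, 4)
  hi <- g2@origin + (g2@dims - 1) * g2@spacing
  expect_true(all(t(cf2$xyz) > g2@origin & t(cf2$xyz) < hi))
  # doubling the margin never shrinks any axis
  g3 <- makeGrid(cs2, 2, 8)
  expect_true(all(g3@dims >= g2@dims))
  expect_error(makeGrid(new("ConformerSet", conformers = list(),
                            aligned = TRUE)), "empty")
})

test_that("electrostatic field matches the hand Coulomb computation", {
  # one atom with q = +0.5 e at 2.0 A from a probe point:
  # 332.06 * 0.5 / 2^2 = 41.5, clamped to +30
  cf <- toyConformer(c(2, 0, 0), "C", 0.5)
  g <- gridSpec(c(0, 0, 0), 1, c(1, 1, 1))
  expect_equal(electrostaticField(cf, g), 30)
  expect_equal(electrostaticField(cf, g, fieldConfig(truncation = 100)),
               332.06 * 0.5 / 4)
  # all-zero charges give an identically zero field
  cf0 <- toyConformer(rnorm(9), rep("C", 3), rep(0, 3))
  g5 <- gridSpec(c(-2, -2, -2), 2, c(3, 3, 3))
  expect_equal(electrostaticField(cf0, g5), rep(0, 27))
  expect_error(electrostaticField(toyConformer(c(0, 0, 0), "C", NA), g5),
               "missing charges")
})

test_that("electrostatic field is linear in charges (superposition)", {
  set.seed(7)
  g <- gridSpec(c(-3, -3, -3), 3, c(3, 3, 3))
  cfg <- fieldConfig(truncation = 1e9)  # pre-truncation linearity
  pts <- gridPoints(g)
  for (rep in 1:5) {
    n <- sample(2:6, 1)
    xyz <- matrix(rnorm(3 * n, sd = 2), ncol = 3)
    q1 <- rnorm(n); q2 <- rnorm(n)
    f1 <- electrostaticField(toyConformer(t(xyz), rep("C", n), q1,
                                          id = rep), g, cfg)
    # against the explicit pairwise double-loop oracle
    expect_equal(f1, bruteCoulomb(pts, xyz, q1), tolerance = 1e-10)
    f2 <- electrostaticField(toyConformer(t(xyz), rep("C", n), q2), g, cfg)
    f12 <- electrostaticField(toyConformer(t(xyz), rep("C", n), q1 + q2),
                              g, cfg)
    expect_equal(f12, f1 + f2, tolerance = 1e-9)
    # two superposed identical charges double the single-charge field
    fD <- electrostaticField(
      toyConformer(t(xyz[c(1, 1), ]), c("C", "C"), rep(q1[1], 2)), g, cfg)
    fS <- electrostaticField(toyConformer(xyz[1, ], "C", q1[1]), g, cfg)
    expect_equal(fD, 2 * fS, tolerance = 1e-9)
  }
})

test_that("steric field has the analytic 12-6 minimum and asymptotics", {
  cfg <- fieldConfig()
  rminC <- 3.851 / 2 + 1.5          # carbon atom + carbon probe
  epsC <- sqrt(0.105 * 0.105)
  probeAt <- function(r) {
    cf <- toyConformer(c(r, 0, 0), "C", 0)
    stericField(cf, gridSpec(c(0, 0, 0), 1, c(1, 1, 1)), cfg)
  }
  expect_equal(probeAt(rminC), -epsC, tolerance = 1e-9)
  # monotone approach to zero from below beyond the minimum
  rs <- seq(rminC, 12, length.out = 30)
  es <- vapply(rs, probeAt, numeric(1))
  expect_true(all(es <= 0))
  expect_true(all(diff(es) > 0))
  expect_lt(abs(es[30]), 1e-3)
  # deep inside the repulsive wall the clamp takes over
  expect_equal(probeAt(0.5 * rminC), 30)
  expect_error(
    stericField(toyConformer(c(0, 0, 0), "Xx", 0),
                gridSpec(c(0, 0, 0), 1, c(1, 1, 1)), cfg),
    "unparameterized")
})

test_that("truncation clamps symmetrically and is idempotent", {
  expect_equal(truncateField(c(45, -60, 3), 30), c(30, -30, 3))
  v <- truncateField(rnorm(100, sd = 50), 30)
  expect_identical(truncateField(v, 30), v)
  expect_error(truncateField(1, 0), "positive")
})

test_that("a mirror-symmetric molecule yields a mirror-symmetric field", {
  # two equal atoms at +/- x, grid symmetric about the yz plane
  cf <- toyConformer(c(1.2, 0.3, -0.4, -1.2, 0.3, -0.4),
                     c("N", "N"), c(0.25, 0.25))
  g <- gridSpec(c(-4, -4, -4), 2, c(5, 5, 5))
  mirrorIdx <- function(g) {
    # index permutation sending x -> -x on the grid
    arr <- array(seq_len(prod(g@dims)), dim = g@dims)
    as.numeric(arr[g@dims[1]:1, , ])
  }
  for (f in list(electrostaticField, stericField)) {
    v <- f(cf, g, fieldConfig())
    expect_equal(v, v[mirrorIdx(g)], tolerance = 1e-9)
  }
})

test_that("translating molecules and grid together leaves fields unchanged", {
  set.seed(11)
  cf <- toyConformer(rnorm(12), c("C", "N", "O", "H"), runif(4, -0.3, 0.3))
  g <- gridSpec(c(-4, -4, -4), 2, c(5, 5, 5))
  shift <- c(7.3, -2.1, 4.4)
  cfT <- cf; cfT$xyz <- sweep(cf$xyz, 2, shift, "+")
  gT <- gridSpec(g@origin + shift, g@spacing, g@dims)
  expect_equal(electrostaticField(cf, g), electrostaticField(cfT, gT),
               tolerance = 1e-9)
  expect_equal(stericField(cf, g), stericField(cfT, gT), tolerance = 1e-9)
})

test_that("descriptor assembly weights, bounds and filters columns", {
  run <- cachedDefaultRun()
  X <- run$descriptors$X
  expect_equal(nrow(X), 25)
  expect_true(all(abs(X) <= 30 * 0.5 + 1e-9))
  np <- prod(run$descriptors$grid@dims)
  expect_lte(ncol(X), 2 * np)
  expect_equal(nrow(run$descriptors$columnIndex), ncol(X))
  # identical molecules: all columns constant, all dropped
  cf <- toyConformer(c(0, 0, 0), "C", 0.1)
  cf2 <- cf; cf2$id <- 2
  cs <- new("ConformerSet", conformers = list(cf, cf2), aligned = TRUE)
  fs <- computeFields(cs, makeGrid(cs, 2, 4))
  d0 <- assembleDescriptorMatrix(fs)
  expect_equal(ncol(d0$X), 0)
  # variance floor 0 keeps every column
  dAll <- assembleDescriptorMatrix(fs, varianceFloor = 0)
  expect_equal(ncol(dAll$X), 2 * 125)
})

test_that("grid files round-trip in cube and dx formats", {
  g <- gridSpec(c(-4, -2, 0), 2, c(5, 4, 3))
  set.seed(2)
  v <- rnorm(prod(g@dims))
  for (fmt in c("cube", "dx")) {
    path <- tempfile(fileext = paste0(".", fmt))
    writeGridField(v, g, path, fmt)
    back <- readGridField(path, fmt)
    expect_equal(back$values, v, tolerance = 1e-5)
    expect_equal(back$dims, g@dims)
    expect_equal(back$origin, g@origin, tolerance = 1e-5)
  }
})
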