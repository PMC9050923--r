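# STDEV*COEFF coefficient grids, percentile contour regions and export.

test_that("coefficient grids place c * sd at mapped points, zero elsewhere", {
  # single retained column with known coefficient and column sd
  X <- matrix(c(0, 1, 2, 5, 5, 5), 3, 2)  # second column constant
  ci <- data.frame(field = "steric", point = c(4L))
  m <- fitPls(X[, 1, drop = FALSE], c(0, 1, 2), 1, columnIndex = ci)
  g <- gridSpec(c(0, 0, 0), 1, c(2, 2, 2))
  vals <- coefficientGrid(m, "steric", X[, 1, drop = FALSE], g)
  expect_equal(vals[4], m@coefficients[1] * sd(X[, 1]))
  expect_equal(vals[-4], rep(0, 7))
  expect_error(coefficientGrid(m, "electrostatic", X[, 1, drop = FALSE], g),
               "absent")
})

test_that("contour regions split at the stated percentiles", {
  r <- contourRegions(c(-1, 0, 0, 1), 20, 80)
  expect_equal(sum(r$favorable), 1)
  expect_equal(sum(r$unfavorable), 1)
  expect_true(r$favorable[4] && r$unfavorable[1])
  # symmetric values give symmetric masks
  v <- c(-3, -2, -1, 0, 1, 2, 3)
  r2 <- contourRegions(v, 25, 75)
  expect_equal(sum(r2$favorable), sum(r2$unfavorable))
  expect_equal(which(r2$favorable), length(v) + 1 - rev(which(r2$unfavorable)))
  # all-zero values give empty masks, not an error
  r0 <- contourRegions(rep(0, 10))
  expect_false(any(r0$favorable) || any(r0$unfavorable))
  expect_error(contourRegions(v, 80, 20), "lowPct < highPct")
})

test_that("masks are disjoint and bounded by the percentile budget", {
  run <- cachedDefaultRun()
  for (ct in run$contours) {
    expect_false(any(ct@favorable & ct@unfavorable))
    nz <- sum(ct@values != 0)
    budget <- (100 - ct@thresholds[2] + ct@thresholds[1]) / 100
    expect_lte(sum(ct@favorable) + sum(ct@unfavorable),
               ceiling(budget * nz) + 1)
  }
})

test_that("higher activity shifts coefficient mass to distinctive columns", {
  # two compounds differing at a single grid point; the compound with the
  # higher response has the larger field value there, so the coefficient at
  # that point must be positive
  X <- rbind(c(1, 0, 0), c(1, 2, 0), c(1, 4, 0), c(1, 6, 0))
  y <- c(0, 1, 2, 3)
  ci <- data.frame(field = "steric", point = 1:3)
  m <- fitPls(X, y, 1, columnIndex = ci)
  g <- gridSpec(c(0, 0, 0), 1, c(3, 1, 1))
  vals <- coefficientGrid(m, "steric", X, g)
  expect_gt(vals[2], 0)
  expect_equal(vals[c(1, 3)], c(0, 0))
})

test_that("planted-support columns are recovered at the pinned seed", {
  # frozen regression values from the seeded recovery run: collinearity of
  # the smoothed contiguous support caps the overlap (see vignette)
  syn <- generateSyntheticQsar(seed = 1)
  d <- syntheticData(syn)
  sel <- chooseComponents(d$X, d$y, 5)
  m <- fitPls(d$X, d$y, sel$ncomp)
  sds <- apply(d$X, 2, sd)
  top <- order(-abs(m@coefficients * sds))[1:10]
  support <- which(d$trueCoefficients != 0)
  jaccard <- length(intersect(top, support)) /
    length(union(top, support))
  expect_equal(jaccard, 0.25, tolerance = 1e-12)
  expect_gte(jaccard, 0.2)
})

test_that("contour export round-trips and summarizes both formats", {
  run <- cachedDefaultRun()
  ct <- run$contours[["steric"]]
  for (fmt in c("cube", "dx")) {
    dir <- file.path(tempdir(), paste0("contours_", fmt))
    paths <- exportContours(ct, dir, fmt)
    vals <- readGridField(paths[1], fmt)
    expect_equal(vals$values, ct@values, tolerance = 1e-5)
    fav <- readGridField(paths[2], fmt)
    expect_equal(fav$values != 0, ct@favorable)
    js <- jsonlite::read_json(paths[4])
    expect_equal(js$n_favorable, sum(ct@favorable))
  }
  # both formats encode identical values
  d1 <- readGridField(file.path(tempdir(), "contours_cube",
                                "steric_values.cube"), "cube")
  d2 <- readGridField(file.path(tempdir(), "contours_dx",
                                "steric_values.dx"), "dx")
  expect_equal(d1$values, d2$values, tolerance = 1e-5)
})
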