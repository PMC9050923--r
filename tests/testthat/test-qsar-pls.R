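# PLS fitting, component selection, splitting, statistics and the report.

# Brute-force statistics on the published experimental/predicted pairs,
# pinned by direct arithmetic on the printed table (training rows).
pinnedTrainR2 <- 0.8122980050
pinnedTrainRmse <- 0.2816866493
pinnedPooledR2 <- 0.7062829940
pinnedPooledRmse <- 0.3940913600

test_that("PLS at full rank equals least squares on random instances", {
  skip_if_not_installed("MASS")
  set.seed(21)
  for (rep in 1:10) {
    X <- matrix(rnorm(40), 8, 5)
    y <- rnorm(8)
    m <- fitPls(X, y, 5)
    # oracle: minimum-norm least squares on centered data via pseudoinverse
    Xc <- scale(X, scale = FALSE)
    bOracle <- MASS::ginv(Xc) %*% (y - mean(y))
    expect_equal(m@coefficients, as.numeric(bOracle), tolerance = 1e-8)
    expect_equal(predict(m, X), as.numeric(Xc %*% bOracle + mean(y)),
                 tolerance = 1e-8)
  }
  # wide case: minimum-norm solution among the infinitely many interpolants
  X <- matrix(rnorm(24), 4, 6)
  y <- rnorm(4)
  m <- fitPls(X, y, 3)
  bOracle <- MASS::ginv(scale(X, scale = FALSE)) %*% (y - mean(y))
  expect_equal(m@coefficients, as.numeric(bOracle), tolerance = 1e-8)
})

test_that("the first PLS direction is proportional to X'y", {
  # hand-computable 3 x 2 instance
  X <- matrix(c(1, 2, 3, 0, 1, -1), 3, 2)
  y <- c(1, 0, 2)
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  w1 <- crossprod(Xc, yc); w1 <- w1 / sqrt(sum(w1^2))
  m <- fitPls(X, y, 1)
  expect_equal(m@weights[, 1], as.numeric(w1), tolerance = 1e-12)
  # and the one-component prediction equals the score regression
  t1 <- Xc %*% w1
  q1 <- sum(yc * t1) / sum(t1^2)
  expect_equal(predict(m, X), as.numeric(t1 * q1 + mean(y)),
               tolerance = 1e-12)
})

test_that("exact linear responses are interpolated at full rank", {
  set.seed(5)
  X <- matrix(rnorm(60), 10, 6)
  b <- rnorm(6)
  y <- as.numeric(X %*% b) + 2
  m <- fitPls(X, y, 6)
  expect_equal(predict(m, X), y, tolerance = 1e-8)
  # a row at the training mean predicts the training mean response
  expect_equal(predict(m, matrix(colMeans(X), 1)), mean(y),
               tolerance = 1e-8)
  # duplicated rows give duplicated predictions
  p2 <- predict(m, X[c(3, 3), ])
  expect_equal(p2[1], p2[2])
  expect_error(predict(m, X[, 1:3]), "column mismatch")
})

test_that("coefficients are invariant to training row permutation", {
  set.seed(6)
  X <- matrix(rnorm(200), 20, 10)
  y <- rnorm(20)
  m1 <- fitPls(X, y, 4)
  ord <- sample(20)
  m2 <- fitPls(X[ord, ], y[ord], 4)
  expect_equal(m1@coefficients, m2@coefficients, tolerance = 1e-10)
})

test_that("PLS predictions agree with an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(8)
  X <- matrix(rnorm(15 * 12), 15, 12,
              dimnames = list(NULL, paste0("d", 1:12)))
  y <- rnorm(15)
  m <- fitPls(X, y, 3)
  mo <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = FALSE)
  po <- predict(mo, X)$predict[, 1, 3]
  expect_equal(predict(m, X), unname(po), tolerance = 1e-6)
})

test_that("leave-one-out q2 matches a naive refit loop", {
  set.seed(9)
  X <- matrix(rnorm(14 * 8), 14, 8)
  y <- rnorm(14)
  for (a in c(1, 3)) {
    # oracle: hold each row out by hand and refit
    press <- 0
    for (i in 1:14) {
      m <- fitPls(X[-i, ], y[-i], a)
      press <- press + (y[i] - predict(m, X[i, , drop = FALSE]))^2
    }
    expect_equal(looQ2(X, y, a), 1 - press / sum((y - mean(y))^2),
                 tolerance = 1e-12)
  }
})

test_that("component choice maximizes q2 and respects the cap", {
  syn <- generateSyntheticQsar(nMol = 30, noiseSd = 0, seed = 5)
  X <- syntheticData(syn)$X
  # pure-noise response: no component count has predictive value, and the
  # returned count is the q2 maximizer (first maximum, favouring fewer)
  set.seed(42)
  yn <- rnorm(30)
  sel <- chooseComponents(X, yn, 5)
  expect_true(all(sel$q2 < 0))
  expect_equal(sel$ncomp, which.max(sel$q2))
  # cap of 1 returns 1
  expect_equal(chooseComponents(X, yn, 1)$ncomp, 1L)
})

test_that("model statistics behave and match the pinned brute force", {
  y <- c(1, 2, 3, 4)
  expect_equal(modelStats(y, y), list(r2 = 1, rmse = 0))
  aff <- modelStats(y, 2 * y + 5)
  expect_equal(aff$r2, 1)
  expect_gt(aff$rmse, 0)
  expect_error(modelStats(y, rep(1, 4)), "zero-variance")
  expect_error(modelStats(y, y[1:2]), "equal length")
  ref <- loadReferencePredictions()
  tr <- !ref$test_set
  st <- modelStats(ref$experimental_pgi50[tr], ref$predicted_pgi50[tr])
  expect_equal(st$r2, pinnedTrainR2, tolerance = 1e-9)
  expect_equal(st$rmse, pinnedTrainRmse, tolerance = 1e-9)
  stAll <- modelStats(ref$experimental_pgi50, ref$predicted_pgi50)
  expect_equal(stAll$r2, pinnedPooledR2, tolerance = 1e-9)
  expect_equal(stAll$rmse, pinnedPooledRmse, tolerance = 1e-9)
})

test_that("splitting honours explicit membership and maximin diversity", {
  ds <- buildQsarDataset(loadPotency())
  sp <- diverseSplit(ds, explicitTest = defaultTestIds())
  expect_equal(sp$test, c(58L, 73L, 78L, 99L, 101L, 120L))
  expect_length(sp$train, 19)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), datasetEntries(ds)$id)
  expect_error(diverseSplit(ds, explicitTest = 7L), "not in dataset")
  # maximin mode: deterministic per seed, test points mutually distant
  run <- cachedDefaultRun()
  X <- run$descriptors$X
  m1 <- diverseSplit(ds, X, nTest = 6, seed = 4)
  m2 <- diverseSplit(ds, X, nTest = 6, seed = 4)
  expect_identical(m1, m2)
  expect_length(m1$test, 6)
  sp0 <- diverseSplit(ds, X, nTest = 0)
  expect_length(sp0$test, 0)
  expect_length(sp0$train, 25)
})

test_that("the residual table is internally consistent", {
  run <- cachedDefaultRun()
  tb <- reportTable(run$report)
  expect_equal(nrow(tb), 25)
  expect_equal(sum(tb$split == "test"), 6)
  expect_equal(tb$experimental - tb$predicted, tb$residual, tolerance = 1e-12)
  st <- reportStats(run$report)
  expect_true(st$r2Train >= 0 && st$r2Train <= 1)
  expect_gte(st$rmseTrain, 0)
})
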