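test_that("preprocessing centers, autoscales and drops constant features", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(10, 10, 10, 10), c = c(5, 1, 9, 2))
  fs <- MetabFeatureSet(x, rep(c("Control", "Model"), each = 2))
  expect_warning(pre <- preprocessFeatures(fs, logTransform = FALSE,
                                           scaling = "center"),
                 "zero-variance")
  expect_false("b" %in% rownames(intensities(pre)))
  expect_lt(max(abs(rowMeans(intensities(pre)))), 1e-12)
  pre2 <- preprocessFeatures(fs[c("a", "c"), ], logTransform = FALSE,
                             scaling = "autoscale")
  expect_lt(max(abs(apply(intensities(pre2), 1, sd) - 1)), 1e-12)
  allflat <- MetabFeatureSet(rbind(a = rep(1, 4)), rep(c("x", "y"), each = 2))
  expect_error(preprocessFeatures(allflat), "zero variance")
})

test_that("PCA recovers a rank-1 matrix and keeps scores orthogonal", {
  set.seed(10)
  u <- rnorm(12); v <- rnorm(6)
  X1 <- outer(u, v)
  m1 <- pcaFit(X1, 1)
  expect_gt(m1@R2X[1], 1 - 1e-9)
  X <- matrix(rnorm(12 * 6), 12, 6)
  m <- pcaFit(X, 4)
  expect_lte(sum(m@R2X), 1)
  g <- crossprod(scores(m))
  expect_lt(max(abs(g - diag(diag(g)))), 1e-9)
  expect_error(pcaFit(X, 12), "ncomp")
  # with all components the centered matrix is reconstructed
  mf <- pcaFit(X, 6)
  rec <- scores(mf) %*% t(loadings2(mf))
  expect_lt(max(abs(rec - sweep(X, 2, colMeans(X)))), 1e-8)
})

test_that("PLS-DA separates distant classes and degrades under label shuffling", {
  set.seed(21)
  fx <- separatedClasses()
  m <- plsdaFit(fx$X, fx$y, ncomp = 2)
  expect_gte(r2y(m), 0.9)
  set.seed(22)
  mShuf <- plsdaFit(fx$X, sample(fx$y), ncomp = 2)
  expect_lt(r2y(mShuf), r2y(m))
  expect_error(plsdaFit(fx$X, rep("A", 20)), "2 classes")
})

test_that("duplicating every feature leaves the PLS score direction unchanged", {
  set.seed(23)
  fx <- separatedClasses(n = 16, p = 10)
  Xs <- scale(fx$X)
  m1 <- plsdaFit(Xs, fx$y, ncomp = 1)
  m2 <- plsdaFit(cbind(Xs, Xs), fx$y, ncomp = 1)
  expect_gt(abs(cor(scores(m1)[, 1], scores(m2)[, 1])), 1 - 1e-9)
})

test_that("OPLS-DA with no orthogonal component reduces to one-component PLS", {
  set.seed(31)
  fx <- separatedClasses(n = 14, p = 8)
  po <- oplsdaFit(fx$X, fx$y, nOrthogonal = 0)
  pl <- plsdaFit(fx$X, fx$y, ncomp = 1)
  s1 <- scores(po)[, 1]; s2 <- scores(pl)[, 1]
  if (sum(s1 * s2) < 0) s2 <- -s2
  expect_lt(max(abs(s1 - s2)), 1e-9)
})

test_that("OPLS-DA orthogonal scores are uncorrelated with class and prediction", {
  set.seed(32)
  fx <- separatedClasses(n = 20, p = 15)
  m <- oplsdaFit(fx$X, fx$y, nOrthogonal = 2)
  yc <- as.numeric(fx$y == "B") - mean(fx$y == "B")
  for (k in seq_len(ncol(m@orthoScores))) {
    expect_lt(abs(sum(m@orthoScores[, k] * yc)), 1e-9)
    expect_lt(abs(sum(m@orthoScores[, k] * scores(m)[, 1])), 1e-9)
  }
  expect_error(oplsdaFit(fx$X, rep(c("A", "B", "C"), length.out = 20)),
               "2 classes")
})

test_that("orthogonal signal correction removes a nuisance direction", {
  set.seed(33)
  n <- 24
  y <- rep(c("A", "B"), each = n / 2)
  yc <- as.numeric(y == "B") - 0.5
  nuis <- rnorm(n)
  nuis <- residuals(lm(nuis ~ yc))  # exactly class-orthogonal
  X <- outer(yc, rnorm(12)) + 3 * outer(nuis, rnorm(12)) +
    matrix(rnorm(n * 12, sd = 0.05), n, 12)
  r2o <- r2y(oplsdaFit(X, y, nOrthogonal = 1))
  r2p <- r2y(plsdaFit(X, y, ncomp = 1))
  expect_gte(r2o, r2p)
})

test_that("VIP obeys its normalization identity and flags pure signal", {
  set.seed(41)
  for (i in 1:5) {
    fx <- separatedClasses(n = 16, p = sample(5:30, 1))
    v <- vipScores(plsdaFit(fx$X, fx$y, ncomp = 2))
    expect_lt(abs(mean(v^2) - 1), 1e-10)
  }
  # one informative and one noise feature
  y <- rep(c("A", "B"), each = 10)
  X <- cbind(signal = as.numeric(y == "B") + rnorm(20, sd = 0.05),
             noise = rnorm(20))
  v <- vipScores(oplsdaFit(X, y, nOrthogonal = 0))
  expect_gt(v["signal"], 1)
  expect_lt(v["noise"], 1)
  # a single-feature model has VIP exactly 1
  v1 <- vipScores(oplsdaFit(X[, 1, drop = FALSE], y, nOrthogonal = 0))
  expect_equal(unname(v1), 1)
  expect_error(vipScores(pcaFit(X, 1)), "PLSDA")
})

test_that("p(corr) hits the +/-1 poles and flags zero-variance features", {
  set.seed(51)
  fx <- separatedClasses(n = 16, p = 6)
  m <- oplsdaFit(fx$X, fx$y)
  tt <- scores(m)[, 1]
  X2 <- cbind(fx$X, plus = tt, minus = -tt, flat = rep(1, 16))
  expect_warning(pc <- pcorrScores(m, X2), "zero-variance")
  expect_equal(unname(pc["plus"]), 1)
  expect_equal(unname(pc["minus"]), -1)
  expect_true(is.na(pc["flat"]))
  expect_true(all(abs(pc[!is.na(pc)]) <= 1 + 1e-12))
})

test_that("Q2 is high for separated classes, low for noise, and below R2Y", {
  set.seed(61)
  fx <- separatedClasses()
  expect_gte(q2CrossVal(fx$X, fx$y, ncomp = 1, seed = 1), 0.5)
  nulls <- vapply(1:10, function(s) {
    set.seed(100 + s)
    X <- matrix(rnorm(24 * 40), 24, 40)
    y <- rep(c("A", "B"), each = 12)
    q2CrossVal(X, y, ncomp = 1, seed = s)
  }, numeric(1))
  expect_true(all(nulls <= 0.2))
  for (s in 1:8) {
    set.seed(200 + s)
    X <- matrix(rnorm(20 * 15), 20, 15)
    X[11:20, 1:3] <- X[11:20, 1:3] + runif(1, 0, 3)
    y <- rep(c("A", "B"), each = 10)
    expect_lte(q2CrossVal(X, y, ncomp = 2, seed = s),
               r2y(plsdaFit(X, y, ncomp = 2)))
  }
  expect_error(q2CrossVal(fx$X, fx$y, folds = 1), "folds")
})

test_that("NIPALS PLS scores agree with an independent PLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(71)
  fx <- separatedClasses(n = 18, p = 12)
  mine <- plsdaFit(fx$X, fx$y, ncomp = 2)
  ref <- mixOmics::plsda(fx$X, factor(fx$y), ncomp = 2, scale = FALSE)
  for (k in 1:2)
    expect_gt(abs(cor(scores(mine)[, k], ref$variates$X[, k])), 1 - 1e-6)
})
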