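makeFs <- function(x, groups) MetabFeatureSet(x, groups)

test_that("univariate statistics behave on identical, shifted and swapped groups", {
  set.seed(1)
  base <- matrix(runif(5 * 4, 100, 200), 5, 4)
  x <- cbind(base, base)  # case == reference
  fs <- makeFs(x, rep(c("Model", "Control"), each = 4))
  u <- univariateStats(fs, "Model", "Control")
  expect_equal(u$fold_change, rep(1, 5))
  expect_equal(u$p_value, rep(1, 5))
  # case at 4x reference with mild noise
  x2 <- cbind(base * 4 * matrix(exp(rnorm(20, 0, 0.03)), 5, 4),
              base * matrix(exp(rnorm(20, 0, 0.03)), 5, 4))
  fs2 <- makeFs(x2, rep(c("Model", "Control"), each = 4))
  u2 <- univariateStats(fs2, "Model", "Control")
  expect_true(all(u2$fold_change > 3.5 & u2$fold_change < 4.5))
  expect_true(all(u2$p_value <= 0.05))
  swapped <- univariateStats(fs2, "Control", "Model")
  expect_lt(max(abs(swapped$fold_change - 1 / u2$fold_change)), 1e-12)
  expect_error(univariateStats(fs2[, 1:5], "Model", "Control"), ">= 2 samples")
})

test_that("screen boundaries are inclusive for VIP and p, strict for FC and p(corr)", {
  rec <- data.frame(
    feature = c("vipEdge", "fcEdge", "pcorrEdge", "pEdge", "allPass", "downReg",
                "none"),
    vip = c(1.0, 2, 2, 2, 2, 2, 0.5),
    p_value = c(0.01, 0.01, 0.01, 0.05, 0.01, 0.01, 0.5),
    fold_change = c(3, 2.0, 3, 3, 3, 0.25, 1),
    p_corr = c(0.9, 0.9, 0.6, 0.9, 0.9, -0.9, 0.1))
  out <- screenDifferential(rec)
  sel <- out$feature[out$selected]
  expect_true("vipEdge" %in% sel)   # VIP >= 1 inclusive
  expect_true("pEdge" %in% sel)     # p <= 0.05 inclusive
  expect_false("fcEdge" %in% sel)   # FC > 2 strict
  expect_false("pcorrEdge" %in% sel) # |p(corr)| > 0.6 strict
  expect_true("downReg" %in% sel)   # FC < 1/2 counts (two-sided)
  expect_identical(out$regulated[out$feature == "downReg"], "down")
  expect_false("none" %in% sel)
  expect_error(screenDifferential(rec[, -2]), "missing")
})

test_that("the full contrast screen recovers planted features with low FDP", {
  out <- genMetabolomicsTable(seed = 14)
  scr <- screenContrast(out$features, "Model", "Control", seed = 14)
  truth <- out$truth@diffContrast1
  sel <- selectedFeatures(scr)
  expect_gte(length(intersect(sel, truth)) / length(truth), 0.9)
  expect_lte(length(setdiff(sel, truth)) / max(length(sel), 1), 0.1)
  expect_gt(r2y(scr), 0.8)
  expect_gt(q2(scr), 0.5)
})

test_that("Venn intersection reports regions and handles containment", {
  v <- vennShared(c("a", "b", "c"), c("x", "y"))
  expect_identical(v$shared, character())
  expect_identical(unname(v$counts), c(3L, 2L, 0L))
  v2 <- vennShared(c("a", "b"), c("a", "b", "c"))
  expect_identical(v2$shared, c("a", "b"))
  expect_identical(v2$onlyA, character())
})

test_that("ORA expected counts and p-values match exhaustive enumeration", {
  bg <- paste0("f", 1:20)
  pw <- list(path1 = bg[1:5])
  sel <- c(bg[1:2], bg[10:11])  # q = 4, k = 2
  res <- oraEnrich(sel, pw, bg)
  expect_equal(res$expected, 4 * 5 / 20)  # exactly 1.0
  expect_lt(abs(res$raw_p - enumHyperP(20, 5, 4, 2)), 1e-12)
  # no hits -> p = 1; pathway == background -> p = 1
  expect_equal(oraEnrich(bg[10:12], list(p = bg[1:5]), bg)$raw_p, 1)
  expect_equal(oraEnrich(bg[1:3], list(p = bg), bg)$raw_p, 1)
  expect_error(oraEnrich("zzz", pw, bg), "outside the background")
  expect_error(oraEnrich(character(), pw, character()), "non-empty")
})

test_that("ORA matches enumeration across random small configurations", {
  set.seed(77)
  for (i in 1:12) {
    N <- sample(10:30, 1)
    m <- sample(2:(N - 2), 1)
    q <- sample(2:6, 1)
    bg <- paste0("f", seq_len(N))
    sel <- sample(bg, q)
    pw <- list(p = bg[seq_len(m)])
    k <- length(intersect(sel, pw$p))
    res <- oraEnrich(sel, pw, bg)
    expect_lt(abs(res$raw_p - enumHyperP(N, m, q, k)), 1e-12)
    expect_equal(res$expected, q * m / N)
    expect_equal(res$neg_log_p, -log10(res$raw_p))
  }
})

test_that("ORA sorts by raw p and the BH flag only adds a column", {
  bg <- paste0("f", 1:30)
  pw <- list(strong = bg[1:5], weak = bg[20:28])
  res <- oraEnrich(bg[1:5], pw, bg)
  expect_identical(res$pathway, c("strong", "weak"))
  resAdj <- oraEnrich(bg[1:5], pw, bg, adjust = TRUE)
  expect_identical(res$raw_p, resAdj$raw_p)
  expect_true("fdr" %in% names(resAdj))
})
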