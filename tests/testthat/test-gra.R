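test_that("sequence normalization matches its closed forms and flags degenerate input", {
  expect_equal(as.numeric(normalizeSequences(rbind(c(2, 4, 6)), "mean")),
               c(0.5, 1.0, 1.5))
  expect_equal(as.numeric(normalizeSequences(rbind(c(1, 3, 5)), "minmax")),
               c(0, 0.5, 1))
  expect_equal(as.numeric(normalizeSequences(rbind(c(2, 4, 6)), "initial")),
               c(1, 2, 3))
  x <- rbind(a = c(1.5, 2.5, -4))
  expect_identical(normalizeSequences(x, "none"), x)
  expect_error(normalizeSequences(rbind(z = c(-1, 1)), "mean"), "z")
  expect_error(normalizeSequences(rbind(flat = c(2, 2, 2)), "minmax"), "flat")
  expect_error(normalizeSequences(rbind(a = c(0, 1)), "initial"), "a")
})

test_that("gray coefficients reproduce the hand-worked example", {
  co <- grayCoefficients(c(1, 2, 3), rbind(x1 = c(1, 2, 3), x2 = c(3, 2, 1)),
                         xi = 0.1)
  expect_equal(unname(co["x1", ]), c(1, 1, 1))
  expect_equal(unname(co["x2", ]), c(0.2 / 2.2, 1, 0.2 / 2.2), tolerance = 1e-12)
  expect_equal(unname(grayGrade(co)), c(1, mean(c(0.2 / 2.2, 1, 0.2 / 2.2))),
               tolerance = 1e-12)
})

test_that("a comparison equal to the reference earns coefficient 1 everywhere", {
  set.seed(11)
  x0 <- rnorm(8)
  X <- rbind(copy = x0, other = rnorm(8))
  co <- grayCoefficients(x0, X, xi = 0.1)
  expect_identical(unname(co["copy", ]), rep(1, 8))
  expect_true(all(co > 0 & co <= 1))
})

test_that("coefficients decrease monotonically as xi shrinks at non-minimal deviations", {
  x0 <- c(1, 2, 3)
  X <- rbind(a = c(1, 2, 3), b = c(3, 2, 1))
  co1 <- grayCoefficients(x0, X, xi = 0.5)
  co2 <- grayCoefficients(x0, X, xi = 0.1)
  nonmin <- c(co1["b", 1], co1["b", 3])
  expect_true(all(c(co2["b", 1], co2["b", 3]) < nonmin))
})

test_that("identical comparison set returns all-ones instead of erroring", {
  x0 <- c(2, 4, 6)
  co <- grayCoefficients(x0, rbind(x0, x0), xi = 0.1)
  expect_true(all(co == 1))
})

test_that("grade of an empty coefficient vector is an error", {
  expect_error(grayGrade(numeric()), "empty")
  expect_equal(grayGrade(0.5), 0.5)
})

test_that("pipeline grades equal the loop-based brute-force oracle", {
  set.seed(42)
  for (rep in 1:10) {
    peaks <- matrix(runif(5 * 6, 1, 10), 5, 6,
                    dimnames = list(paste0("c", 1:5), paste0("s", 1:6)))
    effects <- matrix(runif(6 * 3, 1, 10), 6, 3,
                      dimnames = list(paste0("s", 1:6), paste0("i", 1:3)))
    res <- spectrumEffectGRA(peaks, effects)
    ref <- bruteGra(peaks, effects, xi = 0.1)
    expect_lt(max(abs(grades(res) - ref$grades)), 1e-12)
    expect_lt(max(abs(relevancy(res) - ref$relevancy)), 1e-12)
  }
})

test_that("relevancy is invariant to positive rescaling and sample permutation", {
  set.seed(7)
  peaks <- matrix(runif(4 * 8, 1, 5), 4, 8,
                  dimnames = list(paste0("c", 1:4), paste0("s", 1:8)))
  effects <- matrix(runif(8 * 2, 1, 5), 8, 2,
                    dimnames = list(paste0("s", 1:8), paste0("i", 1:2)))
  base <- relevancy(spectrumEffectGRA(peaks, effects))
  scaled <- peaks
  scaled[2, ] <- scaled[2, ] * 137.5
  expect_lt(max(abs(relevancy(spectrumEffectGRA(scaled, effects)) - base)), 1e-12)
  perm <- sample(8)
  expect_lt(max(abs(relevancy(spectrumEffectGRA(peaks[, perm],
                                                effects[perm, ])) - base)), 1e-12)
})

test_that("a component copying an indicator reaches relevancy 1 with one indicator", {
  set.seed(3)
  eff <- matrix(runif(6, 1, 5), 6, 1,
                dimnames = list(paste0("s", 1:6), "INS"))
  peaks <- rbind(copy = eff[, 1] * 3, other = runif(6, 1, 5))
  colnames(peaks) <- rownames(eff)
  r <- relevancy(spectrumEffectGRA(peaks, eff))
  expect_equal(unname(r["copy"]), 1)
})

test_that("selection is strict at the threshold and breaks ties by id", {
  rel <- c(a = 0.9, b = 0.85, c = 0.4)
  expect_identical(selectComponents(rel, 0.85), "a")
  expect_identical(selectComponents(rel, 1e-9), c("a", "b", "c"))
  expect_identical(selectComponents(c(b = 0.9, a = 0.9), 0.8), c("a", "b"))
  expect_identical(selectComponents(c(a = 0.2), 0.85), character())
})

test_that("sample-axis mismatch is reported with the unmatched ids", {
  peaks <- matrix(1:6, 2, 3, dimnames = list(c("c1", "c2"), c("s1", "s2", "s3")))
  effects <- matrix(1:6, 3, 2, dimnames = list(c("s1", "s2", "sX"), c("i1", "i2")))
  expect_error(spectrumEffectGRA(peaks, effects), "sX")
})
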