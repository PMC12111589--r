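test_that("spectrum-effect generator is deterministic and validates arguments", {
  a <- genSpectrumEffect(nComponents = 10, nActive = 3, nSamples = 8, seed = 9)
  b <- genSpectrumEffect(nComponents = 10, nActive = 3, nSamples = 8, seed = 9)
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$effects, b$effects)
  expect_identical(a$truth@activeComponents, b$truth@activeComponents)
  expect_error(genSpectrumEffect(nComponents = 0), "integer")
  expect_error(genSpectrumEffect(nActive = 40, nComponents = 30), "nActive")
  expect_error(genSpectrumEffect(nSamples = 2), "integer")
  expect_true(all(a$peaks > 0) && all(a$effects > 0))
})

test_that("noiseless actives are exact affine transforms of every indicator", {
  sim <- genSpectrumEffect(nComponents = 6, nActive = 2, nSamples = 10,
                           noiseSd = 0, seed = 2)
  for (cid in sim$truth@activeComponents) {
    for (j in seq_len(ncol(sim$effects))) {
      fit <- lm(sim$peaks[cid, ] ~ sim$effects[, j])
      expect_lt(max(abs(residuals(fit))), 1e-9)
    }
  }
})

test_that("at zero signal active components are indistinguishable from inactive", {
  sim <- genSpectrumEffect(nComponents = 20, nActive = 10, nSamples = 50,
                           signal = 0, seed = 6)
  # with no severity slope, correlation with indicators is pure noise for
  # both kinds of component
  act <- sim$truth@activeComponents
  inact <- setdiff(rownames(sim$peaks), act)
  corAbs <- function(ids) mean(abs(cor(t(sim$peaks[ids, ]), sim$effects)))
  expect_lt(abs(corAbs(act) - corAbs(inact)), 0.15)
})

test_that("planted actives outrank all inactives through the GRA stage", {
  sim <- genSpectrumEffect(nComponents = 30, nActive = 8, nSamples = 24,
                           signal = 2.0, noiseSd = 0.3, seed = 1)
  r <- relevancy(spectrumEffectGRA(sim$peaks, sim$effects))
  act <- sim$truth@activeComponents
  expect_gt(min(r[act]), max(r[setdiff(names(r), act)]))
})

test_that("metabolomics generator plants the requested fold changes", {
  out <- genMetabolomicsTable(nFeatures = 60, nDiffShared = 6, nDiffOnly1 = 4,
                              nDiffOnly2 = 4, nPerGroup = 8, fc = 4, cv = 0.05,
                              seed = 3)
  x <- intensities(out$features)
  g <- sampleGroups(out$features)
  tr <- out$truth
  for (f in tr@diffContrast1) {
    ratio <- mean(x[f, g == "Model"]) / mean(x[f, g == "Control"])
    if (ratio < 1) ratio <- 1 / ratio
    expect_gt(ratio, 3)
    expect_lt(ratio, 5.3)
  }
  # contrast-2-only features are silent in contrast 1
  for (f in setdiff(tr@diffContrast2, tr@diffContrast1)) {
    ratio <- mean(x[f, g == "Model"]) / mean(x[f, g == "Control"])
    expect_lt(abs(log(ratio)), 0.25)
  }
})

test_that("metabolomics truth respects the Venn invariant and determinism", {
  out <- genMetabolomicsTable(nFeatures = 40, nDiffShared = 0, nDiffOnly1 = 5,
                              nDiffOnly2 = 5, seed = 8)
  expect_identical(out$truth@sharedDiff, character())
  expect_identical(intersect(out$truth@diffContrast1, out$truth@diffContrast2),
                   character())
  again <- genMetabolomicsTable(nFeatures = 40, nDiffShared = 0, nDiffOnly1 = 5,
                                nDiffOnly2 = 5, seed = 8)
  expect_identical(intensities(out$features), intensities(again$features))
  expect_error(genMetabolomicsTable(fc = 1), "fc")
  expect_error(genMetabolomicsTable(fc = 0.5), "fc")
  # a truth object with an inconsistent shared set is invalid
  expect_error(new("SyntheticTruth", diffContrast1 = "a", diffContrast2 = "b",
                   sharedDiff = "a", seed = 1L), "intersection")
})

test_that("OGTT curves peak at 30 min and ITT uses its own grid", {
  panel <- genGlucosePanel(curveKind = c("OGTT", "ITT"), seed = 5)
  cv <- curves(panel)
  og <- cv[cv$kind == "OGTT", ]
  for (g in unique(subjects(panel)$group)) {
    ids <- subjects(panel)$subject[subjects(panel)$group == g]
    m <- tapply(og$glucose[og$subject %in% ids], og$time[og$subject %in% ids],
                mean)
    expect_equal(as.numeric(names(which.max(m))), 30)
  }
  it <- cv[cv$kind == "ITT", ]
  expect_identical(sort(unique(it$time)), c(0, 15, 30, 45, 60))
  expect_identical(sort(unique(og$time)), seq(0, 180, 30))
  empty <- genGlucosePanel(nPerGroup = 0, seed = 1)
  expect_identical(nrow(subjects(empty)), 0L)
  expect_error(genGlucosePanel(curveKind = "IVGTT"), "unknown curve kind")
})

test_that("toy network hits the requested disease overlap exactly", {
  net <- genToyNetwork(nCompounds = 5, nTargets = 20, nDiseaseGenes = 10,
                       overlap = 6, seed = 7)
  edgeTargets <- unique(net$edges$target)
  expect_identical(length(intersect(edgeTargets, net$diseaseGenes)), 6L)
  # at least one compound has no disease-linked target
  scr <- networkScreen(split(net$edges$target, net$edges$compound),
                       net$diseaseGenes)
  expect_lt(nrow(scr$candidates), length(net$compounds))
  again <- genToyNetwork(nCompounds = 5, nTargets = 20, nDiseaseGenes = 10,
                         overlap = 6, seed = 7)
  expect_identical(net$edges, again$edges)
  expect_error(genToyNetwork(overlap = 50, nTargets = 20, nDiseaseGenes = 10),
               "overlap")
})

test_that("zero overlap leaves nothing after the degree filter", {
  net <- genToyNetwork(nCompounds = 4, nTargets = 10, nDiseaseGenes = 5,
                       overlap = 0, seed = 2)
  expect_identical(intersect(unique(net$edges$target), net$diseaseGenes),
                   character())
  scr <- networkScreen(split(net$edges$target, net$edges$compound),
                       net$diseaseGenes)
  expect_identical(nrow(scr$candidates), 0L)
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(genSpectrumEffect(nComponents = 5, nActive = 2, nSamples = 5, seed = 1))
  invisible(genToyNetwork(seed = 1))
  expect_identical(.Random.seed, before)
})
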