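# Synthetic-data generators. Every generator is a pure function of its
# parameters and seed (the caller's RNG state is saved and restored), and
# returns planted ground truth so downstream recovery can be scored.

.checkCount <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x != round(x) || x < min)
    stop(name, " must be an integer >= ", min)
  as.integer(x)
}

.withSeed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

# serum indicators measured in the pharmacodynamic panel; extended with
# generic ids when more are requested
.indicatorNames <- function(n) {
  base <- c("INS", "TG", "TCHO", "GHb", "HDLC", "LDLC", "KB")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, paste0("IND", seq_len(n - length(base))))
}

#' Simulate a spectrum-effect data set
#'
#' A latent per-sample disease-severity variable z ~ N(0, 1) drives both the
#' pharmacodynamic indicators and the peak responses of the active
#' components: each is an affine function of z (relative amplitude
#' \code{signal} on a fixed base level of 10) times a component-specific
#' positive scale, plus additive Gaussian measurement noise of sd
#' \code{noiseSd}. Inactive components are the same construction with zero
#' severity slope, so at \code{signal = 0} active and inactive components
#' are distributionally identical, and at \code{noiseSd = 0} every active
#' component is an exact affine transform of every indicator. Intensities
#' are clipped at a small positive floor (1e-6 of the row mean) because GRA
#' mean-normalization divides by sequence means.
#'
#' @param nComponents,nActive number of components and of planted actives
#'   (nActive <= nComponents).
#' @param nSamples number of animals (>= 3).
#' @param nIndicators number of serum indicators (>= 1).
#' @param signal severity amplitude (>= 0); default 2 means the severity
#'   swings peak responses by about +/- 50 percent of the base level.
#' @param noiseSd additive measurement-noise sd on the base-10 scale;
#'   default 0.02 (0.2 percent of the base level, instrument-repeatability
#'   territory).
#' @param seed integer seed.
#' @return list(peaks = component x sample matrix,
#'   effects = sample x indicator matrix, truth = \linkS4class{SyntheticTruth}).
#' @export
genSpectrumEffect <- function(nComponents = 30, nActive = 8, nSamples = 24,
                              nIndicators = 7, signal = 2, noiseSd = 0.02,
                              seed = 1) {
  nComponents <- .checkCount(nComponents, "nComponents")
  nActive <- .checkCount(nActive, "nActive", min = 0)
  nSamples <- .checkCount(nSamples, "nSamples", min = 3)
  nIndicators <- .checkCount(nIndicators, "nIndicators")
  if (nActive > nComponents) stop("nActive must be <= nComponents")
  if (signal < 0 || noiseSd < 0) stop("signal and noiseSd must be >= 0")
  .withSeed(seed, {
    base <- 10
    z <- rnorm(nSamples)
    compScale <- runif(nComponents, 0.5, 5)
    indScale <- runif(nIndicators, 0.5, 5)
    active <- seq_len(nActive)
    peaks <- matrix(NA_real_, nComponents, nSamples)
    for (i in seq_len(nComponents)) {
      slope <- if (i %in% active) signal else 0
      peaks[i, ] <- compScale[i] * (base + slope * z + noiseSd * rnorm(nSamples))
    }
    effects <- matrix(NA_real_, nSamples, nIndicators)
    for (j in seq_len(nIndicators))
      effects[, j] <- indScale[j] * (base + signal * z + noiseSd * rnorm(nSamples))
    cid <- sprintf("C%02d", seq_len(nComponents))
    sid <- sprintf("S%02d", seq_len(nSamples))
    dimnames(peaks) <- list(cid, sid)
    dimnames(effects) <- list(sid, .indicatorNames(nIndicators))
    floorAt <- function(m) {
      fl <- 1e-6 * abs(rowMeans(m))
      pmax(m, fl)
    }
    peaks <- floorAt(peaks)
    effects <- t(floorAt(t(effects)))
    truth <- new("SyntheticTruth", activeComponents = cid[active],
                 seed = as.integer(seed))
    list(peaks = peaks, effects = effects, truth = truth)
  })
}

#' Simulate an untargeted-metabolomics feature table
#'
#' Three groups (Control, Model, Treated) of \code{nPerGroup} samples.
#' Planted differential features change by a multiplicative factor
#' \code{fc}, direction alternating up/down, in a pattern that mirrors a
#' disease/treatment design: "shared" features are disturbed in the Model
#' and restored by treatment (differential in both Control-vs-Model and
#' Model-vs-Treated), contrast-1-only features are disturbed and not
#' restored, contrast-2-only features respond to treatment alone. All other
#' features share one group-independent log-normal distribution. Noise is
#' log-normal with coefficient of variation \code{cv}.
#'
#' @param nFeatures total features.
#' @param nDiffShared,nDiffOnly1,nDiffOnly2 planted counts (defaults 18, 10
#'   and 26, matching a 28/44-feature two-contrast design with 18 shared).
#' @param nPerGroup samples per group (>= 3; default 8).
#' @param fc fold change of planted features (> 1; default 4).
#' @param cv relative (log-normal) noise, default 0.2.
#' @param seed integer seed.
#' @return list(features = \linkS4class{MetabFeatureSet},
#'   truth = \linkS4class{SyntheticTruth}).
#' @export
genMetabolomicsTable <- function(nFeatures = 200, nDiffShared = 18,
                                 nDiffOnly1 = 10, nDiffOnly2 = 26,
                                 nPerGroup = 8, fc = 4, cv = 0.2, seed = 1) {
  nFeatures <- .checkCount(nFeatures, "nFeatures")
  nDiffShared <- .checkCount(nDiffShared, "nDiffShared", min = 0)
  nDiffOnly1 <- .checkCount(nDiffOnly1, "nDiffOnly1", min = 0)
  nDiffOnly2 <- .checkCount(nDiffOnly2, "nDiffOnly2", min = 0)
  nPerGroup <- .checkCount(nPerGroup, "nPerGroup", min = 3)
  nPlanted <- nDiffShared + nDiffOnly1 + nDiffOnly2
  if (nPlanted > nFeatures) stop("planted features exceed nFeatures")
  if (!is.numeric(fc) || fc <= 1) stop("fc must be > 1")
  if (cv < 0) stop("cv must be >= 0")
  .withSeed(seed, {
    groups <- rep(c("Control", "Model", "Treated"), each = nPerGroup)
    nS <- length(groups)
    fid <- sprintf("M%03d", seq_len(nFeatures))
    sid <- sprintf("%s_%d", groups, sequence(rep(nPerGroup, 3)))
    mu <- exp(runif(nFeatures, log(1e3), log(1e5)))
    sigma <- sqrt(log(1 + cv^2))
    shared <- seq_len(nDiffShared)
    only1 <- seq_len(nDiffOnly1) + nDiffShared
    only2 <- seq_len(nDiffOnly2) + nDiffShared + nDiffOnly1
    dir <- rep_len(c(1, -1), nPlanted)  # alternate up/down
    fcMat <- matrix(1, nFeatures, nS)
    isModel <- groups == "Model"
    isTreated <- groups == "Treated"
    for (ii in seq_along(shared))
      fcMat[shared[ii], isModel] <- fc^dir[ii]
    for (ii in seq_along(only1))
      fcMat[only1[ii], isModel | isTreated] <- fc^dir[nDiffShared + ii]
    for (ii in seq_along(only2))
      fcMat[only2[ii], isTreated] <- fc^dir[nDiffShared + nDiffOnly1 + ii]
    noise <- matrix(exp(rnorm(nFeatures * nS, -sigma^2 / 2, sigma)),
                    nFeatures, nS)
    x <- mu * fcMat * noise
    dimnames(x) <- list(fid, sid)
    mz <- round(runif(nFeatures, 80, 1000), 4)
    rt <- round(runif(nFeatures, 0.5, 35), 2)
    fs <- MetabFeatureSet(x, groups, mz = mz, rt = rt)
    truth <- new("SyntheticTruth",
                 diffContrast1 = fid[c(shared, only1)],
                 diffContrast2 = fid[c(shared, only2)],
                 sharedDiff = fid[shared],
                 seed = as.integer(seed))
    list(features = fs, truth = truth)
  })
}

# group-level physiology used by the glucose-panel generator; unknown labels
# fall back to the Treated profile
.glucoseProfiles <- list(
  Control = list(fbg = c(6, 0.4), ins = c(10, 1), amp = 6, tau = 25, itt = 0.50),
  Model   = list(fbg = c(14, 1.0), ins = c(17, 1.5), amp = 12, tau = 40, itt = 0.85),
  Treated = list(fbg = c(9, 0.8), ins = c(13, 1.2), amp = 8, tau = 30, itt = 0.65),
  Met     = list(fbg = c(8.5, 0.8), ins = c(12, 1.2), amp = 8, tau = 28, itt = 0.60)
)

#' Simulate a glucose-tolerance subject panel
#'
#' OGTT curves (grid 0, 30, ..., 180 min) rise from the fasting baseline to
#' a peak at 30 min and decay; the Model group has a higher peak and a
#' slower decay. ITT curves (grid 0, 15, 30, 45, 60 min) decay from the
#' baseline, less so for the insulin-resistant Model group. Per-subject FBG
#' (also the curve baseline) and fasting insulin are always included.
#'
#' @param groups group labels; Control, Model, Treated and Met have defined
#'   physiologic profiles, any other label uses the Treated profile.
#' @param nPerGroup subjects per group (0 gives an empty panel).
#' @param curveKind one or more of "OGTT", "ITT".
#' @param seed integer seed.
#' @return a \linkS4class{SubjectPanel}.
#' @export
genGlucosePanel <- function(groups = c("Control", "Model", "Treated", "Met"),
                            nPerGroup = 6, curveKind = "OGTT", seed = 1) {
  nPerGroup <- .checkCount(nPerGroup, "nPerGroup", min = 0)
  bad <- setdiff(curveKind, c("OGTT", "ITT"))
  if (length(bad)) stop("unknown curve kind: ", paste(bad, collapse = ", "))
  .withSeed(seed, {
    subs <- data.frame(subject = character(), group = character(),
                       fbg = numeric(), insulin = numeric(),
                       stringsAsFactors = FALSE)
    cvs <- data.frame(subject = character(), kind = character(),
                      time = numeric(), glucose = numeric(),
                      stringsAsFactors = FALSE)
    for (g in groups) {
      pf <- .glucoseProfiles[[g]]
      if (is.null(pf)) pf <- .glucoseProfiles$Treated
      for (i in seq_len(nPerGroup)) {
        id <- paste0(g, "_", i)
        fbg <- max(rnorm(1, pf$fbg[1], pf$fbg[2]), 3.8)
        ins <- max(rnorm(1, pf$ins[1], pf$ins[2]), 0.5)
        subs <- rbind(subs, data.frame(subject = id, group = g, fbg = fbg,
                                       insulin = ins, stringsAsFactors = FALSE))
        if ("OGTT" %in% curveKind) {
          tt <- seq(0, 180, by = 30)
          gl <- fbg + pf$amp * (tt / 30) * exp((30 - tt) / pf$tau) +
            rnorm(length(tt), 0, 0.3)
          gl[1] <- fbg
          cvs <- rbind(cvs, data.frame(subject = id, kind = "OGTT", time = tt,
                                       glucose = pmax(gl, 0.1),
                                       stringsAsFactors = FALSE))
        }
        if ("ITT" %in% curveKind) {
          tt <- c(0, 15, 30, 45, 60)
          r <- pf$itt
          gl <- fbg * (r + (1 - r) * exp(-tt / 25)) + rnorm(length(tt), 0, 0.3)
          gl[1] <- fbg
          cvs <- rbind(cvs, data.frame(subject = id, kind = "ITT", time = tt,
                                       glucose = pmax(gl, 0.1),
                                       stringsAsFactors = FALSE))
        }
      }
    }
    new("SubjectPanel", subjects = subs, curves = cvs)
  })
}

#' Simulate a toy compound-target network
#'
#' Generates a compound-target edge list and a disease gene set with exactly
#' \code{overlap} targets shared between the two; when at least one target
#' lies outside the disease set (and there are >= 2 compounds), the last
#' compound is wired only to non-disease targets so the downstream
#' degree-greater-than-zero filter has something to remove.
#'
#' @param nCompounds,nTargets,nDiseaseGenes sizes.
#' @param overlap number of targets also in the disease set
#'   (<= min(nTargets, nDiseaseGenes)).
#' @param seed integer seed.
#' @return list(edges = data.frame(compound, target),
#'   diseaseGenes = character, compounds = character, targets = character).
#' @export
genToyNetwork <- function(nCompounds = 5, nTargets = 20, nDiseaseGenes = 10,
                          overlap = 6, seed = 1) {
  nCompounds <- .checkCount(nCompounds, "nCompounds")
  nTargets <- .checkCount(nTargets, "nTargets")
  nDiseaseGenes <- .checkCount(nDiseaseGenes, "nDiseaseGenes")
  overlap <- .checkCount(overlap, "overlap", min = 0)
  if (overlap > nTargets || overlap > nDiseaseGenes)
    stop("overlap must be <= nTargets and <= nDiseaseGenes")
  .withSeed(seed, {
    compounds <- sprintf("CMP%02d", seq_len(nCompounds))
    targets <- sprintf("T%03d", seq_len(nTargets))
    diseaseOnly <- sprintf("G%03d", seq_len(nDiseaseGenes - overlap))
    diseaseGenes <- c(targets[seq_len(overlap)], diseaseOnly)
    nonDisease <- setdiff(targets, diseaseGenes)
    # every target gets at least one compound, so the edge list covers all
    # targets and the edge/disease intersection is exactly `overlap`
    eligible <- if (nCompounds >= 2 && length(nonDisease))
      compounds[-nCompounds] else compounds
    edges <- do.call(rbind, lapply(targets, function(tg) {
      pool <- if (tg %in% nonDisease) compounds else eligible
      k <- sample(seq_len(min(3, length(pool))), 1)
      data.frame(compound = sample(pool, k), target = tg,
                 stringsAsFactors = FALSE)
    }))
    # guarantee the filtered-out compound exists when feasible
    if (nCompounds >= 2 && length(nonDisease)) {
      last <- compounds[nCompounds]
      if (!last %in% edges$compound)
        edges <- rbind(edges, data.frame(compound = last,
                                         target = sample(nonDisease, 1),
                                         stringsAsFactors = FALSE))
    }
    edges <- edges[order(edges$compound, edges$target), ]
    rownames(edges) <- NULL
    list(edges = edges, diseaseGenes = diseaseGenes,
         compounds = compounds, targets = targets)
  })
}
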