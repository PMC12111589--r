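#' Pipeline configuration
#'
#' Defaults are the screening constants used throughout the analysis:
#' distinguishing coefficient xi = 0.1, relevancy threshold 0.85 (strict),
#' candidate degree > 0, VIP >= 1, p <= 0.05, fold change > 2 (two-sided),
#' |p(corr)| > 0.6, annotation tolerance 10 ppm, 7-fold cross-validation.
#' Any value differing from its default is echoed as an override in the run
#' log. Unknown keys are errors.
#'
#' @param seed top-level seed; every stage derives its own seed from it.
#' @param xi,normalization,graThreshold gray relational analysis settings.
#' @param vipMin,pMax,fcMin,pcorrMin metabolite screening thresholds.
#' @param tolPpm annotation tolerance (ppm).
#' @param folds,nOrthogonal OPLS-DA cross-validation settings.
#' @param ... rejected; catches misspelled keys.
#' @return a named list of class \code{specEffectConfig}.
#' @export
pipelineConfig <- function(seed = 1, xi = 0.1, normalization = "mean",
                           graThreshold = 0.85, vipMin = 1, pMax = 0.05,
                           fcMin = 2, pcorrMin = 0.6, tolPpm = 10,
                           folds = 7, nOrthogonal = 1, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(names(extra), collapse = ", "))
  cfg <- list(seed = as.integer(seed), xi = xi, normalization = normalization,
              graThreshold = graThreshold, vipMin = vipMin, pMax = pMax,
              fcMin = fcMin, pcorrMin = pcorrMin, tolPpm = tolPpm,
              folds = folds, nOrthogonal = nOrthogonal)
  defaults <- list(xi = 0.1, normalization = "mean", graThreshold = 0.85,
                   vipMin = 1, pMax = 0.05, fcMin = 2, pcorrMin = 0.6,
                   tolPpm = 10, folds = 7, nOrthogonal = 1)
  cfg$overridden <- names(defaults)[!vapply(names(defaults), function(k)
    isTRUE(all.equal(cfg[[k]], defaults[[k]])), logical(1))]
  class(cfg) <- "specEffectConfig"
  cfg
}

.thresholdLog <- function(cfg) {
  keys <- c("xi", "normalization", "graThreshold", "vipMin", "pMax", "fcMin",
            "pcorrMin", "tolPpm", "folds", "nOrthogonal")
  vapply(keys, function(k)
    sprintf("threshold %s = %s (%s)", k, format(cfg[[k]]),
            if (k %in% cfg$overridden) "override" else "default"),
    character(1))
}

# deterministic synthetic pathway sets over the feature universe: one set
# enriched for the planted shared features, the rest random
.synthPathways <- function(featureIds, sharedIds, seed) {
  .withSeed(seed, {
    hit <- unique(c(sample(sharedIds, min(12, length(sharedIds))),
                    sample(setdiff(featureIds, sharedIds), 8)))
    pw <- list(disease_response = sort(hit))
    for (i in 1:4)
      pw[[paste0("random_set_", i)]] <- sort(sample(featureIds, 20))
    pw
  })
}

#' Run the full screening pipeline
#'
#' Reproduces the analysis order of the study design: network-topology
#' candidate filtering (degree > 0), gray relational spectrum-effect
#' selection (relevancy > threshold), pharmacodynamic group summaries
#' (HOMA indices, OGTT/ITT AUC), and the two pairwise metabolomics screens
#' with Venn intersection and pathway over-representation. Any input not
#' supplied in \code{inputs} is synthesized from the configuration seed
#' (simulate-first mode), so a bare \code{runPipeline(pipelineConfig())} is
#' a complete, deterministic end-to-end run.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param inputs optional named list overriding synthetic inputs: peaks,
#'   effects, features (a \linkS4class{MetabFeatureSet}), panel
#'   (a \linkS4class{SubjectPanel}), compoundTargets, diseaseGenes,
#'   pathways.
#' @return list of class \code{specEffectReport} with per-stage results, a
#'   \code{summary} list and the threshold \code{log}.
#' @export
runPipeline <- function(config = pipelineConfig(), inputs = list()) {
  cfg <- config
  log <- .thresholdLog(cfg)
  truths <- list()

  # 1. network-topology candidate filter
  if (is.null(inputs$compoundTargets)) {
    net <- genToyNetwork(nCompounds = 8, nTargets = 40, nDiseaseGenes = 25,
                         overlap = 15, seed = cfg$seed + 101L)
    compoundTargets <- split(net$edges$target, net$edges$compound)
    diseaseGenes <- net$diseaseGenes
  } else {
    compoundTargets <- inputs$compoundTargets
    diseaseGenes <- inputs$diseaseGenes
  }
  netRes <- networkScreen(compoundTargets, diseaseGenes)
  log <- c(log, sprintf("network: %d/%d compounds pass degree > 0",
                        nrow(netRes$candidates), length(compoundTargets)))

  # 2. gray relational spectrum-effect selection
  if (is.null(inputs$peaks)) {
    se <- genSpectrumEffect(seed = cfg$seed + 202L)
    peaks <- se$peaks; effects <- se$effects
    truths$spectrum <- se$truth
  } else {
    peaks <- inputs$peaks; effects <- inputs$effects
  }
  gra <- spectrumEffectGRA(peaks, effects, xi = cfg$xi,
                           normalization = cfg$normalization,
                           threshold = cfg$graThreshold)
  log <- c(log, sprintf("gra: %d components with relevancy > %s",
                        length(selectedComponents(gra)),
                        format(cfg$graThreshold)))

  # 3. pharmacodynamic indices
  panel <- if (is.null(inputs$panel))
    genGlucosePanel(curveKind = c("OGTT", "ITT"), seed = cfg$seed + 303L)
  else inputs$panel
  pharm <- list(
    HOMA_IR = groupSummary(panel, "HOMA_IR"),
    AUC_OGTT = groupSummary(panel, "AUC_OGTT"),
    AUC_ITT = groupSummary(panel, "AUC_ITT"))

  # 4. metabolomics screening cascade
  if (is.null(inputs$features)) {
    met <- genMetabolomicsTable(seed = cfg$seed + 404L)
    features <- met$features
    truths$metabolomics <- met$truth
  } else features <- inputs$features
  scr1 <- screenContrast(features, "Model", "Control",
                         nOrthogonal = cfg$nOrthogonal, folds = cfg$folds,
                         seed = cfg$seed + 505L, vip_min = cfg$vipMin,
                         p_max = cfg$pMax, fc_min = cfg$fcMin,
                         pcorr_min = cfg$pcorrMin)
  scr2 <- screenContrast(features, "Treated", "Model",
                         nOrthogonal = cfg$nOrthogonal, folds = cfg$folds,
                         seed = cfg$seed + 506L, vip_min = cfg$vipMin,
                         p_max = cfg$pMax, fc_min = cfg$fcMin,
                         pcorr_min = cfg$pcorrMin)
  venn <- vennShared(scr1, scr2)
  log <- c(log, sprintf("screen: %d + %d differential features, %d shared",
                        length(selectedFeatures(scr1)),
                        length(selectedFeatures(scr2)), length(venn$shared)))

  background <- rownames(intensities(features))
  pathways <- if (is.null(inputs$pathways))
    .synthPathways(background,
                   if (length(venn$shared)) venn$shared else background,
                   cfg$seed + 606L)
  else inputs$pathways
  ora <- oraEnrich(venn$shared, pathways, background)

  report <- list(
    config = cfg,
    network = netRes,
    gra = gra,
    pharmacodynamics = pharm,
    screen1 = scr1, screen2 = scr2,
    venn = venn,
    ora = ora,
    truths = truths,
    log = log,
    summary = list(
      seed = cfg$seed,
      candidates_degree_gt0 = netRes$candidates$node,
      selected_components = selectedComponents(gra),
      relevancy = round(sort(relevancy(gra), decreasing = TRUE), 6),
      differential_contrast1 = selectedFeatures(scr1),
      differential_contrast2 = selectedFeatures(scr2),
      shared_metabolites = venn$shared,
      ora_top = ora[1, c("pathway", "expected", "raw_p", "neg_log_p")]
    )
  )
  class(report) <- "specEffectReport"
  report
}

#' Write a pipeline report bundle
#'
#' Emits per-stage TSVs, the JSON summary and the threshold log under
#' \code{dir}. The JSON is written deterministically, so identical
#' configurations give byte-identical summaries.
#'
#' @param report a \code{specEffectReport} from \code{\link{runPipeline}}.
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
writeReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(
    relevancy = file.path(dir, "gra_relevancy.tsv"),
    candidates = file.path(dir, "network_candidates.tsv"),
    screen1 = file.path(dir, "screen_contrast1.tsv"),
    screen2 = file.path(dir, "screen_contrast2.tsv"),
    ora = file.path(dir, "ora.tsv"),
    summary = file.path(dir, "summary.json"),
    log = file.path(dir, "log.txt"))
  rel <- relevancy(report$gra)
  writeTsv(data.frame(component = names(rel), relevancy = rel,
                      selected = names(rel) %in% selectedComponents(report$gra)),
           files["relevancy"])
  writeTsv(report$network$candidates, files["candidates"])
  writeTsv(screenTable(report$screen1), files["screen1"])
  writeTsv(screenTable(report$screen2), files["screen2"])
  writeTsv(report$ora, files["ora"])
  json <- jsonlite::toJSON(report$summary, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", pretty = TRUE)
  writeLines(json, files["summary"])
  writeLines(report$log, files["log"])
  invisible(files)
}
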