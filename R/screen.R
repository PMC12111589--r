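#' Univariate volcano statistics
#'
#' Fold change is the ratio of raw group-mean intensities (case over
#' reference); the p-value comes from a two-sided Welch t-test on
#' log-transformed intensities (zeros get a pseudo-count of 1).
#'
#' @param object a \linkS4class{MetabFeatureSet} with raw intensities.
#' @param case,reference group labels of the two contrasted groups (>= 2
#'   samples each).
#' @return data.frame(feature, fold_change, p_value); the fold change is NA
#'   when the reference mean is zero.
#' @export
univariateStats <- function(object, case, reference) {
  g <- sampleGroups(object)
  ic <- which(g == case)
  ir <- which(g == reference)
  if (length(ic) < 2 || length(ir) < 2)
    stop("both groups need >= 2 samples")
  x <- intensities(object)
  mc <- rowMeans(x[, ic, drop = FALSE])
  mr <- rowMeans(x[, ir, drop = FALSE])
  fc <- ifelse(mr == 0, NA_real_, mc / mr)
  lx <- x
  lx[lx == 0] <- 1
  lx <- log(lx)
  p <- vapply(seq_len(nrow(x)), function(i) {
    a <- lx[i, ic]; b <- lx[i, ir]
    if (sd(a) == 0 && sd(b) == 0)
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    t.test(a, b)$p.value
  }, numeric(1))
  data.frame(feature = rownames(x), fold_change = fc, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Four-criterion differential screen
#'
#' A feature is selected when all four hold: VIP >= 1 (inclusive),
#' p <= 0.05 (inclusive), fold change > 2 or < 1/2 (strict, two-sided) and
#' |p(corr)| > 0.6 (strict). Boundary semantics follow the screening
#' phrasing exactly: a VIP of exactly 1 passes, a fold change of exactly 2
#' does not.
#'
#' @param records data.frame with columns feature, vip, p_value,
#'   fold_change, p_corr. Rows with NA statistics never pass.
#' @param vip_min,p_max,fc_min,pcorr_min the four thresholds
#'   (defaults 1, 0.05, 2, 0.6).
#' @return data.frame: the input plus pass flags (pass_vip, pass_p, pass_fc,
#'   pass_pcorr), regulated ("up"/"down"), and selected (logical).
#' @export
screenDifferential <- function(records, vip_min = 1, p_max = 0.05,
                               fc_min = 2, pcorr_min = 0.6) {
  need <- c("feature", "vip", "p_value", "fold_change", "p_corr")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing column(s): ", paste(miss, collapse = ", "))
  r <- records
  r$pass_vip <- !is.na(r$vip) & r$vip >= vip_min
  r$pass_p <- !is.na(r$p_value) & r$p_value <= p_max
  r$pass_fc <- !is.na(r$fold_change) &
    (r$fold_change > fc_min | r$fold_change < 1 / fc_min)
  r$pass_pcorr <- !is.na(r$p_corr) & abs(r$p_corr) > pcorr_min
  r$regulated <- ifelse(is.na(r$fold_change), NA_character_,
                        ifelse(r$fold_change > 1, "up", "down"))
  r$selected <- r$pass_vip & r$pass_p & r$pass_fc & r$pass_pcorr
  r
}

#' Run one pairwise metabolomics contrast end to end
#'
#' Subsets the feature table to the two groups, computes univariate volcano
#' statistics on the raw intensities, fits an OPLS-DA model on the
#' log-transformed autoscaled data, derives VIP and p(corr), cross-validates
#' Q2, and applies the four-criterion screen.
#'
#' @param object a \linkS4class{MetabFeatureSet} with raw intensities.
#' @param case,reference the contrasted group labels.
#' @param nOrthogonal orthogonal components for the OPLS-DA fit (default 1).
#' @param folds,seed Q2 cross-validation settings.
#' @param vip_min,p_max,fc_min,pcorr_min screening thresholds.
#' @param scaling feature scaling for the multivariate model.
#' @return a \linkS4class{DifferentialScreen}.
#' @export
screenContrast <- function(object, case, reference, nOrthogonal = 1,
                           folds = 7, seed = 1,
                           vip_min = 1, p_max = 0.05, fc_min = 2,
                           pcorr_min = 0.6, scaling = "autoscale") {
  g <- sampleGroups(object)
  sub <- object[, g %in% c(case, reference)]
  uni <- univariateStats(sub, case, reference)
  pre <- suppressWarnings(
    preprocessFeatures(sub, logTransform = TRUE, scaling = scaling))
  X <- .modelMatrix(pre)
  y <- sampleGroups(pre)
  model <- oplsdaFit(X, y, nOrthogonal = nOrthogonal)
  vip <- vipScores(model)
  pc <- suppressWarnings(pcorrScores(model, X))
  qq <- q2CrossVal(X, y, ncomp = 1, folds = folds, seed = seed,
                   nOrthogonal = nOrthogonal)
  tab <- data.frame(feature = uni$feature,
                    vip = vip[uni$feature],
                    p_value = uni$p_value,
                    fold_change = uni$fold_change,
                    p_corr = pc[uni$feature],
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- screenDifferential(tab, vip_min = vip_min, p_max = p_max,
                            fc_min = fc_min, pcorr_min = pcorr_min)
  new("DifferentialScreen", table = tab,
      selected = tab$feature[tab$selected],
      thresholds = list(vip_min = vip_min, p_max = p_max, fc_min = fc_min,
                        pcorr_min = pcorr_min),
      contrast = paste(case, "vs", reference),
      model = model, R2Y = model@R2Y, Q2 = qq)
}

#' Venn intersection of two differential sets
#'
#' @param setA,setB character vectors of feature ids (or
#'   \linkS4class{DifferentialScreen} objects).
#' @return list with \code{shared}, \code{onlyA}, \code{onlyB} and a named
#'   \code{counts} vector (A_only, B_only, shared).
#' @export
vennShared <- function(setA, setB) {
  if (is(setA, "DifferentialScreen")) setA <- selectedFeatures(setA)
  if (is(setB, "DifferentialScreen")) setB <- selectedFeatures(setB)
  setA <- unique(setA); setB <- unique(setB)
  shared <- sort(intersect(setA, setB))
  onlyA <- sort(setdiff(setA, setB))
  onlyB <- sort(setdiff(setB, setA))
  list(shared = shared, onlyA = onlyA, onlyB = onlyB,
       counts = c(A_only = length(onlyA), B_only = length(onlyB),
                  shared = length(shared)))
}

#' Hypergeometric pathway over-representation analysis
#'
#' For a selected set of size q from a background of size N, a pathway with
#' m background members and k hits has expected hits \eqn{q m / N} and raw
#' p-value \eqn{P(X \ge k)} under the hypergeometric null. Records are
#' sorted by raw p ascending; \code{neg_log_p} is \eqn{-\log_{10} p}.
#'
#' @param selected character vector of selected ids (must lie in the
#'   background).
#' @param pathways named list, pathway name -> member ids (intersected with
#'   the background before testing).
#' @param background character vector of all testable ids.
#' @param adjust apply Benjamini-Hochberg correction in an extra column
#'   (default FALSE; the raw p is what the screen uses).
#' @return data.frame(pathway, m, hits, expected, raw_p, neg_log_p\[, fdr\]).
#' @export
oraEnrich <- function(selected, pathways, background, adjust = FALSE) {
  background <- unique(background)
  if (!length(background)) stop("background must be non-empty")
  selected <- unique(selected)
  out <- setdiff(selected, background)
  if (length(out))
    stop("selected ids outside the background: ", paste(out, collapse = ", "))
  N <- length(background)
  q <- length(selected)
  rows <- lapply(names(pathways), function(nm) {
    mem <- intersect(unique(pathways[[nm]]), background)
    m <- length(mem)
    k <- length(intersect(mem, selected))
    rawp <- if (k == 0) 1 else phyper(k - 1, m, N - m, q, lower.tail = FALSE)
    data.frame(pathway = nm, m = m, hits = k, expected = q * m / N,
               raw_p = rawp, neg_log_p = -log10(rawp),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$raw_p, res$pathway), , drop = FALSE]
  if (adjust) res$fdr <- stats::p.adjust(res$raw_p, method = "BH")
  rownames(res) <- NULL
  res
}
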