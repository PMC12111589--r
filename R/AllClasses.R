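#' @import methods
#' @importFrom stats cor sd var rnorm runif phyper t.test setNames qnorm
#' @importFrom utils read.table write.table head
NULL

#' Ground truth planted by the synthetic generators
#'
#' Records which components/features were generated as truly "active" or
#' differential, so recovery by the screening stages can be scored.
#'
#' @slot activeComponents ids of components whose peak responses track the
#'   latent disease-severity variable.
#' @slot diffContrast1 ids of features planted as differential in the
#'   Control-vs-Model contrast.
#' @slot diffContrast2 ids of features planted as differential in the
#'   Model-vs-Treated contrast.
#' @slot sharedDiff intersection of the two planted sets.
#' @slot seed integer seed the generator was called with.
#' @export
setClass("SyntheticTruth",
  representation(
    activeComponents = "character",
    diffContrast1 = "character",
    diffContrast2 = "character",
    sharedDiff = "character",
    seed = "integer"
  ),
  prototype(
    activeComponents = character(), diffContrast1 = character(),
    diffContrast2 = character(), sharedDiff = character(), seed = NA_integer_
  )
)

setValidity("SyntheticTruth", function(object) {
  shared <- sort(intersect(object@diffContrast1, object@diffContrast2))
  if (!identical(sort(object@sharedDiff), shared))
    return("sharedDiff must equal the intersection of the two contrast sets")
  TRUE
})

#' Gray relational analysis result
#'
#' Holds the full coefficient tensor (indicator x component x sample), the
#' gray relational grade (GRG) matrix, the per-component mean relevancy and
#' the components selected above the threshold.
#'
#' @slot coefficients 3-d array indicator x component x sample of gray
#'   relational coefficients, each in (0, 1].
#' @slot grades indicator x component matrix of GRG values (mean coefficient
#'   over samples).
#' @slot relevancy named numeric, per-component mean GRG over indicators.
#' @slot selected component ids with relevancy strictly above the threshold,
#'   ordered by relevancy descending (ties by id).
#' @slot params list of the parameters used (xi, normalization, scope,
#'   threshold).
#' @export
setClass("GraResult",
  representation(
    coefficients = "array",
    grades = "matrix",
    relevancy = "numeric",
    selected = "character",
    params = "list"
  )
)

setValidity("GraResult", function(object) {
  co <- object@coefficients
  if (length(co) && (min(co) <= 0 || max(co) > 1 + 1e-12))
    return("coefficients must lie in (0, 1]")
  if (!identical(dim(object@grades), dim(co)[1:2]))
    return("grades dimensions must match coefficients")
  TRUE
})

#' Latent-variable model (PCA / PLS-DA / OPLS-DA)
#'
#' @slot kind one of "PCA", "PLSDA", "OPLSDA".
#' @slot scores sample x component matrix of predictive scores.
#' @slot loadings feature x component loading matrix.
#' @slot weights feature x component PLS weight matrix (empty for PCA).
#' @slot orthoScores,orthoLoadings orthogonal-component scores/loadings
#'   (OPLS-DA only; zero columns otherwise).
#' @slot R2X per-component fraction of X variance explained.
#' @slot R2Y in-sample explained response variance (NA for PCA).
#' @slot Q2 cross-validated predictive ability (NA until computed).
#' @slot ssy per-component response sum of squares explained (used by VIP).
#' @slot yLoadings response loading matrix (components x response columns).
#' @slot classes class labels in encoding order (discriminant models).
#' @slot center,scale per-feature centering/scaling applied at fit time.
#' @export
setClass("LatentModel",
  representation(
    kind = "character",
    scores = "matrix",
    loadings = "matrix",
    weights = "matrix",
    orthoScores = "matrix",
    orthoLoadings = "matrix",
    R2X = "numeric",
    R2Y = "numeric",
    Q2 = "numeric",
    ssy = "numeric",
    yLoadings = "matrix",
    classes = "character",
    center = "numeric",
    scale = "numeric"
  ),
  prototype(R2Y = NA_real_, Q2 = NA_real_)
)

setValidity("LatentModel", function(object) {
  if (!object@kind %in% c("PCA", "PLSDA", "OPLSDA"))
    return("kind must be PCA, PLSDA or OPLSDA")
  if (!is.na(object@R2Y) && object@R2Y > 1 + 1e-9) return("R2Y must be <= 1")
  if (!is.na(object@Q2) && object@Q2 > 1 + 1e-9) return("Q2 must be <= 1")
  TRUE
})

#' Per-animal pharmacodynamic panel
#'
#' Fasting blood glucose (FBG, mmol/L), fasting insulin (mIU/L) and glucose
#' time-courses (OGTT/ITT) per subject, with group labels.
#'
#' @slot subjects data.frame with columns subject, group, fbg, insulin.
#' @slot curves data.frame with columns subject, kind, time, glucose
#'   (long format; time in minutes, glucose in mmol/L).
#' @export
setClass("SubjectPanel",
  representation(subjects = "data.frame", curves = "data.frame")
)

setValidity("SubjectPanel", function(object) {
  s <- object@subjects
  need <- c("subject", "group", "fbg", "insulin")
  if (!all(need %in% names(s)))
    return(paste("subjects needs columns:", paste(need, collapse = ", ")))
  if (nrow(s) && any(!is.finite(s$fbg) | s$fbg <= 0))
    return("FBG must be finite and positive")
  cv <- object@curves
  needc <- c("subject", "kind", "time", "glucose")
  if (!all(needc %in% names(cv)))
    return(paste("curves needs columns:", paste(needc, collapse = ", ")))
  if (nrow(cv)) {
    if (any(cv$glucose < 0)) return("glucose values must be >= 0")
    bad <- vapply(split(cv, list(cv$subject, cv$kind), drop = TRUE),
      function(d) {
        tt <- d$time[order(d$time)]
        !(identical(tt, d$time) && d$time[1] == 0 && all(diff(d$time) > 0))
      }, logical(1))
    if (any(bad))
      return("each curve's times must start at 0 and be strictly increasing")
  }
  TRUE
})

#' Differential-metabolite screening result
#'
#' Per-feature statistics (VIP, p, fold change, p(corr)), the boolean pass
#' flag per criterion and the selected set under the four-criterion cascade.
#'
#' @slot table data.frame with one row per feature: feature, vip, p_value,
#'   fold_change, p_corr, pass flags, regulated direction, selected.
#' @slot selected ids of features passing all four criteria.
#' @slot thresholds list(vip_min, p_max, fc_min, pcorr_min).
#' @slot contrast character "case vs reference".
#' @slot model fitted OPLS-DA \linkS4class{LatentModel}.
#' @slot R2Y,Q2 model quality statistics.
#' @export
setClass("DifferentialScreen",
  representation(
    table = "data.frame",
    selected = "character",
    thresholds = "list",
    contrast = "character",
    model = "LatentModel",
    R2Y = "numeric",
    Q2 = "numeric"
  )
)

#' Metabolite feature table
#'
#' A \linkS4class{SummarizedExperiment} of feature x sample intensities with
#' a mandatory per-sample group label and optional per-feature m/z and
#' retention time.
#'
#' @export
setClass("MetabFeatureSet", contains = "SummarizedExperiment")

setValidity("MetabFeatureSet", function(object) {
  if (!"group" %in% names(SummarizedExperiment::colData(object)))
    return("colData must contain a 'group' column")
  g <- SummarizedExperiment::colData(object)$group
  if (any(is.na(g)) || any(!nzchar(g)))
    return("group labels must be present for every sample")
  a <- SummarizedExperiment::assay(object)
  if (!is.numeric(a)) return("intensity assay must be numeric")
  if (any(!is.finite(a))) return("intensities must be finite")
  TRUE
})
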