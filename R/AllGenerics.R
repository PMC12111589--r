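#' @rdname GraResult-class
#' @param object,x a \linkS4class{GraResult}
#' @export
setGeneric("relevancy", function(object) standardGeneric("relevancy"))

#' @rdname GraResult-class
#' @export
setGeneric("grades", function(object) standardGeneric("grades"))

#' @rdname GraResult-class
#' @export
setGeneric("graCoefficients", function(object) standardGeneric("graCoefficients"))

#' @rdname GraResult-class
#' @export
setGeneric("selectedComponents", function(object) standardGeneric("selectedComponents"))

#' @rdname DifferentialScreen-class
#' @export
setGeneric("selectedFeatures", function(object) standardGeneric("selectedFeatures"))

#' @rdname DifferentialScreen-class
#' @export
setGeneric("screenTable", function(object) standardGeneric("screenTable"))

#' @rdname LatentModel-class
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))

#' @rdname LatentModel-class
#' @export
setGeneric("loadings2", function(object) standardGeneric("loadings2"))

#' @rdname LatentModel-class
#' @export
setGeneric("r2y", function(object) standardGeneric("r2y"))

#' @rdname LatentModel-class
#' @export
setGeneric("q2", function(object) standardGeneric("q2"))

#' @rdname MetabFeatureSet
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))

#' @rdname SubjectPanel-class
#' @export
setGeneric("subjects", function(object) standardGeneric("subjects"))

#' @rdname SubjectPanel-class
#' @export
setGeneric("curves", function(object) standardGeneric("curves"))

# -- accessors -----------------------------------------------------------

#' @rdname GraResult-class
setMethod("relevancy", "GraResult", function(object) object@relevancy)

#' @rdname GraResult-class
setMethod("grades", "GraResult", function(object) object@grades)

#' @rdname GraResult-class
setMethod("graCoefficients", "GraResult", function(object) object@coefficients)

#' @rdname GraResult-class
setMethod("selectedComponents", "GraResult", function(object) object@selected)

#' @rdname DifferentialScreen-class
#' @param object a \linkS4class{DifferentialScreen}
setMethod("selectedFeatures", "DifferentialScreen", function(object) object@selected)

#' @rdname DifferentialScreen-class
setMethod("screenTable", "DifferentialScreen", function(object) object@table)

#' @rdname LatentModel-class
#' @param object a \linkS4class{LatentModel}
setMethod("scores", "LatentModel", function(object) object@scores)

#' @rdname LatentModel-class
setMethod("loadings2", "LatentModel", function(object) object@loadings)

#' @rdname LatentModel-class
setMethod("r2y", "LatentModel", function(object) object@R2Y)

#' @rdname LatentModel-class
setMethod("q2", "LatentModel", function(object) object@Q2)

#' @rdname DifferentialScreen-class
setMethod("r2y", "DifferentialScreen", function(object) object@R2Y)

#' @rdname DifferentialScreen-class
setMethod("q2", "DifferentialScreen", function(object) object@Q2)

#' @rdname MetabFeatureSet
#' @param object a \linkS4class{MetabFeatureSet}
setMethod("sampleGroups", "MetabFeatureSet", function(object)
  as.character(SummarizedExperiment::colData(object)$group))

#' @rdname SubjectPanel-class
#' @param object a \linkS4class{SubjectPanel}
setMethod("subjects", "SubjectPanel", function(object) object@subjects)

#' @rdname SubjectPanel-class
setMethod("curves", "SubjectPanel", function(object) object@curves)

# -- show methods --------------------------------------------------------

setMethod("show", "GraResult", function(object) {
  cat("GraResult:", ncol(object@grades), "components x",
      nrow(object@grades), "indicators\n")
  cat("  xi =", object@params$xi, "| normalization =",
      object@params$normalization, "| threshold =", object@params$threshold, "\n")
  top <- sort(object@relevancy, decreasing = TRUE)
  cat("  top relevancy:\n")
  print(round(head(top, 5), 4))
  cat("  selected (", length(object@selected), "):",
      paste(object@selected, collapse = ", "), "\n")
})

setMethod("show", "LatentModel", function(object) {
  cat(object@kind, "model:", nrow(object@scores), "samples,",
      nrow(object@loadings), "features,", ncol(object@scores),
      "predictive component(s)")
  if (ncol(object@orthoScores)) cat(",", ncol(object@orthoScores), "orthogonal")
  cat("\n")
  if (length(object@R2X))
    cat("  R2X:", paste(round(object@R2X, 3), collapse = " "), "\n")
  if (!is.na(object@R2Y)) cat("  R2Y:", round(object@R2Y, 4), "\n")
  if (!is.na(object@Q2)) cat("  Q2: ", round(object@Q2, 4), "\n")
})

setMethod("show", "DifferentialScreen", function(object) {
  cat("DifferentialScreen [", object@contrast, "]:",
      nrow(object@table), "features,", length(object@selected), "selected\n")
  cat("  thresholds: VIP >=", object@thresholds$vip_min,
      "| p <=", object@thresholds$p_max,
      "| FC >", object@thresholds$fc_min,
      "| |p(corr)| >", object@thresholds$pcorr_min, "\n")
  if (!is.na(object@R2Y))
    cat("  R2Y =", round(object@R2Y, 4), " Q2 =", round(object@Q2, 4), "\n")
})

setMethod("show", "SubjectPanel", function(object) {
  cat("SubjectPanel:", nrow(object@subjects), "subjects in",
      length(unique(object@subjects$group)), "group(s)\n")
  if (nrow(object@curves))
    cat("  curves:", paste(unique(object@curves$kind), collapse = ", "), "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth (seed", object@seed, "):",
      length(object@activeComponents), "active components;",
      length(object@diffContrast1), "/", length(object@diffContrast2),
      "differential features (", length(object@sharedDiff), "shared )\n")
})
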