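#' Construct a metabolite feature table
#'
#' @param intensity feature x sample numeric matrix, non-negative, with
#'   feature rownames and sample colnames.
#' @param groups character vector of group labels, one per sample (or named
#'   by sample id).
#' @param mz,rt optional per-feature m/z and retention time.
#' @return a \linkS4class{MetabFeatureSet}.
#' @rdname MetabFeatureSet
#' @export
MetabFeatureSet <- function(intensity, groups, mz = NULL, rt = NULL) {
  intensity <- as.matrix(intensity)
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (is.null(rownames(intensity)))
    rownames(intensity) <- paste0("F", seq_len(nrow(intensity)))
  if (is.null(colnames(intensity)))
    colnames(intensity) <- paste0("S", seq_len(ncol(intensity)))
  if (!is.null(names(groups))) groups <- groups[colnames(intensity)]
  if (length(groups) != ncol(intensity))
    stop("need one group label per sample")
  rd <- S4Vectors::DataFrame(row.names = rownames(intensity))
  if (!is.null(mz)) rd$mz <- mz
  if (!is.null(rt)) rd$rt <- rt
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = rd,
    colData = S4Vectors::DataFrame(group = as.character(groups),
                                   row.names = colnames(intensity)))
  new("MetabFeatureSet", se)
}

#' Intensity matrix of a feature table
#'
#' @param object a \linkS4class{MetabFeatureSet}.
#' @return feature x sample numeric matrix.
#' @rdname MetabFeatureSet
#' @export
intensities <- function(object) SummarizedExperiment::assay(object)

#' Pre-treat a feature table for multivariate modelling
#'
#' Optionally log-transforms (natural log; zeros get a pseudo-count of 1 so
#' they map to 0) and scales each feature. Zero-variance features carry no
#' discriminant information and are dropped with a warning.
#'
#' @param object a \linkS4class{MetabFeatureSet}.
#' @param logTransform logical, apply the log transform first.
#' @param scaling per-feature scaling: \code{"autoscale"} (unit variance),
#'   \code{"pareto"} (divide by sqrt sd), \code{"center"} (mean only) or
#'   \code{"none"}.
#' @return a new \linkS4class{MetabFeatureSet}; the applied steps are noted
#'   in \code{metadata()}.
#' @export
preprocessFeatures <- function(object, logTransform = TRUE,
                               scaling = c("autoscale", "pareto", "center", "none")) {
  scaling <- match.arg(scaling)
  x <- SummarizedExperiment::assay(object)
  v <- apply(x, 1, var)
  drop <- v == 0
  if (all(drop)) stop("all features have zero variance")
  if (any(drop)) {
    warning("dropping ", sum(drop), " zero-variance feature(s)")
    x <- x[!drop, , drop = FALSE]
  }
  if (logTransform) {
    x[x == 0] <- 1
    x <- log(x)
  }
  m <- rowMeans(x)
  s <- apply(x, 1, sd)
  x <- switch(scaling,
    none = x,
    center = x - m,
    autoscale = (x - m) / s,
    pareto = (x - m) / sqrt(s))
  out <- object[!drop, ]
  SummarizedExperiment::assay(out) <- x
  S4Vectors::metadata(out)$preprocess <-
    list(logTransform = logTransform, scaling = scaling,
         dropped = sum(drop))
  out
}

# samples x features orientation used by the latent models
.modelMatrix <- function(object) t(SummarizedExperiment::assay(object))
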