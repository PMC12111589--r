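#' Normalize sequences for gray relational analysis
#'
#' Sequences mixing peak areas and serum concentrations must be made
#' dimensionless before deviations are compared. Each row of \code{x} is one
#' sequence over the shared sample axis.
#'
#' @param x numeric matrix, one sequence per row (rownames are sequence ids).
#' @param method \code{"mean"} divides each sequence by its own mean (the
#'   classic GRA averaging pre-treatment, the default elsewhere in the
#'   package); \code{"minmax"} maps affinely to \[0, 1\];
#'   \code{"initial"} divides by the first element; \code{"none"} is the
#'   identity.
#' @return matrix of the same shape.
#' @examples
#' normalizeSequences(rbind(a = c(2, 4, 6)), "mean")  # 0.5 1.0 1.5
#' @export
normalizeSequences <- function(x, method = c("mean", "minmax", "initial", "none")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("sequences must be finite numeric")
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  if (method == "none") return(x)
  if (method == "mean") {
    m <- rowMeans(x)
    bad <- which(m == 0)
    if (length(bad))
      stop("degenerate sequence (zero mean): ", paste(ids[bad], collapse = ", "))
    return(x / m)
  }
  if (method == "initial") {
    f <- x[, 1]
    bad <- which(f == 0)
    if (length(bad))
      stop("degenerate sequence (zero first element): ",
           paste(ids[bad], collapse = ", "))
    return(x / f)
  }
  # minmax
  lo <- apply(x, 1, min)
  hi <- apply(x, 1, max)
  bad <- which(hi == lo)
  if (length(bad))
    stop("degenerate sequence (constant, min = max): ",
         paste(ids[bad], collapse = ", "))
  (x - lo) / (hi - lo)
}

#' Gray relational coefficients
#'
#' For a reference sequence \eqn{x_0} and comparison sequences \eqn{x_i},
#' the coefficient at sample \eqn{k} is
#' \deqn{\gamma(x_0(k), x_i(k)) = \frac{\Delta_{min} + \xi\,\Delta_{max}}
#'   {\Delta_i(k) + \xi\,\Delta_{max}}}
#' with \eqn{\Delta_i(k) = |x_0(k) - x_i(k)|} and, under the default global
#' scope, \eqn{\Delta_{min} = \min_i \min_k \Delta_i(k)} and
#' \eqn{\Delta_{max} = \max_i \max_k \Delta_i(k)} taken over all comparison
#' sequences for this reference.
#'
#' @param x0 numeric reference sequence of length n.
#' @param X matrix of comparison sequences, one per row, n columns.
#' @param xi distinguishing coefficient in (0, 1]; default 0.1.
#' @param scope \code{"global"} takes the deviation extrema over all
#'   comparison rows and samples; \code{"per_pair"} restricts them to each
#'   single pair (sensitivity analysis only).
#' @return matrix (rows = comparison sequences) of coefficients in (0, 1].
#'   If every deviation is zero the coefficients are all 1 (the limit of the
#'   formula), not an error.
#' @export
grayCoefficients <- function(x0, X, xi = 0.1, scope = c("global", "per_pair")) {
  scope <- match.arg(scope)
  if (!is.numeric(xi) || length(xi) != 1 || xi <= 0 || xi > 1)
    stop("xi must be a single value in (0, 1]")
  X <- as.matrix(X)
  if (length(x0) != ncol(X))
    stop("x0 and comparison sequences must share length")
  dev <- abs(sweep(X, 2, x0))
  if (scope == "global") {
    dmin <- min(dev)
    dmax <- max(dev)
    if (dmax == 0) {
      out <- dev
      out[] <- 1
      return(out)
    }
    (dmin + xi * dmax) / (dev + xi * dmax)
  } else {
    out <- dev
    for (i in seq_len(nrow(dev))) {
      dmin <- min(dev[i, ])
      dmax <- max(dev[i, ])
      out[i, ] <- if (dmax == 0) 1 else (dmin + xi * dmax) / (dev[i, ] + xi * dmax)
    }
    out
  }
}

#' Gray relational grade
#'
#' The grade (GRG) of a comparison sequence is the arithmetic mean of its
#' gray relational coefficients over the n sample points.
#'
#' @param coefficients numeric vector of per-sample coefficients, or a matrix
#'   with one comparison sequence per row.
#' @return a single grade, or a named vector of per-row grades.
#' @export
grayGrade <- function(coefficients) {
  if (is.matrix(coefficients)) {
    if (ncol(coefficients) == 0) stop("empty coefficient matrix")
    return(rowMeans(coefficients))
  }
  if (length(coefficients) == 0) stop("empty coefficient vector")
  mean(coefficients)
}

#' Spectrum-effect relevancy by gray relational analysis
#'
#' Treats each pharmacodynamic indicator in turn as the primary (reference)
#' sequence and every chromatographic component as a secondary (comparison)
#' sequence, computes the GRG matrix, and averages over indicators to give
#' each component's relevancy. Components whose relevancy strictly exceeds
#' the threshold are selected as candidate active constituents.
#'
#' @param peaks component x sample matrix of peak responses.
#' @param effects sample x indicator matrix of pharmacodynamic readouts.
#' @param xi distinguishing coefficient (default 0.1).
#' @param normalization pre-treatment applied to every sequence
#'   (see \code{\link{normalizeSequences}}); default \code{"mean"}.
#' @param scope deviation-extrema scope, see \code{\link{grayCoefficients}}.
#' @param threshold relevancy cut for selection (default 0.85, strict
#'   inequality).
#' @return a \linkS4class{GraResult}.
#' @examples
#' sim <- genSpectrumEffect(nComponents = 10, nActive = 3, nSamples = 12, seed = 1)
#' res <- spectrumEffectGRA(sim$peaks, sim$effects)
#' selectedComponents(res)
#' @export
spectrumEffectGRA <- function(peaks, effects, xi = 0.1,
                              normalization = c("mean", "minmax", "initial", "none"),
                              scope = c("global", "per_pair"),
                              threshold = 0.85) {
  normalization <- match.arg(normalization)
  scope <- match.arg(scope)
  peaks <- as.matrix(peaks)
  effects <- as.matrix(effects)
  ps <- colnames(peaks)
  es <- rownames(effects)
  if (!is.null(ps) && !is.null(es)) {
    missing1 <- setdiff(ps, es)
    missing2 <- setdiff(es, ps)
    if (length(missing1) || length(missing2))
      stop("sample axes do not match; unmatched: ",
           paste(c(missing1, missing2), collapse = ", "))
    effects <- effects[ps, , drop = FALSE]
  } else if (ncol(peaks) != nrow(effects)) {
    stop("sample axes do not match: ", ncol(peaks), " vs ", nrow(effects))
  }
  comp <- normalizeSequences(peaks, normalization)
  ind <- t(normalizeSequences(t(effects), normalization))
  nInd <- ncol(ind); nComp <- nrow(comp); nSamp <- ncol(comp)
  cid <- rownames(comp); if (is.null(cid)) cid <- paste0("C", seq_len(nComp))
  iid <- colnames(ind); if (is.null(iid)) iid <- paste0("I", seq_len(nInd))
  co <- array(NA_real_, dim = c(nInd, nComp, nSamp),
              dimnames = list(iid, cid, colnames(comp)))
  for (j in seq_len(nInd))
    co[j, , ] <- grayCoefficients(ind[, j], comp, xi = xi, scope = scope)
  gr <- apply(co, c(1, 2), mean)
  rel <- colMeans(gr)
  sel <- selectComponents(rel, threshold)
  new("GraResult", coefficients = co, grades = gr, relevancy = rel,
      selected = sel,
      params = list(xi = xi, normalization = normalization, scope = scope,
                    threshold = threshold))
}

#' Select components above a relevancy threshold
#'
#' Selection is strict (relevancy must exceed the threshold, so a component
#' sitting exactly at the cut is excluded), ordered by relevancy descending
#' with ties broken by component id.
#'
#' @param relevancy named numeric of per-component relevancies, or a
#'   \linkS4class{GraResult}.
#' @param threshold cut in (0, 1]; default 0.85.
#' @return character vector of selected component ids, ordered.
#' @export
selectComponents <- function(relevancy, threshold = 0.85) {
  if (is(relevancy, "GraResult")) relevancy <- relevancy@relevancy
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  keep <- relevancy[relevancy > threshold]
  if (!length(keep)) return(character())
  names(keep)[order(-keep, names(keep))]
}
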