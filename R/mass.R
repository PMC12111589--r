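# Monoisotopic masses of the most abundant isotopes (Da), NIST values.
.ISOTOPE_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.99491461956,
  S = 31.97207100,
  P = 30.97376163,
  Na = 22.9897692809,
  Cl = 34.96885268,
  F = 18.99840322,
  K = 38.96370668
)

.PROTON_MASS <- 1.00727646688   # mass of H minus the electron
.ELECTRON_MASS <- 0.00054857991
# formate anion CHO2- (includes the extra electron)
.FORMATE_MASS <- 12.0 + 1.00782503207 + 2 * 15.99491461956 + .ELECTRON_MASS

#' Parse a molecular formula
#'
#' Accepts plain Hill notation ("C21H20O9") and the underscore-decorated
#' variant used in instrument reports ("C_21_H_20_O_9_"). Elements may
#' repeat; counts accumulate.
#'
#' @param x formula string.
#' @return named integer vector, element -> count.
#' @examples
#' parseFormula("C6H12O6")
#' parseFormula("C_21_H_20_O_9_")
#' @export
parseFormula <- function(x) {
  if (!is.character(x) || length(x) != 1 || !nzchar(x))
    stop("formula must be a non-empty string")
  s <- gsub("_", "", x)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (!length(toks) || sum(attr(m, "match.length")) != nchar(s))
    stop("cannot parse formula: ", x)
  counts <- integer(0)
  for (tk in toks) {
    el <- sub("[0-9]*$", "", tk)
    n <- sub("^[A-Za-z]+", "", tk)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.ISOTOPE_MASS))
      stop("unknown element symbol: ", el)
    counts[el] <- if (el %in% names(counts)) counts[[el]] + n else n
  }
  counts
}

#' Format a formula in Hill order
#'
#' Carbon first, hydrogen second, then remaining elements alphabetically;
#' without carbon, all elements are alphabetical.
#'
#' @param counts named integer vector as from \code{\link{parseFormula}}.
#' @return canonical formula string.
#' @export
formatFormula <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) stop("empty formula")
  els <- names(counts)
  ord <- if ("C" %in% els) {
    c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  } else sort(els)
  paste0(vapply(ord, function(e)
    paste0(e, if (counts[[e]] > 1) counts[[e]] else ""), character(1)),
    collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of the most-abundant-isotope masses over the element counts.
#'
#' @param formula a formula string or a named count vector.
#' @return mass in Da.
#' @examples
#' monoisotopicMass("H2O")      # 18.010565
#' monoisotopicMass("C6H12O6")  # 180.063388
#' @export
monoisotopicMass <- function(formula) {
  if (is.character(formula)) formula <- parseFormula(formula)
  if (!length(formula) || all(formula == 0)) stop("empty formula")
  unknown <- setdiff(names(formula), names(.ISOTOPE_MASS))
  if (length(unknown))
    stop("unknown element symbol: ", paste(unknown, collapse = ", "))
  sum(.ISOTOPE_MASS[names(formula)] * formula)
}

#' Negative-mode adduct m/z
#'
#' Supported singly charged negative adducts: deprotonation
#' \eqn{[M-H]^-} (m/z = M - 1.007276, the proton mass, so the retained
#' electron is accounted for) and formate attachment \eqn{[M+HCOO]^-}
#' (m/z = M + 44.998203).
#'
#' @param mass neutral monoisotopic mass, Da (> 0).
#' @param kind adduct name: "[M-H]-" or "[M+HCOO]-" (the shorthand "-H" and
#'   "+HCOO" used in instrument tables is also accepted).
#' @return m/z in Th.
#' @examples
#' adductMz(monoisotopicMass("C6H12O6"), "[M-H]-")  # 179.056112
#' @export
adductMz <- function(mass, kind) {
  if (any(!is.finite(mass)) || any(mass <= 0)) stop("mass must be positive")
  kind <- switch(kind,
    "[M-H]-" = , "-H" = "mh",
    "[M+HCOO]-" = , "+HCOO" = "hcoo",
    stop("unsupported adduct kind: ", kind))
  if (kind == "mh") mass - .PROTON_MASS else mass + .FORMATE_MASS
}

#' Signed parts-per-million mass error
#'
#' @param observed observed m/z (Th).
#' @param theoretical theoretical m/z (Th, > 0).
#' @return signed ppm: (observed - theoretical) / theoretical * 1e6.
#' @export
ppmError <- function(observed, theoretical) {
  if (any(!is.finite(theoretical)) || any(theoretical <= 0))
    stop("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Match an observed m/z against candidate formulas
#'
#' Computes the theoretical adduct m/z for each candidate and keeps those
#' within the ppm tolerance, sorted by absolute ppm error ascending.
#'
#' @param observed observed m/z (Th).
#' @param candidates data.frame with columns id, formula, adduct.
#' @param tolPpm tolerance in ppm (default 10, the usual high-accuracy
#'   identification margin; some instrument tables use wider windows, so it
#'   is a per-call parameter).
#' @return data.frame(id, formula, adduct, theoretical, ppm), filtered and
#'   sorted.
#' @export
matchWithinTolerance <- function(observed, candidates, tolPpm = 10) {
  if (!is.numeric(tolPpm) || tolPpm <= 0) stop("tolPpm must be > 0")
  need <- c("id", "formula", "adduct")
  miss <- setdiff(need, names(candidates))
  if (length(miss)) stop("candidates missing column(s): ", paste(miss, collapse = ", "))
  theo <- mapply(function(f, a) adductMz(monoisotopicMass(f), a),
                 as.character(candidates$formula),
                 as.character(candidates$adduct))
  ppm <- ppmError(observed, theo)
  out <- data.frame(id = as.character(candidates$id),
                    formula = as.character(candidates$formula),
                    adduct = as.character(candidates$adduct),
                    theoretical = as.numeric(theo), ppm = as.numeric(ppm),
                    stringsAsFactors = FALSE)
  out <- out[abs(out$ppm) <= tolPpm, , drop = FALSE]
  out <- out[order(abs(out$ppm)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
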