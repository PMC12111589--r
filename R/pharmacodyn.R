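#' Homeostasis-model assessment of insulin resistance (HOMA-IR)
#'
#' \deqn{HOMA\text{-}IR = FBG \times INS / 22.5}
#' with fasting blood glucose in mmol/L and fasting plasma insulin in mIU/L.
#'
#' @param fbg fasting blood glucose, mmol/L (> 0).
#' @param ins fasting plasma insulin, mIU/L (>= 0).
#' @return numeric, same length as the inputs.
#' @examples
#' homaIR(4.5, 5)  # 1.0
#' @export
homaIR <- function(fbg, ins) {
  if (any(!is.finite(fbg)) || any(fbg <= 0))
    stop("fbg must be finite and positive (mmol/L)")
  if (any(!is.finite(ins)) || any(ins < 0))
    stop("ins must be finite and non-negative (mIU/L)")
  fbg * ins / 22.5
}

#' Homeostasis-model assessment of beta-cell function (HOMA-beta)
#'
#' \deqn{HOMA\text{-}\beta = 20 \times INS / (FBG - 3.5)}
#' The index has a pole at FBG = 3.5 mmol/L and is non-physiologic below it,
#' so \code{fbg} must exceed 3.5.
#'
#' @inheritParams homaIR
#' @return numeric.
#' @examples
#' homaBeta(5.5, 10)  # 100
#' @export
homaBeta <- function(fbg, ins) {
  if (any(!is.finite(fbg)))
    stop("fbg must be finite (mmol/L)")
  if (any(fbg <= 3.5))
    stop("HOMA-beta is undefined for FBG <= 3.5 mmol/L")
  if (any(!is.finite(ins)) || any(ins < 0))
    stop("ins must be finite and non-negative (mIU/L)")
  20 * ins / (fbg - 3.5)
}

#' Trapezoidal area under a glucose-time curve
#'
#' Total (not baseline-subtracted) AUC by the composite trapezoid rule,
#' \eqn{\sum_j (t_{j+1}-t_j)(v_j+v_{j+1})/2}, in mmol/L * min.
#'
#' @param times time points, minutes, strictly increasing, length >= 2.
#' @param values glucose values, mmol/L, same length.
#' @return numeric scalar.
#' @examples
#' aucTrapezoid(seq(0, 180, 30), rep(10, 7))  # 1800
#' @export
aucTrapezoid <- function(times, values) {
  if (length(times) != length(values))
    stop("times and values must have the same length")
  if (length(times) < 2) stop("need at least 2 points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  sum(diff(times) * (values[-length(values)] + values[-1]) / 2)
}

#' Per-subject pharmacodynamic metric
#'
#' @param panel a \linkS4class{SubjectPanel}.
#' @param metric one of FBG, HOMA_IR, HOMA_beta, AUC_OGTT, AUC_ITT.
#' @return named numeric, one value per subject (NA where a curve is absent).
#' @export
subjectMetric <- function(panel,
                          metric = c("FBG", "HOMA_IR", "HOMA_beta",
                                     "AUC_OGTT", "AUC_ITT")) {
  metric <- match.arg(metric)
  s <- subjects(panel)
  if (metric == "FBG") return(setNames(s$fbg, s$subject))
  if (metric == "HOMA_IR") return(setNames(homaIR(s$fbg, s$insulin), s$subject))
  if (metric == "HOMA_beta") return(setNames(homaBeta(s$fbg, s$insulin), s$subject))
  kind <- sub("AUC_", "", metric)
  cv <- curves(panel)
  cv <- cv[cv$kind == kind, , drop = FALSE]
  vapply(s$subject, function(id) {
    d <- cv[cv$subject == id, , drop = FALSE]
    if (nrow(d) < 2) return(NA_real_)
    d <- d[order(d$time), , drop = FALSE]
    aucTrapezoid(d$time, d$glucose)
  }, numeric(1))
}

#' Group summaries of a pharmacodynamic metric
#'
#' Per-group mean, sd and n, the ratio of each group mean to the reference
#' group mean, and a Welch two-sided p-value against a designated comparator
#' group. Groups with no usable subjects are excluded with a warning;
#' single-subject groups report the mean with sd = NA.
#'
#' @inheritParams subjectMetric
#' @param reference group whose mean anchors the ratios (default "Control").
#' @param comparator group each group is Welch-tested against (default
#'   "Model"); the comparator's own p is NA.
#' @return data.frame(group, n, mean, sd, ratio, p_welch).
#' @export
groupSummary <- function(panel, metric = c("FBG", "HOMA_IR", "HOMA_beta",
                                           "AUC_OGTT", "AUC_ITT"),
                         reference = "Control", comparator = "Model") {
  metric <- match.arg(metric)
  vals <- subjectMetric(panel, metric)
  s <- subjects(panel)
  grp <- split(vals[s$subject], s$group)
  grp <- lapply(grp, function(v) v[is.finite(v)])
  empty <- names(grp)[lengths(grp) == 0]
  if (length(empty)) {
    warning("excluding empty group(s): ", paste(empty, collapse = ", "))
    grp <- grp[lengths(grp) > 0]
  }
  if (!reference %in% names(grp))
    stop("reference group not present: ", reference)
  refMean <- mean(grp[[reference]])
  comp <- if (comparator %in% names(grp)) grp[[comparator]] else NULL
  out <- do.call(rbind, lapply(names(grp), function(g) {
    v <- grp[[g]]
    p <- NA_real_
    if (!is.null(comp) && g != comparator && length(v) >= 2 &&
        length(comp) >= 2 && (sd(v) > 0 || sd(comp) > 0))
      p <- t.test(v, comp)$p.value
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) >= 2) sd(v) else NA_real_,
               ratio = mean(v) / refMean, p_welch = p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
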