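# One-hot (dummy) class encoding, centered, used by the discriminant fits.
.classDummy <- function(y) {
  y <- as.character(y)
  cls <- sort(unique(y))
  Y <- vapply(cls, function(cl) as.numeric(y == cl), numeric(length(y)))
  colnames(Y) <- cls
  Y
}

.center <- function(X) sweep(X, 2, colMeans(X))

#' Principal component analysis
#'
#' Successive variance-maximizing orthogonal components computed by singular
#' value decomposition of the column-centered matrix.
#'
#' @param X samples x features numeric matrix (preprocessed; see
#'   \code{\link{preprocessFeatures}}).
#' @param ncomp number of components, at most \code{min(n - 1, p)}.
#' @return a \linkS4class{LatentModel} of kind PCA; \code{R2X} holds the
#'   per-component explained-variance fractions.
#' @export
pcaFit <- function(X, ncomp = 2) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (ncomp < 1 || ncomp > min(n - 1, p))
    stop("ncomp must be in [1, min(n - 1, p)] = [1, ", min(n - 1, p), "]")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = ncomp, nv = ncomp)
  scores <- sv$u %*% diag(sv$d[seq_len(ncomp)], ncomp)
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(ncomp))
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(X), colnames(scores))
  r2x <- sv$d[seq_len(ncomp)]^2 / sum(sv$d^2)
  new("LatentModel", kind = "PCA", scores = scores, loadings = loadings,
      weights = matrix(0, 0, 0), orthoScores = matrix(0, n, 0),
      orthoLoadings = matrix(0, p, 0), R2X = r2x, R2Y = NA_real_,
      Q2 = NA_real_, ssy = numeric(), yLoadings = matrix(0, 0, 0),
      classes = character(), center = mu, scale = rep(1, p))
}

# NIPALS PLS2 core on centered X, Y. Returns weights W, scores T, loadings P,
# y-loadings Q, per-component explained response SS.
.plsNipals <- function(Xc, Yc, ncomp, tol = 1e-12, maxit = 1000) {
  n <- nrow(Xc); p <- ncol(Xc); q <- ncol(Yc)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); Qm <- matrix(0, q, ncomp)
  ssy <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    u <- Yc[, which.max(apply(Yc, 2, var)), drop = TRUE]
    if (all(abs(u) < 1e-300)) break
    t0 <- rep(Inf, n)
    for (it in seq_len(maxit)) {
      w <- crossprod(Xc, u) / sum(u^2)
      w <- w / sqrt(sum(w^2))
      tt <- Xc %*% w
      qq <- crossprod(Yc, tt) / sum(tt^2)
      u <- Yc %*% qq / sum(qq^2)
      if (sum((tt - t0)^2) / max(sum(tt^2), 1e-300) < tol) break
      t0 <- tt
    }
    pp <- crossprod(Xc, tt) / sum(tt^2)
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt; Qm[, a] <- qq
    ssy[a] <- sum(tt^2) * sum(qq^2)
    Xc <- Xc - tt %*% t(pp)
    Yc <- Yc - tt %*% t(qq)
  }
  list(W = W, P = P, T = Tm, Q = Qm, ssy = ssy, Yres = Yc)
}

#' Partial least squares discriminant analysis
#'
#' NIPALS PLS with a centered one-hot class response. \code{R2Y} is
#' \eqn{1 - SS_{res}/SS_{tot}} on the centered response.
#'
#' @inheritParams pcaFit
#' @param y class labels (>= 2 classes).
#' @return a \linkS4class{LatentModel} of kind PLSDA.
#' @export
plsdaFit <- function(X, y, ncomp = 2) {
  X <- as.matrix(X)
  y <- as.character(y)
  tab <- table(y)
  if (length(tab) < 2) stop("need at least 2 classes")
  if (any(tab < 1)) stop("every class needs at least one sample")
  if (any(tab < 2)) warning("class(es) with a single sample: ",
                            paste(names(tab)[tab < 2], collapse = ", "))
  if (ncomp < 1) stop("ncomp must be >= 1")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  Y <- .classDummy(y)
  Yc <- .center(Y)
  sstot <- sum(Yc^2)
  fit <- .plsNipals(Xc, Yc, ncomp)
  r2y <- 1 - sum(fit$Yres^2) / sstot
  ssx <- sum(Xc^2)
  r2x <- vapply(seq_len(ncomp), function(a)
    sum(fit$T[, a]^2) * sum(fit$P[, a]^2) / ssx, numeric(1))
  dimnames(fit$T) <- list(rownames(X), paste0("comp", seq_len(ncomp)))
  dimnames(fit$P) <- list(colnames(X), colnames(fit$T))
  dimnames(fit$W) <- dimnames(fit$P)
  new("LatentModel", kind = "PLSDA", scores = fit$T, loadings = fit$P,
      weights = fit$W, orthoScores = matrix(0, nrow(X), 0),
      orthoLoadings = matrix(0, ncol(X), 0), R2X = r2x, R2Y = r2y,
      Q2 = NA_real_, ssy = fit$ssy, yLoadings = t(fit$Q),
      classes = colnames(Y), center = mu, scale = rep(1, ncol(X)))
}

#' Orthogonal PLS discriminant analysis (two classes)
#'
#' Orthogonal-signal-corrected PLS: class-orthogonal variation is peeled off
#' into \code{nOrthogonal} components, then a single predictive component is
#' fitted on the filtered matrix. Orthogonal scores are exactly uncorrelated
#' with the class encoding, and the predictive scores are orthogonal to the
#' orthogonal scores.
#'
#' @inheritParams pcaFit
#' @param y class labels; exactly 2 classes (run multi-group designs as
#'   pairwise contrasts).
#' @param nOrthogonal number of orthogonal components (>= 0); with 0 the fit
#'   reduces to one-component PLS.
#' @return a \linkS4class{LatentModel} of kind OPLSDA.
#' @export
oplsdaFit <- function(X, y, nOrthogonal = 1) {
  X <- as.matrix(X)
  y <- as.character(y)
  cls <- sort(unique(y))
  if (length(cls) != 2)
    stop("OPLS-DA takes exactly 2 classes; got ", length(cls),
         " (use pairwise contrasts)")
  if (nOrthogonal < 0) stop("nOrthogonal must be >= 0")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  yv <- as.numeric(y == cls[2])
  yc <- yv - mean(yv)
  sstot <- sum(yc^2)
  w <- crossprod(Xc, yc) / sum(yc^2)
  w <- w / sqrt(sum(w^2))
  n <- nrow(X); p <- ncol(X)
  To <- matrix(0, n, 0); Po <- matrix(0, p, 0)
  for (o in seq_len(nOrthogonal)) {
    tt <- Xc %*% w
    pp <- crossprod(Xc, tt) / sum(tt^2)
    wo <- pp - as.numeric(crossprod(w, pp)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break  # no orthogonal variation left
    wo <- wo / nwo
    to <- Xc %*% wo
    po <- crossprod(Xc, to) / sum(to^2)
    Xc <- Xc - to %*% t(po)
    To <- cbind(To, to); Po <- cbind(Po, po)
  }
  tt <- Xc %*% w
  pp <- crossprod(Xc, tt) / sum(tt^2)
  cc <- sum(yc * tt) / sum(tt^2)
  r2y <- 1 - sum((yc - cc * tt)^2) / sstot
  ssx <- sum(sweep(X, 2, mu)^2)
  r2x <- sum(tt^2) * sum(pp^2) / ssx
  scores <- matrix(tt, n, 1, dimnames = list(rownames(X), "predictive"))
  if (ncol(To)) colnames(To) <- paste0("ortho", seq_len(ncol(To)))
  new("LatentModel", kind = "OPLSDA", scores = scores,
      loadings = matrix(pp, p, 1, dimnames = list(colnames(X), "predictive")),
      weights = matrix(w, p, 1, dimnames = list(colnames(X), "predictive")),
      orthoScores = To, orthoLoadings = Po, R2X = r2x, R2Y = r2y,
      Q2 = NA_real_, ssy = sum(tt^2) * cc^2,
      yLoadings = matrix(cc, 1, 1), classes = cls, center = mu,
      scale = rep(1, p))
}

#' Variable importance in projection (VIP)
#'
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{aj}/\|w_a\|)^2 / \sum_a SSY_a}}
#' where \eqn{SSY_a} is the response sum of squares explained by component
#' a. The mean of the squared VIPs is exactly 1. For OPLS-DA the VIP is
#' computed on the predictive part.
#'
#' @param model a fitted PLSDA or OPLSDA \linkS4class{LatentModel}.
#' @return named numeric vector of VIP scores (>= 0).
#' @export
vipScores <- function(model) {
  if (!is(model, "LatentModel") || model@kind == "PCA")
    stop("VIP is defined for PLSDA/OPLSDA models only")
  W <- model@weights
  ssy <- model@ssy
  keep <- ssy > 0
  W <- W[, keep, drop = FALSE]
  ssy <- ssy[keep]
  p <- nrow(W)
  Wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  v <- sqrt(p * as.numeric(Wn^2 %*% ssy) / sum(ssy))
  names(v) <- rownames(W)
  v
}

#' Correlation-scaled loadings p(corr)
#'
#' The S-plot ordinate: Pearson correlation between each feature's centered
#' intensities and the model's predictive score vector.
#'
#' @param model a \linkS4class{LatentModel} with predictive scores.
#' @param X the samples x features matrix the model was fitted on.
#' @return named numeric in \[-1, 1\]; zero-variance features get NA with a
#'   warning (they are excluded from screening).
#' @export
pcorrScores <- function(model, X) {
  X <- as.matrix(X)
  tt <- model@scores[, 1]
  s <- apply(X, 2, sd)
  out <- rep(NA_real_, ncol(X))
  ok <- s > 0
  if (any(!ok)) warning(sum(!ok), " zero-variance feature(s): p(corr) undefined")
  out[ok] <- as.numeric(cor(X[, ok, drop = FALSE], tt))
  names(out) <- colnames(X)
  out
}

# Stratified fold assignment; guarantees every class appears in every
# training set when each class has >= 2 samples.
.stratifiedFolds <- function(y, folds) {
  y <- as.character(y)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep(seq_len(folds), length.out = length(idx))
  }
  fold
}

#' Cross-validated predictive ability Q2
#'
#' Stratified k-fold cross-validation of a PLS-DA (or, for two classes with
#' \code{nOrthogonal > 0}, OPLS-DA) model:
#' \eqn{Q^2 = 1 - PRESS / SS_{tot}} with strictly out-of-fold predictions of
#' the centered class encoding. Can be negative when the model predicts
#' worse than the class mean.
#'
#' @inheritParams plsdaFit
#' @param folds number of folds (default 7).
#' @param seed integer seed for the fold assignment.
#' @param nOrthogonal orthogonal components (OPLS-DA route, two classes).
#' @return numeric Q2 (<= 1, possibly negative).
#' @export
q2CrossVal <- function(X, y, ncomp = 2, folds = 7, seed = 1, nOrthogonal = 0) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (folds < 2) stop("folds must be >= 2")
  tab <- table(y)
  if (any(tab < 2))
    stop("cross-validation needs >= 2 samples per class")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- .stratifiedFolds(y, folds)
  Y <- .classDummy(y)
  press <- 0
  for (f in sort(unique(fold))) {
    te <- fold == f
    tr <- !te
    if (length(unique(y[tr])) < length(unique(y)))
      stop("a training fold lost a class; reduce folds")
    mu <- colMeans(X[tr, , drop = FALSE])
    Xtr <- sweep(X[tr, , drop = FALSE], 2, mu)
    Xte <- sweep(X[te, , drop = FALSE], 2, mu)
    my <- colMeans(Y[tr, , drop = FALSE])
    Ytr <- sweep(Y[tr, , drop = FALSE], 2, my)
    if (nOrthogonal > 0 && ncol(Y) == 2) {
      # OSC filter estimated on the training fold, applied to both
      yc <- Ytr[, 2]
      w <- crossprod(Xtr, yc) / sum(yc^2)
      w <- w / sqrt(sum(w^2))
      for (o in seq_len(nOrthogonal)) {
        tt <- Xtr %*% w
        pp <- crossprod(Xtr, tt) / sum(tt^2)
        wo <- pp - as.numeric(crossprod(w, pp)) * w
        nwo <- sqrt(sum(wo^2))
        if (nwo < 1e-12) break
        wo <- wo / nwo
        to <- Xtr %*% wo
        po <- crossprod(Xtr, to) / sum(to^2)
        Xtr <- Xtr - to %*% t(po)
        Xte <- Xte - (Xte %*% wo) %*% t(po)
      }
      ncompUse <- 1
    } else ncompUse <- ncomp
    fit <- .plsNipals(Xtr, Ytr, ncompUse)
    B <- .plsCoef(fit)
    Yhat <- Xte %*% B
    Yte <- sweep(Y[te, , drop = FALSE], 2, my)
    press <- press + sum((Yte - Yhat)^2)
  }
  sstot <- sum(.center(Y)^2)
  1 - press / sstot
}

# regression coefficients B = W (P'W)^-1 Q'
.plsCoef <- function(fit) {
  keep <- colSums(abs(fit$W)) > 0
  W <- fit$W[, keep, drop = FALSE]
  P <- fit$P[, keep, drop = FALSE]
  Q <- fit$Q[, keep, drop = FALSE]
  W %*% solve(crossprod(P, W)) %*% t(Q)
}

# save/restore the RNG state so seeded helpers do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
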