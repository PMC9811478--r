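#' Partial least squares regression (NIPALS)
#'
#' Fits a PLS model with `A` latent components by NIPALS with deflation.
#' `X` and `Y` are centered internally; the stored weights `W`,
#' x-loadings `P`, y-loadings `Q` and scores `T` satisfy the usual NIPALS
#' orthogonality (score vectors mutually orthogonal), and predictions are
#' `yhat = (x - xmean) %*% B + ymean` with
#' `B = W (P'W)^-1 Q'`.
#'
#' @param X numeric matrix, samples x features.
#' @param Y numeric matrix (or vector), samples x targets.
#' @param A number of components, `A <= min(nrow(X) - 1, ncol(X))`.
#' @param tol NIPALS inner-loop convergence tolerance.
#' @param max_iter inner-loop cap.
#' @return list of class `"PLSModel"`: `W`, `P`, `Q`, `T`, `B`, `R`
#'   (projection `W (P'W)^-1`), `xmean`, `ymean`, `A`.
#' @seealso [plsTransform()], [plsPredict()], [plsdaFit()]
#' @export
plsFit <- function(X, Y, A, tol = 1e-10, max_iter = 200) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  stopifnot(nrow(Y) == n, A >= 1)
  if (A > min(n - 1, p))
    stop("A exceeds min(samples - 1, features)")
  xmean <- colMeans(X); ymean <- colMeans(Y)
  Xc <- sweep(X, 2, xmean); Yc <- sweep(Y, 2, ymean)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Q <- matrix(0, q, A); Tm <- matrix(0, n, A)
  for (a in seq_len(A)) {
    u <- Yc[, which.max(colSums(Yc^2))]
    if (sum(u^2) < 1e-14)
      stop("Y deflated to zero before reaching A components ",
           "(A exceeds the predictive rank)")
    tOld <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xc, u); w <- w / sqrt(sum(w^2))
      tt <- drop(Xc %*% w)
      qv <- crossprod(Yc, tt) / sum(tt^2)
      u <- drop(Yc %*% qv) / sum(qv^2)
      if (sqrt(sum((tt - tOld)^2)) < tol * sqrt(sum(tt^2))) break
      tOld <- tt
    }
    pv <- crossprod(Xc, tt) / sum(tt^2)
    Xc <- Xc - tcrossprod(tt, pv)
    Yc <- Yc - tcrossprod(tt, qv)
    W[, a] <- w; P[, a] <- pv; Q[, a] <- qv; Tm[, a] <- tt
  }
  R <- W %*% solve(crossprod(P, W))
  B <- R %*% t(Q)
  structure(list(W = W, P = P, Q = Q, T = Tm, B = B, R = R,
                 xmean = xmean, ymean = ymean, A = A),
            class = "PLSModel")
}

#' Project new samples into the PLS score space
#'
#' @param model a `"PLSModel"`.
#' @param Xnew samples x features matrix (feature count must match).
#' @return samples x A score matrix; training samples map to the stored
#'   `T`.
#' @export
plsTransform <- function(model, Xnew) {
  Xnew <- rbind(as.matrix(Xnew))
  if (ncol(Xnew) != length(model$xmean))
    stop("feature count mismatch: expected ", length(model$xmean))
  sweep(Xnew, 2, model$xmean) %*% model$R
}

#' Predict responses from a PLS model
#'
#' @inheritParams plsTransform
#' @return samples x targets matrix of predictions.
#' @export
plsPredict <- function(model, Xnew) {
  Xnew <- rbind(as.matrix(Xnew))
  if (ncol(Xnew) != length(model$xmean))
    stop("feature count mismatch: expected ", length(model$xmean))
  sweep(sweep(Xnew, 2, model$xmean) %*% model$B, 2, model$ymean, "+")
}

#' PLS discriminant analysis
#'
#' Fits PLS regression against a one-column-per-class \{0, 1\} indicator
#' matrix; a sample is assigned to the class with the largest predicted
#' indicator, ties going to the earliest class in the (sorted) class
#' list.
#'
#' @param X samples x features matrix.
#' @param labels class labels (>= 2 classes present).
#' @param A number of PLS components.
#' @return list of class `"DiscriminantModel"`: `pls` (the underlying
#'   `"PLSModel"`), `classes`.
#' @export
plsdaFit <- function(X, labels, A) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need >= 2 classes")
  Y <- outer(labels, classes, `==`) * 1
  colnames(Y) <- classes
  structure(list(pls = plsFit(X, Y, A), classes = classes),
            class = "DiscriminantModel")
}

#' @rdname plsdaFit
#' @param model a `"DiscriminantModel"`.
#' @param Xnew samples x features matrix.
#' @return `plsdaPredict`: character vector of predicted labels.
#' @export
plsdaPredict <- function(model, Xnew) {
  S <- plsPredict(model$pls, Xnew)
  model$classes[max.col(S, ties.method = "first")]
}

#' @rdname plsdaFit
#' @return `plsdaScores`: samples x classes matrix of predicted
#'   indicator values.
#' @export
plsdaScores <- function(model, Xnew) {
  S <- plsPredict(model$pls, Xnew)
  colnames(S) <- model$classes
  S
}
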