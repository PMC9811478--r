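#' Trim spectra to a wavenumber range
#'
#' Retains exactly the channels with `lo <= wavenumber <= hi` (the
#' default keeps the 535-1717 cm^-1 fingerprint region); sample metadata
#' is untouched.
#'
#' @param x a [RamanSpectraSet-class].
#' @param lo,hi range bounds in cm^-1, `lo < hi`.
#' @return The trimmed `RamanSpectraSet`.
#' @export
trimSpectra <- function(x, lo = 535, hi = 1717) {
  stopifnot(lo < hi)
  keep <- wavenumbers(x) >= lo & wavenumbers(x) <= hi
  if (!any(keep)) stop("no channels in range [", lo, ", ", hi, "]")
  .logStep(x[keep, ], sprintf("trim[%g,%g]", lo, hi))
}

# Legendre polynomials (three-term recurrence) evaluated on u in [-1,1];
# columns P_0..P_order.
.legendreBasis <- function(u, order) {
  P <- matrix(0, length(u), order + 1)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- u
  if (order >= 2)
    for (k in 2:order)
      P[, k + 1] <- ((2 * k - 1) * u * P[, k] - (k - 1) * P[, k - 1]) / k
  P
}

#' Extended multiplicative signal correction
#'
#' Regresses every spectrum `x` onto a reference `r` plus a polynomial in
#' the rescaled wavenumber axis: `x ~ b*r + sum_k c_k P_k(u)`, with `P_k`
#' Legendre polynomials on `u in [-1, 1]` and `k = 0..order` (default 6).
#' The corrected spectrum is `(x - sum_k c_k P_k) / b`, which removes
#' additive (baseline-like) and multiplicative (scatter/gain) artifacts
#' by scaling every spectrum to the reference — by default the set's mean
#' spectrum.
#'
#' @param x a [RamanSpectraSet-class] (at least 2 spectra when
#'   `reference` is omitted).
#' @param order polynomial order.
#' @param reference numeric reference spectrum on the same grid; default
#'   the mean spectrum of `x`.
#' @param b_min multiplicative coefficients with `|b| < b_min` mark the
#'   spectrum as failed (correction undefined); such spectra are returned
#'   uncorrected and flagged.
#' @return list of class `"EMSCResult"`: `set` (corrected
#'   `RamanSpectraSet`), `b` (per-spectrum multiplicative coefficient),
#'   `coef` (polynomial coefficients, `(order+1) x n`), `reference`, and
#'   `failed` (logical per spectrum).
#' @export
emscCorrect <- function(x, order = 6, reference = NULL, b_min = 1e-8) {
  X <- intensities(x)
  if (is.null(reference)) {
    if (ncol(X) < 2) stop("need >= 2 spectra when reference is omitted")
    reference <- rowMeans(X)
  }
  stopifnot(length(reference) == nrow(X))
  wn <- wavenumbers(x)
  u <- 2 * (wn - min(wn)) / diff(range(wn)) - 1
  P <- .legendreBasis(u, order)
  D <- cbind(r = reference, P)
  qrD <- qr(D)
  cf <- qr.coef(qrD, X)                      # (order+2) x n
  b <- cf[1, ]
  cc <- cf[-1, , drop = FALSE]
  failed <- !is.finite(b) | abs(b) < b_min
  corr <- sweep(X - P %*% cc, 2, b, "/")
  corr[, failed] <- X[, failed]
  out <- x
  out <- .setIntensity(out, corr)
  out <- .logStep(out, sprintf("emsc[order=%d]", order))
  structure(list(set = out, b = b, coef = cc, reference = reference,
                 failed = failed),
            class = "EMSCResult")
}

#' Asymmetric least squares baseline
#'
#' Estimates a smooth fluorescence background `z` under the Raman peaks
#' by iterating the weighted Whittaker smoother
#' `(W + lambda * D'D) z = W y`, with `D` the second-difference operator
#' and asymmetric weights `w_i = p` where `y_i > z_i` (points above the
#' baseline — peaks — are nearly ignored) and `1 - p` elsewhere.
#' Iteration stops when the weight vector stabilizes or after `max_iter`
#' sweeps.
#'
#' @param y intensity vector (length >= 4).
#' @param lambda smoothness penalty, > 0.
#' @param p asymmetry in (0, 1).
#' @param max_iter maximum weight updates.
#' @return numeric baseline `z` of `length(y)`, with attribute
#'   `converged` (logical; `FALSE` means the weights were still changing
#'   at `max_iter` and the last iterate was returned).
#' @export
alsBaseline <- function(y, lambda = 1e5, p = 0.001, max_iter = 50) {
  n <- length(y)
  stopifnot(n >= 4, lambda > 0, p > 0, p < 1)
  D <- Matrix::bandSparse(n - 2, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  converged <- FALSE
  z <- y
  wUsed <- w
  for (it in seq_len(max_iter)) {
    Wm <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(Wm + DtD, w * y))
    wUsed <- w
    wNew <- ifelse(y > z, p, 1 - p)
    if (identical(wNew, w)) { converged <- TRUE; break }
    w <- wNew
  }
  if (!converged)
    warning("ALS weights did not stabilize within max_iter; ",
            "returning last iterate")
  attr(z, "converged") <- converged
  attr(z, "weights") <- wUsed   # the weights that produced this iterate
  z
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing (default 15-point window,
#' 3rd-order polynomial).  Series length is preserved; the edge values
#' come from the polynomial fits anchored at the boundary windows, so any
#' polynomial up to the filter order is reproduced exactly, edges
#' included.
#'
#' @param y intensity vector (or matrix, smoothed column-wise).
#' @param window odd window length, `polyorder < window <= length(y)`.
#' @param polyorder polynomial order.
#' @return smoothed vector/matrix, same shape as `y`.
#' @export
savgolSmooth <- function(y, window = 15, polyorder = 3) {
  stopifnot(window %% 2 == 1, polyorder < window)
  if (is.matrix(y)) {
    stopifnot(window <= nrow(y))
    return(apply(y, 2, signal::sgolayfilt, p = polyorder, n = window))
  }
  stopifnot(window <= length(y))
  signal::sgolayfilt(y, p = polyorder, n = window)
}

#' Mean centering
#'
#' Subtracts the per-channel mean spectrum (the set's center of gravity),
#' or a supplied `center` (e.g. one stored from a training set, for
#' applying the same translation to held-out data).
#'
#' @param x a [RamanSpectraSet-class].
#' @param center optional numeric vector; default the per-channel mean of
#'   `x`.
#' @return Centered `RamanSpectraSet`; the vector used is stored in
#'   `metadata()$center`.
#' @export
meanCenter <- function(x, center = NULL) {
  X <- intensities(x)
  if (is.null(center)) center <- rowMeans(X)
  stopifnot(length(center) == nrow(X))
  out <- x
  out <- .setIntensity(out, X - center)
  md <- metadata(out); md$center <- center; metadata(out) <- md
  .logStep(out, "meanCenter")
}

# Q / T2 outlier statistics for one subject's samples x channels matrix.
.qt2Subject <- function(Xs, confidence, var_explained, max_components) {
  n <- nrow(Xs)
  mu <- colMeans(Xs)
  Xc <- sweep(Xs, 2, mu)
  sv <- svd(Xc)
  ev <- sv$d^2 / (n - 1)                     # covariance eigenvalues
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  A <- which(cumsum(ev) / sum(ev) >= var_explained)[1]
  A <- min(A, max_components, rank - 1)
  A <- max(A, 1L)
  scores <- sv$u[, 1:A, drop = FALSE] %*% diag(sv$d[1:A], A)
  T2 <- rowSums(sweep(scores^2, 2, ev[1:A], "/"))
  T2lim <- A * (n - 1) * (n + 1) / (n * (n - A)) *
    stats::qf(confidence, A, n - A)
  resid <- Xc - scores %*% t(sv$v[, 1:A, drop = FALSE])
  Q <- rowSums(resid^2)
  note <- ""
  evd <- ev[seq.int(A + 1, length.out = max(0, rank - A))]
  th1 <- sum(evd); th2 <- sum(evd^2); th3 <- sum(evd^3)
  if (th1 <= 0 || th2 <= 0) {
    Qlim <- Inf                              # rank deficient: T2 only
    note <- "Q limit undefined (rank deficiency); T2-only rule"
  } else {
    h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
    if (h0 <= 0) h0 <- 1e-3
    ca <- stats::qnorm(confidence)
    Qlim <- th1 * (ca * sqrt(2 * th2 * h0^2) / th1 + 1 +
                     th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
  }
  list(Q = Q, T2 = T2, Qlim = Qlim, T2lim = T2lim, A = A, note = note)
}

#' PCA outlier rejection per subject
#'
#' Fits an individual PCA to each subject's spectra (components chosen as
#' the smallest number explaining `var_explained` of the variance, capped
#' at `min(max_components, rank - 1)`), computes Hotelling's T2 on the
#' retained scores with its F-distribution limit at `confidence`, and the
#' Q residual (squared reconstruction error) with the Jackson-Mudholkar
#' limit from the discarded eigenvalues.  A sample beyond either limit is
#' discarded.
#'
#' @param x a [RamanSpectraSet-class].
#' @param confidence confidence level of both limits.
#' @param var_explained cumulative variance threshold for choosing the
#'   number of components.
#' @param max_components cap on the number of components.
#' @return list: `set` (retained spectra) and `report` (`data.frame` per
#'   sample: `sample_id`, `subject_id`, `Q`, `T2`, `Qlim`, `T2lim`,
#'   `n_components`, `discarded`, `note`).
#' @export
pcaOutlierFilter <- function(x, confidence = 0.95, var_explained = 0.9,
                             max_components = 10) {
  subj <- subjects(x)
  rep_rows <- list()
  for (s in unique(subj)) {
    idx <- which(subj == s)
    Xs <- t(intensities(x)[, idx, drop = FALSE])
    if (nrow(Xs) < 4)
      stop("subject ", s, " has too few spectra for the outlier filter")
    st <- .qt2Subject(Xs, confidence, var_explained, max_components)
    rep_rows[[s]] <- data.frame(
      sample_id = colData(x)$sample_id[idx],
      subject_id = s,
      Q = st$Q, T2 = st$T2, Qlim = st$Qlim, T2lim = st$T2lim,
      n_components = st$A,
      discarded = st$Q > st$Qlim | st$T2 > st$T2lim,
      note = st$note,
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rep_rows)
  rownames(report) <- NULL
  report <- report[match(colData(x)$sample_id, report$sample_id), ]
  keep <- !report$discarded
  out <- .logStep(x[, keep],
                  sprintf("pcaOutlierFilter[conf=%g, discarded=%d]",
                          confidence, sum(!keep)))
  list(set = out, report = report)
}

#' Full preprocessing chain
#'
#' Applies, in order: trim to the fingerprint region, EMSC, ALS baseline
#' subtraction (per spectrum), Savitzky-Golay smoothing, per-subject PCA
#' outlier rejection, and mean centering.  Any stage can be disabled;
#' with every stage disabled the input is returned unchanged.
#'
#' @param x a [RamanSpectraSet-class] of raw spectra.
#' @param trim `c(lo, hi)` in cm^-1, or `NULL` to skip.
#' @param emsc_order EMSC polynomial order, or `NULL` to skip EMSC.
#' @param emsc_reference optional fixed EMSC reference spectrum (e.g.
#'   from a training set); default the set mean.
#' @param als list `list(lambda=, p=, max_iter=)`, or `NULL` to skip
#'   baseline subtraction.
#' @param savgol list `list(window=, polyorder=)`, or `NULL` to skip.
#' @param outlier list `list(confidence=, var_explained=,
#'   max_components=)`, or `NULL` to skip the filter.
#' @param center `TRUE` to mean center (optionally a numeric vector to
#'   center on), `FALSE`/`NULL` to skip.
#' @return list of class `"PreprocessResult"`: `set` (processed
#'   spectra), `outlier_report` (or `NULL`), `emsc` (coefficients, or
#'   `NULL`) and `log`.
#' @examples
#' ds <- simulateStudy(studyConfig(n_subjects = 3, seed = 1))
#' pp <- preprocessSpectra(ds)
#' pp$set
#' @export
preprocessSpectra <- function(x,
                              trim = c(535, 1717),
                              emsc_order = 6,
                              emsc_reference = NULL,
                              als = list(lambda = 1e5, p = 0.001,
                                         max_iter = 50),
                              savgol = list(window = 15, polyorder = 3),
                              outlier = list(confidence = 0.95,
                                             var_explained = 0.9,
                                             max_components = 10),
                              center = TRUE) {
  stopifnot(ncol(x) > 0)
  emscRes <- NULL; outlierReport <- NULL
  if (!is.null(trim)) x <- trimSpectra(x, trim[1], trim[2])
  if (!is.null(emsc_order)) {
    emscRes <- emscCorrect(x, order = emsc_order,
                           reference = emsc_reference)
    x <- emscRes$set
  }
  if (!is.null(als)) {
    X <- intensities(x)
    Z <- apply(X, 2, function(y)
      suppressWarnings(alsBaseline(y, als$lambda, als$p, als$max_iter)))
    x <- .setIntensity(x, X - Z)
    x <- .logStep(x, sprintf("als[lambda=%g,p=%g]", als$lambda, als$p))
  }
  if (!is.null(savgol)) {
    x <- .setIntensity(x, savgolSmooth(intensities(x), savgol$window,
                                       savgol$polyorder))
    x <- .logStep(x, sprintf("savgol[%d,%d]", savgol$window,
                             savgol$polyorder))
  }
  if (!is.null(outlier)) {
    flt <- pcaOutlierFilter(x, outlier$confidence, outlier$var_explained,
                            outlier$max_components)
    x <- flt$set
    outlierReport <- flt$report
  }
  if (isTRUE(center) || is.numeric(center))
    x <- meanCenter(x, if (is.numeric(center)) center else NULL)
  structure(list(set = x, outlier_report = outlierReport,
                 emsc = emscRes, log = processingLog(x)),
            class = "PreprocessResult")
}
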