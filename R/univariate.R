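#' Align sparse blood-gas samples to spectrum times
#'
#' Piecewise-linear interpolation: between every two consecutive
#' blood-gas samples of a subject, a straight line is fitted per
#' parameter and the in-between spectrum times are read off it; values
#' at sample times are exact, and targets before the first / after the
#' last sample are clamped to the nearest endpoint (noted in the
#' `clamped` column).
#'
#' @param bloodgas `data.frame` with `subject_id`, `time` and the
#'   physiological parameter columns (as stored by [simulateStudy()] in
#'   `metadata()$bloodgas`).
#' @param samples `data.frame` with one row per spectrum: `sample_id`,
#'   `subject_id`, `phase`, `time_min`.
#' @return `data.frame` (the aligned clinical table): one row per
#'   spectrum with the interpolated parameters, plus `clamped`.
#' @export
interpolateBloodGas <- function(bloodgas, samples) {
  pars <- setdiff(colnames(bloodgas),
                  c("subject_id", "time", "oxygenation"))
  out <- samples[, c("sample_id", "subject_id", "phase", "time_min")]
  for (p in pars) out[[p]] <- NA_real_
  out$clamped <- FALSE
  for (s in unique(samples$subject_id)) {
    bg <- bloodgas[bloodgas$subject_id == s, ]
    if (nrow(bg) < 2) stop("need >= 2 blood-gas samples for subject ", s)
    idx <- which(samples$subject_id == s)
    tt <- samples$time_min[idx]
    for (p in pars)
      out[[p]][idx] <- stats::approx(bg$time, bg[[p]], xout = tt,
                                     rule = 2)$y
    out$clamped[idx] <- tt < min(bg$time) | tt > max(bg$time)
  }
  out
}

#' @rdname interpolateBloodGas
#' @param x a [RamanSpectraSet-class] from [simulateStudy()] (uses the
#'   blood gas stored in its metadata).
#' @export
alignedClinicalTable <- function(x) {
  bg <- metadata(x)$bloodgas
  if (is.null(bg)) stop("no blood-gas table in metadata(x)")
  smp <- as.data.frame(colData(x))
  interpolateBloodGas(bg, smp)
}

#' Mann-Whitney U test with rank-biserial effect size
#'
#' U is taken as `min(U1, U2)` so that the rank-biserial effect size
#' `1 - 2U/(n1*n2)` lands in \[0, 1\] (0 = no group difference,
#' 1 = complete separation).  The p-value comes from
#' [stats::wilcox.test()]: exact when `n1*n2 <= 400` and the data are
#' tie-free, otherwise the two-sided normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y the two groups' values.
#' @return list of class `"UnivariateTestResult"`: `U`, `U1`, `n1`,
#'   `n2`, `p`, `effect_size`.
#' @export
mannWhitneyU <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(x, y))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U <- min(U1, n1 * n2 - U1)
  if (length(unique(c(x, y))) == 1L) {
    p <- 1
  } else {
    ties <- anyDuplicated(c(x, y)) > 0
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = (n1 * n2 <= 400) && !ties,
                         correct = TRUE)$p.value)
  }
  structure(list(U = U, U1 = U1, n1 = n1, n2 = n2, p = p,
                 effect_size = rankBiserial(U, n1, n2)),
            class = "UnivariateTestResult")
}

#' Rank-biserial effect size from a Mann-Whitney U statistic
#'
#' `1 - 2*min(U, n1*n2 - U) / (n1*n2)`: 0 for no group difference
#' (U at its null mean), 1 for complete separation (U = 0).
#'
#' @param U the U statistic, `0 <= U <= n1*n2` (either orientation).
#' @param n1,n2 group sizes.
#' @return value in \[0, 1\].
#' @examples
#' rankBiserial(0, 3, 3)    # 1
#' rankBiserial(25, 10, 10) # 0.5
#' @export
rankBiserial <- function(U, n1, n2) {
  if (U < 0 || U > n1 * n2) stop("U out of [0, n1*n2]")
  Umin <- min(U, n1 * n2 - U)
  1 - 2 * Umin / (n1 * n2)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values, with the two-sided
#' p-value from the t approximation on `n - 2` degrees of freedom (via
#' [stats::cor.test()]).
#'
#' @param x,y paired values, `length >= 3`.
#' @return list: `rho`, `p`.
#' @export
spearmanRho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0)
    stop("zero rank variance: correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE,
                    continuity = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Clinical cut-off classification
#'
#' Classifies spectra as positive (asphyxia) by a strict single-parameter
#' threshold — the clinical rules are `pH < 7.20` and `lactate > 4.8` mM
#' — and reports the confusion-matrix figures of merit, with AUROC
#' computed from the continuous parameter oriented by the rule's
#' direction.
#'
#' @param table aligned clinical table ([interpolateBloodGas()]),
#'   already restricted to the two phases of the problem.
#' @param parameter column to threshold (`"pH"` or `"lactate"`).
#' @param threshold cut-off value.
#' @param direction `"below"` (value < threshold is positive) or
#'   `"above"`.
#' @param positive_phases phase labels counting as true positives
#'   (e.g. `"HI"`).
#' @return list: `pred` (logical, positive per row), `metrics` (one-row
#'   `data.frame` as in [binaryMetrics()]).
#' @export
cutoffClassify <- function(table, parameter = c("pH", "lactate"),
                           threshold = NULL,
                           direction = NULL,
                           positive_phases = "HI") {
  parameter <- match.arg(parameter)
  if (!parameter %in% colnames(table))
    stop("missing parameter column: ", parameter)
  if (is.null(threshold))
    threshold <- if (parameter == "pH") 7.20 else 4.8
  if (is.null(direction))
    direction <- if (parameter == "pH") "below" else "above"
  v <- table[[parameter]]
  pred <- if (direction == "below") v < threshold else v > threshold
  truth <- ifelse(as.character(table$phase) %in% positive_phases,
                  "pos", "neg")
  score <- if (direction == "below") -v else v
  if (length(unique(truth)) == 2) {
    metrics <- binaryMetrics(truth, ifelse(pred, "pos", "neg"),
                             scores = score, positive = "pos")
  } else {
    # degenerate table (one phase only): report what is defined
    isPos <- truth == "pos"
    metrics <- data.frame(
      sensitivity = if (any(isPos)) 100 * mean(pred[isPos]) else NA_real_,
      specificity = if (any(!isPos)) 100 * mean(!pred[!isPos])
                    else NA_real_,
      accuracy = 100 * mean(pred == isPos),
      balanced_accuracy = NA_real_, auroc = NA_real_)
  }
  list(pred = pred, metrics = metrics)
}

#' Univariate phase statistics for every blood-gas parameter
#'
#' For each of the eight parameters: Mann-Whitney U with rank-biserial
#' effect size for BC vs HI and BC vs HIp, and Spearman correlation
#' against the ordinal clinical state (BC = 0, HI = 1, HIp = 2).
#' Significant p-values (< `alpha`) are starred.
#'
#' @param table aligned clinical table ([alignedClinicalTable()]).
#' @param alpha significance-flag threshold.
#' @return list: `tests` (`data.frame`: parameter, comparison, U, n1,
#'   n2, p, effect_size, flag), `spearman` (`data.frame`: parameter,
#'   rho, p, flag).
#' @export
phaseStatistics <- function(table, alpha = 0.05) {
  pars <- intersect(c("pH", "pCO2", "pO2", "SO2", "BE", "HCO3", "TCO2",
                      "lactate"), colnames(table))
  ph <- as.character(table$phase)
  state <- c(BC = 0, HI = 1, HIp = 2)[ph]
  tests <- list(); spear <- list()
  for (p in pars) {
    for (cmp in c("HI", "HIp")) {
      mw <- mannWhitneyU(table[[p]][ph == "BC"], table[[p]][ph == cmp])
      tests[[paste(p, cmp)]] <- data.frame(
        parameter = p, comparison = paste0("BC_vs_", cmp),
        U = mw$U, n1 = mw$n1, n2 = mw$n2, p_value = mw$p,
        effect_size = mw$effect_size,
        flag = ifelse(mw$p < alpha, "*", ""),
        stringsAsFactors = FALSE)
    }
    sr <- spearmanRho(table[[p]], state)
    spear[[p]] <- data.frame(parameter = p, rho = sr$rho, p_value = sr$p,
                             flag = ifelse(sr$p < alpha, "*", ""),
                             stringsAsFactors = FALSE)
  }
  list(tests = do.call(rbind, c(tests, make.row.names = FALSE)),
       spearman = do.call(rbind, c(spear, make.row.names = FALSE)))
}
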