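#' Model builders for cross-validation
#'
#' A builder is a `function(X, labels)` returning a fitted model that
#' [predictModel()] (and optionally [scoreModel()]) understands.
#' `plsdaBuilder(A)` gives direct PLS-DA; `hybridBuilder(A1, base, seed)`
#' the two-stage hybrid scheme; `classifierBuilder(spec)` a bare base
#' classifier on the raw features.
#'
#' @param A,A1 PLS component counts.
#' @param base,spec a [classifierSpec()].
#' @param seed adapter seed.
#' @return a builder function.
#' @export
plsdaBuilder <- function(A) {
  force(A)
  function(X, labels) plsdaFit(X, labels, A)
}

#' @rdname plsdaBuilder
#' @export
hybridBuilder <- function(A1, base = classifierSpec("svm"), seed = 1L) {
  force(A1); force(base); force(seed)
  function(X, labels) hybridFit(X, labels, A1, base, seed)
}

#' @rdname plsdaBuilder
#' @export
classifierBuilder <- function(spec) {
  force(spec)
  function(X, labels) fitClassifier(spec, X, labels)
}

#' Predict labels / per-class scores from any fitted model
#'
#' S3 dispatch over the package's model classes
#' (`"DiscriminantModel"`, `"HybridModel"`, `"BaseClassifier"`).
#'
#' @param model a fitted model.
#' @param X samples x features matrix.
#' @return `predictModel`: character labels; `scoreModel`: samples x
#'   classes numeric matrix.
#' @export
predictModel <- function(model, X) UseMethod("predictModel")

#' @export
predictModel.DiscriminantModel <- function(model, X) plsdaPredict(model, X)

#' @export
predictModel.HybridModel <- function(model, X) hybridPredict(model, X)

#' @export
predictModel.BaseClassifier <- function(model, X) classifierPredict(model, X)

#' @rdname predictModel
#' @export
scoreModel <- function(model, X) UseMethod("scoreModel")

#' @export
scoreModel.DiscriminantModel <- function(model, X) plsdaScores(model, X)

#' @export
scoreModel.HybridModel <- function(model, X) hybridScores(model, X)

#' @export
scoreModel.BaseClassifier <- function(model, X) classifierScores(model, X)

#' Leave-one-subject-out fold plan
#'
#' One fold per subject (sorted subject ids): the fold's test set is all
#' of that subject's samples, the training set everything else.  Test
#' sets are disjoint and exhaustive; no subject ever appears on both
#' sides of a fold.
#'
#' @param subject_ids per-sample subject identifiers (>= 2 distinct).
#' @return list of class `"FoldPlan"`; each element has `subject`,
#'   `train` and `test` (sample indices).
#' @export
losocvFolds <- function(subject_ids) {
  subject_ids <- as.character(subject_ids)
  subj <- sort(unique(subject_ids))
  if (length(subj) < 2) stop("need >= 2 subjects for LOSOCV")
  plan <- lapply(subj, function(s)
    list(subject = s,
         train = which(subject_ids != s),
         test = which(subject_ids == s)))
  structure(plan, class = "FoldPlan")
}

#' Cross-validate a model over a subject-wise fold plan
#'
#' Fits the builder on each fold's training samples and predicts its
#' held-out subject, so every sample receives exactly one out-of-fold
#' prediction; figures of merit are computed on the pooled predictions
#' (per-fold accuracies are also reported).  A fold whose training set
#' contains a single class is skipped with a report entry (its samples
#' get `NA` predictions).
#'
#' @param X samples x features matrix.
#' @param labels class labels.
#' @param subject_ids per-sample subject ids (or a ready `"FoldPlan"`).
#' @param builder see [plsdaBuilder()].
#' @param seed seed set before each fold's fit.
#' @param positive positive-class label for binary metrics; default the
#'   non-`"BC"` class when exactly two classes are present.
#' @return list: `pred` (pooled out-of-fold labels), `scores` (pooled
#'   per-class score matrix, if the model provides scores), `metrics`
#'   (one-row `data.frame`, see [binaryMetrics()] /
#'   [multiclassMetrics()]), `per_fold`, `skipped`.
#' @export
crossValidate <- function(X, labels, subject_ids, builder, seed = 1L,
                          positive = NULL) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  plan <- if (inherits(subject_ids, "FoldPlan")) subject_ids
          else losocvFolds(subject_ids)
  classes <- sort(unique(labels))
  pred <- rep(NA_character_, nrow(X))
  scores <- matrix(NA_real_, nrow(X), length(classes),
                   dimnames = list(NULL, classes))
  haveScores <- TRUE
  per_fold <- list(); skipped <- character()
  for (f in plan) {
    stopifnot(length(intersect(f$train, f$test)) == 0)   # no leakage
    ytr <- labels[f$train]
    if (length(unique(ytr)) < 2) {
      skipped <- c(skipped, f$subject)
      next
    }
    set.seed(seed)
    m <- builder(X[f$train, , drop = FALSE], ytr)
    pred[f$test] <- predictModel(m, X[f$test, , drop = FALSE])
    sc <- tryCatch(scoreModel(m, X[f$test, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(sc) || !all(classes %in% colnames(sc))) haveScores <- FALSE
    else scores[f$test, ] <- sc[, classes, drop = FALSE]
    per_fold[[f$subject]] <- data.frame(
      subject = f$subject, n = length(f$test),
      accuracy = 100 * mean(pred[f$test] == labels[f$test]),
      stringsAsFactors = FALSE)
  }
  ok <- !is.na(pred)
  if (length(unique(labels[ok])) < 2) {
    metrics <- data.frame(sensitivity = NA_real_, specificity = NA_real_,
                          accuracy = NA_real_,
                          balanced_accuracy = NA_real_, auroc = NA_real_)
  } else if (length(classes) == 2) {
    pos <- if (!is.null(positive)) positive
           else if ("BC" %in% classes) setdiff(classes, "BC") else classes[2]
    sc <- if (haveScores) scores[ok, pos] else NULL
    metrics <- binaryMetrics(labels[ok], pred[ok], scores = sc,
                             positive = pos)
  } else {
    metrics <- multiclassMetrics(labels[ok], pred[ok], classes)
  }
  list(pred = pred, scores = if (haveScores) scores else NULL,
       metrics = metrics,
       per_fold = do.call(rbind, per_fold), skipped = skipped)
}

.auroc <- function(scores, truth_pos) {
  n1 <- sum(truth_pos); n2 <- sum(!truth_pos)
  r <- rank(scores)
  (sum(r[truth_pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Binary figures of merit
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy,
#' balanced accuracy `(sens+spec)/2`, and (when continuous scores are
#' given) AUROC computed by the rank (concordant-pair) formula with ties
#' counted 1/2.  All reported in percent.
#'
#' @param y_true,y_pred true and predicted labels (both classes must be
#'   present in `y_true`).
#' @param scores optional numeric scores oriented so larger means more
#'   positive.
#' @param positive positive-class label.
#' @return one-row `data.frame`: `sensitivity`, `specificity`,
#'   `accuracy`, `balanced_accuracy`, `auroc` (NA without scores), with
#'   the confusion matrix in attribute `"confusion"`.
#' @export
binaryMetrics <- function(y_true, y_pred, scores = NULL, positive) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  isPos <- y_true == positive
  if (!any(isPos) || all(isPos))
    stop("both classes must be present in y_true")
  predPos <- y_pred == positive
  tp <- sum(isPos & predPos); fn <- sum(isPos & !predPos)
  tn <- sum(!isPos & !predPos); fp <- sum(!isPos & predPos)
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  out <- data.frame(
    sensitivity = sens, specificity = spec,
    accuracy = 100 * (tp + tn) / length(y_true),
    balanced_accuracy = (sens + spec) / 2,
    auroc = if (is.null(scores)) NA_real_
            else 100 * .auroc(scores, isPos))
  attr(out, "confusion") <- matrix(c(tp, fn, fp, tn), 2, 2,
    dimnames = list(truth = c(positive, "other"),
                    pred = c(positive, "other")))
  out
}

#' Multiclass figures of merit
#'
#' Accuracy is the confusion-matrix trace over the total; sensitivity
#' and specificity are one-vs-rest per class, macro-averaged; balanced
#' accuracy is the macro-averaged sensitivity.  All in percent.
#'
#' @param y_true,y_pred true and predicted labels.
#' @param classes class list; default the sorted classes present in
#'   `y_true`.
#' @return one-row `data.frame` (`sensitivity`, `specificity`,
#'   `accuracy`, `balanced_accuracy`, `auroc = NA`) with per-class rates
#'   in attribute `"per_class"` and the confusion matrix in
#'   `"confusion"`.
#' @export
multiclassMetrics <- function(y_true, y_pred,
                              classes = sort(unique(as.character(y_true)))) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (!all(y_true %in% classes) || !all(y_pred %in% classes))
    stop("labels outside the class list")
  cm <- table(factor(y_true, classes), factor(y_pred, classes))
  sens <- spec <- numeric(length(classes))
  for (i in seq_along(classes)) {
    isPos <- y_true == classes[i]; predPos <- y_pred == classes[i]
    sens[i] <- 100 * sum(isPos & predPos) / sum(isPos)
    spec[i] <- 100 * sum(!isPos & !predPos) / sum(!isPos)
  }
  out <- data.frame(
    sensitivity = mean(sens), specificity = mean(spec),
    accuracy = 100 * sum(diag(cm)) / length(y_true),
    balanced_accuracy = mean(sens),
    auroc = NA_real_)
  attr(out, "per_class") <- data.frame(class = classes,
                                       sensitivity = sens,
                                       specificity = spec)
  attr(out, "confusion") <- cm
  out
}

#' Permutation feature importance
#'
#' For every feature, the mean decrease in accuracy (percentage points)
#' when that single feature is randomly shuffled, averaged over
#' `n_repeats` independent shuffles; a constant feature scores exactly 0
#' because shuffling it is the identity.
#'
#' @param model fitted model ([predictModel()] dispatch).
#' @param X samples x features matrix.
#' @param y true labels.
#' @param n_repeats shuffles per feature (>= 1).
#' @param seed RNG seed.
#' @param feature_names optional names for the output (default column
#'   names of `X`, else indices).
#' @return `data.frame` of class `"ImportanceProfile"`: `feature`,
#'   `importance` (mean accuracy decrease, percentage points), `sd`
#'   (over repeats); baseline accuracy (%) in attribute `"baseline"`.
#' @export
permutationImportance <- function(model, X, y, n_repeats = 10, seed = 1L,
                                  feature_names = NULL) {
  stopifnot(n_repeats >= 1)
  X <- as.matrix(X); y <- as.character(y)
  set.seed(seed)
  base <- mean(predictModel(model, X) == y)
  p <- ncol(X)
  if (is.null(feature_names))
    feature_names <- colnames(X) %||% as.character(seq_len(p))
  imp <- sdv <- numeric(p)
  n <- nrow(X)
  for (j in seq_len(p)) {
    if (length(unique(X[, j])) == 1L) next   # shuffle is the identity
    drops <- vapply(seq_len(n_repeats), function(r) {
      Xp <- X
      Xp[, j] <- X[sample.int(n), j]
      base - mean(predictModel(model, Xp) == y)
    }, numeric(1))
    imp[j] <- 100 * mean(drops)
    sdv[j] <- 100 * stats::sd(drops)
  }
  structure(data.frame(feature = feature_names, importance = imp,
                       sd = sdv, stringsAsFactors = FALSE),
            class = c("ImportanceProfile", "data.frame"),
            baseline = 100 * base, n_repeats = n_repeats, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subject-averaged learning curve
#'
#' For every validation subject and every training-set size
#' `k = 1..S-1`, the model is trained on subsets of `k` of the other
#' subjects — all `choose(S-1, k)` subsets, or `max_draws` uniformly
#' sampled ones when the count exceeds the cap — and its error rate on
#' the validation subject is averaged; the curve reports, per `k`, the
#' mean and standard error of those per-subject averages across
#' subjects.
#'
#' @param X samples x features matrix.
#' @param labels class labels.
#' @param subject_ids per-sample subject ids (>= 3 subjects).
#' @param builder see [plsdaBuilder()].
#' @param max_draws cap on subsets per (subject, k).
#' @param seed RNG seed (subset sampling).
#' @param k_values which training-set sizes to evaluate; default all of
#'   `1..S-1`.
#' @return `data.frame` of class `"LearningCurveResult"`: `k`,
#'   `mean_error` (%), `se` (%), `n_draws`.
#' @export
learningCurve <- function(X, labels, subject_ids, builder,
                          max_draws = 100, seed = 1L, k_values = NULL) {
  X <- as.matrix(X); labels <- as.character(labels)
  subject_ids <- as.character(subject_ids)
  subj <- sort(unique(subject_ids))
  S <- length(subj)
  stopifnot(S >= 3)
  if (is.null(k_values)) k_values <- seq_len(S - 1)
  set.seed(seed)
  rows <- list()
  for (k in k_values) {
    perSubj <- rep(NA_real_, S); draws <- 0L
    for (vi in seq_len(S)) {
      v <- subj[vi]
      others <- setdiff(subj, v)
      nsub <- choose(length(others), k)
      sets <- if (nsub <= max_draws) {
        utils::combn(others, k, simplify = FALSE)
      } else {
        lapply(seq_len(max_draws), function(i) sample(others, k))
      }
      errs <- vapply(sets, function(tr) {
        idx <- subject_ids %in% tr
        if (length(unique(labels[idx])) < 2) return(NA_real_)
        m <- builder(X[idx, , drop = FALSE], labels[idx])
        vidx <- subject_ids == v
        mean(predictModel(m, X[vidx, , drop = FALSE]) != labels[vidx])
      }, numeric(1))
      perSubj[vi] <- mean(errs, na.rm = TRUE)
      draws <- draws + sum(!is.na(errs))
    }
    rows[[as.character(k)]] <- data.frame(
      k = k, mean_error = 100 * mean(perSubj),
      se = 100 * stats::sd(perSubj) / sqrt(S), n_draws = draws)
  }
  structure(do.call(rbind, rows),
            class = c("LearningCurveResult", "data.frame"))
}
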