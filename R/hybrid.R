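#' Base-classifier specification
#'
#' Adapter contract for the classifier applied in the 2-component latent
#' plane of a hybrid model (or directly on any point set).  Supported
#' algorithms: `"plsda"` (this package), `"rf"` (randomForest), `"svm"`
#' (e1071, radial kernel), `"gb"` (gradient boosting via xgboost
#' configured as plain unregularized boosting: exact greedy trees, no
#' row/column subsampling, `lambda = 0`), `"xgb"` (xgboost defaults).
#' Every adapter is deterministic given `seed`.
#'
#' @param algorithm one of `"plsda"`, `"rf"`, `"svm"`, `"gb"`, `"xgb"`.
#' @param params named list of hyperparameters overriding the adapter
#'   defaults (`ntree`, `cost`, `gamma`, `nrounds`, `max_depth`, `eta`).
#' @param seed integer seed handed to the stochastic adapters.
#' @return list of class `"ClassifierSpec"`.
#' @export
classifierSpec <- function(algorithm = c("plsda", "rf", "svm", "gb",
                                         "xgb"),
                           params = list(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  structure(list(algorithm = algorithm, params = params,
                 seed = as.integer(seed)),
            class = "ClassifierSpec")
}

.param <- function(spec, name, default) {
  if (!is.null(spec$params[[name]])) spec$params[[name]] else default
}

#' Fit a base classifier on a point set
#'
#' @param spec a [classifierSpec()].
#' @param X samples x features matrix.
#' @param labels class labels.
#' @return list of class `"BaseClassifier"` with the fitted object,
#'   `classes` and the spec.
#' @export
fitClassifier <- function(spec, X, labels) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need >= 2 classes")
  set.seed(spec$seed)
  fit <- switch(
    spec$algorithm,
    plsda = plsdaFit(X, labels, A = min(2, ncol(X))),
    rf = randomForest::randomForest(
      x = X, y = factor(labels, levels = classes),
      ntree = .param(spec, "ntree", 500)),
    svm = e1071::svm(
      x = X, y = factor(labels, levels = classes),
      kernel = "radial",
      cost = .param(spec, "cost", 1),
      gamma = .param(spec, "gamma", 1 / ncol(X)),
      probability = TRUE),
    gb = ,
    xgb = {
      yi <- match(labels, classes) - 1L
      binary <- length(classes) == 2
      par <- list(nthread = 1, seed = spec$seed,
                  max_depth = .param(spec, "max_depth", 3),
                  eta = .param(spec, "eta",
                               if (spec$algorithm == "gb") 0.1 else 0.3))
      if (spec$algorithm == "gb")
        par <- c(par, list(lambda = 0, alpha = 0, subsample = 1,
                           colsample_bytree = 1, tree_method = "exact"))
      if (binary) {
        par$objective <- "binary:logistic"
      } else {
        par$objective <- "multi:softprob"
        par$num_class <- length(classes)
      }
      xgboost::xgb.train(
        params = par,
        data = xgboost::xgb.DMatrix(X, label = yi),
        nrounds = .param(spec, "nrounds", 100), verbose = 0)
    })
  structure(list(fit = fit, classes = classes, spec = spec),
            class = "BaseClassifier")
}

#' Per-class scores from a fitted base classifier
#'
#' @param object a `"BaseClassifier"`.
#' @param X samples x features matrix.
#' @return samples x classes numeric matrix (class-indicator
#'   predictions, vote fractions, probabilities or decision scores,
#'   depending on the adapter); columns named by class.
#' @export
classifierScores <- function(object, X) {
  X <- rbind(as.matrix(X))
  cls <- object$classes
  S <- switch(
    object$spec$algorithm,
    plsda = plsdaScores(object$fit, X),
    rf = {
      p <- stats::predict(object$fit, X, type = "prob")
      p[, cls, drop = FALSE]
    },
    svm = {
      p <- attr(stats::predict(object$fit, X, probability = TRUE),
                "probabilities")
      p[, cls, drop = FALSE]
    },
    gb = ,
    xgb = {
      p <- stats::predict(object$fit, xgboost::xgb.DMatrix(X))
      if (length(cls) == 2) cbind(1 - p, p) else p
    })
  S <- rbind(S)
  colnames(S) <- cls
  S
}

#' Predict labels from a fitted base classifier
#'
#' @inheritParams classifierScores
#' @return character vector of predicted labels.
#' @export
classifierPredict <- function(object, X) {
  S <- classifierScores(object, X)
  object$classes[max.col(S, ties.method = "first")]
}

#' Hybrid PLS + classifier model
#'
#' The two-stage latent scheme: PLS with `A1` components is fitted on `X`
#' against the class-indicator matrix; a second PLS with 2 components is
#' fitted on the stage-1 scores against the same indicators, so that the
#' class structure is captured in a 2-D latent plane; the base classifier
#' is then fitted on those 2-D points.  Prediction composes the two
#' projections and the classifier.
#'
#' @param X samples x features matrix.
#' @param labels class labels.
#' @param A1 stage-1 component count (>= 2).
#' @param base a [classifierSpec()].
#' @param seed seed forwarded to the base adapter (overrides the spec's).
#' @return list of class `"HybridModel"`: `stage1`, `stage2`
#'   (`"PLSModel"`s), `base` (`"BaseClassifier"`), `classes`, `points`
#'   (training 2-D scores).
#' @export
hybridFit <- function(X, labels, A1, base = classifierSpec("svm"),
                      seed = NULL) {
  stopifnot(A1 >= 2)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  Y <- outer(labels, classes, `==`) * 1
  if (!is.null(seed)) base$seed <- as.integer(seed)
  stage1 <- plsFit(X, Y, A1)
  stage2 <- plsFit(stage1$T, Y, 2)
  pts <- stage2$T
  colnames(pts) <- c("LV1", "LV2")
  bc <- fitClassifier(base, pts, labels)
  structure(list(stage1 = stage1, stage2 = stage2, base = bc,
                 classes = classes, points = pts),
            class = "HybridModel")
}

#' @rdname hybridFit
#' @param model a `"HybridModel"`.
#' @param Xnew samples x features matrix.
#' @return `hybridTransform`: samples x 2 matrix of latent-plane
#'   coordinates.
#' @export
hybridTransform <- function(model, Xnew) {
  plsTransform(model$stage2, plsTransform(model$stage1, Xnew))
}

#' @rdname hybridFit
#' @return `hybridPredict`: character vector of predicted labels.
#' @export
hybridPredict <- function(model, Xnew) {
  classifierPredict(model$base, hybridTransform(model, Xnew))
}

#' @rdname hybridFit
#' @return `hybridScores`: samples x classes score matrix.
#' @export
hybridScores <- function(model, Xnew) {
  classifierScores(model$base, hybridTransform(model, Xnew))
}

#' Decision region of a hybrid model in the latent plane
#'
#' Evaluates the base classifier on a regular grid covering the 2-D
#' stage-2 plane, for decision-region plots.
#'
#' @param model a `"HybridModel"`.
#' @param bounds `list(x = c(lo, hi), y = c(lo, hi))`; default the range
#'   of the training scores padded by 10%.
#' @param resolution grid points per axis.
#' @return `data.frame` with `LV1`, `LV2`, `label`.
#' @export
decisionRegion <- function(model, bounds = NULL, resolution = 100) {
  if (is.null(bounds)) {
    pad <- function(r) r + c(-1, 1) * 0.1 * diff(r)
    bounds <- list(x = pad(range(model$points[, 1])),
                   y = pad(range(model$points[, 2])))
  }
  g <- expand.grid(
    LV1 = seq(bounds$x[1], bounds$x[2], length.out = resolution),
    LV2 = seq(bounds$y[1], bounds$y[2], length.out = resolution))
  g$label <- classifierPredict(model$base, as.matrix(g))
  g
}

#' Choose the stage-1 component count by LOSOCV balanced accuracy
#'
#' For every candidate `A`, runs leave-one-subject-out cross-validation
#' of the model (direct PLS-DA when `base` is `NULL`, otherwise the
#' hybrid scheme) and scores the pooled out-of-fold predictions by
#' balanced accuracy; returns the maximizer, ties going to the smallest
#' `A`.
#'
#' @param X samples x features matrix.
#' @param labels class labels.
#' @param subject_ids per-sample subject identifiers (fold grouping).
#' @param A_range candidate component counts.
#' @param base `NULL` or a [classifierSpec()].
#' @param seed seed for stochastic adapters.
#' @return list: `A` (selected), `scores` (named balanced accuracies, %).
#' @export
selectComponents <- function(X, labels, subject_ids, A_range,
                             base = NULL, seed = 1L) {
  stopifnot(length(A_range) >= 1)
  scores <- vapply(A_range, function(A) {
    builder <- if (is.null(base)) plsdaBuilder(A)
               else hybridBuilder(A, base, seed)
    cv <- crossValidate(X, labels, subject_ids, builder, seed = seed)
    cv$metrics$balanced_accuracy
  }, numeric(1))
  names(scores) <- A_range
  list(A = A_range[which.max(scores)], scores = scores)
}
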