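test_that("LOSOCV fold plans are disjoint, exhaustive and leakage-free", {
  subj <- rep(sprintf("P%d", 1:9), each = 7)
  plan <- losocvFolds(subj)
  expect_length(plan, 9)
  tests <- unlist(lapply(plan, `[[`, "test"))
  expect_setequal(tests, seq_along(subj))
  expect_equal(anyDuplicated(tests), 0)
  for (f in plan) {
    expect_length(intersect(f$train, f$test), 0)
    expect_false(f$subject %in% subj[f$train])
  }
  expect_error(losocvFolds(rep("solo", 5)), "2 subjects")
})

test_that("cross-validation pools one out-of-fold prediction per sample", {
  cl <- gaussClouds(n_per = 45, centers = list(c(-5, 0), c(5, 0)),
                    seed = 2, subjects_per_class = 5)
  cv <- crossValidate(cl$X, cl$y, cl$subjects, plsdaBuilder(2))
  expect_false(anyNA(cv$pred))
  expect_equal(cv$metrics$accuracy, 100)
  expect_equal(nrow(cv$per_fold), 5)
  # a fold whose training data is single-class is skipped with a note
  y1 <- c(rep("A", 30), rep("B", 30))
  X1 <- matrix(rnorm(120), ncol = 2)
  s1 <- c(rep("S1", 15), rep("S2", 15), rep("S3", 15), rep("S4", 15))
  # holding out S1 or S2 leaves pure-B or mixed training sets:
  y1[s1 %in% c("S1", "S2")] <- "A"; y1[s1 %in% c("S3", "S4")] <- "B"
  cv1 <- crossValidate(X1, y1, s1, plsdaBuilder(1))
  expect_length(cv1$skipped, 0)
  y2 <- rep("A", 60); y2[s1 == "S4"] <- "B"
  cv2 <- crossValidate(X1, y2, s1, plsdaBuilder(1))
  expect_equal(cv2$skipped, "S4")
  expect_true(all(is.na(cv2$pred[s1 == "S4"])))
  expect_true(is.na(cv2$metrics$accuracy))   # only class A left pooled
})

test_that("binary figures of merit match their confusion-matrix arithmetic", {
  y_true <- c(rep("HI", 10), rep("BC", 10))
  y_pred <- c(rep("HI", 9), "BC", rep("BC", 8), "HI", "HI")
  m <- binaryMetrics(y_true, y_pred, positive = "HI")
  expect_equal(m$sensitivity, 90)
  expect_equal(m$specificity, 80)
  expect_equal(m$accuracy, 85)
  expect_equal(m$balanced_accuracy, 85)
  # swapping the positive class swaps sensitivity and specificity
  m2 <- binaryMetrics(y_true, y_pred, positive = "BC")
  expect_equal(m2$sensitivity, m$specificity)
  expect_equal(m2$specificity, m$sensitivity)
  # perfectly ordered scores give AUROC 100
  sc <- c(11:20, 1:10)
  expect_equal(binaryMetrics(y_true, y_pred, sc, positive = "HI")$auroc,
               100)
  expect_error(binaryMetrics(rep("HI", 5), y_pred[1:5], positive = "HI"),
               "both classes")
})

test_that("rank-formula AUROC equals brute-force pair counting", {
  set.seed(3)
  for (n in c(20, 80, 300)) {
    y <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(y)) < 2) next
    sc <- round(rnorm(n), 1)     # rounding forces ties
    got <- binaryMetrics(ifelse(y, "pos", "neg"),
                         sample(c("pos", "neg"), n, TRUE),
                         scores = sc, positive = "pos")$auroc
    expect_equal(got, 100 * aurocBrute(sc, y), tolerance = 1e-12)
  }
})

test_that("multiclass metrics macro-average one-vs-rest rates", {
  expect_equal(multiclassMetrics(c("a", "b", "c"), c("a", "b", "c"))$accuracy,
               100)
  # confusion [[8,1,1],[2,7,1],[0,2,8]] by rows of truth a,b,c
  y_true <- rep(c("a", "b", "c"), each = 10)
  y_pred <- c(rep("a", 8), "b", "c",
              rep("a", 2), rep("b", 7), "c",
              rep("b", 2), rep("c", 8))
  m <- multiclassMetrics(y_true, y_pred)
  expect_equal(m$accuracy, 100 * 23 / 30, tolerance = 1e-10)
  sensBrute <- mean(c(8, 7, 8) / 10)
  specBrute <- mean(c(1 - 2 / 20, 1 - 3 / 20, 1 - 2 / 20))
  expect_equal(m$sensitivity, 100 * sensBrute, tolerance = 1e-10)
  expect_equal(m$specificity, 100 * specBrute, tolerance = 1e-10)
  # class order does not change macro metrics
  m2 <- multiclassMetrics(y_true, y_pred, classes = c("c", "a", "b"))
  expect_equal(m2$sensitivity, m$sensitivity)
  expect_equal(m2$specificity, m$specificity)
})

test_that("permutation importance finds planted features and respects seeds", {
  set.seed(4)
  n <- 150
  X <- matrix(rnorm(n * 20), ncol = 20)
  y <- ifelse(X[, 7] + rnorm(n, sd = 0.3) > 0, "hi", "lo")
  X <- cbind(X, const = 1)     # constant feature (centered away by PLS)
  m <- plsdaFit(X, y, A = 2)
  imp <- permutationImportance(m, X, y, n_repeats = 5, seed = 1)
  expect_equal(imp$importance[21], 0)       # constant: shuffle = identity
  expect_equal(which.max(imp$importance), 7L)
  imp2 <- permutationImportance(m, X, y, n_repeats = 5, seed = 1)
  expect_identical(imp, imp2)
  expect_gt(attr(imp, "baseline"), 80)
})

test_that("learning curves enumerate subsets and improve with more subjects", {
  cl <- gaussClouds(n_per = 60, centers = list(c(-4, 0), c(4, 0)),
                    sd = 1.2, seed = 5, subjects_per_class = 5)
  lc <- learningCurve(cl$X, cl$y, cl$subjects, plsdaBuilder(2),
                      max_draws = 100, seed = 1)
  expect_equal(lc$k, 1:4)
  # C(4, 2) = 6 subsets per validation subject, 5 subjects
  expect_equal(lc$n_draws[lc$k == 2], 6 * 5)
  expect_lte(lc$mean_error[lc$k == 4], lc$mean_error[lc$k == 1])
  expect_true(all(is.finite(lc$se)))
  # k = S-1 agrees with LOSOCV per-subject mean error
  cv <- crossValidate(cl$X, cl$y, cl$subjects, plsdaBuilder(2))
  expect_equal(lc$mean_error[lc$k == 4],
               mean(100 - cv$per_fold$accuracy), tolerance = 1e-10)
  # determinism under a fixed seed when sampling kicks in
  lcA <- learningCurve(cl$X, cl$y, cl$subjects, plsdaBuilder(2),
                       max_draws = 3, seed = 7, k_values = 2)
  lcB <- learningCurve(cl$X, cl$y, cl$subjects, plsdaBuilder(2),
                       max_draws = 3, seed = 7, k_values = 2)
  expect_identical(lcA, lcB)
})
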