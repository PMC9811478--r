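test_that("trimming keeps exactly the requested channels and is idempotent", {
  wn <- seq(100, 3000, by = 4)
  x <- RamanSpectraSet(matrix(rnorm(length(wn) * 3), ncol = 3), wn,
                       data.frame(sample_id = paste0("s", 1:3),
                                  subject_id = "A", phase = "BC",
                                  time_min = 1:3))
  tr <- trimSpectra(x, 535, 1717)
  expect_true(all(wavenumbers(tr) >= 535 & wavenumbers(tr) <= 1717))
  expect_equal(sum(wn >= 535 & wn <= 1717), nrow(tr))
  expect_equal(intensities(trimSpectra(tr, 535, 1717)), intensities(tr))
  expect_identical(as.data.frame(colData(tr)), as.data.frame(colData(x)))
  expect_error(trimSpectra(tr, 2000, 2100), "no channels")
})

test_that("EMSC recovers multiplicative and additive components", {
  x <- toySet(n = 5)
  r <- rowMeans(intensities(x))
  wn <- wavenumbers(x)
  u <- 2 * (wn - min(wn)) / diff(range(wn)) - 1
  # self-fit: reference spectrum passes through unchanged
  xr <- RamanSpectraSet(cbind(r, r), wn,
                        data.frame(sample_id = c("a", "b"),
                                   subject_id = "A", phase = "BC",
                                   time_min = 1:2))
  res <- emscCorrect(xr, reference = r)
  expect_equal(unname(res$b), c(1, 1), tolerance = 1e-10)
  expect_equal(max(abs(res$coef)), 0, tolerance = 1e-8)
  # constructed distortion: x = 2r + (0.3 + 0.1u) recovered exactly
  xd <- RamanSpectraSet(cbind(2 * r + 0.3 + 0.1 * u, r), wn,
                        data.frame(sample_id = c("a", "b"),
                                   subject_id = "A", phase = "BC",
                                   time_min = 1:2))
  res2 <- emscCorrect(xd, reference = r)
  expect_equal(unname(res2$b[1]), 2, tolerance = 1e-8)
  expect_equal(unname(intensities(res2$set)[, 1]), unname(r),
               tolerance = 1e-8)
  # least-squares optimality: residuals orthogonal to the design columns
  res3 <- emscCorrect(x)
  P <- RamanPhase:::.legendreBasis(u, 6)
  D <- cbind(res3$reference, P)
  fitted <- D %*% rbind(res3$b, res3$coef)
  resid <- intensities(x) - fitted
  expect_lt(max(abs(crossprod(D, resid))) / max(abs(intensities(x))),
            1e-8)
  # corrected spectra re-fit against r with unit slope
  res4 <- emscCorrect(res3$set, reference = res3$reference)
  expect_equal(unname(res4$b), rep(1, 5), tolerance = 1e-6)
})

test_that("ALS baseline solves the weighted Whittaker system and hugs the background", {
  # lambda -> 0: fit dominates, z -> y
  y <- rnorm(50)
  z0 <- alsBaseline(y, lambda = 1e-10, p = 0.5)
  expect_equal(as.numeric(z0), y, tolerance = 1e-6)
  # a gently curved quadratic without peaks is tracked closely (the
  # asymmetric weights sag under strong curvature, so fluorescence-like
  # dominantly-linear backgrounds are the regime ALS is meant for)
  t <- seq(0, 1, length.out = 500)
  q <- 3 + 2 * t - 0.2 * t^2
  zq <- alsBaseline(q, lambda = 1e5, p = 0.001)
  expect_lt(max(abs(zq - q)), 0.01 * diff(range(q)))
  # a positive peak does not drag the baseline up
  peak <- 5 * exp(-((t - 0.5) / 0.02)^2)
  zp <- alsBaseline(q + peak, lambda = 1e5, p = 0.001)
  under <- abs(t - 0.5) < 0.06
  expect_lt(max(abs(zp[under] - q[under])), 0.05 * diff(range(q + peak)))
  # fixed point satisfies the dense normal equations
  w <- attr(zp, "weights")
  n <- length(q)
  D <- diff(diag(n), differences = 2)
  A <- diag(w) + 1e5 * crossprod(D)
  zDense <- solve(A, w * (q + peak))
  expect_lt(max(abs(zDense - zp)) / max(abs(zp)), 1e-8)
})

test_that("Savitzky-Golay reproduces polynomials and damps noise", {
  x <- seq(0, 5, length.out = 80)
  cubic <- 1 - 2 * x + 0.5 * x^2 + 0.25 * x^3
  expect_equal(savgolSmooth(cubic), cubic, tolerance = 1e-10)
  expect_equal(savgolSmooth(rep(3, 40)), rep(3, 40), tolerance = 1e-12)
  set.seed(1)
  noise <- rnorm(500)
  expect_lt(var(savgolSmooth(noise)), var(noise))
  expect_error(savgolSmooth(rnorm(10), window = 15), "window")
  # matrix input smooths column-wise
  M <- cbind(cubic, cubic)
  expect_equal(savgolSmooth(M)[, 1], cubic, tolerance = 1e-10)
})

test_that("mean centering zeroes channel means and is reusable", {
  x <- toySet(n = 8)
  c1 <- meanCenter(x)
  expect_lt(max(abs(rowMeans(intensities(c1)))), 1e-12)
  # centering twice changes nothing more
  c2 <- meanCenter(c1)
  expect_equal(intensities(c2), intensities(c1), tolerance = 1e-12)
  # applying the stored mean reproduces the centered set
  c3 <- meanCenter(x, center = metadata(c1)$center)
  expect_equal(intensities(c3), intensities(c1))
})

test_that("PCA outlier filter flags planted spikes but spares inliers", {
  wn <- seq(535, 1715, by = 4)
  makeSubject <- function(seed, spike = FALSE) {
    set.seed(seed)
    base <- vapply(seq_len(60), function(i)
      5 * pseudoVoigt(wn, 1005, 12) + rnorm(length(wn), sd = 0.05),
      numeric(length(wn)))
    if (spike) base[150, 7] <- base[150, 7] + 20 * 0.05 * 20
    RamanSpectraSet(base, wn,
                    data.frame(sample_id = sprintf("s%d", 1:60),
                               subject_id = "A", phase = "BC",
                               time_min = 1:60))
  }
  hits <- vapply(1:25, function(s) {
    flt <- pcaOutlierFilter(makeSubject(s, spike = TRUE))
    flt$report$discarded[7]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  fp <- vapply(26:45, function(s) {
    flt <- pcaOutlierFilter(makeSubject(s))
    mean(flt$report$discarded)
  }, numeric(1))
  expect_lte(mean(fp), 0.10)
  # a duplicated inlier is flagged iff its original is
  x <- makeSubject(99)
  flt0 <- pcaOutlierFilter(x)
  pick <- which(!flt0$report$discarded)[1]
  dup <- RamanSpectraSet(cbind(intensities(x),
                               intensities(x)[, pick]),
                         wn,
                         rbind(as.data.frame(colData(x)),
                               data.frame(sample_id = "dup",
                                          subject_id = "A", phase = "BC",
                                          time_min = 61)))
  flt1 <- pcaOutlierFilter(dup)
  expect_equal(flt1$report$discarded[61], flt1$report$discarded[pick])
})

test_that("the full chain logs its stages, preserves metadata and sharpens class structure", {
  ds <- smallStudy()
  # identity configuration returns the input untouched
  id <- preprocessSpectra(ds, trim = NULL, emsc_order = NULL, als = NULL,
                          savgol = NULL, outlier = NULL, center = FALSE)
  expect_equal(intensities(id$set), intensities(ds))
  pp <- preprocessSpectra(ds)
  # grid preserved, retained samples keep their order and metadata
  expect_equal(wavenumbers(pp$set), wavenumbers(ds))
  kept <- colData(pp$set)$sample_id
  expect_identical(kept,
                   colData(ds)$sample_id[colData(ds)$sample_id %in% kept])
  # centering-last: zero channel means over retained samples
  expect_lt(max(abs(rowMeans(intensities(pp$set)))), 1e-10)
  # report lists limits and exactly the discarded ids per subject
  rep <- pp$outlier_report
  expect_setequal(setdiff(colData(ds)$sample_id, kept),
                  rep$sample_id[rep$discarded])
  expect_true(all(is.finite(rep$T2lim)))
  expect_equal(length(unique(rep$Qlim)), 3)   # one limit per subject
  # phase separability in the leading PCs improves with preprocessing
  skip_if_not_installed("cluster")
  sil <- function(set) {
    pc <- prcomp(t(intensities(set)), rank. = 2)
    mean(cluster::silhouette(as.integer(phases(set)),
                             dist(pc$x))[, "sil_width"])
  }
  expect_gt(sil(pp$set), sil(ds))
})
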