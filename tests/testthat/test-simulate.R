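test_that("timeline phases are contiguous with the documented durations", {
  cfg <- studyConfig(hi_sd_minutes = 0)
  tl <- simulateTimeline(cfg, "P1", seed = 1)
  expect_equal(tl$bc, c(0, 60))
  expect_equal(tl$hi, c(60, 109))
  expect_equal(tl$hip, c(109, 169))
  # determinism under a fixed seed
  expect_identical(tl, simulateTimeline(cfg, "P1", seed = 1))
  # truncation floor
  cfg2 <- studyConfig(hi_mean_minutes = 5, hi_min_minutes = 10,
                      hi_sd_minutes = 0)
  expect_equal(simulateTimeline(cfg2, "P1", seed = 1)$d, 10)
  # random durations never fall below the floor
  ds <- vapply(1:50, function(s)
    simulateTimeline(studyConfig(hi_sd_minutes = 40), "P", seed = s)$d,
    numeric(1))
  expect_true(all(ds >= 10))
})

test_that("blood-gas trajectories behave like the modelled insult", {
  cfg <- studyConfig(hi_sd_minutes = 0)
  tl <- simulateTimeline(cfg, "P1", seed = 1)
  st <- simulateBloodGas(tl, seq(0, 168), noise = FALSE)
  inHI <- st$time >= 60 & st$time < 109
  inBC <- st$time < 60
  inHIp <- st$time >= 109
  # lactate strictly non-decreasing during HI (noise-free construction)
  expect_true(all(diff(st$lactate[inHI]) >= 0))
  # end-point criteria reachable at the default 49-min insult
  expect_true(max(st$lactate) >= 12)
  expect_true(min(st$pH) <= 7)
  expect_true(min(st$BE) <= -15)
  # oxygenation recovers fast, metabolic parameters slowly
  expect_lt(abs(mean(st$SO2[inHIp]) - mean(st$SO2[inBC])) /
              mean(st$SO2[inBC]), 0.05)
  expect_gt(mean(st$lactate[inHIp]), mean(st$lactate[inBC]))
  # all emitted values inside the configured plausible ranges
  pp <- physioParams()
  stN <- simulateBloodGas(tl, seq(0, 168), noise = TRUE, seed = 4)
  for (i in seq_len(nrow(pp))) {
    v <- stN[[pp$name[i]]]
    expect_true(all(v >= pp$lo[i] & v <= pp$hi[i]), label = pp$name[i])
  }
})

test_that("rendered spectra carry the planted band structure", {
  wn <- seq(535, 1715, by = 4)
  bands <- ramanBands()
  state <- data.frame(lactate = 8, oxygenation = 0.5)
  # lactate-only spectrum peaks at the lactate band centers
  bl <- bands
  bl$amplitude[bl$driver != "lactate"] <- 0
  y <- renderSpectrum(state, wn, bl)
  locmax <- wn[which(diff(sign(diff(y))) == -2) + 1]
  centers <- bands$center[bands$driver == "lactate"]
  # every local maximum sits on the grid channel nearest a lactate band
  # (within half a 4 cm^-1 step) and every band produces one
  expect_true(all(vapply(locmax, function(m)
    min(abs(centers - m)) <= 2, logical(1))))
  expect_true(all(vapply(centers, function(cc)
    min(abs(locmax - cc)) <= 2, logical(1))))
  # doubling the gain doubles every intensity
  y1 <- renderSpectrum(state, wn, bands, gain = 1)
  y2 <- renderSpectrum(state, wn, bands, gain = 2)
  expect_equal(y2, 2 * y1, tolerance = 1e-12)
  # the default grid has 296 channels
  expect_length(wn, 296)
})

test_that("spike injection follows its rate and is seed-reproducible", {
  y <- rep(1, 100)
  r0 <- injectSpikes(y, 0, 5, seed = 1)
  expect_identical(r0$intensity, y)
  expect_false(r0$flagged)
  r1 <- injectSpikes(y, 1, 5, seed = 3)
  expect_true(r1$flagged)
  expect_equal(max(r1$intensity - y), 5)
  expect_equal(which.max(r1$intensity - y), r1$channel)
  expect_identical(r1, injectSpikes(y, 1, 5, seed = 3))
})

test_that("simulateStudy is deterministic and label-consistent", {
  ds <- smallStudy()
  ds2 <- simulateStudy(studyConfig(n_subjects = 3, seed = 11))
  expect_identical(intensities(ds), intensities(ds2))
  expect_identical(as.data.frame(colData(ds)), as.data.frame(colData(ds2)))
  # phase label equals the phase of the timestamp in the subject timeline
  tls <- metadata(ds)$truth$timelines
  cd <- as.data.frame(colData(ds))
  for (s in unique(cd$subject_id)) {
    rows <- cd[cd$subject_id == s, ]
    expect_equal(as.character(rows$phase),
                 phaseAt(tls[[s]], rows$time_min))
  }
  # blood gas at every 10th spectrum time
  bg <- metadata(ds)$bloodgas
  expect_true(all(bg$time %% 10 == 0))
  # different config -> different subject count
  expect_equal(length(unique(subjects(ds))), 3)
})

test_that("with artifacts off, the HI-BC difference spectrum peaks at driver bands", {
  cfg <- studyConfig(n_subjects = 2, seed = 5, noise_sd = 0,
                     baseline_amp = 0, gain_sd = 0, subject_gain_sd = 0,
                     spike_rate = 0)
  ds <- simulateStudy(cfg)
  X <- intensities(ds)
  ph <- as.character(phases(ds))
  dif <- abs(rowMeans(X[, ph == "HI"]) - rowMeans(X[, ph == "BC"]))
  wn <- wavenumbers(ds)
  bands <- ramanBands()
  moving <- bands$center[bands$driver %in% c("lactate", "oxyHb",
                                             "deoxyHb")]
  nearest <- unique(vapply(moving, function(cc)
    which.min(abs(wn - cc)), integer(1)))
  neighborhood <- unique(pmax(1, pmin(length(wn),
                                      c(nearest - 1, nearest,
                                        nearest + 1))))
  top <- order(dif, decreasing = TRUE)[1:10]
  expect_true(all(top %in% neighborhood))
})
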