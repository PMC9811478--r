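#' Configuration of a synthetic asphyxia study
#'
#' Bundles every knob of the generator.  Defaults reproduce the design of
#' the emulated piglet experiment: nine subjects, a 60-min basal (BC)
#' phase, a hypoxic-ischemic (HI) phase whose duration is drawn from
#' Normal(49, 15) minutes truncated below at 10 min, a 60-min
#' post-insult (HIp) phase, one spectrum per minute on a 535..1715 cm^-1
#' grid with 4 cm^-1 spacing (296 channels), and a blood-gas sample at
#' every 10th spectrum.
#'
#' @param n_subjects number of subjects.
#' @param bc_minutes,hip_minutes fixed durations of the BC and HIp phases
#'   (min).
#' @param hi_mean_minutes,hi_sd_minutes,hi_min_minutes mean, SD and lower
#'   truncation (min) of the HI-phase duration.
#' @param spectra_per_min acquisition rate (spectra per minute).
#' @param bloodgas_every one blood-gas sample per this many spectra.
#' @param grid_start,grid_stop,grid_step wavenumber grid (cm^-1).
#' @param noise_sd SD of additive white noise on each channel (intensity
#'   units; the planted band amplitudes are O(0.3-5)).
#' @param band_amp_sd log-scale SD of per-subject band-amplitude factors
#'   (each subject's tissue expresses each band a bit stronger or weaker
#'   — the between-subject heterogeneity that limits
#'   leave-one-subject-out performance on real data).
#' @param amp_jitter_sd log-scale SD of the per-spectrum, per-band
#'   amplitude jitter (probe repositioning between acquisitions).
#' @param baseline_amp overall scale of the polynomial fluorescence
#'   baseline (same units).
#' @param gain_sd,subject_gain_sd log-scale SDs of the per-spectrum and
#'   per-subject multiplicative gain (log-normal, median 1).
#' @param spike_rate probability that a spectrum carries one cosmic-spike
#'   artifact, in \[0, 1\].
#' @param spike_amplitude height of an injected spike (intensity units).
#' @param lactate_ref lactate concentration (mM) at which a lactate band
#'   has its base amplitude.
#' @param effect_scale named numeric: effect-size multipliers per driver
#'   (`lactate`, `oxyHb`, `deoxyHb`).  A band's amplitude is modulated as
#'   `amplitude * (1 + effect_scale * (m - 1))` where `m` is the raw
#'   physiological modulation (`lactate/lactate_ref`, oxygenation, or its
#'   complement); 1 means the full raw swing, smaller values damp the
#'   spectral expression of the physiological change toward the subtle
#'   in-vivo regime.
#' @param bands band model, see [ramanBands()].
#' @param physio physiological-parameter table, see [physioParams()].
#' @param seed integer master seed; the whole study is reproducible from
#'   it.
#'
#' @return A validated list of class `"StudyConfig"`.
#' @seealso [simulateStudy()]
#' @export
studyConfig <- function(n_subjects = 9,
                        bc_minutes = 60, hip_minutes = 60,
                        hi_mean_minutes = 49, hi_sd_minutes = 15,
                        hi_min_minutes = 10,
                        spectra_per_min = 1, bloodgas_every = 10,
                        grid_start = 535, grid_stop = 1715, grid_step = 4,
                        noise_sd = 0.05, baseline_amp = 2,
                        band_amp_sd = 0.3, amp_jitter_sd = 0.1,
                        gain_sd = 0.1, subject_gain_sd = 0.1,
                        spike_rate = 0.01, spike_amplitude = 5,
                        lactate_ref = 4,
                        effect_scale = c(lactate = 0.2, oxyHb = 0.35,
                                         deoxyHb = 0.35),
                        bands = ramanBands(),
                        physio = physioParams(),
                        seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              bc_minutes = bc_minutes, hip_minutes = hip_minutes,
              hi_mean_minutes = hi_mean_minutes,
              hi_sd_minutes = hi_sd_minutes,
              hi_min_minutes = hi_min_minutes,
              spectra_per_min = spectra_per_min,
              bloodgas_every = as.integer(bloodgas_every),
              grid_start = grid_start, grid_stop = grid_stop,
              grid_step = grid_step,
              noise_sd = noise_sd, baseline_amp = baseline_amp,
              band_amp_sd = band_amp_sd, amp_jitter_sd = amp_jitter_sd,
              gain_sd = gain_sd, subject_gain_sd = subject_gain_sd,
              spike_rate = spike_rate, spike_amplitude = spike_amplitude,
              lactate_ref = lactate_ref, effect_scale = effect_scale,
              bands = bands, physio = physio, seed = as.integer(seed))
  class(cfg) <- "StudyConfig"
  validateStudyConfig(cfg)
  cfg
}

#' @rdname studyConfig
#' @param config a `"StudyConfig"` list.
#' @export
validateStudyConfig <- function(config) {
  stopifnot(inherits(config, "StudyConfig"))
  with(config, {
    stopifnot(n_subjects >= 1,
              bc_minutes > 0, hip_minutes > 0,
              hi_mean_minutes > 0, hi_sd_minutes >= 0, hi_min_minutes > 0,
              spectra_per_min > 0, bloodgas_every >= 1,
              grid_start < grid_stop, grid_step > 0,
              noise_sd >= 0, baseline_amp >= 0,
              band_amp_sd >= 0, amp_jitter_sd >= 0,
              spike_rate >= 0, spike_rate <= 1,
              lactate_ref > 0,
              all(effect_scale >= 0),
              all(c("lactate", "oxyHb", "deoxyHb") %in%
                    names(effect_scale)))
    stopifnot(all(bands$center >= grid_start & bands$center <= grid_stop),
              all(bands$width > 0))
  })
  invisible(config)
}

#' Physiological parameter table
#'
#' Baseline and hypoxic-ischemic target values, response dynamics, and
#' plausible clamping ranges for the eight blood-gas parameters.  The
#' `driver` column selects which latent response each parameter follows:
#' `"slow"` parameters (lactate, pH, base excess, HCO3-, TCO2) track the
#' metabolic insult, rising/falling during HI with time constant
#' `tau_rise` and recovering slowly (`tau_slow`, ~45 min) after
#' re-ventilation; `"fast"` parameters (SO2, pO2, pCO2) track oxygenation
#' and CO2 administration, and relax back with the short `tau_fast`
#' (~2 min).  Ranges are the plausible-value clamps; units: pH unitless,
#' pCO2/pO2 mmHg, SO2 %, base excess mEq/L, HCO3-/TCO2 mmol/L, lactate
#' mM.
#'
#' @param tau_rise,tau_fast,tau_slow time constants in minutes (onset,
#'   fast oxygen recovery, slow metabolic recovery).
#' @return `data.frame` with one row per parameter: `name`, `base`,
#'   `hi_target`, `driver`, `lo`, `hi`, `meas_sd` (measurement noise SD),
#'   `subject_sd` (between-subject baseline SD), and the time constants.
#' @export
physioParams <- function(tau_rise = 15, tau_fast = 2, tau_slow = 45) {
  data.frame(
    name = c("pH", "pCO2", "pO2", "SO2", "BE", "HCO3", "TCO2", "lactate"),
    base = c(7.45, 40, 90, 97, 4, 25, 26, 1.5),
    hi_target = c(6.95, 72, 22, 20, -18, 13, 14, 13.5),
    driver = c("slow", "fast", "fast", "fast", "slow", "slow", "slow",
               "slow"),
    lo = c(6.88, 30.3, 14, 13, -20, 11.9, 13, 0.41),
    hi = c(7.55, 85, 608, 100, 13, 37.2, 39, 14.2),
    meas_sd = c(0.01, 1, 2, 0.5, 0.5, 0.4, 0.4, 0.15),
    subject_sd = c(0.02, 2, 5, 1, 1, 1, 1, 0.3),
    tau_rise = tau_rise, tau_fast = tau_fast, tau_slow = tau_slow,
    stringsAsFactors = FALSE)
}

#' Simulate one subject's phase timeline
#'
#' BC occupies `[0, bc)`, HI `[bc, bc + d)` and HIp
#' `[bc + d, bc + d + hip)` minutes, with the HI duration `d` drawn from
#' Normal(`hi_mean_minutes`, `hi_sd_minutes`) truncated below at
#' `hi_min_minutes`.
#'
#' @param config a [studyConfig()].
#' @param subject_id identifier stored in the timeline.
#' @param seed optional integer; if given, seeds the draw (otherwise the
#'   current RNG stream is used).
#' @return list of class `"SubjectTimeline"` with elements `subject_id`,
#'   `bc`, `hi`, `hip` (each `c(start, end)` in minutes) and `d`.
#' @examples
#' tl <- simulateTimeline(studyConfig(hi_sd_minutes = 0), "P1", seed = 1)
#' tl$hi   # c(60, 109)
#' @export
simulateTimeline <- function(config, subject_id, seed = NULL) {
  validateStudyConfig(config)
  if (!is.null(seed)) set.seed(seed)
  d <- stats::rnorm(1, config$hi_mean_minutes, config$hi_sd_minutes)
  d <- max(config$hi_min_minutes, round(d))
  tl <- list(subject_id = subject_id,
             bc = c(0, config$bc_minutes),
             hi = c(config$bc_minutes, config$bc_minutes + d),
             hip = c(config$bc_minutes + d,
                     config$bc_minutes + d + config$hip_minutes),
             d = d)
  class(tl) <- "SubjectTimeline"
  tl
}

#' Phase label at a time point
#'
#' @param timeline a `"SubjectTimeline"`.
#' @param t time(s) in minutes.
#' @return character vector of `"BC"`, `"HI"` or `"HIp"` (times at or
#'   beyond the end of HIp also map to `"HIp"`).
#' @export
phaseAt <- function(timeline, t) {
  ifelse(t < timeline$bc[2], "BC",
         ifelse(t < timeline$hi[2], "HI", "HIp"))
}

# Latent response drivers: s(t) rises towards 1 during HI and decays after
# it; the metabolic (slow) and oxygenation (fast) versions differ in their
# recovery time constants.  Monotone during HI by construction.
.driverCurve <- function(t, timeline, tau_up, tau_down) {
  t0 <- timeline$hi[1]; t1 <- timeline$hi[2]
  v <- numeric(length(t))
  inHI <- t >= t0 & t < t1
  post <- t >= t1
  v[inHI] <- 1 - exp(-(t[inHI] - t0) / tau_up)
  vEnd <- 1 - exp(-(t1 - t0) / tau_up)
  v[post] <- vEnd * exp(-(t[post] - t1) / tau_down)
  v
}

# Noise-free trajectories of the 8 parameters plus the latent oxygenation
# fraction; offsets is a named numeric of per-subject baseline shifts.
.physioState <- function(timeline, t, physio, offsets = NULL) {
  if (is.null(offsets)) {
    offsets <- stats::setNames(numeric(nrow(physio)), physio$name)
  }
  slow <- .driverCurve(t, timeline, physio$tau_rise[1], physio$tau_slow[1])
  fast <- .driverCurve(t, timeline, physio$tau_fast[1] * 2,
                       physio$tau_fast[1])
  out <- data.frame(time = t)
  for (i in seq_len(nrow(physio))) {
    p <- physio[i, ]
    drv <- if (p$driver == "slow") slow else fast
    v <- (p$base + offsets[[p$name]]) + (p$hi_target - p$base) * drv
    out[[p$name]] <- pmin(p$hi, pmax(p$lo, v))
  }
  out$oxygenation <- pmax(0, pmin(1, 1 - 0.85 * fast))
  out
}

#' Simulate blood-gas trajectories for one subject
#'
#' Evaluates the piecewise-smooth physiological model of [physioParams()]
#' at the requested times: during HI, lactate rises while pH, base
#' excess, HCO3- and TCO2 fall towards end-point territory; oxygenation
#' (SO2, pO2) collapses quickly and recovers quickly once ventilation is
#' restored, whereas the metabolic parameters recover slowly.  All values
#' are clamped to the plausible ranges.
#'
#' @param timeline a `"SubjectTimeline"`.
#' @param times sample times in minutes.
#' @param physio parameter table, see [physioParams()].
#' @param noise add i.i.d. measurement noise (`meas_sd` per parameter)?
#' @param offsets optional named numeric of per-subject baseline shifts
#'   (one per parameter); `NULL` means none.
#' @param seed optional integer seed for the noise draws.
#' @return `data.frame` with columns `time`, the 8 parameters, and the
#'   latent `oxygenation` fraction.
#' @export
simulateBloodGas <- function(timeline, times, physio = physioParams(),
                             noise = TRUE, offsets = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- .physioState(timeline, times, physio, offsets)
  if (noise) {
    for (i in seq_len(nrow(physio))) {
      p <- physio[i, ]
      v <- st[[p$name]] + stats::rnorm(nrow(st), 0, p$meas_sd)
      st[[p$name]] <- pmin(p$hi, pmax(p$lo, v))
    }
  }
  st
}

# Fluorescence baseline: polynomial with non-negative coefficients on the
# unit-rescaled axis, scaled by baseline_amp.
.fluorBaseline <- function(wn, coef, amp) {
  u <- (wn - min(wn)) / diff(range(wn))
  amp * drop(outer(u, seq_along(coef) - 1, `^`) %*% coef)
}

#' Render one Raman spectrum from a physiological state
#'
#' Intensity model:
#' `gain * (sum_bands ampEff * pseudoVoigt + baseline) + noise`.  Each
#' driven band's raw modulation `m` is `lactate / lactate_ref` (lactate
#' bands), the oxygenation fraction (oxyHb) or its complement (deoxyHb);
#' the effective amplitude is `amplitude * (1 + effect_scale*(m - 1))`,
#' so `effect_scale = 1` expresses the full physiological swing and
#' smaller values the subtler in-vivo contrast.  Protein/constant bands
#' keep their base amplitude.
#'
#' @param state one-row `data.frame` from [simulateBloodGas()] (needs
#'   `lactate` and `oxygenation`).
#' @param wn wavenumber grid (cm^-1).
#' @param bands band model ([ramanBands()]).
#' @param lactate_ref,effect_scale see [studyConfig()].
#' @param baseline_coef non-negative polynomial coefficients of the
#'   fluorescence baseline (constant term first); `NULL` for none.
#' @param baseline_amp baseline scale.
#' @param gain multiplicative gain.
#' @param noise_sd additive noise SD.
#' @param amp_factors optional per-band amplitude multipliers (length
#'   `nrow(bands)`), e.g. subject-level heterogeneity factors.
#' @param seed optional seed for the noise draw.
#' @return numeric intensity vector of `length(wn)`.
#' @export
renderSpectrum <- function(state, wn, bands = ramanBands(),
                           lactate_ref = 4,
                           effect_scale = c(lactate = 1, oxyHb = 1,
                                            deoxyHb = 1),
                           baseline_coef = NULL,
                           baseline_amp = 0, gain = 1, noise_sd = 0,
                           amp_factors = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(amp_factors)) amp_factors <- rep(1, nrow(bands))
  sig <- numeric(length(wn))
  for (i in seq_len(nrow(bands))) {
    b <- bands[i, ]
    m <- switch(b$driver,
                lactate = state$lactate / lactate_ref,
                oxyHb = state$oxygenation,
                deoxyHb = 1 - state$oxygenation,
                1)
    es <- if (b$driver %in% names(effect_scale))
      effect_scale[[b$driver]] else 1
    amp <- b$amplitude * (1 + es * (m - 1))
    sig <- sig + amp_factors[i] * amp *
      pseudoVoigt(wn, b$center, b$width, b$eta)
  }
  if (!is.null(baseline_coef))
    sig <- sig + .fluorBaseline(wn, baseline_coef, baseline_amp)
  y <- gain * sig
  if (noise_sd > 0) y <- y + stats::rnorm(length(wn), 0, noise_sd)
  y
}

#' Inject a cosmic-spike artifact
#'
#' With probability `spike_rate`, adds one narrow positive spike (one
#' channel at full `spike_amplitude`, plus half amplitude on a neighbor
#' channel when the spike is two channels wide) at a random position.
#'
#' @param y intensity vector.
#' @param spike_rate probability in \[0, 1\].
#' @param spike_amplitude spike height.
#' @param seed optional seed.
#' @return list with `intensity` (modified vector), `flagged` (logical)
#'   and `channel` (index or `NA`).
#' @export
injectSpikes <- function(y, spike_rate, spike_amplitude, seed = NULL) {
  stopifnot(spike_rate >= 0, spike_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  flagged <- spike_rate > 0 && stats::runif(1) < spike_rate
  channel <- NA_integer_
  if (flagged) {
    channel <- sample.int(length(y), 1)
    y[channel] <- y[channel] + spike_amplitude
    if (stats::runif(1) < 0.5) {     # two-channel spike
      nb <- if (channel < length(y)) channel + 1L else channel - 1L
      y[nb] <- y[nb] + spike_amplitude / 2
    }
  }
  list(intensity = y, flagged = flagged, channel = channel)
}

#' Simulate a complete synthetic study
#'
#' Draws, for every subject, a phase timeline, subject-level random
#' effects (physiological baseline shifts, gain, fluorescence shape), a
#' noise-free physiological state at every acquisition time, one rendered
#' spectrum per time point (with baseline, gain jitter, additive noise
#' and rare spike artifacts), and a noisy blood-gas sample at every
#' `bloodgas_every`-th spectrum.  The entire dataset is reproducible from
#' `config$seed`.
#'
#' @param config a [studyConfig()].
#' @return A [RamanSpectraSet-class] whose `colData` carries
#'   `sample_id`, `subject_id`, `phase`, `time_min` and the ground-truth
#'   `spike` flag, and whose `metadata()` holds `bloodgas` (the sparse
#'   noisy samples), `truth` (timelines, noise-free states, spike
#'   channels) and `config`.
#' @examples
#' ds <- simulateStudy(studyConfig(n_subjects = 2, seed = 7))
#' ds
#' @export
simulateStudy <- function(config = studyConfig()) {
  validateStudyConfig(config)
  set.seed(config$seed)
  wn <- seq(config$grid_start, config$grid_stop, by = config$grid_step)
  physio <- config$physio
  specs <- list(); cdat <- list(); bglist <- list()
  timelines <- list(); states <- list(); spikechan <- list()
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("P%d", s)
    tl <- simulateTimeline(config, sid)
    offsets <- stats::setNames(
      stats::rnorm(nrow(physio), 0, physio$subject_sd), physio$name)
    sgain <- exp(stats::rnorm(1, 0, config$subject_gain_sd))
    sband <- exp(stats::rnorm(nrow(config$bands), 0,
                              config$band_amp_sd))
    bcoef <- stats::runif(5, 0, 1) / (1:5)   # decaying positive poly
    dt <- 1 / config$spectra_per_min
    times <- seq(0, tl$hip[2] - dt, by = dt)
    st <- .physioState(tl, times, physio, offsets)
    n <- length(times)
    mat <- matrix(0, nrow = length(wn), ncol = n)
    spike <- logical(n); schan <- rep(NA_integer_, n)
    for (j in seq_len(n)) {
      gain <- sgain * exp(stats::rnorm(1, 0, config$gain_sd))
      jitter <- exp(stats::rnorm(nrow(config$bands), 0,
                                 config$amp_jitter_sd))
      y <- renderSpectrum(st[j, ], wn, config$bands, config$lactate_ref,
                          config$effect_scale,
                          baseline_coef = bcoef,
                          baseline_amp = config$baseline_amp,
                          gain = gain, noise_sd = config$noise_sd,
                          amp_factors = sband * jitter)
      sp <- injectSpikes(y, config$spike_rate, config$spike_amplitude)
      mat[, j] <- sp$intensity
      spike[j] <- sp$flagged; schan[j] <- sp$channel
    }
    bg_idx <- seq(1, n, by = config$bloodgas_every)
    bg <- simulateBloodGas(tl, times[bg_idx], physio, noise = TRUE,
                           offsets = offsets)
    bg <- cbind(subject_id = sid, bg)
    specs[[s]] <- mat
    cdat[[s]] <- data.frame(
      sample_id = sprintf("%s_t%03d", sid, seq_len(n) - 1L),
      subject_id = sid,
      phase = phaseAt(tl, times),
      time_min = times,
      spike = spike,
      stringsAsFactors = FALSE)
    bglist[[s]] <- bg
    timelines[[sid]] <- tl
    states[[sid]] <- st
    spikechan[[sid]] <- schan
  }
  RamanSpectraSet(
    intensity = do.call(cbind, specs),
    wavenumber = wn,
    sampleData = do.call(rbind, cdat),
    metadata = list(
      log = "simulate",
      bloodgas = do.call(rbind, bglist),
      truth = list(timelines = timelines, states = states,
                   spike_channels = spikechan),
      config = config))
}
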