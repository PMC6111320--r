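fs <- 1000

test_that("band power concentrates where the signal lives", {
  t <- (0:1999) / fs
  x <- detrend_normalize(sin(2 * pi * 10 * t))
  inband <- band_power(x, c(4, 13), fs)$value
  out <- band_power(x, c(25, 45), fs)$value
  expect_gt(inband, 0.9)        # z-scored sine: integrated power ~ 1, all in-band
  expect_lt(out / inband, 1e-6)
  # equal-amplitude 10 + 30 Hz mixture: equal band powers within 1%
  m <- detrend_normalize(sin(2 * pi * 10 * t) + sin(2 * pi * 30 * t))
  p1 <- band_power(m, c(4, 13), fs)$value
  p2 <- band_power(m, c(25, 45), fs)$value
  expect_equal(p2 / p1, 1, tolerance = 0.01)
  expect_error(band_power(x, c(4, 600), fs), "Nyquist")
})

test_that("white-noise band power is proportional to bandwidth (20/9)", {
  set.seed(31)
  nrep <- 400
  m <- matrix(rnorm(2000 * nrep), 2000)
  m <- detrend_normalize(m)
  gp <- stressmark:::band_power_matrix(m, c(25, 45), fs)
  tp <- stressmark:::band_power_matrix(m, c(4, 13), fs)
  # ratio of long-run average band powers converges to the bandwidth ratio
  expect_equal(mean(gp) / mean(tp), 20 / 9, tolerance = 0.03)
})

test_that("relative gamma is a scale-invariant power ratio", {
  set.seed(32)
  t <- (0:1999) / fs
  ep <- vapply(1:4, function(j) {
    sin(2 * pi * 10 * t + runif(1)) + sin(2 * pi * 30 * t + runif(1)) +
      0.05 * rnorm(2000)
  }, numeric(2000))
  rg <- compute_rg(detrend_normalize(ep), fs)
  expect_equal(rg, 1, tolerance = 0.05)   # equal-power mixture
  # amplitude scaling of the raw epoch leaves RG unchanged
  for (c in c(0.1, 3, 1000)) {
    expect_equal(compute_rg(detrend_normalize(c * ep), fs), rg,
                 tolerance = 1e-9)
  }
  # dominant gamma drives RG far above 1
  g <- vapply(1:4, function(j) sin(2 * pi * 30 * t) + 1e-3 * rnorm(2000),
              numeric(2000))
  expect_gt(compute_rg(detrend_normalize(g), fs), 100)
})

test_that("R-peak detection recovers programmed beat trains", {
  spec <- filter_preset("ecg", fs)
  make_train <- function(rate_hz, dur_s) {
    n <- dur_s * fs
    sig <- numeric(n)
    beats <- seq(0.5, dur_s - 0.5, by = 1 / rate_hz)
    idx <- round(beats * fs) + 1
    tt <- -40:40
    g <- exp(-(tt / fs)^2 / (2 * 0.012^2))
    for (k in seq_along(tt)) sig[idx + tt[k]] <- sig[idx + tt[k]] + g[k]
    list(sig = sig, beats = (idx - 1) / fs)
  }
  tr <- make_train(1, 60)
  pk <- detect_r_peaks(filter_zero_phase(tr$sig, spec), fs)
  expect_length(pk, length(tr$beats))
  expect_lt(max(abs(pk - tr$beats)), 0.010)          # within +-10 ms
  # 2 Hz train: mean detected rate 120 +- 1 bpm
  tr2 <- make_train(2, 60)
  pk2 <- detect_r_peaks(filter_zero_phase(tr2$sig, spec), fs)
  expect_equal(60 / mean(diff(pk2)), 120, tolerance = 1 / 120)
  # flat signal: no peaks
  expect_length(detect_r_peaks(rep(0, 20000), fs), 0)
})

test_that("heart rate follows HR = 60 / AvRR", {
  g <- build_epoch_grid(0, 10, 10)
  expect_equal(compute_hr(seq(0, 10, by = 1.0), g)$hr_bpm, 60)
  expect_equal(compute_hr(seq(0, 10, by = 0.8), g)$hr_bpm, 75)
  # alternating 0.6 / 1.0 s intervals: AvRR = 0.8 -> 75 bpm
  pk <- cumsum(c(0.1, rep(c(0.6, 1.0), 6)))
  out <- compute_hr(pk, g)
  expect_equal(out$avrr_s, 0.8)
  expect_equal(out$hr_bpm, 75)
  # epoch without any interval onset is missing
  g2 <- build_epoch_grid(0, 30, 10)
  out2 <- compute_hr(c(1, 2, 25, 26), g2)
  expect_true(is.na(out2$hr_bpm[2]))
  expect_false(anyNA(out2$hr_bpm[c(1, 3)]))
})

test_that("spline interpolation reproduces constants, lines and curves", {
  g10 <- build_epoch_grid(0, 120, 10)
  g2 <- build_epoch_grid(0, 120, 2)
  const <- data.frame(epoch_start_s = g10$epoch_starts, avrr_s = 60 / 72,
                      hr_bpm = 72)
  expect_equal(interpolate_hr(const, g2), rep(72, 60))
  lin <- const
  lin$hr_bpm <- seq(60, 90, length.out = 12)
  got <- interpolate_hr(lin, g2)
  mid10 <- g10$epoch_starts + 5
  mid2 <- pmin(pmax(g2$epoch_starts + 1, min(mid10)), max(mid10))
  want <- approx(mid10, lin$hr_bpm, xout = mid2)$y
  expect_equal(got, want, tolerance = 1e-9)
  # smooth sinusoidal profile: within 1 bpm of a dense-resampled oracle
  sine <- const
  sine$hr_bpm <- 75 + 10 * sin(2 * pi * mid10 / 120)
  got <- interpolate_hr(sine, g2)
  oracle <- spline(mid10, sine$hr_bpm, xout = mid2, method = "natural")$y
  expect_lt(max(abs(got - oracle)), 1e-9)
  expect_lt(max(abs(got - (75 + 10 * sin(2 * pi * mid2 / 120)))), 1)
  # sparse support: linear fallback, then error
  expect_equal(interpolate_hr(const[1:3, ], g2), rep(72, 60))
  expect_error(interpolate_hr(const[1, ], g2), "at least 2")
})

test_that("differential EMG subtracts lateral from medial", {
  x <- rnorm(100)
  expect_equal(differential_emg(x, x), rep(0, 100))
  expect_equal(differential_emg(x, numeric(100)), x)
  expect_equal(differential_emg(x, -x), 2 * x)
  expect_error(differential_emg(x, x[-1]), "length")
})

test_that("trapezius activity is the RMS ratio to the MVC reference", {
  t <- (0:1999) / fs
  mvc_seg <- 3 * sin(2 * pi * 80 * t)
  mvc <- rms(mvc_seg)
  expect_equal(compute_ta(mvc_seg, mvc), 1.0)
  expect_equal(compute_ta(0.5 * mvc_seg, mvc), 0.5)
  # sine amplitude a vs MVC sine amplitude b: TA = a/b
  expect_equal(compute_ta(1.2 * sin(2 * pi * 80 * t), mvc), 1.2 / 3,
               tolerance = 1e-12)
  expect_error(compute_ta(mvc_seg, 0), "positive")
})

test_that("skin conductance is affine in mean voltage with exact slope", {
  expect_equal(compute_sc(rep(0.5, 100)), 0)
  expect_equal(compute_sc(rep(1.0, 100)), 1e-5)
  expect_equal(compute_sc(rep(0.75, 100)), 5e-6)
  # slope exactly 2/100000 for arbitrary epochs
  set.seed(33)
  v <- runif(200, 0.6, 3)
  base <- compute_sc(v)
  expect_equal(compute_sc(v + 0.1) - base, 2 * 0.1 / 100000,
               tolerance = 1e-12)
  expect_warning(compute_sc(rep(0.2, 10)), "negative")
})

test_that("marker extraction yields 630 aligned epochs, deterministically", {
  p <- sim_params()
  s <- generate_session("S01", p, seed = 101)
  mk <- extract_markers(s)
  expect_s3_class(mk, "marker_set")
  expect_identical(nrow(mk), 630L)
  expect_false(anyNA(mk))
  expect_true(all(mk$rg > 0))
  expect_true(all(mk$ta >= 0))
  expect_identical(extract_markers(s), mk)     # deterministic pipeline
  # HR values are physiologically plausible on synthetic data
  expect_true(all(mk$hr > 20 & mk$hr < 250))
  # missing MVC window is a configuration error naming the marker
  tl <- unclass(s$timeline)
  tl["mvc_end"] <- tl["mvc_start"]
  s2 <- s
  s2$timeline <- event_timeline(tl)
  expect_error(extract_markers(s2), "mvc_start")
})

test_that("programmed heart rates are recovered within 1 bpm", {
  tl <- mini_timeline()
  for (rate in c(50, 70, 100, 140)) {
    p <- sim_params(timeline = tl, hr_range_bpm = c(rate, rate),
                    hr_jitter_bpm = 0)
    set.seed(40 + rate)
    ecg <- generate_modality("ecg", flat_profile(tl, 0.5), p)
    filt <- filter_zero_phase(ecg, filter_preset("ecg", fs))
    pk <- detect_r_peaks(filt, fs)
    hr <- compute_hr(pk, build_epoch_grid(10, 140, 10))
    expect_lt(max(abs(hr$hr_bpm - rate)), 1)
    # programmed beats are the oracle: detected times match them
    beats <- attr(ecg, "beat_times")
    expect_equal(length(pk), length(beats), tolerance = 0.01)
  }
})

test_that("programmed MVC fractions are recovered within 5%", {
  tl <- mini_timeline()
  for (frac in c(0.2, 0.5)) {
    p <- sim_params(timeline = tl, emg_frac_range = c(frac, frac))
    set.seed(50)
    emg <- generate_modality("emg", flat_profile(tl, 0.5), p)
    dif <- filter_zero_phase(differential_emg(emg[, 1], emg[, 2]),
                             filter_preset("emg", fs))
    mvc_rms <- rms(dif[(tl[["mvc_start"]] * fs + 1):(tl[["mvc_end"]] * fs)])
    em <- stressmark:::region_epoch_matrix(dif, fs, 60, 120, 2)
    ta <- sqrt(colMeans(em$m^2)) / mvc_rms
    expect_equal(mean(ta), frac, tolerance = 0.05)
  }
})

test_that("programmed gamma ratios are recovered from EEG epochs", {
  tl <- mini_timeline()
  p <- sim_params(timeline = tl, rg_range = c(2, 2), eeg_noise = 0,
                  eeg_pink = 0)
  set.seed(60)
  eeg <- generate_modality("eeg", flat_profile(tl, 0.3, "eeg"), p)
  em <- stressmark:::region_epoch_matrix(eeg[, 1], fs, 60, 120, 2)
  rgs <- vapply(seq_len(ncol(em$m)), function(i) {
    ep <- vapply(1:4, function(j) {
      stressmark:::region_epoch_matrix(eeg[, j], fs, 60, 120, 2)$m[, i]
    }, numeric(2000))
    compute_rg(detrend_normalize(ep), fs)
  }, numeric(1))
  expect_equal(mean(rgs), 2, tolerance = 0.05)
})
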