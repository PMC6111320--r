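#' Band power of an epoch via Hann-windowed periodogram
#'
#' The epoch is tapered with a Hann window and its one-sided periodogram
#' (power spectral density) is integrated over the frequency bins whose
#' centres fall in the half-open band `[low_hz, high_hz)`. With 2-s epochs at
#' 1000 samples/s the bin spacing is 0.5 Hz, so band power is proportional to
#' nominal bandwidth for a flat spectrum: the gamma (25-45 Hz) to
#' theta-alpha (4-13 Hz) ratio of white noise converges to 20/9.
#'
#' @param x Numeric epoch (one channel), typically detrended and z-scored.
#' @param band Numeric `c(low_hz, high_hz)`.
#' @param fs Sampling rate, samples/s.
#' @return List with `band` and non-negative `value` (integrated band power).
#' @export
band_power <- function(x, band, fs) {
  p <- band_power_matrix(as.matrix(x), band, fs)
  list(band = band, value = as.numeric(p))
}

# Vectorized core: columns of `m` are epochs (or channels); returns the
# integrated PSD over [low, high) per column.
band_power_matrix <- function(m, band, fs) {
  n <- nrow(m)
  if (band[1] < 0 || band[2] <= band[1]) stop("invalid band")
  if (band[2] > fs / 2) stop("band extends beyond the Nyquist frequency")
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  mw <- m * w
  X <- stats::mvfft(mw)
  df <- fs / n
  f <- (seq_len(n) - 1) * df
  keep <- f >= band[1] & f < band[2] & f > 0 & f <= fs / 2
  # one-sided PSD: 2|X|^2 / (fs * sum(w^2)); integrated power = sum * df
  scale <- 2 / (fs * sum(w^2))
  colSums(abs(X[keep, , drop = FALSE])^2) * scale * df
}

#' Relative gamma (RG) of a four-channel EEG epoch
#'
#' RG is the ratio of the channel-averaged gamma-band (25-45 Hz) power to the
#' channel-averaged theta-alpha-band (4-13 Hz) power, computed on filtered,
#' detrended, z-scored 2-s epochs.
#'
#' @param eeg_epoch Numeric matrix, one column per EEG channel (4 columns).
#' @param fs Sampling rate, samples/s.
#' @param gamma_band,theta_alpha_band Band definitions in Hz.
#' @return RG value (strictly positive scalar).
#' @export
compute_rg <- function(eeg_epoch, fs,
                       gamma_band = c(25, 45), theta_alpha_band = c(4, 13)) {
  m <- as.matrix(eeg_epoch)
  num <- mean(band_power_matrix(m, gamma_band, fs))
  den <- mean(band_power_matrix(m, theta_alpha_band, fs))
  if (den <= 0) stop("undefined marker: zero theta-alpha power in epoch")
  num / den
}

#' Detect R-peaks in a band-passed ECG signal
#'
#' Operates on the 16-24 Hz filtered ECG. Candidate peaks are local maxima of
#' the signal magnitude above an adaptive threshold (a fraction of the
#' rolling 95th percentile of the magnitude, computed per 10-s block); peaks
#' closer together than the refractory period are resolved by keeping the
#' larger one.
#'
#' @param ecg_filtered Band-passed ECG samples.
#' @param fs Sampling rate, samples/s.
#' @param refractory_s Minimum inter-peak interval, seconds (default 0.25).
#' @param threshold_frac Fraction of the blockwise 95th percentile used as
#'   detection threshold (default 0.5).
#' @param block_s Threshold block length, seconds (default 10).
#' @return Strictly increasing peak times in seconds (possibly empty).
#' @export
detect_r_peaks <- function(ecg_filtered, fs, refractory_s = 0.25,
                           threshold_frac = 0.5, block_s = 10) {
  env <- abs(ecg_filtered)
  n <- length(env)
  block_len <- max(1L, as.integer(round(block_s * fs)))
  blk <- (seq_len(n) - 1L) %/% block_len
  q95 <- tapply(env, blk, stats::quantile, probs = 0.95, names = FALSE)
  thr <- threshold_frac * as.numeric(q95)[blk + 1L]
  d <- diff(env)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L   # local maxima
  cand <- cand[env[cand] > thr[cand] & env[cand] > 0]
  if (!length(cand)) return(numeric(0))
  refr <- refractory_s * fs
  keep <- integer(length(cand))
  k <- 0L
  for (i in cand) {
    if (k > 0L && i - keep[k] < refr) {
      if (env[i] > env[keep[k]]) keep[k] <- i       # larger peak wins
    } else {
      k <- k + 1L
      keep[k] <- i
    }
  }
  (keep[seq_len(k)] - 1L) / fs
}

#' Mean heart rate per 10-s epoch
#'
#' For each epoch of the grid, the mean R-R interval (AvRR) is taken over the
#' intervals whose onset (earlier peak) lies inside the epoch, and
#' `HR = 60 / AvRR` beats per minute. Epochs without any interval onset are
#' marked missing (NA) and excluded from downstream spline support.
#'
#' @param peaks Strictly increasing R-peak times, seconds.
#' @param grid A 10-s [build_epoch_grid()].
#' @return data.frame with `epoch_start_s`, `avrr_s`, `hr_bpm` (NA when the
#'   epoch holds no interval).
#' @export
compute_hr <- function(peaks, grid) {
  stopifnot(inherits(grid, "epoch_grid"))
  if (is.unsorted(peaks, strictly = TRUE)) stop("peak times must be strictly increasing")
  onsets <- peaks[-length(peaks)]
  rr <- diff(peaks)
  res <- vapply(grid$epoch_starts, function(s0) {
    sel <- onsets >= s0 & onsets < s0 + grid$window_s
    if (length(rr) == 0L || !any(sel)) return(c(NA_real_, NA_real_))
    avrr <- mean(rr[sel])
    c(avrr, 60 / avrr)
  }, numeric(2))
  data.frame(epoch_start_s = grid$epoch_starts,
             avrr_s = res[1, ], hr_bpm = res[2, ])
}

#' Interpolate 10-s heart-rate values onto a 2-s epoch grid
#'
#' A natural cubic spline is fitted through the non-missing 10-s epoch
#' midpoints and evaluated at the 2-s epoch midpoints; beyond the first/last
#' knot the value is clamped to the nearest knot value. With fewer than 4
#' support points a linear interpolation is used; fewer than 2 is an error.
#'
#' @param hr data.frame from [compute_hr()].
#' @param target A 2-s [build_epoch_grid()].
#' @return Numeric vector of HR values, one per target epoch.
#' @export
interpolate_hr <- function(hr, target) {
  stopifnot(inherits(target, "epoch_grid"))
  ok <- !is.na(hr$hr_bpm)
  kx <- hr$epoch_start_s[ok] + 5       # 10-s epoch midpoints
  ky <- hr$hr_bpm[ok]
  if (length(kx) < 2L) stop("need at least 2 heart-rate support points")
  xout <- target$epoch_starts + target$window_s / 2
  xcl <- pmin(pmax(xout, min(kx)), max(kx))   # clamp outside the knot span
  if (length(kx) >= 4L) {
    fn <- stats::splinefun(kx, ky, method = "natural")
    fn(xcl)
  } else {
    stats::approx(kx, ky, xout = xcl)$y
  }
}

#' Differential trapezius EMG
#'
#' Subtracts the electrode further from the backbone (lateral) from the one
#' closer to it (medial), cancelling common-mode pickup.
#'
#' @param medial,lateral Equal-length numeric sample sequences.
#' @return `medial - lateral`.
#' @export
differential_emg <- function(medial, lateral) {
  if (length(medial) != length(lateral)) {
    stop("medial and lateral channels differ in length")
  }
  medial - lateral
}

#' Root mean square
#' @param x Numeric vector.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) sqrt(mean(x^2))

#' Trapezius activity (TA) of an epoch
#'
#' Ratio of the epoch RMS of the differential EMG to the RMS of the maximum
#' voluntary contraction (MVC) test.
#'
#' @param emg_epoch Differential EMG epoch samples.
#' @param mvc_rms RMS of the differential EMG over the MVC window; must be
#'   positive.
#' @return Non-negative TA value.
#' @export
compute_ta <- function(emg_epoch, mvc_rms) {
  if (!is.finite(mvc_rms) || mvc_rms <= 0) {
    stop("configuration error: MVC reference RMS must be positive")
  }
  rms(emg_epoch) / mvc_rms
}

#' Skin conductance (SC) of an epoch
#'
#' Converts the mean sensor voltage of the epoch to conductance in Siemens
#' with the affine map `SC = 2 * (AvVoltage - 0.5) / 100000` used by the
#' acquisition front-end. A mean voltage below 0.5 V yields a negative SC,
#' which is emitted as-is with a warning.
#'
#' @param gsr_epoch GSR voltage samples of the epoch.
#' @return SC in Siemens.
#' @export
compute_sc <- function(gsr_epoch) {
  av <- mean(gsr_epoch)
  sc <- 2 * (av - 0.5) / 100000
  if (sc < 0) warning("negative skin conductance (mean voltage below 0.5 V)")
  sc
}

#' MVC reference RMS of a session
#'
#' Filters the differential trapezius EMG (1-350 Hz preset) over the whole
#' channel and returns its RMS over the `[mvc_start, mvc_end)` window.
#'
#' @param session A `subject_session`.
#' @return Positive scalar RMS.
#' @export
mvc_reference <- function(session) {
  tl <- session$timeline
  if (!(tl[["mvc_end"]] > tl[["mvc_start"]])) {
    stop("configuration error: MVC window missing or empty (mvc_start = ",
         tl[["mvc_start"]], ")")
  }
  fs <- session$sampling_rate
  dif <- differential_emg(session_channel(session, "EMG_medial"),
                          session_channel(session, "EMG_lateral"))
  dif <- filter_zero_phase(dif, filter_preset("emg", fs))
  i0 <- time_to_sample(tl[["mvc_start"]], fs)
  i1 <- time_to_sample(tl[["mvc_end"]], fs) - 1L
  v <- rms(dif[i0:i1])
  if (!is.finite(v) || v <= 0) stop("configuration error: MVC reference RMS is zero")
  v
}

# internal: cut a vector into a (window x n_epochs) matrix for a region
region_epoch_matrix <- function(x, fs, start_s, end_s, window_s) {
  grid <- build_epoch_grid(start_s, end_s, window_s)
  wlen <- as.integer(round(window_s * fs))
  idx <- outer(seq_len(wlen) - 1L, time_to_sample(grid$epoch_starts, fs), "+")
  list(grid = grid, m = matrix(x[idx], nrow = wlen))
}

#' Extract the four stress markers of a session
#'
#' Runs the full marker pipeline on the session's regions of interest:
#' relative gamma (RG) from the four filtered, detrended, z-scored EEG
#' channels; heart rate (HR) from R-peaks of the filtered ECG on a 10-s grid,
#' spline-interpolated to the 2-s grid; trapezius activity (TA) from the
#' filtered differential EMG normalized by the MVC reference; and skin
#' conductance (SC) from the raw GSR voltage. All markers are aligned on the
#' common 2-s epoch grid.
#'
#' @param session A valid `subject_session`.
#' @param regions data.frame of regions (`region`, `start_s`, `end_s`);
#'   defaults to [regions_of_interest()], which yields 630 epochs on the
#'   default timeline.
#' @return data.frame (`marker_set`) with columns `subject_id`, `region`,
#'   `epoch_start_s`, `rg`, `hr`, `ta`, `sc`; one row per 2-s epoch, no
#'   missing values.
#' @export
extract_markers <- function(session, regions = NULL) {
  validate_session(session)
  fs <- session$sampling_rate
  tl <- session$timeline
  if (is.null(regions)) regions <- regions_of_interest(tl)

  eeg <- filter_zero_phase(
    vapply(c("EEG_Fp1", "EEG_Fp2", "EEG_F3", "EEG_F4"),
           function(r) session_channel(session, r),
           numeric(nrow(session$channels))),
    filter_preset("eeg", fs))
  ecg <- filter_zero_phase(session_channel(session, "ECG"),
                           filter_preset("ecg", fs))
  emg <- filter_zero_phase(
    differential_emg(session_channel(session, "EMG_medial"),
                     session_channel(session, "EMG_lateral")),
    filter_preset("emg", fs))
  gsr <- session_channel(session, "GSR_voltage")
  peaks <- detect_r_peaks(ecg, fs)
  if (!(tl[["mvc_end"]] > tl[["mvc_start"]])) {
    stop("configuration error: MVC window missing or empty (mvc_start = ",
         tl[["mvc_start"]], ")")
  }
  mvc <- rms(emg[time_to_sample(tl[["mvc_start"]], fs):
                   (time_to_sample(tl[["mvc_end"]], fs) - 1L)])
  if (!is.finite(mvc) || mvc <= 0) {
    stop("configuration error: MVC reference RMS is zero")
  }

  out <- lapply(seq_len(nrow(regions)), function(i) {
    start_s <- regions$start_s[i]; end_s <- regions$end_s[i]
    # RG: per-channel band powers on detrended, z-scored 2-s epochs
    chans <- lapply(1:4, function(j) {
      em <- region_epoch_matrix(eeg[, j], fs, start_s, end_s, 2)
      z <- detrend_normalize(em$m)
      list(g = band_power_matrix(z, c(25, 45), fs),
           ta = band_power_matrix(z, c(4, 13), fs))
    })
    gp <- rowMeans(vapply(chans, `[[`, numeric(length(chans[[1]]$g)), "g"))
    tp <- rowMeans(vapply(chans, `[[`, numeric(length(chans[[1]]$ta)), "ta"))
    if (any(tp <= 0)) stop("undefined marker: zero theta-alpha power in epoch")
    rg <- gp / tp
    # HR: 10-s grid then spline to the 2-s grid
    grid10 <- build_epoch_grid(start_s, end_s, 10)
    grid2 <- build_epoch_grid(start_s, end_s, 2)
    hr10 <- compute_hr(peaks, grid10)
    hr2 <- interpolate_hr(hr10, grid2)
    # TA
    emm <- region_epoch_matrix(emg, fs, start_s, end_s, 2)
    ta <- sqrt(colMeans(emm$m^2)) / mvc
    # SC
    gmm <- region_epoch_matrix(gsr, fs, start_s, end_s, 2)
    sc <- 2 * (colMeans(gmm$m) - 0.5) / 100000
    data.frame(subject_id = session$subject_id,
               region = regions$region[i],
               epoch_start_s = grid2$epoch_starts,
               rg = rg, hr = hr2, ta = ta, sc = sc,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (anyNA(res)) stop("marker extraction produced missing values")
  class(res) <- c("marker_set", "data.frame")
  res
}
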