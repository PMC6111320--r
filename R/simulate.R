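#' Simulation parameters for synthetic sessions
#'
#' Bundles the timeline, the arousal dynamics, the per-modality couplings
#' that map arousal onto signal features, the noise amplitudes, and the
#' magnitude of per-subject offsets. Defaults encode the protocol conditions:
#' baseline arousal during the resting blocks, a gradual rise over the
#' stressor, a fast post-stressor decay for the EEG/ECG/EMG-borne markers and
#' a slow decay for skin conductance (sweat is reabsorbed slowly), plus a
#' slow late drift of the EEG ratio during relaxation (boredom effect).
#'
#' @param sampling_rate Samples per second (default 1000).
#' @param timeline An `event_timeline` (default [default_timeline()]).
#' @param baseline_arousal Arousal level during resting blocks, in \[0, 1\].
#' @param relax_floor Arousal floor approached during relaxation.
#' @param tau_fast_s,tau_slow_s Post-stressor exponential decay constants in
#'   seconds: fast for EEG/ECG/EMG dynamics, slow for skin conductance.
#' @param eeg_drift Late-relaxation upward arousal drift of the EEG modality
#'   (added linearly after `eeg_drift_delay_s` into the relaxation block).
#' @param eeg_drift_delay_s Delay before the EEG drift starts, seconds.
#' @param rg_range Gamma to theta-alpha power ratio at arousal 0 and 1.
#' @param hr_range_bpm Heart rate at arousal 0 and 1, bpm; must lie in
#'   (30, 200).
#' @param emg_frac_range Trapezius EMG RMS as a fraction of the MVC RMS at
#'   arousal 0 and 1; must lie in (0, 1\].
#' @param gsr_volt_range GSR sensor voltage at arousal 0 and 1, volts; must
#'   lie in (0.5, 5).
#' @param eeg_noise,eeg_pink White and low-frequency (AR(1)) EEG background
#'   amplitudes relative to the unit-amplitude theta-alpha oscillation.
#' @param ecg_beat_sd_s Gaussian R-wave template width, seconds.
#' @param ecg_noise ECG additive noise amplitude relative to the unit R-wave.
#' @param hr_jitter_bpm Slow random heart-rate modulation, bpm.
#' @param emg_common Common-mode EMG amplitude (cancelled by the
#'   differential montage), relative to the MVC RMS.
#' @param mvc_rms RMS of the MVC burst, arbitrary units.
#' @param gsr_noise_v GSR additive noise, volts.
#' @param subject_sd Named list of per-subject offset standard deviations:
#'   `hr_bpm`, `rg`, `emg_frac`, `gsr_v`. Offsets are drawn once per subject
#'   and shift that subject's coupling ranges, which is what degrades
#'   leave-one-subject-out generalization.
#' @param subject_offset_scale Multiplier on `subject_sd` (0 makes subjects
#'   exchangeable).
#' @return A `sim_params` object (list).
#' @export
sim_params <- function(sampling_rate = 1000,
                       timeline = default_timeline(),
                       baseline_arousal = 0.15,
                       relax_floor = 0.05,
                       tau_fast_s = 20,
                       tau_slow_s = 180,
                       eeg_drift = 0.35,
                       eeg_drift_delay_s = 120,
                       rg_range = c(0.4, 2.0),
                       hr_range_bpm = c(65, 95),
                       emg_frac_range = c(0.08, 0.5),
                       gsr_volt_range = c(1.0, 3.0),
                       eeg_noise = 0.10,
                       eeg_pink = 0.15,
                       ecg_beat_sd_s = 0.012,
                       ecg_noise = 0.02,
                       hr_jitter_bpm = 1,
                       emg_common = 0.05,
                       mvc_rms = 1,
                       gsr_noise_v = 0.01,
                       subject_sd = list(hr_bpm = 5, rg = 0.25,
                                         emg_frac = 0.06, gsr_v = 0.3),
                       subject_offset_scale = 1) {
  if (any(hr_range_bpm <= 30) || any(hr_range_bpm >= 200)) {
    stop("hr_range_bpm must lie within (30, 200)")
  }
  if (any(emg_frac_range <= 0) || any(emg_frac_range > 1)) {
    stop("emg_frac_range must lie within (0, 1]")
  }
  if (any(gsr_volt_range <= 0.5) || any(gsr_volt_range >= 5)) {
    stop("gsr_volt_range must lie within (0.5, 5)")
  }
  stopifnot(baseline_arousal >= 0, baseline_arousal <= 1,
            relax_floor >= 0, relax_floor <= 1,
            tau_fast_s > 0, tau_slow_s > 0)
  p <- as.list(environment())
  p$timeline <- event_timeline(timeline)
  structure(p, class = "sim_params")
}

#' Modality-specific arousal profile
#'
#' Builds the per-second arousal level a(t) in \[0, 1\] driving a modality:
#' baseline during rest, a linear rise across the stressor (training + task),
#' an exponential decay toward the relaxation floor after the stressor ends
#' (slow time constant for the GSR modality, fast for the others), an
#' exponential return toward baseline after the relaxation block, and, for
#' the EEG modality only, a linear upward drift late in the relaxation block.
#'
#' @param timeline An `event_timeline`.
#' @param params A [sim_params()].
#' @param modality One of `"eeg"`, `"ecg"`, `"emg"`, `"gsr"`.
#' @return An `arousal_profile`: list with `times` (seconds), `a`, `modality`.
#' @export
stress_profile <- function(timeline, params,
                           modality = c("eeg", "ecg", "emg", "gsr")) {
  modality <- match.arg(modality)
  tl <- event_timeline(timeline)
  a0 <- params$baseline_arousal
  fl <- params$relax_floor
  tau <- if (modality == "gsr") params$tau_slow_s else params$tau_fast_s
  times <- seq(0, ceiling(tl[["rs2_end"]]), by = 1)
  ms <- tl[["mist_train_start"]]; me <- tl[["mist_end"]]
  rs <- tl[["relax_start"]]; re <- tl[["relax_end"]]
  a <- numeric(length(times))
  pre <- times < ms
  a[pre] <- a0
  ramp <- times >= ms & times < me
  a[ramp] <- a0 + (1 - a0) * (times[ramp] - ms) / (me - ms)
  dec <- times >= me & times < re
  a[dec] <- fl + (1 - fl) * exp(-(times[dec] - me) / tau)
  if (modality == "eeg") {
    d0 <- rs + params$eeg_drift_delay_s
    dr <- times >= d0 & times < re
    a[dr] <- a[dr] + params$eeg_drift * (times[dr] - d0) / (re - d0)
  }
  a_end <- fl + (1 - fl) * exp(-(re - me) / tau) +
    if (modality == "eeg") params$eeg_drift else 0
  post <- times >= re
  a[post] <- a0 + (a_end - a0) * exp(-(times[post] - re) / tau)
  a <- pmin(1, pmax(0, a))
  structure(list(times = times, a = a, modality = modality),
            class = "arousal_profile")
}

# arousal per sample over the whole recording
profile_at_samples <- function(profile, n, fs) {
  stats::approx(profile$times, profile$a, xout = (seq_len(n) - 1) / fs,
                rule = 2)$y
}

#' Generate one modality's raw signal
#'
#' Signal models, with `a(t)` the modality's arousal profile:
#' * `eeg`: unit-amplitude 10-Hz theta-alpha oscillation plus a 35-Hz gamma
#'   oscillation whose power ratio to the former equals the programmed
#'   arousal-dependent ratio, plus white and low-frequency background noise.
#'   Returns a 4-column matrix (independent noise and phases per channel).
#' * `ecg`: Gaussian R-wave templates at beat times obtained by integrating
#'   the instantaneous rate `hr_range_bpm[1] + a(t) * diff(hr_range_bpm)`
#'   plus slow rate jitter; programmed beat times are attached as attribute
#'   `"beat_times"`. Returns a vector.
#' * `emg`: band-limited (20-250 Hz) noise with RMS equal to
#'   `fraction(a(t)) * mvc_rms`, a maximal burst (fraction 1) during the MVC
#'   window, and common-mode noise on both electrodes. Returns a 2-column
#'   matrix (medial, lateral).
#' * `gsr`: sensor voltage affine in `a(t)` over `gsr_volt_range` plus small
#'   noise. Returns a vector.
#'
#' @param modality One of `"eeg"`, `"ecg"`, `"emg"`, `"gsr"`.
#' @param profile An `arousal_profile` covering the timeline.
#' @param params A [sim_params()].
#' @param seed Optional integer; when given, seeds the RNG for a
#'   reproducible stand-alone call. Leave `NULL` inside a seeded stream.
#' @return Numeric vector or matrix of samples (see above).
#' @export
generate_modality <- function(modality, profile, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fs <- params$sampling_rate
  tl <- params$timeline
  n <- as.integer(round(tl[["rs2_end"]] * fs))
  a <- profile_at_samples(profile, n, fs)
  t <- (seq_len(n) - 1) / fs
  switch(modality,
    eeg = {
      ratio <- pmax(0.01, params$rg_range[1] + diff(params$rg_range) * a)
      amp_g <- sqrt(ratio)
      out <- matrix(0, n, 4)
      for (j in 1:4) {
        ph <- stats::runif(2, 0, 2 * pi)
        pink <- drop(iir_filter(1, c(1, -0.98), stats::rnorm(n))) *
          sqrt(1 - 0.98^2)
        out[, j] <- sin(2 * pi * 10 * t + ph[1]) +
          amp_g * sin(2 * pi * 35 * t + ph[2]) +
          params$eeg_noise * stats::rnorm(n) +
          params$eeg_pink * pink
      }
      out
    },
    ecg = {
      jit <- stats::rnorm(length(profile$times), 0, params$hr_jitter_bpm)
      jit <- as.numeric(stats::filter(jit, rep(1 / 10, 10), sides = 2))
      jit[is.na(jit)] <- 0
      jit_s <- stats::approx(profile$times, jit, xout = t, rule = 2)$y
      rate <- params$hr_range_bpm[1] + diff(params$hr_range_bpm) * a + jit_s
      rate <- pmin(195, pmax(35, rate))
      phase <- cumsum(rate / 60) / fs
      beat_idx <- which(diff(floor(c(0, phase))) >= 1)
      sig <- stats::rnorm(n, 0, params$ecg_noise)
      half <- as.integer(round(4 * params$ecg_beat_sd_s * fs))
      tt <- (-half):half
      g <- exp(-(tt / fs)^2 / (2 * params$ecg_beat_sd_s^2))
      for (k in seq_along(tt)) {
        pos <- beat_idx + tt[k]
        ok <- pos >= 1L & pos <= n
        sig[pos[ok]] <- sig[pos[ok]] + g[k]
      }
      attr(sig, "beat_times") <- (beat_idx - 1) / fs
      sig
    },
    emg = {
      frac <- pmin(1, pmax(0.005,
        params$emg_frac_range[1] + diff(params$emg_frac_range) * a))
      in_mvc <- t >= tl[["mvc_start"]] & t < tl[["mvc_end"]]
      frac[in_mvc] <- 1
      ba <- signal::butter(2, c(20, min(250, 0.45 * fs)) / (fs / 2),
                           type = "pass")
      e <- drop(iir_filter(ba$b, ba$a, stats::rnorm(n)))
      e <- e / stats::sd(e)
      s <- params$mvc_rms * frac * e
      common <- params$emg_common * params$mvc_rms * stats::rnorm(n)
      cbind(medial = common + s, lateral = common)
    },
    gsr = {
      v <- params$gsr_volt_range[1] + diff(params$gsr_volt_range) * a +
        params$gsr_noise_v * stats::rnorm(n)
      pmin(4.99, pmax(0.51, v))
    },
    stop("unknown modality: ", modality))
}

# per-subject coupling offsets, drawn from the current RNG stream
draw_subject_offsets <- function(params) {
  sd <- params$subject_sd
  sc <- params$subject_offset_scale
  list(hr_bpm = stats::rnorm(1, 0, sd$hr_bpm * sc),
       rg = stats::rnorm(1, 0, sd$rg * sc),
       emg_frac = stats::rnorm(1, 0, sd$emg_frac * sc),
       gsr_v = stats::rnorm(1, 0, sd$gsr_v * sc))
}

# shift a coupling range by a subject offset, clamped to physiological
# bounds without shrinking its width (so within-subject class separation is
# invariant under offsets of any size)
shift_range <- function(range, off, lo_bound, hi_bound) {
  w <- range[2] - range[1]
  lo <- min(max(range[1] + off, lo_bound), hi_bound - w)
  c(lo, lo + w)
}

# apply offsets to a copy of the params
shift_params <- function(params, off) {
  p <- params
  p$hr_range_bpm <- shift_range(params$hr_range_bpm, off$hr_bpm, 35, 195)
  p$rg_range <- shift_range(params$rg_range, off$rg, 0.05, Inf)
  p$emg_frac_range <- shift_range(params$emg_frac_range, off$emg_frac, 0.01, 1)
  p$gsr_volt_range <- shift_range(params$gsr_volt_range, off$gsr_v, 0.55, 4.9)
  p
}

#' Generate one synthetic subject session
#'
#' Draws the subject's coupling offsets, builds the four modality profiles,
#' synthesizes all eight channels, and derives the three self-perceived
#' stress ratings (0-4) from the arousal level at the rating times.
#'
#' @param subject_id Subject label.
#' @param params A [sim_params()].
#' @param seed Integer seed; identical (params, seed) give bit-identical
#'   sessions.
#' @return A `subject_session` with attributes `programmed_beats` (true ECG
#'   beat times) and `subject_offsets`.
#' @export
generate_session <- function(subject_id, params = sim_params(), seed = 1) {
  set.seed(seed)
  tl <- params$timeline
  off <- draw_subject_offsets(params)
  p <- shift_params(params, off)
  prof <- lapply(stats::setNames(nm = c("eeg", "ecg", "emg", "gsr")),
                 function(m) stress_profile(tl, p, m))
  eeg <- generate_modality("eeg", prof$eeg, p)
  ecg <- generate_modality("ecg", prof$ecg, p)
  emg <- generate_modality("emg", prof$emg, p)
  gsr <- generate_modality("gsr", prof$gsr, p)
  # self-ratings track the fast-decaying arousal (no EEG boredom drift):
  # low before the stressor, maximal right after it, low again after relaxing
  a_rate <- stats::approx(prof$ecg$times, prof$ecg$a,
                          xout = tl[c("t1", "t2", "t3")], rule = 2)$y
  spsl <- pmin(4L, pmax(0L, as.integer(round(4 * a_rate + stats::rnorm(3, 0, 0.5)))))
  ch <- cbind(eeg, ecg, emg[, "medial"], emg[, "lateral"], gsr)
  s <- subject_session(subject_id, ch, tl,
                       sampling_rate = params$sampling_rate,
                       map = channel_map(), spsl = spsl)
  attr(s, "programmed_beats") <- attr(ecg, "beat_times")
  attr(s, "subject_offsets") <- off
  s
}

#' Generate a cohort of synthetic sessions
#'
#' One master seed fans out to per-subject sub-seeds (drawn once from the
#' seeded stream), so cohorts of any size are reproducible and subject k is
#' identical whatever the cohort size.
#'
#' @param n_subjects Number of subjects (default 10, the study cohort size).
#' @param params A [sim_params()].
#' @param seed Integer master seed.
#' @return List of `subject_session` objects.
#' @export
generate_cohort <- function(n_subjects = 10, params = sim_params(), seed = 1) {
  if (n_subjects < 1) stop("n_subjects must be at least 1")
  seeds <- cohort_subject_seeds(seed, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    generate_session(sprintf("S%02d", i), params, seeds[i])
  })
}

#' Per-subject sub-seeds derived from a master seed
#' @param seed Master seed.
#' @param n Number of subjects.
#' @return Integer vector of length `n`.
#' @export
cohort_subject_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Apply large disjoint per-subject marker offsets
#'
#' Adds a constant shift to every marker column of each subject's table,
#' modelling subjects whose marker operating points differ grossly and
#' idiosyncratically. Each subject receives a distinct sign pattern across
#' the four markers (the binary code of its index) and a magnitude of at
#' least four separation units per marker, so the subjects' marker
#' distributions are pairwise disjoint in feature space and no common
#' offset-free discriminative subspace survives pooling. (Shifts collinear
#' across subjects would not achieve this: contrasts between markers would
#' cancel the offsets and between-subject classification would partly
#' survive.) Within-subject structure -- hence leave-one-epoch-out accuracy
#' -- is invariant under constant shifts; leave-one-subject-out accuracy
#' collapses toward the 1/3 chance level.
#'
#' @param per_subject List of per-subject data.frames carrying the four
#'   marker columns (`marker_set`s or `labeled_dataset`s).
#' @param unit Named per-marker shift unit, roughly one within-subject
#'   class separation for each marker on the default couplings.
#' @param magnitudes Offset magnitudes in separation units, one per
#'   subject; default cycles through 4..10.
#' @return The list with shifted marker columns.
#' @export
offset_marker_sets <- function(per_subject,
                               unit = c(rg = 1.2, hr = 20, ta = 0.3,
                                        sc = 1.2e-5),
                               magnitudes = NULL) {
  n <- length(per_subject)
  if (is.null(magnitudes)) magnitudes <- 4 + (seq_len(n) - 1) %% 7
  stopifnot(length(magnitudes) == n)
  lapply(seq_len(n), function(i) {
    d <- per_subject[[i]]
    for (k in seq_along(unit)) {
      sgn <- if (bitwAnd(i - 1L, bitwShiftL(1L, k - 1L)) > 0L) -1 else 1
      f <- names(unit)[k]
      d[[f]] <- d[[f]] + sgn * magnitudes[i] * unit[[f]]
    }
    d
  })
}

#' Simulate a cohort and extract its markers, one subject at a time
#'
#' Streaming variant of [generate_cohort()] + [extract_markers()] that never
#' holds more than one raw session in memory; raw channels are discarded
#' after marker extraction.
#'
#' @param n_subjects Number of subjects.
#' @param params A [sim_params()].
#' @param seed Master seed (same fan-out as [generate_cohort()]).
#' @param include_rs1_late Also compute markers over the last 30 s of RS1
#'   (needed by the between-period comparisons).
#' @return List with `markers` (list of per-subject `marker_set`s) and
#'   `spsl` (n x 3 integer matrix of ratings).
#' @export
simulate_cohort_markers <- function(n_subjects = 10, params = sim_params(),
                                    seed = 1, include_rs1_late = TRUE) {
  seeds <- cohort_subject_seeds(seed, n_subjects)
  regions <- regions_of_interest(params$timeline,
                                 include_rs1_late = include_rs1_late)
  spsl <- matrix(NA_integer_, n_subjects, 3,
                 dimnames = list(NULL, c("t1", "t2", "t3")))
  markers <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    s <- generate_session(sprintf("S%02d", i), params, seeds[i])
    markers[[i]] <- extract_markers(s, regions = regions)
    spsl[i, ] <- s$spsl
    rm(s)
  }
  list(markers = markers, spsl = spsl)
}
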