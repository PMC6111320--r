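# shared fixtures and independent oracles used across test files

# a short but structurally valid timeline for I/O and bookkeeping tests
mini_timeline <- function() {
  default_timeline(mvc_s = 2, rs1_s = 20, train_s = 20, task_s = 30,
                   relax_s = 40, rs2_s = 20, transition_s = 5)
}

# small random-but-valid session (not produced by the generator, so
# constructor and I/O paths are exercised independently of it)
make_mini_session <- function(seed = 1, fs = 50, subject_id = "mini") {
  set.seed(seed)
  tl <- mini_timeline()
  n <- as.integer(round(tl[["rs2_end"]] * fs))
  subject_session(subject_id,
                  channels = matrix(stats::rnorm(n * 8), n, 8),
                  timeline = tl, sampling_rate = fs,
                  map = channel_map(), spsl = c(1L, 3L, 0L))
}

# constant-arousal profile covering a timeline (for programmed-signal tests)
flat_profile <- function(timeline, a, modality = "ecg") {
  times <- seq(0, ceiling(timeline[["rs2_end"]]))
  structure(list(times = times, a = rep(a, length(times)),
                 modality = modality),
            class = "arousal_profile")
}

# squared analog Butterworth band-pass magnitude (zero-phase effective
# response), used as an independent oracle for the designed filters
butter_mag2 <- function(f, low, high, order) {
  w <- 2 * pi * f
  wl <- 2 * pi * low
  wh <- 2 * pi * high
  # analog prototype band-pass: |H|^2 = 1 / (1 + ((w^2 - wl wh)/(w (wh - wl)))^(2 order))
  x <- (w^2 - wl * wh) / (w * (wh - wl))
  (1 / (1 + x^(2 * order)))^2
}

# lag (in samples) of the peak of the cross-correlation of two sequences
xcorr_peak_lag <- function(x, y, max_lag = 50) {
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(L) {
    if (L >= 0) {
      sum(x[seq_len(length(x) - L)] * y[seq_len(length(y) - L) + L])
    } else {
      sum(x[seq_len(length(x) + L) - L] * y[seq_len(length(y) + L)])
    }
  }, numeric(1))
  lags[which.max(cc)]
}

# write a minimal EDF file (one data record per second) for import tests
write_mini_edf <- function(path, channels, fs, labels) {
  ns <- ncol(channels)
  rec_n <- as.integer(fs)
  n_rec <- nrow(channels) %/% rec_n
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, w) {
    s <- substr(s, 1, w)
    writeChar(formatC(s, width = -w), con, nchars = w, eos = NULL)
  }
  pad("0", 8); pad("test patient", 80); pad("test recording", 80)
  pad("01.01.24", 8); pad("00.00.00", 8)
  pad(as.character(256 * (1 + ns)), 8); pad("", 44)
  pad(as.character(n_rec), 8); pad("1", 8); pad(as.character(ns), 4)
  for (l in labels) pad(l, 16)
  for (i in 1:ns) pad("test", 80)
  for (i in 1:ns) pad("uV", 8)
  phys_min <- apply(channels, 2, min)
  phys_max <- apply(channels, 2, max) + 1e-6
  for (i in 1:ns) pad(sprintf("%.3f", phys_min[i]), 8)
  for (i in 1:ns) pad(sprintf("%.3f", phys_max[i]), 8)
  for (i in 1:ns) pad("-32768", 8)
  for (i in 1:ns) pad("32767", 8)
  for (i in 1:ns) pad("", 80)
  for (i in 1:ns) pad(as.character(rec_n), 8)
  for (i in 1:ns) pad("", 32)
  dig <- matrix(0L, nrow(channels), ns)
  for (j in 1:ns) {
    dig[, j] <- as.integer(round(-32768 + (channels[, j] - phys_min[j]) /
                                   (phys_max[j] - phys_min[j]) * 65535))
  }
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * rec_n + 1):(r * rec_n)
    for (j in 1:ns) {
      writeBin(dig[rows, j], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
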