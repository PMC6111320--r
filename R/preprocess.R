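#' Design a zero-phase Butterworth band-pass filter
#'
#' The filter is designed once at the stated order and applied forward and
#' backward by [filter_zero_phase()], so the effective magnitude response is
#' the squared Butterworth magnitude and the net phase is zero.
#'
#' @param low_hz,high_hz Pass-band edges in Hz, `0 < low < high < fs/2`.
#' @param order Filter order of the designed (single-pass) filter; 2 or 4.
#' @param fs Sampling rate in samples/s.
#' @return A `filter_spec` object holding the transfer-function coefficients.
#' @export
design_bandpass <- function(low_hz, high_hz, order, fs) {
  if (!(order %in% c(2L, 4L))) stop("order must be 2 or 4")
  if (low_hz <= 0 || high_hz <= low_hz) stop("need 0 < low_hz < high_hz")
  if (high_hz >= fs / 2) {
    stop("band edge ", high_hz, " Hz is at or above the Nyquist frequency ",
         fs / 2, " Hz")
  }
  ba <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order, fs = fs,
                 b = ba$b, a = ba$a, family = "butterworth"),
            class = "filter_spec")
}

#' Named filter presets
#'
#' Pass-band and order presets for the three filtered modalities:
#' `eeg` 1-48 Hz order 4, `ecg` 16-24 Hz order 2 (enhances the R-peak of the
#' QRS complex), `emg` 1-350 Hz order 2.
#'
#' @param name One of `"eeg"`, `"ecg"`, `"emg"`.
#' @param fs Sampling rate in samples/s.
#' @return A `filter_spec`.
#' @export
filter_preset <- function(name = c("eeg", "ecg", "emg"), fs = 1000) {
  name <- match.arg(name)
  p <- switch(name,
              eeg = c(1, 48, 4),
              ecg = c(16, 24, 2),
              emg = c(1, 350, 2))
  design_bandpass(p[1], p[2], p[3], fs)
}

#' Minimum input length accepted by [filter_zero_phase()]
#' @param spec A `filter_spec`.
#' @return Number of samples.
#' @export
filter_min_length <- function(spec) {
  ceiling(3 * spec$order * spec$fs / spec$low_hz)
}

# single-pass IIR transfer-function filter on a plain vector or matrix
# (columns filtered independently), zero initial conditions; compiled
# direct-form-II-transposed kernel
iir_filter <- function(b, a, x) {
  cpp_iir(as.numeric(b), as.numeric(a), as.matrix(x))
}

#' Apply a filter with zero phase (forward-backward)
#'
#' The input is extended at both ends by odd reflection (point symmetry about
#' the end sample) before the forward and backward passes, which suppresses
#' the start-up transient of the IIR filter; the padding is discarded so the
#' output has exactly the input length and zero group delay.
#'
#' @param x Numeric sample sequence, or a matrix whose columns are filtered
#'   independently; must have at least [filter_min_length()] samples so the
#'   filter is warmed up.
#' @param spec A `filter_spec` from [design_bandpass()] or [filter_preset()].
#' @return Filtered sequence (or matrix), same shape as `x`.
#' @export
filter_zero_phase <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  vec <- is.null(dim(x))
  m <- as.matrix(x)
  n <- nrow(m)
  nmin <- filter_min_length(spec)
  if (n < nmin) {
    stop("input has ", n, " samples; zero-phase filtering with this band needs ",
         "at least ", nmin)
  }
  pad <- min(n - 1L, nmin)
  head_pad <- 2 * rep(m[1L, ], each = pad) - m[(pad + 1L):2L, , drop = FALSE]
  tail_pad <- 2 * rep(m[n, ], each = pad) - m[(n - 1L):(n - pad), , drop = FALSE]
  xp <- rbind(head_pad, m, tail_pad)
  y <- iir_filter(spec$b, spec$a, xp)
  y <- iir_filter(spec$b, spec$a, y[nrow(y):1L, , drop = FALSE])
  out <- y[(nrow(y) - pad):(pad + 1L), , drop = FALSE]
  if (vec) drop(out) else out
}

#' Detrend and z-score normalize an epoch
#'
#' Removes the least-squares linear trend from each channel, then scales to
#' zero mean and unit standard deviation. A (near-)constant channel cannot be
#' normalized and is mapped to all zeros with a warning, keeping batch
#' pipelines total.
#'
#' @param epoch Numeric vector, or matrix with one column per channel.
#' @return Object of the same shape.
#' @export
detrend_normalize <- function(epoch) {
  vec <- is.null(dim(epoch))
  m <- as.matrix(epoch)
  n <- nrow(m)
  if (n < 2L) stop("epoch must have at least 2 samples")
  tc <- seq_len(n) - (n + 1) / 2              # centered time axis
  stt <- sum(tc^2)
  slope <- drop(tc %*% m) / stt
  r <- sweep(m, 2L, colMeans(m)) - outer(tc, slope)
  s <- sqrt(colSums(r^2) / (n - 1))
  flat <- s < 1e-12 * pmax(1, abs(colMeans(m)))
  if (any(flat)) {
    warning("constant epoch channel(s) mapped to zeros")
    s[flat] <- 1
    r[, flat] <- 0
  }
  out <- sweep(r, 2L, s, "/")
  if (vec) drop(out) else out
}

#' Regions of interest of a session
#'
#' The marker analysis is restricted to the central minute of each
#' resting-state block, the full stressor session (training plus task), and
#' the full relaxation block.
#'
#' @param timeline An `event_timeline`.
#' @param include_rs1_late If `TRUE`, append the last 30 s of RS1 as an extra
#'   `rs1_late` region. The between-period comparisons contrast the last
#'   30 s of RS1 with stressor/relaxation windows, and that interval lies
#'   outside the central minute, so markers must be computed there too.
#' @return data.frame with columns `region`, `start_s`, `end_s`.
#' @export
regions_of_interest <- function(timeline, include_rs1_late = FALSE) {
  tl <- event_timeline(timeline)
  out <- data.frame(
    region = c("rs1", "mist", "relax", "rs2"),
    start_s = c(tl[["rs1_start"]] + 30, tl[["mist_train_start"]],
                tl[["relax_start"]], tl[["rs2_start"]] + 30),
    end_s = c(tl[["rs1_start"]] + 90, tl[["mist_end"]],
              tl[["relax_end"]], tl[["rs2_start"]] + 90),
    stringsAsFactors = FALSE)
  if (include_rs1_late) {
    out <- rbind(out,
                 data.frame(region = "rs1_late",
                            start_s = tl[["rs1_end"]] - 30,
                            end_s = tl[["rs1_end"]]))
    out <- out[order(out$start_s), ]
    rownames(out) <- NULL
  }
  out
}

#' Cut a filtered channel region into epochs
#'
#' Filtering is applied to the whole continuous channel first and the region
#' is segmented afterwards, so epoch interiors are free of filter edge
#' transients.
#'
#' @param session A `subject_session`.
#' @param roles Character vector of channel roles to extract.
#' @param region Numeric `c(start_s, end_s)` region bounds.
#' @param window_s Epoch length, seconds.
#' @param preset Name of a filter preset (`"eeg"`, `"ecg"`, `"emg"`), a
#'   `filter_spec`, or `NULL` for no filtering (GSR).
#' @return List of epochs; each epoch is a list with `samples` (matrix, one
#'   column per role), `start_s`, `window_s` and `roles`.
#' @export
extract_region_epochs <- function(session, roles, region, window_s,
                                  preset = NULL) {
  validate_session(session)
  fs <- session$sampling_rate
  n <- nrow(session$channels)
  if (region[1] < 0 || region[2] > n / fs + 1e-9) {
    stop("region [", region[1], ", ", region[2], ") outside recording")
  }
  ch <- vapply(roles, function(r) session_channel(session, r), numeric(n))
  if (!is.null(preset)) {
    spec <- if (inherits(preset, "filter_spec")) preset else filter_preset(preset, fs)
    ch <- filter_zero_phase(ch, spec)
  }
  grid <- build_epoch_grid(region[1], region[2], window_s)
  wlen <- as.integer(round(window_s * fs))
  lapply(grid$epoch_starts, function(s0) {
    i0 <- time_to_sample(s0, fs)
    list(samples = ch[i0:(i0 + wlen - 1L), , drop = FALSE],
         start_s = s0, window_s = window_s, roles = roles)
  })
}
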