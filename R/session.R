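#' Channel roles of an eight-channel recording
#'
#' The montage carries four frontal EEG electrodes (Fp1, Fp2, F3, F4 of the
#' 10-20 system), one ECG electrode, two EMG electrodes over the trapezius
#' (one closer to the backbone, "medial", one further away, "lateral"), and
#' one analogue voltage channel from a galvanic skin response sensor.
#'
#' @format Character vector of the eight recognised channel roles.
#' @export
CHANNEL_ROLES <- c(
  "EEG_Fp1", "EEG_Fp2", "EEG_F3", "EEG_F4",
  "ECG", "EMG_medial", "EMG_lateral", "GSR_voltage"
)

#' Ordered names of the session event markers
#'
#' Events are expressed in seconds from recording start and must be
#' non-decreasing in this order: maximum voluntary contraction (MVC) test,
#' first resting-state block (RS1), first stress self-rating (T1), mental
#' arithmetic stressor (training then task), second self-rating (T2),
#' relaxation block, third self-rating (T3), second resting-state block (RS2).
#'
#' @format Character vector of the fourteen marker names.
#' @export
TIMELINE_MARKERS <- c(
  "mvc_start", "mvc_end", "rs1_start", "rs1_end", "t1",
  "mist_train_start", "mist_task_start", "mist_end", "t2",
  "relax_start", "relax_end", "t3", "rs2_start", "rs2_end"
)

#' Construct and validate a channel map
#'
#' @param roles Character vector of length 8 giving the role of channels
#'   0..7 in order. Must be a permutation of [CHANNEL_ROLES].
#' @return A `channel_map` object (named character vector, names "0".."7").
#' @export
channel_map <- function(roles = CHANNEL_ROLES) {
  roles <- as.character(roles)
  if (length(roles) != 8L) {
    stop("a channel map needs exactly 8 entries, got ", length(roles))
  }
  if (anyDuplicated(roles)) {
    stop("duplicate channel role(s): ",
         paste(unique(roles[duplicated(roles)]), collapse = ", "))
  }
  missing <- setdiff(CHANNEL_ROLES, roles)
  if (length(missing)) {
    stop("missing channel role(s): ", paste(missing, collapse = ", "))
  }
  structure(stats::setNames(roles, as.character(0:7)), class = "channel_map")
}

#' Construct an event timeline
#'
#' @param markers Named numeric vector containing all of [TIMELINE_MARKERS],
#'   in seconds from recording start.
#' @return An `event_timeline` object (named numeric vector).
#' @export
event_timeline <- function(markers) {
  markers <- unlist(markers)
  missing <- setdiff(TIMELINE_MARKERS, names(markers))
  if (length(missing)) {
    stop("timeline is missing marker(s): ", paste(missing, collapse = ", "))
  }
  tl <- as.numeric(markers[TIMELINE_MARKERS])
  names(tl) <- TIMELINE_MARKERS
  if (any(!is.finite(tl)) || any(tl < 0)) {
    stop("timeline markers must be finite and non-negative")
  }
  if (any(diff(tl) < 0)) {
    bad <- TIMELINE_MARKERS[which(diff(tl) < 0) + 1L][1L]
    stop("timeline markers out of order at '", bad, "'")
  }
  structure(tl, class = "event_timeline")
}

#' Default session timeline
#'
#' Builds the standard protocol timeline: a 5-s MVC test, 2 min of resting
#' state (RS1), 3 min of stressor training followed by a 6-min stressor task,
#' 10 min of relaxation, and a final 2-min resting state (RS2), with a
#' configurable transition gap between blocks. Self-rating points T1/T2/T3
#' fall at the end of RS1, the stressor, and the relaxation block.
#'
#' @param mvc_s,rs1_s,train_s,task_s,relax_s,rs2_s Block durations in seconds.
#' @param transition_s Gap between consecutive blocks, seconds.
#' @return An `event_timeline`.
#' @export
default_timeline <- function(mvc_s = 5, rs1_s = 120, train_s = 180,
                             task_s = 360, relax_s = 600, rs2_s = 120,
                             transition_s = 30) {
  t <- 0
  tl <- c(mvc_start = t, mvc_end = t + mvc_s)
  t <- t + mvc_s + transition_s
  tl <- c(tl, rs1_start = t, rs1_end = t + rs1_s, t1 = t + rs1_s)
  t <- t + rs1_s + transition_s
  tl <- c(tl, mist_train_start = t, mist_task_start = t + train_s,
          mist_end = t + train_s + task_s, t2 = t + train_s + task_s)
  t <- t + train_s + task_s + transition_s
  tl <- c(tl, relax_start = t, relax_end = t + relax_s, t3 = t + relax_s)
  t <- t + relax_s + transition_s
  tl <- c(tl, rs2_start = t, rs2_end = t + rs2_s)
  event_timeline(tl)
}

#' Construct a subject session
#'
#' @param subject_id Opaque subject label.
#' @param channels Numeric matrix, one column per channel (8 columns), in the
#'   order given by `map`.
#' @param timeline An [event_timeline()].
#' @param sampling_rate Samples per second (default 1000).
#' @param map A [channel_map()].
#' @param spsl Integer vector of length 3, self-perceived stress level (0-4)
#'   at T1, T2, T3.
#' @return A `subject_session` object.
#' @export
subject_session <- function(subject_id, channels, timeline,
                            sampling_rate = 1000, map = channel_map(),
                            spsl = c(NA_integer_, NA_integer_, NA_integer_)) {
  if (!inherits(map, "channel_map")) map <- channel_map(map)
  if (!inherits(timeline, "event_timeline")) timeline <- event_timeline(timeline)
  channels <- as.matrix(channels)
  storage.mode(channels) <- "double"
  s <- structure(
    list(subject_id = as.character(subject_id),
         sampling_rate = as.numeric(sampling_rate),
         channels = channels,
         channel_map = map,
         timeline = timeline,
         spsl = as.integer(spsl)),
    class = "subject_session")
  validate_session(s)
  s
}

#' Validate a subject session
#'
#' Checks the session invariants: eight equal-length channels, positive
#' sampling rate, a recording that spans at least the end of RS2, a valid
#' channel map and timeline, and SPSL ratings on the 0-4 scale (or NA).
#'
#' @param session A `subject_session`.
#' @return The session, invisibly; errors otherwise.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "subject_session"))
  ch <- session$channels
  if (ncol(ch) != 8L) stop("session must have exactly 8 channels")
  if (nrow(ch) < 1L) stop("session channels are empty")
  if (!is.numeric(session$sampling_rate) || session$sampling_rate <= 0) {
    stop("sampling_rate must be positive")
  }
  channel_map(session$channel_map)        # re-validate roles
  event_timeline(session$timeline)        # re-validate ordering
  span <- nrow(ch) / session$sampling_rate
  if (span < session$timeline[["rs2_end"]] - 1e-9) {
    stop("recording spans ", span, " s but timeline ends at ",
         session$timeline[["rs2_end"]], " s")
  }
  if (length(session$spsl) != 3L ||
      any(!is.na(session$spsl) & (session$spsl < 0L | session$spsl > 4L))) {
    stop("spsl must be three integers in 0..4 (or NA)")
  }
  invisible(session)
}

#' Extract one channel by role
#'
#' @param session A `subject_session`.
#' @param role One of [CHANNEL_ROLES].
#' @return Numeric vector of samples.
#' @export
session_channel <- function(session, role) {
  idx <- match(role, session$channel_map)
  if (is.na(idx)) stop("unknown channel role: ", role)
  session$channels[, idx]
}

#' Build a non-overlapping epoch grid over a region
#'
#' Epochs are half-open `[start, start + window)` intervals tiling the region
#' from its start; a trailing remainder shorter than one window is dropped
#' (floor semantics), so a 120-s region yields exactly 60 two-second epochs.
#'
#' @param region_start_s,region_end_s Region bounds in seconds.
#' @param window_s Epoch length in seconds (2 or 10 in this pipeline).
#' @return An `epoch_grid` object: list with `region_start_s`, `region_end_s`,
#'   `window_s` and `epoch_starts`.
#' @export
build_epoch_grid <- function(region_start_s, region_end_s, window_s) {
  if (region_end_s <= region_start_s) stop("region end must exceed its start")
  if (window_s <= 0) stop("window_s must be positive")
  n <- floor((region_end_s - region_start_s) / window_s + 1e-9)
  starts <- if (n >= 1) region_start_s + window_s * (seq_len(n) - 1) else numeric(0)
  structure(list(region_start_s = region_start_s,
                 region_end_s = region_end_s,
                 window_s = window_s,
                 epoch_starts = starts),
            class = "epoch_grid")
}

#' Convert a time in seconds to a 1-based sample index
#' @param t_s Time in seconds from recording start.
#' @param fs Sampling rate.
#' @return Integer sample index (sample 1 covers t = 0).
#' @keywords internal
time_to_sample <- function(t_s, fs) as.integer(round(t_s * fs)) + 1L

#' Write a session in the native on-disk format
#'
#' The native format is three sibling files sharing a path stem: a delimited
#' samples table `<stem>_samples.csv` (first column `sample`, then one column
#' per channel named by role), an events sidecar `<stem>_events.json`
#' (marker name to seconds), and `<stem>_meta.json` (subject id, sampling
#' rate, SPSL triple, channel order). Sample values are written with
#' round-trip (shortest exact) precision so that [read_session()] inverts
#' this function bit-exactly.
#'
#' @param session A valid `subject_session`.
#' @param stem Path stem (directory must exist and be writable).
#' @return `stem`, invisibly.
#' @export
write_session <- function(session, stem) {
  validate_session(session)
  dir <- dirname(stem)
  if (!dir.exists(dir)) stop("unwritable path: directory does not exist: ", dir)
  # %.17g guarantees bit-exact doubles on re-read
  dt <- data.table::as.data.table(
    matrix(sprintf("%.17g", session$channels), nrow(session$channels)))
  data.table::setnames(dt, as.character(session$channel_map))
  dt <- cbind(data.table::data.table(sample = seq_len(nrow(dt))), dt)
  data.table::fwrite(dt, paste0(stem, "_samples.csv"), quote = FALSE)
  jsonlite::write_json(as.list(unclass(session$timeline)),
                       paste0(stem, "_events.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(subject_id = session$subject_id,
         sampling_rate = session$sampling_rate,
         spsl = session$spsl,
         channel_map = as.character(session$channel_map)),
    paste0(stem, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read a session from disk
#'
#' @param stem Path stem for the native format (see [write_session()]), or
#'   the path of an EDF file when `format = "edf"`. EDF carries no event
#'   timeline, so an events sidecar `<path-sans-ext>_events.json` and
#'   metadata sidecar `<path-sans-ext>_meta.json` (optional; defaults
#'   applied) accompany the EDF file.
#' @param format `"native"` or `"edf"`.
#' @return A validated `subject_session`.
#' @export
read_session <- function(stem, format = c("native", "edf")) {
  format <- match.arg(format)
  if (format == "edf") return(read_edf_session(stem))
  sf <- paste0(stem, "_samples.csv")
  ef <- paste0(stem, "_events.json")
  mf <- paste0(stem, "_meta.json")
  for (f in c(sf, ef, mf)) if (!file.exists(f)) stop("missing file: ", f)
  dt <- data.table::fread(sf)
  if (names(dt)[1] != "sample") stop("format error: first column must be 'sample'")
  roles <- names(dt)[-1]
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  events <- unlist(jsonlite::read_json(ef, simplifyVector = TRUE))
  ch <- as.matrix(dt[, -1, with = FALSE])
  subject_session(subject_id = meta$subject_id,
                  channels = ch,
                  timeline = event_timeline(events),
                  sampling_rate = meta$sampling_rate,
                  map = channel_map(roles),
                  spsl = meta$spsl)
}

# --- minimal EDF (European Data Format) import -------------------------------
# EDF is a fixed-layout binary format: a 256-byte static header, 256 bytes of
# header per signal, then data records of 2-byte little-endian integers.
# Values are mapped to physical units by the per-signal affine calibration.
# No R reader for EDF is available in this toolchain, so a compact read-only
# importer is provided here. Channel labels are matched case-insensitively
# to the montage roles.

read_edf_header <- function(con) {
  txt <- function(nc) trimws(rawToChar(readBin(con, "raw", nc)))
  h <- list(version = txt(8), patient = txt(80), recording = txt(80),
            startdate = txt(8), starttime = txt(8),
            header_bytes = as.integer(txt(8)), reserved = txt(44),
            n_records = as.integer(txt(8)),
            record_duration_s = as.numeric(txt(8)),
            ns = as.integer(txt(4)))
  fld <- function(nc) vapply(seq_len(h$ns), function(i) txt(nc), character(1))
  h$labels <- fld(16); h$transducer <- fld(80); h$phys_dim <- fld(8)
  h$phys_min <- as.numeric(fld(8)); h$phys_max <- as.numeric(fld(8))
  h$dig_min <- as.numeric(fld(8)); h$dig_max <- as.numeric(fld(8))
  h$prefilter <- fld(80); h$samples_per_record <- as.integer(fld(8))
  h$sig_reserved <- fld(32)
  h
}

match_edf_label <- function(label) {
  key <- tolower(gsub("[^A-Za-z0-9]", "", label))
  pats <- c(EEG_Fp1 = "fp1", EEG_Fp2 = "fp2", EEG_F3 = "f3", EEG_F4 = "f4",
            ECG = "ecg|ekg", EMG_medial = "emg.*(med|1)|medial",
            EMG_lateral = "emg.*(lat|2)|lateral", GSR_voltage = "gsr|eda|skin")
  for (role in names(pats)) {
    if (grepl(pats[[role]], key)) return(role)
  }
  NA_character_
}

read_edf_session <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  if (h$ns != 8L) stop("format error: expected 8 signals, found ", h$ns)
  spr <- h$samples_per_record
  if (length(unique(spr)) != 1L) {
    stop("format error: signals with differing sampling rates are not supported")
  }
  roles <- vapply(h$labels, match_edf_label, character(1))
  if (anyNA(roles)) {
    stop("format error: unmatched channel label(s): ",
         paste(h$labels[is.na(roles)], collapse = ", "))
  }
  if (anyDuplicated(roles)) stop("format error: duplicate channel role")
  fs <- spr[1] / h$record_duration_s
  n <- h$n_records * spr[1]
  raw <- readBin(con, "integer", n = h$n_records * sum(spr), size = 2,
                 signed = TRUE, endian = "little")
  dat <- matrix(0, nrow = n, ncol = 8)
  # records are interleaved: all samples of signal 1, then signal 2, ...
  idx <- array(seq_along(raw), dim = c(spr[1], 8, h$n_records))
  for (j in 1:8) {
    dig <- raw[as.vector(idx[, j, ])]
    scale <- (h$phys_max[j] - h$phys_min[j]) / (h$dig_max[j] - h$dig_min[j])
    dat[, j] <- h$phys_min[j] + (dig - h$dig_min[j]) * scale
  }
  stem <- sub("\\.edf$", "", path, ignore.case = TRUE)
  ef <- paste0(stem, "_events.json")
  if (!file.exists(ef)) stop("missing events sidecar: ", ef)
  events <- unlist(jsonlite::read_json(ef, simplifyVector = TRUE))
  mf <- paste0(stem, "_meta.json")
  meta <- if (file.exists(mf)) jsonlite::read_json(mf, simplifyVector = TRUE) else list()
  subject_session(
    subject_id = meta$subject_id %||% h$patient,
    channels = dat,
    timeline = event_timeline(events),
    sampling_rate = fs,
    map = channel_map(roles),
    spsl = meta$spsl %||% c(NA_integer_, NA_integer_, NA_integer_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
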