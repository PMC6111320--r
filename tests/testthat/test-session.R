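test_that("channel map enforces the eight-role montage", {
  expect_s3_class(channel_map(), "channel_map")
  expect_error(channel_map(CHANNEL_ROLES[1:7]), "exactly 8")
  expect_error(channel_map(c(CHANNEL_ROLES[1:7], "EEG_Fp1")), "duplicate")
  expect_error(channel_map(c(CHANNEL_ROLES[1:7], "EEG_Oz")), "missing")
  # permuted order is a valid map
  expect_s3_class(channel_map(rev(CHANNEL_ROLES)), "channel_map")
})

test_that("event timeline enforces marker order and completeness", {
  tl <- default_timeline()
  expect_true(all(diff(unclass(tl)) >= 0))
  bad <- unclass(tl)
  bad["relax_start"] <- bad["mist_end"] - 5   # relax before stressor ends
  expect_error(event_timeline(bad), "out of order")
  expect_error(event_timeline(unclass(tl)[-1]), "missing marker")
})

test_that("default timeline has the protocol block durations", {
  tl <- default_timeline()
  expect_equal(tl[["mvc_end"]] - tl[["mvc_start"]], 5)
  expect_equal(tl[["rs1_end"]] - tl[["rs1_start"]], 120)
  expect_equal(tl[["mist_task_start"]] - tl[["mist_train_start"]], 180)
  expect_equal(tl[["mist_end"]] - tl[["mist_task_start"]], 360)
  expect_equal(tl[["relax_end"]] - tl[["relax_start"]], 600)
  expect_equal(tl[["rs2_end"]] - tl[["rs2_start"]], 120)
  # block durations alone sum to 1385 s; transitions extend the span
  expect_gte(tl[["rs2_end"]], 1385)
})

test_that("session invariants are enforced", {
  s <- make_mini_session()
  expect_silent(validate_session(s))
  expect_error(subject_session("x", s$channels[, 1:7], s$timeline,
                               sampling_rate = 50),
               "8 channels")
  expect_error(subject_session("x", s$channels[1:100, ], s$timeline,
                               sampling_rate = 50),
               "spans")
  expect_error(subject_session("x", s$channels, s$timeline,
                               sampling_rate = 50, spsl = c(1L, 7L, 0L)),
               "spsl")
})

test_that("epoch grids follow floor semantics and never overlap", {
  expect_length(build_epoch_grid(0, 120, 2)$epoch_starts, 60)
  expect_length(build_epoch_grid(0, 119.9, 2)$epoch_starts, 59)
  expect_length(build_epoch_grid(0, 60, 10)$epoch_starts, 6)
  # property over random regions
  set.seed(11)
  for (i in 1:50) {
    a <- runif(1, 0, 100)
    len <- runif(1, 0.1, 300)
    w <- sample(c(2, 10), 1)
    g <- build_epoch_grid(a, a + len, w)
    expect_length(g$epoch_starts, floor(len / w + 1e-9))
    if (length(g$epoch_starts)) {
      expect_true(all(diff(g$epoch_starts) == w))            # contiguous
      expect_lte(max(g$epoch_starts) + w, a + len + 1e-9)    # inside region
    }
  }
  expect_length(build_epoch_grid(0, 1.5, 2)$epoch_starts, 0) # short: empty
  expect_error(build_epoch_grid(10, 10, 2), "exceed")
})

test_that("native format round-trips sessions bit-exactly", {
  for (seed in 1:3) {
    s <- make_mini_session(seed)
    stem <- file.path(withr::local_tempdir(), "sess")
    write_session(s, stem)
    expect_true(file.exists(paste0(stem, "_samples.csv")))
    expect_true(file.exists(paste0(stem, "_events.json")))
    r <- read_session(stem)
    expect_identical(unname(r$channels), unname(s$channels))
    expect_identical(unclass(r$timeline), unclass(s$timeline))
    expect_identical(r$spsl, s$spsl)
    expect_identical(r$subject_id, s$subject_id)
    expect_identical(r$sampling_rate, s$sampling_rate)
    expect_identical(as.character(r$channel_map), as.character(s$channel_map))
  }
})

test_that("reading rejects malformed inputs", {
  s <- make_mini_session()
  stem <- file.path(withr::local_tempdir(), "sess")
  write_session(s, stem)
  # events violating the marker order fail validation on read
  ev <- jsonlite::read_json(paste0(stem, "_events.json"), simplifyVector = TRUE)
  ev$relax_start <- ev$mist_end - 1
  jsonlite::write_json(ev, paste0(stem, "_events.json"), auto_unbox = TRUE)
  expect_error(read_session(stem), "out of order")
  expect_error(read_session(file.path(tempdir(), "nope")), "missing file")
  expect_error(write_session(s, "/no/such/dir/x"), "unwritable")
})

test_that("EDF import maps labels to roles and recovers signals", {
  fs <- 50
  tl <- mini_timeline()
  n_rec <- floor(tl[["rs2_end"]])
  set.seed(4)
  ch <- matrix(rnorm(n_rec * fs * 8, sd = 20), ncol = 8)
  labels <- c("EEG Fp1", "EEG Fp2", "EEG F3", "EEG F4", "ECG lead",
              "EMG medial", "EMG lateral", "GSR")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rec.edf")
  write_mini_edf(path, ch, fs, labels)
  jsonlite::write_json(as.list(unclass(tl)), file.path(dir, "rec_events.json"),
                       auto_unbox = TRUE, digits = NA)
  s <- read_session(path, format = "edf")
  expect_identical(as.character(s$channel_map), CHANNEL_ROLES)
  expect_equal(s$sampling_rate, fs)
  # 16-bit quantization: signals recovered to the quantization step
  step <- (max(ch[, 1]) - min(ch[, 1])) / 65535
  expect_lt(max(abs(session_channel(s, "EEG_Fp1") - ch[, 1])), 2 * step)
  # unmatched label is a format error
  write_mini_edf(path, ch, fs, c("bogus", labels[-1]))
  expect_error(read_session(path, format = "edf"), "unmatched")
})
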