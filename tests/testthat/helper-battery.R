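# Shared 20-seed synthetic cohort battery, computed once per test session.
#
# Study conditions: 10 subjects per cohort at the default couplings,
# offsets and timeline. Within-subject checks (LOOCV accuracy, region
# contrasts, paired window tests, permutation null) use the cohorts as
# generated. The chance-level LOSO scenario additionally applies large
# disjoint per-subject marker offsets (offset_marker_sets), the regime in
# which between-subject generalization collapses.
battery_env <- new.env(parent = emptyenv())

battery_params <- function() sim_params()

battery_feature_sets <- list(all = c("rg", "hr", "ta", "sc"),
                             rg = "rg", hr = "hr", ta = "ta", sc = "sc")

run_battery_cohort <- function(seed, params = battery_params()) {
  cm <- simulate_cohort_markers(10, params, seed, include_rs1_late = TRUE)
  tl <- params$timeline
  roi <- lapply(cm$markers, function(m) m[m$region != "rs1_late", ])
  labeled <- lapply(roi, label_epochs, timeline = tl)
  loocv_acc <- sapply(battery_feature_sets, function(fs) {
    mean(vapply(labeled, function(d) loocv(d, fs)$p_a, numeric(1)))
  })
  loso_acc <- loso(labeled, c("rg", "hr", "ta", "sc"))$mean_accuracy
  loso_offset_acc <- loso(offset_marker_sets(labeled),
                          c("rg", "hr", "ta", "sc"))$mean_accuracy
  # permutation null: labels shuffled within one subject's dataset
  set.seed(10000 + seed)
  shuf <- labeled[[1]]
  shuf$label <- sample(shuf$label)
  perm_acc <- loocv(shuf, c("rg", "hr", "ta", "sc"))$p_a
  # within-subject region contrast (stressor minus first resting baseline)
  contrast <- sapply(c("rg", "hr", "ta", "sc"), function(f) {
    mean(vapply(roi, function(m) {
      mean(m[[f]][m$region == "mist"]) - mean(m[[f]][m$region == "rs1"])
    }, numeric(1)))
  })
  tests <- marker_window_tests(cm$markers, tl)
  p_mist_relax <- tests[tests$window_a == "mist_late" &
                          tests$window_b == "relax_late", c("marker", "p")]
  list(seed = seed, loocv = loocv_acc, loso = loso_acc,
       loso_offset = loso_offset_acc, perm = perm_acc,
       contrast = contrast,
       p_ta = p_mist_relax$p[p_mist_relax$marker == "ta"],
       p_sc = p_mist_relax$p[p_mist_relax$marker == "sc"])
}

get_battery <- function(n_seeds = 20) {
  key <- paste0("battery_", n_seeds)
  if (is.null(battery_env[[key]])) {
    battery_env[[key]] <- lapply(seq_len(n_seeds), run_battery_cohort)
  }
  battery_env[[key]]
}
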