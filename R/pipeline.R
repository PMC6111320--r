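#' Default pipeline configuration
#'
#' @param n_subjects Cohort size (default 10).
#' @param seed Master seed; fans out to per-subject sub-seeds via
#'   [cohort_subject_seeds()].
#' @param features Marker subset used by the classification stage.
#' @param cv Cross-validation scheme: `"loocv"`, `"loso"`, or both.
#' @param sim Optional list of [sim_params()] overrides.
#' @param write_sessions Also write every raw session in the native format
#'   (large files; off by default).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 10, seed = 1,
                            features = MARKER_FEATURES,
                            cv = c("loocv", "loso"),
                            sim = list(),
                            write_sessions = FALSE) {
  bad <- setdiff(features, MARKER_FEATURES)
  if (length(bad)) stop("config error: unknown feature name(s): ",
                        paste(bad, collapse = ", "))
  cv <- match.arg(cv, several.ok = TRUE)
  bad_sim <- setdiff(names(sim), names(formals(sim_params)))
  if (length(bad_sim)) stop("config error: unknown sim parameter(s): ",
                            paste(bad_sim, collapse = ", "))
  structure(list(n_subjects = n_subjects, seed = as.integer(seed),
                 features = features, cv = cv, sim = sim,
                 write_sessions = write_sessions),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with any subset of the [pipeline_config()] fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Chains simulate -> extract -> analyze -> classify on a synthetic cohort
#' and writes all result tables plus a run manifest to `out_dir`:
#' `markers.csv` (all subjects' per-epoch markers), `group_curves.csv`
#' (grand-averaged marker curves with SEM), `ttest_markers.csv` and
#' `ttest_spsl.csv` (paired between-period tests), `correlations.csv`
#' (pairwise marker correlations with Fisher CIs), `accuracy_<cv>.csv`
#' (per-subject accuracy with binomial CI, plus a mean row), and
#' `manifest.json` (seed, per-subject seeds, package version, config hash).
#' The run is fully deterministic given the seed.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage log messages (written to stderr).
#' @return Invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) if (!quiet) message(format(Sys.time(), "%H:%M:%S"),
                                                 " [", ..., "]")
  params <- do.call(sim_params, config$sim)
  tl <- params$timeline

  log_stage("simulate+extract: ", config$n_subjects, " subjects, seed ",
            config$seed)
  if (config$write_sessions) {
    seeds <- cohort_subject_seeds(config$seed, config$n_subjects)
    regions <- regions_of_interest(tl, include_rs1_late = TRUE)
    markers <- vector("list", config$n_subjects)
    spsl <- matrix(NA_integer_, config$n_subjects, 3)
    for (i in seq_len(config$n_subjects)) {
      s <- generate_session(sprintf("S%02d", i), params, seeds[i])
      write_session(s, file.path(out_dir, sprintf("session_S%02d", i)))
      markers[[i]] <- extract_markers(s, regions = regions)
      spsl[i, ] <- s$spsl
    }
    sim <- list(markers = markers, spsl = spsl)
  } else {
    sim <- simulate_cohort_markers(config$n_subjects, params, config$seed,
                                   include_rs1_late = TRUE)
  }
  all_markers <- do.call(rbind, sim$markers)
  utils::write.csv(all_markers, file.path(out_dir, "markers.csv"),
                   row.names = FALSE)

  log_stage("analyze: grand averages, t-tests, correlations")
  roi <- lapply(sim$markers, function(m) m[m$region != "rs1_late", ])
  curves <- lapply(stats::setNames(nm = MARKER_FEATURES), function(f) {
    grand_average(lapply(roi, `[[`, f))
  })
  gc_df <- data.frame(epoch = seq_len(nrow(curves$rg)))
  for (f in MARKER_FEATURES) {
    gc_df[[paste0(f, "_mean")]] <- curves[[f]]$mean
    gc_df[[paste0(f, "_sem")]] <- curves[[f]]$sem
  }
  utils::write.csv(gc_df, file.path(out_dir, "group_curves.csv"),
                   row.names = FALSE)
  tt <- marker_window_tests(sim$markers, tl)
  utils::write.csv(tt, file.path(out_dir, "ttest_markers.csv"),
                   row.names = FALSE)
  utils::write.csv(spsl_tests(sim$spsl), file.path(out_dir, "ttest_spsl.csv"),
                   row.names = FALSE)
  corr <- correlation_table(curves)
  utils::write.csv(corr, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)

  log_stage("classify: ", paste(config$cv, collapse = "+"), " on ",
            paste(config$features, collapse = "+"))
  labeled <- lapply(roi, label_epochs, timeline = tl)
  acc <- list()
  if ("loocv" %in% config$cv) {
    per <- lapply(labeled, loocv, features = config$features)
    df <- data.frame(
      subject_id = vapply(labeled, function(d) d$subject_id[1], character(1)),
      p_a = vapply(per, `[[`, numeric(1), "p_a"),
      n = vapply(per, `[[`, numeric(1), "n"),
      ci_half_width = vapply(per, `[[`, numeric(1), "ci_half_width"))
    df$display <- mapply(format_accuracy, df$p_a, df$n)
    df <- rbind(df, data.frame(subject_id = "mean", p_a = mean(df$p_a),
                               n = sum(df$n), ci_half_width = NA,
                               display = sprintf("%d ± %d",
                                 round_half_up(100 * mean(df$p_a)),
                                 round_half_up(100 * stats::sd(df$p_a)))))
    utils::write.csv(df, file.path(out_dir, "accuracy_loocv.csv"),
                     row.names = FALSE)
    acc$loocv <- df
  }
  if ("loso" %in% config$cv) {
    ls <- loso(labeled, features = config$features)
    df <- data.frame(
      subject_id = names(ls$per_subject),
      p_a = vapply(ls$per_subject, `[[`, numeric(1), "p_a"),
      n = vapply(ls$per_subject, `[[`, numeric(1), "n"),
      ci_half_width = vapply(ls$per_subject, `[[`, numeric(1), "ci_half_width"))
    df$display <- mapply(format_accuracy, df$p_a, df$n)
    df <- rbind(df, data.frame(subject_id = "mean", p_a = ls$mean_accuracy,
                               n = sum(df$n), ci_half_width = NA,
                               display = sprintf("%d ± %d",
                                 round_half_up(100 * ls$mean_accuracy),
                                 round_half_up(100 * stats::sd(df$p_a[df$subject_id != "mean"])))))
    utils::write.csv(df, file.path(out_dir, "accuracy_loso.csv"),
                     row.names = FALSE)
    acc$loso <- df
  }

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE)
  manifest <- list(
    seed = config$seed,
    subject_seeds = cohort_subject_seeds(config$seed, config$n_subjects),
    package_version = as.character(utils::packageVersion("stressmark")),
    config_hash = unname(tools::md5sum(cfg_path)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  log_stage("done: outputs in ", out_dir)
  invisible(list(markers = sim$markers, spsl = sim$spsl, curves = curves,
                 ttests = tt, correlations = corr, accuracy = acc))
}
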