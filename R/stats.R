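#' Centered moving average with edge shrinkage
#'
#' A 10-sample centered window (offsets -4 .. +5 around each sample) that
#' shrinks to the available samples at the series edges, preserving event
#' alignment and series length.
#'
#' @param x Numeric vector.
#' @param width Window width in samples (default 10).
#' @return Smoothed vector, same length.
#' @export
moving_average <- function(x, width = 10) {
  n <- length(x)
  lo <- floor((width - 1) / 2)          # samples taken before i
  hi <- width - 1 - lo                  # samples taken after i
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  from <- pmax(1L, i - lo)
  to <- pmin(n, i + hi)
  (cs[to + 1L] - cs[from]) / (to - from + 1L)
}

# z-score a series; constant series map to zeros with a warning
zscore_guard <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12 * max(1, abs(mean(x)))) {
    warning("constant series mapped to zeros in z-scoring")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Grand-average of per-subject marker series
#'
#' Each subject's series is z-scored over its full region-of-interest extent,
#' smoothed with a 10-sample centered moving average, and the per-epoch mean
#' and standard error of the mean (SEM) across subjects are returned.
#'
#' @param per_subject_series List (one element per subject) of equal-length
#'   numeric vectors, one value per 2-s epoch.
#' @param smooth_width Moving-average width in samples (default 10).
#' @return A `group_curve` data.frame with columns `mean` and `sem`, plus a
#'   `smoothed` attribute holding the matrix of processed per-subject series.
#' @export
grand_average <- function(per_subject_series, smooth_width = 10) {
  ns <- length(per_subject_series)
  if (ns < 2L) stop("grand average needs at least 2 subjects")
  len <- lengths(per_subject_series)
  if (length(unique(len)) != 1L) stop("per-subject series differ in length")
  sm <- vapply(per_subject_series,
               function(x) moving_average(zscore_guard(x), smooth_width),
               numeric(len[1]))
  out <- data.frame(mean = rowMeans(sm),
                    sem = apply(sm, 1L, stats::sd) / sqrt(ns))
  attr(out, "smoothed") <- sm
  class(out) <- c("group_curve", "data.frame")
  out
}

#' Paired-sample t-test
#'
#' Classical paired t-test on the differences, two-sided. Degenerate inputs
#' are kept total: identical vectors give `t = 0, p = 1`; identical nonzero
#' differences (zero variance) give an infinite t with `p = 0`, flagged.
#'
#' @param a,b Equal-length numeric vectors (paired observations).
#' @param alpha Significance level (default 0.05).
#' @return List with `t`, `p`, `df`, `alpha`, `significant`, `degenerate`.
#' @export
paired_ttest <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("paired samples differ in length")
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs")
  d <- a - b
  res <- if (stats::sd(d) < 1e-12 * max(1, abs(mean(d)))) {
    if (all(abs(d) < 1e-300)) {
      list(t = 0, p = 1, degenerate = FALSE)
    } else {
      list(t = sign(mean(d)) * Inf, p = 0, degenerate = TRUE)
    }
  } else {
    tt <- stats::t.test(a, b, paired = TRUE)
    list(t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
  }
  res$df <- n - 1L
  res$alpha <- alpha
  res$significant <- res$p < alpha
  res[c("t", "p", "df", "alpha", "significant", "degenerate")]
}

#' Between-period comparison windows
#'
#' The three 30-s windows contrasted by the marker t-tests: the last 30 s of
#' the first resting-state block, the last 30 s of the stressor session, and
#' the second-to-last 30 s of the relaxation block (i.e. ending 30 s before
#' the block does). Each holds 15 two-second epochs.
#'
#' @param timeline An `event_timeline`.
#' @return data.frame with columns `window`, `start_s`, `end_s`.
#' @export
comparison_windows <- function(timeline) {
  tl <- event_timeline(timeline)
  if (tl[["relax_end"]] - tl[["relax_start"]] < 60) {
    stop("relaxation block shorter than 60 s: comparison windows undefined")
  }
  if (tl[["rs1_end"]] - tl[["rs1_start"]] < 30 ||
      tl[["mist_end"]] - tl[["mist_train_start"]] < 30) {
    stop("comparison windows extend outside their blocks")
  }
  data.frame(
    window = c("rs1_late", "mist_late", "relax_late"),
    start_s = c(tl[["rs1_end"]] - 30, tl[["mist_end"]] - 30,
                tl[["relax_end"]] - 60),
    end_s = c(tl[["rs1_end"]], tl[["mist_end"]], tl[["relax_end"]] - 30),
    stringsAsFactors = FALSE)
}

#' Per-subject marker means over the comparison windows
#'
#' @param per_subject_markers List of `marker_set`s (one per subject) whose
#'   epochs cover the comparison windows (use
#'   `regions_of_interest(timeline, include_rs1_late = TRUE)` when
#'   extracting).
#' @param timeline An `event_timeline`.
#' @return data.frame with columns `subject_id`, `window`, `rg`, `hr`, `ta`,
#'   `sc` (mean marker value over the window's epochs).
#' @export
window_marker_means <- function(per_subject_markers, timeline) {
  win <- comparison_windows(timeline)
  rows <- lapply(per_subject_markers, function(mk) {
    do.call(rbind, lapply(seq_len(nrow(win)), function(i) {
      sel <- mk$epoch_start_s >= win$start_s[i] & mk$epoch_start_s < win$end_s[i]
      if (!any(sel)) {
        stop("no marker epochs inside window '", win$window[i],
             "' [", win$start_s[i], ", ", win$end_s[i], ")")
      }
      data.frame(subject_id = mk$subject_id[1], window = win$window[i],
                 rg = mean(mk$rg[sel]), hr = mean(mk$hr[sel]),
                 ta = mean(mk$ta[sel]), sc = mean(mk$sc[sel]),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired t-tests of markers between comparison windows
#'
#' For every marker and every pair of comparison windows, a paired t-test
#' across subjects of the per-subject window means. No multiple-testing
#' correction is applied (each test at `alpha`).
#'
#' @inheritParams window_marker_means
#' @param alpha Significance level (default 0.05).
#' @return data.frame with columns `marker`, `window_a`, `window_b`, `t`,
#'   `p`, `significant`.
#' @export
marker_window_tests <- function(per_subject_markers, timeline, alpha = 0.05) {
  wm <- window_marker_means(per_subject_markers, timeline)
  wins <- unique(wm$window)
  pairs <- utils::combn(wins, 2, simplify = FALSE)
  out <- list()
  for (marker in c("rg", "hr", "ta", "sc")) {
    for (pr in pairs) {
      a <- wm[wm$window == pr[1], marker]
      b <- wm[wm$window == pr[2], marker]
      tt <- paired_ttest(a, b, alpha)
      out[[length(out) + 1L]] <- data.frame(
        marker = marker, window_a = pr[1], window_b = pr[2],
        t = tt$t, p = tt$p, significant = tt$significant,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Paired t-tests of the self-perceived stress ratings
#'
#' Compares the 0-4 self-ratings across subjects between the three rating
#' points (before the stressor, after the stressor, after relaxation).
#'
#' @param spsl n x 3 matrix of ratings (columns T1, T2, T3).
#' @param alpha Significance level.
#' @return data.frame with one row per rating-point pair.
#' @export
spsl_tests <- function(spsl, alpha = 0.05) {
  spsl <- as.matrix(spsl)
  stopifnot(ncol(spsl) == 3)
  pairs <- list(c(1, 2), c(2, 3), c(1, 3))
  do.call(rbind, lapply(pairs, function(pr) {
    tt <- paired_ttest(spsl[, pr[1]], spsl[, pr[2]], alpha)
    data.frame(point_a = paste0("T", pr[1]), point_b = paste0("T", pr[2]),
               t = tt$t, p = tt$p, significant = tt$significant,
               stringsAsFactors = FALSE)
  }))
}

#' Pearson correlation with Fisher-transform 95% confidence interval
#'
#' The interval is `tanh(atanh(r) +- z / sqrt(n - 3))` with `z = 1.96`.
#' Either two equal-length series or a precomputed `(r, n)` pair may be
#' supplied. `|r| = 1` yields the degenerate interval `(r, r)`.
#'
#' @param x,y Paired numeric series (optional when `r` and `n` are given).
#' @param r Pearson coefficient (computed from `x`, `y` when omitted).
#' @param n Number of pairs (taken from `x` when omitted); must be >= 4.
#' @param z Normal quantile for the interval (default 1.96).
#' @return A `correlation_result` list: `pcc`, `n`, `ci_low`, `ci_up`.
#' @export
pearson_ci <- function(x = NULL, y = NULL, r = NULL, n = NULL, z = 1.96) {
  if (is.null(r)) {
    if (length(x) != length(y)) stop("x and y differ in length")
    r <- stats::cor(x, y)
    n <- length(x)
  }
  if (is.null(n)) stop("n is required when r is supplied directly")
  if (n < 4) stop("need at least 4 pairs for a Fisher interval")
  if (abs(r) >= 1) {
    ci <- c(r, r)
  } else {
    zr <- atanh(r)
    ci <- tanh(zr + c(-1, 1) * z / sqrt(n - 3))
  }
  structure(list(pcc = r, n = n, ci_low = ci[1], ci_up = ci[2]),
            class = "correlation_result")
}

#' Pairwise correlation table of grand-averaged markers
#'
#' Computes the Pearson coefficient and Fisher 95% CI between every pair of
#' grand-averaged (z-scored, smoothed) marker curves, with `n` equal to the
#' number of epoch pairs.
#'
#' @param curves Named list of four `group_curve`s (rg, hr, ta, sc) of equal
#'   length.
#' @return data.frame shaped like the reference correlation table: columns
#'   `pair`, `pcc`, `ci_low`, `ci_up`, `n`.
#' @export
correlation_table <- function(curves) {
  nm <- names(curves)
  prs <- utils::combn(nm, 2, simplify = FALSE)
  do.call(rbind, lapply(prs, function(pr) {
    ci <- pearson_ci(curves[[pr[1]]]$mean, curves[[pr[2]]]$mean)
    data.frame(pair = paste(toupper(pr), collapse = ", "),
               pcc = ci$pcc, ci_low = ci$ci_low, ci_up = ci$ci_up, n = ci$n,
               stringsAsFactors = FALSE)
  }))
}
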