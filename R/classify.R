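#' Class labels in fixed order
#'
#' Deterministic tie-breaks and confusion tables use this order:
#' stress < relax < neutral.
#' @format Character vector of the three class labels.
#' @export
STRESS_CLASSES <- c("stress", "relax", "neutral")

#' Marker feature names
#' @format Character vector of the four marker column names.
#' @export
MARKER_FEATURES <- c("rg", "hr", "ta", "sc")

#' Label marker epochs for three-level classification
#'
#' Class windows on the default timeline: minutes 7-8 of the stressor
#' session (training start + 360 s to + 480 s, the period of maximum stress)
#' are `stress`; minutes 2-3 of the relaxation block (+60 s to +180 s, the
#' period of minimum stress) are `relax`; the central minute of each
#' resting-state block is `neutral`. With 2-s epochs this yields 60
#' observations per class, 180 per subject.
#'
#' @param markers A `marker_set` covering the regions of interest.
#' @param timeline The session's `event_timeline`.
#' @return A `labeled_dataset` data.frame: `subject_id`, `epoch_start_s`,
#'   `label` (factor with levels [STRESS_CLASSES]), and the four marker
#'   columns.
#' @export
label_epochs <- function(markers, timeline) {
  tl <- event_timeline(timeline)
  win <- class_windows(tl)
  lab <- rep(NA_character_, nrow(markers))
  for (i in seq_len(nrow(win))) {
    sel <- markers$epoch_start_s >= win$start_s[i] &
      markers$epoch_start_s < win$end_s[i]
    lab[sel] <- win$class[i]
  }
  keep <- !is.na(lab)
  out <- data.frame(subject_id = markers$subject_id[keep],
                    epoch_start_s = markers$epoch_start_s[keep],
                    label = factor(lab[keep], levels = STRESS_CLASSES),
                    markers[keep, MARKER_FEATURES],
                    stringsAsFactors = FALSE)
  counts <- table(out$label)
  expected <- vapply(split(win, win$class), function(w) {
    sum((w$end_s - w$start_s) / 2)
  }, numeric(1))[STRESS_CLASSES]
  if (any(counts != expected)) {
    stop("class window epoch counts ",
         paste(sprintf("%s=%d (expected %d)", names(counts), counts,
                       expected), collapse = ", "),
         "; markers must cover all class windows")
  }
  rownames(out) <- NULL
  class(out) <- c("labeled_dataset", "data.frame")
  out
}

# the four labeling windows; errors if a block is too short for its window
class_windows <- function(tl) {
  if (tl[["relax_end"]] - tl[["relax_start"]] < 180) {
    stop("relaxation block shorter than 180 s: relax class window undefined")
  }
  if (tl[["mist_end"]] - tl[["mist_train_start"]] < 480) {
    stop("stressor session shorter than 480 s: stress class window undefined")
  }
  data.frame(
    class = c("stress", "relax", "neutral", "neutral"),
    start_s = c(tl[["mist_train_start"]] + 360, tl[["relax_start"]] + 60,
                tl[["rs1_start"]] + 30, tl[["rs2_start"]] + 30),
    end_s = c(tl[["mist_train_start"]] + 480, tl[["relax_start"]] + 180,
              tl[["rs1_start"]] + 90, tl[["rs2_start"]] + 90),
    stringsAsFactors = FALSE)
}

#' Fit a linear discriminant model
#'
#' Gaussian classes with shared covariance: per-class means and the pooled
#' within-class covariance are estimated, priors are equal (the design is
#' balanced at 60 epochs per class), and a small ridge
#' (`1e-6 * trace / dim`) is added to the pooled covariance so degenerate
#' cross-validation folds cannot produce a singular fit.
#'
#' @param train A `labeled_dataset` (or data.frame with a `label` factor and
#'   marker columns).
#' @param features Subset of [MARKER_FEATURES] to use.
#' @return An `lda_model`: class means, pooled covariance (inverse), priors.
#' @export
fit_lda <- function(train, features = MARKER_FEATURES) {
  bad <- setdiff(features, MARKER_FEATURES)
  if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  y <- droplevels(factor(train$label, levels = STRESS_CLASSES))
  if (nlevels(y) < 2L) stop("training data must contain at least 2 classes")
  X <- as.matrix(train[, features, drop = FALSE])
  if (!all(is.finite(X))) stop("non-finite feature values in training data")
  d <- ncol(X)
  if (any(table(y) < d + 1L)) {
    stop("each class needs at least ", d + 1L, " training rows")
  }
  fit <- lda_fit_xy(X, y)
  fit$features <- features
  structure(fit, class = "lda_model")
}

#' Predict class labels with a fitted LDA model
#'
#' Assigns the class maximizing the linear discriminant score
#' `x' S^-1 m_k - m_k' S^-1 m_k / 2 + log prior_k`; exact ties are broken by
#' the fixed class order (stress < relax < neutral).
#'
#' @param object An `lda_model`.
#' @param newdata data.frame with the model's feature columns, or a numeric
#'   matrix/vector in feature order.
#' @param ... Unused.
#' @return Factor of predicted labels (levels [STRESS_CLASSES]).
#' @export
predict.lda_model <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) {
    as.matrix(newdata[, object$features, drop = FALSE])
  } else if (is.null(dim(newdata))) {
    rbind(newdata)                       # single feature vector
  } else {
    as.matrix(newdata)
  }
  if (ncol(X) != length(object$features)) {
    stop("feature dimension mismatch: expected ", length(object$features))
  }
  if (!all(is.finite(X))) stop("non-finite feature values")
  # ties broken by max.col(..., "first"): columns are in fixed class order
  lda_predict_xy(object, X)
}

#' Binomial half-width of the accuracy confidence interval
#'
#' `1.96 * sqrt(p (1 - p) / n)`, the normal-approximation 95% interval
#' half-width of a success probability estimated from n observations.
#'
#' @param p_a Success probability in \[0, 1\].
#' @param n Number of observations.
#' @return Half-width on the probability scale.
#' @export
accuracy_ci <- function(p_a, n) {
  stopifnot(p_a >= 0, p_a <= 1, n >= 1)
  1.96 * sqrt(p_a * (1 - p_a) / n)
}

# round half up (the table-display convention; R's round() is half-even)
round_half_up <- function(x) floor(x + 0.5)

#' Format an accuracy with its CI as integer percentages
#' @param p_a Success probability.
#' @param n Number of observations.
#' @return String `"NN ± M"` (both rounded half-up to integer percent).
#' @export
format_accuracy <- function(p_a, n) {
  sprintf("%d ± %d", round_half_up(100 * p_a),
          round_half_up(100 * accuracy_ci(p_a, n)))
}

# build an accuracy_result from truth/prediction factors
accuracy_result <- function(truth, pred, n_skipped = 0L) {
  n <- length(truth)
  confusion <- table(truth = truth, predicted = pred)
  p_a <- sum(diag(confusion)) / n
  structure(list(p_a = p_a, n = n, ci_half_width = accuracy_ci(p_a, n),
                 confusion = confusion, n_skipped = n_skipped),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat("accuracy", format_accuracy(x$p_a, x$n), "% (n =", x$n, ")\n")
  print(x$confusion)
  invisible(x)
}

# matrix-level LDA fit (classes = present levels of y, in level order)
lda_fit_xy <- function(X, y) {
  classes <- levels(y)[tabulate(y, nlevels(y)) > 0L]
  d <- ncol(X)
  counts <- table(factor(y, levels = classes))
  means <- rowsum(X, y) / as.numeric(counts)
  scatter <- crossprod(X) - crossprod(sqrt(as.numeric(counts)) * means)
  sigma <- scatter / (nrow(X) - length(classes))
  sigma <- sigma + diag(1e-6 * sum(diag(sigma)) / d, d)
  list(classes = classes, means = means, sigma = sigma,
       sigma_inv = solve(sigma),
       priors = stats::setNames(rep(1 / length(classes), length(classes)),
                                classes))
}

lda_predict_xy <- function(fit, X) {
  W <- fit$sigma_inv %*% t(fit$means)
  b <- -0.5 * colSums(t(fit$means) * W) + log(fit$priors)
  scores <- X %*% W + matrix(b, nrow(X), length(b), byrow = TRUE)
  factor(fit$classes[max.col(scores, ties.method = "first")],
         levels = STRESS_CLASSES)
}

#' Leave-one-epoch-out cross-validation
#'
#' For each observation, the model is trained on the remaining n - 1
#' observations and used to classify the held-out one. Folds whose training
#' part loses a class entirely are skipped with a warning and n adjusted.
#'
#' @param dataset A `labeled_dataset` (one subject's 180 epochs in the
#'   default design).
#' @param features Marker subset to use.
#' @return An `accuracy_result`: `p_a`, `n`, `ci_half_width` (binomial),
#'   per-class `confusion` counts.
#' @export
loocv <- function(dataset, features = MARKER_FEATURES) {
  n <- nrow(dataset)
  if (n < 2L) stop("leave-one-out needs at least 2 observations")
  bad <- setdiff(features, MARKER_FEATURES)
  if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  y <- factor(dataset$label, levels = STRESS_CLASSES)
  X <- as.matrix(dataset[, features, drop = FALSE])
  if (!all(is.finite(X))) stop("non-finite feature values")
  nlev <- nlevels(droplevels(y))
  pred <- factor(rep(NA_character_, n), levels = STRESS_CLASSES)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    yt <- y[-i]
    if (nlevels(droplevels(yt)) < nlev) {
      ok[i] <- FALSE
      next
    }
    fit <- lda_fit_xy(X[-i, , drop = FALSE], yt)
    pred[i] <- lda_predict_xy(fit, X[i, , drop = FALSE])
  }
  if (!all(ok)) {
    warning(sum(!ok), " fold(s) skipped: a class vanished from training")
  }
  accuracy_result(y[ok], pred[ok], n_skipped = sum(!ok))
}

#' Leave-one-subject-out cross-validation
#'
#' Each subject's epochs are classified by a model trained on the pooled
#' epochs of all remaining subjects. Features enter as raw marker values
#' with no per-subject recalibration, so systematic between-subject offsets
#' directly degrade this scheme.
#'
#' @param per_subject List of `labeled_dataset`s, one per subject.
#' @param features Marker subset to use.
#' @return List with `per_subject` (named list of `accuracy_result`s, CI at
#'   each subject's n) and `mean_accuracy`.
#' @export
loso <- function(per_subject, features = MARKER_FEATURES) {
  if (length(per_subject) < 2L) stop("leave-one-subject-out needs >= 2 subjects")
  ids <- vapply(per_subject, function(d) as.character(d$subject_id[1]),
                character(1))
  res <- lapply(seq_along(per_subject), function(i) {
    train <- do.call(rbind, per_subject[-i])
    fit <- fit_lda(train, features)
    test <- per_subject[[i]]
    pred <- predict(fit, test)
    accuracy_result(factor(test$label, levels = STRESS_CLASSES), pred)
  })
  names(res) <- ids
  list(per_subject = res,
       mean_accuracy = mean(vapply(res, `[[`, numeric(1), "p_a")))
}
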