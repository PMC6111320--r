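# small labeled dataset with gaussian classes at given means
make_clouds <- function(mu, n = 60, sd = 1, d = 2, seed = 1,
                        subject_id = "S") {
  set.seed(seed)
  X <- do.call(rbind, lapply(mu, function(m) {
    matrix(rnorm(n * d, mean = m, sd = sd), n, d)
  }))
  df <- data.frame(subject_id = subject_id,
                   epoch_start_s = seq_len(nrow(X)),
                   label = factor(rep(STRESS_CLASSES, each = n),
                                  levels = STRESS_CLASSES))
  df$rg <- X[, 1]
  df$hr <- if (d >= 2) X[, 2] else X[, 1]
  df
}

test_that("class labeling carves 60 epochs per class from the markers", {
  p <- sim_params()
  tl <- p$timeline
  mk <- extract_markers(generate_session("S07", p, seed = 77))
  lab <- label_epochs(mk, tl)
  expect_identical(as.integer(table(lab$label)), c(60L, 60L, 60L))
  expect_identical(nrow(lab), 180L)
  # class windows are pairwise disjoint in time
  w <- stressmark:::class_windows(tl)
  for (i in 1:3) for (j in (i + 1):4) {
    if (j > 4) break
    expect_true(w$end_s[i] <= w$start_s[j] || w$end_s[j] <= w$start_s[i])
  }
  # stress window is minutes 7-8 of the 9-min stressor session
  expect_equal(w$start_s[w$class == "stress"], tl[["mist_train_start"]] + 360)
  # too-short relaxation block cannot host the relax window
  expect_error(stressmark:::class_windows(
    event_timeline(default_timeline(relax_s = 150))), "180 s")
})

test_that("LDA separates symmetric classes at the midpoint boundary", {
  df <- make_clouds(c(-1, 1, 30), n = 40, sd = 0.2, d = 1, seed = 2)
  fit <- fit_lda(df, "rg")
  # 1-D symmetric classes at -1 / +1: boundary at 0
  expect_identical(as.character(predict(fit, data.frame(rg = -0.05))), "stress")
  expect_identical(as.character(predict(fit, data.frame(rg = 0.05))), "relax")
  # a class mean classifies as its own class
  expect_identical(as.character(predict(fit, data.frame(rg = 30))), "neutral")
  # batch predict equals the map of single predictions
  nd <- data.frame(rg = c(-2, 0.5, 29, -0.9))
  expect_identical(predict(fit, nd),
                   factor(vapply(nd$rg, function(v) {
                     as.character(predict(fit, data.frame(rg = v)))
                   }, character(1)), levels = STRESS_CLASSES))
})

test_that("LDA with shared isotropic covariance is nearest-centroid", {
  set.seed(3)
  for (rep in 1:10) {
    mu <- runif(3, -3, 3)
    df <- make_clouds(mu, n = 25, sd = 1, d = 2, seed = 100 + rep)
    fit <- fit_lda(df, c("rg", "hr"))
    # force a shared isotropic covariance: LDA must then equal the
    # nearest-class-mean rule exactly (equal priors cancel)
    fit$sigma_inv <- diag(2)
    grid <- data.frame(rg = runif(50, -5, 5), hr = runif(50, -5, 5))
    got <- predict(fit, grid)
    centroids <- fit$means
    want <- apply(grid, 1, function(x) {
      d2 <- rowSums(sweep(centroids, 2, as.numeric(x))^2)
      fit$classes[which.min(d2)]
    })
    expect_identical(as.character(got), unname(want))
  }
})

test_that("LDA predictions agree with an independent implementation", {
  df <- make_clouds(c(0, 1.5, 3), n = 60, sd = 1, d = 2, seed = 4)
  fit <- fit_lda(df, c("rg", "hr"))
  ref <- MASS::lda(df[, c("rg", "hr")], grouping = df$label,
                   prior = rep(1 / 3, 3))
  got <- predict(fit, df)
  want <- predict(ref, df[, c("rg", "hr")])$class
  expect_identical(as.character(got), as.character(want))
})

test_that("ridge keeps duplicated feature columns usable", {
  df <- make_clouds(c(0, 2, 4), n = 30, sd = 1, d = 1, seed = 5)
  df$hr <- df$rg                        # exactly collinear
  single <- predict(fit_lda(df, "rg"), df)
  dup <- predict(fit_lda(df, c("rg", "hr")), df)
  expect_identical(dup, single)
})

test_that("ties break deterministically by fixed class order", {
  df <- data.frame(label = factor(rep(STRESS_CLASSES[1:2], each = 10),
                                  levels = STRESS_CLASSES),
                   rg = rep(c(-1, 1), each = 10))
  fit <- fit_lda(df, "rg")
  # exactly equidistant point: stress wins (first in class order)
  expect_identical(as.character(predict(fit, data.frame(rg = 0))), "stress")
})

test_that("input validation catches bad features and dimensions", {
  df <- make_clouds(c(0, 2, 4), seed = 6)
  expect_error(fit_lda(df, "bogus"), "unknown feature")
  expect_error(fit_lda(df[df$label == "stress", ], "rg"), "2 classes")
  fit <- fit_lda(df, c("rg", "hr"))
  expect_error(predict(fit, matrix(1, 2, 3)), "dimension")
})

test_that("LOOCV is perfect on well-separated clouds", {
  df <- make_clouds(c(0, 300, 600), n = 60, sd = 0.01, d = 2, seed = 7)
  res <- loocv(df, c("rg", "hr"))
  expect_equal(res$p_a, 1.0)
  expect_identical(res$n, 180L)
  expect_equal(res$ci_half_width, 0)
  expect_equal(sum(res$confusion), 180)
  expect_equal(sum(diag(res$confusion)), 180)
})

test_that("binomial accuracy interval matches the reference cells", {
  expect_equal(accuracy_ci(0.98, 180), 0.0205, tolerance = 1e-2)
  expect_identical(format_accuracy(0.98, 180), "98 ± 2")
  expect_equal(accuracy_ci(0.51, 180), 0.0730, tolerance = 1e-2)
  expect_identical(format_accuracy(0.51, 180), "51 ± 7")
  expect_identical(accuracy_ci(0, 180), 0)
  expect_identical(accuracy_ci(1, 180), 0)
})

test_that("LOSO trains across subjects and is deterministic", {
  per <- lapply(1:3, function(i) {
    make_clouds(c(0, 3, 6), n = 30, sd = 0.5, d = 2, seed = 10 + i,
                subject_id = paste0("S", i))
  })
  r1 <- loso(per, c("rg", "hr"))
  r2 <- loso(per, c("rg", "hr"))
  expect_identical(r1, r2)
  # homogeneous subjects: LOSO is near-perfect like LOOCV
  expect_gt(r1$mean_accuracy, 0.95)
  # large disjoint per-subject offsets push LOSO toward chance
  per_off <- lapply(seq_along(per), function(i) {
    d <- per[[i]]
    d$rg <- d$rg + i * 50
    d$hr <- d$hr + i * 50
    d
  })
  ro <- loso(per_off, c("rg", "hr"))
  expect_lt(ro$mean_accuracy, 0.6)
  expect_error(loso(per[1]), "2 subjects")
})
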