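make_feat <- function(vec, index = 0L, label = NA) {
  pose <- structure(list(scale = vec[1], pitch = vec[2], yaw = vec[3],
                         roll = vec[4], shift_x = vec[5], shift_y = vec[6]),
                    class = "pf_pose")
  frame_features(pose, vec[7:15] / sum(vec[7:15]), frame_index = index,
                 label = label)
}

# synthetic 15-dim feature vectors with a positive LBP block
rand_feat <- function(label, shift = 0, index = 0L) {
  v <- c(rnorm(6), abs(rnorm(9)) + 0.1 + shift)
  make_feat(v, index = index, label = label)
}

test_that("class templates are per-class means of z-normalised peaks", {
  set.seed(10)
  one <- list(rand_feat(1, 0, 0L), rand_feat(2, 1, 1L), rand_feat(3, 2, 2L))
  tm <- build_class_templates(one)
  expect_equal(dim(tm$templates), c(3L, 15L))
  expect_equal(unname(tm$support), c(1L, 1L, 1L))
  # with one frame per class, templates equal those normalised vectors
  Z <- painface:::pf_znorm(features_matrix(one), tm)
  expect_equal(unname(tm$templates), unname(Z), tolerance = 1e-12)

  # duplicating the training set leaves the templates unchanged
  tm2 <- build_class_templates(c(one, one))
  expect_equal(tm2$templates, tm$templates)

  expect_error(build_class_templates(one[1:2]), class = "pf_training_error")
})

test_that("templates recover planted Gaussian cluster means", {
  set.seed(11)
  mu <- list(`1` = rep(0, 15), `2` = c(rep(2, 6), rep(1, 9)),
             `3` = c(rep(-1, 6), rep(3, 9)))
  feats <- list(); labs <- c()
  for (cl in 1:3) for (i in 1:50) {
    v <- mu[[cl]] + rnorm(15, sd = 0.5)
    v[7:15] <- abs(v[7:15]) + 0.05
    feats <- c(feats, list(make_feat(v, label = cl)))
  }
  tm <- build_class_templates(feats)
  X <- features_matrix(feats)
  labels <- vapply(feats, function(f) f$label, numeric(1))
  Z <- painface:::pf_znorm(X, tm)
  for (cl in 1:3) {
    truth <- colMeans(Z[labels == cl, ])
    sds <- apply(Z[labels == cl, ], 2, sd)
    expect_true(all(abs(tm$templates[cl, ] - truth) <= 3 * sds / sqrt(50) + 1e-9))
  }
})

test_that("frame distance is a plain Euclidean norm", {
  expect_equal(frame_distance(rep(1, 15), rep(1, 15)), 0)
  expect_equal(frame_distance(rep(0, 15), c(3, 4, rep(0, 13))), 5)
  set.seed(12)
  a <- rnorm(15); b <- rnorm(15)
  expect_equal(frame_distance(a, b), sqrt(sum((a - b)^2)), tolerance = 1e-12)
  expect_error(frame_distance(rnorm(4), rnorm(5)), class = "pf_contract_error")
})

test_that("the soft-threshold rule matches its brute-force form everywhere", {
  th <- threshold_config(1, 2)
  # the decision rule at the stated evaluation points
  expect_equal(classify_frame(0.5 * th$delta1, th), 1L)
  expect_equal(classify_frame((th$delta1 + th$delta2) / 2, th), 3L)
  expect_equal(classify_frame(2 * th$delta2, th), 2L)
  # boundary equalities fall to the more severe branch
  expect_equal(classify_frame(th$delta1, th), 3L)
  expect_equal(classify_frame(th$delta2, th), 2L)

  # brute-force conditional over a 10,000-point grid
  grid <- seq(0, 4, length.out = 10000)
  fast <- classify_frame(grid, th)
  slow <- vapply(grid, function(d) {
    if (d < 1) 1L else if (d < 2) 3L else 2L
  }, integer(1))
  expect_equal(unname(fast), slow)

  # monotone: increasing diff never moves the label back toward neutral
  sev <- c(`1` = 1L, `3` = 2L, `2` = 3L)  # severity ordering
  expect_true(all(diff(sev[as.character(fast)]) >= 0))

  expect_error(threshold_config(2, 1), class = "pf_config_error")
  expect_error(threshold_config(-1, 1), class = "pf_config_error")
})

test_that("threshold calibration separates separable distance clusters", {
  set.seed(13)
  d <- c(runif(40, 0.5, 1.5), runif(40, 4.5, 5.5), runif(40, 8.5, 9.5))
  labs <- rep(c(1L, 3L, 2L), each = 40)
  th <- calibrate_thresholds(d, labs)
  # thresholds sit between the clusters (candidates are observed
  # distances, so a boundary may land exactly on a cluster's lowest value)
  expect_gt(th$delta1, 1.5); expect_lte(th$delta1, min(d[labs == 3L]))
  expect_gt(th$delta2, 5.5); expect_lte(th$delta2, min(d[labs == 2L]))
  expect_equal(attr(th, "accuracy"), 1)
  # exhaustive oracle: no (d1, d2) pair does better than perfect
  expect_true(all(classify_frame(d, th) == labs))

  # duplication invariance
  th2 <- calibrate_thresholds(c(d, d), c(labs, labs))
  expect_equal(th2$delta1, th$delta1)
  expect_equal(th2$delta2, th$delta2)

  # degenerate: all distances identical
  expect_warning(thd <- calibrate_thresholds(rep(2, 30), rep(1:3, 10)),
                 "degenerate")
  expect_lt(thd$delta1, thd$delta2)

  expect_error(calibrate_thresholds(1:5, c(1, 1, 2, 2, 2)),
               class = "pf_training_error")
})

test_that("calibration never returns delta1 >= delta2 (property)", {
  set.seed(14)
  for (rep in 1:10) {
    d <- abs(rnorm(60, mean = sample(1:5, 1)))
    labs <- sample(1:3, 60, replace = TRUE)
    while (!all(1:3 %in% labs)) labs <- sample(1:3, 60, replace = TRUE)
    th <- suppressWarnings(calibrate_thresholds(d, labs))
    expect_lt(th$delta1, th$delta2)
  }
})

test_that("classify_stream labels frames against the neutral template", {
  set.seed(15)
  feats <- list()
  for (i in 1:30) feats <- c(feats, list(rand_feat(1, 0, i - 1L)))
  for (i in 31:60) feats <- c(feats, list(rand_feat(2, 3, i - 1L)))
  for (i in 61:90) feats <- c(feats, list(rand_feat(3, 1, i - 1L)))
  tm <- build_class_templates(feats)
  Z <- painface:::pf_znorm(features_matrix(feats), tm)
  d <- sqrt(rowSums(sweep(Z, 2, tm$templates["neutral_face", ])^2))
  labs <- vapply(feats, function(f) as.integer(f$label), integer(1))
  th <- calibrate_thresholds(d, labs)

  out <- classify_stream(feats, tm, th, reference = "neutral_template")
  expect_equal(nrow(out), 90L)
  expect_equal(out$diff, d, tolerance = 1e-12)
  expect_true(all(out$status == "classified"))
  expect_true(all(c("d_neutral", "d_pain", "d_not_pain") %in% names(out)))

  # empty input, and skipped frames
  expect_equal(nrow(classify_stream(list(), tm, th)), 0L)
  out2 <- classify_stream(c(feats[1:2], list(NULL)), tm, th)
  expect_equal(out2$status[3], "skipped")
  expect_true(is.na(out2$label[3]))

  # determinism (under the adaptive default reference too)
  expect_identical(out, classify_stream(feats, tm, th,
                                        reference = "neutral_template"))
  expect_identical(classify_stream(feats, tm, th),
                   classify_stream(feats, tm, th))
})

test_that("running-peak reference flags a class change within one GOP", {
  set.seed(16)
  feats <- list()
  for (i in 1:45) feats <- c(feats, list(rand_feat(1, 0, i - 1L)))
  for (i in 46:90) feats <- c(feats, list(rand_feat(2, 5, i - 1L)))
  tmpl_feats <- c(feats, list(rand_feat(3, 2, 90L)))  # all classes present
  tm <- build_class_templates(tmpl_feats)
  th <- threshold_config(2, 4)
  out <- classify_stream(feats, tm, th, gop = 15, reference = "running_peak")
  # the first frames after the switch are far from the stale neutral peak
  switch_window <- out$label[46:60]
  expect_true(any(switch_window == 2L))
  # and the very first frame (its own reference) is neutral
  expect_equal(out$label[1], 1L)
})
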