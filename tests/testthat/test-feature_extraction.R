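test_that("pose features are exact on synthetic projections", {
  ref <- project_template()
  # identical landmarks: identity pose
  p0 <- estimate_pose_features(ref, ref)
  expect_equal(p0$scale, 1, tolerance = 1e-8)
  expect_equal(c(p0$pitch, p0$yaw, p0$roll), c(0, 0, 0), tolerance = 1e-6)
  expect_equal(c(p0$shift_x, p0$shift_y), c(0, 0), tolerance = 1e-8)

  # pure in-plane rotation shows up as roll only
  rot <- project_template(pose = modifyList(pf_id_pose, list(roll = 10)))
  pr <- estimate_pose_features(rot, ref)
  expect_equal(pr$roll, 10, tolerance = 0.1)
  expect_lt(abs(pr$pitch) + abs(pr$yaw), 0.1)

  # pure translation
  tr <- project_template(pose = modifyList(pf_id_pose, list(tx = 5, ty = -3)))
  pt <- estimate_pose_features(tr, ref)
  expect_equal(pt$shift_x, 5, tolerance = 1e-6)
  expect_equal(pt$shift_y, -3, tolerance = 1e-6)

  # full 3-D pose recovered through the weak-perspective fit
  pose <- list(scale = 1.1, pitch = -12, yaw = 17, roll = -8, tx = 9, ty = 4)
  full <- estimate_pose_features(project_template(pose = pose), ref)
  expect_equal(full$scale, 1.1, tolerance = 1e-4)
  expect_equal(full$pitch, -12, tolerance = 0.01)
  expect_equal(full$yaw, 17, tolerance = 0.01)
  expect_equal(full$roll, -8, tolerance = 0.01)

  degenerate <- matrix(rep(c(1, 2), each = 66), 66, 2)
  expect_error(estimate_pose_features(degenerate, ref),
               class = "pf_pose_error")
})

test_that("LBP histogram matches a naive double-loop recount", {
  # constant image: every neighbour ties, all mass in bin 8
  h <- lbp_histogram(matrix(7, 8, 8))
  expect_equal(h, c(rep(0, 8), 1))

  # one bright centre pixel on black lands in bin 0
  m <- matrix(0, 5, 5); m[3, 3] <- 200
  h2 <- lbp_histogram(m)
  expect_gt(h2[1], 0)

  # random crop vs brute force
  set.seed(5)
  crop <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  fast <- lbp_histogram(crop)
  counts <- integer(9)
  for (i in 2:63) for (j in 2:63) {
    pop <- 0L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      if (crop[i + di, j + dj] >= crop[i, j]) pop <- pop + 1L
    }
    counts[pop + 1L] <- counts[pop + 1L] + 1L
  }
  expect_equal(fast, counts / sum(counts))
  expect_equal(sum(fast), 1, tolerance = 1e-12)

  expect_error(lbp_histogram(matrix(1, 2, 2)), class = "pf_data_error")
})

test_that("LBP histogram is invariant to strictly monotone remapping", {
  set.seed(6)
  crop <- matrix(sample(0:200, 32 * 32, TRUE), 32, 32)
  remapped <- 255 * (crop / 255)^0.4 + crop / 100  # strictly increasing
  expect_equal(lbp_histogram(crop), lbp_histogram(remapped))
})

test_that("peak frame selection is periodic with the per-segment budget", {
  p <- select_peak_frames(0:149, gop = 15)
  expect_equal(p$indices, seq(0L, 135L, by = 15L))
  expect_length(p$indices, 10L)

  expect_equal(select_peak_frames(0:6, gop = 15)$indices, 0L)
  expect_length(select_peak_frames(integer(0))$indices, 0L)

  # a 2000-frame training segment is capped at 50 peaks
  long <- select_peak_frames(0:1999, gop = 15,
                             segment_ids = rep(1L, 2000))
  expect_equal(length(long$indices), 50L)
  expect_true(all(long$indices %in% seq(0L, 1999L, by = 15L)))

  # determinism
  expect_identical(select_peak_frames(0:149, 15), select_peak_frames(0:149, 15))
  expect_error(select_peak_frames(0:10, gop = 0), class = "pf_config_error")
})

test_that("frame features serialise to CSV and back", {
  pose <- structure(list(scale = 1.05, pitch = -3, yaw = 7, roll = 0.5,
                         shift_x = 2, shift_y = -1), class = "pf_pose")
  f <- frame_features(pose, rep(1 / 9, 9), frame_index = 12L, label = 2L)
  expect_length(features_vector(f), 15L)
  path <- tempfile(fileext = ".csv")
  write_features(list(f, f), path)
  back <- read_features(path)
  expect_length(back, 2L)
  expect_equal(features_vector(back[[1]]), features_vector(f))
  expect_equal(back[[2]]$label, 2L)
  expect_error(frame_features(pose, rep(0.2, 9)), class = "pf_contract_error")
})
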