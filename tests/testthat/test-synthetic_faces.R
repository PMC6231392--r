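test_that("zero-amplitude scripts are pure rigid transforms of the template", {
  scr <- expression_script(data.frame(expression = "smile", duration = 6,
                                      amplitude = 0), seed = 3, noise_sd = 0)
  recs <- suppressWarnings(generate_expression_sequence(scr))
  tpl <- face_template()
  for (r in recs[c(1, 4, 6)]) {
    # re-project the undeformed template at the recorded ground-truth pose
    pose <- list(scale = r$pose$scale, pitch = r$pose$pitch, yaw = r$pose$yaw,
                 roll = r$pose$roll, tx = r$pose$shift_x, ty = r$pose$shift_y)
    expected <- painface:::pf_project_points(cbind(tpl$xy, tpl$z), pose,
                                             c(160, 120), 0.62)
    expect_equal(r$landmarks$points, expected, tolerance = 1e-10)
  }
})

test_that("sequences are bit-identical under a fixed seed", {
  scr <- expression_script(data.frame(expression = c("neutral", "pain"),
                                      duration = c(4, 4),
                                      amplitude = c(0, 1)), seed = 11)
  a <- suppressWarnings(generate_expression_sequence(scr))
  b <- suppressWarnings(generate_expression_sequence(scr))
  expect_identical(lapply(a, function(r) r$frame$pixels),
                   lapply(b, function(r) r$frame$pixels))
  expect_identical(lapply(a, function(r) r$landmarks$points),
                   lapply(b, function(r) r$landmarks$points))
})

test_that("segment structure drives record counts and label order", {
  scr <- expression_script(data.frame(
    expression = c("neutral", "surprise", "pain"),
    duration = c(45, 45, 45), amplitude = c(0, 0.9, 0.9)), seed = 5)
  recs <- suppressWarnings(generate_expression_sequence(scr))
  expect_length(recs, 135L)
  labs <- vapply(recs, function(r) as.integer(r$label), integer(1))
  expect_equal(unique(labs), c(1L, 3L, 2L))
  expect_equal(labs, rep(c(1L, 3L, 2L), each = 45))
  segs <- vapply(recs, `[[`, integer(1), "segment")
  expect_equal(segs, rep(1:3, each = 45))

  expect_error(expression_script(data.frame(expression = "pain", duration = 500,
                                            amplitude = 1)),
               class = "pf_config_error")
  expect_error(expression_script(data.frame(expression = "bored", duration = 5,
                                            amplitude = 1)),
               class = "pf_config_error")
})

test_that("renders are deterministic and track illumination gain", {
  pts <- project_template()
  r1 <- render_frame(pts, illumination = 1, noise_sd = 0)
  r2 <- render_frame(pts, illumination = 1, noise_sd = 0)
  expect_identical(r1, r2)

  dim1 <- render_frame(pts, illumination = 0.4, noise_sd = 0)
  ratio <- mean(dim1) / mean(r1)
  expect_equal(ratio, 0.4, tolerance = 0.05)

  # the blob detector finds exactly one face region on a clean render
  crop <- detect_and_crop_face(pf_frame(r1))
  expect_s3_class(crop, "pf_face_crop")
  lm <- pts
  expect_true(all(lm[, 1] >= crop$bbox[1] - 2 &
                    lm[, 1] <= crop$bbox[1] + crop$bbox[3] + 2))
})

test_that("rigid motion, gain and landmarks stay inside their stated ranges", {
  scr <- expression_script(data.frame(expression = "neutral", duration = 80,
                                      amplitude = 0), seed = 17)
  recs <- suppressWarnings(generate_expression_sequence(scr))
  poses <- do.call(rbind, lapply(recs, function(r)
    unlist(r$pose[c("scale", "pitch", "yaw", "roll")])))
  expect_true(all(poses[, "scale"] >= 0.8 & poses[, "scale"] <= 1.2))
  expect_true(all(abs(poses[, "roll"]) <= 15))
  expect_true(all(abs(poses[, "yaw"]) <= 20))
  expect_true(all(abs(poses[, "pitch"]) <= 20))
  for (r in recs) {
    p <- r$landmarks$points
    expect_true(all(p[, 1] >= 1 & p[, 1] <= 320 &
                      p[, 2] >= 1 & p[, 2] <= 240))
  }
})

test_that("generated datasets land on disk with a consistent manifest", {
  dir <- file.path(tempdir(), "pfds")
  on.exit(unlink(dir, recursive = TRUE))
  m <- generate_dataset(dir, n_videos = 2, seed = 4, segment_frames = 5,
                        write_frames = TRUE)
  expect_equal(nrow(m), 6L)  # 2 videos x 3 segments
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(dir.exists(file.path(dir, "video_01")))
  # same seed: identical manifests
  dir2 <- file.path(tempdir(), "pfds2")
  on.exit(unlink(dir2, recursive = TRUE), add = TRUE)
  m2 <- generate_dataset(dir2, n_videos = 2, seed = 4, segment_frames = 5)
  expect_identical(m, m2)

  # round-trips through the frame reader without frame loss
  frames <- read_frames(frame_source(file.path(dir, "video_01"), fps = 15),
                        stream_config(target_fps = 15))
  expect_length(frames, 15L)

  # and back into records with landmarks attached
  recs <- load_video_dir(file.path(dir, "video_01"))
  expect_length(recs, 15L)
  expect_s3_class(recs[[1]]$landmarks, "pf_landmarks")
})
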