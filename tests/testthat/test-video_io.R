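test_that("read_frames resamples by uniform striding and honours the budget", {
  blank <- function(v) array(v, c(24, 32, 3))
  frames300 <- lapply(seq_len(300), function(i) blank(i %% 200))
  out <- read_frames(frame_source(frames300, fps = 30),
                     stream_config(max_frames = 300, target_fps = 15))
  expect_equal(length(out), 150L)  # stride 2 over 300 frames
  idx <- vapply(out, `[[`, integer(1), "index")
  expect_equal(idx, seq(0L, 298L, by = 2L))
  expect_true(all(diff(idx) > 0))

  frames10 <- lapply(seq_len(10), function(i) blank(i))
  out10 <- read_frames(frame_source(frames10, fps = 15),
                       stream_config(max_frames = 300, target_fps = 15))
  expect_equal(vapply(out10, `[[`, integer(1), "index"), 0:9)

  # live FIFO overwrite keeps the most recent frames
  frames400 <- lapply(seq_len(400), function(i) blank(i %% 250))
  live <- read_frames(frame_source(frames400, fps = 15),
                      stream_config(max_frames = 300, target_fps = 15,
                                    overwrite_buffer = TRUE))
  expect_equal(length(live), 300L)
  expect_equal(live[[300]]$index, 399L)
  expect_equal(live[[1]]$index, 100L)

  expect_error(read_frames(frame_source(function() NULL)),
               class = "pf_empty_input_error")
})

test_that("RGB to YCbCr follows the full-range matrix and round-trips", {
  px <- array(0, c(1, 3, 3))
  px[1, 1, ] <- c(255, 255, 255)
  px[1, 2, ] <- c(0, 0, 0)
  px[1, 3, ] <- c(255, 0, 0)
  out <- rgb_to_ycbcr(pf_frame(px))
  expect_equal(out$colour_space, "YCbCr")
  expect_equal(out$pixels[1, 1, ], c(255, 128, 128))
  expect_equal(out$pixels[1, 2, ], c(0, 128, 128))
  # hand evaluation of the stated matrix with round-and-clip
  expect_equal(out$pixels[1, 3, ], c(76, 85, 255))

  expect_error(rgb_to_ycbcr(out), class = "pf_contract_error")

  # inverse reproduces RGB within +/- 1 per channel (rounding only)
  set.seed(42)
  rnd <- array(sample(0:255, 20 * 20 * 3, replace = TRUE), c(20, 20, 3))
  back <- ycbcr_to_rgb(rgb_to_ycbcr(pf_frame(rnd)))
  expect_lte(max(abs(back$pixels - rnd)), 1)
})

test_that("face detection crops to 64x64, returns NULL on blank frames, and
           prefers the larger of two faces", {
  rec <- make_frame()
  crop <- detect_and_crop_face(rec$frame)
  expect_s3_class(crop, "pf_face_crop")
  expect_equal(dim(crop$pixels), c(64L, 64L))
  lm <- rec$landmarks$points
  expect_true(all(lm[, 1] >= crop$bbox[1] &
                    lm[, 1] <= crop$bbox[1] + crop$bbox[3]))

  # override hook forces the output shape regardless of content
  forced <- detect_and_crop_face(rec$frame, bbox_override = c(10, 10, 50, 50))
  expect_equal(dim(forced$pixels), c(64L, 64L))

  blank <- pf_frame(array(128, c(240, 320, 3)))
  expect_null(detect_and_crop_face(blank))

  # two bright blobs: the larger wins
  two <- matrix(20, 240, 320)
  two[20:60, 20:60] <- 200      # small
  two[100:220, 100:260] <- 200  # large
  fr2 <- pf_frame(array(rep(two, 3), c(240, 320, 3)))
  expect_warning(cr2 <- detect_and_crop_face(fr2), "largest")
  expect_gte(cr2$bbox[1], 90)  # bbox sits on the large blob
})

test_that("shot_filter drops missing and blurred crops and is idempotent", {
  sharp <- make_frame()
  cr <- detect_and_crop_face(sharp$frame)
  blurred <- cr
  blurred$pixels <- matrix(mean(cr$pixels), 64, 64)  # no structure at all
  frames <- rep(list(sharp$frame), 10)
  crops <- rep(list(cr), 10)
  crops[c(2, 5, 9)] <- list(NULL)
  expect_equal(shot_filter(frames, crops), setdiff(1:10, c(2, 5, 9)))

  crops[[3]] <- blurred
  kept <- shot_filter(frames, crops)
  expect_false(3 %in% kept)

  # brute-force re-evaluation of both predicates
  oracle <- which(vapply(seq_along(crops), function(i) {
    !is.null(crops[[i]]) &&
      painface:::pf_laplacian_variance(crops[[i]]$pixels) >= 10
  }, logical(1)))
  expect_equal(kept, oracle)

  # idempotence: filtering the retained subset keeps everything
  expect_equal(shot_filter(frames[kept], crops[kept]), seq_along(kept))
  expect_equal(shot_filter(list(), list()), integer(0))
})
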