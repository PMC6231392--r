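#' Pipeline configuration
#'
#' Nested configuration for the end-to-end pipeline. Defaults follow the
#' method's printed operating point: logarithm enhancement with
#' \code{c = 3.5} (exponential: \code{c = 3}, \code{gamma = 2}), GOP 15,
#' 64 x 64 crops, 66 landmarks, 9 LBP bins, 5-15 fps and a 300-frame
#' budget, 30-50 peak frames per expression segment.
#'
#' @param stream A \code{\link{stream_config}}.
#' @param pointop A \code{\link{pointop_params}}.
#' @param gop Group-of-pictures length (default 15).
#' @param variance_fraction Shape-model retained variance (default 0.95).
#' @param patch_size Patch template side (odd, default 11).
#' @param search_window Landmark search window side (odd, default 15).
#' @param appearance_modes Appearance-model mode count (default 5).
#' @param classifier \code{"ed_histogram"} (distance thresholds) or
#'   \code{"mlbpnn"}.
#' @param thresholds \code{"calibrate"} or a \code{\link{threshold_config}}.
#' @param reference Distance reference mode for classification (see
#'   \code{\link{classify_stream}}): \code{"baseline_peak"} (default),
#'   \code{"neutral_template"} or \code{"running_peak"}.
#' @param min_peaks,max_peaks Per-segment peak budget (30-50).
#' @param clamp_sd Shape coefficient clamp (default 3).
#' @param fit_max_iter,fit_tol Landmark fitter iteration cap and
#'   convergence tolerance.
#' @param sharpness_threshold Shot-filter sharpness floor.
#' @param seed Integer seed (MLBPNN initialisation; generation).
#' @return An object of class \code{pf_pipeline_config}.
#' @export
pipeline_config <- function(stream = stream_config(),
                            pointop = pointop_params(),
                            gop = 15L, variance_fraction = 0.95,
                            patch_size = 11L, search_window = 15L,
                            appearance_modes = 5L,
                            classifier = c("ed_histogram", "mlbpnn"),
                            thresholds = "calibrate",
                            reference = c("baseline_peak", "neutral_template",
                                          "running_peak"),
                            min_peaks = 30L, max_peaks = 50L,
                            clamp_sd = 3, fit_max_iter = 20L, fit_tol = 0.1,
                            sharpness_threshold = 10, seed = 1L) {
  classifier <- match.arg(classifier)
  reference <- match.arg(reference)
  structure(list(stream = stream, pointop = pointop, gop = as.integer(gop),
                 variance_fraction = variance_fraction,
                 patch_size = as.integer(patch_size),
                 search_window = as.integer(search_window),
                 appearance_modes = as.integer(appearance_modes),
                 classifier = classifier, thresholds = thresholds,
                 reference = reference,
                 min_peaks = as.integer(min_peaks),
                 max_peaks = as.integer(max_peaks),
                 clamp_sd = clamp_sd, fit_max_iter = as.integer(fit_max_iter),
                 fit_tol = fit_tol,
                 sharpness_threshold = sharpness_threshold,
                 seed = as.integer(seed)),
            class = "pf_pipeline_config")
}

# map frame-coordinate points into 64 x 64 crop coordinates (and back)
pf_to_crop_coords <- function(points, bbox, size = 64L) {
  sweep(sweep(pf_points_of(points), 2, bbox[1:2] - 0.5), 2,
        rep(size / bbox[3], 2), `*`)
}

pf_from_crop_coords <- function(points, bbox, size = 64L) {
  sweep(sweep(pf_points_of(points), 2, rep(bbox[3] / size, 2), `*`), 2,
        bbox[1:2] - 0.5, `+`)
}

#' Load a generated video directory into records
#'
#' Reads the PNG frames, landmark sidecars and label file written by
#' \code{\link{generate_dataset}} back into the in-memory record format
#' of \code{\link{generate_expression_sequence}}.
#'
#' @param dir Per-video directory.
#' @param read_pixels Read PNG frames too (default TRUE).
#' @return List of records.
#' @export
load_video_dir <- function(dir, read_pixels = TRUE) {
  labels <- utils::read.csv(file.path(dir, "labels.csv"))
  lapply(seq_len(nrow(labels)), function(i) {
    stem <- sprintf("frame_%04d", labels$frame_index[i])
    lm <- read_landmarks(file.path(dir, paste0(stem, ".pts.txt")))
    lm$frame_index <- labels$frame_index[i]
    frame <- NULL
    if (read_pixels) {
      px <- png::readPNG(file.path(dir, paste0(stem, ".png")))
      if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
      frame <- pf_frame(px[, , 1:3, drop = FALSE] * 255,
                        index = labels$frame_index[i])
    }
    list(frame = frame, landmarks = lm, label = labels$label[i],
         expression = labels$expression[i], segment = labels$segment[i])
  })
}

# preprocess one video's records: colour conversion, detection, cropping,
# shot filtering, enhancement; returns aligned per-retained-frame lists
pf_preprocess_video <- function(records, config) {
  n <- length(records)
  crops <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- records[[i]]$frame
    if (fr$colour_space == "RGB") fr <- rgb_to_ycbcr(fr)
    crops[i] <- list(detect_and_crop_face(fr))  # keep NULLs as elements
  }
  retained <- shot_filter(lapply(records, `[[`, "frame"), crops,
                          sharpness_threshold = config$sharpness_threshold)
  crops <- crops[retained]
  enhanced <- lapply(crops, function(cr)
    enhance_crop(normalize_crop(cr), config$pointop))
  annotations <- lapply(seq_along(retained), function(k) {
    rec <- records[[retained[k]]]
    if (is.null(rec$landmarks)) return(NULL)
    pf_to_crop_coords(rec$landmarks, crops[[k]]$bbox)
  })
  list(retained = retained,
       frame_indices = vapply(records[retained], function(r) r$frame$index,
                              integer(1)),
       crops = crops, enhanced = enhanced, annotations = annotations,
       labels = vapply(records[retained], function(r) as.integer(r$label),
                       integer(1)),
       segments = vapply(records[retained], function(r)
         as.integer(r$segment %||% 1L), integer(1)))
}

# fit/track landmarks over a preprocessed video; returns per-frame features
pf_track_features <- function(prep, archive) {
  config <- archive$config
  models <- list(shape = archive$shape_model, patch = archive$patch_model,
                 tree = archive$tree)
  ref <- archive$reference_shape
  prev <- NULL
  feats <- vector("list", length(prep$enhanced))
  if (length(prep$enhanced) > 0L) {
    # warm start: the first frame is fitted twice so tracking begins from
    # a converged shape rather than the cold mean-shape placement
    warm <- fit_landmarks(prep$enhanced[[1]]$pixels, NULL, models,
                          search_window = config$search_window,
                          max_iter = config$fit_max_iter,
                          tol = config$fit_tol, clamp_sd = config$clamp_sd)
    prev <- warm$landmarks$points
  }
  for (k in seq_along(prep$enhanced)) {
    fit <- fit_landmarks(prep$enhanced[[k]]$pixels, prev, models,
                         search_window = config$search_window,
                         max_iter = config$fit_max_iter,
                         tol = config$fit_tol, clamp_sd = config$clamp_sd)
    if (fit$quality < 0.55 && !is.null(prev)) {
      # tracking degraded: refit from a fresh mean-shape placement and
      # keep whichever solution the patch experts endorse more strongly
      refit <- fit_landmarks(prep$enhanced[[k]]$pixels, NULL, models,
                             search_window = config$search_window,
                             max_iter = config$fit_max_iter,
                             tol = config$fit_tol, clamp_sd = config$clamp_sd)
      if (refit$quality > fit$quality) fit <- refit
    }
    prev <- fit$landmarks$points
    pose <- estimate_pose_features(fit$landmarks, ref)
    feats[[k]] <- frame_features(pose,
                                 lbp_histogram(prep$enhanced[[k]]$pixels),
                                 frame_index = prep$frame_indices[k],
                                 label = prep$labels[k])
  }
  pf_smooth_features(feats)
}

# temporal smoothing of the per-frame features: a running median of three
# on every dimension. Head motion and expressions are smooth in time, so
# an isolated single-frame glitch (a fitting failure, a sensor-noise
# excursion of the texture histogram) is replaced by its neighbours'
# consensus while expression steps are preserved up to one frame. The
# smoothed histogram is renormalised.
pf_smooth_features <- function(feats) {
  n <- length(feats)
  if (n < 3L) return(feats)
  keys <- c("scale", "pitch", "yaw", "roll", "shift_x", "shift_y")
  M <- features_matrix(feats)
  S <- M
  for (j in seq_len(ncol(M))) {
    S[2:(n - 1), j] <- vapply(2:(n - 1), function(i)
      sort(M[(i - 1):(i + 1), j])[2], numeric(1))
    S[1, j] <- sort(M[1:3, j])[2]
    S[n, j] <- sort(M[(n - 2):n, j])[2]
  }
  for (i in seq_len(n)) {
    feats[[i]][keys] <- as.list(S[i, 1:6])
    h <- S[i, 7:15]
    feats[[i]]$lbp_hist <- h / sum(h)
  }
  feats
}

# running median-of-3 on a per-video distance sequence: suppresses
# isolated distance spikes and, at an expression boundary, lets the two
# same-expression neighbours outvote the stale side
pf_smooth_distances <- function(d) {
  n <- length(d)
  if (n < 3L) return(d)
  s <- d
  s[2:(n - 1)] <- vapply(2:(n - 1), function(i)
    sort(d[(i - 1):(i + 1)])[2], numeric(1))
  s
}

#' Train the pain-recognition pipeline
#'
#' Runs the full training chain on labelled videos: decode, colour
#' conversion, face detection and cropping, shot filtering, point-operation
#' enhancement; Procrustes + PCA shape model, per-landmark patch model,
#' tree connectivity and PCA appearance model built from the annotated
#' peak frames; landmark fitting/tracking over every training frame;
#' pose + LBP feature extraction; per-class template construction on the
#' peak frames and soft-threshold calibration (or MLBPNN training).
#'
#' @param videos List of videos: each a record list (from
#'   \code{\link{generate_expression_sequence}}), a zero-argument
#'   generator function returning records (memory-friendly), or from
#'   \code{\link{load_video_dir}} /
#'   \code{\link{load_video_dir}}) or a directory path.
#' @param config A \code{\link{pipeline_config}}.
#' @return A model archive (class \code{pf_model_archive}): models,
#'   templates, thresholds and/or network, normalisation statistics,
#'   config snapshot, training log.
#' @export
run_training <- function(videos, config = pipeline_config()) {
  # each video may be a record list, a directory path, or a zero-argument
  # function returning records; paths and functions are realised one video
  # at a time so only the 64 x 64 crops stay resident
  preps <- lapply(videos, function(v) {
    if (is.character(v)) v <- load_video_dir(v)
    if (is.function(v)) v <- v()
    pf_preprocess_video(v, config = config)
  })

  # peak frames per video (per-segment 30-50 budget) drive model building
  peak_crops <- list(); peak_shapes <- list()
  for (p in preps) {
    if (length(p$retained) == 0L) next
    pk <- select_peak_frames(p$frame_indices, gop = config$gop,
                             segment_ids = p$segments,
                             min_peaks = config$min_peaks,
                             max_peaks = config$max_peaks)
    sel <- which(p$frame_indices %in% pk$indices & !vapply(p$annotations,
                                                           is.null, logical(1)))
    peak_crops <- c(peak_crops, lapply(p$enhanced[sel], `[[`, "pixels"))
    peak_shapes <- c(peak_shapes, p$annotations[sel])
  }
  if (length(peak_shapes) < 2L)
    pf_stop("pf_training_error", "not enough annotated peak frames to train")

  gpa <- procrustes_align(peak_shapes)
  shape_model <- build_shape_model(gpa$aligned,
                                   variance_fraction = config$variance_fraction)
  patch_model <- build_patch_model(peak_crops, peak_shapes,
                                   patch_size = config$patch_size)
  tree <- build_tree(rep(TRUE, 66L), pf_vec_to_shape(shape_model$mean_shape))
  appearance_model <- build_appearance_model(peak_crops, peak_shapes,
                                             shape_model,
                                             l = config$appearance_modes)
  reference_shape <- pf_base_mesh(shape_model)$points

  archive <- structure(list(version = "painface-archive-1",
                            config = config, shape_model = shape_model,
                            patch_model = patch_model, tree = tree,
                            appearance_model = appearance_model,
                            reference_shape = reference_shape),
                       class = "pf_model_archive")

  # fit/track + features over every training frame
  feats <- list(); labels <- integer(0); peak_flag <- logical(0)
  video_id <- integer(0)
  for (v in seq_along(preps)) {
    p <- preps[[v]]
    if (length(p$retained) == 0L) next
    f <- pf_track_features(p, archive)
    pk <- select_peak_frames(p$frame_indices, gop = config$gop,
                             segment_ids = p$segments,
                             min_peaks = config$min_peaks,
                             max_peaks = config$max_peaks)
    feats <- c(feats, f)
    labels <- c(labels, p$labels)
    peak_flag <- c(peak_flag, p$frame_indices %in% pk$indices)
    video_id <- c(video_id, rep(v, length(f)))
  }

  templates <- build_class_templates(feats[peak_flag])
  archive$templates <- templates

  Z <- pf_znorm(features_matrix(feats), templates)
  dists <- pf_training_distances(Z, labels, video_id, templates, config)
  if (config$classifier == "ed_histogram") {
    thresholds <- if (inherits(config$thresholds, "pf_thresholds"))
      config$thresholds else calibrate_thresholds(dists, labels)
    archive$thresholds <- thresholds
    pred <- classify_frame(dists, thresholds)
  } else {
    net <- train_mlbpnn(features_matrix(feats), labels,
                        mlbpnn_config(seed = config$seed))
    archive$mlbpnn <- net
    pred <- predict_mlbpnn(net, features_matrix(feats))
    # thresholds still calibrated so distance-based reporting works
    archive$thresholds <- calibrate_thresholds(dists, labels)
  }
  archive$training_log <- list(
    n_videos = length(videos),
    n_frames = length(feats), n_peaks = sum(peak_flag),
    training_accuracy = mean(pred == labels),
    shape_modes = shape_model$k,
    appearance_modes = appearance_model$l)
  archive
}

# training-time distances: exactly the inference-time reference policy
# (which is label-free), applied per training video
pf_training_distances <- function(Z, labels, video_id, templates, config) {
  ref0 <- templates$templates["neutral_face", ]
  dists <- numeric(nrow(Z))
  for (v in unique(video_id)) {
    ix <- which(video_id == v)
    ref <- ref0
    peak_buf <- NULL; peak_d0 <- numeric(0)
    for (k in seq_along(ix)) {
      i <- ix[k]
      is_peak <- (k - 1L) %% config$gop == 0L
      if (is_peak) {
        if (config$reference == "running_peak") ref <- Z[i, ]
        if (config$reference == "baseline_peak") {
          peak_buf <- rbind(peak_buf, Z[i, ])
          peak_d0 <- c(peak_d0, sqrt(sum((Z[i, 7:15] - ref0[7:15])^2)))
          if (length(peak_d0) > 8L) {
            peak_buf <- peak_buf[-1L, , drop = FALSE]
            peak_d0 <- peak_d0[-1L]
          }
          ref <- peak_buf[which.min(peak_d0), ]
        }
      }
      dists[i] <- sqrt(sum((Z[i, ] - ref)^2))
    }
    dists[ix] <- pf_smooth_distances(dists[ix])
  }
  dists
}

#' Classify a video with a trained archive
#'
#' Runs the inference chain per frame (colour conversion, detection,
#' cropping, enhancement, landmark fitting with tracking, feature
#' extraction, distance classification) and returns the per-frame result
#' table, plus an evaluation report when ground-truth labels are
#' available.
#'
#' @param archive A \code{pf_model_archive} from \code{\link{run_training}}.
#' @param video Record list, directory path, or list of \code{pf_frame}.
#' @param truth Optional integer class codes per frame (defaults to the
#'   record labels when present).
#' @return List with \code{results} (data frame: frame_index, diff,
#'   label, status, per-class distances) and \code{report}
#'   (\code{pf_eval_report} or \code{NULL}).
#' @export
run_classification <- function(archive, video, truth = NULL) {
  if (!inherits(archive, "pf_model_archive") ||
      !identical(archive$version, "painface-archive-1"))
    pf_stop("pf_model_error", "incompatible or missing model archive")
  config <- archive$config
  if (is.character(video)) video <- load_video_dir(video)
  if (is.function(video)) video <- video()
  if (length(video) > 0L && inherits(video[[1]], "pf_frame"))
    video <- lapply(video, function(f) list(frame = f, landmarks = NULL,
                                            label = NA, segment = 1L))
  prep <- pf_preprocess_video(video, config)
  if (length(prep$retained) == 0L) {
    warning("no usable face frames in input")
    return(list(results = classify_stream(list(), archive$templates,
                                          archive$thresholds),
                report = NULL))
  }
  feats <- pf_track_features(prep, archive)
  results <- classify_stream(feats, archive$templates, archive$thresholds,
                             gop = config$gop, reference = config$reference)
  if (config$classifier == "mlbpnn")
    results$label <- predict_mlbpnn(archive$mlbpnn, features_matrix(feats))
  if (is.null(truth)) {
    truth_all <- vapply(video, function(r)
      if (is.null(r$label) || is.na(r$label)) NA_integer_
      else as.integer(r$label), integer(1))
    truth <- truth_all[prep$retained]
  } else {
    truth <- as.integer(truth)[prep$retained]
  }
  report <- if (!all(is.na(truth)))
    eval_report(results, truth, gop = config$gop) else NULL
  list(results = results, report = report)
}

#' Save / load a model archive
#'
#' Serialises the trained archive (models, templates, thresholds,
#' normalisation statistics, config snapshot) to a single versioned file.
#' Serialisation is deterministic: training twice with the same seed and
#' inputs yields byte-identical archives.
#'
#' @param archive A \code{pf_model_archive}.
#' @param path File path.
#' @return \code{load_model_archive}: the archive.
#' @export
save_model_archive <- function(archive, path) {
  saveRDS(archive, path, version = 3L, compress = FALSE)
  invisible(path)
}

#' @rdname save_model_archive
#' @export
load_model_archive <- function(path) {
  archive <- readRDS(path)
  if (!inherits(archive, "pf_model_archive"))
    pf_stop("pf_model_error", "not a painface model archive: %s", path)
  archive
}

#' Write classification results to CSV
#'
#' @param results Result data frame from \code{\link{run_classification}}.
#' @param path CSV path.
#' @export
write_results <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
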