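#' Six-parameter head-pose features from landmarks
#'
#' Describes a landmark set relative to a reference shape by six pose
#' parameters: scale, pitch, yaw, roll (degrees) and the x/y centroid
#' shifts (pixels). All four of scale/pitch/yaw/roll come from a single
#' weak-perspective fit of the canonical 3-D mean-landmark template (see
#' \code{\link{face_template}}) to the observed 2-D points: the scaled
#' rotation matrix that best maps the centred template onto the centred
#' points is recovered by least squares and orthonormalised, and Euler
#' angles are extracted under the roll-yaw-pitch (Rz Ry Rx) convention.
#' The reference shape is fitted the same way, and scale/rotation are
#' reported relative to it, so a landmark set identical to the reference
#' yields scale 1 and zero angles and shifts.
#'
#' @param landmarks \code{pf_landmarks} or 66 x 2 matrix.
#' @param reference Reference shape (the model mean shape placed at its
#'   training pose), same format.
#' @return An object of class \code{pf_pose} with fields \code{scale},
#'   \code{pitch}, \code{yaw}, \code{roll} (degrees), \code{shift_x},
#'   \code{shift_y}.
#' @export
estimate_pose_features <- function(landmarks, reference) {
  obs <- pf_points_of(landmarks)
  ref <- pf_points_of(reference)
  vis <- if (inherits(landmarks, "pf_landmarks")) landmarks$visibility
         else rep(TRUE, nrow(obs))
  # drop low-confidence landmarks from the pose fit when enough remain
  subset <- if (sum(vis) >= 20L) which(vis) else seq_len(nrow(obs))
  fo <- pf_pos_fit(obs, subset)
  fr <- pf_pos_fit(ref, subset)
  R <- fo$R %*% t(fr$R)
  ang <- pf_euler_zyx(R)
  structure(list(scale = fo$s / fr$s,
                 pitch = ang[1], yaw = ang[2], roll = ang[3],
                 shift_x = mean(obs[, 1]) - mean(ref[, 1]),
                 shift_y = mean(obs[, 2]) - mean(ref[, 2])),
            class = "pf_pose")
}

# weak-perspective (POS-style) fit of the canonical 3-D template to centred
# 2-D points: Y ~ s * (R X)[1:2, ], solved by least squares + orthonormalisation
pf_pos_fit <- function(points, subset = NULL) {
  tpl <- face_template()
  X <- cbind(tpl$xy, tpl$z)
  X <- sweep(X, 2, colMeans(X))
  Y <- sweep(points, 2, colMeans(points))
  if (!is.null(subset) && length(subset) < nrow(points)) {
    X <- X[subset, , drop = FALSE]
    X <- sweep(X, 2, colMeans(X))
    Y <- points[subset, , drop = FALSE]
    Y <- sweep(Y, 2, colMeans(Y))
  }
  A <- tryCatch(solve(crossprod(X), crossprod(X, Y)),
                error = function(e) pf_stop("pf_pose_error",
                                            "degenerate landmark configuration"))
  a1 <- A[, 1]; a2 <- A[, 2]
  s <- (sqrt(sum(a1^2)) + sqrt(sum(a2^2))) / 2
  if (s < 1e-12) pf_stop("pf_pose_error", "degenerate landmark configuration")
  r1 <- a1 / sqrt(sum(a1^2))
  r2 <- a2 - sum(a2 * r1) * r1
  r2 <- r2 / sqrt(sum(r2^2))
  r3 <- c(r1[2] * r2[3] - r1[3] * r2[2],
          r1[3] * r2[1] - r1[1] * r2[3],
          r1[1] * r2[2] - r1[2] * r2[1])
  list(s = s, R = rbind(r1, r2, r3))
}

# Euler angles (pitch about x, yaw about y, roll about z) in degrees from
# R = Rz(roll) %*% Ry(yaw) %*% Rx(pitch)
pf_euler_zyx <- function(R) {
  yaw <- asin(pmin(pmax(-R[3, 1], -1), 1))
  pitch <- atan2(R[3, 2], R[3, 3])
  roll <- atan2(R[2, 1], R[1, 1])
  c(pitch, yaw, roll) * 180 / pi
}

#' 9-bin local binary pattern histogram
#'
#' For every interior pixel, each of the 8 neighbours is compared to the
#' centre (neighbour >= centre scores 1, the tie counting as 1), and the
#' pixel's code is summarised by its number of set bits (0-8). The 9
#' resulting pattern counts are normalised to a histogram summing to 1.
#' The histogram is invariant to any strictly increasing remapping of the
#' intensities.
#'
#' @param crop Single-channel matrix, at least 3 x 3.
#' @return Numeric vector of length 9 (bins for popcounts 0-8), summing
#'   to 1.
#' @export
lbp_histogram <- function(crop) {
  if (inherits(crop, "pf_face_crop")) crop <- crop$pixels
  H <- nrow(crop); W <- ncol(crop)
  if (is.null(H) || H < 3L || W < 3L)
    pf_stop("pf_data_error", "LBP needs a crop of at least 3 x 3 pixels")
  ctr <- crop[2:(H - 1), 2:(W - 1)]
  pop <- matrix(0L, H - 2L, W - 2L)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    nb <- crop[(2 + dy):(H - 1 + dy), (2 + dx):(W - 1 + dx)]
    pop <- pop + (nb >= ctr)
  }
  counts <- tabulate(as.integer(pop) + 1L, nbins = 9L)
  counts / sum(counts)
}

#' Frame features: pose + LBP histogram
#'
#' Bundles the six pose features and the 9-bin LBP histogram of one frame
#' into the 15-dimensional descriptor used by the classifiers.
#'
#' @param pose A \code{pf_pose}.
#' @param lbp_hist Length-9 normalised histogram.
#' @param frame_index Integer frame number.
#' @param label Optional class code (1/2/3) or \code{NA}.
#' @return An object of class \code{pf_frame_features}.
#' @export
frame_features <- function(pose, lbp_hist, frame_index = 0L, label = NA) {
  if (abs(sum(lbp_hist) - 1) > 1e-9)
    pf_stop("pf_contract_error", "lbp_hist must sum to 1")
  structure(list(scale = pose$scale, pitch = pose$pitch, yaw = pose$yaw,
                 roll = pose$roll, shift_x = pose$shift_x,
                 shift_y = pose$shift_y, lbp_hist = as.numeric(lbp_hist),
                 frame_index = as.integer(frame_index), label = label),
            class = "pf_frame_features")
}

#' @rdname frame_features
#' @param x A \code{pf_frame_features} or list of them.
#' @return \code{features_vector}: the numeric 15-vector (scale, pitch,
#'   yaw, roll, shift_x, shift_y, lbp_0..lbp_8);
#'   \code{features_matrix}: one row per frame.
#' @export
features_vector <- function(x) {
  c(x$scale, x$pitch, x$yaw, x$roll, x$shift_x, x$shift_y, x$lbp_hist)
}

#' @rdname frame_features
#' @export
features_matrix <- function(x) {
  m <- t(vapply(x, features_vector, numeric(15L)))
  colnames(m) <- c("scale", "pitch", "yaw", "roll", "shift_x", "shift_y",
                   paste0("lbp_", 0:8))
  m
}

#' Select periodic peak (reference) frames
#'
#' Peak frames are the reference frames taken periodically: every
#' \code{gop}-th retained frame starting at the first. In training mode
#' (when \code{segment_ids} is given) each expression segment contributes
#' between \code{min_peaks} and \code{max_peaks} peaks: segments with more
#' candidate peaks are evenly subsampled down to \code{max_peaks}.
#'
#' @param frame_indices Sorted integer vector of retained frame indices.
#' @param gop Sampling period (Group of Pictures length, default 15).
#' @param segment_ids Optional vector aligned with \code{frame_indices}
#'   marking expression segments (training mode).
#' @param min_peaks,max_peaks Per-segment peak budget (defaults 30, 50).
#' @return An object of class \code{pf_peak_frames} with sorted
#'   \code{indices} and \code{gop}.
#' @export
select_peak_frames <- function(frame_indices, gop = 15L, segment_ids = NULL,
                               min_peaks = 30L, max_peaks = 50L) {
  gop <- as.integer(gop)
  if (gop < 1L) pf_stop("pf_config_error", "gop must be >= 1")
  if (length(frame_indices) == 0L)
    return(structure(list(indices = integer(0), gop = gop),
                     class = "pf_peak_frames"))
  take_every <- function(idx) idx[seq(1L, length(idx), by = gop)]
  if (is.null(segment_ids)) {
    peaks <- take_every(frame_indices)
  } else {
    peaks <- unlist(lapply(split(frame_indices, segment_ids), function(idx) {
      p <- take_every(sort(idx))
      if (length(p) > max_peaks)
        p <- p[unique(round(seq(1L, length(p), length.out = max_peaks)))]
      p
    }), use.names = FALSE)
  }
  structure(list(indices = sort(as.integer(peaks)), gop = gop),
            class = "pf_peak_frames")
}

#' Write / read frame features as CSV
#'
#' Tabular text serialisation with columns \code{frame_index, scale,
#' pitch, yaw, roll, shift_x, shift_y, lbp_0..lbp_8, label}.
#'
#' @param features List of \code{pf_frame_features}.
#' @param path CSV file path.
#' @return \code{read_features}: a list of \code{pf_frame_features}.
#' @export
write_features <- function(features, path) {
  m <- features_matrix(features)
  df <- data.frame(frame_index = vapply(features, `[[`, integer(1), "frame_index"),
                   m,
                   label = vapply(features, function(f)
                     if (is.na(f$label)) NA_integer_ else as.integer(f$label),
                     integer(1)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path)
  lapply(seq_len(nrow(df)), function(i) {
    pose <- structure(list(scale = df$scale[i], pitch = df$pitch[i],
                           yaw = df$yaw[i], roll = df$roll[i],
                           shift_x = df$shift_x[i], shift_y = df$shift_y[i]),
                      class = "pf_pose")
    frame_features(pose, as.numeric(df[i, paste0("lbp_", 0:8)]),
                   frame_index = df$frame_index[i], label = df$label[i])
  })
}
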