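#' Expression script for the synthetic generator
#'
#' Describes a synthetic face video as an ordered list of expression
#' segments. Labels use the pipeline's class vocabulary; the not-pain
#' class carries a sub-expression (\code{smile}, \code{surprise},
#' \code{angry}).
#'
#' @param segments Data frame with columns \code{expression} (one of
#'   \code{"neutral"}, \code{"pain"}, \code{"smile"}, \code{"surprise"},
#'   \code{"angry"}), \code{duration} (frames, >= 1) and \code{amplitude}
#'   (in \code{[0, 1]}).
#' @param fps Nominal frame rate of the synthetic video.
#' @param resolution \code{"QVGA"} or \code{"VGA"}.
#' @param seed Integer seed; the whole sequence is reproducible per seed.
#' @param noise_sd Additive Gaussian pixel noise standard deviation
#'   (8-bit units, default 2).
#' @param max_frames Total frame budget (default 300).
#' @return An object of class \code{pf_expression_script}.
#' @export
expression_script <- function(segments, fps = 15, resolution = "QVGA",
                              seed = 1L, noise_sd = 2, max_frames = 300L) {
  stopifnot(is.data.frame(segments),
            all(c("expression", "duration", "amplitude") %in% names(segments)))
  if (any(segments$duration < 1))
    pf_stop("pf_config_error", "segment durations must be >= 1")
  if (any(segments$amplitude < 0 | segments$amplitude > 1))
    pf_stop("pf_config_error", "amplitudes must lie in [0, 1]")
  if (sum(segments$duration) > max_frames)
    pf_stop("pf_config_error", "script exceeds the frame budget (%d > %d)",
            sum(segments$duration), max_frames)
  ok <- c("neutral", "pain", "smile", "surprise", "angry")
  if (!all(segments$expression %in% ok))
    pf_stop("pf_config_error", "unknown expression in script")
  structure(list(segments = segments, fps = fps, resolution = resolution,
                 seed = as.integer(seed), noise_sd = noise_sd,
                 max_frames = as.integer(max_frames)),
            class = "pf_expression_script")
}

pf_expression_label <- function(expression) {
  switch(expression, neutral = PF_CLASSES[["neutral_face"]],
         pain = PF_CLASSES[["pain_face"]], PF_CLASSES[["not_pain_face"]])
}

# smooth bounded random walk: AR(1) innovations, squashed into [-1, 1];
# slow dynamics emulate a seated subject whose head wanders gently while
# different seeds start the walk at different points of the range
pf_smooth_walk <- function(n, inertia = 0.997, step_sd = 0.035) {
  v <- numeric(n); x <- stats::rnorm(1, sd = 0.5)
  for (t in seq_len(n)) {
    x <- inertia * x + stats::rnorm(1, sd = step_sd)
    v[t] <- tanh(x)
  }
  v
}

# rigid-motion track over n frames within the generator's stated ranges
pf_motion_track <- function(n) {
  list(scale = 1.0 + 0.2 * pf_smooth_walk(n),     # [0.8, 1.2]
       roll = 15 * pf_smooth_walk(n),             # degrees
       yaw = 20 * pf_smooth_walk(n),
       pitch = 20 * pf_smooth_walk(n),
       tx = 20 * pf_smooth_walk(n),               # pixels
       ty = 20 * pf_smooth_walk(n),
       gain = 0.8 + 0.4 * pf_smooth_walk(n))      # [0.4, 1.2]
}

pf_rot3 <- function(pitch, yaw, roll) {
  p <- pitch * pi / 180; y <- yaw * pi / 180; r <- roll * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(p), -sin(p)), c(0, sin(p), cos(p)))
  Ry <- rbind(c(cos(y), 0, sin(y)), c(0, 1, 0), c(-sin(y), 0, cos(y)))
  Rz <- rbind(c(cos(r), -sin(r), 0), c(sin(r), cos(r), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# project the (optionally deformed) template under a weak-perspective pose
pf_project_points <- function(xyz, pose, centre, base_scale) {
  R <- pf_rot3(pose$pitch, pose$yaw, pose$roll)
  X <- sweep(xyz, 2, colMeans(xyz))
  P <- t(R %*% t(X))[, 1:2, drop = FALSE] * (base_scale * pose$scale)
  sweep(P, 2, c(centre[1] + pose$tx, centre[2] + pose$ty), `+`)
}

#' Generate a synthetic annotated face-video sequence
#'
#' Starts from the canonical 66-point template, applies per-segment
#' expression deformation fields scaled by amplitude, a seeded smooth
#' random-walk rigid motion (scale in \code{[0.8, 1.2]}, roll within
#' \code{±}15 degrees, yaw/pitch within \code{±}20 degrees,
#' translation within \code{±}20 px), a seeded smooth illumination
#' gain in \code{[0.4, 1.2]}, and additive Gaussian pixel noise; every
#' frame is rendered schematically and returned with its ground-truth
#' landmarks, class label and pose. Fully reproducible per seed. If a
#' pose would push landmarks outside the frame, the translation is
#' clamped and a warning is issued.
#'
#' @param script A \code{\link{expression_script}}.
#' @param base_scale Pixels per template unit at pose scale 1
#'   (default 0.62).
#' @return List of records, each with fields \code{frame}
#'   (\code{pf_frame}), \code{landmarks} (\code{pf_landmarks}),
#'   \code{label} (class code), \code{expression}, \code{pose}
#'   (ground-truth scale/pitch/yaw/roll/shift_x/shift_y), \code{segment}.
#' @export
generate_expression_sequence <- function(script, base_scale = 0.62) {
  old <- .Random.seed_exists()
  set.seed(script$seed)
  on.exit(.Random.seed_restore(old), add = TRUE)

  tpl <- face_template()
  wh <- pf_resolution_wh(script$resolution)
  W <- wh[1]; H <- wh[2]
  centre <- c(W / 2, H / 2)
  n <- sum(script$segments$duration)
  track <- pf_motion_track(n)
  seg_of <- rep(seq_len(nrow(script$segments)), script$segments$duration)

  records <- vector("list", n)
  for (t in seq_len(n)) {
    seg <- script$segments[seg_of[t], ]
    field <- expression_field(seg$expression) * seg$amplitude
    xyz <- cbind(tpl$xy + field, tpl$z)
    pose <- list(scale = track$scale[t], pitch = track$pitch[t],
                 yaw = track$yaw[t], roll = track$roll[t],
                 tx = track$tx[t], ty = track$ty[t])
    pts <- pf_project_points(xyz, pose, centre, base_scale)
    # clamp translation so the whole face stays inside the frame
    margin <- 24  # room for the skin outline beyond the landmarks
    shift_x <- max(margin - min(pts[, 1]), 0) - max(max(pts[, 1]) - (W - margin), 0)
    shift_y <- max(margin - min(pts[, 2]), 0) - max(max(pts[, 2]) - (H - margin), 0)
    if (shift_x != 0 || shift_y != 0) {
      warning("pose left the frame; translation clamped")
      pose$tx <- pose$tx + shift_x; pose$ty <- pose$ty + shift_y
      pts <- pf_project_points(xyz, pose, centre, base_scale)
    }
    px <- render_frame(pts, illumination = track$gain[t],
                       noise_sd = script$noise_sd,
                       resolution = script$resolution)
    records[[t]] <- list(
      frame = pf_frame(px, index = t - 1L, source_fps = script$fps),
      landmarks = pf_landmarks(pts, frame_index = t - 1L),
      label = pf_expression_label(seg$expression),
      expression = seg$expression,
      pose = list(scale = pose$scale, pitch = pose$pitch, yaw = pose$yaw,
                  roll = pose$roll, shift_x = pose$tx, shift_y = pose$ty),
      segment = seg_of[t])
  }
  records
}

# dense template-space outline of the skin ellipse (head boundary)
pf_skin_outline <- function() {
  a <- seq(0, 2 * pi, length.out = 48)[-48]
  cbind(66 * cos(a), 8 + 86 * sin(a))
}

#' Render a schematic face frame from landmarks
#'
#' Renders a grayscale-on-RGB face as a mosaic of textured regions: a
#' bright skin ellipse, dark finely-textured eye and inner-mouth
#' polygons, obliquely striped lips and brows, and a textured nose
#' ridge, over a textured background. All face textures are defined in
#' template coordinates (recovered from the landmarks by the
#' weak-perspective template fit), so they move rigidly with the head
#' and are stable under scale, roll and translation once the face is
#' cropped and size-normalised; their amplitudes are chosen well above
#' typical sensor noise so local binary pattern codes are dominated by
#' structure rather than noise. Each region family has a distinct
#' texture signature, which is what makes expression-driven region-area
#' changes (eye closure, jaw drop, lip stretch) detectable downstream.
#' Deterministic given its inputs when \code{noise_sd = 0} (noise draws
#' from the current RNG stream otherwise).
#'
#' @param landmarks \code{pf_landmarks} or 66 x 2 matrix in frame pixels.
#' @param illumination Multiplicative illumination gain.
#' @param noise_sd Additive Gaussian noise standard deviation (8-bit).
#' @param resolution \code{"QVGA"} or \code{"VGA"}.
#' @return H x W x 3 pixel array in \code{[0, 255]}.
#' @export
render_frame <- function(landmarks, illumination = 1.0, noise_sd = 0,
                         resolution = "QVGA") {
  pts <- pf_points_of(landmarks)
  wh <- pf_resolution_wh(resolution)
  W <- wh[1]; H <- wh[2]
  tpl <- face_template()
  g <- tpl$groups

  # recover the pose so the head outline and textures follow the landmarks
  fit <- pf_pos_fit(pts)
  ctr <- colMeans(pts)
  outline3 <- cbind(pf_skin_outline(), rep(-6, 47))
  tplc <- colMeans(cbind(tpl$xy, tpl$z))
  Xo <- sweep(outline3, 2, tplc)
  skin <- sweep((Xo %*% t(fit$R))[, 1:2] * fit$s, 2, ctr, `+`)

  # per-pixel template coordinates via the inverse similarity transform
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  ang <- atan2(fit$R[2, 1], fit$R[1, 1])
  co <- cos(ang); si <- sin(ang)
  ux <- ((xs - ctr[1]) * co + (ys - ctr[2]) * si) / fit$s + tplc[1]
  uy <- (-(xs - ctr[1]) * si + (ys - ctr[2]) * co) / fit$s + tplc[2]

  # de-rotated landmark positions in template coordinates: invert the
  # weak-perspective projection using the template depths, so muscle-state
  # measurements below are pose-invariant
  Yc <- sweep(pts, 2, ctr) / fit$s
  R2 <- fit$R[1:2, 1:2]
  lm_t <- t(solve(R2, t(Yc - outer(tpl$z - mean(tpl$z), fit$R[1:2, 3],
                                   `*`))))
  lm_t <- sweep(lm_t, 2, tplc[1:2], `+`)

  # expression-driven skin state, derived purely from landmark geometry:
  # lowered brows furrow the forehead, raised brows stretch it, raised
  # mouth corners crease the cheeks (nasolabial folds)
  eye_cy <- (mean(lm_t[g$eye_left, 2]) + mean(lm_t[g$eye_right, 2])) / 2
  brow_cy <- mean(lm_t[c(g$brow_left, g$brow_right), 2])
  d0 <- mean(c(mean(face_template()$xy[g$eye_left, 2]),
               mean(face_template()$xy[g$eye_right, 2]))) -
    mean(face_template()$xy[c(g$brow_left, g$brow_right), 2])
  d_be <- eye_cy - brow_cy
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  # muscle states in [0, 1]; they modulate the AREA each skin feature
  # covers (LBP codes are contrast-invariant above the noise floor, so
  # coverage, not amplitude, is what carries intensity downstream)
  furrow_state <- clamp01(((d0 - d_be) / d0 - 0.08) / 0.14)
  raise_state <- clamp01(((d_be - d0) / d0 - 0.05) / 0.25)
  # brow knit: inward displacement of the inner brow ends
  knit <- (lm_t[g$brow_left[5], 1] - face_template()$xy[g$brow_left[5], 1] +
             face_template()$xy[g$brow_right[1], 1] - lm_t[g$brow_right[1], 1]) / 2
  knit_state <- clamp01((knit / 3 - 0.2) / 0.6)
  tpl_corners <- face_template()$xy[g$mouth_outer[c(1, 7)], ]
  corner_raise <- mean(tpl_corners[, 2]) -
    mean(lm_t[g$mouth_outer[c(1, 7)], 2])
  # cheek folds appear when the corners are raised (smile) or displaced
  # horizontally (grimace tightening): use whichever is larger
  corner_tight <- mean(abs(lm_t[g$mouth_outer[c(1, 7)], 1] -
                             tpl_corners[, 1]))
  cheek_state <- clamp01((max(corner_raise, corner_tight) / 5 - 0.35) / 0.45)
  smile_state <- clamp01((corner_raise / 6 - 0.1) / 0.65)
  # lip press (mentalis tension): how far the inner-mouth aperture has
  # closed relative to the canonical template
  h0_inner <- diff(range(face_template()$xy[g$mouth_inner, 2]))
  h_inner <- diff(range(lm_t[g$mouth_inner, 2]))
  press_state <- clamp01(((1 - h_inner / h0_inner) - 0.2) / 0.5)
  # orbicularis squeeze: how far the eye aperture has closed
  ap0 <- diff(range(face_template()$xy[g$eye_left, 2]))
  ap <- (diff(range(lm_t[g$eye_left, 2])) +
           diff(range(lm_t[g$eye_right, 2]))) / 2
  squeeze_state <- clamp01(((1 - ap / ap0) - 0.25) / 0.45)

  canvas <- matrix(50 + 14 * rep(seq_len(H) / H, W), H, W)  # background
  mask <- pf_fill_polygon(skin, W, H)
  # skin textures are evaluated only at skin pixels (index vectors)
  si <- which(mask)
  sx <- ux[si]; sy <- uy[si]
  skv <- rep(165, length(si))
  if (furrow_state > 0) {  # horizontal furrows creep up the forehead
    band <- sx > -46 & sx < 46 & sy < (brow_cy - 3) &
      sy > (brow_cy - 3 - 40 * furrow_state)
    skv[band] <- 165 + 50 * sign(sin(2 * pi * sy[band] / 12))
  }
  if (knit_state > 0) {    # glabella lines between the brows
    glab <- abs(sx) < (3 + 10 * knit_state) & sy > (brow_cy - 2) & sy < -14
    skv[glab] <- 165 + 45 * sign(sin(2 * pi * sx[glab] / 10))
  }
  if (raise_state > 0) {   # smooth vertical stretch lines when brows raised
    band <- sx > -46 & sx < 46 & sy < (brow_cy - 3) &
      sy > (brow_cy - 3 - 3 * raise_state)
    skv[band] <- skv[band] + 30 * sin(2 * pi * sx[band] / 16)
  }
  if (cheek_state > 0) {   # cheek creases: smooth cross-hatch shading
    # grimace tightening recruits a larger cheek area than a smile
    r <- if (corner_tight > corner_raise) 17 * sqrt(cheek_state)
         else 2.5 * sqrt(cheek_state)
    cheek <- (((abs(sx) - 34) / r)^2 + ((sy - 20) / r)^2) < 1
    skv[cheek] <- 165 + 26 * sin(2 * pi * (sx[cheek] + sy[cheek]) / 13) +
      26 * sin(2 * pi * (sx[cheek] - sy[cheek]) / 16)
  }
  if (furrow_state > 0) {  # levator creases beside the nose: fine knots
    wing <- abs(sx) > 11 & abs(sx) < (11 + 23 * furrow_state) &
      sy > -8 & sy < 22
    skv[wing] <- 165 + 48 * sin(2 * pi * sx[wing] / 8.5) *
      sin(2 * pi * sy[wing] / 9.5)
  }
  if (press_state > 0) {   # chin wrinkles when the lips are pressed
    chin <- abs(sx) < (10 + 18 * press_state) & sy > 53 & sy < 75
    skv[chin] <- 165 + 40 * sign(sin(2 * pi * sx[chin] / 10.5))
  }
  if (squeeze_state > 0) { # under-eye bunching when the eyes are squeezed
    for (cx in c(-28, 28)) {
      under <- abs(sx - cx) < (7 + 12 * squeeze_state) & sy > -8 &
        sy < (-8 + 13 * squeeze_state)
      skv[under] <- 165 +
        42 * sign(sin(2 * pi * (sx[under] - cx + sy[under]) / 10))
    }
  }
  canvas[si] <- skv

  sc <- fit$s  # stroke widths scale with the face
  if (smile_state > 0.5) {  # nasolabial folds from nose wings to mouth corners
    # full contrast once engaged: the fold is either visible or absent, so
    # its edge codes never sit in the noise-ambiguous mid-contrast regime
    for (side in c(1, 7)) {
      seg <- rbind(pts[g$nose_base[if (side == 1) 1 else 5], ],
                   pts[g$mouth_outer[side], ])
      canvas[pf_stroke_mask(seg, W, H, 0.9 * sc)] <- 120
    }
  }
  canvas[pf_stroke_mask(pts[g$brow_left, ], W, H, 3 * sc)] <- 55
  canvas[pf_stroke_mask(pts[g$brow_right, ], W, H, 3 * sc)] <- 55
  canvas[pf_stroke_mask(pts[g$nose_bridge, ], W, H, 1.8 * sc)] <- 135
  canvas[pf_stroke_mask(pts[g$nose_base, ], W, H, 1.6 * sc)] <- 135
  canvas[pf_fill_polygon(pts[g$mouth_outer, ], W, H)] <- 105
  # inner mouth: high-contrast vertical "teeth" stripes (template-attached)
  mi <- which(pf_fill_polygon(pts[g$mouth_inner, ], W, H))
  canvas[mi] <- 92 + 60 * sin(2 * pi * ux[mi] / 8)
  # eyes: concentric high-contrast iris rings around each eye centre
  for (idx in list(g$eye_left, g$eye_right)) {
    cen <- colMeans(tpl$xy[idx, ])
    a <- diff(range(tpl$xy[idx, 1])) / 2
    b <- diff(range(tpl$xy[idx, 2])) / 2
    ei <- which(pf_fill_polygon(pts[idx, ], W, H))
    re <- sqrt(((ux[ei] - cen[1]) / a)^2 + ((uy[ei] - cen[2]) / b)^2)
    canvas[ei] <- 90 - 60 * cos(2 * pi * re / 0.7)  # smooth iris rings
  }

  canvas <- canvas * illumination
  if (noise_sd > 0)
    canvas <- canvas + matrix(stats::rnorm(H * W, sd = noise_sd), H, W)
  canvas <- pmin(pmax(round(canvas), 0), 255)
  array(rep(canvas, 3L), c(H, W, 3L))
}

# even-odd polygon fill over an H x W canvas (vertices in (x, y) pixels)
pf_fill_polygon <- function(poly, W, H) {
  nx <- nrow(poly)
  x0 <- max(1L, floor(min(poly[, 1]))); x1 <- min(W, ceiling(max(poly[, 1])))
  y0 <- max(1L, floor(min(poly[, 2]))); y1 <- min(H, ceiling(max(poly[, 2])))
  mask <- matrix(FALSE, H, W)
  if (x1 < x0 || y1 < y0) return(mask)
  gx <- rep(x0:x1, each = y1 - y0 + 1L)
  gy <- rep(y0:y1, times = x1 - x0 + 1L)
  inside <- rep(FALSE, length(gx))
  j <- nx
  for (i in seq_len(nx)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > gy) != (yj > gy)) &
      (gx < (xj - xi) * (gy - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  mask[cbind(gy[inside], gx[inside])] <- TRUE
  mask
}

# mask of pixels within `width` of the polyline through p
pf_stroke_mask <- function(p, W, H, width) {
  mask <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(p) - 1L)) {
    a <- p[i, ]; b <- p[i + 1L, ]
    x0 <- max(1L, floor(min(a[1], b[1]) - width))
    x1 <- min(W, ceiling(max(a[1], b[1]) + width))
    y0 <- max(1L, floor(min(a[2], b[2]) - width))
    y1 <- min(H, ceiling(max(a[2], b[2]) + width))
    if (x1 < x0 || y1 < y0) next
    gx <- rep(x0:x1, each = y1 - y0 + 1L)
    gy <- rep(y0:y1, times = x1 - x0 + 1L)
    ab <- b - a
    len2 <- sum(ab^2)
    tt <- if (len2 < 1e-12) rep(0, length(gx))
          else pmin(pmax(((gx - a[1]) * ab[1] + (gy - a[2]) * ab[2]) / len2, 0), 1)
    d2 <- (gx - (a[1] + tt * ab[1]))^2 + (gy - (a[2] + tt * ab[2]))^2
    hit <- d2 <= width^2
    mask[cbind(gy[hit], gx[hit])] <- TRUE
  }
  mask
}

#' Generate a synthetic labelled video dataset on disk
#'
#' Writes \code{n_videos} synthetic face videos as per-video PNG frame
#' folders with ground-truth landmark sidecars (one text file per frame)
#' and per-video label files, plus a top-level manifest CSV (video,
#' segment, expression, label, frames). Each video is a short scripted
#' sequence of expression segments (neutral / pain / one other
#' expression) in the 30-50-frame-per-segment regime.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_videos Number of videos (default 22).
#' @param seed Integer master seed.
#' @param segment_frames Frames per segment (default 45).
#' @param amplitude_range Expression amplitude range (default
#'   \code{c(0.8, 1)}).
#' @param noise_sd Pixel noise standard deviation (default 2).
#' @param resolution \code{"QVGA"} or \code{"VGA"}.
#' @param write_frames Write PNG frames (TRUE) or landmark/label sidecars
#'   only.
#' @return The manifest data frame, invisibly; files under
#'   \code{out_dir}.
#' @export
generate_dataset <- function(out_dir, n_videos = 22L, seed = 1L,
                             segment_frames = 45L,
                             amplitude_range = c(0.8, 1),
                             noise_sd = 2, resolution = "QVGA",
                             write_frames = TRUE) {
  if (n_videos < 1L) pf_stop("pf_config_error", "n_videos must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    pf_stop("pf_io_error", "cannot create output directory '%s'", out_dir)
  manifest <- NULL
  others <- c("smile", "surprise", "angry")
  for (v in seq_len(n_videos)) {
    vseed <- seed * 1000L + v
    old <- .Random.seed_exists(); set.seed(vseed)
    amp <- stats::runif(3, amplitude_range[1], amplitude_range[2])
    other <- others[(v - 1L) %% 3L + 1L]
    .Random.seed_restore(old)
    segments <- data.frame(
      expression = c("neutral", other, "pain"),
      duration = rep(segment_frames, 3L),
      amplitude = c(0, amp[2], amp[3]))
    script <- expression_script(segments, seed = vseed, noise_sd = noise_sd,
                                resolution = resolution)
    records <- generate_expression_sequence(script)
    vdir <- file.path(out_dir, sprintf("video_%02d", v))
    dir.create(vdir, showWarnings = FALSE)
    labels <- data.frame(
      frame_index = vapply(records, function(r) r$landmarks$frame_index,
                           integer(1)),
      label = vapply(records, function(r) as.integer(r$label), integer(1)),
      expression = vapply(records, `[[`, character(1), "expression"),
      segment = vapply(records, `[[`, integer(1), "segment"))
    utils::write.csv(labels, file.path(vdir, "labels.csv"), row.names = FALSE)
    for (r in records) {
      stem <- sprintf("frame_%04d", r$landmarks$frame_index)
      write_landmarks(r$landmarks, file.path(vdir, paste0(stem, ".pts.txt")))
      if (write_frames)
        png::writePNG(r$frame$pixels / 255, file.path(vdir, paste0(stem, ".png")))
    }
    manifest <- rbind(manifest, data.frame(
      video = sprintf("video_%02d", v), segment = 1:3,
      expression = segments$expression,
      label = vapply(segments$expression, pf_expression_label, integer(1)),
      frames = segments$duration, seed = vseed))
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
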