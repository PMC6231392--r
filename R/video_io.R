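#' Stream configuration
#'
#' Configuration for frame ingestion: frame budget, target frame rate and
#' working resolution. The defaults match the pipeline's operating point:
#' at most 300 frames per run, 5-15 fps, QVGA (320 x 240) or VGA
#' (640 x 480) working resolution.
#'
#' @param max_frames Integer frame budget, in \code{[1, 300]} by default.
#' @param target_fps Target frame rate in \code{[5, 15]}.
#' @param resolution \code{"QVGA"} (320 x 240) or \code{"VGA"} (640 x 480).
#' @param overwrite_buffer Logical; in live mode, keep only the most recent
#'   \code{max_frames} frames (FIFO overwrite) instead of stopping early.
#' @return An object of class \code{pf_stream_config}.
#' @export
stream_config <- function(max_frames = 300L, target_fps = 15,
                          resolution = c("QVGA", "VGA"),
                          overwrite_buffer = FALSE) {
  resolution <- match.arg(resolution)
  max_frames <- as.integer(max_frames)
  if (is.na(max_frames) || max_frames < 1L)
    pf_stop("pf_config_error", "max_frames must be a positive integer")
  if (target_fps < 5 || target_fps > 15)
    pf_stop("pf_config_error", "target_fps must lie in [5, 15]")
  structure(list(max_frames = max_frames, target_fps = target_fps,
                 resolution = resolution,
                 overwrite_buffer = isTRUE(overwrite_buffer)),
            class = "pf_stream_config")
}

pf_resolution_wh <- function(resolution) {
  switch(resolution, QVGA = c(320L, 240L), VGA = c(640L, 480L))
}

#' Construct a video frame
#'
#' @param pixels H x W x 3 numeric array with channel values in
#'   \code{[0, 255]}, or an H x W matrix for \code{"GRAY"}.
#' @param index Nonnegative integer frame number.
#' @param colour_space One of \code{"RGB"}, \code{"YCbCr"}, \code{"GRAY"}.
#' @param source_fps Source frame rate (frames/second).
#' @return An object of class \code{pf_frame}.
#' @export
pf_frame <- function(pixels, index = 0L, colour_space = "RGB",
                     source_fps = 30) {
  if (is.matrix(pixels)) colour_space <- "GRAY"
  if (!colour_space %in% c("RGB", "YCbCr", "GRAY"))
    pf_stop("pf_config_error", "unknown colour space '%s'", colour_space)
  if (min(pixels) < 0 || max(pixels) > 255)
    pf_stop("pf_data_error", "pixel values must lie in [0, 255]")
  structure(list(index = as.integer(index), pixels = pixels,
                 colour_space = colour_space, source_fps = source_fps),
            class = "pf_frame")
}

#' Frame sources
#'
#' A frame source is anything that yields \code{(index, RGB image)} pairs:
#' a directory of numbered PNG frames, an in-memory list of H x W x 3
#' arrays (values in \code{[0,255]} or \code{[0,1]}), or a generator
#' function that returns the next image or \code{NULL} when exhausted.
#' Container formats (.avi/.mp4/...) are supported through the same
#' interface by pointing an external decoder at a frame directory.
#'
#' @param x A directory path, a list of arrays, or a function.
#' @param fps Frame rate to record on the frames read from this source.
#' @return An object of class \code{pf_frame_source} with a \code{next_frame}
#'   closure.
#' @export
frame_source <- function(x, fps = 30) {
  if (is.character(x) && length(x) == 1L) {
    if (!dir.exists(x))
      pf_stop("pf_decode_error", "frame directory '%s' does not exist", x)
    files <- sort(list.files(x, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L)
      pf_stop("pf_empty_input_error", "no frames found under '%s'", x)
    i <- 0L
    nxt <- function() {
      if (i >= length(files)) return(NULL)
      i <<- i + 1L
      px <- png::readPNG(files[i])
      if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
      px[, , 1:3, drop = FALSE] * 255
    }
  } else if (is.list(x)) {
    if (length(x) == 0L)
      pf_stop("pf_empty_input_error", "empty frame list")
    i <- 0L
    nxt <- function() {
      if (i >= length(x)) return(NULL)
      i <<- i + 1L
      px <- x[[i]]
      if (max(px) <= 1) px <- px * 255
      px
    }
  } else if (is.function(x)) {
    nxt <- x
  } else {
    pf_stop("pf_decode_error",
            "unreadable source: expected directory, list or function")
  }
  structure(list(next_frame = nxt, fps = fps), class = "pf_frame_source")
}

#' Read, resample and resize frames from a source
#'
#' Pulls frames from a video frame source, resamples to the configured
#' target rate by uniform index striding (stride =
#' \code{round(source_fps / target_fps)}, no interpolation), resizes to the
#' configured working resolution, and enforces the frame budget. With
#' \code{overwrite_buffer} the source is drained and only the most recent
#' \code{max_frames} frames are kept (live-stream FIFO overwrite);
#' otherwise reading stops once the budget is filled.
#'
#' @param source A \code{pf_frame_source}, or anything accepted by
#'   \code{\link{frame_source}}.
#' @param config A \code{\link{stream_config}}.
#' @return List of \code{pf_frame} objects with strictly increasing
#'   source indices (0-based).
#' @export
read_frames <- function(source, config = stream_config()) {
  if (!inherits(source, "pf_frame_source")) source <- frame_source(source)
  stride <- max(1L, as.integer(round(source$fps / config$target_fps)))
  wh <- pf_resolution_wh(config$resolution)
  out <- list(); idx <- -1L
  repeat {
    px <- source$next_frame()
    if (is.null(px)) break
    idx <- idx + 1L
    if (idx %% stride != 0L) next
    px <- pf_resize_rgb(px, wh[1], wh[2])
    out[[length(out) + 1L]] <- pf_frame(px, index = idx,
                                        source_fps = source$fps)
    if (!config$overwrite_buffer && length(out) >= config$max_frames) break
    if (config$overwrite_buffer && length(out) > config$max_frames)
      out <- out[-1L]
  }
  if (length(out) == 0L)
    pf_stop("pf_empty_input_error", "source yielded no frames")
  out
}

# resize of an H x W x 3 array (or H x W matrix) to w x h pixels;
# "bilinear" for display-quality resizes, "none" (nearest neighbour) where
# scale-independent sampling statistics matter (face crops)
pf_resize_rgb <- function(px, w, h, filter = "bilinear") {
  d <- dim(px)
  if (d[1] == h && d[2] == w) return(px)
  img <- EBImage::Image(aperm(px, if (length(d) == 3L) c(2, 1, 3) else c(2, 1)) / 255,
                        colormode = if (length(d) == 3L) "Color" else "Grayscale")
  res <- EBImage::resize(img, w = w, h = h, filter = filter)
  out <- aperm(EBImage::imageData(res), if (length(d) == 3L) c(2, 1, 3) else c(2, 1))
  pmin(pmax(out * 255, 0), 255)
}

#' RGB to YCbCr colour conversion
#'
#' Full-range (JFIF) conversion: \code{Y = 0.299 R + 0.587 G + 0.114 B},
#' \code{Cb = 128 - 0.168736 R - 0.331264 G + 0.5 B},
#' \code{Cr = 128 + 0.5 R - 0.418688 G - 0.081312 B}, with each output
#' channel rounded to nearest and clipped to \code{[0, 255]}.
#'
#' @param frame A \code{pf_frame} tagged \code{"RGB"}.
#' @return The frame with converted pixels, tagged \code{"YCbCr"}.
#' @export
rgb_to_ycbcr <- function(frame) {
  if (!inherits(frame, "pf_frame") || frame$colour_space != "RGB")
    pf_stop("pf_contract_error", "rgb_to_ycbcr expects an RGB pf_frame")
  px <- frame$pixels
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  out <- array(0, dim(px))
  out[, , 1] <- 0.299 * r + 0.587 * g + 0.114 * b
  out[, , 2] <- 128 - 0.168736 * r - 0.331264 * g + 0.5 * b
  out[, , 3] <- 128 + 0.5 * r - 0.418688 * g - 0.081312 * b
  frame$pixels <- pmin(pmax(round(out), 0), 255)
  frame$colour_space <- "YCbCr"
  frame
}

#' YCbCr to RGB (inverse of \code{\link{rgb_to_ycbcr}})
#'
#' @param frame A \code{pf_frame} tagged \code{"YCbCr"}.
#' @return The frame converted back to RGB (round-trips within +/- 1 per
#'   channel, rounding only).
#' @export
ycbcr_to_rgb <- function(frame) {
  if (!inherits(frame, "pf_frame") || frame$colour_space != "YCbCr")
    pf_stop("pf_contract_error", "ycbcr_to_rgb expects a YCbCr pf_frame")
  px <- frame$pixels
  y <- px[, , 1]; cb <- px[, , 2] - 128; cr <- px[, , 3] - 128
  out <- array(0, dim(px))
  out[, , 1] <- y + 1.402 * cr
  out[, , 2] <- y - 0.344136 * cb - 0.714136 * cr
  out[, , 3] <- y + 1.772 * cb
  frame$pixels <- pmin(pmax(round(out), 0), 255)
  frame$colour_space <- "RGB"
  frame
}

#' Detect and crop the face in a frame
#'
#' Locates the face region and returns it as a 64 x 64 grayscale crop.
#' Detection is a deterministic intensity-blob detector suited to
#' frontal-face imagery with a face brighter than its background: the
#' luma channel is Otsu-thresholded, connected components are labelled,
#' and the largest sufficiently large component's bounding box (squared up
#' and clamped inside the frame) is taken as the face. When several
#' candidate regions are present the largest box wins (single-subject
#' assumption) and a warning is issued. An externally supplied bounding
#' box overrides detection entirely, so detections from any external
#' detector (or ground-truth fixtures) plug in unchanged.
#'
#' @param frame A \code{pf_frame} (any colour space).
#' @param bbox_override Optional numeric \code{c(x, y, w, h)} bounding box
#'   (1-based pixel units in the source frame) that bypasses detection.
#' @param min_area Minimum component area in pixels for a detection.
#' @return A \code{pf_face_crop} (fields \code{pixels} 64 x 64,
#'   \code{bbox}, \code{frame_index}) or \code{NULL} when no face is found.
#' @export
detect_and_crop_face <- function(frame, bbox_override = NULL,
                                 min_area = 400) {
  px <- frame$pixels
  gray <- if (frame$colour_space == "GRAY") px
          else if (frame$colour_space == "YCbCr") px[, , 1]
          else 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  H <- nrow(gray); W <- ncol(gray)
  if (is.null(bbox_override)) {
    g <- gray / 255
    if (max(g) - min(g) < 1e-3) return(NULL)  # uniform frame: no face
    img <- EBImage::Image(t(g))
    th <- EBImage::otsu(img)
    mask <- EBImage::bwlabel(img > th)
    tab <- tabulate(as.integer(EBImage::imageData(mask)))
    if (length(tab) == 0L || max(tab) < min_area) return(NULL)
    if (sum(tab >= min_area) > 1L)
      warning("multiple face candidates detected; keeping the largest")
    lab <- which.max(tab)
    idx <- which(EBImage::imageData(mask) == lab, arr.ind = TRUE)
    # EBImage images are transposed (x = rows of imageData)
    x0 <- min(idx[, 1]); x1 <- max(idx[, 1])
    y0 <- min(idx[, 2]); y1 <- max(idx[, 2])
    bbox <- pf_square_bbox(c(x0, y0, x1 - x0 + 1, y1 - y0 + 1), W, H)
  } else {
    bbox <- pf_square_bbox(bbox_override, W, H)
  }
  sub <- gray[bbox[2]:(bbox[2] + bbox[4] - 1),
              bbox[1]:(bbox[1] + bbox[3] - 1), drop = FALSE]
  crop <- round(pf_resize_rgb(sub, 64L, 64L, filter = "none"))  # 8-bit
  structure(list(pixels = crop, bbox = bbox, frame_index = frame$index),
            class = "pf_face_crop")
}

# square up a (x, y, w, h) box and clamp it inside a W x H frame
pf_square_bbox <- function(bbox, W, H) {
  x <- bbox[1]; y <- bbox[2]; w <- bbox[3]; h <- bbox[4]
  side <- min(max(w, h), W, H)
  cx <- x + w / 2; cy <- y + h / 2
  x <- round(cx - side / 2); y <- round(cy - side / 2)
  x <- min(max(1, x), W - side + 1)
  y <- min(max(1, y), H - side + 1)
  as.integer(c(x, y, side, side))
}

#' Filter out unusable frames
#'
#' Drops frames whose face was not detected and frames whose crop is too
#' blurred to carry alignment information, measured as the variance of a
#' 3 x 3 Laplacian response over the 64 x 64 crop falling below a
#' threshold (default 10 on 8-bit intensities). Returns the retained
#' frame positions (1-based into the input sequence), ascending.
#'
#' @param frames List of \code{pf_frame}.
#' @param crops Aligned list of \code{pf_face_crop} or \code{NULL}.
#' @param sharpness_threshold Minimum Laplacian-response variance.
#' @return Integer vector of retained positions (possibly empty).
#' @export
shot_filter <- function(frames, crops, sharpness_threshold = 10) {
  if (length(frames) != length(crops))
    pf_stop("pf_contract_error", "frames and crops must be aligned")
  if (length(frames) == 0L) return(integer(0))
  keep <- vapply(seq_along(crops), function(i) {
    cr <- crops[[i]]
    if (is.null(cr)) return(FALSE)
    pf_laplacian_variance(cr$pixels) >= sharpness_threshold
  }, logical(1))
  which(keep)
}

#' Normalise a face crop: contrast stretch and noise removal
#'
#' The last preprocessing step before enhancement: a robust percentile
#' contrast stretch (2nd-98th percentile mapped to the full 8-bit range),
#' which cancels global illumination gain, followed by a 3 x 3 median
#' filter that removes isolated sensor noise while preserving edges.
#'
#' @param crop A \code{pf_face_crop}.
#' @param stretch_quantiles Lower/upper percentiles for the stretch.
#' @param median_radius Median filter radius in pixels (0 disables).
#' @return The crop with normalised pixels (8-bit values).
#' @export
normalize_crop <- function(crop, stretch_quantiles = c(0.02, 0.98),
                           median_radius = 1L) {
  m <- crop$pixels
  q <- stats::quantile(m, stretch_quantiles, names = FALSE)
  if (q[2] > q[1])
    m <- pmin(pmax((m - q[1]) / (q[2] - q[1]) * 255, 0), 255)
  if (median_radius > 0L) m <- pf_median3(m)
  crop$pixels <- round(m)
  crop
}

# 3 x 3 median filter via a 19-exchange sorting network on edge-replicated
# shifted copies (much faster than per-pixel sorting)
pf_median3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  ri <- function(d) pmin(pmax(seq_len(H) + d, 1L), H)
  ci <- function(d) pmin(pmax(seq_len(W) + d, 1L), W)
  p <- vector("list", 9L)
  k <- 0L
  for (dy in -1:1) for (dx in -1:1) {
    k <- k + 1L
    p[[k]] <- m[ri(dy), ci(dx)]
  }
  sw <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6); sw(5, 8); sw(5, 3); sw(7, 5)
  sw(5, 3)
  p[[5]]
}

pf_laplacian_variance <- function(gray) {
  k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  resp <- EBImage::filter2(EBImage::Image(t(gray)), k)
  stats::var(as.numeric(EBImage::imageData(resp)))
}
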