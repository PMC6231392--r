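#' Point-operation parameters
#'
#' Defaults follow the settings found to give the best feature extraction:
#' \code{c = 3.5} for the logarithm operation and \code{c = 3},
#' \code{gamma = 2} for the exponential (power-law) operation.
#'
#' @param c_log Positive constant of the logarithm operation.
#' @param c_exp Positive constant of the exponential operation.
#' @param gamma Positive exponent of the exponential operation.
#' @param mode Which enhancement runs in the pipeline: \code{"log"}
#'   (default), \code{"exp"}, \code{"none"}, or \code{"sharper"}
#'   (run both and keep the sharper result).
#' @return An object of class \code{pf_pointop_params}.
#' @export
pointop_params <- function(c_log = 3.5, c_exp = 3.0, gamma = 2.0,
                           mode = c("log", "exp", "none", "sharper")) {
  mode <- match.arg(mode)
  if (c_log <= 0 || c_exp <= 0 || gamma <= 0)
    pf_stop("pf_config_error", "point-operation constants must be positive")
  structure(list(c_log = c_log, c_exp = c_exp, gamma = gamma, mode = mode),
            class = "pf_pointop_params")
}

#' Logarithm point operation
#'
#' Amplifies dark pixel values while compressing bright ones. The input is
#' normalised to \code{r = pixel / 255} in \code{[0, 1]}, transformed as
#' \code{s = c * log(1 + r)} (natural logarithm), rescaled back to 8-bit
#' range by \code{255 * s / (c * log(2))}, rounded half-up and clipped to
#' \code{[0, 255]}. Monotone, concave, and brightening: the output never
#' falls below the identity map.
#'
#' @param image Single-channel matrix with values in \code{[0, 255]}.
#' @param c Positive constant (default 3.5).
#' @return Matrix of the same shape, values in \code{[0, 255]}.
#' @export
log_transform <- function(image, c = 3.5) {
  if (length(image) == 0L)
    pf_stop("pf_data_error", "empty image")
  if (!is.numeric(c) || c <= 0)
    pf_stop("pf_config_error", "log-transform constant c must be positive")
  r <- image / 255
  s <- c * log1p(r)
  out <- s / (c * log(2)) * 255
  pf_round_clip_255(out)
}

#' Exponential (power-law) point operation
#'
#' Enhances the contrast of brighter regions. The input is normalised to
#' \code{r = pixel / 255}, transformed as \code{s = c * r^gamma},
#' rescaled by \code{255 * s / c}, rounded half-up and clipped to
#' \code{[0, 255]}. Monotone and, for \code{gamma > 1}, convex.
#'
#' @param image Single-channel matrix with values in \code{[0, 255]}.
#' @param c Positive constant (default 3).
#' @param gamma Positive exponent (default 2).
#' @return Matrix of the same shape, values in \code{[0, 255]}.
#' @export
exp_transform <- function(image, c = 3.0, gamma = 2.0) {
  if (length(image) == 0L)
    pf_stop("pf_data_error", "empty image")
  if (!is.numeric(c) || c <= 0 || !is.numeric(gamma) || gamma <= 0)
    pf_stop("pf_config_error", "exp-transform parameters must be positive")
  r <- image / 255
  s <- c * r^gamma
  out <- s / c * 255
  pf_round_clip_255(out)
}

# round half up (not banker's rounding), then clip to [0, 255]
pf_round_clip_255 <- function(x) {
  pmin(pmax(floor(x + 0.5), 0), 255)
}

#' Apply the configured point operation to a face crop
#'
#' @param crop A \code{pf_face_crop}.
#' @param params A \code{\link{pointop_params}}.
#' @return The crop with enhanced pixels.
#' @export
enhance_crop <- function(crop, params = pointop_params()) {
  crop$pixels <- switch(params$mode,
    none = crop$pixels,
    log = log_transform(crop$pixels, params$c_log),
    exp = exp_transform(crop$pixels, params$c_exp, params$gamma),
    sharper = {
      a <- log_transform(crop$pixels, params$c_log)
      b <- exp_transform(crop$pixels, params$c_exp, params$gamma)
      if (pf_laplacian_variance(a) >= pf_laplacian_variance(b)) a else b
    })
  crop
}

#' Pack a face crop into a compact integer matrix record
#'
#' Stores the 64 x 64 crop as a compact 8-bit-valued integer matrix along
#' with its source bounding box and frame index, so processed frames can be
#' stored and retrieved in matrix form without any loss. Unpacking
#' reproduces the crop bit-identically.
#'
#' @param crop A \code{pf_face_crop}.
#' @return An object of class \code{pf_packed_frame} with fields
#'   \code{data} (integer matrix), \code{bbox}, \code{frame_index}.
#' @export
pack_frame_matrix <- function(crop) {
  m <- crop$pixels
  storage.mode(m) <- "integer"
  structure(list(data = m, bbox = crop$bbox, frame_index = crop$frame_index),
            class = "pf_packed_frame")
}

#' Unpack a packed frame record back into a face crop
#'
#' @param packed A \code{pf_packed_frame}.
#' @return The original \code{pf_face_crop} (bit-identical pixels).
#' @export
unpack_frame_matrix <- function(packed) {
  m <- packed$data
  storage.mode(m) <- "double"
  structure(list(pixels = m, bbox = packed$bbox,
                 frame_index = packed$frame_index),
            class = "pf_face_crop")
}
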