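#' Construct a 66-point landmark set
#'
#' @param points 66 x 2 matrix of (x, y) pixel coordinates, ordered by the
#'   canonical layout (jaw 0-16, brows 17-26, nose 27-35, eyes 36-47,
#'   mouth 48-65; 1-based in R).
#' @param visibility Logical vector of length 66.
#' @param frame_index Integer frame number.
#' @return An object of class \code{pf_landmarks}.
#' @export
pf_landmarks <- function(points, visibility = rep(TRUE, 66L),
                         frame_index = 0L) {
  points <- as.matrix(points)
  if (nrow(points) != 66L || ncol(points) != 2L)
    pf_stop("pf_contract_error", "a landmark set has exactly 66 (x, y) points")
  if (!all(is.finite(points)))
    pf_stop("pf_data_error", "landmark coordinates must be finite")
  structure(list(points = points, visibility = as.logical(visibility),
                 frame_index = as.integer(frame_index)),
            class = "pf_landmarks")
}

pf_points_of <- function(x) if (inherits(x, "pf_landmarks")) x$points else as.matrix(x)

# optimal rotation angle aligning points x onto m (rotation about origin),
# closed form of the 2-D orthogonal Procrustes problem
pf_opt_rotation <- function(x, m) {
  atan2(sum(m[, 2] * x[, 1] - m[, 1] * x[, 2]),
        sum(m[, 1] * x[, 1] + m[, 2] * x[, 2]))
}

pf_rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Generalised Procrustes alignment of landmark shapes
#'
#' Removes translation, scale and in-plane rotation from a set of 66-point
#' shapes: each shape is centred at its centroid and scaled to unit
#' Frobenius norm, then rotated to the running mean shape; the mean is
#' recomputed and renormalised until it moves by less than \code{tol}
#' (Frobenius norm) between iterations.
#'
#' @param shapes List of \code{pf_landmarks} or 66 x 2 matrices (>= 2).
#' @param tol Convergence tolerance on the mean shape (default 1e-8).
#' @param max_iter Iteration cap.
#' @return List with \code{aligned} (list of 66 x 2 matrices),
#'   \code{mean_shape} (66 x 2, unit norm, centred) and \code{transforms}
#'   (per-shape list of \code{centroid}, \code{scale}, \code{angle} mapping
#'   the original shape into the aligned frame).
#' @export
procrustes_align <- function(shapes, tol = 1e-8, max_iter = 200L) {
  if (length(shapes) < 2L)
    pf_stop("pf_contract_error", "need at least two shapes to align")
  pts <- lapply(shapes, pf_points_of)
  centred <- lapply(pts, function(p) sweep(p, 2, colMeans(p)))
  norms <- vapply(centred, function(p) sqrt(sum(p^2)), numeric(1))
  if (any(norms < 1e-12))
    pf_stop("pf_alignment_error", "degenerate shape: all points coincident")
  scaled <- Map(function(p, n) p / n, centred, norms)
  mean_shape <- scaled[[1L]]
  angles <- numeric(length(scaled))
  for (it in seq_len(max_iter)) {
    aligned <- vector("list", length(scaled))
    for (i in seq_along(scaled)) {
      angles[i] <- pf_opt_rotation(scaled[[i]], mean_shape)
      aligned[[i]] <- scaled[[i]] %*% t(pf_rot2(angles[i]))
    }
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) break
  }
  transforms <- Map(function(p, n, a) {
    list(centroid = colMeans(p), scale = 1 / n, angle = a)
  }, pts, norms, angles)
  list(aligned = aligned, mean_shape = mean_shape, transforms = transforms)
}

#' Build the PCA shape model
#'
#' Stacks Procrustes-aligned shapes as 132-vectors (x1, y1, ..., x66, y66),
#' eigendecomposes their covariance and retains the smallest number of
#' modes whose eigenvalues account for at least \code{variance_fraction}
#' of the total variance.
#'
#' @param aligned List of aligned 66 x 2 matrices (from
#'   \code{\link{procrustes_align}}).
#' @param variance_fraction Fraction of variance to retain, in (0, 1]
#'   (default 0.95).
#' @return An object of class \code{pf_shape_model} with \code{mean_shape}
#'   (132-vector), \code{shape_vectors} (132 x k orthonormal matrix),
#'   \code{eigenvalues} (descending) and \code{k}.
#' @export
build_shape_model <- function(aligned, variance_fraction = 0.95) {
  if (length(aligned) < 2L)
    pf_stop("pf_model_error", "need at least two shapes to build a shape model")
  X <- t(vapply(aligned, function(p) as.numeric(t(pf_points_of(p))),
                numeric(132L)))
  mu <- colMeans(X)
  C <- stats::cov(X)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  total <- sum(vals)
  if (total < 1e-12) {
    k <- 0L
  } else {
    k <- which(cumsum(vals) / total >= variance_fraction)[1L]
  }
  structure(list(mean_shape = mu,
                 shape_vectors = e$vectors[, seq_len(k), drop = FALSE],
                 eigenvalues = vals[seq_len(k)], k = as.integer(k)),
            class = "pf_shape_model")
}

# 132-vector <-> 66 x 2 conversions (interleaved x1, y1, x2, y2, ...)
pf_vec_to_shape <- function(v) matrix(v, ncol = 2, byrow = TRUE)
pf_shape_to_vec <- function(p) as.numeric(t(p))

#' Project a shape onto the shape-model subspace with coefficient clamping
#'
#' Similarity-aligns the input shape to the model mean (full Procrustes:
#' translation, scale, rotation), expresses the residual in the model's
#' eigenbasis, clamps each coefficient to \code{clamp_sd} standard
#' deviations (\code{|q_i| <= clamp_sd * sqrt(lambda_i)}), reconstructs,
#' and maps back to the input frame. A shape already inside the clamped
#' subspace is returned unchanged (to numerical precision).
#'
#' @param points 66 x 2 matrix in any image frame.
#' @param model A \code{pf_shape_model}.
#' @param clamp_sd Per-mode clamp in standard deviations (default 3).
#' @return 66 x 2 matrix of the regularised shape in the input frame.
#' @export
project_to_shape_model <- function(points, model, clamp_sd = 3) {
  p <- pf_points_of(points)
  ctr <- colMeans(p)
  pc <- sweep(p, 2, ctr)
  if (sqrt(sum(pc^2)) < 1e-12)
    pf_stop("pf_alignment_error", "degenerate shape: all points coincident")
  mu <- pf_vec_to_shape(model$mean_shape)
  # alternate between similarity alignment onto the current reconstruction
  # and clamped subspace coefficients; converges quadratically, so a shape
  # already inside the clamped subspace is an exact fixed point
  target <- mu
  q <- numeric(model$k)
  ang <- 0; s <- 1
  for (it in 1:6) {
    ang <- pf_opt_rotation(pc, target)
    rot <- pc %*% t(pf_rot2(ang))
    s <- sum(rot * target) / sum(rot^2)
    y <- rot * s
    if (model$k > 0L) {
      q <- as.numeric(crossprod(model$shape_vectors,
                                pf_shape_to_vec(y) - model$mean_shape))
      lim <- clamp_sd * sqrt(model$eigenvalues)
      q <- pmin(pmax(q, -lim), lim)
      target <- pf_vec_to_shape(model$mean_shape +
                                  as.numeric(model$shape_vectors %*% q))
    }
  }
  out <- target %*% t(pf_rot2(-ang)) / s
  sweep(out, 2, ctr, `+`)
}

#' Build the per-landmark patch model
#'
#' Crops a fixed odd-sided patch around each of the 66 landmarks of every
#' peak (reference) training frame, normalises each patch to zero mean and
#' unit variance, averages per landmark across frames, and renormalises.
#' Patches leaving the image are padded by edge replication.
#'
#' @param crops List of 64 x 64 grayscale matrices (enhanced face crops).
#' @param landmarks Aligned list of \code{pf_landmarks} in crop
#'   coordinates.
#' @param patch_size Odd patch side (default 11).
#' @return An object of class \code{pf_patch_model} with \code{patches}
#'   (list of 66 templates) and \code{patch_size}.
#' @export
build_patch_model <- function(crops, landmarks, patch_size = 11L) {
  patch_size <- as.integer(patch_size)
  if (patch_size %% 2L == 0L)
    pf_stop("pf_config_error", "patch_size must be odd")
  if (length(crops) == 0L || length(crops) != length(landmarks))
    pf_stop("pf_contract_error", "crops and landmarks must be aligned and non-empty")
  acc <- rep(list(matrix(0, patch_size, patch_size)), 66L)
  for (f in seq_along(crops)) {
    p <- pf_points_of(landmarks[[f]])
    for (j in 1:66) {
      patch <- pf_extract_patch(crops[[f]], p[j, 1], p[j, 2], patch_size)
      acc[[j]] <- acc[[j]] + pf_normalise_patch(patch)
    }
  }
  patches <- lapply(acc, function(m) pf_normalise_patch(m / length(crops)))
  structure(list(patches = patches, patch_size = patch_size),
            class = "pf_patch_model")
}

pf_extract_patch <- function(image, x, y, size) {
  hp <- size %/% 2L
  rows <- pmin(pmax(round(y) + (-hp:hp), 1L), nrow(image))
  cols <- pmin(pmax(round(x) + (-hp:hp), 1L), ncol(image))
  image[rows, cols, drop = FALSE]
}

pf_normalise_patch <- function(m) {
  m <- m - mean(m)
  s <- stats::sd(as.numeric(m))
  if (s < 1e-8) matrix(0, nrow(m), ncol(m)) else m / s
}

#' Build the PCA appearance model
#'
#' Warps each training crop onto the base mesh (the model mean shape
#' placed in the 64 x 64 crop domain) by a piecewise-affine map over the
#' template triangulation, then computes the mean image and the top
#' \code{l} eigenimages over the base-shape pixel domain.
#'
#' @param crops List of 64 x 64 grayscale crops.
#' @param landmarks Aligned list of \code{pf_landmarks} in crop
#'   coordinates.
#' @param shape_model A \code{pf_shape_model} providing the base shape.
#' @param l Number of appearance modes to retain.
#' @return An object of class \code{pf_appearance_model} with
#'   \code{base_appearance} (mean image vector over the domain),
#'   \code{appearance_images} (domain x l orthonormal matrix),
#'   \code{eigenvalues}, \code{l}, and the warp geometry (\code{domain},
#'   base mesh) needed to warp new crops.
#' @export
build_appearance_model <- function(crops, landmarks, shape_model, l = 5L) {
  n <- length(crops)
  if (n < 2L || n != length(landmarks))
    pf_stop("pf_model_error", "need >= 2 shape-annotated crops on a common domain")
  base <- pf_base_mesh(shape_model)
  A <- vapply(seq_len(n), function(i) {
    pf_warp_to_base(crops[[i]], pf_points_of(landmarks[[i]]), base)
  }, numeric(nrow(base$bary)))
  mu <- rowMeans(A)
  Xc <- A - mu
  sv <- svd(Xc)
  pos <- sum(sv$d > 1e-8)
  if (l > n) {
    warning(sprintf("l = %d exceeds sample size %d; clipping", l, n))
    l <- n
  }
  l_eff <- min(l, pos)
  structure(list(base_appearance = mu,
                 appearance_images = sv$u[, seq_len(l_eff), drop = FALSE],
                 eigenvalues = (sv$d[seq_len(l_eff)]^2) / (n - 1),
                 l = as.integer(l_eff), base = base),
            class = "pf_appearance_model")
}

# place the (unit-norm, centred) model mean shape into the 64 x 64 crop
# domain and precompute the pixel -> triangle barycentric geometry
pf_base_mesh <- function(shape_model, size = 64L, fill = 0.88) {
  mu <- pf_vec_to_shape(shape_model$mean_shape)
  ext <- max(apply(mu, 2, function(v) diff(range(v))))
  scale <- fill * size / ext
  pts <- sweep(mu * scale, 2, c((size + 1) / 2, (size + 1) / 2), `+`)
  tri <- pf_template_triangles
  gx <- rep(seq_len(size), each = size)   # x (col) per pixel, row-major
  gy <- rep(seq_len(size), times = size)  # y (row)
  tri_id <- integer(size * size)
  b1 <- b2 <- numeric(size * size)
  for (k in seq_len(nrow(tri))) {
    A <- pts[tri[k, 1], ]; B <- pts[tri[k, 2], ]; C <- pts[tri[k, 3], ]
    det <- (B[1] - A[1]) * (C[2] - A[2]) - (C[1] - A[1]) * (B[2] - A[2])
    if (abs(det) < 1e-12) next
    l1 <- ((gx - A[1]) * (C[2] - A[2]) - (C[1] - A[1]) * (gy - A[2])) / det
    l2 <- ((B[1] - A[1]) * (gy - A[2]) - (gx - A[1]) * (B[2] - A[2])) / det
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & (l1 + l2) <= 1 + 1e-9 & tri_id == 0L
    tri_id[inside] <- k
    b1[inside] <- l1[inside]; b2[inside] <- l2[inside]
  }
  keep <- tri_id > 0L
  list(points = pts, triangles = tri,
       pix_x = gx[keep], pix_y = gy[keep],
       tri_id = tri_id[keep],
       bary = cbind(1 - b1[keep] - b2[keep], b1[keep], b2[keep]))
}

# piecewise-affine warp of a crop onto the base mesh; returns the vector
# of sampled intensities over the base-shape pixel domain
pf_warp_to_base <- function(crop, landmarks, base) {
  tri <- base$triangles[base$tri_id, , drop = FALSE]
  sx <- base$bary[, 1] * landmarks[tri[, 1], 1] +
        base$bary[, 2] * landmarks[tri[, 2], 1] +
        base$bary[, 3] * landmarks[tri[, 3], 1]
  sy <- base$bary[, 1] * landmarks[tri[, 1], 2] +
        base$bary[, 2] * landmarks[tri[, 2], 2] +
        base$bary[, 3] * landmarks[tri[, 3], 2]
  pf_bilinear_sample(crop, sx, sy)
}

pf_bilinear_sample <- function(image, x, y) {
  H <- nrow(image); W <- ncol(image)
  x <- pmin(pmax(x, 1), W); y <- pmin(pmax(y, 1), H)
  x0 <- pmin(floor(x), W - 1L); y0 <- pmin(floor(y), H - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0 - 1) * H + y0
  (1 - fx) * (1 - fy) * image[i00] +
    fx * (1 - fy) * image[i00 + H] +
    (1 - fx) * fy * image[i00 + 1] +
    fx * fy * image[i00 + H + 1]
}

#' Minimum-spanning-tree connectivity over visible landmarks
#'
#' Builds the tree connectivity structure over the visible landmarks of
#' the mean shape: Prim's algorithm with Euclidean edge weights and a
#' deterministic tie-break by the lower (i, j) vertex index pair.
#'
#' @param visibility Logical vector of length 66.
#' @param coordinates 66 x 2 mean-shape coordinates.
#' @return An object of class \code{pf_tree} with \code{vertices} (visible
#'   indices), \code{edges} (m x 2 matrix, i < j) and \code{n}.
#' @export
build_tree <- function(visibility, coordinates) {
  verts <- which(as.logical(visibility))
  if (length(verts) < 2L)
    pf_stop("pf_contract_error", "need at least two visible points")
  P <- pf_points_of(coordinates)[verts, , drop = FALSE]
  n <- length(verts)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  edges <- matrix(0L, n - 1L, 2L)
  for (e in seq_len(n - 1L)) {
    best <- NULL; best_w <- Inf
    for (a in which(in_tree)) for (b in which(!in_tree)) {
      w <- sqrt(sum((P[a, ] - P[b, ])^2))
      cand <- sort(c(verts[a], verts[b]))
      better <- w < best_w - 1e-12 ||
        (abs(w - best_w) <= 1e-12 && !is.null(best) &&
           (cand[1] < best[1] || (cand[1] == best[1] && cand[2] < best[2])))
      if (better) { best_w <- w; best <- cand; new_b <- b }
    }
    edges[e, ] <- best
    in_tree[new_b] <- TRUE
  }
  structure(list(vertices = verts, edges = edges, n = n),
            class = "pf_tree")
}

#' Fit landmarks to a face crop (constrained local model)
#'
#' Iterates a per-landmark mean-shift step on a normalised
#' cross-correlation response map (each landmark's patch template scored
#' in a local search window) with a global shape constraint (projection
#' onto the PCA shape subspace with coefficients clamped to
#' \code{clamp_sd} standard deviations). Stops when the mean point
#' displacement falls below \code{tol} pixels or after \code{max_iter}
#' rounds. For tracking, pass the previous frame's fit as \code{init};
#' with \code{init = NULL} the mean shape is placed into the crop.
#'
#' @param crop 64 x 64 grayscale matrix (enhanced face crop) or
#'   \code{pf_face_crop}.
#' @param init \code{pf_landmarks} (or 66 x 2 matrix) initial estimate in
#'   crop coordinates, or \code{NULL}.
#' @param models List with elements \code{shape} (\code{pf_shape_model}),
#'   \code{patch} (\code{pf_patch_model}) and optionally \code{tree}.
#' @param search_window Odd search-window side (default 15).
#' @param max_iter Iteration cap (default 20).
#' @param tol Mean displacement convergence tolerance in pixels
#'   (default 0.1).
#' @param clamp_sd Shape coefficient clamp (default 3).
#' @param visibility_floor Minimum NCC peak for a landmark to count as
#'   visible (default 0.3).
#' @return A list with \code{landmarks} (\code{pf_landmarks} with
#'   per-point visibility), \code{pose} (similarity transform of the mean
#'   shape into the crop: \code{scale}, \code{angle}, \code{centroid}),
#'   \code{converged}, and \code{iterations}.
#' @export
fit_landmarks <- function(crop, init, models, search_window = 15L,
                          max_iter = 20L, tol = 0.1, clamp_sd = 3,
                          visibility_floor = 0.3) {
  image <- if (inherits(crop, "pf_face_crop")) crop$pixels else crop
  frame_index <- if (inherits(crop, "pf_face_crop")) crop$frame_index else 0L
  sm <- models$shape; pm <- models$patch
  if (is.null(sm) || is.null(pm))
    pf_stop("pf_contract_error", "models must contain shape and patch models")
  if (is.null(init)) {
    init <- pf_base_mesh(sm, size = nrow(image))$points
  }
  pts <- pf_points_of(init)
  size <- pm$patch_size
  # unit-L2 templates so the C++ response is a true NCC in [-1, 1]
  templ <- lapply(pm$patches, function(t) {
    n2 <- sqrt(sum(t^2)); if (n2 < 1e-12) t else t / n2
  })
  peak <- numeric(66L)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # anneal the search window: wide first, narrow once roughly in place;
    # the per-landmark mean-shift step (squared positive NCC responses
    # under a Gaussian spatial prior) runs in compiled code
    win <- if (it <= 2L) search_window else max(7L, search_window - 6L)
    ms <- clm_mean_shift(image, templ, pts, as.integer(win))
    peak <- ms[, 3]
    target <- ms[, 1:2, drop = FALSE]
    new_pts <- project_to_shape_model(target, sm, clamp_sd = clamp_sd)
    disp <- mean(sqrt(rowSums((new_pts - pts)^2)))
    pts <- new_pts
    if (disp < tol) { converged <- TRUE; break }
  }
  # pose of the fitted shape relative to the model mean
  ctr <- colMeans(pts)
  pc <- sweep(pts, 2, ctr)
  nrm <- sqrt(sum(pc^2))
  mu <- pf_vec_to_shape(sm$mean_shape)
  ang <- pf_opt_rotation(mu, pc / nrm)  # rotation taking the mean to the fit
  list(landmarks = pf_landmarks(pts, visibility = peak >= visibility_floor,
                                frame_index = frame_index),
       pose = list(scale = nrm, angle = ang, centroid = ctr),
       quality = mean(peak),
       converged = converged, iterations = it)
}

#' Read / write landmark text files
#'
#' Two dialects are supported: the package's per-frame points format
#' (whitespace-separated columns \code{index x y visible}, one landmark
#' per line) and the common pts dialect (\code{version: 1},
#' \code{n_points: 66}, coordinates between braces).
#'
#' @param path File path.
#' @param landmarks A \code{pf_landmarks} (for writing).
#' @param format \code{"table"} or \code{"pts"}.
#' @return \code{read_landmarks}: a \code{pf_landmarks};
#'   \code{write_landmarks}: the path, invisibly.
#' @export
write_landmarks <- function(landmarks, path, format = c("table", "pts")) {
  format <- match.arg(format)
  p <- landmarks$points
  if (format == "table") {
    df <- data.frame(index = 0:65, x = p[, 1], y = p[, 2],
                     visible = as.integer(landmarks$visibility))
    utils::write.table(df, path, row.names = FALSE, col.names = TRUE,
                       quote = FALSE)
  } else {
    lines <- c("version: 1", sprintf("n_points: %d", nrow(p)), "{",
               sprintf("%.6f %.6f", p[, 1], p[, 2]), "}")
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path, format = c("table", "pts")) {
  format <- match.arg(format)
  if (format == "table") {
    df <- utils::read.table(path, header = TRUE)
    pf_landmarks(cbind(df$x, df$y), visibility = df$visible > 0)
  } else {
    lines <- readLines(path)
    open <- which(trimws(lines) == "{"); close <- which(trimws(lines) == "}")
    coords <- do.call(rbind, lapply(lines[(open + 1):(close - 1)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    pf_landmarks(coords)
  }
}
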