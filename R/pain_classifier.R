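#' Threshold configuration for the soft-threshold rule
#'
#' @param delta1 Nonnegative lower threshold (neutral / not-pain boundary).
#' @param delta2 Upper threshold, strictly greater than \code{delta1}
#'   (not-pain / pain boundary).
#' @return An object of class \code{pf_thresholds}.
#' @export
threshold_config <- function(delta1, delta2) {
  if (delta1 < 0 || delta2 <= delta1)
    pf_stop("pf_config_error", "thresholds must satisfy 0 <= delta1 < delta2")
  structure(list(delta1 = delta1, delta2 = delta2), class = "pf_thresholds")
}

#' Train per-class feature templates (histogram technique)
#'
#' Computes per-dimension normalisation statistics (mean and standard
#' deviation, floored at 1e-6) over all training peak frames, then builds
#' one template per class as the mean of that class's z-normalised
#' 15-dimensional feature vectors (6 pose features + 9 LBP histogram
#' bins).
#'
#' @param features List of \code{pf_frame_features} with labels set.
#' @param peaks Optional \code{pf_peak_frames}; if given, only frames
#'   whose index is a peak index are used.
#' @return An object of class \code{pf_class_templates} with
#'   \code{templates} (3 x 15 matrix, rows neutral/pain/not-pain),
#'   \code{support} (peak count per class), \code{center}, \code{scale}
#'   (normalisation statistics).
#' @export
build_class_templates <- function(features, peaks = NULL) {
  if (!is.null(peaks)) {
    idx <- vapply(features, `[[`, integer(1), "frame_index")
    features <- features[idx %in% peaks$indices]
  }
  labels <- vapply(features, function(f) as.integer(f$label), integer(1))
  missing <- setdiff(PF_CLASSES, labels)
  if (length(missing) > 0L)
    pf_stop("pf_training_error", "no training peak frames for class %s",
            paste(pf_label_name(missing), collapse = ", "))
  X <- features_matrix(features)
  center <- colMeans(X)
  # population standard deviation, so duplicating the training set leaves
  # the normalisation (and hence the templates) unchanged
  scale <- pmax(sqrt(colMeans(sweep(X, 2, center)^2)), 1e-6)
  Z <- sweep(sweep(X, 2, center), 2, scale, `/`)
  templates <- t(vapply(PF_CLASSES, function(cl)
    colMeans(Z[labels == cl, , drop = FALSE]), numeric(ncol(Z))))
  rownames(templates) <- names(PF_CLASSES)
  structure(list(templates = templates,
                 support = vapply(PF_CLASSES, function(cl) sum(labels == cl),
                                  integer(1)),
                 center = center, scale = scale),
            class = "pf_class_templates")
}

# z-normalise a feature vector (or matrix rows) with template statistics
pf_znorm <- function(x, tmpl) {
  if (is.matrix(x)) sweep(sweep(x, 2, tmpl$center), 2, tmpl$scale, `/`)
  else (x - tmpl$center) / tmpl$scale
}

#' Euclidean distance between feature vectors
#'
#' Standard L2 norm of the difference of two equally normalised feature
#' vectors.
#'
#' @param features Numeric vector (or \code{pf_frame_features}).
#' @param reference Numeric vector of the same length (or a template row).
#' @return Nonnegative scalar.
#' @export
frame_distance <- function(features, reference) {
  a <- if (inherits(features, "pf_frame_features")) features_vector(features)
       else as.numeric(features)
  b <- as.numeric(reference)
  if (length(a) != length(b))
    pf_stop("pf_contract_error", "feature dimension mismatch (%d vs %d)",
            length(a), length(b))
  sqrt(sum((a - b)^2))
}

#' Classify one frame by its distance value
#'
#' The soft-threshold decision rule: \code{diff < delta1} is a neutral
#' face; \code{delta1 <= diff < delta2} is a not-pain face; \code{diff >=
#' delta2} is a pain face. Boundary equalities fall to the higher (more
#' severe) branch so a tie never misses pain.
#'
#' @param diff Nonnegative distance value(s).
#' @param thresholds A \code{\link{threshold_config}}.
#' @return Integer class code(s): 1 neutral_face, 3 not_pain_face,
#'   2 pain_face.
#' @export
classify_frame <- function(diff, thresholds) {
  ifelse(diff < thresholds$delta1, PF_CLASSES[["neutral_face"]],
         ifelse(diff < thresholds$delta2, PF_CLASSES[["not_pain_face"]],
                PF_CLASSES[["pain_face"]]))
}

#' Calibrate the two soft thresholds on training distances
#'
#' Grid-searches candidate (delta1, delta2) pairs drawn from the pooled
#' distance quantiles (1% steps), maximising macro-averaged per-class
#' training accuracy under the decision rule, with a deterministic
#' tie-break preferring smaller delta1 then smaller delta2. Degenerate
#' input (all distances equal) falls back to the 33%/66% quantiles with a
#' warning.
#'
#' @param distances Numeric distance per training frame.
#' @param labels Integer class codes (1/2/3) aligned with
#'   \code{distances}; all three classes must be present.
#' @return A \code{pf_thresholds} with the achieved training accuracy in
#'   attribute \code{"accuracy"}.
#' @export
calibrate_thresholds <- function(distances, labels) {
  labels <- as.integer(labels)
  if (!all(PF_CLASSES %in% labels))
    pf_stop("pf_training_error", "distances for all three classes required")
  # inverse-ECDF quantiles (type 1): candidates are observed distances, and
  # duplicating the training set leaves the candidate grid unchanged
  qs <- unique(stats::quantile(distances, probs = seq(0, 1, by = 0.01),
                               names = FALSE, type = 1))
  if (length(qs) < 2L) {
    warning("degenerate calibration input (all distances equal); quantile defaults")
    d1 <- stats::quantile(distances, 1 / 3, names = FALSE, type = 1)
    d2 <- stats::quantile(distances, 2 / 3, names = FALSE, type = 1)
    if (d2 <= d1) d2 <- d1 + 1e-6
    out <- threshold_config(max(d1, 0), d2)
    attr(out, "accuracy") <- pf_macro_accuracy(distances, labels, out)
    return(out)
  }
  best <- NULL; best_acc <- -1
  for (i in seq_along(qs)) {
    for (j in seq_along(qs)) {
      if (qs[j] <= qs[i] || qs[i] < 0) next
      th <- list(delta1 = qs[i], delta2 = qs[j])
      acc <- pf_macro_accuracy(distances, labels, th)
      if (acc > best_acc + 1e-12) { best_acc <- acc; best <- th }
    }
  }
  out <- threshold_config(best$delta1, best$delta2)
  attr(out, "accuracy") <- best_acc
  out
}

pf_macro_accuracy <- function(distances, labels, thresholds) {
  pred <- classify_frame(distances, thresholds)
  mean(vapply(PF_CLASSES, function(cl) {
    n <- sum(labels == cl)
    if (n == 0L) return(NA_real_)
    sum(pred[labels == cl] == cl) / n
  }, numeric(1)), na.rm = TRUE)
}

#' Classify a stream of frame features
#'
#' Applies the distance rule frame by frame. The reference the distance
#' is measured against comes in three flavours:
#' \describe{
#'   \item{\code{"baseline_peak"} (default)}{an adaptive baseline: of
#'     the most recent \code{baseline_window} peak frames (every
#'     \code{gop}-th frame), the one whose features lie closest to the
#'     trained neutral-class template serves as the reference. The
#'     selection is purely relative within the stream -- under shared
#'     head pose and lighting the most relaxed recent peak always wins
#'     -- so no label feedback is involved and the reference stays a
#'     recent frame of the same subject. Pose- and illumination-driven
#'     feature drift therefore cancels in the distance, which isolates
#'     the departure from the subject's relaxed baseline: neutral frames
#'     sit close to it, other expressions at an intermediate distance,
#'     pain far away.}
#'   \item{\code{"neutral_template"}}{the fixed trained neutral-class
#'     template.}
#'   \item{\code{"running_peak"}}{the most recent peak frame regardless
#'     of its label, refreshed every \code{gop} frames: a pure
#'     change-detection reading.}
#' }
#'
#' @param features List of \code{pf_frame_features} in frame order
#'   (entries may be \code{NULL} for frames with no fit: these are emitted
#'   with label \code{NA} / status \code{"skipped"}).
#' @param templates A \code{pf_class_templates}.
#' @param thresholds A \code{pf_thresholds}.
#' @param gop Reference refresh period (Group of Pictures length).
#' @param reference Reference mode (see above).
#' @param baseline_window Number of recent peaks the baseline is chosen
#'   from under \code{"baseline_peak"} (default 8).
#' @return A data frame with columns \code{frame_index}, \code{diff},
#'   \code{label} (integer code or NA), \code{status}, and per-class
#'   distances \code{d_neutral}, \code{d_pain}, \code{d_not_pain}.
#' @export
classify_stream <- function(features, templates, thresholds, gop = 15L,
                            reference = c("baseline_peak", "neutral_template",
                                          "running_peak"),
                            baseline_window = 8L) {
  reference <- match.arg(reference)
  n <- length(features)
  out <- data.frame(frame_index = rep(NA_integer_, n),
                    diff = rep(NA_real_, n),
                    label = rep(NA_integer_, n),
                    status = rep("skipped", n),
                    d_neutral = rep(NA_real_, n), d_pain = rep(NA_real_, n),
                    d_not_pain = rep(NA_real_, n))
  if (n == 0L) return(out)
  neutral_tmpl <- templates$templates["neutral_face", ]
  ref_vec <- neutral_tmpl
  peak_buf <- list()  # recent peaks: list of (z, distance to neutral template)
  seen <- 0L
  for (i in seq_len(n)) {
    f <- features[[i]]
    if (is.null(f)) {
      out$frame_index[i] <- NA_integer_; out$status[i] <- "skipped"
      next
    }
    z <- pf_znorm(features_vector(f), templates)
    is_peak <- seen %% gop == 0L
    seen <- seen + 1L
    if (is_peak) {
      if (reference == "running_peak") ref_vec <- z
      if (reference == "baseline_peak") {
        # rank candidate baselines by their LBP block only: the texture
        # histogram is insensitive to head pose, so the comparison stays
        # valid across the whole window
        peak_buf[[length(peak_buf) + 1L]] <-
          list(z = z, d0 = frame_distance(z[7:15], neutral_tmpl[7:15]))
        if (length(peak_buf) > baseline_window)
          peak_buf <- peak_buf[-1L]
        d0s <- vapply(peak_buf, `[[`, numeric(1), "d0")
        ref_vec <- peak_buf[[which.min(d0s)]]$z
      }
    }
    d <- frame_distance(z, ref_vec)
    out$frame_index[i] <- f$frame_index
    out$diff[i] <- d
    out$status[i] <- "classified"
    out$d_neutral[i] <- frame_distance(z, templates$templates["neutral_face", ])
    out$d_pain[i] <- frame_distance(z, templates$templates["pain_face", ])
    out$d_not_pain[i] <- frame_distance(z, templates$templates["not_pain_face", ])
  }
  # under the adaptive baseline, a running median of three on the distance
  # track suppresses isolated spikes before the threshold rule is applied
  ok <- out$status == "classified"
  if (reference == "baseline_peak" && sum(ok) >= 3L) {
    dd <- out$diff[ok]
    sm <- dd
    nn <- length(dd)
    sm[2:(nn - 1)] <- vapply(2:(nn - 1), function(i)
      sort(dd[(i - 1):(i + 1)])[2], numeric(1))
    out$diff[ok] <- sm
  }
  out$label[ok] <- classify_frame(out$diff[ok], thresholds)
  out
}
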