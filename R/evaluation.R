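#' Hit rate and false acceptance rate
#'
#' HR is the fraction of truly-pain frames labelled pain (true-positive
#' rate); FAR is the fraction of truly not-pain frames (neutral and
#' not-pain pooled) labelled pain (false-positive rate). Skipped frames
#' (predicted label \code{NA}) are excluded.
#'
#' @param predicted Integer class codes (1/2/3), \code{NA} for skipped
#'   frames, or a \code{classify_stream} result data frame.
#' @param truth Integer class codes aligned with \code{predicted}.
#' @return List with \code{hr} (or \code{NA} when the truth contains no
#'   pain frames) and \code{far}.
#' @export
compute_hr_far <- function(predicted, truth) {
  if (is.data.frame(predicted)) predicted <- predicted$label
  keep <- !is.na(predicted)
  predicted <- predicted[keep]; truth <- as.integer(truth)[keep]
  pain <- PF_CLASSES[["pain_face"]]
  n_pain <- sum(truth == pain)
  n_rest <- sum(truth != pain)
  hr <- if (n_pain == 0L) NA_real_
        else sum(truth == pain & predicted == pain) / n_pain
  far <- if (n_rest == 0L) NA_real_
         else sum(truth != pain & predicted == pain) / n_rest
  list(hr = hr, far = far)
}

#' ROC curve and AUC for the pain-distance score
#'
#' Sweeps the pain threshold over all distinct distance values (a frame
#' is called pain when its distance is >= the threshold), yielding one
#' (FAR, HR) point per threshold plus the two trivial endpoints, and
#' integrates the curve by the trapezoidal rule.
#'
#' @param diffs Per-frame distance scores.
#' @param truth Logical (or 0/1) pain indicator per frame.
#' @return List with \code{roc_points} (data frame \code{far}, \code{hr},
#'   sorted by far) and \code{auc}.
#' @export
roc_curve <- function(diffs, truth) {
  truth <- as.logical(truth)
  if (!any(truth) || all(truth))
    pf_stop("pf_data_error", "ROC needs at least one positive and one negative")
  thr <- c(sort(unique(diffs)), Inf)
  pts <- t(vapply(thr, function(t) {
    pred <- diffs >= t
    c(far = sum(pred & !truth) / sum(!truth),
      hr = sum(pred & truth) / sum(truth))
  }, numeric(2)))
  pts <- rbind(pts, c(1, 1))
  pts <- pts[order(pts[, "far"], pts[, "hr"]), , drop = FALSE]
  auc <- sum(diff(pts[, "far"]) *
               (utils::head(pts[, "hr"], -1) + utils::tail(pts[, "hr"], -1)) / 2)
  list(roc_points = data.frame(far = pts[, "far"], hr = pts[, "hr"]),
       auc = auc)
}

#' HR range over GOP windows
#'
#' Partitions the frame sequence into consecutive windows of \code{gop}
#' frames, computes the hit rate in every window containing at least one
#' true pain frame, and reports the minimum and maximum (the windowed
#' "HR in range" presentation).
#'
#' @param predicted Integer class codes or a \code{classify_stream} result.
#' @param truth Integer class codes aligned with \code{predicted}.
#' @param gop Window length in frames (default 15).
#' @return List with \code{min}, \code{max} and the per-window data frame
#'   \code{windows} (window, hr).
#' @export
hr_range_by_gop <- function(predicted, truth, gop = 15L) {
  if (is.data.frame(predicted)) predicted <- predicted$label
  gop <- as.integer(gop)
  if (gop < 1L) pf_stop("pf_config_error", "gop must be >= 1")
  n <- length(predicted)
  win <- (seq_len(n) - 1L) %/% gop + 1L
  pain <- PF_CLASSES[["pain_face"]]
  hrs <- vapply(split(seq_len(n), win), function(ix) {
    t <- truth[ix]; p <- predicted[ix]
    keep <- !is.na(p)
    t <- t[keep]; p <- p[keep]
    if (sum(t == pain) == 0L) return(NA_real_)
    sum(t == pain & p == pain) / sum(t == pain)
  }, numeric(1))
  ok <- !is.na(hrs)
  if (!any(ok))
    return(list(min = NA_real_, max = NA_real_,
                windows = data.frame(window = integer(0), hr = numeric(0))))
  list(min = min(hrs[ok]), max = max(hrs[ok]),
       windows = data.frame(window = which(ok), hr = hrs[ok]))
}

#' Full evaluation report
#'
#' Bundles HR, FAR, the per-GOP HR range, the ROC curve over the distance
#' scores and its AUC.
#'
#' @param results A \code{classify_stream} result data frame.
#' @param truth Integer class codes aligned with the rows of
#'   \code{results}.
#' @param gop GOP window length (default 15).
#' @return An object of class \code{pf_eval_report}.
#' @export
eval_report <- function(results, truth, gop = 15L) {
  hf <- compute_hr_far(results, truth)
  rng <- hr_range_by_gop(results, truth, gop)
  pain <- PF_CLASSES[["pain_face"]]
  keep <- !is.na(results$label)
  roc <- tryCatch(roc_curve(results$diff[keep], truth[keep] == pain),
                  error = function(e) list(roc_points = NULL, auc = NA_real_))
  structure(list(hr = hf$hr, far = hf$far,
                 hr_range = c(min = rng$min, max = rng$max),
                 roc_points = roc$roc_points, auc = roc$auc,
                 gop = as.integer(gop)),
            class = "pf_eval_report")
}

#' @export
print.pf_eval_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "n/a" else sprintf("%.2f%%", 100 * v)
  cat("Evaluation report (GOP =", x$gop, ")\n")
  cat("  HR (pain):   ", fmt(x$hr), "\n")
  cat("  FAR:         ", fmt(x$far), "\n")
  cat("  HR range:    ", fmt(x$hr_range[["min"]]), "-",
      fmt(x$hr_range[["max"]]), "per GOP window\n")
  cat("  AUC:         ", if (is.na(x$auc)) "n/a" else sprintf("%.4f", x$auc),
      "\n")
  invisible(x)
}
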