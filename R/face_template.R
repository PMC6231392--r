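#' Canonical 66-point face landmark template
#'
#' Returns the package's canonical 66-point face layout, constructed
#' parametrically (ellipse arcs and arches) in "template units" where the
#' face is roughly 124 units wide and 120 units tall, centred near the
#' origin, with image-style coordinates (y grows downward). The layout
#' follows the conventional 66-point indexing (0-based in the documentation,
#' 1-based in R): jaw 0-16, brows 17-26, nose 27-35, eyes 36-47, mouth
#' 48-65 (12 outer + 6 inner lip points).
#'
#' Each point also carries a depth coordinate \code{z} (larger = closer to
#' the camera: nose forward, ears back), giving the fixed canonical 3-D
#' mean-landmark template used for weak-perspective yaw/pitch estimation.
#'
#' @return A list with elements \code{xy} (66 x 2 matrix), \code{z}
#'   (length-66 numeric), \code{groups} (named list of 1-based index
#'   vectors) and \code{triangles} (m x 3 matrix of 1-based vertex indices,
#'   a fixed triangulation of the layout used for piecewise-affine warping).
#' @export
face_template <- function() {
  deg <- function(a) a * pi / 180

  # jaw: lower half-ellipse, left ear to chin to right ear
  t <- seq(0, pi, length.out = 17)
  jaw <- cbind(-62 * cos(t), 76 * sin(t))
  jaw_z <- -22 + 20 * sin(t)

  # brows: arched segments above the eyes
  bt <- seq(0, 1, length.out = 5)
  lbrow <- cbind(seq(-46, -14, length.out = 5), -34 - 8 * sin(pi * bt))
  rbrow <- cbind(seq(14, 46, length.out = 5), -34 - 8 * sin(pi * bt))
  brow_z <- rep(6, 5)

  # nose: bridge (4 points) + base (5 points)
  bridge <- cbind(rep(0, 4), seq(-24, 6, length.out = 4))
  bridge_z <- seq(8, 20, length.out = 4)
  base <- cbind(c(-12, -6, 0, 6, 12), c(14, 16, 17, 16, 14))
  base_z <- c(8, 12, 16, 12, 8)

  # eyes: 6-point ellipses; index 1 of each eye block is the corner nearest
  # the left image border (outer for the left eye, inner for the right)
  eye <- function(cx, cy, a = 13.5, b = 7) {
    ang <- deg(c(180, 120, 60, 0, 300, 240))
    cbind(cx + a * cos(ang), cy - b * sin(ang))
  }
  leye <- eye(-28, -16)
  reye <- eye(28, -16)
  eye_z <- rep(2, 6)

  # mouth: 12 outer + 6 inner lip points
  ang_o <- deg(seq(180, -150, by = -30))
  outer <- cbind(23 * cos(ang_o), 44 - 11 * sin(ang_o))
  outer_z <- c(0, rep(4, 5), 0, rep(4, 5))
  ang_i <- deg(c(180, 120, 60, 0, 300, 240))
  inner <- cbind(15 * cos(ang_i), 44 - 4 * sin(ang_i))
  inner_z <- rep(2, 6)

  xy <- rbind(jaw, lbrow, rbrow, bridge, base, leye, reye, outer, inner)
  z <- c(jaw_z, brow_z, brow_z, bridge_z, base_z, eye_z, eye_z,
         outer_z, inner_z)
  dimnames(xy) <- NULL

  groups <- list(
    jaw = 1:17, brow_left = 18:22, brow_right = 23:27,
    nose_bridge = 28:31, nose_base = 32:36,
    eye_left = 37:42, eye_right = 43:48,
    mouth_outer = 49:60, mouth_inner = 61:66
  )

  list(xy = xy, z = z, groups = groups, triangles = pf_template_triangles)
}

#' Expression deformation fields
#'
#' Hand-authored sparse displacement fields on the canonical 66-point
#' template, one per expression, in template units at unit amplitude.
#' \code{pain} lowers and knits the brows, narrows the eyes and tightens
#' the lip corners; \code{smile} raises the mouth corners; \code{surprise}
#' raises the brows, widens the eyes and drops the jaw; \code{angry} knits
#' the brows and presses the lips. \code{neutral} is the zero field.
#'
#' @param expression One of \code{"neutral"}, \code{"pain"}, \code{"smile"},
#'   \code{"surprise"}, \code{"angry"}.
#' @return A 66 x 2 displacement matrix (dx, dy) at amplitude 1.
#' @export
expression_field <- function(expression = c("neutral", "pain", "smile",
                                            "surprise", "angry")) {
  expression <- match.arg(expression)
  d <- matrix(0, 66, 2)
  g <- face_template()$groups
  lb <- g$brow_left; rb <- g$brow_right
  le <- g$eye_left; re <- g$eye_right
  mo <- g$mouth_outer; mi <- g$mouth_inner

  if (expression == "pain") {
    # brows pulled down hard and inward, more at the inner ends
    d[lb, 2] <- d[lb, 2] + seq(6, 11, length.out = 5)
    d[rb, 2] <- d[rb, 2] + seq(11, 6, length.out = 5)
    d[lb, 1] <- d[lb, 1] + seq(0, 4, length.out = 5)
    d[rb, 1] <- d[rb, 1] - seq(4, 0, length.out = 5)
    # eyes squeezed nearly shut: upper lids down, lower lids up
    up <- c(le[2:3], re[2:3]); lo <- c(le[5:6], re[5:6])
    d[up, 2] <- d[up, 2] + 7
    d[lo, 2] <- d[lo, 2] - 5.5
    # lips pressed and corners tightened inward
    d[mo[1], 1] <- 5; d[mo[7], 1] <- -5
    d[mi, 2] <- d[mi, 2] + (44 - face_template()$xy[mi, 2]) * 0.85
    d[mo[10], 2] <- d[mo[10], 2] - 3  # lower lip pulled up
  } else if (expression == "smile") {
    d[mo[1], ] <- c(-5, -4.5); d[mo[7], ] <- c(5, -4.5)
    d[mo[c(2, 6)], ] <- cbind(c(-3, 3), c(-2.5, -2.5))
    d[mo[c(12, 8)], ] <- cbind(c(-3, 3), c(1.5, 1.5))
    d[mi[1], ] <- c(-2, -1.5); d[mi[4], ] <- c(2, -1.5)
    # slight cheek raise narrows the lower lids a touch
    lo <- c(le[5:6], re[5:6]); d[lo, 2] <- d[lo, 2] - 1
  } else if (expression == "surprise") {
    d[c(lb, rb), 2] <- -7
    up <- c(le[2:3], re[2:3]); lo <- c(le[5:6], re[5:6])
    d[up, 2] <- d[up, 2] - 1; d[lo, 2] <- d[lo, 2] + 1
    # jaw drop and open mouth
    d[mi[5:6], 2] <- 4; d[mi[c(1, 4)], 2] <- 2
    d[mo[8:12], 2] <- 4
    jaw_mid <- g$jaw[7:11]; d[jaw_mid, 2] <- c(4, 8, 10, 8, 4)
  } else if (expression == "angry") {
    d[lb, 2] <- d[lb, 2] + seq(1, 3, length.out = 5)
    d[rb, 2] <- d[rb, 2] + seq(3, 1, length.out = 5)
    d[lb, 1] <- d[lb, 1] + seq(0, 2.4, length.out = 5)
    d[rb, 1] <- d[rb, 1] - seq(2.4, 0, length.out = 5)
    up <- c(le[2:3], re[2:3]); lo <- c(le[5:6], re[5:6])
    d[up, 2] <- d[up, 2] + 2; d[lo, 2] <- d[lo, 2] - 1.5
    d[mo[1], ] <- c(2, 3); d[mo[7], ] <- c(-2, 3)
    d[mi, 2] <- d[mi, 2] + (44 - face_template()$xy[mi, 2]) * 0.3
  }
  d
}
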