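#' Piecewise two-argument arctangent
#'
#' The quadrant-aware arctangent used for all segment orientations,
#' implemented as the explicit six-branch piecewise definition:
#' `arctan(y/x)` for `x > 0`; `arctan(y/x) + pi` for `x < 0, y >= 0`;
#' `arctan(y/x) - pi` for `x < 0, y < 0`; `+pi/2` / `-pi/2` on the positive /
#' negative y-axis; undefined at the origin. Values lie in `(-pi, pi]`.
#'
#' @param y,x numeric scalars (note the argument order, matching the
#'   mathematical convention `atan2(y, x)`).
#' @return Angle in radians in `(-pi, pi]`.
#' @examples
#' atan2_piecewise(1, 0)   # pi/2
#' atan2_piecewise(1, -1)  # 3*pi/4
#' @export
atan2_piecewise <- function(y, x) {
  stopifnot(is.numeric(y), is.numeric(x), length(y) == 1L, length(x) == 1L)
  if (x == 0 && y == 0)
    stop("atan2 undefined at x = 0, y = 0")
  if (x > 0) return(atan(y / x))
  if (x < 0 && y >= 0) return(atan(y / x) + pi)
  if (x < 0 && y < 0) return(atan(y / x) - pi)
  if (y > 0) pi / 2 else -pi / 2
}

#' Deviation of a two-point segment from an image axis
#'
#' The angle between the directed segment `a -> b` and a reference axis of
#' the image, in degrees, folded into `[0, fold_max]`. Image coordinates:
#' origin top-left, x rightward, y downward. With `dx = b.x - a.x` and
#' `dy = b.y - a.y`:
#' * `axis = "horizontal"`: `theta = |deg(atan2(dy, dx))|`
#' * `axis = "vertical"` (downward): `theta = |deg(atan2(dx, dy))|`
#'
#' Folding maps `theta > fold_max` to `180 - theta` when `fold_max = 90`, so
#' a vertical reference measures the same deviation whether the segment
#' points up or down. The result is invariant under translation, uniform
#' scaling, and swapping the two endpoints.
#'
#' @param a,b keypoints: any objects with `$x`, `$y` and `$present` fields
#'   (single rows of a `skeleton_frame` work), or plain `c(x, y)` vectors.
#' @param axis `"horizontal"` or `"vertical"`.
#' @param fold_max 90 for symmetric deviations, 180 for full half-turn
#'   parameters such as arm abduction.
#' @return Angle in degrees in `[0, fold_max]`, or `NA` with a warning-free
#'   invalid signal if either keypoint is absent (see [measure_frame()]).
#'   Coincident points raise an undefined-angle error.
#' @export
segment_deviation <- function(a, b, axis = c("horizontal", "vertical"),
                              fold_max = 90) {
  axis <- match.arg(axis)
  stopifnot(fold_max %in% c(90, 180))
  pa <- as_point(a); pb <- as_point(b)
  dx <- pb[1] - pa[1]
  dy <- pb[2] - pa[2]
  if (dx == 0 && dy == 0)
    stop("undefined angle: coincident keypoints")
  theta <- if (axis == "horizontal") {
    abs(atan2_piecewise(dy, dx)) * 180 / pi
  } else {
    abs(atan2_piecewise(dx, dy)) * 180 / pi
  }
  fold_angle(theta, fold_max)
}

fold_angle <- function(theta, fold_max) {
  if (theta > fold_max) 180 - theta else theta
}

as_point <- function(p) {
  if (is.data.frame(p)) c(p$x[1], p$y[1])
  else if (is.list(p)) c(p$x, p$y)
  else c(p[1], p[2])
}

#' Postural parameter definitions
#'
#' The four parameters measurable from a frontal camera view, each bound to
#' its keypoint pair, reference axis, fold range, and the range-table row
#' that classifies it:
#'
#' * `shoulder_alignment`: left_shoulder -> right_shoulder vs. horizontal,
#'   fold 90 (level shoulders measure 0).
#' * `neck_lateral_bend`: neck -> nose vs. vertical, fold 90 (upright head
#'   measures 0).
#' * `right_arm_abduction`, `left_arm_abduction`: shoulder -> same-side
#'   elbow vs. vertical, fold 180 (hanging arm 0, horizontal upper arm 90,
#'   arm overhead up to 180).
#'
#' @return data.frame with columns `parameter`, `point_a`, `point_b`,
#'   `axis`, `fold_max`, `range_row`.
#' @export
parameter_definitions <- function() {
  data.frame(
    parameter = c("neck_lateral_bend", "shoulder_alignment",
                  "right_arm_abduction", "left_arm_abduction"),
    point_a = c("neck", "left_shoulder", "right_shoulder", "left_shoulder"),
    point_b = c("nose", "right_shoulder", "right_elbow", "left_elbow"),
    axis = c("vertical", "horizontal", "vertical", "vertical"),
    fold_max = c(90, 90, 180, 180),
    range_row = c("neck_lateral_bend", "shoulder_alignment",
                  "arms_abduction", "arms_abduction"),
    stringsAsFactors = FALSE
  )
}

#' Measure the postural parameters of one frame
#'
#' @param frame a `skeleton_frame`.
#' @param defs parameter definitions, by default [parameter_definitions()].
#' @param min_confidence keypoints with confidence below this are treated as
#'   absent; the default 0 disables the gate (keypoints without a confidence
#'   value are never gated).
#' @return data.frame with one row per definition: `parameter`, `angle`
#'   (degrees, `NA` when invalid), `valid`. A measurement is invalid when
#'   either keypoint is absent (or gated out) or the two points coincide.
#' @export
measure_frame <- function(frame, defs = parameter_definitions(),
                          min_confidence = 0) {
  kp_ok <- function(row) {
    if (!row$present) return(FALSE)
    if (min_confidence > 0 && !is.na(row$confidence) &&
        row$confidence < min_confidence) return(FALSE)
    TRUE
  }
  out <- data.frame(parameter = defs$parameter, angle = NA_real_,
                    valid = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(defs))) {
    a <- frame[frame$name == defs$point_a[i], , drop = FALSE]
    b <- frame[frame$name == defs$point_b[i], , drop = FALSE]
    if (!kp_ok(a) || !kp_ok(b)) next
    ang <- tryCatch(
      segment_deviation(a, b, defs$axis[i], defs$fold_max[i]),
      error = function(e) NA_real_
    )
    if (!is.na(ang)) {
      out$angle[i] <- ang
      out$valid[i] <- TRUE
    }
  }
  out
}

#' Measure the postural parameters of every frame in a stream
#'
#' @param stream a `keypoint_stream`.
#' @inheritParams measure_frame
#' @return data.frame with columns `frame`, `t`, `parameter`, `angle`,
#'   `valid`; one row per frame per parameter.
#' @export
measure_stream <- function(stream, defs = parameter_definitions(),
                           min_confidence = 0) {
  nf <- n_frames(stream)
  out <- vector("list", nf)
  for (i in seq_len(nf)) {
    f <- stream_frame(stream, i)
    m <- measure_frame(f, defs, min_confidence)
    m <- cbind(frame = attr(f, "frame_index"), t = attr(f, "timestamp"), m)
    out[[i]] <- m
  }
  if (!nf) {
    return(data.frame(frame = integer(), t = numeric(),
                      parameter = character(), angle = numeric(),
                      valid = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
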