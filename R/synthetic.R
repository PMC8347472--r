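#' Canonical upper-body skeleton template
#'
#' A neutral seated subject filmed frontally in a 640x480 frame: level
#' shoulders, nose directly above the neck, arms hanging straight down.
#' All four measurable postural parameters read exactly 0 degrees on the
#' noise-free template. Segment lengths are pixels; face and leg points sit
#' at plausible fixed offsets and only matter for topology completeness.
#'
#' @return list with named `c(x, y)` keypoint positions plus segment
#'   lengths `shoulder_halfwidth`, `neck_length`, `upper_arm`, `forearm`.
#' @export
skeleton_template <- function() {
  list(
    neck = c(320, 220), nose = c(320, 170),
    shoulder_mid = c(320, 220),
    shoulder_halfwidth = 80, neck_length = 50,
    upper_arm = 70, forearm = 60,
    left_hip = c(350, 370), right_hip = c(290, 370),
    left_knee = c(360, 450), right_knee = c(280, 450),
    left_ankle = c(365, 478), right_ankle = c(275, 478),
    eye_offset = c(15, -10), ear_offset = c(28, 0)
  )
}

#' Pose the template at requested parameter angles
#'
#' Articulates the template so that [measure_frame()] on the returned frame
#' recovers exactly the requested angles (noise-free): the shoulder line is
#' rotated about its midpoint for shoulder alignment, the nose swings about
#' the neck for neck lateral bend, and each elbow rotates about its
#' shoulder (measured from vertical-down) for arm abduction; wrists extend
#' the upper-arm direction.
#'
#' @param angles named numeric vector/list with any of
#'   `neck_lateral_bend`, `shoulder_alignment` (degrees in `[0, 90]`) and
#'   `left_arm_abduction`, `right_arm_abduction` (degrees in `[0, 180]`);
#'   omitted parameters default to 0.
#' @param frame_index,timestamp frame metadata.
#' @param template a [skeleton_template()].
#' @return A `skeleton_frame` with all 18 keypoints present.
#' @export
pose_template <- function(angles = c(), frame_index = 0L, timestamp = 0,
                          template = skeleton_template()) {
  get_ang <- function(nm, fold) {
    v <- if (nm %in% names(angles)) as.numeric(angles[[nm]]) else 0
    if (is.na(v) || v < 0 || v > fold)
      stop(nm, " must lie in [0, ", fold, "], got ", v)
    v * pi / 180
  }
  al <- get_ang("shoulder_alignment", 90)
  nb <- get_ang("neck_lateral_bend", 90)
  ra <- get_ang("right_arm_abduction", 180)
  la <- get_ang("left_arm_abduction", 180)
  tp <- template
  mid <- tp$shoulder_mid; w <- tp$shoulder_halfwidth
  # shoulder line rotated by `al`: left shoulder dips below the horizontal
  ls <- mid + w * c(cos(al), sin(al))
  rs <- mid - w * c(cos(al), sin(al))
  # elbows measured from vertical-down; left arm abducts toward image-right
  le <- ls + tp$upper_arm * c(sin(la), cos(la))
  re <- rs + tp$upper_arm * c(-sin(ra), cos(ra))
  lw <- le + tp$forearm * c(sin(la), cos(la))
  rw <- re + tp$forearm * c(-sin(ra), cos(ra))
  # nose swings about the neck; upright head is straight up (y decreasing)
  nose <- tp$neck + tp$neck_length * c(sin(nb), -cos(nb))
  eo <- tp$eye_offset; ao <- tp$ear_offset
  skeleton_frame(list(
    nose = nose,
    left_eye = nose + c(eo[1], eo[2]), right_eye = nose + c(-eo[1], eo[2]),
    left_ear = nose + c(ao[1], ao[2]), right_ear = nose + c(-ao[1], ao[2]),
    left_shoulder = ls, right_shoulder = rs,
    left_elbow = le, right_elbow = re,
    left_wrist = lw, right_wrist = rw,
    left_hip = tp$left_hip, right_hip = tp$right_hip,
    left_knee = tp$left_knee, right_knee = tp$right_knee,
    left_ankle = tp$left_ankle, right_ankle = tp$right_ankle,
    neck = tp$neck
  ), frame_index = frame_index, timestamp = timestamp)
}

#' Generation configuration for synthetic labelled streams
#'
#' Defaults emulate the scale of a small multi-subject desk-posture study:
#' 12 subjects of 13 frames each (156 frames), ground-truth zones balanced
#' over 0-3 for every parameter, with per-keypoint isotropic Gaussian
#' jitter standing in for pose-estimator noise.
#'
#' Per-parameter `targets` entries may be
#' * `list(mode = "zone_balanced")` (default): each frame's zone cycles
#'   through 0-3 (balanced), with the angle drawn uniformly inside the
#'   zone's interval (zone 3 capped at its lower bound + 30 degrees);
#' * `list(mode = "fixed_zone", zone =)`: as above, one zone throughout;
#' * `list(mode = "fixed_angle", angle =)`: a constant angle;
#' * `list(mode = "drift", from =, to =)`: linear angle ramp over each
#'   subject's frames.
#'
#' @param n_subjects,frames_per_subject stream size (defaults 12 and 13).
#' @param targets named list of per-parameter target specifications.
#' @param jitter_sd Gaussian keypoint jitter sigma, pixels (default 2).
#' @param dropout_prob probability each keypoint is missing (default 0).
#' @param fps nominal frame rate (default 25).
#' @param seed integer RNG seed.
#' @param table `range_table` used both to sample zone-conditional angles
#'   and to derive ground-truth zones.
#' @return An object of class `generation_config`.
#' @export
generation_config <- function(n_subjects = 12L, frames_per_subject = 13L,
                              targets = list(), jitter_sd = 2,
                              dropout_prob = 0, fps = 25, seed = 1L,
                              table = default_range_table()) {
  stopifnot(n_subjects >= 1L, frames_per_subject >= 1L,
            jitter_sd >= 0, dropout_prob >= 0, dropout_prob < 1)
  defs <- parameter_definitions()
  full <- stats::setNames(
    rep(list(list(mode = "zone_balanced")), nrow(defs)), defs$parameter)
  for (nm in names(targets)) {
    if (!nm %in% defs$parameter) stop("unknown parameter in targets: ", nm)
    full[[nm]] <- targets[[nm]]
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 frames_per_subject = as.integer(frames_per_subject),
                 targets = full, jitter_sd = jitter_sd,
                 dropout_prob = dropout_prob, fps = fps,
                 seed = as.integer(seed), table = table),
            class = "generation_config")
}

zone_interval <- function(table, row, zone) {
  i <- match(row, table$parameter)
  u <- c(table$u0[i], table$u1[i], table$u2[i])
  switch(as.character(zone),
         "0" = c(0, u[1]),
         "1" = c(u[1], u[2]),
         "2" = c(u[2], u[3]),
         "3" = c(u[3], u[3] + 30),
         stop("zone must be 0-3"))
}

sample_zone_angle <- function(table, row, zone, fold_max) {
  iv <- zone_interval(table, row, zone)
  iv[2] <- min(iv[2], fold_max)
  stats::runif(1, iv[1], iv[2])
}

#' Generate a synthetic labelled keypoint stream
#'
#' Draws per-frame target angles according to the configuration, poses the
#' template, adds independent Gaussian jitter to every coordinate, drops
#' keypoints at random, and records the noise-free ground truth (angle and
#' zone per parameter). Fully reproducible given the config seed.
#'
#' @param config a [generation_config()].
#' @return list with
#'   * `stream`: a `keypoint_stream` of
#'     `n_subjects * frames_per_subject` frames;
#'   * `labels`: data.frame `frame`, `subject`, then `<parameter>_angle`
#'     (true degrees) and `<parameter>_truth` (true zone) per parameter.
#' @export
generate_stream <- function(config = generation_config()) {
  stopifnot(inherits(config, "generation_config"))
  set.seed(config$seed)
  defs <- parameter_definitions()
  nf <- config$n_subjects * config$frames_per_subject
  frames <- vector("list", nf)
  labels <- vector("list", nf)
  topo <- default_topology()
  k <- 0L
  for (subj in seq_len(config$n_subjects)) {
    for (j in seq_len(config$frames_per_subject)) {
      k <- k + 1L
      ang <- numeric(0)
      for (i in seq_len(nrow(defs))) {
        p <- defs$parameter[i]
        tg <- config$targets[[p]]
        row <- defs$range_row[i]
        ang[p] <- switch(tg$mode,
          zone_balanced = sample_zone_angle(config$table, row,
                                            (k - 1L + i) %% 4L, defs$fold_max[i]),
          fixed_zone = sample_zone_angle(config$table, row, tg$zone,
                                         defs$fold_max[i]),
          fixed_angle = tg$angle,
          drift = tg$from + (tg$to - tg$from) *
            (j - 1L) / max(1L, config$frames_per_subject - 1L),
          stop("unknown target mode: ", tg$mode))
      }
      f <- pose_template(ang, frame_index = k - 1L,
                         timestamp = (k - 1L) / config$fps)
      if (config$jitter_sd > 0) {
        f$x <- f$x + stats::rnorm(nrow(f), 0, config$jitter_sd)
        f$y <- f$y + stats::rnorm(nrow(f), 0, config$jitter_sd)
      }
      if (config$dropout_prob > 0) {
        drop <- stats::runif(nrow(f)) < config$dropout_prob
        f$present[drop] <- FALSE
        f$x[drop] <- NA_real_; f$y[drop] <- NA_real_
      }
      frames[[k]] <- f
      lab <- data.frame(frame = k - 1L, subject = subj)
      for (i in seq_len(nrow(defs))) {
        p <- defs$parameter[i]
        lab[[paste0(p, "_angle")]] <- ang[[p]]
        lab[[paste0(p, "_truth")]] <-
          classify_angle(config$table, defs$range_row[i], ang[[p]])
      }
      labels[[k]] <- lab
    }
  }
  list(stream = frames_to_stream(frames, topo, source = "synthetic",
                                 fps = config$fps),
       labels = do.call(rbind, c(labels, list(make.row.names = FALSE))))
}

#' Run the measurement pipeline and pair predictions with ground truth
#'
#' Measures and classifies every frame of a (typically synthetic) stream
#' and joins the predicted zones to the ground-truth labels, producing the
#' labelled-sample layout consumed by [evaluate_samples()].
#'
#' @param stream a `keypoint_stream`.
#' @param labels ground-truth labels with `frame` and `<parameter>_truth`
#'   columns (as from [generate_stream()]).
#' @param table `range_table` used for prediction.
#' @return labelled-samples data.frame (`frame`, `<parameter>_truth`,
#'   `<parameter>_pred`; `NA` predictions where the measurement was
#'   invalid).
#' @export
label_predictions <- function(stream, labels,
                              table = default_range_table()) {
  cls <- classify_stream(measure_stream(stream), table)
  params <- intersect(unique(cls$parameter), sample_parameters(labels))
  out <- data.frame(frame = sort(unique(labels$frame)))
  for (p in params) {
    out[[paste0(p, "_truth")]] <-
      labels[[paste0(p, "_truth")]][match(out$frame, labels$frame)]
    sub <- cls[cls$parameter == p, , drop = FALSE]
    out[[paste0(p, "_pred")]] <- sub$zone[match(out$frame, sub$frame)]
  }
  out
}
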