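#' Alert policy for sustained-posture monitoring
#'
#' Per-frame zone assignments are too jittery to notify on directly: a
#' single mis-estimated frame must never page the worker. The policy
#' smooths zones over a trailing window, requires a violation to persist
#' for a dwell time before alerting, and rate-limits repeats.
#'
#' @param window seconds of trailing majority-vote smoothing (default 2).
#' @param trigger_zone minimum zone counting as a violation (default 2, the
#'   lower edge of the dangerous band).
#' @param dwell seconds a violation must persist before an alert opens
#'   (default 10).
#' @param cooldown seconds after an alert closes during which a renewed
#'   violation extends that alert instead of opening a new one (default 60).
#' @return An object of class `alert_policy`.
#' @export
alert_policy <- function(window = 2, trigger_zone = 2L, dwell = 10,
                         cooldown = 60) {
  stopifnot(window > 0, dwell > 0, cooldown > 0,
            trigger_zone %in% 1:3)
  structure(list(window = window, trigger_zone = as.integer(trigger_zone),
                 dwell = dwell, cooldown = cooldown),
            class = "alert_policy")
}

recommendation_messages <- c(
  neck_lateral_bend   = "Straighten your head: avoid tilting the neck sideways.",
  shoulder_alignment  = "Level your shoulders: one shoulder is markedly higher.",
  right_arm_abduction = "Lower your right arm: keep the elbow close to the body.",
  left_arm_abduction  = "Lower your left arm: keep the elbow close to the body."
)

#' Trailing-window majority smoothing of zone series
#'
#' For each parameter, the smoothed zone at time `t` is the majority zone
#' among valid assignments in the trailing window `(t - window, t]`; ties go
#' to the higher (more dangerous) zone, erring on the side of caution.
#' Windows containing no valid frame yield an invalid smoothed zone.
#'
#' @param assignments output of [classify_stream()] (time-ordered).
#' @param window smoothing window in seconds.
#' @return `assignments` with an added integer column `smoothed_zone`
#'   (`NA` when no valid frame falls in the window).
#' @export
smooth_zones <- function(assignments, window = 2) {
  stopifnot(window > 0)
  out <- assignments
  out$smoothed_zone <- rep(NA_integer_, nrow(out))
  for (p in unique(out$parameter)) {
    sel <- which(out$parameter == p)
    tt <- out$t[sel]
    zz <- out$zone[sel]
    ok <- out$valid[sel] & !is.na(zz)
    for (k in seq_along(sel)) {
      in_win <- ok & tt > tt[k] - window & tt <= tt[k]
      if (!any(in_win)) next
      votes <- table(zz[in_win])
      best <- votes[votes == max(votes)]
      out$smoothed_zone[sel[k]] <- max(as.integer(names(best)))
    }
  }
  out
}

#' Monitor a classified stream for sustained bad posture
#'
#' Runs the alert policy over smoothed zone series and aggregates a session
#' report. An alert opens once a parameter's smoothed zone has been
#' `>= trigger_zone` continuously for `dwell` seconds (the alert `start` is
#' the moment the dwell is satisfied) and closes when the smoothed zone
#' drops below `trigger_zone` (or at stream end). A violation episode that
#' re-qualifies within `cooldown` seconds of the previous close extends the
#' previous alert rather than opening a new one.
#'
#' Frame durations are the timestamp differences to the next frame, with
#' the final frame lasting one nominal frame period (`1/fps`).
#'
#' @param assignments output of [classify_stream()].
#' @param policy an [alert_policy()].
#' @param fps nominal frame rate, used for the final frame's duration.
#' @return list with components
#'   * `alerts`: data.frame `parameter`, `start`, `end`, `peak_zone`,
#'     `message` (one row per alert);
#'   * `report`: data.frame `parameter`, `time_in_zone0..3` (seconds over
#'     the smoothed series), `invalid_time`, `frames_valid_fraction` (raw
#'     per-frame validity). Per parameter the four zone times sum to the
#'     total valid observed time.
#' @export
monitor <- function(assignments, policy = alert_policy(), fps = 25) {
  smoothed <- smooth_zones(assignments, policy$window)
  params <- unique(smoothed$parameter)
  alerts <- list()
  report <- list()
  for (p in params) {
    s <- smoothed[smoothed$parameter == p, , drop = FALSE]
    s <- s[order(s$t), , drop = FALSE]
    dur <- c(diff(s$t), 1 / fps)
    z <- s$smoothed_zone
    tz <- vapply(0:3, function(k) sum(dur[!is.na(z) & z == k]), numeric(1))
    report[[p]] <- data.frame(
      parameter = p,
      time_in_zone0 = tz[1], time_in_zone1 = tz[2],
      time_in_zone2 = tz[3], time_in_zone3 = tz[4],
      invalid_time = sum(dur[is.na(z)]),
      frames_valid_fraction = mean(s$valid),
      stringsAsFactors = FALSE
    )
    # alert state machine over the smoothed series
    violating <- !is.na(z) & z >= policy$trigger_zone
    viol_start <- NA_real_
    open_i <- NA_integer_   # index into alerts[] of the currently open alert
    last_close <- -Inf
    peak <- NA_integer_
    msg <- if (p %in% names(recommendation_messages))
      recommendation_messages[[p]] else paste0("Adjust posture: ", p)
    for (k in seq_along(z)) {
      if (violating[k]) {
        if (is.na(viol_start)) { viol_start <- s$t[k]; peak <- z[k] }
        else peak <- max(peak, z[k])
        if (is.na(open_i) && s$t[k] - viol_start >= policy$dwell) {
          if (length(alerts) && alerts[[length(alerts)]]$parameter == p &&
              viol_start + policy$dwell - last_close <= policy$cooldown) {
            open_i <- length(alerts)  # reopen: extend the previous alert
            alerts[[open_i]]$peak_zone <- max(alerts[[open_i]]$peak_zone, peak)
          } else {
            alerts[[length(alerts) + 1L]] <- data.frame(
              parameter = p, start = viol_start + policy$dwell,
              end = NA_real_, peak_zone = peak, message = msg,
              stringsAsFactors = FALSE)
            open_i <- length(alerts)
          }
        }
        if (!is.na(open_i))
          alerts[[open_i]]$peak_zone <- max(alerts[[open_i]]$peak_zone, z[k])
      } else {
        if (!is.na(open_i)) {
          alerts[[open_i]]$end <- s$t[k]
          last_close <- s$t[k]
          open_i <- NA_integer_
        }
        viol_start <- NA_real_
      }
    }
    if (!is.na(open_i)) {
      alerts[[open_i]]$end <- s$t[length(z)] + 1 / fps
    }
  }
  alerts_df <- if (length(alerts)) do.call(rbind, alerts) else
    data.frame(parameter = character(), start = numeric(), end = numeric(),
               peak_zone = integer(), message = character(),
               stringsAsFactors = FALSE)
  alerts_df <- alerts_df[order(alerts_df$start), , drop = FALSE]
  rownames(alerts_df) <- NULL
  list(alerts = alerts_df, report = do.call(rbind, c(report,
       list(make.row.names = FALSE))))
}
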