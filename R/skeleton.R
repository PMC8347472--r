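#' The 18-point upper-body skeleton topology
#'
#' Returns the keypoint topology used throughout the package: the 17 COCO
#' body landmarks plus a neck point, i.e. the output dialect of the common
#' real-time pose estimators that drive desk-posture monitoring. Coordinates
#' are image pixels, origin at the top-left corner, x rightward, y downward.
#' Left/right are the subject's anatomical sides as labelled by the upstream
#' estimator; mirror-image cameras are the adapter's responsibility.
#'
#' @return An object of class `keypoint_topology`: a list with `names`
#'   (ordered character vector of 18 unique labels) and `bones` (two-column
#'   character matrix of connected label pairs, used only for validation and
#'   overlay rendering).
#' @examples
#' topo <- default_topology()
#' length(topo$names)  # 18
#' @export
default_topology <- function() {
  names <- c(
    "nose", "left_eye", "right_eye", "left_ear", "right_ear",
    "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
    "left_wrist", "right_wrist", "left_hip", "right_hip",
    "left_knee", "right_knee", "left_ankle", "right_ankle", "neck"
  )
  bones <- matrix(c(
    "nose", "left_eye",
    "nose", "right_eye",
    "left_eye", "left_ear",
    "right_eye", "right_ear",
    "nose", "neck",
    "neck", "left_shoulder",
    "neck", "right_shoulder",
    "left_shoulder", "left_elbow",
    "right_shoulder", "right_elbow",
    "left_elbow", "left_wrist",
    "right_elbow", "right_wrist",
    "neck", "left_hip",
    "neck", "right_hip",
    "left_hip", "left_knee",
    "right_hip", "right_knee",
    "left_knee", "left_ankle",
    "right_knee", "right_ankle"
  ), ncol = 2, byrow = TRUE, dimnames = list(NULL, c("from", "to")))
  topo <- structure(list(names = names, bones = bones),
                    class = "keypoint_topology")
  validate_topology(topo)
  topo
}

validate_topology <- function(topo) {
  stopifnot(inherits(topo, "keypoint_topology"))
  if (length(topo$names) != 18L)
    stop("topology must have exactly 18 keypoint names, got ",
         length(topo$names))
  if (anyDuplicated(topo$names))
    stop("topology keypoint names must be unique")
  bad <- setdiff(as.vector(topo$bones), topo$names)
  if (length(bad))
    stop("bone endpoints not in topology: ", paste(bad, collapse = ", "))
  invisible(topo)
}

#' Construct a keypoint stream
#'
#' A `keypoint_stream` holds an ordered sequence of skeleton frames in long
#' form: one row per frame per keypoint, always all 18 topology slots per
#' frame (absent keypoints are kept with `present = FALSE`, never dropped,
#' so downstream validity propagation is deterministic).
#'
#' @param data data.frame with columns `frame` (non-negative integer,
#'   strictly increasing across frames), `t` (seconds from stream start),
#'   `name` (topology label), `x`, `y` (pixels; may be `NA` when absent),
#'   `confidence` (in `[0,1]` or `NA`), `present` (logical).
#' @param topology a `keypoint_topology`, by default [default_topology()].
#' @param source free-text source identifier recorded in the metadata.
#' @param fps nominal frame rate in frames/second (used for the duration of
#'   the final frame when integrating time-in-zone).
#' @return An object of class `keypoint_stream`.
#' @export
keypoint_stream <- function(data, topology = default_topology(),
                            source = "unknown", fps = 25) {
  stream <- structure(
    list(topology = topology, data = data,
         meta = list(source = source, fps = fps)),
    class = "keypoint_stream"
  )
  validate_stream(stream)
  stream
}

validate_stream <- function(stream) {
  stopifnot(inherits(stream, "keypoint_stream"))
  validate_topology(stream$topology)
  d <- stream$data
  need <- c("frame", "t", "name", "x", "y", "confidence", "present")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("stream data missing columns: ", paste(miss, collapse = ", "))
  if (nrow(d) == 0L) return(invisible(stream))
  bad <- setdiff(unique(d$name), stream$topology$names)
  if (length(bad))
    stop("unknown keypoint label(s): ", paste(bad, collapse = ", "))
  idx <- unique(d$frame)
  if (any(idx < 0)) stop("frame indices must be non-negative")
  if (is.unsorted(idx, strictly = TRUE))
    stop("frame indices must be strictly increasing")
  if (any(d$t < 0)) stop("timestamps must be non-negative")
  per <- table(d$frame)
  if (any(per != 18L))
    stop("every frame must carry exactly 18 keypoint slots")
  if (any(d$present & (!is.finite(d$x) | !is.finite(d$y))))
    stop("present keypoints must have finite coordinates")
  cc <- d$confidence[!is.na(d$confidence)]
  if (length(cc) && (any(cc < 0) || any(cc > 1)))
    stop("confidence values must lie in [0, 1]")
  invisible(stream)
}

#' @export
print.keypoint_stream <- function(x, ...) {
  nfr <- length(unique(x$data$frame))
  cat(sprintf("<keypoint_stream> %d frame(s), 18 keypoints/frame, %s @ %g fps\n",
              nfr, x$meta$source, x$meta$fps))
  invisible(x)
}

#' Number of frames in a stream
#' @param stream a `keypoint_stream`.
#' @return integer frame count.
#' @export
n_frames <- function(stream) {
  length(unique(stream$data$frame))
}

#' Extract one skeleton frame
#'
#' @param stream a `keypoint_stream`.
#' @param i position in the stream (1-based), not the frame index.
#' @return A `skeleton_frame`: an 18-row data.frame (one row per topology
#'   label, topology order) with columns `name`, `x`, `y`, `confidence`,
#'   `present`, and attributes `frame_index` and `timestamp`.
#' @export
stream_frame <- function(stream, i) {
  idx <- unique(stream$data$frame)
  if (i < 1L || i > length(idx)) stop("frame position out of range: ", i)
  d <- stream$data[stream$data$frame == idx[i], , drop = FALSE]
  d <- d[match(stream$topology$names, d$name), , drop = FALSE]
  out <- d[, c("name", "x", "y", "confidence", "present")]
  rownames(out) <- NULL
  structure(out, frame_index = idx[i], timestamp = d$t[1],
            class = c("skeleton_frame", "data.frame"))
}

#' Build a skeleton frame from named coordinates
#'
#' Convenience constructor: keypoints not listed in `coords` are marked
#' absent.
#'
#' @param coords named list; each element a numeric `c(x, y)` or
#'   `c(x, y, confidence)`.
#' @param frame_index non-negative integer frame index.
#' @param timestamp seconds from stream start.
#' @param topology a `keypoint_topology`.
#' @return A `skeleton_frame`.
#' @export
skeleton_frame <- function(coords, frame_index = 0L, timestamp = 0,
                           topology = default_topology()) {
  bad <- setdiff(names(coords), topology$names)
  if (length(bad))
    stop("unknown keypoint label(s): ", paste(bad, collapse = ", "))
  n <- length(topology$names)
  out <- data.frame(
    name = topology$names,
    x = NA_real_, y = NA_real_, confidence = NA_real_,
    present = FALSE, stringsAsFactors = FALSE
  )
  for (nm in names(coords)) {
    v <- coords[[nm]]
    j <- match(nm, topology$names)
    out$x[j] <- v[1]; out$y[j] <- v[2]
    out$confidence[j] <- if (length(v) >= 3) v[3] else NA_real_
    out$present[j] <- TRUE
  }
  structure(out, frame_index = as.integer(frame_index), timestamp = timestamp,
            class = c("skeleton_frame", "data.frame"))
}

#' Assemble frames into a stream
#'
#' @param frames list of `skeleton_frame` objects, in time order.
#' @inheritParams keypoint_stream
#' @return A `keypoint_stream`.
#' @export
frames_to_stream <- function(frames, topology = default_topology(),
                             source = "memory", fps = 25) {
  if (!length(frames)) {
    d <- data.frame(frame = integer(), t = numeric(), name = character(),
                    x = numeric(), y = numeric(), confidence = numeric(),
                    present = logical(), stringsAsFactors = FALSE)
    return(keypoint_stream(d, topology, source, fps))
  }
  rows <- lapply(frames, function(f) {
    data.frame(frame = attr(f, "frame_index"), t = attr(f, "timestamp"),
               name = f$name, x = f$x, y = f$y, confidence = f$confidence,
               present = f$present, stringsAsFactors = FALSE)
  })
  keypoint_stream(do.call(rbind, rows), topology, source, fps)
}

## ---- on-disk formats -------------------------------------------------------

## JSON-Lines: one object per frame,
##   {"frame": i, "t": s, "kp": {"<label>": [x, y, c] | null, ...}}
## CSV: columns frame, t, then <label>_x, <label>_y, <label>_c triplets in
## topology order; empty cells mean absent. Both are also the adapter
## contract for external pose estimators feeding the tool.

#' Read a keypoint stream from disk
#'
#' @param path file path.
#' @param format `"jsonl"` or `"csv"`; by default inferred from the file
#'   extension.
#' @param topology expected `keypoint_topology`.
#' @param fps nominal frame rate recorded in the stream metadata; the
#'   default `NULL` infers it from the median timestamp spacing (falling
#'   back to 25 for streams shorter than two frames).
#' @return A validated `keypoint_stream`. Absent keypoints come back with
#'   `present = FALSE`; unknown labels raise a schema error; malformed
#'   records raise a parse error naming the line.
#' @export
read_stream <- function(path, format = c("auto", "jsonl", "csv"),
                        topology = default_topology(), fps = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  if (!file.exists(path)) stop("no such file: ", path)
  s <- if (format == "jsonl") read_stream_jsonl(path, topology, 25)
       else read_stream_csv(path, topology, 25)
  if (is.null(fps)) {
    ts <- unique(s$data$t)
    fps <- if (length(ts) >= 2 && stats::median(diff(ts)) > 0)
      1 / stats::median(diff(ts)) else 25
  }
  s$meta$fps <- fps
  s
}

read_stream_jsonl <- function(path, topology, fps) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  frames <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e)
                      stop("parse error at line ", i, ": ", conditionMessage(e),
                           call. = FALSE))
    if (is.null(rec$frame) || is.null(rec$t) || is.null(rec$kp))
      stop("parse error at line ", i, ": record needs frame, t and kp fields",
           call. = FALSE)
    bad <- setdiff(names(rec$kp), topology$names)
    if (length(bad))
      stop("schema error at line ", i, ": unknown keypoint label(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    coords <- list()
    for (nm in names(rec$kp)) {
      v <- rec$kp[[nm]]
      if (is.null(v)) next
      v <- unlist(lapply(v, function(z) if (is.null(z)) NA_real_ else as.numeric(z)))
      if (length(v) < 2)
        stop("parse error at line ", i, ": keypoint ", nm,
             " needs [x, y] at least", call. = FALSE)
      coords[[nm]] <- v
    }
    frames[[i]] <- skeleton_frame(coords, frame_index = rec$frame,
                                  timestamp = rec$t, topology = topology)
  }
  frames_to_stream(frames, topology, source = path, fps = fps)
}

read_stream_csv <- function(path, topology, fps) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  want <- c("frame", "t",
            as.vector(t(outer(topology$names, c("_x", "_y", "_c"), paste0))))
  miss <- setdiff(want, names(d))
  if (length(miss))
    stop("schema error: csv missing column(s) ", paste(miss, collapse = ", "))
  extra <- setdiff(names(d), want)
  if (length(extra))
    stop("schema error: unknown column(s) ", paste(extra, collapse = ", "))
  frames <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    coords <- list()
    for (nm in topology$names) {
      x <- d[[paste0(nm, "_x")]][i]
      y <- d[[paste0(nm, "_y")]][i]
      cc <- d[[paste0(nm, "_c")]][i]
      if (is.na(x) || is.na(y)) next
      coords[[nm]] <- c(x, y, if (!is.na(cc)) cc)
    }
    frames[[i]] <- skeleton_frame(coords, frame_index = d$frame[i],
                                  timestamp = d$t[i], topology = topology)
  }
  frames_to_stream(frames, topology, source = path, fps = fps)
}

#' Write a keypoint stream to disk
#'
#' Coordinates are serialized at full double precision, so
#' `read_stream(write_stream(s))` reproduces `s` exactly in either format.
#'
#' @param stream a `keypoint_stream`.
#' @param path destination file.
#' @param format `"jsonl"` or `"csv"` (default inferred from the extension).
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path, format = c("auto", "jsonl", "csv")) {
  validate_stream(stream)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  if (format == "jsonl") write_stream_jsonl(stream, path)
  else write_stream_csv(stream, path)
  invisible(path)
}

num17 <- function(v) {
  ifelse(is.na(v), "", sprintf("%.17g", v))
}

write_stream_jsonl <- function(stream, path) {
  topo <- stream$topology
  idx <- unique(stream$data$frame)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(idx)) {
    f <- stream_frame(stream, i)
    kps <- character(nrow(f))
    for (j in seq_len(nrow(f))) {
      if (!f$present[j]) {
        kps[j] <- sprintf("\"%s\":null", f$name[j])
      } else {
        c_str <- if (is.na(f$confidence[j])) "null" else sprintf("%.17g", f$confidence[j])
        kps[j] <- sprintf("\"%s\":[%.17g,%.17g,%s]",
                          f$name[j], f$x[j], f$y[j], c_str)
      }
    }
    writeLines(sprintf("{\"frame\":%d,\"t\":%.17g,\"kp\":{%s}}",
                       attr(f, "frame_index"), attr(f, "timestamp"),
                       paste(kps, collapse = ",")), con)
  }
}

write_stream_csv <- function(stream, path) {
  topo <- stream$topology
  idx <- unique(stream$data$frame)
  header <- c("frame", "t",
              as.vector(t(outer(topo$names, c("_x", "_y", "_c"), paste0))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  for (i in seq_along(idx)) {
    f <- stream_frame(stream, i)
    cells <- character(0)
    for (j in seq_len(nrow(f))) {
      if (!f$present[j]) cells <- c(cells, "", "", "")
      else cells <- c(cells, num17(f$x[j]), num17(f$y[j]), num17(f$confidence[j]))
    }
    writeLines(paste(c(sprintf("%d", attr(f, "frame_index")),
                       num17(attr(f, "timestamp")), cells), collapse = ","), con)
  }
}
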