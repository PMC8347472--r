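#' Default ergonomic range-of-motion table
#'
#' Zone boundaries (inclusive upper bounds `u0 < u1 < u2`, in degrees) for
#' nine postural parameters, taken from the ergonomic range-of-motion
#' literature that grades joint strain into four zones: zone 0 (very low
#' strain) up to zone 3 (high strain, unbounded above). Only four parameters
#' are measurable from a frontal camera; the remaining rows are exposed for
#' users supplying angles from other instruments.
#'
#' Printed band tables list integer ranges ("0-5, 6-12, 13-24, 25+"); for
#' real-valued angles the bands are treated as left-open/right-closed on the
#' three printed upper bounds, so zone 0 is `[0, u0]`, zone 1 `(u0, u1]`,
#' zone 2 `(u1, u2]`, zone 3 `(u2, Inf)`. This matches every printed integer
#' band while covering the continuum without gaps.
#'
#' @return An object of class `range_table`: data.frame with columns
#'   `parameter`, `u0`, `u1`, `u2`.
#' @export
default_range_table <- function() {
  tab <- data.frame(
    parameter = c("back_lateral_bend", "back_flexion", "back_extension",
                  "shoulder_alignment", "arms_adduction", "arms_abduction",
                  "neck_lateral_bend", "neck_flexion", "neck_extension"),
    u0 = c(5, 10, 5, 5, 5, 13, 5, 9, 6),
    u1 = c(10, 25, 10, 10, 12, 34, 12, 22, 15),
    u2 = c(20, 45, 20, 20, 24, 67, 24, 45, 30),
    stringsAsFactors = FALSE
  )
  range_table(tab)
}

#' Construct / validate a range table
#'
#' @param tab data.frame with columns `parameter`, `u0`, `u1`, `u2`;
#'   each row requires `0 < u0 < u1 < u2`.
#' @return The validated table with class `range_table`.
#' @export
range_table <- function(tab) {
  stopifnot(all(c("parameter", "u0", "u1", "u2") %in% names(tab)))
  if (anyDuplicated(tab$parameter)) stop("duplicate parameter rows")
  ok <- tab$u0 > 0 & tab$u1 > tab$u0 & tab$u2 > tab$u1
  if (!all(ok))
    stop("range bounds must satisfy 0 < u0 < u1 < u2; offending row(s): ",
         paste(tab$parameter[!ok], collapse = ", "))
  structure(tab, class = c("range_table", "data.frame"))
}

#' Read a range-table override from a YAML configuration file
#'
#' Format: one key per parameter mapping to the three upper bounds, e.g.
#' `neck_lateral_bend: [5, 12, 24]`. Parameters not listed keep their
#' defaults.
#'
#' @param path YAML file path.
#' @param base table to override, by default [default_range_table()].
#' @return A `range_table`.
#' @export
read_range_table <- function(path, base = default_range_table()) {
  cfg <- yaml::read_yaml(path)
  for (nm in names(cfg)) {
    v <- as.numeric(cfg[[nm]])
    if (length(v) != 3L)
      stop("range override for ", nm, " must have exactly 3 bounds")
    if (nm %in% base$parameter) {
      base[base$parameter == nm, c("u0", "u1", "u2")] <- as.list(v)
    } else {
      base <- rbind(base, data.frame(parameter = nm, u0 = v[1], u1 = v[2],
                                     u2 = v[3], stringsAsFactors = FALSE))
    }
  }
  range_table(as.data.frame(base))
}

#' Classify an angle into its range-of-motion zone
#'
#' @param table a `range_table`.
#' @param parameter row name in the table (e.g. `"neck_lateral_bend"`).
#' @param angle angle in degrees, `>= 0`; vectorized.
#' @return Integer zone(s) 0-3: 0 if `angle <= u0`, 1 if `u0 < angle <= u1`,
#'   2 if `u1 < angle <= u2`, else 3.
#' @examples
#' classify_angle(default_range_table(), "neck_lateral_bend", 25)  # 3
#' @export
classify_angle <- function(table, parameter, angle) {
  i <- match(parameter, table$parameter)
  if (is.na(i)) stop("unknown parameter: ", parameter)
  if (any(angle < 0, na.rm = TRUE)) stop("angle must be non-negative")
  ifelse(angle <= table$u0[i], 0L,
         ifelse(angle <= table$u1[i], 1L,
                ifelse(angle <= table$u2[i], 2L, 3L)))
}

#' Collapse a zone to the safe/dangerous dichotomy
#'
#' Zones 0-1 are safe; zones 2-3 are dangerous (the clinically consequential
#' side: a dangerous posture called safe is a critical error).
#'
#' @param zone integer vector of zones 0-3 (`NA` passed through).
#' @return Character vector `"safe"` / `"dangerous"`.
#' @export
collapse_to_binary <- function(zone) {
  bad <- !is.na(zone) & !(zone %in% 0:3)
  if (any(bad)) stop("zone out of range 0-3: ", paste(zone[bad], collapse = ", "))
  ifelse(is.na(zone), NA_character_,
         ifelse(zone >= 2, "dangerous", "safe"))
}

#' Classify the measurements of one frame
#'
#' @param measurements output of [measure_frame()] (columns `parameter`,
#'   `angle`, `valid`).
#' @param table a `range_table`.
#' @param defs parameter definitions binding each measured parameter to its
#'   range-table row.
#' @return data.frame with columns `parameter`, `angle`, `zone`, `binary`,
#'   `valid`; invalid measurements keep `valid = FALSE` with `NA` zone and
#'   class, and leave the other parameters unaffected.
#' @export
classify_frame <- function(measurements, table = default_range_table(),
                           defs = parameter_definitions()) {
  out <- measurements
  out$zone <- rep(NA_integer_, nrow(out))
  out$binary <- rep(NA_character_, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!out$valid[i]) next
    row <- defs$range_row[match(out$parameter[i], defs$parameter)]
    if (is.na(row)) row <- out$parameter[i]
    out$zone[i] <- classify_angle(table, row, out$angle[i])
    out$binary[i] <- collapse_to_binary(out$zone[i])
  }
  out[, c("parameter", "angle", "zone", "binary", "valid")]
}

#' Classify every frame of a measured stream
#'
#' @param measured output of [measure_stream()].
#' @inheritParams classify_frame
#' @return data.frame with columns `frame`, `t`, `parameter`, `angle`,
#'   `zone`, `binary`, `valid`.
#' @export
classify_stream <- function(measured, table = default_range_table(),
                            defs = parameter_definitions()) {
  out <- measured
  out$zone <- rep(NA_integer_, nrow(out))
  out$binary <- rep(NA_character_, nrow(out))
  for (p in unique(out$parameter)) {
    row <- defs$range_row[match(p, defs$parameter)]
    if (is.na(row)) row <- p
    sel <- out$parameter == p & out$valid
    out$zone[sel] <- classify_angle(table, row, out$angle[sel])
    out$binary[sel] <- collapse_to_binary(out$zone[sel])
  }
  out[, c("frame", "t", "parameter", "angle", "zone", "binary", "valid")]
}
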