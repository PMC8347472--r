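# Brute-force oracle: walk the printed integer bands of the default table
# and return the zone whose interval contains the angle.
oracle_bands <- function() {
  list(
    back_lateral_bend = c(5, 10, 20),
    back_flexion = c(10, 25, 45),
    back_extension = c(5, 10, 20),
    shoulder_alignment = c(5, 10, 20),
    arms_adduction = c(5, 12, 24),
    arms_abduction = c(13, 34, 67),
    neck_lateral_bend = c(5, 12, 24),
    neck_flexion = c(9, 22, 45),
    neck_extension = c(6, 15, 30)
  )
}
oracle_zone <- function(row, angle) {
  u <- oracle_bands()[[row]]
  intervals <- rbind(c(0, u[1]), c(u[1], u[2]), c(u[2], u[3]), c(u[3], Inf))
  for (z in 1:4) {
    lo <- intervals[z, 1]; hi <- intervals[z, 2]
    if ((angle > lo || (z == 1 && angle >= 0)) && angle <= hi) return(z - 1L)
  }
  stop("no interval matched")
}

test_that("the default range table carries the published nine-row bands", {
  tab <- default_range_table()
  expect_equal(nrow(tab), 9)
  expect_equal(unlist(tab[tab$parameter == "neck_lateral_bend",
                          c("u0", "u1", "u2")], use.names = FALSE),
               c(5, 12, 24))
  expect_equal(unlist(tab[tab$parameter == "arms_abduction",
                          c("u0", "u1", "u2")], use.names = FALSE),
               c(13, 34, 67))
  expect_equal(unlist(tab[tab$parameter == "shoulder_alignment",
                          c("u0", "u1", "u2")], use.names = FALSE),
               c(5, 10, 20))
  expect_true(all(tab$u0 > 0 & tab$u1 > tab$u0 & tab$u2 > tab$u1))
})

test_that("angle classification matches the interval-scan oracle on an integer sweep", {
  tab <- default_range_table()
  for (row in tab$parameter) {
    got <- classify_angle(tab, row, 0:180)
    want <- vapply(0:180, function(a) oracle_zone(row, a), integer(1))
    expect_identical(got, want, label = row)
  }
})

test_that("classification is monotone with a single safe/dangerous switch at u1", {
  tab <- default_range_table()
  angles <- seq(0, 180, by = 0.25)
  for (row in tab$parameter) {
    z <- classify_angle(tab, row, angles)
    expect_true(all(diff(z) >= 0), label = row)
    b <- collapse_to_binary(z)
    switches <- sum(b[-1] != b[-length(b)])
    expect_equal(switches, 1, label = row)
    u1 <- tab$u1[tab$parameter == row]
    expect_equal(b[angles <= u1][sum(angles <= u1)], "safe")
    expect_equal(b[angles > u1][1], "dangerous")
  }
})

test_that("boundary convention is left-open/right-closed on the printed bounds", {
  tab <- default_range_table()
  # zone 0 is [0, u0] exactly: 5.0 deg stays zone 0, 5.4 deg crosses to 1
  expect_equal(classify_angle(tab, "shoulder_alignment", 5.0), 0L)
  expect_equal(classify_angle(tab, "shoulder_alignment", 5.4), 1L)
  expect_equal(classify_angle(tab, "neck_lateral_bend", 25), 3L)
  expect_equal(classify_angle(tab, "arms_abduction", 35.5), 2L)
  expect_equal(classify_angle(tab, "neck_lateral_bend", 0), 0L)
  expect_error(classify_angle(tab, "neck_lateral_bend", -1), "non-negative")
  expect_error(classify_angle(tab, "elbow_twist", 10), "unknown parameter")
})

test_that("the two-class collapse maps 0-1 safe and 2-3 dangerous", {
  expect_equal(collapse_to_binary(0:3),
               c("safe", "safe", "dangerous", "dangerous"))
  expect_error(collapse_to_binary(4), "out of range")
  expect_error(collapse_to_binary(-1), "out of range")
})

test_that("frame classification keeps parameters independent under invalidity", {
  m <- measure_frame(pose_template(c(neck_lateral_bend = 30,
                                     left_arm_abduction = 40)))
  cls <- classify_frame(m)
  expect_equal(nrow(cls), 4)
  expect_equal(cls$zone[cls$parameter == "neck_lateral_bend"], 3L)
  expect_equal(cls$zone[cls$parameter == "left_arm_abduction"], 2L)
  expect_equal(cls$zone[cls$parameter == "shoulder_alignment"], 0L)
  expect_equal(cls$binary[cls$parameter == "shoulder_alignment"], "safe")

  m$valid[m$parameter == "neck_lateral_bend"] <- FALSE
  m$angle[m$parameter == "neck_lateral_bend"] <- NA
  cls2 <- classify_frame(m)
  expect_true(is.na(cls2$zone[cls2$parameter == "neck_lateral_bend"]))
  expect_equal(cls2$zone[cls2$parameter == "left_arm_abduction"], 2L)
})

test_that("both arms classify against the abduction row, not the adduction row", {
  # 30 deg: adduction row (5/12/24) would say zone 3; abduction (13/34/67) zone 1
  for (p in c("left_arm_abduction", "right_arm_abduction")) {
    ang <- setNames(30, p)
    cls <- classify_frame(measure_frame(pose_template(ang)))
    expect_equal(cls$zone[cls$parameter == p], 1L, label = p)
  }
})

test_that("a YAML override rebinds selected rows and keeps the rest", {
  path <- tempfile(fileext = ".yaml")
  writeLines("neck_lateral_bend: [4, 10, 20]", path)
  tab <- read_range_table(path)
  expect_equal(tab$u0[tab$parameter == "neck_lateral_bend"], 4)
  expect_equal(tab$u2[tab$parameter == "arms_abduction"], 67)
  writeLines("neck_lateral_bend: [10, 5, 20]", path)
  expect_error(read_range_table(path), "u0 < u1 < u2")
  unlink(path)
})
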