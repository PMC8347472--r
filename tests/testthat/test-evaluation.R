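# Two-pass naive summary oracle, independent of summarize_accuracies.
naive_stats <- function(x) {
  m <- 0; for (v in x) m <- m + v; m <- m / length(x)
  s2 <- 0; for (v in x) s2 <- s2 + (v - m)^2
  c(min = sort(x)[1], max = sort(x)[length(x)], mean = m,
    std = sqrt(s2 / length(x)))
}

test_that("confusion matrices count truth rows against prediction columns", {
  s <- data.frame(frame = 0:3,
                  neck_lateral_bend_truth = c(0L, 0L, 2L, 3L),
                  neck_lateral_bend_pred = c(0L, 2L, 2L, 3L))
  m <- confusion_matrix(s, "neck_lateral_bend")
  expect_equal(sum(m), 4)
  expect_equal(m["0", "2"], 1L)
  expect_equal(m["0", "0"], 1L)
  expect_equal(sum(diag(m)), 3)

  s$neck_lateral_bend_pred[2] <- NA
  m2 <- confusion_matrix(s, "neck_lateral_bend")
  expect_equal(sum(m2), 3)
  expect_equal(attr(m2, "n_invalid"), 1)
  expect_error(confusion_matrix(
    data.frame(frame = 0, neck_lateral_bend_truth = 1L,
               neck_lateral_bend_pred = NA_integer_), "neck_lateral_bend"),
    "no valid samples")
})

test_that("per-class scores satisfy the partition identity and the hand-worked case", {
  m <- matrix(c(3L, 0L, 1L, 6L), 2, 2, dimnames = list(0:1, 0:1))
  a <- accuracy(m)
  expect_equal(a$overall, 0.9)
  expect_equal(a$per_class$accuracy, c(0.9, 0.9))
  with(a$per_class, expect_true(all(TP + TN + FP + FN == TOTAL)))

  set.seed(4)
  r <- matrix(rpois(16, 5), 4, 4, dimnames = list(0:3, 0:3))
  ar <- accuracy(r)
  with(ar$per_class, {
    expect_true(all(TP + TN + FP + FN == TOTAL))
    expect_equal(sum(TP + FN), sum(r))  # row sums partition the total
    expect_equal(sum(TP + FP), sum(r))  # so do column sums
  })
  expect_equal(ar$overall, sum(diag(r)) / sum(r))
  expect_equal(accuracy(diag(c(5L, 5L, 5L, 5L)))$overall, 1)
})

test_that("critical errors count only the dangerous-called-safe direction", {
  s <- data.frame(frame = 0:3,
                  neck_lateral_bend_truth = c(3L, 1L, 2L, 2L),
                  neck_lateral_bend_pred = c(1L, 3L, 0L, 2L))
  expect_equal(critical_errors(s, "neck_lateral_bend"), 2)
  perfect <- data.frame(frame = 0:3,
                        neck_lateral_bend_truth = 0:3,
                        neck_lateral_bend_pred = 0:3)
  expect_equal(critical_errors(perfect, "neck_lateral_bend"), 0)
})

test_that("merging to two classes never lowers overall accuracy", {
  for (seed in 1:10) {
    s <- random_samples(n = 50, seed = seed, error_rate = 0.4)
    for (p in c("neck_lateral_bend", "shoulder_alignment")) {
      a4 <- accuracy(confusion_matrix(s, p, 4L))$overall
      a2 <- accuracy(confusion_matrix(to_binary(s), p, 2L))$overall
      expect_gte(a2, a4)
    }
  }
  # within-class merge turns a 1-vs-0 miss into a hit; cross-class persists
  b <- to_binary(data.frame(frame = 0:1,
                            neck_lateral_bend_truth = c(1L, 2L),
                            neck_lateral_bend_pred = c(0L, 0L)))
  expect_equal(b$neck_lateral_bend_truth, c(0L, 1L))
  expect_equal(b$neck_lateral_bend_pred, c(0L, 0L))
})

test_that("summary rows agree with a naive two-pass oracle", {
  set.seed(21)
  for (i in 1:5) {
    v4 <- runif(15, 0.6, 1)
    v2 <- pmin(1, v4 + runif(15, 0, 0.1))
    sm <- summarize_accuracies(v4, v2)
    o4 <- naive_stats(v4); o2 <- naive_stats(v2)
    expect_equal(sm$four, o4, tolerance = 1e-12)
    expect_equal(sm$two, o2, tolerance = 1e-12)
    expect_equal(sm$improve, 100 * (o2[["mean"]] - o4[["mean"]]) / o4[["mean"]],
                 tolerance = 1e-12)
  }
  expect_equal(summarize_accuracies(rep(0.9, 5), rep(0.9, 5))$four[["std"]], 0)
  expect_error(summarize_accuracies(numeric(0), numeric(0)), "empty")
})

test_that("repeated-subset evaluation is seeded and degenerates at fraction 1", {
  s <- random_samples(n = 40, seed = 3, error_rate = 0.3)
  r1 <- resample_eval(s, n_subsets = 8, fraction = 0.5, seed = 42)
  r2 <- resample_eval(s, n_subsets = 8, fraction = 0.5, seed = 42)
  expect_identical(r1, r2)
  expect_equal(nrow(r1$per_subset), 8)

  full <- resample_eval(s, n_subsets = 6, fraction = 1, seed = 1)
  expect_true(all(full$summary$std == 0))
  a4 <- accuracy(confusion_matrix(s, "neck_lateral_bend", 4L))$overall
  expect_true(all(full$per_subset$neck_lateral_bend_4class == a4))
})

test_that("labelled samples survive the CSV round trip and reject bad zones", {
  s <- random_samples(n = 20, seed = 6)
  s$neck_lateral_bend_pred[3] <- NA
  path <- tempfile(fileext = ".csv")
  write_labelled_samples(s, path)
  r <- read_labelled_samples(path)
  expect_equal(r, s)
  d <- utils::read.csv(path)
  d$neck_lateral_bend_truth[1] <- 7
  utils::write.csv(d, path, row.names = FALSE)
  expect_error(read_labelled_samples(path), "row 1")
  unlink(path)
})

test_that("the bundled 15-subset worked example reproduces its summary rows", {
  res <- summarize_subset_table(subset_table_path())
  sm <- res$summary
  row <- function(p, sch) sm[sm$parameter == p & sm$scheme == sch, ]
  expect_equal(round(row("shoulder", "4class")$mean, 3), 0.955)
  expect_equal(round(row("right_arm", "4class")$mean, 3), 0.842)
  expect_equal(round(row("right_arm", "2class")$mean, 3), 0.895)
  expect_equal(round(row("left_arm", "2class")$mean, 3), 0.853)
  expect_equal(row("shoulder", "2class")$mean, 1)
  expect_equal(row("shoulder", "2class")$std, 0)
  expect_equal(round(unname(res$improve["neck"]), 2), 9.54)
})
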