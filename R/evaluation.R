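#' Read / write labelled samples
#'
#' Labelled samples pair, per frame and per parameter, a ground-truth zone
#' with a predicted zone (both 0-3; blank/NA prediction = invalid frame for
#' that parameter). On disk: CSV with column `frame` followed by
#' `<parameter>_truth`, `<parameter>_pred` pairs.
#'
#' @param path CSV file path.
#' @return data.frame of labelled samples.
#' @export
read_labelled_samples <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"frame" %in% names(d)) stop("labelled CSV needs a 'frame' column")
  zcols <- grep("_(truth|pred)$", names(d), value = TRUE)
  for (cl in zcols) {
    v <- d[[cl]]
    bad <- which(!is.na(v) & !(v %in% 0:3))
    if (length(bad))
      stop("malformed label in column ", cl, " at row ", bad[1],
           ": zones must be 0-3")
    d[[cl]] <- as.integer(v)
  }
  d
}

#' @rdname read_labelled_samples
#' @param samples data.frame of labelled samples.
#' @export
write_labelled_samples <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, na = "")
  invisible(path)
}

sample_parameters <- function(samples) {
  sub("_truth$", "", grep("_truth$", names(samples), value = TRUE))
}

#' Confusion matrix for one parameter
#'
#' @param samples labelled samples (see [read_labelled_samples()]).
#' @param parameter parameter name (must have `_truth`/`_pred` columns).
#' @param n_classes 4 for zones, 2 for the safe/dangerous collapse.
#' @return An integer `n_classes x n_classes` matrix, rows = ground truth,
#'   columns = prediction, with attribute `n_invalid` counting excluded
#'   samples (missing prediction or truth).
#' @export
confusion_matrix <- function(samples, parameter, n_classes = 4L) {
  g <- samples[[paste0(parameter, "_truth")]]
  p <- samples[[paste0(parameter, "_pred")]]
  if (is.null(g) || is.null(p))
    stop("no truth/pred columns for parameter: ", parameter)
  ok <- !is.na(g) & !is.na(p)
  if (!any(ok)) stop("no valid samples for parameter: ", parameter)
  lev <- 0:(n_classes - 1L)
  m <- table(factor(g[ok], levels = lev), factor(p[ok], levels = lev))
  m <- matrix(as.integer(m), n_classes, n_classes,
              dimnames = list(truth = lev, pred = lev))
  attr(m, "n_invalid") <- sum(!ok)
  m
}

#' Per-class and overall accuracy from a confusion matrix
#'
#' Per class `c` (one-vs-rest): `TP = counts[c,c]`, `FN` = rest of row `c`,
#' `FP` = rest of column `c`, `TN` = remainder, and the class accuracy is
#' `(TP + TN) / TOTAL` with `TOTAL = TP + TN + FP + FN`. The overall
#' (headline) accuracy is the trace over the total.
#'
#' @param m confusion matrix (rows truth, columns prediction).
#' @return list with `per_class` (data.frame `class`, `TP`, `TN`, `FP`,
#'   `FN`, `TOTAL`, `accuracy`) and `overall` (trace/total).
#' @export
accuracy <- function(m) {
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  k <- nrow(m)
  per <- data.frame(class = rownames(m) %||% as.character(seq_len(k) - 1L),
                    TP = NA_integer_, TN = NA_integer_, FP = NA_integer_,
                    FN = NA_integer_, TOTAL = as.integer(total),
                    accuracy = NA_real_, stringsAsFactors = FALSE)
  for (c in seq_len(k)) {
    tp <- m[c, c]
    fn <- sum(m[c, ]) - tp
    fp <- sum(m[, c]) - tp
    tn <- total - tp - fn - fp
    per$TP[c] <- tp; per$TN[c] <- tn; per$FP[c] <- fp; per$FN[c] <- fn
    per$accuracy[c] <- (tp + tn) / total
  }
  list(per_class = per, overall = sum(diag(m)) / total)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collapse labelled samples to the safe/dangerous scheme
#'
#' Both truth and prediction are mapped through the zone collapse
#' (0-1 -> safe = 0, 2-3 -> dangerous = 1). Merging classes can only keep or
#' add diagonal mass, so two-class accuracy is never below four-class
#' accuracy on the same samples.
#'
#' @param samples labelled samples.
#' @return samples with all `_truth`/`_pred` columns recoded to 0 (safe) /
#'   1 (dangerous).
#' @export
to_binary <- function(samples) {
  out <- samples
  for (cl in grep("_(truth|pred)$", names(out), value = TRUE)) {
    out[[cl]] <- ifelse(is.na(out[[cl]]), NA_integer_,
                        as.integer(out[[cl]] >= 2L))
  }
  out
}

#' Count critical errors for one parameter
#'
#' A critical error is the clinically consequential direction only: a
#' dangerous posture (truth zone 2 or 3) predicted as safe (zone 0 or 1).
#' Safe postures flagged dangerous are false alarms, not critical.
#'
#' @inheritParams confusion_matrix
#' @return integer count over the valid samples.
#' @export
critical_errors <- function(samples, parameter) {
  g <- samples[[paste0(parameter, "_truth")]]
  p <- samples[[paste0(parameter, "_pred")]]
  sum(!is.na(g) & !is.na(p) & g >= 2L & p <= 1L)
}

#' Summary rows for repeated-subset accuracies
#'
#' Given per-subset overall accuracies under the 4-class and 2-class
#' schemes (same subsets), computes the MIN/MAX exact order statistics, the
#' arithmetic MEAN, the population standard deviation (divide by n), and
#' `Improve`, the relative percent gain of the two-class mean over the
#' four-class mean.
#'
#' @param values numeric vector of 4-class per-subset accuracies.
#' @param values_2class numeric vector of 2-class per-subset accuracies.
#' @return list with `four` and `two` (each `c(min, max, mean, std)`) and
#'   `improve` (percent).
#' @export
summarize_accuracies <- function(values, values_2class) {
  if (!length(values) || !length(values_2class))
    stop("empty accuracy list")
  stats_of <- function(x) c(min = min(x), max = max(x), mean = mean(x),
                            std = sqrt(mean((x - mean(x))^2)))
  four <- stats_of(values)
  two <- stats_of(values_2class)
  list(four = four, two = two,
       improve = 100 * (two[["mean"]] - four[["mean"]]) / four[["mean"]])
}

#' Repeated-subsample evaluation
#'
#' Draws `n_subsets` random subsets of the labelled samples, each of size
#' `round(fraction * n)` (without replacement by default: 50% subsampling),
#' evaluates per-parameter overall accuracy under both the 4-class and
#' 2-class schemes on every subset, and summarizes with
#' [summarize_accuracies()]. Fully reproducible given `seed`.
#'
#' @param samples labelled samples.
#' @param n_subsets number of random subsets (default 15).
#' @param fraction proportion of samples per subset (default 0.5).
#' @param seed integer RNG seed.
#' @param replace draw with replacement (true bootstrap) instead of
#'   subsampling.
#' @return list with
#'   * `per_subset`: data.frame `subset`, then `<parameter>_4class` and
#'     `<parameter>_2class` accuracy columns;
#'   * `summary`: data.frame `parameter`, `scheme`, `min`, `max`, `mean`,
#'     `std`;
#'   * `improve`: named numeric vector, percent gain per parameter.
#' @export
resample_eval <- function(samples, n_subsets = 15L, fraction = 0.5,
                          seed = 1L, replace = FALSE) {
  stopifnot(n_subsets >= 1L, fraction > 0, fraction <= 1)
  n <- nrow(samples)
  size <- round(fraction * n)
  if (size < 1L) stop("subset would be empty: too few samples")
  params <- sample_parameters(samples)
  set.seed(seed)
  acc <- matrix(NA_real_, n_subsets, 2L * length(params))
  colnames(acc) <- c(paste0(params, "_4class"), paste0(params, "_2class"))
  for (s in seq_len(n_subsets)) {
    idx <- sample.int(n, size, replace = replace)
    sub4 <- samples[idx, , drop = FALSE]
    sub2 <- to_binary(sub4)
    for (p in params) {
      acc[s, paste0(p, "_4class")] <-
        accuracy(confusion_matrix(sub4, p, 4L))$overall
      acc[s, paste0(p, "_2class")] <-
        accuracy(confusion_matrix(sub2, p, 2L))$overall
    }
  }
  per_subset <- data.frame(subset = seq_len(n_subsets), acc,
                           check.names = FALSE)
  summary_rows <- list()
  improve <- numeric(0)
  for (p in params) {
    sm <- summarize_accuracies(acc[, paste0(p, "_4class")],
                               acc[, paste0(p, "_2class")])
    summary_rows[[paste0(p, ".4")]] <- data.frame(
      parameter = p, scheme = "4class", t(sm$four), stringsAsFactors = FALSE)
    summary_rows[[paste0(p, ".2")]] <- data.frame(
      parameter = p, scheme = "2class", t(sm$two), stringsAsFactors = FALSE)
    improve[p] <- sm$improve
  }
  summary <- do.call(rbind, c(summary_rows, list(make.row.names = FALSE)))
  list(per_subset = per_subset, summary = summary, improve = improve)
}

#' Summarize an externally supplied per-subset accuracy table
#'
#' For re-checking published repeated-subset tables: reads a CSV with one
#' row per subset and one column per parameter/scheme (columns named
#' `<parameter>_4class` / `<parameter>_2class`), and recomputes the
#' MIN/MAX/MEAN/STD/Improve summary rows.
#'
#' @param path CSV path (or a data.frame already in memory).
#' @return As the `summary`/`improve` components of [resample_eval()].
#' @export
summarize_subset_table <- function(path) {
  d <- if (is.data.frame(path)) path else
    utils::read.csv(path, check.names = FALSE)
  d$subset <- NULL
  base <- sub("_(4class|2class)$", "", names(d))
  params <- unique(base[grepl("_4class$", names(d))])
  summary_rows <- list(); improve <- numeric(0)
  for (p in params) {
    v4 <- d[[paste0(p, "_4class")]]
    v2 <- d[[paste0(p, "_2class")]]
    if (is.null(v2)) v2 <- v4
    sm <- summarize_accuracies(v4, v2)
    summary_rows[[paste0(p, ".4")]] <- data.frame(
      parameter = p, scheme = "4class", t(sm$four), stringsAsFactors = FALSE)
    summary_rows[[paste0(p, ".2")]] <- data.frame(
      parameter = p, scheme = "2class", t(sm$two), stringsAsFactors = FALSE)
    improve[p] <- sm$improve
  }
  list(summary = do.call(rbind, c(summary_rows, list(make.row.names = FALSE))),
       improve = improve)
}

#' Full evaluation report for a labelled sample set
#'
#' @param samples labelled samples.
#' @param n_subsets,fraction,seed passed to [resample_eval()].
#' @return list with `per_parameter` (data.frame: 4-class and 2-class
#'   overall accuracy, critical errors, valid sample count per parameter),
#'   `mean_accuracy_4class`, `mean_accuracy_2class`, `confusions` (named
#'   list of 4x4 matrices), `per_class` (named list of one-vs-rest score
#'   tables) and `resampling` (the [resample_eval()] result).
#' @export
evaluate_samples <- function(samples, n_subsets = 15L, fraction = 0.5,
                             seed = 1L) {
  params <- sample_parameters(samples)
  bin <- to_binary(samples)
  rows <- list(); confusions <- list(); per_class <- list()
  for (p in params) {
    m4 <- confusion_matrix(samples, p, 4L)
    m2 <- confusion_matrix(bin, p, 2L)
    a4 <- accuracy(m4); a2 <- accuracy(m2)
    confusions[[p]] <- m4
    per_class[[p]] <- a4$per_class
    rows[[p]] <- data.frame(
      parameter = p, n_valid = sum(m4),
      accuracy_4class = a4$overall, accuracy_2class = a2$overall,
      critical_errors = critical_errors(samples, p),
      stringsAsFactors = FALSE)
  }
  per_parameter <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(per_parameter = per_parameter,
       mean_accuracy_4class = mean(per_parameter$accuracy_4class),
       mean_accuracy_2class = mean(per_parameter$accuracy_2class),
       confusions = confusions,
       per_class = per_class,
       resampling = resample_eval(samples, n_subsets, fraction, seed))
}
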