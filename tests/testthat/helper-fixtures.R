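# Shared fixtures built in code at test time.

# A small random stream with optional missing keypoints, for round-trip and
# propagation tests.
random_stream <- function(n = 5, seed = 1, p_missing = 0.1, with_conf = TRUE) {
  set.seed(seed)
  topo <- default_topology()
  frames <- lapply(seq_len(n), function(i) {
    coords <- list()
    for (nm in topo$names) {
      if (runif(1) < p_missing) next
      v <- c(runif(1, 0, 640), runif(1, 0, 480))
      if (with_conf && runif(1) < 0.8) v <- c(v, runif(1))
      coords[[nm]] <- v
    }
    skeleton_frame(coords, frame_index = i - 1L, timestamp = (i - 1) / 25)
  })
  frames_to_stream(frames, topo, source = "test", fps = 25)
}

# Labelled samples with a fixed number of random errors, for the evaluation
# machinery.
random_samples <- function(n = 60, seed = 2, error_rate = 0.2,
                           params = c("neck_lateral_bend", "shoulder_alignment")) {
  set.seed(seed)
  out <- data.frame(frame = seq_len(n) - 1L)
  for (p in params) {
    truth <- sample(0:3, n, replace = TRUE)
    pred <- truth
    flip <- runif(n) < error_rate
    pred[flip] <- sample(0:3, sum(flip), replace = TRUE)
    out[[paste0(p, "_truth")]] <- truth
    out[[paste0(p, "_pred")]] <- pred
  }
  out
}

# An assignments series (one parameter) with given zones at a fixed frame
# period, for smoothing/monitoring tests.
zone_series <- function(zones, period = 1, parameter = "neck_lateral_bend",
                        valid = rep(TRUE, length(zones))) {
  data.frame(frame = seq_along(zones) - 1L,
             t = (seq_along(zones) - 1) * period,
             parameter = parameter,
             angle = NA_real_,
             zone = ifelse(valid, zones, NA_integer_),
             binary = NA_character_,
             valid = valid,
             stringsAsFactors = FALSE)
}

subset_table_path <- function() {
  system.file("extdata", "resample_accuracy_subsets.csv", package = "ergopose")
}
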