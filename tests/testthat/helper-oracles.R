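# Independent brute-force reference implementations used to cross-check the
# package's vectorized code paths. These deliberately use the slowest,
# most literal formulation of each rule.

# per-frame tally of a track by looping over every frame timestamp
brute_class_distribution <- function(track, fps) {
  n <- round(lapcensor::track_duration(track) * fps)
  counts <- stats::setNames(rep(0, 5), lapcensor::frame_classes())
  for (i in seq_len(n) - 1) {
    lab <- lapcensor::class_at(track, i / fps)
    counts[lab] <- counts[lab] + 1
  }
  counts
}

# double loop confusion matrix
brute_confusion <- function(truth, pred, vocab) {
  m <- matrix(0L, length(vocab), length(vocab), dimnames = list(vocab, vocab))
  for (i in seq_along(truth)) {
    m[truth[i], pred[i]] <- m[truth[i], pred[i]] + 1L
  }
  m
}

# literal fixpoint simulation of the island-removal rule
brute_smooth <- function(labels, sample_rate, min_island_s, privacy_safe) {
  repeat {
    r <- rle(labels)
    k <- length(r$lengths)
    changed <- FALSE
    if (k >= 3) {
      flip <- logical(k)
      for (i in 2:(k - 1)) {
        short <- r$lengths[i] / sample_rate < min_island_s
        shared <- r$values[i - 1] == r$values[i + 1]
        forbidden <- privacy_safe && r$values[i] == "OUTSIDE" &&
          r$values[i - 1] == "INSIDE"
        if (short && shared && !forbidden) flip[i] <- TRUE
      }
      if (any(flip)) {
        # all qualifying runs are reassigned against the pass-start state
        old <- r$values
        for (i in which(flip)) r$values[i] <- old[i - 1]
        labels <- inverse.rle(r)
        changed <- TRUE
      }
    }
    if (!changed) {
      return(labels)
    }
  }
}

# literal per-frame expansion lookup
brute_expand <- function(labels, sample_rate, native_fps, frame_count) {
  out <- character(frame_count)
  for (i in seq_len(frame_count) - 1) {
    slot <- floor((i / native_fps) * sample_rate) + 1
    out[i + 1] <- labels[min(slot, length(labels))]
  }
  out
}

# trivial mean-channel-statistics classifier (the separability oracle)
threshold_classify <- function(frame) {
  if (mean(frame[, , 1]) - mean(frame[, , 3]) > 0.05) "INSIDE" else "OUTSIDE"
}

random_track <- function(seed, n_intervals = 10, fps = 25) {
  set.seed(seed)
  durs <- stats::runif(n_intervals, 0.5, 20)
  labs <- sample(lapcensor::frame_classes(), n_intervals, replace = TRUE)
  ends <- cumsum(durs)
  lapcensor::annotation_track(
    data.frame(start_s = c(0, ends[-n_intervals]), end_s = ends, label = labs),
    video_id = sprintf("rt%d", seed), fps = fps
  )
}
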