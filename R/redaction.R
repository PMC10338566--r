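#' A per-sample binary label timeline
#'
#' Ordered inside/outside labels on the sampling grid (one label per
#' `1/sample_rate` seconds); the carrier between classification and
#' censoring. Five-way labels are collapsed with [to_binary()].
#'
#' @param labels Character vector of class tokens (binary or five-way).
#' @param sample_rate Labels per second (default 1).
#' @return A `label_timeline`: list with `labels` (binary tokens) and
#'   `sample_rate`.
#' @export
label_timeline <- function(labels, sample_rate = 1) {
  stopifnot(sample_rate > 0)
  structure(
    list(labels = to_binary(labels), sample_rate = sample_rate),
    class = "label_timeline"
  )
}

#' @export
print.label_timeline <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf(
    "<label_timeline> %d label(s) @ %g/s (%.1f s), %.1f%% OUTSIDE\n",
    n, x$sample_rate, n / x$sample_rate,
    if (n) 100 * mean(x$labels == "OUTSIDE") else 0
  ))
  invisible(x)
}

#' Redaction policy
#'
#' @param mode Censoring rendition: `"black"` (all-zero pixels; the
#'   default, strongest anonymization) or `"blur"` (heavy box blur, kernel
#'   at least 1/8 of the frame width; keeps temporal context for reviewers
#'   but is weaker anonymization).
#' @param min_island_s Runs shorter than this (seconds) are smoothing
#'   candidates (default 2).
#' @param smoothing `"privacy_safe"` (default: short runs are reassigned to
#'   the surrounding label, but an OUTSIDE run is never flipped to INSIDE —
#'   a flipped outside frame is a privacy breach, a flipped inside frame
#'   only loses data), `"symmetric"` (both directions) or `"off"`.
#' @return A `redaction_policy` list.
#' @export
redaction_policy <- function(mode = c("black", "blur"), min_island_s = 2,
                             smoothing = c("privacy_safe", "symmetric", "off")) {
  mode <- match.arg(mode)
  smoothing <- match.arg(smoothing)
  stopifnot(min_island_s >= 0)
  structure(list(mode = mode, min_island_s = min_island_s, smoothing = smoothing),
    class = "redaction_policy"
  )
}

#' Temporal smoothing of a label timeline
#'
#' Removes isolated classifier outliers: any maximal run of identical
#' labels shorter than `min_island_s` whose two neighbouring runs share a
#' label is reassigned to that label. Runs touching the timeline edges are
#' never reassigned, and in `"privacy_safe"` mode OUTSIDE runs are never
#' reassigned to INSIDE. All qualifying runs are flipped simultaneously and
#' the rule is iterated until a fixpoint is reached.
#'
#' @param timeline A [label_timeline()].
#' @param policy A [redaction_policy()].
#' @return The smoothed `label_timeline`.
#' @export
#' @examples
#' tl <- label_timeline(c("INSIDE", "INSIDE", "OUTSIDE", "INSIDE", "INSIDE"))
#' smooth_timeline(tl, redaction_policy(smoothing = "symmetric"))$labels
smooth_timeline <- function(timeline, policy = redaction_policy()) {
  stopifnot(inherits(timeline, "label_timeline"))
  if (policy$smoothing == "off" || length(timeline$labels) == 0) {
    return(timeline)
  }
  lab <- timeline$labels
  min_len <- policy$min_island_s * timeline$sample_rate
  repeat {
    r <- rle(lab)
    k <- length(r$lengths)
    if (k < 3) break
    flip <- logical(k)
    for (i in 2:(k - 1)) {
      if (r$lengths[i] * 1 >= min_len) next
      if (r$values[i - 1] != r$values[i + 1]) next
      to <- r$values[i - 1]
      if (policy$smoothing == "privacy_safe" &&
        r$values[i] == "OUTSIDE" && to == "INSIDE") {
        next
      }
      flip[i] <- TRUE
    }
    if (!any(flip)) break
    r$values[flip] <- r$values[which(flip) - 1]
    lab <- inverse.rle(r)
  }
  timeline$labels <- lab
  timeline
}

#' Expand a sampled timeline to native frame labels
#'
#' Each sampled label governs all native frames of its sampling period
#' (`1/sample_rate` seconds): native frame `i` (0-based) gets the label of
#' the sampled slot containing `i / native_fps`. Trailing frames beyond the
#' last sampled slot inherit the last label, so every native frame is
#' covered.
#'
#' @param timeline A [label_timeline()].
#' @param native_fps Native frame rate of the video.
#' @param frame_count Number of native frames to label.
#' @return Character vector of `frame_count` binary labels.
#' @export
expand_timeline <- function(timeline, native_fps, frame_count) {
  stopifnot(inherits(timeline, "label_timeline"), native_fps > 0, frame_count >= 0)
  n <- length(timeline$labels)
  if (n == 0) stop("cannot expand an empty timeline", call. = FALSE)
  i <- seq_len(frame_count) - 1
  slot <- floor(i / native_fps * timeline$sample_rate + 1e-9) + 1
  timeline$labels[pmin(slot, n)]
}

#' Censor outside frames of a video
#'
#' Replaces every OUTSIDE-labelled native frame — black mode zeroes all
#' pixels, blur mode applies a box blur with kernel at least 1/8 of the
#' frame width — and passes every INSIDE frame through unmodified. The
#' manifest records exactly which half-open native frame index ranges
#' (0-based) were censored. A label/frame count mismatch is a hard error
#' and no output is written (the pipeline fails closed).
#'
#' @param video Path of the input frame stack (see [write_video()]).
#' @param frame_labels Character vector of per-native-frame binary labels,
#'   one per frame of the video.
#' @param policy A [redaction_policy()].
#' @param out Output video path.
#' @param chunk Frames processed per read chunk (memory control).
#' @return Invisibly, the manifest: list with `video`, `out`, `mode`,
#'   `n_frames`, `n_censored`, `censored_ranges` (list of `c(start, end)`
#'   half-open 0-based index pairs).
#' @export
redact_video <- function(video, frame_labels, policy = redaction_policy(),
                         out, chunk = 200) {
  n <- video_length(video)
  frame_labels <- to_binary(frame_labels)
  if (length(frame_labels) != n) {
    stop(sprintf(
      "label count (%d) does not match frame count (%d); refusing to write output",
      length(frame_labels), n
    ), call. = FALSE)
  }
  censored <- frame_labels == "OUTSIDE"
  frames_out <- vector("list", n)
  for (lo in seq(1, n, by = chunk)) {
    hi <- min(lo + chunk - 1, n)
    block <- read_video(video, which = lo:hi)
    for (j in seq_along(block)) {
      i <- lo + j - 1
      frames_out[[i]] <- if (censored[i]) censor_frame(block[[j]], policy$mode) else block[[j]]
    }
  }
  write_video(frames_out, out)
  r <- rle(censored)
  ends <- cumsum(r$lengths)
  starts <- c(0, ends[-length(ends)])
  ranges <- lapply(which(r$values), function(k) c(starts[k], ends[k]))
  manifest <- list(
    video = video, out = out, mode = policy$mode, n_frames = n,
    n_censored = sum(censored), censored_ranges = ranges
  )
  invisible(manifest)
}

censor_frame <- function(frame, mode) {
  if (mode == "black") {
    return(array(0, dim(frame)))
  }
  k <- max(9, 2 * floor(dim(frame)[2] / 16) + 1) # odd, >= width/8
  brush <- matrix(1 / k^2, k, k)
  for (c in 1:3) frame[, , c] <- EBImage::filter2(frame[, , c], brush)
  frame[frame < 0] <- 0
  frame[frame > 1] <- 1
  frame
}

#' Write a redaction manifest as JSON
#' @param manifest Manifest list from [redact_video()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
save_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write per-frame label tables as CSV
#'
#' The prediction interchange format: one row per sampled frame with
#' `video_id`, `timestamp_s`, `label`.
#'
#' @param labels Tibble with columns `video_id`, `timestamp_s` and `label`
#'   (or `pred`, renamed on write).
#' @param path File path.
#' @return `load_labels()` returns the tibble; `save_labels()` the path,
#'   invisibly.
#' @export
save_labels <- function(labels, path) {
  df <- as.data.frame(labels)
  if (!"label" %in% names(df) && "pred" %in% names(df)) {
    df$label <- df$pred
  }
  utils::write.csv(df[c("video_id", "timestamp_s", "label")], path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname save_labels
#' @export
load_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::tibble(
    video_id = as.character(df$video_id),
    timestamp_s = as.numeric(df$timestamp_s),
    label = as.character(df$label)
  )
}
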