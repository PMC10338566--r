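#' Sampling timestamps at a reduced frame rate
#'
#' Classification runs on a subsampled frame grid (default 1 frame/second)
#' to keep computation tractable; timestamps are `k / sample_rate` for
#' `k = 0 ... floor(duration_s * sample_rate) - 1`.
#'
#' @param duration_s Video duration in seconds (> 0).
#' @param sample_rate Sampling rate in frames/second (default 1).
#' @return Numeric vector of timestamps in seconds (possibly empty for
#'   videos shorter than one sampling period).
#' @export
#' @examples
#' sample_timestamps(10)
sample_timestamps <- function(duration_s, sample_rate = 1) {
  stopifnot(duration_s > 0)
  if (sample_rate <= 0) stop("sample_rate must be > 0", call. = FALSE)
  n <- floor(duration_s * sample_rate + 1e-9)
  if (n < 1) {
    return(numeric())
  }
  (seq_len(n) - 1) / sample_rate
}

#' Preprocess a frame for the classifier
#'
#' Bilinearly resizes to 224x224 and normalizes each channel as
#' `(x - mean) / sd`. The default constants are the ImageNet statistics the
#' pretrained feature extractor expects; note the third mean component
#' (0.456) — kept configurable — differs from the conventional ImageNet
#' blue-channel mean (0.406).
#'
#' @param frame `H x W x 3` array in `[0,1]`.
#' @param mean,sd RGB normalization triples; every `sd` component must be
#'   non-zero.
#' @param size Output side length in pixels.
#' @return `size x size x 3` numeric array.
#' @export
preprocess <- function(frame, mean = c(0.485, 0.456, 0.456),
                       sd = c(0.229, 0.224, 0.225), size = 224) {
  d <- dim(frame)
  stopifnot(length(d) == 3, d[3] == 3, d[1] >= 1, d[2] >= 1)
  if (any(sd == 0)) stop("sd components must be non-zero", call. = FALSE)
  if (d[1] != size || d[2] != size) {
    # EBImage works in (x, y, channel) layout
    img <- EBImage::Image(aperm(frame, c(2, 1, 3)), colormode = "Color")
    img <- EBImage::resize(img, w = size, h = size, filter = "bilinear")
    frame <- aperm(as.array(img), c(2, 1, 3))
  }
  for (c in 1:3) frame[, , c] <- (frame[, , c] - mean[c]) / sd[c]
  frame
}

#' Cut a video's sampled frames into fixed-length sequences
#'
#' The classifier consumes ordered runs of `L` consecutive sampled frames
#' from a single video (non-overlapping by default). In `"train"` mode a
#' trailing remainder shorter than `L` is dropped; in `"inference"` mode the
#' last chunk is padded by repeating its final frame and the number of
#' padded slots is recorded so the padding can be discarded after
#' prediction.
#'
#' @param frames Tibble with one row per sampled frame, in time order, with
#'   at least columns `video_id`, `timestamp_s`, `label` and a list-column
#'   of per-frame data (`image` or `feature`).
#' @param L Sequence length (default 32).
#' @param mode `"train"` or `"inference"`.
#' @param stride Step between sequence starts; defaults to `L`
#'   (non-overlapping).
#' @return List of `sequence_batch` objects: each a list with `video_id`,
#'   `rows` (integer indices into `frames`), `timestamps`, `labels`,
#'   `pad_count`.
#' @export
make_sequences <- function(frames, L = 32, mode = c("train", "inference"),
                           stride = L) {
  mode <- match.arg(mode)
  stopifnot(L >= 1, stride >= 1)
  n <- nrow(frames)
  if (n == 0) {
    if (mode == "inference") stop("no frames to classify", call. = FALSE)
    return(list())
  }
  if (length(unique(frames$video_id)) != 1) {
    stop("sequences must come from a single video", call. = FALSE)
  }
  if (n > 1 && any(diff(frames$timestamp_s) <= 0)) {
    stop("frames must be strictly time-ordered", call. = FALSE)
  }
  starts <- seq(1, n, by = stride)
  out <- list()
  for (s in starts) {
    idx <- s:min(s + L - 1, n)
    pad <- as.integer(L - length(idx))
    if (pad > 0) {
      if (mode == "train") next
      idx <- c(idx, rep(idx[length(idx)], pad))
    }
    out[[length(out) + 1]] <- structure(
      list(
        video_id = frames$video_id[1],
        rows = idx,
        timestamps = frames$timestamp_s[idx],
        labels = frames$label[idx],
        pad_count = pad
      ),
      class = "sequence_batch"
    )
    if (s + L - 1 >= n) break
  }
  out
}

#' Stratified k-fold assignment of whole videos
#'
#' Splits are always by video, never by frame, so no frame of a test video
#' can leak into training. Folds are balanced on operation type and total
#' duration with a deterministic greedy rule: within each operation type,
#' videos are sorted by duration (descending, ties by input order) and each
#' is assigned to the fold with the smallest running total duration (ties
#' broken by fold index). Operation types are processed in order of first
#' appearance.
#'
#' @param videos Tibble of video metadata ([video_record()] rows): columns
#'   `video_id`, `operation_type`, `duration_s`.
#' @param k Number of folds (default 5); must be at least 2 and at most the
#'   number of videos.
#' @param seed Unused by the deterministic rule; kept so callers can treat
#'   fold construction like the other seeded stages.
#' @return A tibble `video_id`, `fold` (integer in `0 .. k-1`), one row per
#'   video.
#' @export
stratified_kfold <- function(videos, k = 5, seed = 0) {
  stopifnot(is.data.frame(videos), all(c("video_id", "operation_type", "duration_s") %in% names(videos)))
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > nrow(videos)) stop("more folds than videos", call. = FALSE)
  if (anyDuplicated(videos$video_id)) stop("duplicate video ids", call. = FALSE)
  totals <- rep(0, k)
  fold <- integer(nrow(videos))
  for (ty in unique(videos$operation_type)) {
    rows <- which(videos$operation_type == ty)
    rows <- rows[order(-videos$duration_s[rows])]
    for (r in rows) {
      f <- which.min(totals) # ties: lowest fold index
      fold[r] <- f - 1L
      totals[f] <- totals[f] + videos$duration_s[r]
    }
  }
  tibble::tibble(video_id = videos$video_id, fold = fold)
}

#' Read / write fold assignments as CSV
#' @param folds Tibble `video_id`, `fold`.
#' @param path File path.
#' @return `load_folds()` returns the tibble; `save_folds()` the path,
#'   invisibly.
#' @export
save_folds <- function(folds, path) {
  utils::write.csv(as.data.frame(folds), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_folds
#' @export
load_folds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::tibble(video_id = as.character(df$video_id), fold = as.integer(df$fold))
}

#' Sample and preprocess frames from a video source
#'
#' Builds the model-ready frame table for one video: timestamps at
#' `sample_rate`, per-frame labels from the annotation track, and
#' preprocessed 224x224x3 images. The source is either a `scenario_spec`
#' (frames are rendered on demand — no video file needed) or the path of a
#' rendered frame stack.
#'
#' @param source A `scenario_spec` or a video file path.
#' @param track The video's [annotation_track()].
#' @param sample_rate Sampling rate in frames/second.
#' @param mean,sd,size Passed to [preprocess()].
#' @return Tibble with columns `video_id`, `timestamp_s`, `label`, `image`
#'   (list-column of preprocessed arrays).
#' @export
sample_frames <- function(source, track, sample_rate = 1,
                          mean = c(0.485, 0.456, 0.456),
                          sd = c(0.229, 0.224, 0.225), size = 224) {
  ts <- sample_timestamps(track_duration(track), sample_rate)
  if (length(ts) == 0) {
    return(tibble::tibble(
      video_id = character(), timestamp_s = numeric(),
      label = character(), image = list()
    ))
  }
  raw <- if (inherits(source, "scenario_spec")) {
    lapply(ts, function(t) render_frame(source, t))
  } else {
    fps <- track_fps(track)
    read_video(source, which = pmin(floor(ts * fps + 1e-9) + 1, video_length(source)))
  }
  tibble::tibble(
    video_id = track_video_id(track),
    timestamp_s = ts,
    label = class_at(track, ts),
    image = lapply(raw, preprocess, mean = mean, sd = sd, size = size)
  )
}
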