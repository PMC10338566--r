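#' Frame class taxonomy
#'
#' Every laparoscopic video frame belongs to exactly one of five classes.
#' Two are intra-abdominal (`ABDOMINAL_CAVITY`, `TROCAR`) and three are
#' extra-abdominal (`OUTSIDE`, `CLEANING`, `TRANSLUCENT_TROCAR`); the latter
#' three are privacy-critical because skin, faces or other identifying
#' content can be visible. The order returned here is the canonical class
#' index order used by confusion matrices and model heads.
#'
#' @return Character vector of the five class tokens, in canonical order.
#' @seealso [to_binary()] for the fixed surjective mapping onto
#'   inside/outside.
#' @export
#' @examples
#' frame_classes()
frame_classes <- function() {
  c("ABDOMINAL_CAVITY", "TROCAR", "OUTSIDE", "CLEANING", "TRANSLUCENT_TROCAR")
}

#' @rdname frame_classes
#' @export
binary_classes <- function() {
  c("INSIDE", "OUTSIDE")
}

#' The four procedure categories used for stratification
#' @return Character vector of category tokens.
#' @export
procedure_categories <- function() {
  c("cholecystectomy", "upper_gastrointestinal", "colorectal", "miscellaneous")
}

#' Collapse five-way frame classes to the binary inside/outside outcome
#'
#' The mapping is total and fixed: `ABDOMINAL_CAVITY` and `TROCAR` are
#' `INSIDE`; `OUTSIDE`, `CLEANING` and `TRANSLUCENT_TROCAR` are `OUTSIDE`.
#' A frame seen through a translucent trocar counts as outside because skin
#' can show through the trocar wall.
#'
#' @param label Character vector of five-way class tokens (binary tokens are
#'   passed through unchanged).
#' @return Character vector of `"INSIDE"` / `"OUTSIDE"`, same length.
#' @export
#' @examples
#' to_binary(c("TROCAR", "CLEANING"))
to_binary <- function(label) {
  map <- c(
    ABDOMINAL_CAVITY = "INSIDE", TROCAR = "INSIDE",
    OUTSIDE = "OUTSIDE", CLEANING = "OUTSIDE", TRANSLUCENT_TROCAR = "OUTSIDE",
    INSIDE = "INSIDE"
  )
  out <- unname(map[as.character(label)])
  if (anyNA(out) && !anyNA(label)) {
    bad <- setdiff(unique(as.character(label)), names(map))
    stop("unknown frame class token(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  out
}

assert_known_labels <- function(label) {
  bad <- setdiff(unique(as.character(label)), frame_classes())
  if (length(bad) > 0) {
    stop("unknown frame class token(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Construct an annotation track
#'
#' An annotation track is the ground-truth (or prediction) carrier for one
#' video: an ordered set of half-open intervals `[start_s, end_s)` in
#' seconds, each labelled with a frame class, that exactly tile
#' `[0, duration_s)` with no gaps or overlaps. Frame `i` (0-based) at
#' frame rate `fps` lives at timestamp `i / fps`, so half-open intervals
#' count every frame exactly once.
#'
#' The constructor normalizes its input: intervals are sorted by start time
#' and adjacent intervals with equal labels are merged (annotation tools cut
#' videos into fixed-length sections, which splits intervals arbitrarily).
#' Violations of the tiling invariant are hard errors — the censoring
#' pipeline fails closed rather than guessing.
#'
#' @param intervals Data frame with columns `start_s`, `end_s`, `label`.
#' @param video_id Identifier of the annotated video.
#' @param fps Native frame rate of the video (frames/second).
#' @param duration_s Total video duration in seconds; defaults to the end of
#'   the last interval.
#' @return A tibble of class `annotation_track` with columns `start_s`,
#'   `end_s`, `label` and attributes `video_id`, `duration_s`, `fps`.
#' @export
#' @examples
#' annotation_track(
#'   data.frame(
#'     start_s = c(0, 10), end_s = c(10, 12),
#'     label = c("ABDOMINAL_CAVITY", "OUTSIDE")
#'   ),
#'   video_id = "vid01", fps = 25
#' )
annotation_track <- function(intervals, video_id, fps, duration_s = NULL) {
  stopifnot(is.data.frame(intervals))
  if (nrow(intervals) == 0) {
    if (is.null(duration_s)) duration_s <- 0
    if (duration_s != 0) {
      stop("track with no intervals must have duration 0", call. = FALSE)
    }
    out <- tibble::tibble(
      start_s = numeric(), end_s = numeric(), label = character()
    )
    return(new_annotation_track(out, video_id, duration_s, fps))
  }
  needed <- c("start_s", "end_s", "label")
  if (!all(needed %in% names(intervals))) {
    stop("intervals need columns start_s, end_s, label", call. = FALSE)
  }
  iv <- tibble::as_tibble(intervals[needed])
  iv$start_s <- as.numeric(iv$start_s)
  iv$end_s <- as.numeric(iv$end_s)
  iv$label <- as.character(iv$label)
  assert_known_labels(iv$label)
  if (any(!is.finite(iv$start_s)) || any(!is.finite(iv$end_s))) {
    stop("interval endpoints must be finite numbers", call. = FALSE)
  }
  if (any(iv$start_s < 0)) stop("interval start times must be >= 0", call. = FALSE)
  if (any(iv$end_s <= iv$start_s)) {
    i <- which(iv$end_s <= iv$start_s)[1]
    stop(sprintf(
      "empty or inverted interval [%g, %g)", iv$start_s[i], iv$end_s[i]
    ), call. = FALSE)
  }
  iv <- iv[order(iv$start_s, iv$end_s), ]
  if (nrow(iv) > 1) {
    overlap <- which(iv$start_s[-1] < iv$end_s[-nrow(iv)] - 1e-9)
    if (length(overlap) > 0) {
      i <- overlap[1]
      stop(sprintf(
        "overlapping intervals: [%g, %g) %s and [%g, %g) %s",
        iv$start_s[i], iv$end_s[i], iv$label[i],
        iv$start_s[i + 1], iv$end_s[i + 1], iv$label[i + 1]
      ), call. = FALSE)
    }
    gap <- which(iv$start_s[-1] > iv$end_s[-nrow(iv)] + 1e-9)
    if (length(gap) > 0) {
      i <- gap[1]
      stop(sprintf(
        "gap in coverage: [%g, %g) is unannotated",
        iv$end_s[i], iv$start_s[i + 1]
      ), call. = FALSE)
    }
  }
  if (abs(iv$start_s[1]) > 1e-9) {
    stop(sprintf("gap in coverage: [0, %g) is unannotated", iv$start_s[1]),
      call. = FALSE
    )
  }
  if (is.null(duration_s)) duration_s <- iv$end_s[nrow(iv)]
  if (abs(iv$end_s[nrow(iv)] - duration_s) > 1e-9) {
    stop(sprintf(
      "gap in coverage: [%g, %g) is unannotated",
      iv$end_s[nrow(iv)], duration_s
    ), call. = FALSE)
  }
  # merge adjacent equal-label intervals (normalized form)
  keep <- c(TRUE, iv$label[-1] != iv$label[-nrow(iv)])
  run <- cumsum(keep)
  out <- tibble::tibble(
    start_s = iv$start_s[keep],
    end_s = as.numeric(tapply(iv$end_s, run, max)),
    label = iv$label[keep]
  )
  new_annotation_track(out, video_id, duration_s, fps)
}

new_annotation_track <- function(tbl, video_id, duration_s, fps) {
  stopifnot(is.numeric(fps), fps > 0)
  structure(tbl,
    class = c("annotation_track", class(tibble::tibble())),
    video_id = as.character(video_id),
    duration_s = as.numeric(duration_s),
    fps = as.numeric(fps)
  )
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf(
    "<annotation_track> video '%s', %.1f s @ %g fps, %d interval(s)\n",
    attr(x, "video_id"), attr(x, "duration_s"), attr(x, "fps"), nrow(x)
  ))
  NextMethod()
}

#' Track metadata accessors
#' @param track An [annotation_track()].
#' @return The video id (character), duration in seconds, or frame rate.
#' @export
track_video_id <- function(track) attr(track, "video_id")

#' @rdname track_video_id
#' @export
track_duration <- function(track) attr(track, "duration_s")

#' @rdname track_video_id
#' @export
track_fps <- function(track) attr(track, "fps")

#' Read / write annotation tracks as interval CSV
#'
#' The on-disk dialect is a UTF-8 CSV with header
#' `video_id,start_s,end_s,label`, one interval per row, seconds as decimal
#' numbers and labels drawn from [frame_classes()]. Tracks are normalized on
#' load (sorted, equal-label neighbours merged) and validated: overlaps,
#' coverage gaps and unknown class tokens are errors, not warnings.
#' `save_track()` followed by `load_track()` is the identity on normalized
#' tracks.
#'
#' @param path Path of the CSV file.
#' @param fps Native frame rate to record on the loaded track.
#' @param duration_s Optional total duration; defaults to the last interval
#'   end.
#' @param track An [annotation_track()] to write.
#' @return `load_track()` returns an [annotation_track()]; `save_track()`
#'   returns `path` invisibly.
#' @export
load_track <- function(path, fps = 25, duration_s = NULL) {
  if (!file.exists(path)) stop("no such annotation file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("video_id", "start_s", "end_s", "label")
  if (!all(needed %in% names(df))) {
    stop(
      "annotation CSV must have header video_id,start_s,end_s,label",
      call. = FALSE
    )
  }
  if (nrow(df) == 0) {
    vid <- sub("\\.[^.]*$", "", basename(path))
    return(annotation_track(df, video_id = vid, fps = fps, duration_s = duration_s))
  }
  vid <- unique(df$video_id)
  if (length(vid) != 1) {
    stop("annotation CSV mixes video ids: ", paste(vid, collapse = ", "),
      call. = FALSE
    )
  }
  annotation_track(df, video_id = vid, fps = fps, duration_s = duration_s)
}

#' @rdname load_track
#' @export
save_track <- function(track, path) {
  stopifnot(inherits(track, "annotation_track"))
  df <- data.frame(
    video_id = rep(track_video_id(track), nrow(track)),
    start_s = track$start_s, end_s = track$end_s, label = track$label,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Class label at a timestamp
#'
#' Looks up the label of the unique half-open interval `[start_s, end_s)`
#' containing each timestamp.
#'
#' @param track An [annotation_track()].
#' @param t Numeric vector of timestamps in seconds, each in
#'   `[0, duration_s)`.
#' @return Character vector of frame class tokens, same length as `t`.
#' @export
class_at <- function(track, t) {
  stopifnot(inherits(track, "annotation_track"))
  dur <- track_duration(track)
  if (any(t < 0 | t >= dur)) {
    bad <- t[t < 0 | t >= dur][1]
    stop(sprintf(
      "timestamp %g s outside the annotated range [0, %g)", bad, dur
    ), call. = FALSE)
  }
  idx <- findInterval(t, track$start_s)
  track$label[idx]
}

#' Per-class frame counts and fractions over a set of tracks
#'
#' Counts frames at the native frame grid: frame `i` (0-based,
#' `i = 0 ... round(duration_s * fps) - 1`) lives at timestamp `i / fps` and
#' contributes to the class of the interval containing that timestamp.
#' Fractions are counts over the grand total, so they sum to 1.
#'
#' @param tracks A single [annotation_track()] or a list of them.
#' @param fps Frame rate at which to count; defaults to each track's own
#'   `fps`.
#' @return A tibble with one row per frame class (canonical order) and
#'   columns `label`, `frame_count`, `fraction`.
#' @export
class_distribution <- function(tracks, fps = NULL) {
  if (inherits(tracks, "annotation_track")) tracks <- list(tracks)
  if (length(tracks) == 0) stop("no tracks given", call. = FALSE)
  counts <- stats::setNames(rep(0, 5), frame_classes())
  for (tr in tracks) {
    f <- if (is.null(fps)) track_fps(tr) else fps
    n <- round(track_duration(tr) * f)
    if (n == 0) next
    # frames within each interval: i in [start*f, end*f) intersected with grid
    lo <- pmin(pmax(ceiling(tr$start_s * f - 1e-9), 0), n)
    hi <- pmin(pmax(ceiling(tr$end_s * f - 1e-9), 0), n)
    per <- hi - lo
    for (k in seq_len(nrow(tr))) {
      counts[tr$label[k]] <- counts[tr$label[k]] + per[k]
    }
  }
  total <- sum(counts)
  if (total == 0) stop("tracks contain no frames", call. = FALSE)
  tibble::tibble(
    label = frame_classes(),
    frame_count = unname(counts),
    fraction = unname(counts) / total
  )
}

#' Video metadata record
#'
#' Describes one video of the corpus: procedure category (one of
#' [procedure_categories()]), free-text operation type, duration, frame rate
#' and resolution. Used by [stratified_kfold()] to balance folds.
#'
#' @param video_id Identifier.
#' @param category One of the four procedure categories.
#' @param operation_type Free-text operation type (e.g. "cholecystectomy").
#' @param duration_s Duration in seconds (> 0).
#' @param fps Frame rate (> 0).
#' @param width,height Frame size in pixels.
#' @return A one-row tibble.
#' @export
video_record <- function(video_id, category, operation_type, duration_s,
                         fps = 25, width = 960, height = 540) {
  category <- match.arg(category, procedure_categories())
  stopifnot(duration_s > 0, fps > 0)
  tibble::tibble(
    video_id = as.character(video_id), category = category,
    operation_type = as.character(operation_type),
    duration_s = as.numeric(duration_s), fps = as.numeric(fps),
    width = as.integer(width), height = as.integer(height)
  )
}
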