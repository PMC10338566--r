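#' Default appearance model for synthetic laparoscopy frames
#'
#' Each frame class gets a mean RGB colour, a smooth texture field and
#' class-specific structure: trocar classes draw a dark vignette ring around
#' a central disc, outside classes scatter skin-coloured patches on a
#' surgical-drape background, and the cleaning class streaks the image
#' horizontally to mimic motion blur from wiping the lens. Colours are
#' chosen so that inside and outside frames are linearly separable on mean
#' channel statistics: the abdominal cavity is red-dominant, the operating
#' room drape blue-dominant (the mean colours differ by well over 0.2 in the
#' red and blue channels).
#'
#' @return A named list, one entry per frame class, with components
#'   `color` (RGB triple in `[0,1]`), `texture_scale` (pixels),
#'   `texture_amp` (`[0,1]`), and optional `vignette_radius` (fraction of
#'   the frame diagonal), `skin` (patch colour + density), `blur_len`
#'   (pixels).
#' @export
default_appearance <- function() {
  list(
    ABDOMINAL_CAVITY = list(
      color = c(0.58, 0.16, 0.12), texture_scale = 18, texture_amp = 0.10
    ),
    TROCAR = list(
      color = c(0.16, 0.07, 0.06), texture_scale = 10, texture_amp = 0.04,
      vignette_radius = 0.38
    ),
    OUTSIDE = list(
      color = c(0.22, 0.34, 0.58), texture_scale = 24, texture_amp = 0.08,
      skin = list(color = c(0.85, 0.64, 0.52), density = 0.25)
    ),
    CLEANING = list(
      color = c(0.72, 0.78, 0.88), texture_scale = 12, texture_amp = 0.12,
      blur_len = 9
    ),
    TRANSLUCENT_TROCAR = list(
      color = c(0.62, 0.47, 0.40), texture_scale = 10, texture_amp = 0.06,
      vignette_radius = 0.38
    )
  )
}

#' Default class time-share targets and segment-length means
#'
#' The targets mirror the class imbalance of real annotated laparoscopy
#' corpora: the abdominal cavity dominates (~81.4% of frames), the outside
#' operation site is the main minority class (~16.1%), and trocar passages,
#' lens cleaning and translucent-trocar glimpses are rare. Segment lengths
#' are multi-second by construction — classes appear as extended runs, never
#' as isolated frames.
#'
#' @return Named list with `fractions` (per-class time share, sums to 1) and
#'   `mean_s` (per-class mean segment duration, seconds).
#' @export
default_scenario_params <- function() {
  list(
    fractions = c(
      ABDOMINAL_CAVITY = 0.8139, TROCAR = 0.0139, OUTSIDE = 0.1607,
      CLEANING = 0.0108, TRANSLUCENT_TROCAR = 0.0007
    ),
    mean_s = c(
      ABDOMINAL_CAVITY = 90, TROCAR = 4, OUTSIDE = 25,
      CLEANING = 10, TRANSLUCENT_TROCAR = 2.5
    )
  )
}

#' Sample a synthetic video scenario
#'
#' Draws an ordered list of `(class, duration)` segments whose expected
#' per-class time share equals the requested fractions. Classes are drawn
#' with probability proportional to `fraction / mean_duration` and segment
#' durations from a shifted gamma distribution (shape 2, minimum 2 s) with
#' the per-class mean, so each class occupies contiguous multi-second runs:
#' long inside runs, short trocar transits, 1–4 s translucent-trocar
#' glimpses. The final segment is cut at the video end.
#'
#' @param rng_seed Integer seed; the same seed yields an identical scenario.
#' @param duration_s Total video duration in seconds.
#' @param params List with `fractions` and `mean_s` as in
#'   [default_scenario_params()]. Fractions must be non-negative and sum
#'   to 1; classes with zero fraction are never drawn.
#' @param video_id Identifier stored in the scenario.
#' @param fps,width,height Render geometry (defaults are the desk-scale
#'   render: 160x90 at 5 fps).
#' @param transition_s Cross-fade length at segment boundaries, seconds.
#' @param noise_sd Standard deviation of the per-frame additive noise.
#' @return A `scenario_spec` object: list with `video_id`, `fps`, `width`,
#'   `height`, `segments` (tibble `label`, `duration_s`), `transition_s`,
#'   `noise_sd`, `seed`.
#' @export
sample_scenario <- function(rng_seed, duration_s = 180,
                            params = default_scenario_params(),
                            video_id = sprintf("synth%05d", rng_seed %% 100000L),
                            fps = 5, width = 160, height = 90,
                            transition_s = 0.5, noise_sd = 0.02) {
  fr <- params$fractions[frame_classes()]
  if (anyNA(fr) || any(fr < 0)) {
    stop("class fractions must be named, non-negative and cover all classes",
      call. = FALSE
    )
  }
  if (abs(sum(fr) - 1) > 1e-6) stop("class fractions must sum to 1", call. = FALSE)
  if (all(fr[c("OUTSIDE", "CLEANING", "TRANSLUCENT_TROCAR")] == 0) &&
    all(fr[c("ABDOMINAL_CAVITY", "TROCAR")] == 0)) {
    stop("infeasible fractions", call. = FALSE)
  }
  m <- params$mean_s[frame_classes()]
  stopifnot(!anyNA(m), all(m > 0), duration_s > 0)
  d_min <- 2
  prob <- ifelse(fr > 0, fr / m, 0)
  prob <- prob / sum(prob)
  draw_len <- function(mu) {
    if (mu <= d_min) mu else d_min + stats::rgamma(1, shape = 2, rate = 2 / (mu - d_min))
  }
  labels <- character()
  durs <- numeric()
  with_seed(as.integer(rng_seed), {
    # stationary start: the window opens mid-segment, so the first class is
    # drawn by time share, its total length from the length-biased law, and
    # the window sees a uniform residual — expected per-class time share in
    # any window then equals the requested fractions exactly
    lab <- sample(frame_classes(), 1, prob = fr)
    mu <- m[[lab]]
    D <- if (mu <= d_min) {
      mu
    } else {
      my <- mu - d_min
      if (stats::runif(1) < d_min / (d_min + my)) {
        d_min + stats::rgamma(1, shape = 2, rate = 2 / my)
      } else {
        d_min + stats::rgamma(1, shape = 3, rate = 2 / my)
      }
    }
    labels <- lab
    durs <- min(D * stats::runif(1), duration_s)
    total <- durs
    while (total < duration_s) {
      lab <- sample(frame_classes(), 1, prob = prob)
      d <- min(draw_len(m[[lab]]), duration_s - total)
      labels <- c(labels, lab)
      durs <- c(durs, d)
      total <- total + d
    }
  })
  # a cut-off final sliver too short for a clean cross-fade is folded into
  # its predecessor
  n <- length(durs)
  if (n > 1 && durs[n] < max(0.5, 2 * transition_s)) {
    durs[n - 1] <- durs[n - 1] + durs[n]
    labels <- labels[-n]
    durs <- durs[-n]
  }
  # consecutive draws of the same class form one segment
  keep <- c(TRUE, labels[-1] != labels[-length(labels)])
  run <- cumsum(keep)
  durs <- as.numeric(tapply(durs, run, sum))
  labels <- labels[keep]
  structure(
    list(
      video_id = video_id, fps = fps, width = as.integer(width),
      height = as.integer(height),
      segments = tibble::tibble(label = labels, duration_s = durs),
      transition_s = transition_s, noise_sd = noise_sd,
      seed = as.integer(rng_seed)
    ),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec> '%s': %d segment(s), %.1f s @ %g fps, %dx%d, seed %d\n",
    x$video_id, nrow(x$segments), sum(x$segments$duration_s), x$fps,
    x$width, x$height, x$seed
  ))
  invisible(x)
}

#' Ground-truth annotation track of a scenario
#'
#' The returned track tiles the scenario duration with its segments; frames
#' inside a cross-fade keep the hard label of the segment that owns their
#' timestamp (transitions blur pixels, never labels).
#'
#' @param spec A `scenario_spec`.
#' @return An [annotation_track()].
#' @export
scenario_track <- function(spec) {
  ends <- cumsum(spec$segments$duration_s)
  starts <- c(0, ends[-length(ends)])
  annotation_track(
    data.frame(start_s = starts, end_s = ends, label = spec$segments$label),
    video_id = spec$video_id, fps = spec$fps, duration_s = ends[length(ends)]
  )
}

#' Serialize scenarios as YAML
#' @param spec A `scenario_spec`.
#' @param path File path.
#' @return `load_scenario()` returns a `scenario_spec`; `save_scenario()`
#'   returns `path` invisibly.
#' @export
save_scenario <- function(spec, path) {
  yaml::write_yaml(list(
    video_id = spec$video_id, fps = spec$fps, width = spec$width,
    height = spec$height, transition_s = spec$transition_s,
    noise_sd = spec$noise_sd, seed = spec$seed,
    segments = lapply(seq_len(nrow(spec$segments)), function(i) {
      list(
        label = spec$segments$label[i],
        duration_s = spec$segments$duration_s[i]
      )
    })
  ), path)
  invisible(path)
}

#' @rdname save_scenario
#' @export
load_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  structure(
    list(
      video_id = y$video_id, fps = y$fps, width = as.integer(y$width),
      height = as.integer(y$height),
      segments = tibble::tibble(
        label = vapply(y$segments, `[[`, "", "label"),
        duration_s = vapply(y$segments, function(s) as.numeric(s$duration_s), 0)
      ),
      transition_s = y$transition_s, noise_sd = y$noise_sd,
      seed = as.integer(y$seed)
    ),
    class = "scenario_spec"
  )
}

scenario_duration <- function(spec) sum(spec$segments$duration_s)

# smooth deterministic texture field in [-1,1], fixed given geometry and class
texture_field <- function(h, w, scale, phase) {
  x <- matrix(seq_len(w), h, w, byrow = TRUE)
  y <- matrix(seq_len(h), h, w)
  sin(2 * pi * x / scale + phase) * cos(2 * pi * y / (scale * 1.3) + 2 * phase) * 0.5 +
    sin(2 * pi * (x + y) / (scale * 2.1) + 3 * phase) * 0.5
}

render_class_frame <- function(spec, class, appearance) {
  h <- spec$height
  w <- spec$width
  ap <- appearance[[class]]
  tex <- texture_field(h, w, ap$texture_scale, phase = match(class, frame_classes()))
  img <- array(0, c(h, w, 3))
  for (c in 1:3) img[, , c] <- ap$color[c] * (1 + ap$texture_amp * tex)
  cx <- (w + 1) / 2
  cy <- (h + 1) / 2
  r <- sqrt(outer(((seq_len(h) - cy) / h)^2, ((seq_len(w) - cx) / h)^2, "+"))
  if (class == "ABDOMINAL_CAVITY") {
    # radial brightening toward the optical centre
    gain <- 1.25 - 0.9 * pmin(r / 0.9, 1)
    for (c in 1:3) img[, , c] <- img[, , c] * gain
  }
  if (!is.null(ap$vignette_radius)) {
    # dark ring outside the trocar bore; interior keeps the class colour
    ring <- 1 / (1 + exp(-(r - ap$vignette_radius) / 0.02))
    for (c in 1:3) img[, , c] <- img[, , c] * (1 - 0.95 * ring) + 0.02 * ring
  }
  if (!is.null(ap$skin)) {
    # deterministic skin-coloured patches (draped patient / staff)
    patch <- texture_field(h, w, ap$texture_scale * 2.5, phase = 7.3)
    mask <- patch > stats::quantile(patch, 1 - ap$skin$density)
    for (c in 1:3) {
      ch <- img[, , c]
      ch[mask] <- ap$skin$color[c]
      img[, , c] <- ch
    }
  }
  if (!is.null(ap$blur_len)) {
    # horizontal streaking: running mean along rows
    k <- ap$blur_len
    for (c in 1:3) {
      ch <- img[, , c]
      cs <- cbind(0, t(apply(ch, 1, cumsum)))
      idx <- seq_len(w)
      lo <- pmax(idx - k %/% 2, 0)
      hi <- pmin(idx + k %/% 2, w)
      img[, , c] <- (cs[, hi + 1, drop = FALSE] - cs[, lo + 1, drop = FALSE]) /
        matrix(hi - lo, h, w, byrow = TRUE)
    }
  }
  img
}

#' Render one synthetic frame
#'
#' Deterministic given `(spec, t)`: the frame is the appearance-model render
#' of the class owning timestamp `t`, cross-faded linearly with the
#' neighbouring class within `transition_s` of a segment boundary, plus
#' seeded additive Gaussian noise (seeded by the scenario seed and the frame
#' index, so repeated calls are bit-identical).
#'
#' @param spec A `scenario_spec`.
#' @param t Timestamp in seconds, `0 <= t <` total duration.
#' @param appearance Appearance model, see [default_appearance()].
#' @return `height x width x 3` array in `[0,1]`.
#' @export
render_frame <- function(spec, t, appearance = default_appearance()) {
  dur <- scenario_duration(spec)
  if (t < 0 || t >= dur) {
    stop(sprintf("timestamp %g s outside [0, %g)", t, dur), call. = FALSE)
  }
  ends <- cumsum(spec$segments$duration_s)
  starts <- c(0, ends[-length(ends)])
  i <- findInterval(t, starts)
  img <- render_class_frame(spec, spec$segments$label[i], appearance)
  tr <- spec$transition_s
  if (tr > 0) {
    # linear cross-fade into the neighbouring segment's class
    if (i > 1 && t - starts[i] < tr) {
      wgt <- 0.5 + 0.5 * (t - starts[i]) / tr
      other <- render_class_frame(spec, spec$segments$label[i - 1], appearance)
      img <- wgt * img + (1 - wgt) * other
    } else if (i < length(ends) && ends[i] - t < tr) {
      wgt <- 0.5 + 0.5 * (ends[i] - t) / tr
      other <- render_class_frame(spec, spec$segments$label[i + 1], appearance)
      img <- wgt * img + (1 - wgt) * other
    }
  }
  if (spec$noise_sd > 0) {
    frame_idx <- floor(t * spec$fps + 1e-9)
    noise_seed <- as.integer((as.double(spec$seed) * 7919 + frame_idx) %% 2147483629)
    with_seed(as.integer(noise_seed), {
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
    })
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Render a scenario to a video file plus its ground-truth track
#'
#' Writes `round(duration * fps)` frames to a multi-page TIFF stack (8-bit
#' RGB, deflate-compressed) — the lossless interchange container used
#' throughout the package — and returns the ground-truth annotation track.
#' Containers requiring an external codec (`.mp4`, `.avi`, `.mov`) are
#' refused with an error naming the container.
#'
#' @param spec A `scenario_spec`.
#' @param out Output path; extension must be `.tif` / `.tiff`.
#' @param appearance Appearance model.
#' @return Invisibly, a list with `path`, `track` (the ground-truth
#'   [annotation_track()]) and `n_frames`.
#' @export
render_video <- function(spec, out, appearance = default_appearance()) {
  ext <- tolower(tools::file_ext(out))
  if (ext %in% c("mp4", "avi", "mov", "mkv")) {
    stop(sprintf(
      "no codec available for container '.%s'; use a .tiff frame stack", ext
    ), call. = FALSE)
  }
  if (!ext %in% c("tif", "tiff")) {
    stop("output container must be .tif/.tiff", call. = FALSE)
  }
  n <- round(scenario_duration(spec) * spec$fps)
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    frames[[i]] <- render_frame(spec, (i - 1) / spec$fps, appearance)
  }
  write_video(frames, out)
  invisible(list(path = out, track = scenario_track(spec), n_frames = n))
}

#' Read / write frame stacks
#'
#' Videos are stored as multi-page 8-bit RGB TIFF stacks. `read_video()`
#' returns frames as `H x W x 3` arrays in `[0,1]`; `which` selects frame
#' indices (1-based) to read, for chunked processing of long videos.
#'
#' @param frames List of `H x W x 3` arrays in `[0,1]`.
#' @param path File path (`.tif`/`.tiff`).
#' @param which Optional integer vector of frame indices to read.
#' @return `read_video()` returns a list of arrays; `video_length()` the
#'   frame count.
#' @export
write_video <- function(frames, path) {
  stopifnot(is.list(frames), length(frames) > 0)
  tiff::writeTIFF(frames, path, bits.per.sample = 8L, compression = "deflate")
  invisible(path)
}

#' @rdname write_video
#' @export
read_video <- function(path, which = NULL) {
  if (!file.exists(path)) stop("no such video: ", path, call. = FALSE)
  out <- if (is.null(which)) {
    tiff::readTIFF(path, all = TRUE)
  } else {
    tiff::readTIFF(path, all = which)
  }
  if (!is.list(out)) out <- list(out)
  lapply(out, function(f) {
    if (length(dim(f)) == 2) f <- array(rep(f, 3), c(dim(f), 3))
    f[, , 1:3, drop = FALSE]
  })
}

#' @rdname write_video
#' @export
video_length <- function(path) {
  # walk the TIFF IFD chain; avoids decoding any pixel data
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 4)
  endian <- if (identical(hdr[1:2], charToRaw("II"))) "little" else "big"
  off <- readBin(con, "integer", 1, size = 4, endian = endian)
  n <- 0L
  while (off != 0) {
    n <- n + 1L
    seek(con, off)
    n_entries <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
    seek(con, off + 2 + 12 * n_entries)
    off <- readBin(con, "integer", 1, size = 4, endian = endian)
  }
  n
}

# run code with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
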