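test_that("symmetric smoothing removes short islands; privacy_safe never unflags outside", {
  tl <- label_timeline(c("INSIDE", "INSIDE", "OUTSIDE", "INSIDE", "INSIDE"))
  sym <- smooth_timeline(tl, redaction_policy(smoothing = "symmetric"))
  expect_equal(sym$labels, rep("INSIDE", 5))

  safe <- smooth_timeline(tl, redaction_policy(smoothing = "privacy_safe"))
  expect_equal(safe$labels, tl$labels) # outside is never flipped to inside

  # inside island inside outside footage is censored under both modes
  tl2 <- label_timeline(c("OUTSIDE", "OUTSIDE", "INSIDE", "OUTSIDE", "OUTSIDE"))
  expect_equal(
    smooth_timeline(tl2, redaction_policy(smoothing = "privacy_safe"))$labels,
    rep("OUTSIDE", 5)
  )

  # runs at the edges are never reassigned
  tl3 <- label_timeline(c("OUTSIDE", "INSIDE", "INSIDE", "INSIDE", "INSIDE"))
  expect_equal(
    smooth_timeline(tl3, redaction_policy(smoothing = "symmetric"))$labels,
    tl3$labels
  )

  # off mode is the identity
  expect_equal(
    smooth_timeline(tl, redaction_policy(smoothing = "off"))$labels,
    tl$labels
  )
})

test_that("smoothing matches the brute-force fixpoint simulator on random timelines", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(5:60, 1)
    labs <- sample(binary_classes(), n, replace = TRUE, prob = c(0.7, 0.3))
    rate <- sample(c(1, 2), 1)
    min_s <- sample(c(1, 2, 3), 1)
    for (mode in c("symmetric", "privacy_safe")) {
      got <- smooth_timeline(
        label_timeline(labs, rate),
        redaction_policy(min_island_s = min_s, smoothing = mode)
      )$labels
      want <- brute_smooth(labs, rate, min_s, privacy_safe = mode == "privacy_safe")
      expect_equal(got, want)
      # switches never increase
      expect_lte(length(rle(got)$lengths), length(rle(labs)$lengths))
      if (mode == "privacy_safe") {
        expect_gte(sum(got == "OUTSIDE"), sum(labs == "OUTSIDE"))
      }
    }
  }
})

test_that("expansion covers every native frame, trailing frames inherit the last label", {
  tl <- label_timeline(c("INSIDE", "OUTSIDE", "INSIDE"))
  ex <- expand_timeline(tl, native_fps = 25, frame_count = 75)
  expect_equal(ex, rep(tl$labels, each = 25))

  ex76 <- expand_timeline(tl, native_fps = 25, frame_count = 76)
  expect_equal(ex76[76], "INSIDE")
  expect_equal(ex76[1:75], ex)

  expect_error(
    expand_timeline(label_timeline(character()), 25, 10),
    "empty timeline"
  )

  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(3:30, 1)
    labs <- sample(binary_classes(), n, replace = TRUE)
    rate <- sample(c(1, 2, 5), 1)
    fps <- sample(c(5, 24, 25), 1)
    count <- sample(1:(ceiling(n / rate * fps) + fps), 1)
    tl <- label_timeline(labs, rate)
    expect_equal(
      expand_timeline(tl, fps, count),
      brute_expand(labs, rate, fps, count)
    )
  }
})

test_that("redaction censors exactly the outside-labelled native frames", {
  sp <- sample_scenario(30, duration_s = 60)
  sp$segments <- tibble::tibble(
    label = c("ABDOMINAL_CAVITY", "OUTSIDE"), duration_s = c(40, 20)
  )
  vid <- withr::local_tempfile(fileext = ".tiff")
  res <- render_video(sp, vid)
  labels <- to_binary(class_at(res$track, (0:299) / 5))

  out <- withr::local_tempfile(fileext = ".tiff")
  man <- redact_video(vid, labels, redaction_policy("black"), out)
  expect_equal(man$n_frames, 300)
  expect_equal(man$n_censored, 100)
  expect_equal(man$censored_ranges, list(c(200, 300))) # half-open, 0-based

  dec <- read_video(out)
  censored_means <- vapply(dec[201:300], mean, 0)
  expect_true(all(censored_means == 0))
  # inside frames pass through (8-bit quantization only)
  orig <- read_video(vid, which = c(1, 100))
  expect_identical(dec[[1]], orig[[1]])
  expect_identical(dec[[100]], orig[[2]])

  # redaction is idempotent in black mode
  out2 <- withr::local_tempfile(fileext = ".tiff")
  redact_video(out, labels, redaction_policy("black"), out2)
  dec2 <- read_video(out2)
  expect_identical(
    vapply(dec2[201:300], mean, 0),
    vapply(dec[201:300], mean, 0)
  )

  # no outside-labelled frame survives uncensored
  expect_true(all(vapply(dec[which(labels == "OUTSIDE")], mean, 0) == 0))
})

test_that("all-inside and all-outside label vectors behave at the extremes", {
  sp <- sample_scenario(31, duration_s = 10)
  vid <- withr::local_tempfile(fileext = ".tiff")
  render_video(sp, vid)
  out <- withr::local_tempfile(fileext = ".tiff")

  man_in <- redact_video(vid, rep("INSIDE", 50), redaction_policy("black"), out)
  expect_equal(man_in$n_censored, 0)
  expect_equal(man_in$censored_ranges, list())

  man_out <- redact_video(vid, rep("OUTSIDE", 50), redaction_policy("black"), out)
  expect_equal(man_out$n_censored, 50)
  expect_true(all(vapply(read_video(out), mean, 0) == 0))
})

test_that("blur mode obscures content with a kernel of at least 1/8 frame width", {
  sp <- sample_scenario(32, duration_s = 4)
  vid <- withr::local_tempfile(fileext = ".tiff")
  render_video(sp, vid)
  out <- withr::local_tempfile(fileext = ".tiff")
  redact_video(vid, rep("OUTSIDE", 20), redaction_policy("blur"), out)
  orig <- read_video(vid, which = 1)[[1]]
  blur <- read_video(out, which = 1)[[1]]
  # heavy blur wipes out local detail: horizontal gradients collapse
  grad <- function(f) mean(abs(f[, -1, ] - f[, -dim(f)[2], ]))
  expect_lt(grad(blur), 0.3 * grad(orig))
  expect_gt(mean(blur), 0) # not black
})

test_that("a label/frame count mismatch aborts before writing any output", {
  sp <- sample_scenario(33, duration_s = 10)
  vid <- withr::local_tempfile(fileext = ".tiff")
  render_video(sp, vid)
  out <- file.path(withr::local_tempdir(), "anon.tiff")
  expect_error(
    redact_video(vid, rep("OUTSIDE", 10), redaction_policy(), out),
    "refusing"
  )
  expect_false(file.exists(out))
})

test_that("label tables round-trip through CSV and manifests serialize", {
  labs <- tibble::tibble(
    video_id = "v1", timestamp_s = 0:9,
    label = rep(c("INSIDE", "OUTSIDE"), 5)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  save_labels(labs, path)
  expect_equal(load_labels(path), labs)

  man <- list(
    video = "a.tiff", out = "b.tiff", mode = "black", n_frames = 10,
    n_censored = 5, censored_ranges = list(c(0, 5))
  )
  mp <- withr::local_tempfile(fileext = ".json")
  save_manifest(man, mp)
  parsed <- jsonlite::read_json(mp)
  expect_equal(parsed$n_censored, 5)
})
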