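#' Run the full pipeline on a synthetic study corpus
#'
#' Generates a seeded corpus of synthetic laparoscopy-like videos with the
#' default class imbalance, runs stratified k-fold cross-validation of the
#' binary inside/outside classifier, and (optionally) anonymizes every
#' held-out video with its predicted labels — smoothing them with the
#' privacy-safe rule, expanding to native frame rate, censoring, and
#' verifying the censored frames by decoding the output. Every stage is
#' driven by `seed`, so the whole study is exactly reproducible.
#'
#' Videos are rendered at the desk-scale default geometry (160x90 at
#' 5 fps); durations are drawn uniformly from `duration_range`. Operation
#' types are assigned from a small synthetic roster so fold stratification
#' balances type and duration as it would on a real corpus.
#'
#' @param seed Master seed for corpus generation, fold assignment, weight
#'   initialization, shuffling and dropout.
#' @param n_videos Number of synthetic videos (default 20).
#' @param duration_range Video duration range in seconds (default 120-300).
#' @param k Cross-validation folds (default 5).
#' @param epochs Training epochs per fold (default 5).
#' @param lr Adam learning rate for the study (default 1e-2, matched to the
#'   tiny backbone widths and the short schedule).
#' @param redact If `TRUE`, render and censor each held-out video and
#'   verify the censoring frame by frame (files are written to `dir` and
#'   removed after verification).
#' @param dir Scratch directory for rendered videos.
#' @return List with `cv` (see [run_cross_validation()]), `glance` (pooled
#'   one-row summary), and `redaction` (per-video tibble: `video_id`,
#'   `n_frames`, `n_censored`, `uncensored_pred_outside`,
#'   `uncensored_true_outside` — the last two are 0 when censoring is
#'   airtight).
#' @export
synthetic_study <- function(seed = 0, n_videos = 20,
                            duration_range = c(120, 300), k = 5, epochs = 5,
                            lr = 1e-2, redact = TRUE, dir = tempdir()) {
  corpus <- study_corpus(seed, n_videos, duration_range)
  specs <- corpus$specs
  cv <- run_cross_validation(
    specs, corpus$tracks,
    k = k,
    config = train_config(epochs = epochs, lr = lr, seed = seed),
    mconfig = model_config(num_classes = 2),
    videos = corpus$videos
  )
  red <- NULL
  if (redact) {
    rows <- lapply(names(specs), function(id) {
      sp <- specs[[id]]
      preds <- dplyr::bind_rows(
        lapply(cv$fold_results, function(fr) fr$predictions)
      )
      preds <- preds[preds$video_id == id, ]
      tl <- smooth_timeline(label_timeline(preds$pred, 1), redaction_policy())
      vid <- file.path(dir, paste0(id, ".tiff"))
      out <- file.path(dir, paste0(id, "_anon.tiff"))
      on.exit(unlink(c(vid, out)), add = TRUE)
      res <- render_video(sp, vid)
      frame_labels <- expand_timeline(tl, native_fps = sp$fps, res$n_frames)
      man <- redact_video(vid, frame_labels, redaction_policy("black"), out)
      # verify: decode every censored frame; an uncensored frame whose
      # prediction (or truth and prediction) is OUTSIDE is a pipeline breach
      truth <- to_binary(class_at(res$track, (seq_len(res$n_frames) - 1) / sp$fps))
      pred_out <- frame_labels == "OUTSIDE"
      censored_ok <- rep(TRUE, res$n_frames)
      if (any(pred_out)) {
        dec_cens <- read_video(out, which = which(pred_out))
        censored_ok[which(pred_out)] <-
          vapply(dec_cens, function(f) all(f == 0), TRUE)
      }
      uncens_pred <- sum(pred_out & !censored_ok)
      uncens_true <- sum(pred_out & truth == "OUTSIDE" & !censored_ok)
      tibble::tibble(
        video_id = id, n_frames = res$n_frames, n_censored = man$n_censored,
        uncensored_pred_outside = uncens_pred,
        uncensored_true_outside = uncens_true
      )
    })
    red <- dplyr::bind_rows(rows)
  }
  list(cv = cv, glance = glance(cv$pooled), redaction = red)
}

#' Build the seeded synthetic study corpus
#'
#' The corpus behind [synthetic_study()]: `n_videos` scenario specs with
#' uniformly drawn durations, their ground-truth tracks, and a video
#' metadata table with operation types drawn from a small synthetic roster
#' (so stratification has types to balance).
#'
#' @inheritParams synthetic_study
#' @return List with `specs`, `tracks` (both named by video id) and
#'   `videos` (tibble for [stratified_kfold()]).
#' @export
study_corpus <- function(seed = 0, n_videos = 20, duration_range = c(120, 300)) {
  types <- c(
    "cholecystectomy", "fundoplication", "right hemicolectomy",
    "proctocolectomy", "diagnostic laparoscopy", "adrenalectomy"
  )
  drawn <- with_seed(as.integer(seed), {
    list(
      durations = stats::runif(n_videos, duration_range[1], duration_range[2]),
      op = sample(types, n_videos, replace = TRUE)
    )
  })
  specs <- lapply(seq_len(n_videos), function(i) {
    sample_scenario(derive_seed(seed, 1000 + i),
      duration_s = drawn$durations[i],
      video_id = sprintf("study%02d", i)
    )
  })
  names(specs) <- vapply(specs, `[[`, "", "video_id")
  tracks <- lapply(specs, scenario_track)
  names(tracks) <- names(specs)
  list(
    specs = specs, tracks = tracks,
    videos = tibble::tibble(
      video_id = names(specs), operation_type = drawn$op,
      duration_s = drawn$durations
    )
  )
}
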