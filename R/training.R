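#' Training configuration
#'
#' Adam with fixed defaults (learning rate 1e-4, betas 0.9/0.999, epsilon
#' 1e-8), 5 epochs, batches of 8 sequences of 32 frames, focal loss with
#' `gamma = 2` and inverse-class-frequency `alpha` (normalized to mean 1).
#' One epoch is one full pass over the assembled training sequences; there
#' is no early stopping and no learning-rate schedule. A single seed
#' governs fold assignment, weight initialization, shuffling and dropout,
#' so runs are exactly reproducible.
#'
#' @param epochs Number of passes over the training sequences (>= 1).
#' @param lr,beta1,beta2,eps Adam hyper-parameters (`lr > 0`).
#' @param batch_size Sequences per gradient step.
#' @param seq_len Frames per sequence (default 32; at a 1 frame/s sampling
#'   rate one sequence spans 32 s of video).
#' @param seed Integer master seed.
#' @param task `"binary"` or `"multiclass"`.
#' @param gamma Focal-loss focusing exponent.
#' @param alpha Optional fixed per-class focal weights; `NULL` means
#'   inverse class frequency computed from the training labels.
#' @param mixed_precision Accepted for interface compatibility; a no-op on
#'   CPU.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 5, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, batch_size = 8, seq_len = 32, seed = 0,
                         task = c("binary", "multiclass"), gamma = 2,
                         alpha = NULL, mixed_precision = FALSE) {
  task <- match.arg(task)
  stopifnot(epochs >= 1, lr > 0, batch_size >= 1, seq_len >= 1)
  structure(list(
    epochs = as.integer(epochs), lr = lr, beta1 = beta1, beta2 = beta2,
    eps = eps, batch_size = as.integer(batch_size),
    seq_len = as.integer(seq_len), seed = as.integer(seed), task = task,
    gamma = gamma, alpha = alpha, mixed_precision = mixed_precision
  ), class = "train_config")
}

#' Read / write training configurations as YAML
#' @param config A [train_config()].
#' @param path File path.
#' @return `load_train_config()` returns a `train_config`;
#'   `save_train_config()` the path, invisibly.
#' @export
save_train_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_train_config
#' @export
load_train_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(train_config, y[!vapply(y, is.null, TRUE)])
}

#' Attach backbone features to a frame table
#'
#' @param model A `lap_model` (its frozen backbone is used).
#' @param frames Frame tibble from [sample_frames()].
#' @return The tibble with an added `feature` list-column; the `image`
#'   column is dropped to free memory.
#' @export
featurize_frames <- function(model, frames) {
  fm <- featurize(model, frames$image)
  frames$feature <- lapply(seq_len(nrow(fm)), function(i) fm[i, ])
  frames$image <- NULL
  frames
}

model_targets <- function(model, labels) {
  lab <- if (model$config$num_classes == 2) to_binary(labels) else labels
  yi <- match(lab, model$vocab)
  if (anyNA(yi)) stop("label outside the model vocabulary", call. = FALSE)
  yi
}

# inverse class frequency, normalized to mean 1 over present classes;
# absent classes get weight 0 (with a warning at the call site)
inverse_freq_alpha <- function(targets, n_classes) {
  cnt <- tabulate(targets, n_classes)
  alpha <- ifelse(cnt > 0, 1 / pmax(cnt, 1), 0)
  present <- cnt > 0
  alpha[present] <- alpha[present] / mean(alpha[present])
  alpha
}

#' Train the upper layers of a classifier
#'
#' Runs `epochs` full passes of mini-batch Adam over the training
#' sequences, backpropagating the focal loss through head, LSTM and FC
#' layer. Only the parameter groups in the model's `trainable_set` are
#' updated; the backbone (and any group outside the set) is bit-identical
#' after training. Fully deterministic given `config$seed`.
#'
#' @param model A `lap_model` from [build_model()].
#' @param frames Frame tibble with `video_id`, `timestamp_s`, `label` and a
#'   `feature` list-column (see [featurize_frames()]); all frames must come
#'   from training videos only.
#' @param config A [train_config()].
#' @return The trained `lap_model`, with a `loss_log` attribute: a tibble
#'   `epoch`, `mean_loss`.
#' @export
train_model <- function(model, frames, config = train_config()) {
  stopifnot(inherits(model, "lap_model"), inherits(config, "train_config"))
  if (is.null(frames$feature)) frames <- featurize_frames(model, frames)
  if (nrow(frames) == 0) stop("empty training set", call. = FALSE)
  seqs <- unlist(
    lapply(
      split(seq_len(nrow(frames)), frames$video_id),
      function(rows) {
        sub <- frames[rows, ]
        lapply(
          make_sequences(sub, L = config$seq_len, mode = "train"),
          function(s) rows[s$rows]
        )
      }
    ),
    recursive = FALSE
  )
  if (length(seqs) == 0) {
    stop("no training sequences (videos shorter than one sequence?)", call. = FALSE)
  }
  nc_ <- model$config$num_classes
  all_targets <- model_targets(model, frames$label)
  alpha <- config$alpha %||% inverse_freq_alpha(all_targets, nc_)
  if (any(tabulate(all_targets, nc_) == 0)) {
    missing <- model$vocab[tabulate(all_targets, nc_) == 0]
    warning(
      "class(es) absent from training labels (focal weight set to 0): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  feat_mat <- do.call(rbind, frames$feature)
  trainable <- intersect(c("fc", "lstm", "head"), translate_trainable(model$config$trainable_set))
  opt <- adam_init(model$params[trainable])
  step <- 0
  log <- numeric(config$epochs)
  L <- config$seq_len
  nf <- model$config$feature_dim
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(length(seqs))
      ep_loss <- 0
      ep_n <- 0
      for (bs in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        B <- length(bs)
        feats <- array(0, c(B, L, nf))
        targ <- matrix(0L, B, L)
        for (i in seq_len(B)) {
          rows <- seqs[[bs[i]]]
          feats[i, , ] <- feat_mat[rows, ]
          targ[i, ] <- all_targets[rows]
        }
        fw <- forward_features(model, feats, train = TRUE)
        S2 <- matrix(fw$scores, B * L, nc_)
        prob <- softmax_rows(S2)
        y <- as.integer(targ) # column-major matches array flattening
        loss <- focal_loss(prob, y, gamma = config$gamma, alpha = alpha)
        dS2 <- focal_loss_grad(prob, y, gamma = config$gamma, alpha = alpha)
        gr <- backward_features(model, fw$cache, dS2)
        step <- step + 1
        res <- adam_step(model$params[trainable], gr[trainable], opt, step,
          lr = config$lr, beta1 = config$beta1, beta2 = config$beta2,
          eps = config$eps
        )
        model$params[trainable] <- res$p
        opt <- res$s
        ep_loss <- ep_loss + loss * B
        ep_n <- ep_n + B
      }
      log[ep] <- ep_loss / ep_n
    }
  })
  attr(model, "loss_log") <- tibble::tibble(
    epoch = seq_len(config$epochs),
    mean_loss = log
  )
  model
}

# user-facing trainable_set uses "recurrent"; the parameter list uses "lstm"
translate_trainable <- function(set) {
  ifelse(set == "recurrent", "lstm", set)
}

#' Per-epoch loss log of a trained model
#' @param model A trained `lap_model`.
#' @return Tibble `epoch`, `mean_loss` (or `NULL` for an untrained model).
#' @export
loss_log <- function(model) attr(model, "loss_log")

#' Predict per-frame labels for one video
#'
#' Samples frames at `sample_rate`, cuts them into inference-mode sequences
#' (the trailing chunk padded by repeating its last frame), runs the
#' classifier and concatenates the unpadded predictions.
#'
#' @param model A trained `lap_model`.
#' @param source A `scenario_spec` or video file path.
#' @param track The video's [annotation_track()] (supplies duration, frame
#'   rate and ground-truth labels).
#' @param sample_rate Sampling rate in frames/second (default 1).
#' @param seq_len Sequence length (default 32).
#' @return Tibble `video_id`, `timestamp_s`, `truth`, `pred` (predicted
#'   tokens in the model's vocabulary).
#' @export
predict_video <- function(model, source, track, sample_rate = 1, seq_len = 32) {
  frames <- sample_frames(source, track, sample_rate)
  frames <- featurize_frames(model, frames)
  predict_frames(model, frames, seq_len)
}

#' @rdname predict_video
#' @param frames An already-featurized frame table for a single video
#'   (from [featurize_frames()]).
#' @export
predict_frames <- function(model, frames, seq_len = 32) {
  seqs <- make_sequences(frames, L = seq_len, mode = "inference")
  feat_mat <- do.call(rbind, frames$feature)
  preds <- lapply(seqs, function(s) {
    out <- forward(model, feat_mat[s$rows, , drop = FALSE])
    predict_labels(out$scores, pad_count = s$pad_count)
  })
  truth <- frames$label
  if (model$config$num_classes == 2) truth <- to_binary(truth)
  tibble::tibble(
    video_id = frames$video_id,
    timestamp_s = frames$timestamp_s,
    truth = truth,
    pred = unlist(preds)
  )
}

#' Stratified cross-validation of the full pipeline
#'
#' Builds a k-fold by-video split with [stratified_kfold()], then for each
#' fold trains on the other k-1 folds and predicts the held-out videos.
#' Frame features are extracted once (the backbone is frozen and shared);
#' the trainable layers are re-initialized per fold from a seed derived
#' from `config$seed`. Train and test video sets are disjoint in every run
#' by construction, and this is re-asserted before each fold is trained.
#'
#' @param sources Named list of video sources (`scenario_spec`s or file
#'   paths), names = video ids.
#' @param tracks Named list of [annotation_track()]s, same names.
#' @param k Number of folds (default 5).
#' @param config A [train_config()].
#' @param mconfig A [model_config()].
#' @param videos Optional [video_record()] tibble for stratification;
#'   defaults to one operation type with durations from the tracks.
#' @param sample_rate Sampling rate in frames/second.
#' @param verbose If `TRUE`, log per-fold progress via [message()].
#' @return List with `folds` (assignment tibble), `fold_results` (per fold:
#'   `model`, `report`, `predictions`), and `pooled` (the pooled
#'   [eval_report()] across folds).
#' @export
run_cross_validation <- function(sources, tracks, k = 5,
                                 config = train_config(),
                                 mconfig = model_config(),
                                 videos = NULL, sample_rate = 1,
                                 verbose = FALSE) {
  ids <- names(tracks)
  stopifnot(!is.null(ids), identical(sort(ids), sort(names(sources))))
  if (is.null(videos)) {
    videos <- tibble::tibble(
      video_id = ids, operation_type = "unspecified",
      duration_s = vapply(tracks, track_duration, 0)
    )
  }
  folds <- stratified_kfold(videos, k = k, seed = config$seed)
  base <- build_model(mconfig, seed = config$seed)
  frames_by_video <- lapply(ids, function(id) {
    featurize_frames(base, sample_frames(sources[[id]], tracks[[id]], sample_rate))
  })
  names(frames_by_video) <- ids
  fold_results <- vector("list", k)
  for (f in 0:(k - 1)) {
    test_ids <- folds$video_id[folds$fold == f]
    train_ids <- folds$video_id[folds$fold != f]
    stopifnot(length(intersect(test_ids, train_ids)) == 0) # leakage guard
    train_frames <- dplyr::bind_rows(frames_by_video[train_ids])
    stopifnot(all(train_frames$video_id %in% train_ids))
    if (verbose) {
      message(sprintf(
        "fold %d/%d: training on %d videos (%d frames), testing %d",
        f + 1, k, length(train_ids), nrow(train_frames), length(test_ids)
      ))
    }
    mod <- reinit_upper(base, seed = derive_seed(config$seed, f + 1))
    mod <- train_model(mod, train_frames, config)
    if (verbose) {
      ll <- loss_log(mod)
      message(sprintf(
        "fold %d/%d: epoch losses %s", f + 1, k,
        paste(sprintf("%.4f", ll$mean_loss), collapse = " ")
      ))
    }
    preds <- dplyr::bind_rows(lapply(
      test_ids,
      function(id) predict_frames(mod, frames_by_video[[id]], config$seq_len)
    ))
    rep <- eval_report(preds$truth, preds$pred, vocab = mod$vocab)
    fold_results[[f + 1]] <- list(model = mod, report = rep, predictions = preds)
  }
  pooled_cm <- confusion_from_counts(
    Reduce(`+`, lapply(fold_results, function(fr) unclass(fr$report$confusion)))
  )
  list(
    folds = folds,
    fold_results = fold_results,
    pooled = eval_report_from_cm(pooled_cm)
  )
}

# fresh seeded init of fc/lstm/head on top of an existing frozen backbone
reinit_upper <- function(model, seed) {
  fresh <- build_model(model$config, seed = seed)
  fresh$params$backbone <- model$params$backbone
  fresh
}

derive_seed <- function(seed, salt) {
  as.integer((as.double(seed) * 7919 + salt * 104729) %% 2147483647)
}
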