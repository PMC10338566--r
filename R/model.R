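#' Classifier configuration
#'
#' The sequence classifier is a frozen convolutional feature extractor
#' followed by trainable upper layers: dropout + fully connected layer
#' (ReLU), a stateless single-layer LSTM, dropout (50%) and a linear head
#' with 2 (binary) or 5 (multiclass) outputs. Only the layers named in
#' `trainable_set` receive gradient updates; the backbone never does.
#'
#' Two backbones are registered. `"tiny_conv"` (the default) is a small
#' three-block convolutional network with randomly initialized, frozen
#' filters and CPU-scale widths (feature dim 64, FC width 128, LSTM hidden
#' 64) — frozen random convolutions are a classical cheap feature extractor
#' and are sufficient for colour/texture-separable scenes.
#' `"alexnet_pretrained"` reproduces the full-scale configuration
#' (feature dim 9216, FC width 4096, LSTM hidden 512) and requires a weights
#' file; no download is ever attempted.
#'
#' @param backbone `"tiny_conv"` or `"alexnet_pretrained"`.
#' @param num_classes 2 (inside/outside) or 5 (full taxonomy).
#' @param fc_width Width of the fully connected layer after the backbone.
#' @param recurrent_hidden LSTM hidden size.
#' @param head_dropout Dropout fraction before the FC layer and the head.
#' @param trainable_set Subset of `c("fc", "recurrent", "head")`; the strict
#'   transfer-learning mode is `trainable_set = "head"`.
#' @param weights_file Path to serialized backbone weights (required for
#'   `alexnet_pretrained`).
#' @return A `model_config` list.
#' @export
model_config <- function(backbone = c("tiny_conv", "alexnet_pretrained"),
                         num_classes = 2,
                         fc_width = NULL, recurrent_hidden = NULL,
                         head_dropout = 0.5,
                         trainable_set = c("fc", "recurrent", "head"),
                         weights_file = NULL) {
  backbone <- match.arg(backbone)
  if (!num_classes %in% c(2L, 5L)) {
    stop("num_classes must be 2 or 5", call. = FALSE)
  }
  bad <- setdiff(trainable_set, c("fc", "recurrent", "head"))
  if (length(bad) > 0) {
    stop(
      "trainable_set may only contain fc, recurrent, head (the backbone is ",
      "always frozen); offending: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  defaults <- switch(backbone,
    tiny_conv = list(feature_dim = 64L, fc_width = 128L, hidden = 64L),
    alexnet_pretrained = list(feature_dim = 9216L, fc_width = 4096L, hidden = 512L)
  )
  structure(list(
    backbone = backbone,
    feature_dim = defaults$feature_dim,
    fc_width = as.integer(fc_width %||% defaults$fc_width),
    recurrent_hidden = as.integer(recurrent_hidden %||% defaults$hidden),
    head_dropout = head_dropout,
    num_classes = as.integer(num_classes),
    trainable_set = trainable_set,
    weights_file = weights_file
  ), class = "model_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

model_vocab <- function(num_classes) {
  if (num_classes == 2) binary_classes() else frame_classes()
}

# classes mapping to the privacy-critical binary OUTSIDE, per vocabulary
outside_indices <- function(vocab) {
  which(to_binary(vocab) == "OUTSIDE")
}

init_mat <- function(nr, nc, scale) matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)

#' Build a classifier
#'
#' Initializes all parameters deterministically from `seed`. The backbone's
#' filters are part of the returned model but are frozen: training never
#' modifies them.
#'
#' @param config A [model_config()].
#' @param seed Integer seed governing every random initialization.
#' @return A `lap_model` object (list with `params`, `config`, `vocab`).
#' @export
build_model <- function(config = model_config(), seed = 0) {
  stopifnot(inherits(config, "model_config"))
  with_seed(as.integer(seed), {
    backbone <- switch(config$backbone,
      tiny_conv = init_tiny_conv(),
      alexnet_pretrained = load_alexnet_weights(config$weights_file)
    )
    nf <- config$feature_dim
    nfc <- config$fc_width
    nh <- config$recurrent_hidden
    nc_ <- config$num_classes
    params <- list(
      backbone = backbone,
      fc = list(W = init_mat(nf, nfc, sqrt(2 / nf)), b = numeric(nfc)),
      lstm = list(
        Wx = init_mat(nfc, 4 * nh, 1 / sqrt(nfc)),
        Wh = init_mat(nh, 4 * nh, 1 / sqrt(nh)),
        b = numeric(4 * nh)
      ),
      head = list(W = init_mat(nh, nc_, 1 / sqrt(nh)), b = numeric(nc_))
    )
    structure(
      list(params = params, config = config, vocab = model_vocab(nc_)),
      class = "lap_model"
    )
  })
}

#' @export
print.lap_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<lap_model> %s backbone (frozen) -> fc %d -> lstm %d -> head %d\n",
    cfg$backbone, cfg$fc_width, cfg$recurrent_hidden, cfg$num_classes
  ))
  cat(
    " trainable:", paste(cfg$trainable_set, collapse = ", "),
    "| classes:", paste(x$vocab, collapse = ", "), "\n"
  )
  invisible(x)
}

# three conv blocks; input 224x224x3, output feature vector of length 64
# (16 channels x 2x2 spatial grid). The first mean-pool trades resolution
# for speed; the final 2x2 grid keeps coarse spatial layout (a trocar's
# dark ring looks different in centre vs corner cells).
init_tiny_conv <- function() {
  list(
    conv1 = list(W = init_mat(9 * 3, 8, sqrt(2 / 27)), b = numeric(8)),
    conv2 = list(W = init_mat(9 * 8, 16, sqrt(2 / 72)), b = numeric(16)),
    conv3 = list(W = init_mat(9 * 16, 16, sqrt(2 / 144)), b = numeric(16))
  )
}

load_alexnet_weights <- function(weights_file) {
  if (is.null(weights_file) || !file.exists(weights_file %||% "")) {
    stop(
      "the alexnet_pretrained backbone needs a local weights file ",
      "(RDS with the five convolution parameter matrices); none was given. ",
      "Use backbone = 'tiny_conv' for a self-contained model.",
      call. = FALSE
    )
  }
  readRDS(weights_file)
}

tiny_conv_features <- function(bk, frame) {
  x <- pool_mean(frame, 4) # 224 -> 56
  x <- relu(conv_forward(x, bk$conv1$W, bk$conv1$b, k = 3, pad = 1))
  x <- pool_mean(x, 2) # 56 -> 28
  x <- relu(conv_forward(x, bk$conv2$W, bk$conv2$b, k = 3, pad = 1))
  x <- pool_mean(x, 2) # 28 -> 14
  x <- relu(conv_forward(x, bk$conv3$W, bk$conv3$b, k = 3, pad = 1))
  as.numeric(pool_mean(x, 7)) # 2x2 grid x 16 channels = 64
}

alexnet_features <- function(bk, frame) {
  x <- relu(conv_forward(frame, bk$conv1$W, bk$conv1$b, k = 11, stride = 4, pad = 2))
  x <- pool_mean(x, 2)
  x <- relu(conv_forward(x, bk$conv2$W, bk$conv2$b, k = 5, pad = 2))
  x <- pool_mean(x, 2)
  x <- relu(conv_forward(x, bk$conv3$W, bk$conv3$b, k = 3, pad = 1))
  x <- relu(conv_forward(x, bk$conv4$W, bk$conv4$b, k = 3, pad = 1))
  x <- relu(conv_forward(x, bk$conv5$W, bk$conv5$b, k = 3, pad = 1))
  as.numeric(pool_mean(x, 2))
}

#' Extract frozen backbone features for preprocessed frames
#'
#' Because the backbone is frozen, per-frame features can be computed once
#' and reused across epochs and folds — this is what makes CPU-scale
#' training practical.
#'
#' @param model A `lap_model`.
#' @param frames List of preprocessed `224 x 224 x 3` arrays.
#' @return Numeric matrix, one row per frame, `feature_dim` columns.
#' @export
featurize <- function(model, frames) {
  fe <- switch(model$config$backbone,
    tiny_conv = tiny_conv_features,
    alexnet_pretrained = alexnet_features
  )
  t(vapply(
    frames, function(f) fe(model$params$backbone, f),
    numeric(model$config$feature_dim)
  ))
}

# core forward on cached features.
# feats: B x L x feature_dim array. train = TRUE samples dropout masks from
# the current RNG state and returns caches for backprop.
forward_features <- function(model, feats, train = FALSE) {
  p <- model$params
  d <- dim(feats)
  B <- d[1]
  L <- d[2]
  nf <- d[3]
  pdrop <- if (train) model$config$head_dropout else 0
  F2 <- matrix(aperm(feats, c(1, 2, 3)), B * L, nf)
  m1 <- if (train) dropout_mask(c(B * L, nf), pdrop) else NULL
  F2d <- if (is.null(m1)) F2 else F2 * m1
  A <- F2d %*% p$fc$W
  A <- sweep(A, 2, p$fc$b, "+")
  X2 <- relu(A)
  X <- array(X2, c(B, L, model$config$fc_width))
  ls <- lstm_forward(X, p$lstm, keep_cache = train)
  H2 <- matrix(ls$H, B * L, model$config$recurrent_hidden)
  m2 <- if (train) dropout_mask(dim(H2), pdrop) else NULL
  H2d <- if (is.null(m2)) H2 else H2 * m2
  S2 <- H2d %*% p$head$W
  S2 <- sweep(S2, 2, p$head$b, "+")
  scores <- array(S2, c(B, L, model$config$num_classes))
  cache <- if (train) {
    list(
      F2d = F2d, m1 = m1, A = A, X2 = X2, lstm = ls$cache, H2d = H2d,
      m2 = m2, B = B, L = L
    )
  }
  list(scores = scores, cache = cache)
}

# gradient of the mean focal loss w.r.t. scores, plus parameter gradients
backward_features <- function(model, cache, dS2) {
  p <- model$params
  B <- cache$B
  L <- cache$L
  gr <- list()
  gr$head <- list(W = crossprod(cache$H2d, dS2), b = colSums(dS2))
  dH2d <- dS2 %*% t(p$head$W)
  dH2 <- if (is.null(cache$m2)) dH2d else dH2d * cache$m2
  dH <- array(dH2, c(B, L, nrow(p$lstm$Wh)))
  lb <- lstm_backward(dH, p$lstm, cache$lstm)
  gr$lstm <- list(Wx = lb$dWx, Wh = lb$dWh, b = lb$db)
  dX2 <- matrix(lb$dX, B * L, model$config$fc_width)
  dA <- dX2 * (cache$A > 0)
  gr$fc <- list(W = crossprod(cache$F2d, dA), b = colSums(dA))
  gr
}

#' Run the classifier on one sequence of frames
#'
#' Stateless: the LSTM hidden state starts at zero for every sequence, so
#' the output never depends on previously processed sequences. In
#' evaluation mode (the default) dropout is inactive and repeated calls are
#' bit-identical.
#'
#' @param model A `lap_model` from [build_model()] or [train_model()].
#' @param frames List of `L` preprocessed `224 x 224 x 3` arrays, or a
#'   precomputed `L x feature_dim` feature matrix.
#' @return List with `scores` (`L x C` matrix) and `prob` (`L x C` softmax
#'   rows, each summing to 1).
#' @export
forward <- function(model, frames) {
  feat <- if (is.matrix(frames)) {
    if (ncol(frames) != model$config$feature_dim) {
      stop("feature matrix has wrong width", call. = FALSE)
    }
    frames
  } else {
    if (!is.list(frames)) frames <- list(frames)
    bad <- !vapply(frames, function(f) identical(dim(f), c(224L, 224L, 3L)) ||
      identical(dim(f), c(224, 224, 3)), TRUE)
    if (any(bad)) stop("frames must be preprocessed 224x224x3 arrays", call. = FALSE)
    featurize(model, frames)
  }
  L <- nrow(feat)
  fa <- array(0, c(1, L, ncol(feat)))
  fa[1, , ] <- feat
  sc <- forward_features(model, fa, train = FALSE)$scores
  scores <- matrix(sc[1, , ], L, model$config$num_classes)
  colnames(scores) <- model$vocab
  list(scores = scores, prob = softmax_rows(scores))
}

softmax_rows <- function(scores) {
  m <- apply(scores, 1, max)
  e <- exp(scores - m)
  p <- e / rowSums(e)
  dimnames(p) <- dimnames(scores)
  p
}

#' Focal loss
#'
#' Cross-entropy with a modulating factor `(1 - p_true)^gamma` that decays
#' to zero as the confidence in correctly classified frames grows, plus a
#' per-class weight `alpha`; the loss therefore concentrates on hard, rare
#' classes. With `gamma = 0` and unit `alpha` it reduces exactly to
#' cross-entropy. Probabilities are clamped at `1e-12` so the loss is never
#' NaN or infinite.
#'
#' @param prob `L x C` matrix of class probabilities (rows sum to 1).
#' @param targets Integer class indices (1-based) or class tokens matching
#'   the column order.
#' @param gamma Focusing exponent (>= 0, default 2).
#' @param alpha Per-class weights, length `C` (default unit weights).
#' @return Scalar mean loss over the `L` frames.
#' @export
#' @examples
#' p <- matrix(c(0.5, 0.5), 1)
#' focal_loss(p, 1, gamma = 0) # log(2)
focal_loss <- function(prob, targets, gamma = 2, alpha = rep(1, ncol(prob))) {
  stopifnot(gamma >= 0, all(alpha >= 0), length(alpha) == ncol(prob))
  yi <- target_index(targets, prob)
  py <- pmax(prob[cbind(seq_len(nrow(prob)), yi)], 1e-12)
  mean(-alpha[yi] * (1 - py)^gamma * log(py))
}

target_index <- function(targets, prob) {
  if (is.character(targets)) {
    vocab <- colnames(prob)
    if (is.null(vocab)) stop("prob needs class column names for token targets", call. = FALSE)
    yi <- match(targets, vocab)
    if (anyNA(yi)) stop("target label not in vocabulary", call. = FALSE)
    yi
  } else {
    yi <- as.integer(targets)
    if (any(yi < 1 | yi > ncol(prob))) stop("target index out of range", call. = FALSE)
    yi
  }
}

# d(mean focal loss)/d(scores); prob = softmax(scores). Derivation:
#   L = -a (1-p)^g log p,  dL/dp = a g (1-p)^(g-1) log p - a (1-p)^g / p
#   dp_y/dz_j = p_y (1[y=j] - p_j)
focal_loss_grad <- function(prob, targets, gamma, alpha) {
  n <- nrow(prob)
  yi <- target_index(targets, prob)
  py <- pmin(pmax(prob[cbind(seq_len(n), yi)], 1e-12), 1 - 1e-12)
  dLdp <- if (gamma == 0) {
    -alpha[yi] / py
  } else {
    alpha[yi] * (gamma * (1 - py)^(gamma - 1) * log(py) - (1 - py)^gamma / py)
  }
  onehot <- matrix(0, n, ncol(prob))
  onehot[cbind(seq_len(n), yi)] <- 1
  (dLdp * py) * (onehot - prob) / n
}

#' Per-frame predicted labels from a score matrix
#'
#' Row-wise argmax with a fail-closed tie rule: an exact tie is broken
#' toward the tied class that maps to binary OUTSIDE with the lowest class
#' index (a frame we are unsure about is censored, not kept). Padded
#' trailing rows (inference-mode padding) are dropped.
#'
#' @param scores `L x C` matrix with class columns in vocabulary order.
#' @param pad_count Number of trailing padded rows to drop (default 0).
#' @param vocab Class vocabulary; defaults to the score column names.
#' @return Character vector of `L - pad_count` class tokens.
#' @export
predict_labels <- function(scores, pad_count = 0, vocab = colnames(scores)) {
  stopifnot(pad_count < nrow(scores))
  if (is.null(vocab)) {
    vocab <- if (ncol(scores) == 2) binary_classes() else frame_classes()
  }
  out_idx <- outside_indices(vocab)
  pick <- apply(scores, 1, function(r) {
    mx <- max(r)
    tied <- which(r >= mx - 1e-12)
    if (length(tied) > 1) {
      tied_out <- intersect(tied, out_idx)
      if (length(tied_out) > 0) {
        return(tied_out[1])
      }
    }
    tied[1]
  })
  lab <- vocab[pick]
  if (pad_count > 0) lab <- lab[seq_len(length(lab) - pad_count)]
  lab
}

#' Save / load model checkpoints
#'
#' A checkpoint is a single file holding the weights, the
#' [model_config()] and the class vocabulary. Loading refuses a checkpoint
#' whose class count does not match the requested task.
#'
#' @param model A `lap_model`.
#' @param path Checkpoint file path.
#' @param num_classes Optional expected class count (2 or 5).
#' @return `load_checkpoint()` returns the `lap_model`; `save_checkpoint()`
#'   the path, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "lap_model"))
  saveRDS(list(params = model$params, config = unclass(model$config), vocab = model$vocab), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, num_classes = NULL) {
  x <- readRDS(path)
  if (!is.null(num_classes) && x$config$num_classes != num_classes) {
    stop(sprintf(
      "checkpoint has %d classes but %d were requested",
      x$config$num_classes, num_classes
    ), call. = FALSE)
  }
  structure(
    list(
      params = x$params, config = structure(x$config, class = "model_config"),
      vocab = x$vocab
    ),
    class = "lap_model"
  )
}
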