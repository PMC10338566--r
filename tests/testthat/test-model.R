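tiny_model <- function(num_classes = 2, seed = 1, ...) {
  build_model(model_config(num_classes = num_classes, ...), seed = seed)
}

test_that("forward returns row-stochastic L x C scores and is stateless", {
  m <- tiny_model(5)
  set.seed(2)
  feats <- matrix(stats::rnorm(32 * 64), 32, 64)
  out <- forward(m, feats)
  expect_equal(dim(out$scores), c(32, 5))
  expect_equal(rowSums(out$prob), rep(1, 32), tolerance = 1e-6)

  # identical input twice (eval mode: no dropout) -> identical output
  expect_identical(out$scores, forward(m, feats)$scores)

  # statelessness: processing an unrelated sequence in between changes nothing
  forward(m, matrix(stats::rnorm(32 * 64), 32, 64))
  expect_identical(out$scores, forward(m, feats)$scores)

  # degenerate one-frame sequence
  out1 <- forward(m, feats[1, , drop = FALSE])
  expect_equal(dim(out1$scores), c(1, 5))
})

test_that("forward rejects mis-shaped frames and runs fast enough on CPU", {
  m <- tiny_model(2)
  expect_error(forward(m, list(array(0, c(100, 100, 3)))), "224x224x3")
  frames <- replicate(32, array(stats::runif(224 * 224 * 3), c(224, 224, 3)),
    simplify = FALSE
  )
  elapsed <- system.time(out <- forward(m, frames))["elapsed"]
  expect_equal(dim(out$scores), c(32, 2))
  expect_lt(elapsed, 1)
})

test_that("focal loss has its closed-form values and limits", {
  # gamma = 0, alpha = 1: plain cross-entropy
  p <- matrix(c(0.5, 0.5), 1)
  expect_equal(focal_loss(p, 1, gamma = 0), log(2), tolerance = 1e-12)

  # perfectly confident correct prediction: zero loss for any gamma
  p1 <- matrix(c(1, 0), 1)
  for (g in c(0, 1, 2, 5)) {
    expect_equal(focal_loss(p1, 1, gamma = g), 0)
  }

  # hand-computed gamma = 2 case
  p9 <- matrix(c(0.9, 0.1), 1)
  expect_equal(focal_loss(p9, 1, gamma = 2), 0.01 * (-log(0.9)), tolerance = 1e-9)

  # never NaN/Inf even at p_y = 0
  p0 <- matrix(c(0, 1), 1)
  expect_true(is.finite(focal_loss(p0, 1, gamma = 2)))
})

test_that("gamma = 0 focal loss equals cross-entropy on seeded random rows", {
  set.seed(123)
  raw <- matrix(stats::rexp(1000 * 5), 1000, 5)
  p <- raw / rowSums(raw)
  y <- sample(5, 1000, replace = TRUE)
  ce <- -mean(log(p[cbind(1:1000, y)]))
  expect_equal(focal_loss(p, y, gamma = 0, alpha = rep(1, 5)), ce, tolerance = 1e-9)

  # focal loss with gamma > 0 is bounded by cross-entropy, elementwise mean
  expect_lte(focal_loss(p, y, gamma = 2), ce)

  # monotone decreasing in p_y
  ps <- seq(0.05, 0.95, by = 0.05)
  losses <- vapply(ps, function(q) {
    focal_loss(matrix(c(q, 1 - q), 1), 1, gamma = 2)
  }, 0)
  expect_true(all(diff(losses) < 0))
})

test_that("analytic gradients match finite differences through fc/LSTM/head", {
  m <- build_model(
    model_config(num_classes = 2, fc_width = 6, recurrent_hidden = 4,
      head_dropout = 0),
    seed = 5
  )
  set.seed(9)
  B <- 2
  L <- 3
  feats <- array(stats::rnorm(B * L * 64, 0, 0.5), c(B, L, 64))
  y <- sample(2, B * L, replace = TRUE)
  alpha <- c(1.3, 0.7)
  gamma <- 2

  loss_of <- function(model) {
    fw <- lapcensor:::forward_features(model, feats, train = FALSE)
    S2 <- matrix(fw$scores, B * L, 2)
    focal_loss(lapcensor:::softmax_rows(S2), y, gamma = gamma, alpha = alpha)
  }
  fw <- lapcensor:::forward_features(m, feats, train = TRUE)
  S2 <- matrix(fw$scores, B * L, 2)
  prob <- lapcensor:::softmax_rows(S2)
  dS2 <- lapcensor:::focal_loss_grad(prob, y, gamma = gamma, alpha = alpha)
  gr <- lapcensor:::backward_features(m, fw$cache, dS2)

  eps <- 1e-6
  for (grp in c("fc", "lstm", "head")) {
    for (nm in names(gr[[grp]])) {
      g <- gr[[grp]][[nm]]
      idx <- sample(length(g), min(5, length(g)))
      for (i in idx) {
        mp <- m
        mp$params[[grp]][[nm]][i] <- mp$params[[grp]][[nm]][i] + eps
        mm <- m
        mm$params[[grp]][[nm]][i] <- mm$params[[grp]][[nm]][i] - eps
        num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
        expect_equal(g[i], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("argmax prediction breaks ties toward the outside class", {
  sc <- matrix(c(
    0.9, 0.1,
    0.5, 0.5, # exact tie INSIDE vs OUTSIDE -> OUTSIDE
    0.2, 0.8
  ), 3, 2, byrow = TRUE)
  colnames(sc) <- binary_classes()
  expect_equal(predict_labels(sc), c("INSIDE", "OUTSIDE", "OUTSIDE"))

  # five-class tie between TROCAR (inside) and OUTSIDE -> OUTSIDE
  sc5 <- matrix(0, 1, 5, dimnames = list(NULL, frame_classes()))
  sc5[1, c("TROCAR", "OUTSIDE")] <- 1
  expect_equal(predict_labels(sc5), "OUTSIDE")

  # padded rows dropped
  scp <- matrix(stats::rnorm(32 * 2), 32, 2, dimnames = list(NULL, binary_classes()))
  expect_length(predict_labels(scp, pad_count = 28), 4)
})

test_that("training never touches the backbone or layers outside trainable_set", {
  sp <- sample_scenario(18, duration_s = 96)
  tr <- scenario_track(sp)
  m <- tiny_model(2, seed = 3, trainable_set = "head")
  fs <- featurize_frames(m, sample_frames(sp, tr))
  m2 <- train_model(m, fs, train_config(epochs = 2, lr = 1e-2, seed = 1))
  expect_identical(m2$params$backbone, m$params$backbone)
  expect_identical(m2$params$fc, m$params$fc)
  expect_identical(m2$params$lstm, m$params$lstm)
  expect_false(identical(m2$params$head, m$params$head))

  m3 <- tiny_model(2, seed = 3)
  m4 <- train_model(m3, fs, train_config(epochs = 2, lr = 1e-2, seed = 1))
  expect_identical(m4$params$backbone, m3$params$backbone)
  expect_false(identical(m4$params$fc, m3$params$fc))
  expect_false(identical(m4$params$lstm, m3$params$lstm))
})

test_that("checkpoints round-trip and refuse a class-count mismatch", {
  m <- tiny_model(5, seed = 11)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path, num_classes = 5)
  expect_equal(m2$params, m$params)
  expect_equal(m2$vocab, frame_classes())
  set.seed(1)
  feats <- matrix(stats::rnorm(8 * 64), 8, 64)
  expect_identical(forward(m, feats)$scores, forward(m2, feats)$scores)
  expect_error(load_checkpoint(path, num_classes = 2), "5 classes")
})

test_that("model configuration validates its invariants", {
  expect_error(model_config(num_classes = 3), "2 or 5")
  expect_error(model_config(trainable_set = c("head", "backbone")), "frozen")
  cfg <- model_config()
  expect_equal(cfg$fc_width, 128L)
  expect_equal(cfg$recurrent_hidden, 64L)
  expect_error(
    build_model(model_config(backbone = "alexnet_pretrained")),
    "weights file"
  )
})
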