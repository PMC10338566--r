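test_that("confusion counts truth/prediction pairs exactly", {
  truth <- rep("OUTSIDE", 10)
  cm <- confusion(truth, truth)
  expect_equal(sum(diag(cm)), 10)
  expect_equal(sum(cm), 10)

  expect_error(confusion(c("INSIDE"), c("INSIDE", "OUTSIDE")), "equal length")
  expect_error(confusion("INSIDE", "ELSEWHERE"), "vocabulary")
})

test_that("confusion matches the brute-force double loop on random labels", {
  for (seed in 1:5) {
    set.seed(seed)
    truth <- sample(frame_classes(), 200, replace = TRUE)
    pred <- sample(frame_classes(), 200, replace = TRUE)
    expect_equal(
      unclass(confusion(truth, pred)),
      brute_confusion(truth, pred, frame_classes()),
      ignore_attr = TRUE
    )
  }
})

test_that("published binary confusion counts reproduce the printed metrics", {
  # inside: 611,061 of 616,113 matched; outside: 123,757 of 128,079
  cm <- confusion_from_counts(
    matrix(c(611061, 5052, 4322, 123757), 2, 2, byrow = TRUE),
    vocab = binary_classes()
  )
  expect_equal(cm["INSIDE", "OUTSIDE"], 5052)
  expect_equal(cm["OUTSIDE", "INSIDE"], 4322)
  expect_equal(sum(cm) - sum(diag(cm)), 9374) # total disagreement

  out <- metrics(cm, "OUTSIDE")
  expect_equal(round(100 * out$sensitivity, 2), 96.63)
  expect_equal(round(100 * out$specificity, 2), 99.18)
  expect_equal(round(out$f1, 2), 0.96)

  ins <- metrics(cm, "INSIDE")
  expect_equal(round(100 * ins$sensitivity, 2), 99.18)
})

test_that("binary collapse preserves totals and in-group confusions", {
  # diagonal five-class matrix collapses to a diagonal binary matrix
  d <- diag(c(10, 20, 30, 40, 50))
  cmd <- collapse_to_binary(confusion_from_counts(d, frame_classes()))
  expect_equal(cmd["INSIDE", "OUTSIDE"], 0)
  expect_equal(cmd["OUTSIDE", "INSIDE"], 0)
  expect_equal(sum(cmd), 150)

  # trocar frames predicted as abdominal cavity are on the binary diagonal
  m <- matrix(0, 5, 5, dimnames = list(frame_classes(), frame_classes()))
  m["TROCAR", "ABDOMINAL_CAVITY"] <- 4773
  cmb <- collapse_to_binary(confusion_from_counts(m, frame_classes()))
  expect_equal(cmb["INSIDE", "INSIDE"], 4773)
  expect_equal(sum(cmb) - sum(diag(cmb)), 0)

  set.seed(5)
  r <- matrix(rpois(25, 40), 5, 5)
  cmr <- confusion_from_counts(r, frame_classes())
  expect_equal(sum(collapse_to_binary(cmr)), sum(r))

  expect_error(collapse_to_binary(confusion_from_counts(diag(2), binary_classes())), "five")
})

test_that("collapsing the matrix equals collapsing the labels first", {
  set.seed(11)
  truth <- sample(frame_classes(), 500, replace = TRUE)
  pred <- sample(frame_classes(), 500, replace = TRUE)
  expect_equal(
    unclass(collapse_to_binary(confusion(truth, pred))),
    unclass(confusion(to_binary(truth), to_binary(pred))),
    ignore_attr = TRUE
  )
})

test_that("published multiclass counts reproduce the printed row percentages", {
  m <- matrix(0, 5, 5, dimnames = list(frame_classes(), frame_classes()))
  m["ABDOMINAL_CAVITY", "ABDOMINAL_CAVITY"] <- 601161
  m["ABDOMINAL_CAVITY", "TROCAR"] <- 605771 - 601161
  m["TROCAR", "TROCAR"] <- 4345
  m["TROCAR", "ABDOMINAL_CAVITY"] <- 4773
  m["TROCAR", "OUTSIDE"] <- 10342 - 4345 - 4773
  m["CLEANING", "CLEANING"] <- 1036
  m["CLEANING", "OUTSIDE"] <- 6242
  m["CLEANING", "ABDOMINAL_CAVITY"] <- 8061 - 1036 - 6242
  m["OUTSIDE", "OUTSIDE"] <- 114887
  m["OUTSIDE", "CLEANING"] <- 119541 - 114887
  m["TRANSLUCENT_TROCAR", "TROCAR"] <- 206
  m["TRANSLUCENT_TROCAR", "ABDOMINAL_CAVITY"] <- 196
  m["TRANSLUCENT_TROCAR", "OUTSIDE"] <- 477 - 206 - 196
  cm <- confusion_from_counts(m, frame_classes())

  frac <- tidy(cm)
  cell <- function(t, p) frac$fraction[frac$truth == t & frac$pred == p]
  expect_equal(round(100 * cell("TROCAR", "TROCAR"), 2), 42.01)
  expect_equal(round(100 * cell("CLEANING", "OUTSIDE"), 2), 77.43)
  # 114887/119541 = 96.1068%; the published table prints 96.10 (truncated),
  # so agreement is asserted at printed precision
  expect_equal(100 * cell("OUTSIDE", "OUTSIDE"), 96.10, tolerance = 0.011 / 96.1)
  expect_equal(round(100 * cell("TRANSLUCENT_TROCAR", "TROCAR"), 2), 43.19)

  sens <- metrics(cm, "ABDOMINAL_CAVITY")$sensitivity
  expect_equal(round(100 * sens, 2), 99.24)
})

test_that("metrics handle perfect and degenerate matrices", {
  cm <- confusion_from_counts(diag(c(5, 5)), binary_classes())
  m <- metrics(cm)
  expect_true(all(m$sensitivity == 1 & m$specificity == 1 & m$f1 == 1))

  # no outside frames at all: outside sensitivity undefined, never 0
  cm0 <- confusion_from_counts(matrix(c(10, 0, 0, 0), 2, byrow = TRUE), binary_classes())
  m0 <- metrics(cm0, "OUTSIDE")
  expect_true(is.na(m0$sensitivity))
  expect_true(is.na(m0$precision))
})

test_that("privacy report converts error rates into seconds at risk", {
  pr <- privacy_report(0.966, 0.992, 3600, 0.172)
  expect_equal(pr$at_risk_s, 21) # 1-h video, 17.2% outside
  expect_equal(pr$at_risk_s_exact, 3600 * 0.172 * (1 - 0.966), tolerance = 1e-12)

  expect_equal(privacy_report(1, 0.9, 3600, 0.2)$at_risk_s, 0)
  expect_equal(privacy_report(0.5, 0.9, 3600, 0)$at_risk_s, 0)
  expect_error(privacy_report(1.2, 0.9, 100, 0.1))
})

test_that("eval reports bundle matrices, metrics and privacy and serialize", {
  set.seed(2)
  truth <- sample(frame_classes(), 300, replace = TRUE, prob = c(0.6, 0.05, 0.25, 0.07, 0.03))
  pred <- ifelse(stats::runif(300) < 0.9, truth, sample(frame_classes(), 300, replace = TRUE))
  rep <- eval_report(truth, pred)
  expect_s3_class(rep, "lap_eval_report")
  expect_equal(sum(rep$confusion), 300)
  expect_equal(unclass(rep$binary), unclass(collapse_to_binary(rep$confusion)))

  td <- tidy(rep)
  expect_equal(td$label, frame_classes())
  gl <- glance(rep)
  expect_equal(gl$n_frames, 300)
  expect_true(gl$accuracy >= 0 && gl$accuracy <= 1)

  path <- withr::local_tempfile(fileext = ".json")
  save_report(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$n_frames, 300)
  expect_length(parsed$confusion, 5)

  expect_output(print(rep), "Outside class")
})

test_that("plot builders return ggplot objects", {
  set.seed(3)
  truth <- sample(binary_classes(), 50, replace = TRUE)
  cm <- confusion(truth, truth)
  expect_s3_class(autoplot(cm), "ggplot")
  tr <- random_track(1, n_intervals = 5)
  expect_s3_class(autoplot(tr), "ggplot")
  expect_s3_class(plot_class_distribution(class_distribution(tr)), "ggplot")
})
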