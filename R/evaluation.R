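#' Confusion matrix of per-frame labels
#'
#' Rows are annotated (truth) classes, columns predicted classes, in
#' canonical vocabulary order; `counts[i, j]` is the number of frames
#' annotated `i` and predicted `j`.
#'
#' @param truth,pred Equal-length character vectors of class tokens.
#' @param vocab Class vocabulary; inferred (binary vs five-way) when `NULL`.
#' @return An integer `C x C` matrix of class `confusion_matrix` with
#'   dimnames `truth` x `pred`.
#' @export
confusion <- function(truth, pred, vocab = NULL) {
  if (length(truth) != length(pred)) {
    stop("truth and pred must have equal length", call. = FALSE)
  }
  if (is.null(vocab)) {
    vocab <- if (all(c(truth, pred) %in% binary_classes())) {
      binary_classes()
    } else {
      frame_classes()
    }
  }
  bad <- setdiff(unique(c(truth, pred)), vocab)
  if (length(bad) > 0) {
    stop("label(s) outside the vocabulary: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  m <- table(
    factor(truth, levels = vocab),
    factor(pred, levels = vocab)
  )
  new_confusion(matrix(as.integer(m), length(vocab),
    dimnames = list(truth = vocab, pred = vocab)
  ))
}

new_confusion <- function(m) {
  structure(m, class = c("confusion_matrix", class(matrix())))
}

#' Build a confusion matrix from known counts
#'
#' Convenience constructor for published or externally computed counts.
#'
#' @param counts Square numeric matrix (rows truth, columns pred).
#' @param vocab Class vocabulary in row/column order.
#' @return A `confusion_matrix`.
#' @export
confusion_from_counts <- function(counts, vocab = rownames(counts)) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), !is.null(vocab))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  dimnames(counts) <- list(truth = vocab, pred = vocab)
  new_confusion(counts)
}

#' Collapse a five-class confusion matrix onto inside/outside
#'
#' Both axes are summed under [to_binary()], so the grand total is
#' preserved. Confusions inside the same binary group (e.g. trocar frames
#' predicted as abdominal cavity) land on the binary diagonal — they are
#' not privacy errors.
#'
#' @param cm A `confusion_matrix` over the five-way vocabulary.
#' @return A `confusion_matrix` over `INSIDE`/`OUTSIDE`.
#' @export
collapse_to_binary <- function(cm) {
  if (!identical(rownames(cm), frame_classes())) {
    stop("expected a confusion matrix over the five frame classes", call. = FALSE)
  }
  g <- to_binary(rownames(cm))
  m <- t(rowsum(t(rowsum(unclass(cm), g)), g))
  m <- m[binary_classes(), binary_classes()]
  dimnames(m) <- list(truth = binary_classes(), pred = binary_classes())
  new_confusion(m)
}

#' Per-class one-vs-rest metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)` and F1 (harmonic mean of precision and sensitivity). A
#' ratio with zero denominator is reported as `NA`, never as 0. For the
#' privacy task the key numbers are the outside class's sensitivity (are
#' all outside frames caught?) and specificity (how much inside footage is
#' needlessly censored?).
#'
#' @param cm A `confusion_matrix`.
#' @param target_class Optional single class token; `NULL` returns all
#'   classes.
#' @return Tibble `label`, `sensitivity`, `specificity`, `precision`, `f1`.
#' @export
metrics <- function(cm, target_class = NULL) {
  vocab <- rownames(cm)
  total <- sum(cm)
  out <- lapply(vocab, function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- total - tp - fn - fp
    ratio <- function(num, den) if (den == 0) NA_real_ else num / den
    sens <- ratio(tp, tp + fn)
    spec <- ratio(tn, tn + fp)
    prec <- ratio(tp, tp + fp)
    f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0) {
      2 * prec * sens / (prec + sens)
    } else {
      NA_real_
    }
    tibble::tibble(
      label = cl, sensitivity = sens, specificity = spec,
      precision = prec, f1 = f1
    )
  })
  out <- dplyr::bind_rows(out)
  if (!is.null(target_class)) {
    if (!target_class %in% vocab) stop("unknown target class", call. = FALSE)
    out <- out[out$label == target_class, ]
  }
  out
}

#' Expected privacy risk of an imperfect classifier
#'
#' For a video of `duration_s` seconds of which a fraction
#' `outside_fraction` is extra-abdominal: footage *at risk* is outside
#' footage missed by the classifier (predicted inside, hence left
#' uncensored), `duration_s * outside_fraction * (1 - sensitivity)`;
#' footage *lost* is inside footage wrongly censored,
#' `duration_s * (1 - outside_fraction) * (1 - specificity)`. Both are
#' rounded to whole seconds for display; exact values are kept alongside.
#'
#' @param sensitivity,specificity Outside-class sensitivity / specificity
#'   in `[0,1]`.
#' @param duration_s Video duration in seconds.
#' @param outside_fraction Fraction of the video that is outside, `[0,1]`.
#' @return Tibble with `duration_s`, `outside_fraction`, `at_risk_s`,
#'   `lost_s` (whole seconds) and `at_risk_s_exact`, `lost_s_exact`.
#' @export
#' @examples
#' privacy_report(0.966, 0.992, 3600, 0.172) # 21 s at risk in one hour
privacy_report <- function(sensitivity, specificity, duration_s,
                           outside_fraction) {
  stopifnot(
    sensitivity >= 0, sensitivity <= 1, specificity >= 0, specificity <= 1,
    duration_s >= 0, outside_fraction >= 0, outside_fraction <= 1
  )
  at_risk <- duration_s * outside_fraction * (1 - sensitivity)
  lost <- duration_s * (1 - outside_fraction) * (1 - specificity)
  tibble::tibble(
    duration_s = duration_s, outside_fraction = outside_fraction,
    at_risk_s = round(at_risk), lost_s = round(lost),
    at_risk_s_exact = at_risk, lost_s_exact = lost
  )
}

#' Evaluation report for one experiment
#'
#' Bundles the confusion matrix, per-class one-vs-rest metrics, the binary
#' collapse (for a five-class run) and the privacy-risk summary into one
#' object.
#'
#' @param truth,pred Equal-length label vectors.
#' @param vocab Class vocabulary (inferred when `NULL`).
#' @param sample_rate Sampling rate the labels were produced at
#'   (frames/second); used to convert frame counts to seconds.
#' @return A `lap_eval_report`: list with `confusion`, `metrics`, `binary`
#'   (binary confusion), `binary_metrics`, `privacy`, `n_frames`,
#'   `sample_rate`.
#' @export
eval_report <- function(truth, pred, vocab = NULL, sample_rate = 1) {
  cm <- confusion(truth, pred, vocab)
  eval_report_from_cm(cm, sample_rate)
}

#' @rdname eval_report
#' @param cm A `confusion_matrix` (five-class or binary).
#' @export
eval_report_from_cm <- function(cm, sample_rate = 1) {
  bin <- if (identical(rownames(cm), frame_classes())) collapse_to_binary(cm) else cm
  bm <- metrics(bin)
  om <- bm[bm$label == "OUTSIDE", ]
  n <- sum(cm)
  dur <- n / sample_rate
  out_frac <- sum(bin["OUTSIDE", ]) / n
  priv <- privacy_report(
    sensitivity = ifelse(is.na(om$sensitivity), 1, om$sensitivity),
    specificity = ifelse(is.na(om$specificity), 1, om$specificity),
    duration_s = dur, outside_fraction = out_frac
  )
  structure(list(
    confusion = cm, metrics = metrics(cm), binary = bin, binary_metrics = bm,
    privacy = priv, n_frames = n, sample_rate = sample_rate
  ), class = "lap_eval_report")
}

#' @export
print.lap_eval_report <- function(x, ...) {
  cat(sprintf("<lap_eval_report> %d frames @ %g frame(s)/s\n", x$n_frames, x$sample_rate))
  cat("\nConfusion (truth x pred):\n")
  print(unclass(x$confusion))
  cat("\nPer-class metrics (one-vs-rest):\n")
  m <- x$metrics
  m[-1] <- lapply(m[-1], function(v) round(v, 4))
  print(as.data.frame(m), row.names = FALSE)
  om <- x$binary_metrics[x$binary_metrics$label == "OUTSIDE", ]
  cat(sprintf(
    "\nOutside class: sensitivity %.2f%%, specificity %.2f%%, F1 %.2f\n",
    100 * om$sensitivity, 100 * om$specificity, om$f1
  ))
  cat(sprintf(
    "Privacy: %d s at risk, %d s lost per %.0f s of video (%.1f%% outside)\n",
    x$privacy$at_risk_s, x$privacy$lost_s, x$privacy$duration_s,
    100 * x$privacy$outside_fraction
  ))
  invisible(x)
}

#' Serialize an evaluation report as JSON
#' @param report A `lap_eval_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
save_report <- function(report, path) {
  jsonlite::write_json(list(
    n_frames = report$n_frames,
    sample_rate = report$sample_rate,
    vocabulary = rownames(report$confusion),
    confusion = unclass(report$confusion),
    metrics = report$metrics,
    binary_confusion = unclass(report$binary),
    binary_metrics = report$binary_metrics,
    privacy = report$privacy
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation report into per-class metric rows
#' @param x A `lap_eval_report`.
#' @param ... Unused.
#' @return Tibble with one row per class and metric columns.
#' @export
tidy.lap_eval_report <- function(x, ...) x$metrics

#' One-row summary of an evaluation report
#' @param x A `lap_eval_report`.
#' @param ... Unused.
#' @return One-row tibble: frame count, accuracy, outside-class
#'   sensitivity/specificity/F1 and privacy seconds.
#' @export
glance.lap_eval_report <- function(x, ...) {
  om <- x$binary_metrics[x$binary_metrics$label == "OUTSIDE", ]
  tibble::tibble(
    n_frames = x$n_frames,
    accuracy = sum(diag(x$confusion)) / sum(x$confusion),
    outside_sensitivity = om$sensitivity,
    outside_specificity = om$specificity,
    outside_f1 = om$f1,
    at_risk_s = x$privacy$at_risk_s,
    lost_s = x$privacy$lost_s
  )
}

#' Tidy a confusion matrix into long form
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return Tibble `truth`, `pred`, `n`, `fraction` (row-normalized).
#' @export
tidy.confusion_matrix <- function(x, ...) {
  m <- unclass(x)
  long <- as.data.frame(as.table(m), stringsAsFactors = FALSE)
  names(long) <- c("truth", "pred", "n")
  rowtot <- rowSums(m)[long$truth]
  long$fraction <- ifelse(rowtot > 0, long$n / rowtot, NA_real_)
  tibble::as_tibble(long)
}

#' Heatmap of a confusion matrix
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot object (row-normalized fractions as fill, counts as
#'   text).
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  d <- tidy.confusion_matrix(object)
  d$truth <- factor(d$truth, levels = rev(rownames(object)))
  d$pred <- factor(d$pred, levels = colnames(object))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pred, y = .data$truth)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$fraction), colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(
      low = "white", high = "#2c7fb8",
      limits = c(0, 1), na.value = "grey90"
    ) +
    ggplot2::labs(
      x = "predicted", y = "annotated", fill = "row fraction",
      title = "Frame classification confusion"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of the per-class frame distribution
#' @param distribution Tibble from [class_distribution()].
#' @return A ggplot object.
#' @export
plot_class_distribution <- function(distribution) {
  d <- distribution
  d$label <- factor(d$label, levels = frame_classes())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$fraction)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.2f%%", 100 * .data$fraction)),
      vjust = -0.4, size = 3
    ) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "share of frames", title = "Class distribution") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Timeline plot of an annotation track
#' @param object An [annotation_track()].
#' @param ... Unused.
#' @return A ggplot object showing the labelled intervals over time.
#' @export
autoplot.annotation_track <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$label <- factor(d$label, levels = frame_classes())
  ggplot2::ggplot(d) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start_s, xmax = .data$end_s, ymin = 0, ymax = 1,
      fill = .data$label
    )) +
    ggplot2::scale_fill_brewer(palette = "Set2", drop = FALSE) +
    ggplot2::labs(
      x = "time (s)", y = NULL,
      title = sprintf("Annotation track: %s", track_video_id(object))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      panel.grid.major.y = ggplot2::element_blank()
    )
}
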