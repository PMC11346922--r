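#' Confusion counts at a score threshold
#'
#' FTMH is the positive class; a scan is predicted positive when its score
#' is `>= threshold` (the boundary score counts as positive).
#'
#' @param labels logical (or 0/1) vector, `TRUE` = FTMH.
#' @param scores numeric FTMH scores in `[0, 1]`.
#' @param threshold decision threshold (default 0.5).
#' @return A list of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores))
    stop_domain("labels and scores must have equal length")
  labels <- as.logical(labels)
  pred <- scores >= threshold
  structure(list(tp = sum(pred & labels), fp = sum(pred & !labels),
                 fn = sum(!pred & labels), tn = sum(!pred & !labels),
                 threshold = threshold),
            class = "confusion_counts")
}

#' Confusion-derived classification rates
#'
#' Precision `tp/(tp+fp)`, sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, and `F1 = 2 * precision * sensitivity / (precision +
#' sensitivity)`. Undefined ratios (0/0) are reported as 0 with the
#' corresponding name listed in `degenerate`.
#'
#' @param counts a [confusion_counts()].
#' @return A list of class `metrics_rates` with the four rates, the
#'   counts, and a `degenerate` character vector.
#' @export
classification_metrics <- function(counts) {
  safe <- function(num, den, what, env) {
    if (den == 0) {
      env$degenerate <- c(env$degenerate, what)
      return(0)
    }
    num / den
  }
  env <- new.env()
  env$degenerate <- character(0)
  precision <- safe(counts$tp, counts$tp + counts$fp, "precision", env)
  sensitivity <- safe(counts$tp, counts$tp + counts$fn, "sensitivity", env)
  specificity <- safe(counts$tn, counts$tn + counts$fp, "specificity", env)
  f1 <- safe(2 * precision * sensitivity, precision + sensitivity, "f1", env)
  structure(list(precision = precision, sensitivity = sensitivity,
                 specificity = specificity, f1 = f1, counts = counts,
                 degenerate = env$degenerate),
            class = "metrics_rates")
}

#' ROC curve by threshold sweep and trapezoidal AUC
#'
#' Thresholds sweep the unique scores; tied scores enter simultaneously.
#' The trapezoidal area equals the Mann-Whitney U statistic divided by
#' `n_pos * n_neg` (ties counted half).
#'
#' @param labels logical vector, `TRUE` = positive; both classes required.
#' @param scores numeric scores.
#' @return A list of class `roc_curve` with `points` (a `data.frame` of
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve_auc <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop_domain("labels and scores must have equal length")
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop_domain("ROC requires both classes present")
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores >= t & labels) / n_pos, numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & !labels) / n_neg, numeric(1))
  fpr_all <- c(0, fpr, 1); tpr_all <- c(0, tpr, 1)
  auc <- sum(diff(fpr_all) * (head(tpr_all, -1) + tpr_all[-1]) / 2)
  structure(list(points = data.frame(threshold = c(Inf, th, -Inf),
                                     fpr = fpr_all, tpr = tpr_all),
                 auc = auc),
            class = "roc_curve")
}

#' Per-replicate metrics report (both classes, ROC, AUC)
#'
#' Scores each class as the positive one in turn: the control row uses
#' `1 - score` against inverted labels, mirroring a two-column F1 report.
#'
#' @param labels logical vector, `TRUE` = FTMH.
#' @param scores FTMH scores in `[0, 1]`.
#' @param threshold decision threshold (default 0.5).
#' @return A list of class `metrics_report` with `ftmh`, `control`
#'   ([classification_metrics()] each), `roc`, `auc`, `threshold`, `n`.
#' @export
metrics_report <- function(labels, scores, threshold = 0.5) {
  labels <- as.logical(labels)
  ftmh <- classification_metrics(confusion_counts(labels, scores, threshold))
  # control as positive: predicted control when score < threshold
  ctrl_counts <- structure(list(tp = ftmh$counts$tn, fp = ftmh$counts$fn,
                                fn = ftmh$counts$fp, tn = ftmh$counts$tp,
                                threshold = threshold),
                           class = "confusion_counts")
  control <- classification_metrics(ctrl_counts)
  roc <- if (any(labels) && !all(labels)) roc_curve_auc(labels, scores) else NULL
  structure(list(ftmh = ftmh, control = control, roc = roc,
                 auc = if (is.null(roc)) NA_real_ else roc$auc,
                 threshold = threshold, n = length(labels)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics (threshold %.2f, n = %d):\n", x$threshold, x$n))
  cat(sprintf("  FTMH:    precision %.3f  sensitivity %.3f  specificity %.3f  F1 %.3f\n",
              x$ftmh$precision, x$ftmh$sensitivity, x$ftmh$specificity,
              x$ftmh$f1))
  cat(sprintf("  control: precision %.3f  sensitivity %.3f  F1 %.3f\n",
              x$control$precision, x$control$sensitivity, x$control$f1))
  if (!is.na(x$auc)) cat(sprintf("  AUC %.3f\n", x$auc))
  invisible(x)
}

#' Aggregate metrics across replicates as mean +- SD
#'
#' @param reports list of [metrics_report()] objects.
#' @return A `data.frame` with one row per metric: `mean`, `sd` (sample
#'   SD, n - 1) and a `formatted` column in the form `"1.000 +- 0.000"`.
#' @export
aggregate_replicates <- function(reports) {
  pull <- function(r) c(precision_ftmh = r$ftmh$precision,
                        specificity = r$ftmh$specificity,
                        sensitivity_ftmh = r$ftmh$sensitivity,
                        f1_ftmh = r$ftmh$f1,
                        f1_control = r$control$f1,
                        auc = r$auc)
  M <- do.call(rbind, lapply(reports, pull))
  mu <- colMeans(M)
  s <- apply(M, 2, sd)
  if (nrow(M) == 1L) s[] <- 0
  data.frame(metric = colnames(M), mean = as.numeric(mu), sd = as.numeric(s),
             formatted = sprintf("%.3f ± %.3f", mu, s),
             stringsAsFactors = FALSE)
}

#' Evaluate an ensemble on the lamellar/pseudohole challenge set
#'
#' Only central B-scans are evaluated; the ground truth is FTMH-negative
#' for every eye, so accuracy is the fraction classified FTMH-negative.
#'
#' @param ensemble a trained `rascl_ensemble` (see [train_ensemble()]).
#' @param volumes named list of challenge [bscan_volume()].
#' @return A list with `accuracy` and `predictions` (`data.frame` of
#'   `eye_id`, `score`, `label`).
#' @export
evaluate_challenge <- function(ensemble, volumes) {
  if (length(volumes) == 0) stop_domain("empty challenge set")
  images <- lapply(volumes, central_slice)
  pred <- ensemble_predict(ensemble, images)
  data <- data.frame(eye_id = vapply(volumes, `[[`, "", "eye_id"),
                     score = pred$score, label = pred$label,
                     stringsAsFactors = FALSE, row.names = NULL)
  list(accuracy = mean(!pred$label), predictions = data)
}

#' Gradient saliency map for one image
#'
#' `method = "gradcam"`: Grad-CAM on the final convolutional block — the
#' channel-wise gradients of the target-class logit are globally averaged
#' into weights, the weighted activation sum is rectified and upsampled
#' bilinearly to the input resolution. `method = "input_grad"`: absolute
#' input-gradient map. Both are max-normalized to `[0, 1]` and
#' deterministic for fixed weights.
#'
#' @param encoder a [build_encoder()] result.
#' @param head a classifier-mode [build_head()] result.
#' @param image numeric matrix in `[0, 1]`.
#' @param target_class 1 (control) or 2 (FTMH).
#' @param method `"gradcam"` or `"input_grad"`.
#' @return A non-negative matrix of the input's spatial shape with maximum
#'   1 (all-zero if the gradient vanishes everywhere).
#' @export
saliency_map <- function(encoder, head, image, target_class = 2L,
                         method = c("gradcam", "input_grad")) {
  method <- match.arg(method)
  if (!target_class %in% seq_len(head$spec$n_classes))
    stop_domain("invalid target class index")
  fwd <- encoder_forward(encoder, image, train = FALSE)
  hfwd <- head_forward(head, fwd$out)
  dlogits <- matrix(0, 1, head$spec$n_classes)
  dlogits[1, target_class] <- 1
  hb <- head_backward(head, hfwd$caches, dlogits)
  # walk encoder layers backward, recording the gradient entering each layer
  layers <- encoder$layers
  caches <- fwd$caches
  dout <- hb$dX
  layer_inputs_grad <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dout)
    layer_inputs_grad[[i]] <- r$dx
    dout <- r$dx
  }
  if (method == "input_grad") {
    # sum of absolute gradients over (replicated) input channels
    g <- apply(abs(dout[, , , 1, drop = FALSE]), c(1, 2), sum)
  } else {
    conv_idx <- max(which(vapply(layers, function(l)
      l$type %in% c("conv", "residual"), logical(1))))
    if (conv_idx >= length(layers))
      stop_domain("encoder has no pooling layer after its last conv block")
    act <- seq_forward(layers[seq_len(conv_idx)],
                       stack_images(image, encoder$spec$input_size[3]),
                       train = FALSE)$out
    grad_act <- layer_inputs_grad[[conv_idx + 1]]
    alpha <- apply(grad_act[, , , 1, drop = FALSE], 3, mean)
    cam <- matrix(0, dim(act)[1], dim(act)[2])
    for (c in seq_along(alpha)) cam <- cam + alpha[c] * act[, , c, 1]
    g <- pmax(cam, 0)
    g <- resize_image_cpp(g, nrow(image), ncol(image), 1L)
    g <- pmax(g, 0)
  }
  if (max(g) > 0) g <- g / max(g)
  g
}
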