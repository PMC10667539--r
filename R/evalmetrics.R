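# Clinical diagnostic evaluation: confusion matrices, the six report
# metrics with prevalence-adjusted predictive values, ROC/AUC with the
# sensitivity-equals-specificity operating point, Grad-CAM saliency, and the
# original-vs-synthesized comparison table.

as_binary_labels <- function(x) {
  if (is.numeric(x)) {
    kv_assert(all(x %in% c(0, 1)), "labels must be binary")
    return(as.integer(x))
  }
  kv_assert(all(x %in% c("normal", POSITIVE_LABEL)),
            "labels must be 'normal'/'kcn' or 0/1")
  as.integer(x == POSITIVE_LABEL)
}

#' Confusion matrix
#'
#' @param y_true,y_pred binary labels (`0/1` or `"normal"/"kcn"`; keratoconus
#'   is the positive class), equal length.
#' @return a list of class `confusion_matrix` with counts `tp, fn, fp, tn`.
#' @export
confusion <- function(y_true, y_pred) {
  kv_assert(length(y_true) == length(y_pred),
            "confusion: length mismatch")
  t <- as_binary_labels(y_true); p <- as_binary_labels(y_pred)
  structure(list(tp = sum(t == 1 & p == 1), fn = sum(t == 1 & p == 0),
                 fp = sum(t == 0 & p == 1), tn = sum(t == 0 & p == 0)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, byrow = TRUE,
              dimnames = list(truth = c("kcn", "normal"),
                              predicted = c("kcn", "normal")))
  print(m); invisible(x)
}

#' Diagnostic metrics from a confusion matrix
#'
#' Accuracy, sensitivity and specificity from the raw counts. Predictive
#' values either from the raw counts (`prevalence = NULL`) or adjusted to a
#' stated disease prevalence `p` by Bayes' rule:
#' `PPV = sens * p / (sens * p + (1 - spec) * (1 - p))` and
#' `NPV = spec * (1 - p) / (spec * (1 - p) + (1 - sens) * p)`. A metric whose
#' margin is empty (for example sensitivity with no positives) is returned
#' as `NA` with its name listed in `undefined`.
#'
#' @param cm a [confusion()] matrix.
#' @param prevalence disease prevalence in `(0, 1)`, or `NULL` for raw
#'   counts.
#' @param auc optional AUC to carry in the report.
#' @return a list of class `metric_report` with `accuracy, sensitivity,
#'   specificity, ppv, npv, auc, prevalence_used, undefined`.
#' @export
diagnostic_metrics <- function(cm, prevalence = NULL, auc = NA_real_) {
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  kv_assert(n > 0, "empty confusion matrix")
  if (!is.null(prevalence))
    kv_assert(prevalence > 0 && prevalence < 1,
              "prevalence must be in (0, 1)")
  undefined <- character(0)
  sens <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else
    { undefined <- c(undefined, "sensitivity"); NA_real_ }
  spec <- if (cm$tn + cm$fp > 0) cm$tn / (cm$tn + cm$fp) else
    { undefined <- c(undefined, "specificity"); NA_real_ }
  acc <- (cm$tp + cm$tn) / n
  if (!is.null(prevalence) && !is.na(sens) && !is.na(spec)) {
    p <- prevalence
    ppv <- sens * p / (sens * p + (1 - spec) * (1 - p))
    npv <- spec * (1 - p) / (spec * (1 - p) + (1 - sens) * p)
  } else {
    ppv <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else
      { undefined <- c(undefined, "ppv"); NA_real_ }
    npv <- if (cm$tn + cm$fn > 0) cm$tn / (cm$tn + cm$fn) else
      { undefined <- c(undefined, "npv"); NA_real_ }
  }
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 ppv = ppv, npv = npv, auc = auc,
                 prevalence_used = if (is.null(prevalence)) NA_real_
                                   else prevalence,
                 undefined = undefined),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f  sensitivity %.4f  specificity %.4f  ppv %.4f  npv %.4f  auc %s%s\n",
    x$accuracy, x$sensitivity, x$specificity, x$ppv, x$npv,
    ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc)),
    if (!is.na(x$prevalence_used))
      sprintf("  (PPV/NPV at prevalence %.2f)", x$prevalence_used) else ""))
  invisible(x)
}

#' ROC curve, AUC and the sensitivity-equals-specificity cutoff
#'
#' Thresholds are the unique scores plus infinite sentinels; a sample is
#' called positive when `score >= threshold`. AUC is the trapezoidal area
#' over (FPR, TPR), which equals the probability of pairwise concordance
#' with ties counted 1/2. The optimal cutoff is the threshold minimizing
#' `|sensitivity - specificity|`, ties broken by larger
#' `sensitivity + specificity`, then by smaller threshold.
#'
#' @param scores numeric scores in `[0, 1]` (1 = keratoconus).
#' @param labels binary labels; both classes must be present
#'   (`undefined_roc` otherwise).
#' @return a list of class `roc_curve` with `points` (data frame
#'   `threshold, fpr, tpr`), `auc`, `optimal_threshold`.
#' @export
roc_curve_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  kv_assert(length(scores) == length(y), "roc: length mismatch")
  if (length(unique(y)) < 2)
    kv_error("both classes must be present", "undefined_roc")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / n_neg, 0)
  points <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  points <- points[order(points$threshold), ]
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(o)]) / 2)
  structure(list(points = points, auc = auc,
                 optimal_threshold = optimal_cutoff_points(points)),
            class = "roc_curve")
}

optimal_cutoff_points <- function(points) {
  sens <- points$tpr
  spec <- 1 - points$fpr
  gap <- abs(sens - spec)
  best <- which(gap == min(gap))
  if (length(best) > 1) {
    s <- sens[best] + spec[best]
    best <- best[s == max(s)]
    if (length(best) > 1) best <- best[which.min(points$threshold[best])]
  }
  points$threshold[best]
}

#' Optimal ROC cutoff
#'
#' @param curve a [roc_curve_auc()] result, or a data frame of
#'   `threshold, fpr, tpr` points.
#' @return the threshold closest to sensitivity = specificity (tie-breaks:
#'   larger sensitivity + specificity, then smaller threshold).
#' @export
optimal_cutoff <- function(curve) {
  pts <- if (inherits(curve, "roc_curve")) curve$points else curve
  kv_assert(nrow(pts) > 0, "empty ROC curve")
  optimal_cutoff_points(pts)
}

#' Grad-CAM saliency heatmap
#'
#' Gradient-weighted class activation mapping at a convolutional layer of a
#' trained classifier: channel weights are the spatial averages of the
#' positive-class score gradient at the target layer, the heat is the
#' rectified weighted activation sum, min-max normalized to `[0, 1]` and
#' bilinearly upsampled to the input size. All-zero gradients yield an
#' all-zero map with attribute `"warning"` set.
#'
#' @param model a trained `kv_cnn`.
#' @param image prepared input array for the model.
#' @param target_layer index of the target convolution layer (default: the
#'   last one).
#' @return a list of class `gradcam_map` with `heat` (input-sized matrix in
#'   `[0, 1]`) and `target_layer`.
#' @export
gradcam_heatmap <- function(model, image, target_layer = NULL) {
  net <- model$net
  conv_idx <- which(vapply(net$layers, function(l) l$type == "conv",
                           logical(1)))
  if (is.null(target_layer)) target_layer <- utils::tail(conv_idx, 1)
  kv_assert(target_layer %in% conv_idx, "target_layer must be a conv layer")
  fwd <- nn_forward(net, image)
  bw <- nn_backward(net, fwd$caches, matrix(1, 1, 1), capture = target_layer)
  act <- fwd$caches[[target_layer]]$out            # npos x channels
  grad <- bw$captured
  g <- net$layers[[target_layer]]$geom
  warn <- FALSE
  if (is.null(grad) || all(grad == 0)) {
    heat <- matrix(0, g$out_h, g$out_w)
    warn <- TRUE
  } else {
    wts <- colMeans(grad)                          # spatially averaged grads
    heat <- matrix(pmax(act %*% wts, 0), g$out_h, g$out_w)
    rng <- range(heat)
    heat <- if (rng[2] > rng[1]) (heat - rng[1]) / (rng[2] - rng[1])
            else heat * 0
  }
  d <- dim(image)
  heat <- clamp01(resize_bilinear(heat, d[1], d[2]))
  structure(list(heat = heat, target_layer = target_layer, warning = warn),
            class = "gradcam_map")
}

#' Overlay a heatmap on an image
#'
#' `output = (1 - alpha) * image + alpha * colorized(heat)`; the heat is
#' colorized through the same dioptric color scale machinery as the map
#' renderer.
#'
#' @param image RGB array in `[0, 1]`.
#' @param heat a [gradcam_heatmap()] result or a matrix in `[0, 1]` of the
#'   same spatial shape.
#' @param alpha blend weight in `[0, 1]`.
#' @param scale color scale used to colorize the heat.
#' @return blended RGB array.
#' @export
overlay_heatmap <- function(image, heat, alpha = 0.5,
                            scale = default_color_scale()) {
  image <- as_rgb01(image)
  h <- if (inherits(heat, "gradcam_map")) heat$heat else heat
  kv_assert(all(dim(image)[1:2] == dim(h)),
            "overlay_heatmap: shape mismatch")
  colored <- colorize_gray(h, scale)
  clamp01((1 - alpha) * image + alpha * colored)
}

#' Original-vs-synthesized comparison table
#'
#' One row per (model, condition) with the six report metrics, plus per-model
#' flags for whether each metric improved when training included
#' synthesized images.
#'
#' @param results named list: per model, a list with elements `original`
#'   and/or `synthesized`, each a [diagnostic_metrics()] report.
#' @return a list of class `comparison_table` with `table` (metric rows) and
#'   `improved` (logical flags per model and metric; `NA` where a condition
#'   is missing).
#' @export
compare_experiments <- function(results) {
  kv_assert(length(results) > 0 && !is.null(names(results)),
            "results must be a named list of models")
  metrics <- c("accuracy", "sensitivity", "specificity", "ppv", "npv", "auc")
  rows <- list(); flags <- list()
  any_complete <- FALSE
  for (m in names(results)) {
    for (cond in c("original", "synthesized")) {
      rep <- results[[m]][[cond]]
      vals <- if (is.null(rep))
        stats::setNames(rep(NA_real_, length(metrics)), metrics) else
        vapply(metrics, function(k)
          if (is.null(rep[[k]])) NA_real_ else rep[[k]], 0)
      rows[[paste(m, cond)]] <- data.frame(
        model = m, condition = cond, t(vals),
        missing = is.null(rep))
    }
    o <- results[[m]]$original; s <- results[[m]]$synthesized
    if (!is.null(o) && !is.null(s)) any_complete <- TRUE
    flags[[m]] <- data.frame(
      model = m,
      t(vapply(metrics, function(k) {
        if (is.null(o) || is.null(s)) return(NA)
        isTRUE(s[[k]] > o[[k]])
      }, logical(1))))
  }
  kv_assert(any_complete,
            "at least one model needs both original and synthesized results")
  structure(list(table = do.call(rbind, rows),
                 improved = do.call(rbind, flags)),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 4)
  cat("\nimproved with synthesized training images:\n")
  print(x$improved, row.names = FALSE)
  invisible(x)
}

#' Evaluate prediction scores end to end
#'
#' Convenience wrapper: thresholds scores at `cutoff`, builds the confusion
#' matrix and the full metric report including AUC.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels binary labels.
#' @param prevalence optional prevalence for the predictive values (the
#'   default screening prevalence is 0.44).
#' @param cutoff decision threshold (default 0.5).
#' @return a [diagnostic_metrics()] report (with `auc`), the confusion
#'   matrix attached as attribute `"confusion"`.
#' @export
evaluate_predictions <- function(scores, labels, prevalence = NULL,
                                 cutoff = 0.5) {
  cm <- confusion(labels, as.integer(scores >= cutoff))
  roc <- roc_curve_auc(scores, labels)
  rep <- diagnostic_metrics(cm, prevalence, auc = roc$auc)
  attr(rep, "confusion") <- cm
  attr(rep, "roc") <- roc
  rep
}
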