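# Diagnostic evaluation: confusion counts, prevalence-adjusted metrics,
# ROC/AUC against brute-force concordance, cutoff selection, Grad-CAM,
# overlays, comparison tables.

test_that("confusion counts the four cells", {
  y <- rep(c(1, 0), each = 5)
  cm <- confusion(y, y)
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]), c(tp = 5, fn = 0,
                                                        fp = 0, tn = 5))
  all_neg <- confusion(y, rep(0, 10))
  expect_equal(unlist(all_neg[c("tp", "fn", "fp", "tn")]),
               c(tp = 0, fn = 5, fp = 0, tn = 5))
  # 800-image test set, 13 errors of which 5 false negatives (400/400 truth)
  truth <- rep(c(1, 0), each = 400)
  pred <- truth
  pred[1:5] <- 0          # 5 KCN called normal
  pred[401:408] <- 1      # 8 normals called KCN
  cm800 <- confusion(truth, pred)
  expect_equal(unlist(cm800[c("tp", "fn", "fp", "tn")]),
               c(tp = 395, fn = 5, fp = 8, tn = 392))
  expect_error(confusion(c(0, 1), c(1)), "length")
  expect_error(confusion(c(0, 2), c(1, 1)), "binary")
})

test_that("diagnostic metrics follow the count and Bayes formulas", {
  cm <- structure(list(tp = 395, fn = 5, fp = 8, tn = 392),
                  class = "confusion_matrix")
  r <- diagnostic_metrics(cm)
  expect_equal(r$sensitivity, 0.9875)
  expect_equal(r$specificity, 0.98)
  expect_equal(r$accuracy, 0.98375)

  perfect <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  rp <- diagnostic_metrics(perfect, prevalence = 0.44)
  expect_true(all(unlist(rp[c("accuracy", "sensitivity", "specificity",
                              "ppv", "npv")]) == 1))

  # sens 0.9, spec 0.8 at prevalence 0.5: ppv = 0.9 / 1.1
  cm2 <- structure(list(tp = 90, fn = 10, fp = 20, tn = 80),
                   class = "confusion_matrix")
  r2 <- diagnostic_metrics(cm2, prevalence = 0.5)
  expect_equal(r2$ppv, 0.9 / 1.1, tolerance = 1e-12)
  expect_equal(r2$npv, 0.8 * 0.5 / (0.8 * 0.5 + 0.1 * 0.5), tolerance = 1e-12)
})

test_that("prevalence at the sample positive fraction reproduces raw counts", {
  set.seed(7)
  for (i in 1:20) {
    cm <- structure(as.list(stats::setNames(sample(5:60, 4),
                                            c("tp", "fn", "fp", "tn"))),
                    class = "confusion_matrix")
    n <- cm$tp + cm$fn + cm$fp + cm$tn
    p <- (cm$tp + cm$fn) / n
    raw <- diagnostic_metrics(cm)
    adj <- diagnostic_metrics(cm, prevalence = p)
    expect_equal(adj$ppv, raw$ppv, tolerance = 1e-12)
    expect_equal(adj$npv, raw$npv, tolerance = 1e-12)
  }
})

test_that("metrics are invariant to scaling all counts", {
  cm <- structure(list(tp = 30, fn = 6, fp = 4, tn = 40),
                  class = "confusion_matrix")
  base <- diagnostic_metrics(cm, prevalence = 0.44)
  for (k in c(2, 7)) {
    cmk <- structure(list(tp = 30 * k, fn = 6 * k, fp = 4 * k, tn = 40 * k),
                     class = "confusion_matrix")
    sk <- diagnostic_metrics(cmk, prevalence = 0.44)
    for (m in c("accuracy", "sensitivity", "specificity", "ppv", "npv"))
      expect_equal(sk[[m]], base[[m]], tolerance = 1e-12)
  }
})

test_that("empty margins yield flagged undefined metrics", {
  cm <- confusion(c(0, 0, 0), c(0, 1, 0))
  r <- diagnostic_metrics(cm)
  expect_true("sensitivity" %in% r$undefined)
  expect_true(is.na(r$sensitivity))
})

test_that("ROC endpoints, the worked example, and the null are right", {
  sep <- roc_curve_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(sep$auc, 1.0)
  ex <- roc_curve_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(ex$auc, 0.75)  # 3 of 4 concordant pos-neg pairs
  expect_true(all(ex$points$fpr >= 0 & ex$points$fpr <= 1))
  expect_true(all(diff(ex$points$threshold) >= 0))
  set.seed(12)
  null <- roc_curve_auc(runif(1e4), rbinom(1e4, 1, 0.5))
  expect_lt(abs(null$auc - 0.5), 0.02)
  expect_error(roc_curve_auc(runif(5), rep(1, 5)), class = "undefined_roc")
})

test_that("trapezoidal AUC equals pairwise concordance with half ties", {
  concordance <- function(scores, y) {
    pos <- scores[y == 1]; neg <- scores[y == 0]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 1)  # coarse scores force ties
    expect_equal(roc_curve_auc(scores, y)$auc, concordance(scores, y),
                 tolerance = 1e-9)
  }
})

test_that("our AUC matches the reference implementation in pROC", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:10) {
    y <- c(0, 1, rbinom(30, 1, 0.4))
    s <- round(runif(32), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_curve_auc(s, y)$auc, ref, tolerance = 1e-12)
  }
})

test_that("the optimal cutoff targets sensitivity = specificity with tie-breaks", {
  pts <- data.frame(threshold = c(0.3, 0.5, 0.7),
                    fpr = c(0.4, 0.1, 0.02),
                    tpr = c(0.99, 0.9, 0.6))
  expect_equal(optimal_cutoff(pts), 0.5)        # sens 0.9 = spec 0.9
  two <- data.frame(threshold = c(0.4, 0.6),
                    fpr = c(0.20, 0.12),
                    tpr = c(0.95, 0.85))
  expect_equal(optimal_cutoff(two), 0.6)        # |diff| 0.03 < 0.15
  tie <- data.frame(threshold = c(0.2, 0.8),
                    fpr = c(1 - 0.85, 1 - 0.88),
                    tpr = c(0.90, 0.85))        # |diff| = 0.05 and 0.03
  expect_equal(optimal_cutoff(tie), 0.8)
  sums <- data.frame(threshold = c(0.3, 0.6),
                     fpr = c(1 - 0.85, 1 - 0.84),
                     tpr = c(0.90, 0.89))       # |diff| 0.05 both; sums 1.75/1.73
  expect_equal(optimal_cutoff(sums), 0.3)
})

test_that("Grad-CAM heat is normalized, input-sized, and scale-invariant", {
  model <- build_custom_cnn(custom_cnn_config(input_shape = c(24, 24, 3)),
                            seed = 6)
  x <- array(runif(24 * 24 * 3), c(24, 24, 3))
  gc <- gradcam_heatmap(model, x)
  expect_equal(dim(gc$heat), c(24, 24))
  expect_true(all(gc$heat >= 0 & gc$heat <= 1))
  # positive rescaling of the final-layer weights leaves the map unchanged
  scaled <- model
  k <- length(scaled$net$layers)
  scaled$net$layers[[k]]$W <- scaled$net$layers[[k]]$W * 7
  gc2 <- gradcam_heatmap(scaled, x)
  expect_equal(gc$heat, gc2$heat, tolerance = 1e-9)
  # zero gradients: zero map plus warning flag
  dead <- model
  dead$net$layers[[k]]$W <- dead$net$layers[[k]]$W * 0
  gc0 <- gradcam_heatmap(dead, x)
  expect_true(gc0$warning)
  expect_true(all(gc0$heat == 0))
})

test_that("heatmap overlays are exact affine blends", {
  img <- fixture_map(canvas_side = 64)
  heat <- matrix(runif(64 * 64), 64)
  expect_equal(overlay_heatmap(img, heat, alpha = 0), img,
               ignore_attr = TRUE)
  colored <- colorize_gray(heat, default_color_scale())
  expect_equal(overlay_heatmap(img, heat, alpha = 1), colored,
               ignore_attr = TRUE)
  mid <- overlay_heatmap(img, heat, alpha = 0.5)
  expect_equal(mid, (img + colored) / 2, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(overlay_heatmap(img, matrix(0, 3, 3)), "shape")
})

test_that("the comparison table flags per-metric improvement", {
  mk <- function(acc) {
    cm <- structure(list(tp = round(acc * 50), fn = 50 - round(acc * 50),
                         fp = 50 - round(acc * 50), tn = round(acc * 50)),
                    class = "confusion_matrix")
    diagnostic_metrics(cm, auc = acc)
  }
  res <- compare_experiments(list(cnn = list(original = mk(0.950),
                                             synthesized = mk(0.974))))
  expect_equal(nrow(res$table), 2)
  expect_true(res$improved$accuracy[res$improved$model == "cnn"])
  same <- compare_experiments(list(cnn = list(original = mk(0.9),
                                              synthesized = mk(0.9))))
  expect_false(any(unlist(same$improved[, -1])))
  gap <- compare_experiments(list(
    a = list(original = mk(0.9), synthesized = mk(0.95)),
    b = list(original = mk(0.9))))
  expect_true(any(gap$table$missing))
  expect_true(all(is.na(gap$improved[gap$improved$model == "b", -1])))
})
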