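# Dataset splitting and the two classifier protocols: a from-scratch custom
# CNN (fivefold cross-validation, RMSprop) and the transfer-learning recipe
# (frozen feature extraction with Adam, then fine-tuning of the top backbone
# layers). The positive class (score 1) is keratoconus.

POSITIVE_LABEL <- "kcn"

label_to_y <- function(label) as.numeric(label == POSITIVE_LABEL)

#' Train/test split specification
#'
#' 80/20 stratified split with 10% of the training portion held out for
#' validation; by default the test partition is drawn exclusively from
#' original (non-synthesized) images.
#'
#' @param train_frac training fraction (test fraction is its complement).
#' @param val_frac_of_train validation fraction carved out of the training
#'   portion.
#' @param stratified stratify all partitions by class.
#' @param test_originals_only restrict the test partition to
#'   `origin = "original"` images.
#' @param seed integer seed.
#' @return a list of class `split_spec`.
#' @export
split_spec <- function(train_frac = 0.8, val_frac_of_train = 0.1,
                       stratified = TRUE, test_originals_only = TRUE,
                       seed = 0) {
  kv_assert(train_frac > 0 && train_frac < 1, "train_frac must be in (0, 1)")
  structure(list(train_frac = train_frac, test_frac = 1 - train_frac,
                 val_frac_of_train = val_frac_of_train,
                 stratified = stratified,
                 test_originals_only = test_originals_only, seed = seed),
            class = "split_spec")
}

#' Split a labelled dataset into train / validation / test
#'
#' Partitions are disjoint and exhaustive, stratified per class, and
#' deterministic given the spec seed. When `test_originals_only` is set,
#' each class must contain at least its test share of original images
#' (`insufficient_original_images` otherwise).
#'
#' @param dataset a [kv_dataset()].
#' @param spec a [split_spec()].
#' @return list with `train`, `val`, `test` ([kv_dataset()]s) and
#'   `manifest` (data frame `id, label, origin, partition`).
#' @export
split_dataset <- function(dataset, spec = split_spec()) {
  n <- length(dataset)
  part <- character(n)
  with_seed(spec$seed, {
    for (cl in sort(unique(dataset$label))) {
      idx <- which(dataset$label == cl)
      n_test <- round(spec$test_frac * length(idx))
      pool <- if (spec$test_originals_only)
        idx[dataset$origin[idx] == "original"] else idx
      if (length(pool) < n_test)
        kv_error(sprintf(
          "class '%s' has %d original images but the test share is %d",
          cl, length(pool), n_test), "insufficient_original_images")
      test_idx <- sort(sample(pool, n_test))
      rest <- setdiff(idx, test_idx)
      n_val <- round(spec$val_frac_of_train * length(rest))
      val_idx <- sort(sample(rest, n_val))
      part[test_idx] <- "test"
      part[val_idx] <- "val"
      part[setdiff(rest, val_idx)] <- "train"
    }
  })
  manifest <- data.frame(id = dataset$id, label = dataset$label,
                         origin = dataset$origin, partition = part)
  list(train = dataset[part == "train"],
       val = dataset[part == "val"],
       test = dataset[part == "test"],
       manifest = manifest)
}

# --- custom CNN --------------------------------------------------------------

#' Custom CNN configuration
#'
#' The from-scratch classifier: 50 x 50 x 3 input, three 3 x 3 stride-2
#' convolutions with 64, 32 and 16 filters, two fully connected layers with
#' one 0.25-rate dropout layer between them, and a single sigmoid output
#' neuron. Trained with binary cross-entropy and RMSprop (learning rate
#' 1e-4) under fivefold cross-validation, 15 epochs per fold.
#'
#' @param input_shape input image shape.
#' @param conv_filters three convolution filter counts.
#' @param kernel,stride convolution geometry.
#' @param fc_widths the two fully connected widths.
#' @param dropout dropout rate between the FC layers.
#' @param folds cross-validation folds.
#' @param epochs epochs per fold.
#' @param learning_rate,optimizer,batch_size optimization protocol.
#' @param aug_flip,aug_rotation_frac training-time augmentation.
#' @return a list of class `custom_cnn_config`.
#' @export
custom_cnn_config <- function(input_shape = c(50, 50, 3),
                              conv_filters = c(64, 32, 16), kernel = 3,
                              stride = 2, fc_widths = c(128, 64),
                              dropout = 0.25, folds = 5, epochs = 15,
                              learning_rate = 1e-4, optimizer = "rmsprop",
                              batch_size = 32, aug_flip = TRUE,
                              aug_rotation_frac = 0) {
  structure(as.list(environment()), class = "custom_cnn_config")
}

#' Build the custom CNN
#'
#' @param config a [custom_cnn_config()].
#' @param seed parameter-initialization seed.
#' @return an object of class `kv_cnn`: the compiled network (final layer is
#'   the single-unit logit; the sigmoid is applied at prediction time and
#'   listed in the summary), its config, and the architecture summary.
#' @export
build_custom_cnn <- function(config = custom_cnn_config(), seed = 1) {
  specs <- c(
    lapply(config$conv_filters, function(f)
      layer_conv(f, config$kernel, config$stride, "relu")),
    list(layer_flatten(),
         layer_dense(config$fc_widths[1], "relu"),
         layer_dropout(config$dropout),
         layer_dense(config$fc_widths[2], "relu"),
         layer_dense(1, "linear", name = "logit")))
  net <- nn_build(specs, config$input_shape, seed = seed)
  summary <- rbind(net$summary,
                   data.frame(layer = "sigmoid", type = "activation",
                              output_shape = "1", n_params = 0))
  structure(list(net = net, config = config, summary = summary),
            class = "kv_cnn")
}

#' @export
print.kv_cnn <- function(x, ...) {
  cat("<kv_cnn>\n"); print(x$summary, row.names = FALSE); invisible(x)
}

#' Predict keratoconus scores
#'
#' @param model a trained `kv_cnn`.
#' @param inputs list of prepared input arrays (see [prepare_input()]).
#' @return numeric scores in `[0, 1]` (1 = keratoconus).
#' @export
predict_cnn <- function(model, inputs) {
  vapply(inputs, function(x) {
    logit <- nn_forward(model$net, x)$out$mat[1, 1]
    1 / (1 + exp(-logit))
  }, numeric(1))
}

# shared supervised training loop on prepared inputs
train_cnn_loop <- function(net, inputs, y, epochs, batch_size, lr, optimizer,
                           aug_flip = FALSE, aug_rot_frac = 0, seed = 0,
                           trainable = NULL, backbone = NULL,
                           backbone_trainable = integer(0),
                           val_inputs = NULL, val_y = NULL) {
  opt <- make_optimizer(optimizer, lr = lr)
  n <- length(inputs)
  hist <- vector("list", epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        bs <- length(idx)
        g_net <- NULL; g_bb <- NULL
        for (i in idx) {
          x <- inputs[[i]]
          if (aug_flip && runif(1) < 0.5) x <- flip_horizontal(x)
          if (aug_rot_frac > 0)
            x <- rotate_image(x, runif(1, -1, 1) * aug_rot_frac * 2 * pi)
          bb_fwd <- NULL
          if (!is.null(backbone)) {
            bb_fwd <- nn_forward(backbone, x, training = FALSE)
            x <- bb_fwd$out
          }
          fwd <- nn_forward(net, x, training = TRUE)
          l <- bce_logit(fwd$out$mat[1, 1], y[i])
          bw <- nn_backward(net, fwd$caches, matrix(l$dlogit, 1))
          g_net <- add_grads(g_net, bw$grads)
          if (!is.null(backbone) && length(backbone_trainable) > 0) {
            bwb <- nn_backward(backbone, bb_fwd$caches, bw$dinput)
            g_bb <- add_grads(g_bb, bwb$grads)
          }
          ep_loss <- ep_loss + l$loss
        }
        net <- opt_step(opt, net, scale_grads(g_net, 1 / bs),
                        prefix = "head", trainable = trainable)
        if (!is.null(g_bb))
          backbone <- opt_step(opt, backbone, scale_grads(g_bb, 1 / bs),
                               prefix = "backbone",
                               trainable = backbone_trainable)
      }
      row <- data.frame(epoch = ep, loss = ep_loss / n, val_loss = NA_real_)
      if (!is.null(val_inputs) && length(val_inputs) > 0) {
        vl <- 0
        for (i in seq_along(val_inputs)) {
          x <- val_inputs[[i]]
          if (!is.null(backbone)) x <- nn_forward(backbone, x)$out
          vl <- vl + bce_logit(nn_forward(net, x)$out$mat[1, 1], val_y[i])$loss
        }
        row$val_loss <- vl / length(val_inputs)
      }
      hist[[ep]] <- row
    }
  })
  list(net = net, backbone = backbone, history = do.call(rbind, hist))
}

#' Prepare every image of a dataset for a model input
#'
#' Grayscale images are recolored through the scale first (decoder outputs
#' return to color space before classification), then passed through
#' [prepare_input()].
#'
#' @param dataset a [kv_dataset()].
#' @param target,size_override,scale see [prepare_input()].
#' @return list of prepared arrays.
#' @export
dataset_inputs <- function(dataset, target = "custom_cnn",
                           size_override = NULL,
                           scale = default_color_scale()) {
  lapply(dataset$images, function(img) {
    if (is.matrix(img) && target != "vae") img <- colorize_gray(img, scale)
    prepare_input(img, target, size_override, scale)
  })
}

#' Train the custom CNN with cross-validation
#'
#' Shuffles the pool with the seed, splits it into `config$folds` folds,
#' trains a fresh model on each fold complement and predicts the held-out
#' fold, so every sample is held out exactly once.
#'
#' @param pool a [kv_dataset()] (the train + validation pool).
#' @param config a [custom_cnn_config()].
#' @param seed integer seed.
#' @param scale color scale for input preparation.
#' @return list of class `cv_records`: per fold, `fold`, `history`,
#'   `predictions` (data frame `id, score, label`) and the trained `model`.
#' @export
train_custom_cnn_cv <- function(pool, config = custom_cnn_config(), seed = 0,
                                scale = default_color_scale()) {
  n <- length(pool)
  kv_assert(n >= config$folds, "pool smaller than the number of folds")
  inputs <- dataset_inputs(pool, "custom_cnn", config$input_shape[1], scale)
  y <- label_to_y(pool$label)
  fold_of <- with_seed(derive_seed(seed, "folds"), {
    sample(rep(seq_len(config$folds), length.out = n))
  })
  records <- lapply(seq_len(config$folds), function(f) {
    hold <- which(fold_of == f)
    tr <- which(fold_of != f)
    model <- build_custom_cnn(config, seed = derive_seed(seed, paste0("m", f)))
    fit <- train_cnn_loop(model$net, inputs[tr], y[tr], config$epochs,
                          config$batch_size, config$learning_rate,
                          config$optimizer, config$aug_flip,
                          config$aug_rotation_frac,
                          seed = derive_seed(seed, paste0("f", f)))
    model$net <- fit$net
    scores <- predict_cnn(model, inputs[hold])
    list(fold = f, history = fit$history,
         predictions = data.frame(id = pool$id[hold], score = scores,
                                  label = pool$label[hold], fold = f),
         model = model)
  })
  structure(records, class = "cv_records", fold_of = fold_of)
}

#' Train the custom CNN on a pool and score a test set
#'
#' Single fit (no cross-validation): used for the paired
#' originals-vs-augmented comparison where both conditions share one test
#' set.
#'
#' @param train_pool,test [kv_dataset()]s.
#' @param config a [custom_cnn_config()].
#' @param seed integer seed.
#' @param scale color scale for input preparation.
#' @return list with `model`, `history`, `predictions`
#'   (data frame `id, score, label` on `test`).
#' @export
train_custom_cnn <- function(train_pool, test, config = custom_cnn_config(),
                             seed = 0, scale = default_color_scale()) {
  inputs <- dataset_inputs(train_pool, "custom_cnn", config$input_shape[1],
                           scale)
  y <- label_to_y(train_pool$label)
  model <- build_custom_cnn(config, seed = derive_seed(seed, "model"))
  fit <- train_cnn_loop(model$net, inputs, y, config$epochs,
                        config$batch_size, config$learning_rate,
                        config$optimizer, config$aug_flip,
                        config$aug_rotation_frac,
                        seed = derive_seed(seed, "fit"))
  model$net <- fit$net
  test_in <- dataset_inputs(test, "custom_cnn", config$input_shape[1], scale)
  list(model = model, history = fit$history,
       predictions = data.frame(id = test$id,
                                score = predict_cnn(model, test_in),
                                label = test$label))
}

# --- transfer learning -------------------------------------------------------

#' Stub convolutional backbone
#'
#' A small fixed-weight convolutional feature extractor implementing the
#' backbone interface (declared input side, spatial feature-map output).
#' Used wherever a pretrained backbone would plug in, so the transfer recipe
#' is testable without external weight assets.
#'
#' @param input_side declared input side in pixels.
#' @param filters filter counts of the stub's convolution layers.
#' @param seed weight seed.
#' @return an object of class `kv_backbone` with `net`, `input_side`,
#'   `param_layers` (indices of parameterized layers).
#' @export
stub_backbone <- function(input_side = 64, filters = c(8, 8, 8), seed = 42) {
  specs <- lapply(filters, function(f) layer_conv(f, 3, 2, "relu"))
  net <- nn_build(specs, c(input_side, input_side, 3), seed = seed)
  structure(list(net = net, input_side = input_side,
                 param_layers = which(vapply(net$layers, function(l)
                   !is.null(l$W), logical(1)))),
            class = "kv_backbone")
}

#' Transfer-learning configuration
#'
#' Frozen feature extraction (15 epochs, Adam, learning rate 1e-4, binary
#' cross-entropy) followed by fine-tuning of the top backbone layers for 10
#' more epochs. The classification head is global average pooling, a
#' 512-unit dense layer, 0.2-rate dropout and a single sigmoid neuron; the
#' input pipeline applies random horizontal flips, rotations up to 20% of a
#' turn, and the `[0, 255] -> [-1, 1]` rescale.
#'
#' @param backbone a backbone object (see [stub_backbone()]).
#' @param head_dense,head_dropout head architecture.
#' @param aug_flip,aug_rotation_frac augmentation.
#' @param frozen_epochs,finetune_epochs epochs per phase.
#' @param finetune_unfrozen_layers number of top backbone layers unfrozen in
#'   the fine-tuning phase.
#' @param learning_rate,optimizer,batch_size optimization protocol.
#' @return a list of class `transfer_config`.
#' @export
transfer_config <- function(backbone, head_dense = 512, head_dropout = 0.2,
                            aug_flip = TRUE, aug_rotation_frac = 0.20,
                            frozen_epochs = 15, finetune_epochs = 10,
                            finetune_unfrozen_layers = 3,
                            learning_rate = 1e-4, optimizer = "adam",
                            batch_size = 32) {
  kv_assert(!is.null(backbone$input_side),
            "backbone must declare its input side")
  structure(as.list(environment()), class = "transfer_config")
}

#' Build the transfer model
#'
#' Pipeline: augmentation -> rescale -> frozen backbone -> global average
#' pool -> dense head -> dropout -> single-unit sigmoid.
#'
#' @param config a [transfer_config()].
#' @param seed head-initialization seed.
#' @return an object of class `kv_transfer` with `backbone`, `head` and the
#'   combined `summary`.
#' @export
build_transfer_model <- function(config, seed = 1) {
  bb <- config$backbone
  kv_assert(!is.null(bb$input_side), "backbone must declare its input side")
  out_row <- utils::tail(bb$net$summary, 1)
  shape <- as.integer(strsplit(out_row$output_shape, " x ")[[1]])
  kv_assert(length(shape) == 3, "backbone must emit a spatial feature map")
  head <- nn_build(list(layer_gap(),
                        layer_dense(config$head_dense, "relu"),
                        layer_dropout(config$head_dropout),
                        layer_dense(1, "linear", name = "logit")),
                   shape, seed = seed)
  summary <- rbind(cbind(part = "backbone", bb$net$summary),
                   cbind(part = "head", head$summary),
                   data.frame(part = "head", layer = "sigmoid",
                              type = "activation", output_shape = "1",
                              n_params = 0))
  structure(list(backbone = bb, head = head, config = config,
                 summary = summary),
            class = "kv_transfer")
}

#' Predict with a transfer model
#'
#' @param model a `kv_transfer`.
#' @param inputs list of prepared arrays (`[-1, 1]`, backbone input side).
#' @return scores in `[0, 1]`.
#' @export
predict_transfer <- function(model, inputs) {
  vapply(inputs, function(x) {
    feat <- nn_forward(model$backbone$net, x)$out
    logit <- nn_forward(model$head, feat)$out$mat[1, 1]
    1 / (1 + exp(-logit))
  }, numeric(1))
}

#' Train the transfer model: frozen phase then fine-tuning
#'
#' Phase 1 updates only the head; backbone parameters are bit-identical
#' before and after. Phase 2 additionally unfreezes exactly
#' `finetune_unfrozen_layers` top backbone layers.
#'
#' @param model a [build_transfer_model()] result.
#' @param splits a [split_dataset()] result (train and val are used).
#' @param seed integer seed.
#' @param scale color scale for input preparation.
#' @return list with the trained `model` and two records `frozen` /
#'   `finetune`, each holding `history` and `predictions` on the validation
#'   set.
#' @export
train_transfer <- function(model, splits, seed = 0,
                           scale = default_color_scale()) {
  cfg <- model$config
  side <- model$backbone$input_side
  tr_in <- dataset_inputs(splits$train, "transfer", side, scale)
  tr_y <- label_to_y(splits$train$label)
  val_in <- dataset_inputs(splits$val, "transfer", side, scale)
  val_y <- label_to_y(splits$val$label)
  # phase 1: frozen backbone, head only
  fit1 <- train_cnn_loop(model$head, tr_in, tr_y, cfg$frozen_epochs,
                         cfg$batch_size, cfg$learning_rate, cfg$optimizer,
                         cfg$aug_flip, cfg$aug_rotation_frac,
                         seed = derive_seed(seed, "frozen"),
                         backbone = model$backbone$net,
                         backbone_trainable = integer(0),
                         val_inputs = val_in, val_y = val_y)
  model$head <- fit1$net
  rec1 <- list(phase = "frozen", history = fit1$history,
               predictions = data.frame(
                 id = splits$val$id, score = predict_transfer(model, val_in),
                 label = splits$val$label))
  # phase 2: unfreeze the top parameterized backbone layers
  pl <- model$backbone$param_layers
  unfrozen <- utils::tail(pl, cfg$finetune_unfrozen_layers)
  fit2 <- train_cnn_loop(model$head, tr_in, tr_y, cfg$finetune_epochs,
                         cfg$batch_size, cfg$learning_rate, cfg$optimizer,
                         cfg$aug_flip, cfg$aug_rotation_frac,
                         seed = derive_seed(seed, "finetune"),
                         backbone = model$backbone$net,
                         backbone_trainable = unfrozen,
                         val_inputs = val_in, val_y = val_y)
  model$head <- fit2$net
  model$backbone$net <- fit2$backbone
  rec2 <- list(phase = "finetune", history = fit2$history,
               predictions = data.frame(
                 id = splits$val$id, score = predict_transfer(model, val_in),
                 label = splits$val$label))
  list(model = model, frozen = rec1, finetune = rec2)
}
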