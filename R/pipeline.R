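# Experiment orchestration: one YAML config drives cohort synthesis,
# preprocessing, VAE training, augmentation, the paired
# originals-vs-augmented classifier comparison, and evaluation.

scale_presets <- list(
  paper = list(n_normal = 978, n_kcn = 780, per_class_target = 2000,
               vae_epochs = 50, cnn_epochs = 15, folds = 5,
               render_chain = TRUE),
  demo = list(n_normal = 100, n_kcn = 100, per_class_target = 200,
              vae_epochs = 3, cnn_epochs = 5, folds = 3,
              render_chain = TRUE)
)

default_config <- function(scale = "demo") {
  p <- scale_presets[[scale]]
  list(
    scale = scale,
    seed = 0,
    out_dir = file.path("runs", scale),
    synthmap = list(n_normal = p$n_normal, n_kcn = p$n_kcn,
                    noise = list(period = 16, amplitude = 0.25,
                                 orientation = "rows",
                                 impulse_density = 0.01),
                    canvas = list(height = 300, width = 300)),
    preprocess = list(target_size = 104, render_chain = p$render_chain),
    vae = list(input_size = 104, epochs = p$vae_epochs, batch_size = 32,
               latent_dim = 1, learning_rate = 1e-4),
    classify = list(model = "custom", epochs = p$cnn_epochs,
                    folds = p$folds, per_class_target = p$per_class_target,
                    batch_size = 32, learning_rate = 1e-4),
    evaluate = list(prevalence = 0.44, gradcam_alpha = 0.5, n_gradcam = 4)
  )
}

#' Validate and normalize an experiment configuration
#'
#' Reads the YAML file (or takes a list), fills defaults from the `scale`
#' preset (`"demo"`: 100 + 100 originals, target 200 per class, short
#' training; `"paper"`: 978 + 780 originals, target 2000 per class, full
#' epochs), rejects inconsistent blocks, and warns about unknown keys
#' (ignored, but recorded in the returned config under `ignored_keys`).
#'
#' @param config path to a YAML file or a configuration list.
#' @return the normalized configuration list (class `experiment_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  kv_assert(is.list(config), "config must be a list or a YAML path")
  scale <- if (!is.null(config$scale)) config$scale else "demo"
  kv_assert(scale %in% names(scale_presets),
            sprintf("unknown scale '%s' (use %s)", scale,
                    paste(names(scale_presets), collapse = "/")))
  base <- default_config(scale)
  ignored <- setdiff(names(config), c(names(base), "scale"))
  for (k in ignored)
    warning(sprintf("unknown config key '%s' ignored", k), call. = FALSE)
  config <- config[setdiff(names(config), ignored)]
  merged <- utils::modifyList(base, config)
  if (merged$vae$input_size != merged$preprocess$target_size)
    kv_error(sprintf(
      "vae.input_size (%d) must equal preprocess.target_size (%d)",
      merged$vae$input_size, merged$preprocess$target_size),
      "kv_config_error")
  merged$ignored_keys <- ignored
  structure(merged, class = c("experiment_config", "list"))
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Paired originals-vs-augmented classifier comparison
#'
#' The package's central experiment in memory: synthesize an original
#' cohort, split it (test = originals only), train the VAE on the training
#' portion, expand that portion to a per-class target with synthesized
#' images, train the custom CNN once on the originals-only pool and once on
#' the augmented pool, and evaluate both on the *same* test set, so the
#' comparison is paired.
#'
#' @param n_normal,n_kcn original cohort composition.
#' @param per_class_target augmented per-class size.
#' @param seed global seed (stage seeds are derived from it).
#' @param vae_epochs,cnn_epochs training lengths.
#' @param size map side in pixels.
#' @param prevalence prevalence for the predictive values.
#' @param scale color scale.
#' @param moments optional class-moment override passed to
#'   [sample_cohort()].
#' @return list with `original` and `synthesized` metric reports, the raw
#'   accuracies, predictions, and the augmented-pool class counts.
#' @export
augmentation_experiment <- function(n_normal = 100, n_kcn = 100,
                                    per_class_target = 200, seed = 0,
                                    vae_epochs = 3, cnn_epochs = 5,
                                    size = 104, prevalence = NULL,
                                    scale = default_color_scale(),
                                    moments = NULL) {
  args <- list(n_normal, n_kcn, derive_seed(seed, "cohort"), size = size,
               scale = scale)
  if (!is.null(moments)) args$moments <- moments
  cohort <- do.call(cohort_graymaps, args)
  splits <- split_dataset(cohort, split_spec(seed = derive_seed(seed, "split")))
  train_pool <- c(splits$train, splits$val)
  cfg_vae <- vae_config(input_shape = c(size, size, 1),
                        dec_dense = vae_flat_units(size),
                        epochs = vae_epochs)
  fit <- train_vae(train_pool, cfg_vae, seed = derive_seed(seed, "vae"))
  augmented <- synthesize_to_target(train_pool, fit$model, per_class_target,
                                    seed = derive_seed(seed, "aug"))
  cfg_cnn <- custom_cnn_config(epochs = cnn_epochs)
  run_orig <- train_custom_cnn(train_pool, splits$test, cfg_cnn,
                               seed = derive_seed(seed, "cnn_orig"),
                               scale = scale)
  run_aug <- train_custom_cnn(augmented, splits$test, cfg_cnn,
                              seed = derive_seed(seed, "cnn_aug"),
                              scale = scale)
  rep_o <- evaluate_predictions(run_orig$predictions$score,
                                run_orig$predictions$label, prevalence)
  rep_s <- evaluate_predictions(run_aug$predictions$score,
                                run_aug$predictions$label, prevalence)
  list(original = rep_o, synthesized = rep_s,
       accuracy_original = rep_o$accuracy,
       accuracy_augmented = rep_s$accuracy,
       predictions = list(original = run_orig$predictions,
                          synthesized = run_aug$predictions),
       augmented_counts = table(augmented$label),
       n_test = length(splits$test),
       vae_history = fit$history)
}

# flattened encoder width for a given input side (three stride-2 layers,
# 16 filters at the last one)
vae_flat_units <- function(size, stride = 2, n_conv = 3, last_filters = 16) {
  s <- size
  for (i in seq_len(n_conv)) s <- ceiling(s / stride)
  s * s * last_filters
}

#' Run the full experiment from a configuration
#'
#' Executes all stages in order — cohort synthesis, preprocessing (render,
#' acquisition noise, denoising, HSV cornea segmentation, order-preserving
#' grayscale), VAE training, dataset expansion, paired classifier training
#' (originals-only vs augmented, identical test set), evaluation with the
#' comparison table, and Grad-CAM overlays — writing CSV/JSON/PNG artifacts
#' under `config$out_dir` and returning a run manifest. A failing stage is
#' recorded in the manifest with partial outputs preserved.
#'
#' @param config an [validate_config()]-normalized configuration (or a list
#'   or YAML path, normalized on entry).
#' @return the run manifest (list, also written as `manifest.json`).
#' @export
run_experiment <- function(config) {
  if (!inherits(config, "experiment_config")) config <- validate_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  manifest <- list(config_hash = config_hash(config), seed = seed,
                   scale = config$scale, stages = list(),
                   artifacts = character(0),
                   ignored_keys = config$ignored_keys)
  scale_obj <- default_color_scale()
  state <- new.env(parent = emptyenv())

  add_artifact <- function(path) {
    manifest$artifacts <<- c(manifest$artifacts, path)
    path
  }
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({ fun(); "complete" },
                    error = function(e) paste("failed:",
                                              conditionMessage(e)))
    manifest$stages[[name]] <<- list(
      status = res, seconds = round(proc.time()[["elapsed"]] - t0, 2))
    message(sprintf("[%s] %s (%.1fs)", name, res,
                    manifest$stages[[name]]$seconds))
    if (!identical(res, "complete")) kv_error(
      sprintf("stage '%s' failed", name), "kv_stage_error")
    invisible(NULL)
  }

  ok <- tryCatch({
    stage("synth_cohort", function() {
      state$params <- sample_cohort(config$synthmap$n_normal,
                                    config$synthmap$n_kcn,
                                    derive_seed(seed, "cohort"))
      state$labels <- vapply(state$params, `[[`, "", "label")
    })
    stage("preprocess", function() {
      size <- config$preprocess$target_size
      canvas <- do.call(map_canvas, config$synthmap$canvas)
      grays <- lapply(seq_along(state$params), function(i) {
        p <- state$params[[i]]
        if (isTRUE(config$preprocess$render_chain)) {
          img <- synth_topomap(p, scale_obj, canvas)
          img <- add_acquisition_noise(img, config$synthmap$noise,
                                       seed = derive_seed(seed, paste0("nz", i)))
          img <- remove_regular_noise(img)
          crop <- segment_cornea(img)
          ordered_grayscale(crop$image, scale_obj, size)
        } else {
          field_to_graymap(curvature_field(p, c(size, size)), scale_obj, size)
        }
      })
      state$originals <- kv_dataset(grays, state$labels)
      utils::write.csv(
        data.frame(id = state$originals$id, label = state$labels,
                   pattern = vapply(state$params, `[[`, "", "pattern"),
                   ave_k = vapply(state$params, `[[`, 0, "ave_k"),
                   cyl = vapply(state$params, `[[`, 0, "cyl"),
                   origin = "original"),
        add_artifact(file.path(out, "cohort_manifest.csv")),
        row.names = FALSE)
    })
    stage("split", function() {
      state$splits <- split_dataset(
        state$originals, split_spec(seed = derive_seed(seed, "split")))
      utils::write.csv(state$splits$manifest,
                       add_artifact(file.path(out, "split_manifest.csv")),
                       row.names = FALSE)
      state$train_pool <- c(state$splits$train, state$splits$val)
    })
    stage("train_vae", function() {
      size <- config$preprocess$target_size
      cfg <- vae_config(input_shape = c(size, size, 1),
                        dec_dense = vae_flat_units(size),
                        latent_dim = config$vae$latent_dim,
                        learning_rate = config$vae$learning_rate,
                        epochs = config$vae$epochs,
                        batch_size = config$vae$batch_size)
      fit <- train_vae(state$train_pool, cfg, seed = derive_seed(seed, "vae"))
      state$vae <- fit$model
      utils::write.csv(fit$history,
                       add_artifact(file.path(out, "vae_history.csv")),
                       row.names = FALSE)
      save_model(state$vae, add_artifact(file.path(out, "vae_weights.rds")))
      lat <- encode_latents(state$train_pool, state$vae,
                            scatter_png = add_artifact(
                              file.path(out, "latent_scatter.png")))
      utils::write.csv(lat, add_artifact(file.path(out, "latents.csv")),
                       row.names = FALSE)
    })
    stage("augment", function() {
      state$augmented <- synthesize_to_target(
        state$train_pool, state$vae, config$classify$per_class_target,
        seed = derive_seed(seed, "aug"))
      utils::write.csv(
        data.frame(id = state$augmented$id, label = state$augmented$label,
                   origin = state$augmented$origin),
        add_artifact(file.path(out, "augmented_manifest.csv")),
        row.names = FALSE)
    })
    stage("train_classifiers", function() {
      cfg <- custom_cnn_config(epochs = config$classify$epochs,
                               batch_size = config$classify$batch_size,
                               learning_rate = config$classify$learning_rate,
                               folds = config$classify$folds)
      cv <- train_custom_cnn_cv(state$train_pool, cfg,
                                seed = derive_seed(seed, "cv"),
                                scale = scale_obj)
      cv_pred <- do.call(rbind, lapply(cv, `[[`, "predictions"))
      utils::write.csv(cv_pred,
                       add_artifact(file.path(out, "cv_predictions.csv")),
                       row.names = FALSE)
      state$run_orig <- train_custom_cnn(state$train_pool, state$splits$test,
                                         cfg,
                                         seed = derive_seed(seed, "cnn_orig"),
                                         scale = scale_obj)
      state$run_aug <- train_custom_cnn(state$augmented, state$splits$test,
                                        cfg,
                                        seed = derive_seed(seed, "cnn_aug"),
                                        scale = scale_obj)
      for (cond in c("orig", "aug")) {
        run <- if (cond == "orig") state$run_orig else state$run_aug
        utils::write.csv(run$predictions,
                         add_artifact(file.path(
                           out, sprintf("test_predictions_%s.csv", cond))),
                         row.names = FALSE)
      }
      save_model(state$run_aug$model,
                 add_artifact(file.path(out, "custom_cnn_weights.rds")))
    })
    stage("evaluate", function() {
      prev <- config$evaluate$prevalence
      rep_o <- evaluate_predictions(state$run_orig$predictions$score,
                                    state$run_orig$predictions$label, prev)
      rep_s <- evaluate_predictions(state$run_aug$predictions$score,
                                    state$run_aug$predictions$label, prev)
      comp <- compare_experiments(list(custom_cnn = list(
        original = rep_o, synthesized = rep_s)))
      utils::write.csv(comp$table,
                       add_artifact(file.path(out, "comparison.csv")),
                       row.names = FALSE)
      roc <- attr(rep_s, "roc")
      utils::write.csv(roc$points,
                       add_artifact(file.path(out, "roc_points.csv")),
                       row.names = FALSE)
      jsonlite::write_json(
        list(original = unclass(rep_o)[1:7],
             synthesized = unclass(rep_s)[1:7],
             optimal_threshold = roc$optimal_threshold),
        add_artifact(file.path(out, "metrics.json")),
        auto_unbox = TRUE, digits = NA)
      # Grad-CAM overlays on the first few test maps
      n_gc <- min(config$evaluate$n_gradcam, length(state$splits$test))
      test_in <- dataset_inputs(state$splits$test[seq_len(n_gc)],
                                "custom_cnn", scale = scale_obj)
      for (i in seq_len(n_gc)) {
        gc <- gradcam_heatmap(state$run_aug$model, test_in[[i]])
        ov <- overlay_heatmap(test_in[[i]], gc,
                              alpha = config$evaluate$gradcam_alpha,
                              scale = scale_obj)
        write_image(ov, add_artifact(file.path(
          out, sprintf("gradcam_%02d.png", i))))
      }
      state$comparison <- comp
    })
    TRUE
  }, kv_stage_error = function(e) FALSE)

  manifest$complete <- isTRUE(ok)
  if (isTRUE(ok)) {
    manifest$augmented_counts <- as.list(table(state$augmented$label))
    manifest$test_size <- length(state$splits$test)
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
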