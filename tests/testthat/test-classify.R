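# Splitting and classifier protocols.

test_that("split_dataset stratifies, is exhaustive, and is seeded", {
  ds <- tiny_gray_cohort(5, 5, seed = 1)
  sp <- split_dataset(ds, split_spec(seed = 3))
  expect_equal(length(sp$test), 2)
  expect_equal(as.vector(table(sp$test$label)), c(1, 1))
  expect_equal(length(sp$train) + length(sp$val), 8)
  ids <- c(sp$train$id, sp$val$id, sp$test$id)
  expect_setequal(ids, ds$id)
  expect_equal(anyDuplicated(ids), 0)
  sp2 <- split_dataset(ds, split_spec(seed = 3))
  expect_identical(sp$manifest, sp2$manifest)
  sp3 <- split_dataset(ds, split_spec(seed = 4))
  expect_false(identical(sp$manifest$partition, sp3$manifest$partition))
})

test_that("split proportions hold within one sample per class", {
  ds <- tiny_gray_cohort(57, 43, seed = 2)
  sp <- split_dataset(ds, split_spec(seed = 1))
  m <- sp$manifest
  for (cl in c("normal", "kcn")) {
    n <- sum(m$label == cl)
    expect_lte(abs(sum(m$label == cl & m$partition == "test") - 0.2 * n), 1)
    rest <- n - sum(m$label == cl & m$partition == "test")
    expect_lte(abs(sum(m$label == cl & m$partition == "val") - 0.1 * rest), 1)
  }
})

test_that("the test partition contains only originals, or errors out", {
  ds <- tiny_gray_cohort(10, 10, seed = 5)
  v <- build_vae(tiny_vae_config(), seed = 1)
  aug <- synthesize_to_target(ds, v, 30, seed = 2)
  sp <- split_dataset(aug, split_spec(seed = 0))
  expect_true(all(sp$test$origin == "original"))
  # kcn class reduced to 2 originals among 22 images: test share is 4
  few <- aug[c(which(aug$label == "normal"),
               which(aug$label == "kcn" & aug$origin == "synthesized"),
               which(aug$label == "kcn" & aug$origin == "original")[1:2])]
  expect_error(split_dataset(few, split_spec(seed = 0)),
               class = "insufficient_original_images")
})

test_that("the custom CNN architecture follows its contract", {
  m <- build_custom_cnn()
  shapes <- m$summary$output_shape
  expect_equal(shapes[1:3], c("25 x 25 x 64", "13 x 13 x 32", "7 x 7 x 16"))
  expect_equal(shapes[4], "784")
  expect_equal(sum(m$summary$type == "dropout"), 1)
  drop_layer <- m$net$layers[[which(vapply(m$net$layers, function(l)
    l$type == "dropout", logical(1)))]]
  expect_equal(drop_layer$rate, 0.25)
  # single-unit sigmoid head
  expect_equal(utils::tail(shapes, 2), c("1", "1"))
  expect_equal(utils::tail(m$summary$layer, 1), "sigmoid")
})

test_that("cross-validation covers the pool exactly once and is seeded", {
  pool <- fixture_separable(15)   # 30 images
  cfg <- custom_cnn_config(folds = 5, epochs = 2, batch_size = 8)
  recs <- train_custom_cnn_cv(pool, cfg, seed = 1)
  expect_length(recs, 5)
  held <- unlist(lapply(recs, function(r) r$predictions$id))
  expect_setequal(held, pool$id)
  expect_equal(anyDuplicated(held), 0)
  expect_true(all(unlist(lapply(recs, function(r) r$predictions$score)) >= 0))
  expect_true(all(unlist(lapply(recs, function(r) r$predictions$score)) <= 1))
  recs2 <- train_custom_cnn_cv(pool, cfg, seed = 1)
  expect_identical(attr(recs, "fold_of"), attr(recs2, "fold_of"))
  expect_identical(recs[[1]]$predictions, recs2[[1]]$predictions)
  expect_error(train_custom_cnn_cv(pool[1:3], cfg, 1), "folds")
})

test_that("the custom CNN separates a trivially separable toy dataset", {
  accs <- vapply(0:2, function(s) {
    pool <- fixture_separable(12)
    cfg <- custom_cnn_config(folds = 3, epochs = 40, batch_size = 4,
                             learning_rate = 3e-3)
    recs <- train_custom_cnn_cv(pool, cfg, seed = s)
    preds <- do.call(rbind, lapply(recs, `[[`, "predictions"))
    mean((preds$score >= 0.5) == (preds$label == "kcn"))
  }, 0)
  expect_gte(mean(accs), 0.95)
})

test_that("the transfer head sits on global average pooling of the backbone", {
  bb <- stub_backbone(input_side = 40, filters = c(4, 8), seed = 9)
  model <- build_transfer_model(transfer_config(bb), seed = 1)
  head_rows <- subset(model$summary, part == "head")
  expect_equal(head_rows$output_shape[1], "8")   # GAP width = channels
  expect_equal(head_rows$output_shape[2], "512")
  expect_equal(utils::tail(head_rows$layer, 1), "sigmoid")
  expect_error(transfer_config(list(net = bb$net)), "input side")
  # deterministic scores at inference
  x <- prepare_input(array(runif(40 * 40 * 3), c(40, 40, 3)), "transfer", 40)
  s1 <- predict_transfer(model, list(x))
  s2 <- predict_transfer(model, list(x))
  expect_identical(s1, s2)
  expect_true(s1 >= 0 && s1 <= 1)
})

test_that("freezing and unfreezing behave bitwise as declared", {
  ds <- fixture_separable(8, side = 24)
  sp <- split_dataset(ds, split_spec(seed = 1))
  bb <- stub_backbone(input_side = 24, filters = c(4, 4, 4), seed = 2)
  cfg <- transfer_config(bb, frozen_epochs = 2, finetune_epochs = 2,
                         finetune_unfrozen_layers = 1, batch_size = 8,
                         aug_flip = FALSE, aug_rotation_frac = 0)
  model <- build_transfer_model(cfg, seed = 3)
  before <- lapply(model$backbone$net$layers, `[[`, "W")
  res <- train_transfer(model, sp, seed = 4)
  expect_equal(nrow(res$frozen$history), 2)
  expect_equal(nrow(res$finetune$history), 2)
  expect_false(any(is.na(res$frozen$history$val_loss)))
  after <- lapply(res$model$backbone$net$layers, `[[`, "W")
  # only the topmost backbone layer may change, and only in phase 2
  expect_identical(before[[1]], after[[1]])
  expect_identical(before[[2]], after[[2]])
  expect_false(identical(before[[3]], after[[3]]))

  # with no unfrozen layers the backbone stays bit-identical end to end
  cfg0 <- transfer_config(bb, frozen_epochs = 2, finetune_epochs = 1,
                          finetune_unfrozen_layers = 0, batch_size = 8,
                          aug_flip = FALSE, aug_rotation_frac = 0)
  model0 <- build_transfer_model(cfg0, seed = 3)
  res0 <- train_transfer(model0, sp, seed = 4)
  expect_identical(lapply(res0$model$backbone$net$layers, `[[`, "W"), before)
})
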