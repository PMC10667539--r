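# VAE: architecture closure, reparameterization, the loss terms against
# independent oracles, training/serialization contracts, latent-space ops.

test_that("the architecture closes: 2704 flatten, (104, 104, 1) output, 2 heads", {
  v <- build_vae()
  expect_equal(v$flatten_units, 2704)
  flat_row <- subset(v$summary, part == "encoder" & type == "flatten")
  expect_equal(flat_row$output_shape, "2704")
  expect_equal(utils::tail(v$summary$output_shape, 1), "104 x 104 x 1")
  expect_equal(v$latent_params, 2L)
  # one scalar posterior mean and one scalar posterior sd head
  expect_equal(subset(v$summary, part == "mu_head")$output_shape, "1")
  expect_equal(subset(v$summary, part == "logsig_head")$output_shape, "1")
})

test_that("a shape chain that does not close raises architecture_mismatch", {
  bad <- vae_config(input_shape = c(8, 8, 1))  # flatten 16, dec_dense 2704
  expect_error(build_vae(bad), class = "architecture_mismatch")
  ok <- vae_config(input_shape = c(8, 8, 1), dec_dense = 16)
  expect_equal(build_vae(ok)$flatten_units, 16)
})

test_that("reparameterization is the affine map z = mu + sigma * eps", {
  expect_equal(reparameterize(latent_posterior(0, 1), 0.5)$z, 0.5)
  expect_equal(reparameterize(latent_posterior(2, 0.001), 0)$z, 2.0)
  expect_error(latent_posterior(0, -1), "sigma")
  set.seed(11)
  z <- vapply(rnorm(1e5), function(e)
    reparameterize(latent_posterior(1, 2), e)$z, 0)
  expect_lt(abs(mean(z) - 1), 0.02)
  expect_lt(abs(sd(z) - 2), 0.02)
})

test_that("closed-form KL matches numerical integration of q log(q/p)", {
  expect_equal(kl_divergence(latent_posterior(0, 1)), 0)
  expect_equal(kl_divergence(latent_posterior(1, 1)), 0.5)
  kl_numeric <- function(mu, sigma) {
    stats::integrate(function(z) {
      q <- stats::dnorm(z, mu, sigma)
      ifelse(q > 0, q * (log(q) - stats::dnorm(z, log = TRUE)), 0)
    }, mu - 12 * sigma, mu + 12 * sigma, rel.tol = 1e-10)$value
  }
  expect_equal(kl_divergence(latent_posterior(0.5, 2)), 0.93186,
               tolerance = 1e-4)
  grid <- expand.grid(mu = seq(-3, 3, length.out = 5),
                      sigma = seq(0.2, 3, length.out = 4))
  for (i in seq_len(nrow(grid))) {
    p <- latent_posterior(grid$mu[i], grid$sigma[i])
    expect_lt(abs(kl_divergence(p) - kl_numeric(p$mu, p$sigma)), 1e-6)
  }
})

test_that("reconstruction loss matches the per-pixel Bernoulli oracle", {
  x <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(reconstruction_loss(x, x), 0)
  ones <- matrix(1, 3, 3)
  expect_equal(reconstruction_loss(ones, matrix(0.5, 3, 3)), 9 * log(2))
  set.seed(4)
  a <- matrix(runif(16), 4); b <- matrix(runif(16), 4)
  oracle <- -sum(a * log(b) + (1 - a) * log(1 - b))
  expect_equal(reconstruction_loss(a, b), oracle, tolerance = 1e-12)
  expect_equal(reconstruction_loss(a, b, type = "mse"), sum((a - b)^2))
  expect_error(reconstruction_loss(a, matrix(0.5, 2, 8)), "shape")
})

test_that("the total loss is exactly reconstruction plus KL", {
  x <- matrix(c(0, 1, 1, 0), 2)
  lb <- vae_total_loss(x, x, latent_posterior(0, 1))
  expect_equal(lb$total, 0)
  expect_equal(lb$recon, 0)
  expect_equal(lb$kl, 0)
  set.seed(5)
  a <- matrix(runif(16), 4); b <- matrix(runif(16), 4)
  post <- latent_posterior(0.7, 1.4)
  lb2 <- vae_total_loss(a, b, post)
  expect_equal(lb2$total, lb2$recon + lb2$kl, tolerance = 1e-12)
  expect_equal(lb2$recon, reconstruction_loss(a, b))
  expect_equal(lb2$kl, kl_divergence(post))
  expect_gte(lb2$kl, 0)
})

test_that("training runs to contract: history length, determinism, reload", {
  ds <- tiny_gray_cohort(5, 5, seed = 2)
  cfg <- tiny_vae_config(epochs = 3, batch_size = 4)
  fit <- train_vae(ds, cfg, seed = 0)
  expect_equal(nrow(fit$history), 3)
  expect_true(all(fit$history$kl >= 0))
  fit2 <- train_vae(ds, cfg, seed = 0)
  expect_identical(fit$history, fit2$history)
  expect_error(train_vae(ds[integer(0)], cfg, 0), "empty")

  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit$model, path)
  reloaded <- load_model(path)
  expect_identical(vae_decode(fit$model, 0.3), vae_decode(reloaded, 0.3))
})

test_that("encoding a dataset yields one positive-sd posterior per image", {
  ds <- tiny_gray_cohort(4, 3, seed = 6)
  v <- build_vae(tiny_vae_config(), seed = 1)
  df <- encode_latents(ds, v)
  expect_equal(nrow(df), 7)
  expect_identical(df$id, ds$id)
  expect_true(all(df$sigma > 0))
  png <- withr::local_tempfile(fileext = ".png")
  encode_latents(ds, v, scatter_png = png)
  expect_true(file.exists(png))
})

test_that("latent grid decoding is exhaustive and bit-reproducible", {
  v <- build_vae(tiny_vae_config(), seed = 2)
  one <- latent_grid_decode(v, n_mu = 1, n_sigma = 1, eps_seed = 5)
  expect_equal(length(one), 1)
  g1 <- latent_grid_decode(v, n_mu = 4, n_sigma = 3, eps_seed = 5)
  expect_equal(length(g1), 12)
  expect_true(all(g1$origin == "synthesized"))
  g2 <- latent_grid_decode(v, n_mu = 4, n_sigma = 3, eps_seed = 5)
  expect_identical(g1$images, g2$images)
  expect_error(latent_grid_decode(v, sigma_range = c(-1, 1)), "sigma")
})

test_that("dataset expansion reaches the per-class target and keeps originals", {
  ds <- tiny_gray_cohort(6, 4, seed = 8)
  v <- build_vae(tiny_vae_config(), seed = 3)
  same <- synthesize_to_target(ds, v, 6, seed = 1)
  expect_error(synthesize_to_target(ds, v, 5, seed = 1), "below")
  expect_equal(length(same), 12)  # 6 per class: normal kept, kcn + 2
  aug <- synthesize_to_target(ds, v, 9, seed = 1)
  expect_equal(as.vector(table(aug$label)), c(9, 9))
  expect_equal(sum(aug$origin == "original"), 10)
  synth <- aug[aug$origin == "synthesized"]
  expect_true(all(synth$label %in% ds$label))
  # originals retained unchanged
  expect_identical(aug$images[seq_len(10)], ds$images)
})
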