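# Convolutional variational autoencoder for grayscale topography maps.
#
# Encoder: three stride-2 "same" convolutions (64, 32, 16 filters) take the
# 104 x 104 x 1 input to a 13 x 13 x 16 feature map (2704 units after
# flattening), then a 128-unit dense layer feeds two linear heads: the
# posterior mean and log standard deviation of q(z | x). The latent space is
# one-dimensional by default (two scalar posterior parameters). The decoder
# mirrors the chain: dense 2704 -> reshape 13 x 13 x 16 -> three stride-2
# transposed convolutions (16, 32, 64 filters) -> 1-channel output map.
# Training minimizes reconstruction negative log-likelihood (per-pixel
# Bernoulli by default) plus the closed-form KL divergence of the Gaussian
# posterior against the standard-normal prior.

#' VAE configuration
#'
#' @param input_shape input image shape (grayscale).
#' @param enc_filters encoder convolution filter counts.
#' @param enc_dense encoder dense width.
#' @param latent_dim latent dimension (default 1: scalar mean and scalar
#'   standard deviation).
#' @param dec_dense decoder first dense width; must equal the encoder's
#'   flattened feature count.
#' @param dec_filters decoder transposed-convolution filter counts.
#' @param kernel,stride convolution geometry ("same" padding, ceiling
#'   division).
#' @param learning_rate,epochs,batch_size,optimizer training protocol
#'   (RMSprop, learning rate 1e-4, 50 epochs by default).
#' @param aug_flip random horizontal flip during training.
#' @param aug_rotation_frac random rotation amplitude as a fraction of a
#'   full turn (0.10 = up to +/- 36 degrees).
#' @param recon reconstruction likelihood: `"bernoulli"` (default) or
#'   `"mse"`.
#' @return a list of class `vae_config`.
#' @export
vae_config <- function(input_shape = c(104, 104, 1),
                       enc_filters = c(64, 32, 16), enc_dense = 128,
                       latent_dim = 1, dec_dense = 2704,
                       dec_filters = c(16, 32, 64), kernel = 3, stride = 2,
                       learning_rate = 1e-4, epochs = 50, batch_size = 32,
                       optimizer = "rmsprop", aug_flip = TRUE,
                       aug_rotation_frac = 0.10, recon = "bernoulli") {
  structure(as.list(environment()), class = "vae_config")
}

#' Build the VAE
#'
#' Compiles encoder, posterior heads and decoder, checking that the shape
#' chain closes: the flattened encoder width must equal `dec_dense`
#' (`architecture_mismatch` otherwise).
#'
#' @param config a [vae_config()].
#' @param seed parameter-initialization seed.
#' @return an object of class `kv_vae` with `encoder`, `mu_head`,
#'   `logsig_head`, `decoder` networks, the `config`, and fields
#'   `flatten_units` / `latent_params` / `summary`.
#' @export
build_vae <- function(config = vae_config(), seed = 1) {
  h <- config$input_shape[1]; w <- config$input_shape[2]
  for (i in seq_along(config$enc_filters)) {
    h <- ceiling(h / config$stride); w <- ceiling(w / config$stride)
  }
  flat <- h * w * config$enc_filters[length(config$enc_filters)]
  if (flat != config$dec_dense)
    kv_error(sprintf(
      "encoder flatten width %d does not match dec_dense %d", flat,
      config$dec_dense), "architecture_mismatch")
  enc_specs <- c(
    lapply(config$enc_filters, function(f)
      layer_conv(f, config$kernel, config$stride, "relu")),
    list(layer_flatten(), layer_dense(config$enc_dense, "relu"))
  )
  encoder <- nn_build(enc_specs, config$input_shape,
                      seed = derive_seed(seed, "encoder"))
  mu_head <- nn_build(list(layer_dense(config$latent_dim, "linear")),
                      config$enc_dense, seed = derive_seed(seed, "mu"))
  logsig_head <- nn_build(list(layer_dense(config$latent_dim, "linear")),
                          config$enc_dense, seed = derive_seed(seed, "logsig"))
  dec_specs <- c(
    list(layer_dense(config$dec_dense, "relu"),
         layer_reshape(h, w, config$enc_filters[length(config$enc_filters)])),
    lapply(config$dec_filters, function(f)
      layer_conv_transpose(f, config$kernel, config$stride, "relu")),
    list(layer_conv(1, kernel = 1, stride = 1, activation = "linear",
                    name = "output_logits"))
  )
  decoder <- nn_build(dec_specs, config$latent_dim,
                      seed = derive_seed(seed, "decoder"))
  summary <- rbind(
    cbind(part = "encoder", encoder$summary),
    cbind(part = "mu_head", mu_head$summary),
    cbind(part = "logsig_head", logsig_head$summary),
    cbind(part = "decoder", decoder$summary))
  structure(list(config = config, encoder = encoder, mu_head = mu_head,
                 logsig_head = logsig_head, decoder = decoder,
                 flatten_units = flat, latent_params = 2L,
                 output_shape = c(config$input_shape[1],
                                  config$input_shape[2], 1L),
                 summary = summary),
            class = "kv_vae")
}

#' @export
print.kv_vae <- function(x, ...) {
  cat(sprintf("<kv_vae> latent_dim=%d flatten=%d\n",
              x$config$latent_dim, x$flatten_units))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Latent Gaussian posterior q(z | x)
#'
#' @param mu posterior mean(s).
#' @param sigma posterior standard deviation(s), all `> 0`.
#' @return a list of class `latent_posterior`.
#' @export
latent_posterior <- function(mu, sigma) {
  kv_assert(all(sigma > 0), "sigma must be > 0")
  structure(list(mu = mu, sigma = sigma), class = "latent_posterior")
}

#' Reparameterization trick
#'
#' Draws `z = mu + sigma * eps` for a standard-normal `eps`, making the
#' sampling step differentiable in the posterior parameters.
#'
#' @param post a [latent_posterior()].
#' @param eps standard-normal draw(s), same length as `post$mu`.
#' @return list with `z` and the `eps` used.
#' @export
reparameterize <- function(post, eps) {
  kv_assert(all(post$sigma > 0), "sigma must be > 0")
  list(z = post$mu + post$sigma * eps, eps = eps)
}

#' KL divergence of the posterior against the standard-normal prior
#'
#' Closed form for Gaussians:
#' `KL = -0.5 * sum(1 + log(sigma^2) - mu^2 - sigma^2)`, always `>= 0` and 0
#' exactly when `q = N(0, 1)`.
#'
#' @param post a [latent_posterior()].
#' @return non-negative scalar.
#' @export
kl_divergence <- function(post) {
  kv_assert(all(post$sigma > 0), "sigma must be > 0")
  -0.5 * sum(1 + 2 * log(post$sigma) - post$mu^2 - post$sigma^2)
}

#' Reconstruction negative log-likelihood
#'
#' Per-pixel Bernoulli NLL summed over pixels (`"bernoulli"`, default):
#' `-sum(x * log(y) + (1 - x) * log(1 - y))`, which is 0 iff `y = x` with a
#' binary `x`. `"mse"` returns the summed squared error instead.
#'
#' @param x target image, values in `[0, 1]`.
#' @param y reconstruction, same shape, values in `[0, 1]`.
#' @param type `"bernoulli"` or `"mse"`.
#' @return non-negative scalar.
#' @export
reconstruction_loss <- function(x, y, type = c("bernoulli", "mse")) {
  type <- match.arg(type)
  kv_assert(identical(dim(x), dim(y)) && length(x) == length(y),
            "reconstruction_loss: shape mismatch")
  if (type == "mse") return(sum((x - y)^2))
  eps <- 1e-12
  y <- pmin(pmax(y, eps), 1 - eps)
  -sum(x * log(y) + (1 - x) * log(1 - y))
}

#' Total VAE loss
#'
#' `total = reconstruction + KL`, the negated evidence lower bound of the
#' model.
#'
#' @inheritParams reconstruction_loss
#' @param post a [latent_posterior()].
#' @param epoch optional epoch index carried in the breakdown.
#' @return a list of class `loss_breakdown` with `total`, `recon`, `kl`,
#'   `epoch`.
#' @export
vae_total_loss <- function(x, y, post, type = c("bernoulli", "mse"),
                           epoch = NA_integer_) {
  recon <- reconstruction_loss(x, y, type)
  kl <- kl_divergence(post)
  structure(list(total = recon + kl, recon = recon, kl = kl, epoch = epoch),
            class = "loss_breakdown")
}

# encoder forward to the posterior; returns caches for training
vae_encode_pass <- function(vae, x, training = FALSE) {
  enc <- nn_forward(vae$encoder, x, training)
  h <- enc$out$mat
  muf <- nn_forward(vae$mu_head, h)
  lsf <- nn_forward(vae$logsig_head, h)
  mu <- as.vector(muf$out$mat)
  log_sigma <- as.vector(lsf$out$mat)
  list(mu = mu, sigma = exp(log_sigma), log_sigma = log_sigma,
       enc = enc, muf = muf, lsf = lsf, h = h)
}

#' Encode one image to its latent posterior
#'
#' @param vae a [build_vae()] model.
#' @param image grayscale matrix or `H x W x 1` array sized to the VAE
#'   input.
#' @return a [latent_posterior()].
#' @export
vae_encode <- function(vae, image) {
  p <- vae_encode_pass(vae, vae_input(vae, image))
  latent_posterior(p$mu, p$sigma)
}

#' Decode a latent sample to an image
#'
#' @param vae a [build_vae()] model.
#' @param z latent value(s), length `latent_dim`.
#' @return grayscale matrix (sigmoid of the decoder logits).
#' @export
vae_decode <- function(vae, z) {
  dec <- nn_forward(vae$decoder, matrix(z, 1))
  matrix(1 / (1 + exp(-dec$out$mat)), dec$out$h, dec$out$w)
}

vae_input <- function(vae, image) {
  s <- vae$config$input_shape
  if (is.matrix(image)) {
    kv_assert(all(dim(image) == s[1:2]), "image does not match VAE input")
    array(image, c(s[1], s[2], 1L))
  } else image
}

#' Train the VAE
#'
#' Mini-batch training with the reparameterization trick, light augmentation
#' (random horizontal flip, random rotation up to
#' `aug_rotation_frac` of a turn), and the configured optimizer. Fully
#' deterministic given `(dataset, config, seed)`.
#'
#' @param dataset a [kv_dataset()] of grayscale matrices sized to the VAE
#'   input (see [cohort_graymaps()] / [ordered_grayscale()]).
#' @param config a [vae_config()].
#' @param seed integer seed (initialization, shuffling, augmentation,
#'   latent draws).
#' @param verbose print one line per epoch.
#' @return list with `model` (trained `kv_vae`) and `history` (data frame
#'   `epoch, total, recon, kl`, per-image means).
#' @export
train_vae <- function(dataset, config = vae_config(), seed = 0,
                      verbose = FALSE) {
  kv_assert(length(dataset) > 0, "train_vae: empty dataset")
  vae <- build_vae(config, seed = derive_seed(seed, "init"))
  opt <- make_optimizer(config$optimizer, lr = config$learning_rate)
  n <- length(dataset)
  bern <- identical(config$recon, "bernoulli")
  hist_rows <- vector("list", config$epochs)
  with_seed(derive_seed(seed, "train"), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      tot <- rec <- kl <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        bs <- length(idx)
        g_enc <- g_mu <- g_ls <- g_dec <- NULL
        for (i in idx) {
          g <- dataset$images[[i]]
          if (config$aug_flip && runif(1) < 0.5) g <- flip_horizontal(g)
          if (config$aug_rotation_frac > 0) {
            ang <- runif(1, -1, 1) * config$aug_rotation_frac * 2 * pi
            g <- rotate_image(g, ang)
          }
          x <- array(g, c(nrow(g), ncol(g), 1L))
          ep_pass <- vae_encode_pass(vae, x, training = TRUE)
          eps <- rnorm(config$latent_dim)
          z <- ep_pass$mu + ep_pass$sigma * eps
          dec <- nn_forward(vae$decoder, matrix(z, 1), training = TRUE)
          logit <- dec$out$mat
          y <- 1 / (1 + exp(-logit))
          xv <- as.vector(g)
          if (bern) {
            r_loss <- sum(pmax(logit, 0) - logit * xv +
                            log1p(exp(-abs(logit))))
            dlogit <- y - xv
          } else {
            r_loss <- sum((y - xv)^2)
            dlogit <- 2 * (y - xv) * y * (1 - y)
          }
          kl_loss <- -0.5 * sum(1 + 2 * ep_pass$log_sigma -
                                  ep_pass$mu^2 - ep_pass$sigma^2)
          bw_dec <- nn_backward(vae$decoder, dec$caches,
                                matrix(dlogit, length(dlogit), 1))
          dz <- as.vector(bw_dec$dinput)
          dmu <- dz + ep_pass$mu
          dlog_sigma <- dz * eps * ep_pass$sigma + (ep_pass$sigma^2 - 1)
          bw_mu <- nn_backward(vae$mu_head, ep_pass$muf$caches,
                               matrix(dmu, 1))
          bw_ls <- nn_backward(vae$logsig_head, ep_pass$lsf$caches,
                               matrix(dlog_sigma, 1))
          bw_enc <- nn_backward(vae$encoder, ep_pass$enc$caches,
                                bw_mu$dinput + bw_ls$dinput)
          g_dec <- add_grads(g_dec, bw_dec$grads)
          g_mu <- add_grads(g_mu, bw_mu$grads)
          g_ls <- add_grads(g_ls, bw_ls$grads)
          g_enc <- add_grads(g_enc, bw_enc$grads)
          tot <- tot + r_loss + kl_loss
          rec <- rec + r_loss
          kl <- kl + kl_loss
        }
        vae$encoder <- opt_step(opt, vae$encoder, scale_grads(g_enc, 1 / bs),
                                prefix = "enc")
        vae$mu_head <- opt_step(opt, vae$mu_head, scale_grads(g_mu, 1 / bs),
                                prefix = "mu")
        vae$logsig_head <- opt_step(opt, vae$logsig_head,
                                    scale_grads(g_ls, 1 / bs), prefix = "ls")
        vae$decoder <- opt_step(opt, vae$decoder, scale_grads(g_dec, 1 / bs),
                                prefix = "dec")
      }
      hist_rows[[ep]] <- data.frame(epoch = ep, total = tot / n,
                                    recon = rec / n, kl = kl / n)
      if (verbose)
        message(sprintf("epoch %d/%d total=%.3f recon=%.3f kl=%.3f",
                        ep, config$epochs, tot / n, rec / n, kl / n))
    }
  })
  list(model = vae, history = do.call(rbind, hist_rows))
}

#' Encode a labelled dataset to latent posteriors
#'
#' One posterior per image, order-preserving; optionally writes the
#' mean-vs-sd scatter (colored by class) used to inspect how the latent
#' space clusters the two classes.
#'
#' @param dataset a [kv_dataset()] of grayscale matrices.
#' @param vae trained [build_vae()] model.
#' @param scatter_png optional PNG path for the latent scatter.
#' @param csv optional CSV path for the posterior table.
#' @return data frame `id, mu, sigma, label` (first latent dimension when
#'   `latent_dim > 1`).
#' @export
encode_latents <- function(dataset, vae, scatter_png = NULL, csv = NULL) {
  rows <- lapply(seq_len(length(dataset)), function(i) {
    p <- vae_encode(vae, dataset$images[[i]])
    data.frame(id = dataset$id[i], mu = p$mu[1], sigma = p$sigma[1],
               label = dataset$label[i])
  })
  df <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(df, csv, row.names = FALSE)
  if (!is.null(scatter_png)) {
    grDevices::png(scatter_png, 600, 600)
    cls <- factor(df$label)
    graphics::plot(df$mu, df$sigma, col = as.integer(cls) + 1, pch = 19,
                   xlab = expression(mu), ylab = expression(sigma),
                   main = "Latent posterior by class")
    graphics::legend("topright", legend = levels(cls),
                     col = seq_along(levels(cls)) + 1, pch = 19)
    grDevices::dev.off()
  }
  df
}

#' Decode a latent parameter grid
#'
#' Sweeps evenly spaced `(mu, sigma)` pairs over the given ranges, draws one
#' standard-normal `eps` per grid cell from `eps_seed`, decodes
#' `z = mu + sigma * eps`, and returns the `n_mu * n_sigma` generated
#' images. With the default 30 x 30 grid this produces 900 novel samples.
#'
#' @param vae trained [build_vae()] model.
#' @param mu_range,sigma_range numeric length-2 ranges (`sigma_range` must
#'   be positive).
#' @param n_mu,n_sigma grid sizes, `>= 1`.
#' @param eps_seed integer seed for the per-cell draws.
#' @return a [kv_dataset()] of `n_mu * n_sigma` grayscale images, all
#'   `origin = "synthesized"`, with the grid table attached as attribute
#'   `"grid"`.
#' @export
latent_grid_decode <- function(vae, mu_range = c(-3, 3),
                               sigma_range = c(0.1, 2), n_mu = 30,
                               n_sigma = 30, eps_seed = 0) {
  kv_assert(n_mu >= 1 && n_sigma >= 1, "grid sizes must be >= 1")
  kv_assert(all(sigma_range > 0), "sigma_range must be positive")
  mus <- if (n_mu == 1) mu_range[1] else
    seq(mu_range[1], mu_range[2], length.out = n_mu)
  sigmas <- if (n_sigma == 1) sigma_range[1] else
    seq(sigma_range[1], sigma_range[2], length.out = n_sigma)
  grid <- expand.grid(mu = mus, sigma = sigmas)
  with_seed(eps_seed, {
    grid$eps <- rnorm(nrow(grid))
  })
  imgs <- lapply(seq_len(nrow(grid)), function(i) {
    vae_decode(vae, grid$mu[i] + grid$sigma[i] * grid$eps[i])
  })
  ds <- kv_dataset(imgs, rep("unlabelled", nrow(grid)),
                   origin = rep("synthesized", nrow(grid)),
                   id = sprintf("grid%04d", seq_len(nrow(grid))))
  attr(ds, "grid") <- grid
  ds
}

#' Expand a labelled cohort to a per-class target with synthesized images
#'
#' For each class, original images are drawn (with replacement, seeded),
#' encoded, a latent value is sampled from each source posterior, decoded,
#' and the synthesized image inherits the source's class label with
#' `origin = "synthesized"`, until the class reaches `per_class_target`.
#' All originals are retained unchanged.
#'
#' @param originals a [kv_dataset()] of grayscale originals.
#' @param vae trained [build_vae()] model.
#' @param per_class_target target count per class, `>=` each current class
#'   count.
#' @param seed integer seed (source choice and latent draws).
#' @return the combined [kv_dataset()] with exactly `per_class_target`
#'   images per class.
#' @export
synthesize_to_target <- function(originals, vae, per_class_target, seed = 0) {
  classes <- sort(unique(originals$label))
  counts <- table(originals$label)
  kv_assert(all(per_class_target >= counts),
            sprintf("per_class_target %d below a current class count (max %d)",
                    per_class_target, max(counts)))
  new_imgs <- list(); new_lab <- character(0)
  with_seed(derive_seed(seed, "synthesize"), {
    for (cl in classes) {
      idx <- which(originals$label == cl)
      n_new <- per_class_target - length(idx)
      if (n_new == 0) next
      # encode each class original once, then sample posteriors as needed
      posts <- lapply(idx, function(i) vae_encode(vae, originals$images[[i]]))
      src <- sample(seq_along(idx), n_new, replace = TRUE)
      for (k in seq_len(n_new)) {
        p <- posts[[src[k]]]
        z <- p$mu + p$sigma * rnorm(length(p$mu))
        new_imgs[[length(new_imgs) + 1]] <- vae_decode(vae, z)
        new_lab <- c(new_lab, cl)
      }
    }
  })
  if (length(new_imgs) == 0) return(originals)
  synth <- kv_dataset(new_imgs, new_lab,
                      origin = rep("synthesized", length(new_imgs)),
                      id = sprintf("synth%05d", seq_along(new_imgs)))
  c(originals, synth)
}
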