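# Shared fixtures, all generated in code.

# a clean rendered map fixture (no annotations unless asked)
fixture_map <- function(pattern = "regular_astigmatism", ave_k = 44, cyl = 2,
                        axis = 0, cone_amplitude = 0, canvas_side = 120,
                        annotations = FALSE, ...) {
  p <- map_params(pattern, ave_k, cyl, axis, cone_amplitude, ...)
  synth_topomap(p, default_color_scale(),
                map_canvas(canvas_side, canvas_side,
                           annotations = annotations))
}

# a saturated disc on a gray background (known geometry for segmentation)
fixture_disc <- function(h = 300, w = 300, cy = 150, cx = 150, r = 60,
                         color = c(1, 0, 0), bg = 0.5) {
  img <- array(bg, c(h, w, 3))
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  # pixel centers at integer coordinates; the disc spans [cy - r, cy + r)
  mask <- (yy - cy)^2 + (xx - cx)^2 < r^2
  for (c in 1:3) {
    ch <- img[, , c]; ch[mask] <- color[c]; img[, , c] <- ch
  }
  img
}

# tiny VAE configuration (32 x 32 input) for fast structural tests
tiny_vae_config <- function(...) {
  vae_config(input_shape = c(32, 32, 1), dec_dense = 4 * 4 * 16, ...)
}

tiny_gray_cohort <- function(n_normal, n_kcn, seed, size = 32) {
  cohort_graymaps(n_normal, n_kcn, seed, size = size)
}

# trivially separable color dataset: constant-color images per class
fixture_separable <- function(n_per_class = 20, side = 50) {
  imgs <- c(
    lapply(seq_len(n_per_class), function(i) array(0.2, c(side, side, 3))),
    lapply(seq_len(n_per_class), function(i) array(0.8, c(side, side, 3)))
  )
  kv_dataset(imgs, rep(c("normal", "kcn"), each = n_per_class))
}
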