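# Image cleanup chain: HSV cornea segmentation, structured-noise removal,
# order-preserving grayscale conversion, and per-model input preparation.

#' Segment the cornea disc via an HSV mask
#'
#' Converts the image to hue/saturation/value space, keeps pixels with
#' saturation and value above configurable thresholds (clinical map colors
#' are saturated; backgrounds and annotation text are near-gray or
#' near-black/white), retains the largest connected component, and crops its
#' bounding box padded to a square.
#'
#' @param image RGB array in `[0, 1]`, at least 64 x 64.
#' @param hsv_cfg list with `s_min` (default 0.25) and `v_min` (default 0.2).
#' @return a list of class `cornea_crop` with `image` (square RGB crop,
#'   side >= 32) and `source_bbox` (`c(x0, y0, x1, y1)`, 0-based half-open in
#'   the original image).
#' @section Errors: `no_cornea_found` when no pixel passes the mask;
#'   `segmentation_ambiguous` when the selected component touches all four
#'   image borders.
#' @export
segment_cornea <- function(image, hsv_cfg = list(s_min = 0.25, v_min = 0.2)) {
  image <- as_rgb01(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  kv_assert(h >= 64 && w >= 64, "segment_cornea: image must be >= 64 x 64")
  cfg <- utils::modifyList(list(s_min = 0.25, v_min = 0.2), hsv_cfg)
  rgbm <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgbm, maxColorValue = 1)
  mask <- matrix(hsv[2, ] >= cfg$s_min & hsv[3, ] >= cfg$v_min, h, w)
  if (!any(mask)) kv_error("no pixel passes the HSV mask", "no_cornea_found")
  lab <- EBImage::bwlabel(mask)
  counts <- tabulate(lab[lab > 0])
  biggest <- which.max(counts)
  comp <- lab == biggest
  rows <- which(rowSums(comp) > 0)
  cols <- which(colSums(comp) > 0)
  if (min(rows) == 1 && max(rows) == h && min(cols) == 1 && max(cols) == w)
    kv_error("largest component touches all four borders",
             "segmentation_ambiguous")
  y0 <- min(rows); y1 <- max(rows); x0 <- min(cols); x1 <- max(cols)
  # pad the bounding box to a square, clamped to the image
  side <- max(y1 - y0 + 1, x1 - x0 + 1, 32)
  side <- min(side, h, w)
  grow <- function(lo, hi, side, n) {
    extra <- side - (hi - lo + 1)
    lo <- lo - floor(extra / 2); hi <- hi + ceiling(extra / 2)
    if (lo < 1) { hi <- hi + (1 - lo); lo <- 1 }
    if (hi > n) { lo <- lo - (hi - n); hi <- n }
    c(max(lo, 1), hi)
  }
  ry <- grow(y0, y1, side, h); rx <- grow(x0, x1, side, w)
  crop <- image[ry[1]:ry[2], rx[1]:rx[2], , drop = FALSE]
  structure(list(image = crop,
                 side = dim(crop)[1],
                 source_bbox = c(rx[1] - 1, ry[1] - 1, rx[2], ry[2])),
            class = "cornea_crop")
}

#' Remove regular acquisition noise
#'
#' A 3 x 3 median filter per channel (removing impulse noise and thin scan
#' lines) followed by spectral notch suppression: periodic artifacts leave
#' isolated spikes on the frequency axes of the 2-D spectrum; a candidate
#' frequency whose magnitude exceeds `notch_threshold` times the median of
#' its axis neighborhood is zeroed together with its conjugate. Clean maps
#' have smoothly decaying axis spectra, so the filter is near-identity on
#' them and near-idempotent in general.
#'
#' @param image RGB array in `[0, 1]`.
#' @param cfg list with `median_radius` (default 1, i.e. 3 x 3),
#'   `notch_threshold` (spike-to-local-median ratio that triggers the notch,
#'   default 8), `max_notches` (default 6).
#' @return denoised RGB array, same shape.
#' @export
remove_regular_noise <- function(image,
                                 cfg = list(median_radius = 1,
                                            notch_threshold = 8,
                                            max_notches = 6)) {
  image <- as_rgb01(image)
  cfg <- utils::modifyList(list(median_radius = 1, notch_threshold = 8,
                                max_notches = 6), cfg)
  out <- EBImage::medianFilter(image, cfg$median_radius)
  out <- array(as.numeric(out), dim(image))
  h <- dim(out)[1]; w <- dim(out)[2]
  guard <- 3
  spike_freqs <- function(vals) {
    # local spike detection along one frequency axis
    n <- length(vals)
    hits <- integer(0)
    for (k in seq_len(n)) {
      win <- vals[setdiff(max(1, k - 4):min(n, k + 4), k)]
      if (vals[k] > cfg$notch_threshold * stats::median(win))
        hits <- c(hits, k)
    }
    hits
  }
  for (c in 1:3) {
    ch <- out[, , c]
    f <- stats::fft(ch)
    m <- Mod(f)
    row_axis <- (guard + 1):(floor(h / 2) + 1)
    col_axis <- (guard + 1):(floor(w / 2) + 1)
    hl <- list()
    if (length(row_axis) > 8) {
      rh <- spike_freqs(m[row_axis, 1])
      if (length(rh) > 0) hl <- c(hl, list(cbind(row_axis[rh], 1L)))
    }
    if (length(col_axis) > 8) {
      ch_hits <- spike_freqs(m[1, col_axis])
      if (length(ch_hits) > 0) hl <- c(hl, list(cbind(1L, col_axis[ch_hits])))
    }
    hits <- do.call(rbind, hl)
    if (!is.null(hits) && nrow(hits) > 0) {
      ord <- order(m[hits], decreasing = TRUE)
      hits <- hits[ord[seq_len(min(nrow(hits), cfg$max_notches))], ,
                   drop = FALSE]
      for (k in seq_len(nrow(hits))) {
        i <- hits[k, 1]; j <- hits[k, 2]
        f[i, j] <- 0
        ii <- if (i == 1) 1 else h - i + 2   # conjugate-symmetric partner
        jj <- if (j == 1) 1 else w - j + 2
        f[ii, jj] <- 0
      }
      out[, , c] <- Re(stats::fft(f, inverse = TRUE)) / (h * w)
    }
  }
  clamp01(out)
}

#' Order-preserving grayscale conversion
#'
#' Standard luminance conversion destroys the dioptric ordering of a color
#' scale (red and blue can land on similar gray levels). Instead each pixel
#' is snapped to its nearest scale color (Euclidean RGB distance) and mapped
#' to the intensity `bin / (n_bins - 1)`, which is strictly increasing in
#' the dioptric bin index; the result is resized by area averaging.
#'
#' @param image RGB array in `[0, 1]`.
#' @param scale a [color_scale()] with at least 2 bins.
#' @param size output side (default 104, the VAE input side).
#' @return `size x size` matrix in `[0, 1]`.
#' @export
ordered_grayscale <- function(image, scale = default_color_scale(),
                              size = 104) {
  image <- as_rgb01(image)
  kv_assert(scale$n_bins >= 2, "ordered_grayscale: need >= 2 bins")
  n <- prod(dim(image)[1:2])
  rgbm <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                as.vector(image[, , 3]))
  bin <- nearest_bin(rgbm, scale)
  g <- matrix(bin_to_intensity(bin, scale), dim(image)[1], dim(image)[2])
  if (!all(dim(g) == size)) g <- resize_area(g, size, size)
  clamp01(g)
}

#' Prepare an image for a specific model input
#'
#' * `"vae"`: `104 x 104 x 1` grayscale in `[0, 1]` (grayscale matrices are
#'   resized; RGB inputs are first passed through [ordered_grayscale()]).
#' * `"custom_cnn"`: `50 x 50 x 3` RGB in `[0, 1]`.
#' * `"transfer"`: backbone-specific side (224 or 160, or `size_override`)
#'   RGB rescaled from `[0, 1]` (or 8-bit `[0, 255]`) to `[-1, 1]`.
#'
#' @param image RGB array or grayscale matrix.
#' @param target one of `"vae"`, `"custom_cnn"`, `"transfer"`.
#' @param size_override optional side override.
#' @param scale color scale used for `"vae"` on RGB input.
#' @return numeric array shaped for the model.
#' @export
prepare_input <- function(image, target = c("vae", "custom_cnn", "transfer"),
                          size_override = NULL,
                          scale = default_color_scale()) {
  target <- match.arg(target)
  if (target == "vae") {
    size <- if (is.null(size_override)) 104 else size_override
    g <- if (is.matrix(image)) {
      if (all(dim(image) == size)) image else resize_image(image, size, size)
    } else {
      ordered_grayscale(image, scale, size)
    }
    return(array(clamp01(g), c(size, size, 1L)))
  }
  img <- as_rgb01(image)
  if (target == "custom_cnn") {
    size <- if (is.null(size_override)) 50 else size_override
    out <- resize_image(img, size, size)
    return(clamp01(out))
  }
  size <- if (is.null(size_override)) 224 else size_override
  out <- clamp01(resize_image(img, size, size))
  out * 2 - 1                     # [0,1] -> [-1,1]; 8-bit 128 -> ~0.004
}
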