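# Dioptric color scale: the discrete power -> color map used by clinical
# axial curvature displays, and its inverses (nearest-color lookup,
# order-preserving grayscale).

#' Dioptric color scale
#'
#' A clinical-style discrete color scale for axial curvature maps: an ordered
#' set of power thresholds (lower bin edges, diopters) and one RGB color per
#' bin. Powers below the first edge clamp to the first bin, powers at or
#' above the last edge clamp to the last bin.
#'
#' @param thresholds strictly increasing numeric vector of lower bin edges
#'   (diopters).
#' @param colors numeric matrix `n_bins x 3` of RGB colors in `[0, 1]`, all
#'   rows pairwise distinct.
#' @return an object of class `color_scale` with fields `thresholds`,
#'   `colors`, `n_bins`.
#' @examples
#' sc <- default_color_scale()
#' sc$n_bins
#' @export
color_scale <- function(thresholds, colors) {
  kv_assert(length(thresholds) >= 4, "color_scale: need at least 4 bins")
  kv_assert(all(diff(thresholds) > 0),
            "color_scale: thresholds must be strictly increasing")
  colors <- as.matrix(colors)
  kv_assert(nrow(colors) == length(thresholds) && ncol(colors) == 3,
            "color_scale: colors must be n_bins x 3")
  kv_assert(anyDuplicated(colors) == 0,
            "color_scale: colors must be pairwise distinct")
  structure(list(thresholds = as.numeric(thresholds), colors = colors,
                 n_bins = length(thresholds)),
            class = "color_scale")
}

#' @describeIn color_scale The default scale: 26 bins spanning 34--52 D with
#'   a blue-to-green-to-yellow-to-red hue progression, mirroring standard
#'   axial-map palettes.
#' @param n_bins number of bins.
#' @param range_d numeric length-2, dioptric span covered by the scale.
#' @export
default_color_scale <- function(n_bins = 26, range_d = c(34, 52)) {
  edges <- seq(range_d[1], range_d[2], length.out = n_bins + 1)[seq_len(n_bins)]
  hue <- seq(240, 0, length.out = n_bins) / 360   # blue -> red
  cols <- t(grDevices::col2rgb(grDevices::hsv(hue, 1, 1)) / 255)
  color_scale(edges, cols)
}

#' Map dioptric powers to scale bins
#'
#' @param power numeric vector/matrix of powers (D).
#' @param scale a [color_scale()].
#' @return integer bin indices in `1..n_bins` (same shape as `power`); the
#'   number of clamped out-of-range values is attached as attribute
#'   `"clamped"`.
#' @export
power_to_bin <- function(power, scale) {
  bin <- findInterval(power, scale$thresholds)
  clamped <- sum(bin < 1, na.rm = TRUE) +
    sum(power >= scale$thresholds[scale$n_bins] +
          diff(scale$thresholds)[scale$n_bins - 1], na.rm = TRUE)
  bin[bin < 1] <- 1L
  bin[bin > scale$n_bins] <- scale$n_bins
  if (!is.null(dim(power))) dim(bin) <- dim(power)
  attr(bin, "clamped") <- clamped
  bin
}

#' Nearest scale color of arbitrary RGB pixels
#'
#' Assigns each pixel the bin of the scale color nearest in Euclidean RGB
#' distance; the workhorse of the order-preserving grayscale conversion.
#'
#' @param rgb_mat numeric matrix `n x 3` of RGB values in `[0, 1]`.
#' @param scale a [color_scale()].
#' @return integer vector of bin indices in `1..n_bins`.
#' @export
nearest_bin <- function(rgb_mat, scale) {
  cc <- scale$colors
  # squared distance: |x|^2 - 2 x.c + |c|^2 ; |x|^2 constant per row
  d <- -2 * rgb_mat %*% t(cc) +
    matrix(rowSums(cc^2), nrow(rgb_mat), scale$n_bins, byrow = TRUE)
  max.col(-d, ties.method = "first")
}

#' Intensity of a scale bin
#'
#' Bin `i` maps to intensity `(i - 1) / (n_bins - 1)`, a strictly increasing
#' function of the dioptric bin index.
#' @param bin integer bin indices.
#' @param scale a [color_scale()].
#' @return numeric intensities in `[0, 1]`.
#' @export
bin_to_intensity <- function(bin, scale) (bin - 1) / (scale$n_bins - 1)

#' Recolor a grayscale map through the scale
#'
#' Inverse of the order-preserving grayscale conversion: each intensity is
#' snapped to its nearest bin and painted with that bin's color. Used to
#' return decoder outputs to the original color space before classifier
#' training.
#'
#' @param gray numeric `H x W` matrix in `[0, 1]`.
#' @param scale a [color_scale()].
#' @return `H x W x 3` RGB array.
#' @export
colorize_gray <- function(gray, scale) {
  bin <- pmin(pmax(round(gray * (scale$n_bins - 1)) + 1, 1), scale$n_bins)
  out <- array(0, c(dim(gray), 3L))
  for (c in 1:3) out[, , c] <- matrix(scale$colors[bin, c], nrow(gray))
  out
}
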