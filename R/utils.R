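# Internal helpers: conditions, seeds, image containers, resizing.

#' @keywords internal
kv_error <- function(msg, class) {
  stop(structure(
    class = c(class, "kv_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

kv_assert <- function(cond, msg, class = "kv_argument_error") {
  if (!isTRUE(cond)) kv_error(msg, class)
}

#' Derive a stage seed from a global seed
#'
#' Deterministically maps a global integer seed and a stage label to a new
#' 31-bit integer seed, so that every stochastic stage of a pipeline run
#' draws from an independent, reproducible stream.
#'
#' @param seed integer global seed.
#' @param label character stage label.
#' @return a single integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483587)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# --- image helpers -----------------------------------------------------------
# Images are numeric arrays H x W x 3 (RGB) or H x W matrices (grayscale),
# values in [0, 1]; row index = y (downward), column index = x (rightward).

as_rgb01 <- function(image) {
  if (is.matrix(image)) image <- array(rep(image, 3), c(dim(image), 3L))
  kv_assert(is.array(image) && length(dim(image)) == 3 && dim(image)[3] >= 3,
            "expected an H x W x 3 RGB array")
  image <- image[, , 1:3, drop = FALSE]
  if (is.integer(image) || max(image, na.rm = TRUE) > 1 + 1e-9)
    image <- image / 255
  storage.mode(image) <- "double"
  image
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Peak signal-to-noise ratio between two images
#'
#' @param x,y numeric arrays of identical shape with values in `[0, 1]`.
#' @return PSNR in decibels (`Inf` for identical inputs).
#' @export
psnr <- function(x, y) {
  kv_assert(identical(dim(x), dim(y)), "psnr: shape mismatch")
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

#' Read / write PNG images
#'
#' Thin wrappers around \pkg{png} keeping the package's H x W x channel,
#' `[0, 1]` array convention.
#' @param path file path.
#' @param image numeric array in `[0, 1]`.
#' @return `read_image()` returns the image array; `write_image()` returns
#'   `path` invisibly.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  img
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  png::writePNG(clamp01(image), path)
  invisible(path)
}

# Area-averaging resize (exact box filter; the right choice for downsampling
# piecewise-constant color-band maps). Works on matrices and H x W x C arrays.
resize_area <- function(image, out_h, out_w) {
  area_weights <- function(n_in, n_out) {
    # W[i, j] = fraction of output cell i covered by input cell j
    w <- matrix(0, n_out, n_in)
    scale <- n_in / n_out
    for (i in seq_len(n_out)) {
      lo <- (i - 1) * scale
      hi <- i * scale
      j0 <- floor(lo) + 1
      j1 <- min(ceiling(hi), n_in)
      for (j in j0:j1) {
        ov <- min(hi, j) - max(lo, j - 1)
        if (ov > 0) w[i, j] <- ov / scale
      }
    }
    w
  }
  wr <- area_weights(nrow(image), out_h)
  wc <- area_weights(ncol(image), out_w)
  if (is.matrix(image)) return(wr %*% image %*% t(wc))
  out <- array(0, c(out_h, out_w, dim(image)[3]))
  for (c in seq_len(dim(image)[3])) out[, , c] <- wr %*% image[, , c] %*% t(wc)
  out
}

# Bilinear resize, used for upsampling (Grad-CAM heat, transfer inputs).
resize_bilinear <- function(image, out_h, out_w) {
  h <- nrow(image); w <- ncol(image)
  yy <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  xx <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  y0 <- pmin(pmax(floor(yy), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(xx), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(yy - y0, 0), 1);   fx <- pmin(pmax(xx - x0, 0), 1)
  interp <- function(m) {
    a <- m[y0, x0, drop = FALSE] * (1 - fy) + m[y1, x0, drop = FALSE] * fy
    b <- m[y0, x1, drop = FALSE] * (1 - fy) + m[y1, x1, drop = FALSE] * fy
    a * rep(1 - fx, each = out_h) + b * rep(fx, each = out_h)
  }
  if (is.matrix(image)) return(interp(image))
  out <- array(0, c(out_h, out_w, dim(image)[3]))
  for (c in seq_len(dim(image)[3])) out[, , c] <- interp(image[, , c])
  out
}

resize_image <- function(image, out_h, out_w) {
  if (out_h <= nrow(image) && out_w <= ncol(image)) {
    resize_area(image, out_h, out_w)
  } else {
    resize_bilinear(image, out_h, out_w)
  }
}

# Horizontal flip and small rotation (training-time augmentation).
flip_horizontal <- function(image) {
  if (is.matrix(image)) return(image[, rev(seq_len(ncol(image))), drop = FALSE])
  image[, rev(seq_len(ncol(image))), , drop = FALSE]
}

rotate_image <- function(image, angle, fill = 0) {
  h <- nrow(image); w <- ncol(image)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  gy <- rep(seq_len(h), times = w); gx <- rep(seq_len(w), each = h)
  ca <- cos(angle); sa <- sin(angle)
  sy <- cy + (gy - cy) * ca - (gx - cx) * sa
  sx <- cx + (gy - cy) * sa + (gx - cx) * ca
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  inside <- y0 >= 1 & y0 < h & x0 >= 1 & x0 < w
  sample_ch <- function(m) {
    v <- rep(fill, h * w)
    i00 <- (x0[inside] - 1) * h + y0[inside]
    v[inside] <-
      m[i00] * (1 - fy[inside]) * (1 - fx[inside]) +
      m[i00 + 1] * fy[inside] * (1 - fx[inside]) +
      m[i00 + h] * (1 - fy[inside]) * fx[inside] +
      m[i00 + h + 1] * fy[inside] * fx[inside]
    matrix(v, h, w)
  }
  if (is.matrix(image)) return(sample_ch(image))
  out <- array(fill, dim(image))
  for (c in seq_len(dim(image)[3])) out[, , c] <- sample_ch(image[, , c])
  out
}

# --- labelled image dataset --------------------------------------------------

#' Labelled topography image dataset
#'
#' A lightweight container for a cohort of map images: a list of image
#' arrays (color `H x W x 3` or grayscale matrices), a class label per image
#' (`"normal"` / `"kcn"`), a provenance flag (`"original"` / `"synthesized"`)
#' and an id. Used by every training and evaluation stage.
#'
#' @param images list of numeric arrays/matrices in `[0, 1]`.
#' @param label character vector of class labels.
#' @param origin character vector, `"original"` or `"synthesized"`.
#' @param id character vector of unique ids (generated when missing).
#' @return an object of class `kv_dataset`.
#' @export
kv_dataset <- function(images, label,
                       origin = rep("original", length(images)),
                       id = NULL) {
  kv_assert(length(images) == length(label) && length(label) == length(origin),
            "kv_dataset: images, label and origin lengths differ")
  kv_assert(all(origin %in% c("original", "synthesized")),
            "kv_dataset: origin must be 'original' or 'synthesized'")
  if (is.null(id)) id <- sprintf("img%05d", seq_along(images))
  structure(list(images = images, label = as.character(label),
                 origin = origin, id = id),
            class = "kv_dataset")
}

#' @export
length.kv_dataset <- function(x) length(x$images)

#' @export
`[.kv_dataset` <- function(x, i) {
  kv_dataset(x$images[i], x$label[i], x$origin[i], x$id[i])
}

#' @export
print.kv_dataset <- function(x, ...) {
  cat(sprintf("<kv_dataset> %d images (%s); origin: %s\n",
              length(x),
              paste(sprintf("%s=%d", names(table(x$label)), table(x$label)),
                    collapse = ", "),
              paste(sprintf("%s=%d", names(table(x$origin)), table(x$origin)),
                    collapse = ", ")))
  invisible(x)
}

#' Concatenate datasets
#' @param ... `kv_dataset` objects.
#' @return a single combined `kv_dataset`.
#' @export
c.kv_dataset <- function(...) {
  parts <- list(...)
  ids <- unlist(lapply(parts, `[[`, "id"))
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  kv_dataset(
    do.call(c, lapply(parts, `[[`, "images")),
    unlist(lapply(parts, `[[`, "label")),
    unlist(lapply(parts, `[[`, "origin")),
    ids
  )
}
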