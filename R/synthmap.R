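# Parametric corneal topography simulator.
#
# Clinical axial maps are emulated with a minimal parametric model: a mean
# keratometry offset, a cos(2*theta) bowtie for regular astigmatism, and one
# or two Gaussian cone lobes for the keratoconic patterns (inferior cone,
# central cone, asymmetric bowtie with skewed radial axis). Coordinates:
# pixel (0, 0) top-left, x rightward, y downward, so "inferior" = larger y.

KCN_PATTERNS <- c("inferior_cone", "central_cone", "ab_srax")

#' Parameters of one simulated topography map
#'
#' @param pattern one of `"regular_astigmatism"`, `"inferior_cone"`,
#'   `"central_cone"`, `"ab_srax"`.
#' @param ave_k average keratometry (D), in `[30, 70]`.
#' @param cyl corneal cylinder / astigmatism magnitude (D), `>= 0`.
#' @param axis astigmatism axis (radians).
#' @param cone_amplitude peak cone steepening (D); must be 0 for normal maps
#'   and `> 0` for keratoconic maps.
#' @param cone_center cone center offset `(x, y)` as fractions of the map
#'   radius (y positive downward).
#' @param cone_width cone Gaussian width as a fraction of the radius, `> 0`.
#' @param skew_angle radial-axis skew (radians), used by `"ab_srax"` only.
#' @param label `"normal"` or `"kcn"`; must be consistent with `pattern`.
#' @return an object of class `map_params`.
#' @export
map_params <- function(pattern, ave_k, cyl, axis = 0,
                       cone_amplitude = 0, cone_center = c(0, 0),
                       cone_width = 0.2, skew_angle = 0,
                       label = if (pattern == "regular_astigmatism") "normal" else "kcn") {
  kv_assert(pattern %in% c("regular_astigmatism", KCN_PATTERNS),
            sprintf("unknown pattern '%s'", pattern))
  kv_assert(ave_k >= 30 && ave_k <= 70, "ave_k must lie in [30, 70] D")
  kv_assert(cyl >= 0, "cyl must be >= 0")
  kv_assert(cone_width > 0, "cone_width must be > 0")
  if (label == "normal")
    kv_assert(pattern == "regular_astigmatism" && cone_amplitude == 0,
              "normal maps require regular_astigmatism and cone_amplitude 0")
  if (label == "kcn")
    kv_assert(pattern %in% KCN_PATTERNS && cone_amplitude > 0,
              "kcn maps require a cone pattern with cone_amplitude > 0")
  structure(list(pattern = pattern, ave_k = ave_k, cyl = cyl, axis = axis,
                 cone_amplitude = cone_amplitude, cone_center = cone_center,
                 cone_width = cone_width, skew_angle = skew_angle,
                 label = label),
            class = "map_params")
}

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

#' Sample a cohort of map parameters
#'
#' Draws per-map average keratometry and cylinder from per-class Gaussians
#' matching reference clinical cohorts (keratoconus: AveK 48.68 +/- 3.96 D,
#' Cyl 4.64 +/- 2.53 D; normal: AveK 44.15 +/- 1.57 D, Cyl 1.61 +/- 1.48 D),
#' truncated to the valid parameter ranges. Keratoconic maps draw their
#' pattern from a configurable mixture and receive a seeded cone geometry.
#'
#' @param n_normal,n_kcn non-negative counts per class.
#' @param seed integer seed; the draw is fully deterministic given the seed.
#' @param kcn_mix named numeric mixture over the three keratoconic patterns.
#' @param moments per-class Gaussian moments; override to move the classes
#'   closer together or further apart.
#' @return a list of [map_params()], normals first.
#' @export
sample_cohort <- function(n_normal, n_kcn, seed,
                          kcn_mix = c(inferior_cone = 0.6, central_cone = 0.2,
                                      ab_srax = 0.2),
                          moments = list(
                            normal = list(ave_k = c(44.15, 1.57),
                                          cyl = c(1.61, 1.48)),
                            kcn = list(ave_k = c(48.68, 3.96),
                                       cyl = c(4.64, 2.53)))) {
  kv_assert(n_normal >= 0 && n_kcn >= 0, "counts must be >= 0")
  kv_assert(abs(sum(kcn_mix) - 1) < 1e-8 &&
              setequal(names(kcn_mix), KCN_PATTERNS),
            "kcn_mix must be a mixture over the three keratoconic patterns")
  with_seed(seed, {
    normals <- if (n_normal > 0) {
      ak <- rnorm_trunc(n_normal, moments$normal$ave_k[1],
                        moments$normal$ave_k[2], 30, 70)
      cy <- rnorm_trunc(n_normal, moments$normal$cyl[1],
                        moments$normal$cyl[2], 0, Inf)
      ax <- runif(n_normal, 0, pi)
      lapply(seq_len(n_normal), function(i)
        map_params("regular_astigmatism", ak[i], cy[i], ax[i]))
    } else list()
    kcns <- if (n_kcn > 0) {
      ak <- rnorm_trunc(n_kcn, moments$kcn$ave_k[1],
                        moments$kcn$ave_k[2], 30, 70)
      cy <- rnorm_trunc(n_kcn, moments$kcn$cyl[1], moments$kcn$cyl[2], 0, Inf)
      ax <- runif(n_kcn, 0, pi)
      pat <- sample(KCN_PATTERNS, n_kcn, replace = TRUE,
                    prob = kcn_mix[KCN_PATTERNS])
      amp <- rnorm_trunc(n_kcn, 6, 2, 1, 15)
      wid <- runif(n_kcn, 0.15, 0.3)
      skw <- runif(n_kcn, 10, 40) * pi / 180
      lapply(seq_len(n_kcn), function(i) {
        ctr <- switch(pat[i],
          inferior_cone = c(rnorm(1, 0, 0.08), rnorm_trunc(1, 0.35, 0.08, 0.1, 0.7)),
          central_cone  = c(rnorm(1, 0, 0.05), rnorm(1, 0, 0.05)),
          ab_srax       = c(rnorm(1, 0, 0.08), rnorm_trunc(1, 0.3, 0.08, 0.1, 0.7)))
        map_params(pat[i], ak[i], cy[i], ax[i], cone_amplitude = amp[i],
                   cone_center = ctr, cone_width = wid[i],
                   skew_angle = if (pat[i] == "ab_srax") skw[i] else 0,
                   label = "kcn")
      })
    } else list()
    c(normals, kcns)
  })
}

#' Evaluate the parametric curvature field on a pixel grid
#'
#' The field over the unit disc is
#' `ave_k + (cyl / 2) * cos(2 * (theta - axis)) + cone terms`, where the cone
#' term is a Gaussian bump `cone_amplitude * exp(-d^2 / (2 * cone_width^2))`
#' centered at `cone_center` (distances in units of the disc radius). The
#' `ab_srax` pattern adds a second, half-amplitude lobe on the opposite side,
#' rotated by `skew_angle`, producing the skewed asymmetric bowtie. The mask
#' is the inscribed circle of the grid.
#'
#' @param params a [map_params()].
#' @param grid integer length-2 `(H, W)`, both `>= 16`.
#' @return `H x W` numeric matrix of dioptric powers, `NA` outside the mask;
#'   the logical mask is attached as attribute `"mask"`.
#' @export
curvature_field <- function(params, grid = c(104, 104)) {
  h <- grid[1]; w <- grid[2]
  kv_assert(h >= 16 && w >= 16, "grid must be at least 16 x 16")
  r_pix <- min(h, w) / 2
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  y <- (matrix(seq_len(h), h, w) - cy) / r_pix        # positive downward
  x <- (matrix(seq_len(w), h, w, byrow = TRUE) - cx) / r_pix
  r <- sqrt(x^2 + y^2)
  theta <- atan2(-y, x)                               # math convention, y flip
  f <- params$ave_k + (params$cyl / 2) * cos(2 * (theta - params$axis))
  if (params$cone_amplitude > 0) {
    gauss <- function(ctr, amp) {
      d2 <- (x - ctr[1])^2 + (y - ctr[2])^2
      amp * exp(-d2 / (2 * params$cone_width^2))
    }
    f <- f + gauss(params$cone_center, params$cone_amplitude)
    if (params$pattern == "ab_srax") {
      # opposite lobe, rotated by the skew angle, half amplitude
      phi <- atan2(params$cone_center[2], params$cone_center[1]) + pi +
        params$skew_angle
      rr <- sqrt(sum(params$cone_center^2))
      f <- f + gauss(c(rr * cos(phi), rr * sin(phi)),
                     0.5 * params$cone_amplitude)
    }
  }
  mask <- r <= 1
  f[!mask] <- NA_real_
  attr(f, "mask") <- mask
  f
}

#' Ground-truth grayscale map of a curvature field
#'
#' Maps the field directly through the color scale's bin -> intensity rule
#' (out-of-mask pixels get intensity 0), then resizes by area averaging.
#' This is the image the order-preserving grayscale conversion recovers from
#' a rendered map, and the fast path for building large VAE training sets.
#'
#' @param field output of [curvature_field()].
#' @param scale a [color_scale()].
#' @param size output side in pixels.
#' @return `size x size` matrix in `[0, 1]`.
#' @export
field_to_graymap <- function(field, scale, size = 104) {
  bin <- power_to_bin(field, scale)
  g <- bin_to_intensity(bin, scale)
  g[is.na(field)] <- 0
  dim(g) <- dim(field)
  if (!all(dim(g) == size)) g <- resize_area(g, size, size)
  clamp01(g)
}

#' Canvas configuration for map rendering
#'
#' @param height,width canvas size in pixels.
#' @param radius_frac cornea radius as a fraction of `min(height, width)`.
#' @param background background RGB triple.
#' @param annotations draw pseudo-text annotation blocks (words/numbers
#'   clutter) in the canvas margins — outside a 1.1 x radius ring *and*
#'   outside the disc's square crop region — as on device printouts. The
#'   default canvas is landscape (380 x 300) so side margins exist for them.
#' @param n_annotations number of annotation blocks.
#' @param annotation_seed seed for annotation placement.
#' @return a list of class `map_canvas`.
#' @export
map_canvas <- function(height = 300, width = 380, radius_frac = 0.45,
                       background = c(0.82, 0.82, 0.82), annotations = TRUE,
                       n_annotations = 8, annotation_seed = 0) {
  structure(list(height = height, width = width, radius_frac = radius_frac,
                 background = background, annotations = annotations,
                 n_annotations = n_annotations,
                 annotation_seed = annotation_seed),
            class = "map_canvas")
}

#' Render a curvature field as a color-coded map image
#'
#' Places the field's disc at the canvas center, colors each in-mask pixel by
#' its power bin under the scale (out-of-range powers clamp to the end bins;
#' the clamp count is attached as attribute `"clamped"`), fills the
#' background, and optionally scatters pseudo-text annotation blocks outside
#' a 1.1 x radius ring. The pixel mask of annotation ink is attached as
#' attribute `"annotation_mask"` so preprocessing can be checked against it.
#'
#' @param field output of [curvature_field()]; its grid must fit the canvas.
#' @param scale a [color_scale()].
#' @param canvas a [map_canvas()].
#' @return `H x W x 3` RGB array in `[0, 1]`.
#' @export
render_map <- function(field, scale = default_color_scale(),
                       canvas = map_canvas()) {
  h <- canvas$height; w <- canvas$width
  fh <- nrow(field); fw <- ncol(field)
  kv_assert(fh <= h && fw <= w, "field grid larger than canvas")
  img <- array(rep(canvas$background, each = h * w), c(h, w, 3))
  bin <- power_to_bin(field, scale)
  mask <- attr(field, "mask")
  y0 <- floor((h - fh) / 2); x0 <- floor((w - fw) / 2)
  full_mask <- matrix(FALSE, h, w)
  full_mask[y0 + seq_len(fh), x0 + seq_len(fw)] <- mask
  for (c in 1:3) {
    ch <- img[, , c]
    cols <- matrix(scale$colors[bin, c], fh, fw)
    ch[full_mask] <- cols[mask]
    img[, , c] <- ch
  }
  ann_mask <- matrix(FALSE, h, w)
  if (isTRUE(canvas$annotations) && canvas$n_annotations > 0) {
    ring <- 1.1 * min(fh, fw) / 2
    # annotations must also stay clear of the square crop region (plus the
    # 2 px segmentation slack), so ground-truth crops never contain them
    keep_out <- c(y0 - 2, x0 - 2, y0 + fh + 2, x0 + fw + 2)
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    with_seed(canvas$annotation_seed, {
      placed <- 0; tries <- 0
      while (placed < canvas$n_annotations && tries < 400) {
        tries <- tries + 1
        bh <- sample(4:8, 1); bw <- sample(12:30, 1)
        ty <- sample(seq_len(h - bh), 1); tx <- sample(seq_len(w - bw), 1)
        yy <- ty + seq_len(bh) - 1; xx <- tx + seq_len(bw) - 1
        dd <- sqrt(outer((yy - cy)^2, (xx - cx)^2, `+`))
        if (min(dd) <= ring) next
        overlaps_crop <- max(yy) > keep_out[1] && min(yy) < keep_out[3] &&
          max(xx) > keep_out[2] && min(xx) < keep_out[4]
        if (overlaps_crop) next
        ink <- matrix(runif(bh * bw) < 0.45, bh, bw)  # pseudo-text stipple
        sub <- ann_mask[yy, xx]; sub[ink] <- TRUE; ann_mask[yy, xx] <- sub
        placed <- placed + 1
      }
    })
    for (c in 1:3) {
      ch <- img[, , c]; ch[ann_mask] <- 0.1; img[, , c] <- ch
    }
  }
  attr(img, "clamped") <- attr(bin, "clamped")
  attr(img, "annotation_mask") <- ann_mask
  attr(img, "disc_bbox") <- c(x0, y0, x0 + fw, y0 + fh)  # 0-based half-open
  img
}

#' Render a full map from parameters
#'
#' Convenience wrapper: evaluates [curvature_field()] on a grid sized to the
#' canvas cornea radius and renders it.
#' @inheritParams render_map
#' @param params a [map_params()].
#' @return RGB array as in [render_map()].
#' @export
synth_topomap <- function(params, scale = default_color_scale(),
                          canvas = map_canvas()) {
  side <- 2 * round(canvas$radius_frac * min(canvas$height, canvas$width))
  field <- curvature_field(params, c(side, side))
  render_map(field, scale, canvas)
}

#' Structured acquisition noise
#'
#' Emulates the regular noise of high-resolution topographer captures:
#' periodic axis-aligned scan lines (rows darkened at every multiple of
#' `period`, with optional columns) plus salt-and-pepper impulse noise.
#' Zero amplitude and zero density reproduce the input exactly.
#'
#' @param image RGB array in `[0, 1]`.
#' @param noise_cfg list with `period` (pixels), `amplitude` (intensity drop
#'   on grid lines), `orientation` (`"rows"` or `"grid"`), `impulse_density`
#'   (fraction of pixels hit by impulse noise).
#' @param seed integer seed (impulse placement).
#' @return noised RGB array, same shape.
#' @export
add_acquisition_noise <- function(image,
                                  noise_cfg = list(period = 16,
                                                   amplitude = 0.25,
                                                   orientation = "rows",
                                                   impulse_density = 0.01),
                                  seed = 0) {
  image <- as_rgb01(image)
  cfg <- utils::modifyList(list(period = 16, amplitude = 0.25,
                                orientation = "rows",
                                impulse_density = 0.01), noise_cfg)
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- image
  if (cfg$amplitude > 0) {
    rows <- seq(cfg$period, h, by = cfg$period)
    out[rows, , ] <- out[rows, , ] - cfg$amplitude
    if (identical(cfg$orientation, "grid")) {
      cols <- seq(cfg$period, w, by = cfg$period)
      out[, cols, ] <- out[, cols, ] - cfg$amplitude
    }
  }
  if (cfg$impulse_density > 0) {
    with_seed(seed, {
      n <- round(cfg$impulse_density * h * w)
      if (n > 0) {
        idx <- sample.int(h * w, n)
        val <- sample(c(0, 1), n, replace = TRUE)
        for (c in 1:3) {
          ch <- out[, , c]; ch[idx] <- val; out[, , c] <- ch
        }
      }
    })
  }
  clamp01(out)
}

#' Write a cohort to disk
#'
#' Renders every map, writes PNGs and a manifest CSV with columns
#' `id, label, pattern, ave_k, cyl, axis, cone_amplitude, origin, file`.
#'
#' @param params_list list of [map_params()] from [sample_cohort()].
#' @param dir output directory (created if missing).
#' @param scale,canvas rendering configuration.
#' @param noise_cfg optional noise configuration applied to every image
#'   (`NULL` for clean maps).
#' @param seed seed for noise placement.
#' @return the manifest `data.frame`, invisibly.
#' @export
write_cohort <- function(params_list, dir, scale = default_color_scale(),
                         canvas = map_canvas(), noise_cfg = NULL, seed = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(params_list), function(i) {
    p <- params_list[[i]]
    img <- synth_topomap(p, scale, canvas)
    if (!is.null(noise_cfg))
      img <- add_acquisition_noise(img, noise_cfg, seed = seed + i)
    file <- sprintf("map%05d_%s.png", i, p$label)
    write_image(img, file.path(dir, file))
    data.frame(id = sprintf("map%05d", i), label = p$label,
               pattern = p$pattern, ave_k = p$ave_k, cyl = p$cyl,
               axis = p$axis, cone_amplitude = p$cone_amplitude,
               origin = "original", file = file)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Build an in-memory grayscale cohort
#'
#' Samples a cohort and converts each map's ground-truth field straight to a
#' grayscale image ([field_to_graymap()]), skipping the color rendering step;
#' the fast path for assembling large VAE training sets.
#'
#' @inheritParams sample_cohort
#' @param size grayscale side in pixels.
#' @param scale a [color_scale()].
#' @return a [kv_dataset()] of grayscale matrices, all `origin = "original"`.
#' @export
cohort_graymaps <- function(n_normal, n_kcn, seed,
                            size = 104, scale = default_color_scale(), ...) {
  params <- sample_cohort(n_normal, n_kcn, seed, ...)
  imgs <- lapply(params, function(p)
    field_to_graymap(curvature_field(p, c(size, size)), scale, size))
  kv_dataset(imgs, vapply(params, `[[`, "", "label"))
}
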