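# Parametric topography simulator: cohort sampling, curvature fields,
# rendering, acquisition noise.

test_that("color scale invariants hold and bins clamp out-of-range powers", {
  sc <- default_color_scale()
  expect_gte(sc$n_bins, 4)
  expect_true(all(diff(sc$thresholds) > 0))
  expect_equal(anyDuplicated(sc$colors), 0)
  expect_error(color_scale(c(1, 2, 2, 3), matrix(runif(12), 4)),
               "strictly increasing")
  bins <- power_to_bin(c(10, 44, 100), sc)
  expect_equal(bins[1], 1L)
  expect_equal(bins[3], sc$n_bins)
  expect_true(bins[2] > 1 && bins[2] < sc$n_bins)
})

test_that("sample_cohort returns the requested composition deterministically", {
  expect_length(sample_cohort(0, 0, 1), 0)
  ps <- sample_cohort(978, 780, seed = 7)
  expect_length(ps, 1758)
  labs <- vapply(ps, `[[`, "", "label")
  expect_equal(sum(labs == "normal"), 978)
  expect_equal(sum(labs == "kcn"), 780)
  expect_identical(ps, sample_cohort(978, 780, seed = 7))
  expect_error(sample_cohort(-1, 5, 1), "counts")
})

test_that("cohort parameters respect the per-class constraints", {
  ps <- sample_cohort(200, 200, seed = 3)
  for (p in ps) {
    expect_true(p$ave_k >= 30 && p$ave_k <= 70)
    expect_gte(p$cyl, 0)
    if (p$label == "normal") {
      expect_equal(p$pattern, "regular_astigmatism")
      expect_equal(p$cone_amplitude, 0)
    } else {
      expect_true(p$pattern %in% c("inferior_cone", "central_cone", "ab_srax"))
      expect_gt(p$cone_amplitude, 0)
    }
  }
})

test_that("sampled keratometry moments match the class distributions", {
  ps <- sample_cohort(5000, 5000, seed = 1)
  labs <- vapply(ps, `[[`, "", "label")
  avek <- vapply(ps, `[[`, 0, "ave_k")
  expect_lt(abs(mean(avek[labs == "kcn"]) - 48.68), 0.2)
  expect_lt(abs(mean(avek[labs == "normal"]) - 44.15), 0.1)
})

test_that("curvature_field evaluates the bowtie formula exactly", {
  # degenerate parameters: constant field inside the mask
  p0 <- map_params("regular_astigmatism", 44, 0)
  f0 <- curvature_field(p0, c(64, 64))
  expect_true(all(abs(f0[!is.na(f0)] - 44) < 1e-12))
  expect_true(all(is.na(f0[attr(f0, "mask") == FALSE])))

  # astigmatism: 44 + 1 * cos(2 theta) at mid-radius, axis 0
  p <- map_params("regular_astigmatism", 44, 2, axis = 0)
  f <- curvature_field(p, c(101, 101))
  ctr <- 51; r_pix <- 101 / 2
  expect_equal(f[ctr, ctr + 25], 45.0, tolerance = 1e-12)  # theta = 0
  expect_equal(f[ctr - 25, ctr], 43.0, tolerance = 1e-12)  # theta = pi/2
  expect_error(curvature_field(p, c(8, 20)), "16")
})

test_that("inferior cone puts the field maximum in the inferior half", {
  p <- map_params("inferior_cone", 46, 1, cone_amplitude = 8,
                  cone_center = c(0, 0.4), label = "kcn")
  f <- curvature_field(p, c(80, 80))
  idx <- which(f == max(f, na.rm = TRUE), arr.ind = TRUE)
  expect_gt(idx[1, 1], 40)  # row index beyond center = inferior (y grows down)
})

test_that("class separation: cone excess differs between classes", {
  ps <- sample_cohort(200, 200, seed = 5)
  excess <- vapply(ps, function(p) {
    f <- curvature_field(p, c(48, 48))
    max(f, na.rm = TRUE) - p$ave_k
  }, 0)
  labs <- vapply(ps, `[[`, "", "label")
  expect_gt(median(excess[labs == "kcn"]), median(excess[labs == "normal"]))
})

test_that("render_map colors every in-mask pixel from the scale", {
  sc <- default_color_scale()
  img <- fixture_map(ave_k = 44, cyl = 0)
  bbox <- attr(img, "disc_bbox")
  # constant field: single disc color = the bin color of 44 D
  bin44 <- power_to_bin(44, sc)
  center_px <- img[60, 60, ]
  expect_equal(as.vector(center_px), as.vector(sc$colors[bin44, ]))
  # every in-mask pixel's color is a scale color
  img2 <- fixture_map(ave_k = 44, cyl = 6)
  n <- dim(img2)[1]
  pix <- cbind(as.vector(img2[, , 1]), as.vector(img2[, , 2]),
               as.vector(img2[, , 3]))
  bg <- apply(abs(pix - 0.82) < 1e-9, 1, all)
  on_scale <- vapply(which(!bg), function(i)
    any(colSums(abs(t(sc$colors) - pix[i, ])) < 1e-9), logical(1))
  expect_true(all(on_scale))
})

test_that("rendering then ordered grayscale preserves the power ordering", {
  p <- map_params("regular_astigmatism", 43, 6, axis = 0.4)
  field <- curvature_field(p, c(108, 108))
  img <- render_map(field, default_color_scale(),
                    map_canvas(108, 108, annotations = FALSE))
  g <- ordered_grayscale(img, size = 108)      # same size: no resize blending
  mask <- attr(field, "mask")
  bins <- power_to_bin(field, default_color_scale())
  expect_equal(cor(g[mask], bins[mask], method = "spearman"), 1.0,
               tolerance = 1e-12)
})

test_that("acquisition noise is seeded, structured, and optional", {
  img <- fixture_map()
  same <- add_acquisition_noise(img, list(amplitude = 0, impulse_density = 0))
  expect_equal(same, img, ignore_attr = TRUE)

  p <- 16
  noised <- add_acquisition_noise(img, list(period = p, amplitude = 0.3,
                                            impulse_density = 0))
  d <- abs(noised - img)
  bad_rows <- which(apply(d, 1, max) > 0)
  expect_setequal(bad_rows, seq(p, dim(img)[1], by = p))

  n1 <- add_acquisition_noise(img, seed = 3)
  n2 <- add_acquisition_noise(img, seed = 3)
  expect_identical(n1, n2)
  expect_lt(psnr(n1, img), 30)  # default noise is clearly visible
})

test_that("write_cohort renders files plus a complete manifest", {
  dir <- withr::local_tempdir()
  ps <- sample_cohort(2, 2, seed = 9)
  m <- write_cohort(ps, dir)
  expect_equal(nrow(m), 4)
  expect_true(all(file.exists(file.path(dir, m$file))))
  expect_named(m, c("id", "label", "pattern", "ave_k", "cyl", "axis",
                    "cone_amplitude", "origin", "file"))
  img <- read_image(file.path(dir, m$file[1]))
  expect_equal(dim(img), c(300, 380, 3))  # landscape canvas with margins
})
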