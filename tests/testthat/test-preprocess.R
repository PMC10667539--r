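# Preprocessing chain: HSV segmentation, structured-noise removal,
# order-preserving grayscale, model input preparation.

test_that("segment_cornea recovers a known disc geometry", {
  img <- fixture_disc(300, 300, cy = 150, cx = 150, r = 60)
  crop <- segment_cornea(img)
  expect_s3_class(crop, "cornea_crop")
  expect_equal(dim(crop$image)[1], dim(crop$image)[2])  # square
  expect_gte(crop$side, 32)
  expect_true(all(abs(crop$source_bbox - c(90, 90, 210, 210)) <= 2))
})

test_that("segment_cornea raises typed errors on degenerate inputs", {
  gray <- array(0.5, c(100, 100, 3))
  expect_error(segment_cornea(gray), class = "no_cornea_found")
  full <- array(rep(c(1, 0, 0), each = 100 * 100), c(100, 100, 3))
  expect_error(segment_cornea(full), class = "segmentation_ambiguous")
  expect_error(segment_cornea(fixture_disc(40, 40, 20, 20, 10)), "64")
})

test_that("segmentation recovers the renderer's disc over seeded cohorts", {
  ps <- sample_cohort(15, 15, seed = 21)
  canvas <- map_canvas(300, 300, annotations = TRUE,
                       annotation_seed = 4)
  for (p in ps) {
    img <- synth_topomap(p, canvas = canvas)
    crop <- segment_cornea(img)
    expect_true(all(abs(crop$source_bbox - attr(img, "disc_bbox")) <= 2))
  }
})

test_that("the crop excludes annotation clutter", {
  p <- map_params("regular_astigmatism", 44, 2)
  img <- synth_topomap(p, canvas = map_canvas(300, 300, annotations = TRUE,
                                              n_annotations = 10,
                                              annotation_seed = 11))
  ann <- attr(img, "annotation_mask")
  expect_gt(sum(ann), 0)
  crop <- segment_cornea(img)
  bb <- crop$source_bbox  # 0-based half-open (x0, y0, x1, y1)
  inside <- ann[(bb[2] + 1):bb[4], (bb[1] + 1):bb[3]]
  expect_equal(sum(inside), 0)
})

test_that("remove_regular_noise is near-identity on clean maps and helps on noised ones", {
  clean <- fixture_map(ave_k = 45, cyl = 4, canvas_side = 160)
  out <- remove_regular_noise(clean)
  expect_equal(dim(out), dim(clean))
  expect_gte(psnr(out, clean), 35)

  noised <- add_acquisition_noise(clean, seed = 3)
  denoised <- remove_regular_noise(noised)
  expect_gt(psnr(denoised, clean), psnr(noised, clean))

  twice <- remove_regular_noise(denoised)
  expect_gte(psnr(twice, denoised), 40)  # near-idempotent
})

test_that("ordered grayscale maps bin endpoints to 0 and 1 monotonically", {
  sc <- default_color_scale()
  n <- sc$n_bins
  strip <- array(0, c(n, n, 3))       # square: column b painted bin-b color
  for (b in seq_len(n)) for (c in 1:3) strip[, b, c] <- sc$colors[b, c]
  g <- ordered_grayscale(strip, sc, size = n)   # same size: no resize
  expect_equal(g[1, 1], 0)
  expect_equal(g[1, n], 1)
  expect_true(all(diff(g[1, ]) > 0))            # strictly increasing in bin
  expect_equal(g[1, ], (seq_len(n) - 1) / (n - 1), tolerance = 1e-12)
})

test_that("ordered grayscale agrees with the brute-force oracle on a rendered map", {
  p <- map_params("central_cone", 47, 3, cone_amplitude = 6,
                  cone_center = c(0, 0), label = "kcn")
  field <- curvature_field(p, c(104, 104))
  sc <- default_color_scale()
  img <- render_map(field, sc, map_canvas(104, 104, annotations = FALSE))
  g <- ordered_grayscale(img, sc, size = 104)
  # brute force: per-pixel nearest color by explicit loop over bins
  n <- 104 * 104
  pix <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
               as.vector(img[, , 3]))
  d <- matrix(0, n, sc$n_bins)
  for (b in seq_len(sc$n_bins))
    d[, b] <- (pix[, 1] - sc$colors[b, 1])^2 +
      (pix[, 2] - sc$colors[b, 2])^2 + (pix[, 3] - sc$colors[b, 3])^2
  oracle <- (apply(d, 1, which.min) - 1) / (sc$n_bins - 1)
  mask <- as.vector(attr(field, "mask"))
  expect_gte(mean(abs(g[matrix(mask, 104)] -
                        oracle[mask]) < 1e-9), 0.99)
})

test_that("prepare_input shapes and ranges match each model contract", {
  img <- fixture_map(canvas_side = 300)
  v <- prepare_input(img, "vae")
  expect_equal(dim(v), c(104, 104, 1))
  expect_true(all(v >= 0 & v <= 1))

  cc <- prepare_input(img, "custom_cnn")
  expect_equal(dim(cc), c(50, 50, 3))
  expect_true(all(cc >= 0 & cc <= 1))

  tr <- prepare_input(img, "transfer")
  expect_equal(dim(tr), c(224, 224, 3))
  expect_true(all(tr >= -1 & tr <= 1))
  expect_equal(dim(prepare_input(img, "transfer", size_override = 160))[1], 160)

  # range endpoints of the [-1, 1] rescale on 8-bit constants
  u255 <- array(255L, c(64, 64, 3))
  expect_equal(max(abs(prepare_input(u255, "transfer") - 1)), 0)
  u0 <- array(0L, c(64, 64, 3))
  expect_equal(max(abs(prepare_input(u0, "transfer") + 1)), 0)
  expect_error(prepare_input(img, "nope"))
})

test_that("preprocessing ops are pure: repeated calls are identical", {
  img <- fixture_map(cyl = 5)
  expect_identical(remove_regular_noise(img), remove_regular_noise(img))
  expect_identical(ordered_grayscale(img), ordered_grayscale(img))
  expect_identical(segment_cornea(img)$source_bbox,
                   segment_cornea(img)$source_bbox)
})
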