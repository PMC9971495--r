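test_that("preprocess is an identity at sigma 0 and preserves constants", {
  img <- raster_image(matrix(runif(400, 0, 255), 20, 20), 0.5)
  expect_identical(preprocess(img, 0), img)

  const <- raster_image(matrix(80, 30, 30), 0.5)
  sm <- preprocess(const, 2)
  expect_true(all(abs(sm$pixels - 80) < 1e-6))
})

test_that("Gaussian smoothing conserves total intensity of an interior spot", {
  px <- matrix(0, 41, 41)
  px[21, 21] <- 200
  img <- raster_image(px, 0.5)
  sm <- preprocess(img, 1)  # sd = 2 px, far from the border
  expect_lt(abs(sum(sm$pixels) - 200) / 200, 0.001)
})

test_that("fixed-range binarization keeps intensities inside the band", {
  img <- raster_image(matrix(c(10, 100, 180, 250), 2, 2), 0.5)
  expect_error(binarize(img, "fixed"), "threshold_range")
  expect_error(binarize(img, "fixed", c(200, 100)), "lo <= hi")

  m <- binarize(img, "fixed", c(90, 200))
  expect_identical(m$pixels, matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))

  const <- raster_image(matrix(50, 5, 5), 0.5)
  expect_false(any(binarize(const, "fixed", c(100, 255))$pixels))
})

test_that("Otsu separates a bimodal image exactly and matches an exhaustive scan", {
  px <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  img <- raster_image(px, 0.5)
  m <- binarize(img, "otsu")
  expect_identical(m$pixels, px == 200)

  # random mixtures: the package threshold induces the same partition as the
  # brute-force scan (thresholds themselves may differ within a histogram
  # gap where the objective is flat)
  withr::with_seed(99, {
    for (k in 1:5) {
      vals <- round(c(rnorm(300, 60, 12), rnorm(150, 190, 18)))
      vals <- pmin(pmax(vals, 0), 255)
      img <- raster_image(matrix(vals, 18, 25), 0.5)
      mask <- binarize(img, "otsu")$pixels
      oracle <- exhaustive_otsu(vals)
      expect_identical(as.vector(mask), vals > oracle)
    }
  })
})

test_that("binarizing a noiseless render recovers the rasterized rod exactly", {
  mask_true <- rod_mask(8, 1, angle_deg = 40, ps = 0.25, side = 14)
  f <- structure(
    list(
      fibres = tibble::tibble(
        id = 1L, length_um = 8, width_um = 1, x = 7, y = 7,
        orientation = 40 * pi / 180, bundle_id = 1L, droplet = NA_integer_
      ),
      substrate_width = 14, substrate_height = 14, model_tag = "microdrop"
    ),
    class = "deposition_field"
  )
  r <- render_field(f, render_params(pixel_size = 0.25))
  expect_identical(binarize(r$image)$pixels, mask_true)
})

test_that("labeling honours connectivity, size filtering and border policy", {
  empty <- binary_mask(matrix(FALSE, 5, 5), 1)
  expect_identical(label_objects(empty)$n_objects, 0L)

  diag2 <- matrix(FALSE, 4, 4)
  diag2[2, 2] <- diag2[3, 3] <- TRUE
  m <- binary_mask(diag2, 1)
  expect_identical(label_objects(m, connectivity = 8, min_pixels = 1)$n_objects, 1L)
  expect_identical(label_objects(m, connectivity = 4, min_pixels = 1)$n_objects, 2L)

  # min_pixels removes small speckles but conserves remaining pixel counts
  px <- matrix(FALSE, 10, 10)
  px[2:3, 2:3] <- TRUE        # 4 px object
  px[7, 7] <- TRUE            # 1 px speckle
  lab <- label_objects(binary_mask(px, 1), min_pixels = 4)
  expect_identical(lab$n_objects, 1L)
  expect_identical(sum(lab$pixels > 0), 4L)
  expect_identical(sum(lab$objects$n_pixels), 4L)

  # border policy
  pb <- matrix(FALSE, 6, 6)
  pb[1, 2:3] <- TRUE          # touches top border
  pb[4, 4:5] <- TRUE          # interior
  mb <- binary_mask(pb, 1)
  flagged <- label_objects(mb, min_pixels = 1, border_policy = "flag")
  expect_identical(flagged$n_objects, 2L)
  expect_identical(sum(flagged$objects$touches_border), 1L)
  dropped <- label_objects(mb, min_pixels = 1, border_policy = "drop")
  expect_identical(dropped$n_objects, 1L)
  expect_false(any(dropped$objects$touches_border))
})

test_that("labels are consecutive and connected under the chosen connectivity", {
  withr::with_seed(21, {
    px <- matrix(runif(900) < 0.25, 30, 30)
  })
  lab <- label_objects(binary_mask(px, 1), connectivity = 4, min_pixels = 1)
  if (lab$n_objects > 0) {
    expect_identical(sort(unique(as.vector(lab$pixels[lab$pixels > 0]))),
                     seq_len(lab$n_objects))
  }
  expect_identical(sum(lab$pixels > 0), sum(px))
})

test_that("segmentation recovers the object count of a clean microdrop render", {
  f <- sample_fibres(120, seed = 31)
  fld <- deposit_microdrop(
    f, droplet_grid(n_x = 5, n_y = 5, step_x = 55, step_y = 55), 2,
    seed = 13, avoid_overlap = TRUE, min_separation = 1.5
  )
  r <- render_field(fld, render_params(pixel_size = 0.5))
  lab <- label_objects(binarize(r$image))
  expect_identical(lab$n_objects, nrow(fld$fibres))
})
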