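test_that("sample_fibres validates arguments and respects ranges", {
  expect_error(sample_fibres(-1), "single number|>=")
  expect_error(sample_fibres(10, length_range = c(15, 5)), "min <= max")
  expect_error(sample_fibres(10, width_range = c(-1, 1)), "positive")

  expect_identical(nrow(sample_fibres(0)), 0L)

  f <- sample_fibres(1000, length_range = c(5, 15), width_range = c(0.3, 1),
                     seed = 1)
  expect_identical(nrow(f), 1000L)
  expect_true(all(f$length_um >= 5 & f$length_um <= 15))
  expect_true(all(f$width_um >= 0.3 & f$width_um <= 1))
  expect_true(all(f$length_um >= f$width_um))
})

test_that("sample_fibres mean length matches the uniform expectation", {
  f <- sample_fibres(10000, length_range = c(5, 15), seed = 42)
  se <- (10 / sqrt(12)) / sqrt(10000)
  expect_lt(abs(mean(f$length_um) - 10), 3 * se)
})

test_that("sampling and deposition are deterministic under a fixed seed", {
  expect_identical(sample_fibres(50, seed = 3), sample_fibres(50, seed = 3))
  f <- sample_fibres(100, seed = 1)
  a <- deposit_microdrop(f, droplet_grid(n_x = 3, n_y = 3), 2, seed = 9)
  b <- deposit_microdrop(f, droplet_grid(n_x = 3, n_y = 3), 2, seed = 9)
  expect_identical(a$fibres, b$fibres)
  d1 <- deposit_drop(f, stain_model(drop_radius_initial = 100), seed = 5)
  d2 <- deposit_drop(f, stain_model(drop_radius_initial = 100), seed = 5)
  expect_identical(d1$fibres, d2$fibres)
})

test_that("microdrop deposition follows the Poisson droplet model", {
  f <- sample_fibres(200, seed = 2)
  expect_error(deposit_microdrop(f, droplet_grid(), -1), ">=")

  empty <- deposit_microdrop(f, droplet_grid(n_x = 4, n_y = 4), 0, seed = 1)
  expect_identical(nrow(empty$fibres), 0L)

  grid <- droplet_grid(n_x = 10, n_y = 10, step_x = 60, step_y = 60,
                       origin_x = 50, origin_y = 50)
  fld <- deposit_microdrop(f, grid, 3, seed = 7)
  n <- nrow(fld$fibres)
  expect_lt(abs(n - 300), 3 * sqrt(300))

  # every centroid within footprint + 4 sd jitter of its droplet centre
  cx <- 50 + ((fld$fibres$droplet - 1) %% 10) * 60
  cy <- 50 + ((fld$fibres$droplet - 1) %/% 10) * 60
  d <- sqrt((fld$fibres$x - cx)^2 + (fld$fibres$y - cy)^2)
  expect_true(all(d <= grid$footprint_radius + 4 * grid$placement_jitter_sd))

  # centroids inside the substrate
  expect_true(all(fld$fibres$x >= 0 & fld$fibres$x <= fld$substrate_width))
  expect_true(all(fld$fibres$y >= 0 & fld$fibres$y <= fld$substrate_height))
})

test_that("drop deposition contracts radially and forms bundles", {
  f <- sample_fibres(400, seed = 4)

  plain <- deposit_drop(
    f, stain_model(drop_radius_initial = 100, compression_exponent = 0,
                   bundle_capture_radius = 0), seed = 11
  )
  expect_identical(anyDuplicated(plain$fibres$bundle_id), 0L)
  ctr <- c(plain$substrate_width, plain$substrate_height) / 2
  r0 <- sqrt((plain$fibres$x - ctr[1])^2 + (plain$fibres$y - ctr[2])^2)
  expect_true(all(r0 <= 100 + 1e-9))

  # same seed, exponent 2: the contraction map strictly reduces mean radius
  squeezed <- deposit_drop(
    f, stain_model(drop_radius_initial = 100, compression_exponent = 2,
                   bundle_capture_radius = 0), seed = 11
  )
  ctr2 <- c(squeezed$substrate_width, squeezed$substrate_height) / 2
  r2 <- sqrt((squeezed$fibres$x - ctr2[1])^2 + (squeezed$fibres$y - ctr2[2])^2)
  expect_lt(mean(r2), mean(r0))

  # capture radius >= drop radius: everything in one bundle
  glom <- deposit_drop(
    f, stain_model(drop_radius_initial = 100,
                   bundle_capture_radius = 300), seed = 11
  )
  expect_identical(dplyr::n_distinct(glom$fibres$bundle_id), 1L)
})

test_that("rendering reproduces rod geometry and separability", {
  empty <- structure(
    list(fibres = sample_fibres(0), substrate_width = 20,
         substrate_height = 20, model_tag = "microdrop"),
    class = "deposition_field"
  )
  empty$fibres$x <- numeric()
  empty$fibres$y <- numeric()
  empty$fibres$orientation <- numeric()
  empty$fibres$bundle_id <- integer()
  out <- render_field(empty, render_params(background_level = 30))
  expect_identical(nrow(out$ground_truth), 0L)
  expect_true(all(out$image$pixels == 30))

  # single 10 x 1 um fibre: one component, area near the capsule area,
  # matching an independent pixel-enumeration oracle
  mask <- rod_mask(10, 1, angle_deg = 25, ps = 0.25, side = 16)
  lab <- label_objects(binary_mask(mask, 0.25), min_pixels = 1)
  expect_identical(lab$n_objects, 1L)
  area <- sum(mask) * 0.25^2
  expect_lt(abs(area - 10), 0.5)
  oracle <- enumerate_capsule_pixels(8, 8, 10, 1, 25 * pi / 180, 0.25, 64)
  expect_identical(sum(mask), as.integer(oracle))

  # two parallel fibres >= 5 um apart stay two components
  f2 <- structure(
    list(
      fibres = tibble::tibble(
        id = 1:2, length_um = 10, width_um = 1, x = c(10, 10), y = c(6, 14),
        orientation = 0, bundle_id = 1:2, droplet = NA_integer_
      ),
      substrate_width = 20, substrate_height = 20, model_tag = "microdrop"
    ),
    class = "deposition_field"
  )
  r2 <- render_field(f2, render_params(pixel_size = 0.25))
  lab2 <- label_objects(binarize(r2$image))
  expect_identical(lab2$n_objects, 2L)
  expect_identical(sort(unique(r2$ground_truth$cluster_id)), 1:2)

  # determinism: identical seeds give bit-identical noisy images
  f <- sample_fibres(40, seed = 6)
  fld <- deposit_microdrop(f, droplet_grid(n_x = 3, n_y = 3, step_x = 50,
                                           step_y = 50), 2, seed = 8)
  i1 <- render_field(fld, render_params(noise_sd = 5, psf_sigma = 0.3),
                     seed = 4)
  i2 <- render_field(fld, render_params(noise_sd = 5, psf_sigma = 0.3),
                     seed = 4)
  expect_identical(i1$image$pixels, i2$image$pixels)
  # conservation: ground truth keeps every deposited fibre
  expect_identical(nrow(i1$ground_truth), nrow(fld$fibres))
})

test_that("sub-pixel fibre widths are flagged but still rendered", {
  f <- structure(
    list(
      fibres = tibble::tibble(
        id = 1L, length_um = 8, width_um = 0.3, x = 8, y = 8,
        orientation = 0.4, bundle_id = 1L, droplet = NA_integer_
      ),
      substrate_width = 16, substrate_height = 16, model_tag = "microdrop"
    ),
    class = "deposition_field"
  )
  out <- render_field(f, render_params(pixel_size = 0.5))
  expect_length(attr(out$image, "render_warnings"), 1)
  lab <- label_objects(binarize(out$image), min_pixels = 1)
  expect_identical(lab$n_objects, 1L)
})
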