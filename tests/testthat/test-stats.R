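test_that("class histograms use half-open bins with open extremes", {
  h <- histogram_by_class(c(1.5, 2.0, 2.4, 2.8, 3.5), scheme_ef(), 1)
  expect_identical(h$count, rep(1L, 5))
  expect_equal(h$per_mm2, h$count / 1)
  expect_equal(h$cumulative_pct, c(20, 40, 60, 80, 100))

  # boundary values land in the upper class: [lo, hi)
  hb <- histogram_by_class(c(1.8, 2.2, 2.6, 3), scheme_ef(), 2)
  expect_identical(hb$count, c(0L, 1L, 1L, 1L, 1L))
  expect_equal(hb$per_mm2, hb$count / 2)

  he <- histogram_by_class(numeric(), scheme_ef(), 1)
  expect_identical(sum(he$count), 0L)
  expect_true(all(is.na(he$cumulative_pct)))
})

test_that("printed elongation-factor class counts give the printed cumulatives", {
  h_drop <- histogram_by_class(ef_values_from_counts(table2_ef_drop),
                               scheme_ef(), 3.71)
  expect_identical(h_drop$count, as.integer(table2_ef_drop))
  expect_equal(round(h_drop$cumulative_pct[2], 1), 55.9)
  expect_equal(round(h_drop$cumulative_pct[5], 1), 100)

  h_micro <- histogram_by_class(ef_values_from_counts(table2_ef_micro),
                                scheme_ef(), 0.99)
  expect_equal(round(h_micro$cumulative_pct[3], 2), 50.47)
})

test_that("normalised counts times area reproduce raw counts exactly", {
  withr::with_seed(5, {
    for (k in 1:10) {
      vals <- runif(sample(10:200, 1), 0.5, 6)
      area <- runif(1, 0.2, 5)
      h <- histogram_by_class(vals, scheme_ef(), area)
      expect_equal(h$per_mm2 * area, as.numeric(h$count), tolerance = 1e-12)
      expect_identical(sum(h$count), length(vals))
      expect_true(all(diff(h$cumulative_pct) >= -1e-12))
      expect_equal(h$cumulative_pct[length(h$cumulative_pct)], 100,
                   tolerance = 1e-9)
    }
  })
})

test_that("batch summaries reproduce the reference per-image statistics", {
  drop <- batch_summary(table1_drop_counts, table1_drop_coverage)
  expect_identical(round(drop$mean_count), 24)
  expect_identical(round(drop$rsd_count_report), 48)
  expect_equal(round(drop$mean_coverage, 1), 4.4)
  # the exact-mean RSD and the sample-sd variant differ from the report value
  expect_equal(drop$rsd_count, 47.2, tolerance = 0.05)
  expect_identical(round(100 * sd(table1_drop_counts) /
                           round(mean(table1_drop_counts))), 50)

  micro <- batch_summary(table1_micro_counts, table1_micro_coverage)
  expect_identical(round(micro$mean_count), 212)
  expect_identical(round(micro$rsd_count_report), 31)
  expect_equal(round(micro$mean_coverage, 1), 5.0)
  expect_identical(micro$total_count, 2964)

  const <- batch_summary(c(5, 5, 5))
  expect_equal(const$rsd_count, 0)

  zero <- batch_summary(c(0, 0))
  expect_true(is.na(zero$rsd_count))
})

test_that("densities follow the reference totals and reject zero area", {
  expect_identical(round(fibre_density(330, 3.59)), 92)
  expect_identical(round(fibre_density(364, 0.19)), 1916)
  expect_equal(fibre_density(0, 1), 0)
  expect_error(fibre_density(10, 0), "> 0")
})

test_that("tile homogeneity detects concentration", {
  # perfectly regular grid of fibres, tile = grid period
  xy <- expand.grid(ix = 0:5, iy = 0:5)
  regular <- structure(
    list(
      fibres = tibble::tibble(
        id = seq_len(36), length_um = 8, width_um = 0.5,
        x = 25 + xy$ix * 50, y = 25 + xy$iy * 50,
        orientation = 0, bundle_id = seq_len(36), droplet = NA_integer_
      ),
      substrate_width = 300, substrate_height = 300, model_tag = "microdrop"
    ),
    class = "deposition_field"
  )
  expect_equal(as.numeric(tile_homogeneity(regular, 50)), 0)

  # everything in one tile out of four: population RSD = sqrt(3) * 100
  clumped <- regular
  clumped$fibres$x <- runif(36, 0, 40)
  clumped$fibres$y <- runif(36, 0, 40)
  clumped$substrate_width <- clumped$substrate_height <- 100
  expect_equal(as.numeric(tile_homogeneity(clumped, 50)), sqrt(3) * 100,
               tolerance = 1e-9)

  expect_error(tile_homogeneity(regular, 400), "2 tiles")
})

test_that("microdrop depositions tile more evenly than stain-effect drops", {
  f <- sample_fibres(300, seed = 77)
  md <- deposit_microdrop(
    f, droplet_grid(n_x = 6, n_y = 6, step_x = 60, step_y = 60), 3, seed = 1
  )
  dr <- deposit_drop(
    f, stain_model(drop_radius_initial = md$substrate_width / 2 - 10,
                   compression_exponent = 2), seed = 2
  )
  expect_lt(tile_homogeneity(md, 60), tile_homogeneity(dr, 60))
})
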