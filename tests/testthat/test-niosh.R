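test_that("a straight rod skeletonizes to a single full-length edge", {
  sg <- skeletonize_object(rod_mask(10, 1, 20, ps = 0.25, side = 16), 0.25)
  expect_identical(sum(sg$nodes$type == "endpoint"), 2L)
  expect_identical(sum(sg$nodes$type == "junction"), 0L)
  expect_identical(nrow(sg$edges), 1L)
  expect_identical(sg$n_loops, 0L)
  expect_lt(abs(sg$edges$path_length - 10), 0.5)
  expect_lt(abs(sg$edges$mean_local_width - 1), 0.5)
})

test_that("a perpendicular cross yields one 4-way junction and no loops", {
  fx <- fixture_masks()
  sg <- skeletonize_object(fx$x_90$mask, 0.25)
  expect_identical(sum(sg$nodes$type == "junction"), 1L)
  expect_identical(sum(sg$nodes$type == "endpoint"), 4L)
  expect_identical(nrow(sg$edges), 4L)
  expect_identical(sg$n_loops, 0L)
})

test_that("a ring skeleton carries exactly one loop", {
  fx <- fixture_masks()
  sg <- skeletonize_object(fx$ring_d8$mask, 0.25)
  expect_identical(sg$n_loops, 1L)
  expect_identical(sum(sg$nodes$type == "junction"), 0L)
  # circumference of a diameter-8 ring
  expect_lt(abs(sum(sg$edges$path_length) - 2 * pi * 4), 1.5)
})

test_that("crossings split into two collinear fibre candidates", {
  fx <- fixture_masks()
  for (nm in c("x_90", "x_60")) {
    sg <- skeletonize_object(fx[[nm]]$mask, 0.25)
    cl <- classify_topology(sg)
    expect_identical(cl$topology, "crossed")
    expect_identical(nrow(cl$candidates), 2L)
    expect_true(all(abs(cl$candidates$path_length - 8) < 1))
    # decomposition conserves total skeleton length
    expect_equal(sum(cl$candidates$path_length), sum(sg$edges$path_length),
                 tolerance = 1e-9)
  }
})

test_that("branched objects give one candidate along the longest geodesic", {
  fx <- fixture_masks()
  cl <- classify_topology(skeletonize_object(fx$y_663$mask, 0.25))
  expect_identical(cl$topology, "branched")
  expect_identical(nrow(cl$candidates), 1L)
  expect_lt(abs(cl$candidates$path_length - 12), 1)
})

test_that("entangled clumps produce no candidates", {
  fx <- fixture_masks()
  cl <- classify_topology(skeletonize_object(fx$clump$mask, 0.25))
  expect_identical(cl$topology, "entangled")
  expect_identical(nrow(cl$candidates), 0L)
})

test_that("geometric rules apply strict boundaries and tally rejections", {
  cand <- function(len, wid, blob = 0) {
    tibble::tibble(
      parent_object_id = 1L, path_length = len, mean_width = wid,
      max_attached_blob_diameter = blob, topology = "simple"
    )
  }
  p <- niosh_params()
  expect_identical(nrow(apply_geometric_rules(cand(8, 0.5), p)$accepted), 1L)
  expect_identical(apply_geometric_rules(cand(4, 0.5), p)$rejected[["too_short"]], 1L)
  expect_identical(apply_geometric_rules(cand(8, 3.5), p)$rejected[["too_wide"]], 1L)
  expect_identical(apply_geometric_rules(cand(8, 2.9), p)$rejected[["low_ar"]], 1L)
  expect_identical(apply_geometric_rules(cand(8, 0.5, 4), p)$rejected[["blob"]], 1L)
  # boundary values are rejected (strict inequalities)
  expect_identical(apply_geometric_rules(cand(5, 0.5), p)$rejected[["too_short"]], 1L)
  expect_identical(apply_geometric_rules(cand(9, 3), p)$rejected[["too_wide"]], 1L)
  expect_identical(apply_geometric_rules(cand(6, 2), p)$rejected[["low_ar"]], 1L)
  # blob limit is inclusive: exactly 3 um is tolerated
  expect_identical(nrow(apply_geometric_rules(cand(8, 0.5, 3), p)$accepted), 1L)
})

test_that("counting matches the hand-labeled fixture catalogue exactly", {
  fx <- fixture_masks()
  expect_gte(length(fx), 20)
  for (nm in names(fx)) {
    cnt <- count_fibres(label_objects(binary_mask(fx[[nm]]$mask, 0.25)))
    expect_identical(cnt$n_fibres, fx[[nm]]$expected_fibres,
                     label = sprintf("fixture %s", nm))
  }
})

test_that("accepted plus rejected candidates are conserved", {
  fx <- fixture_masks()
  for (nm in names(fx)) {
    cnt <- count_fibres(label_objects(binary_mask(fx[[nm]]$mask, 0.25)))
    rule_rejects <- sum(cnt$rejected[c("too_short", "too_wide", "low_ar",
                                       "blob")])
    expect_identical(cnt$n_fibres + rule_rejects, cnt$n_candidates)
    expect_identical(length(cnt$fibre_lengths), cnt$n_fibres)
    expect_equal(cnt$fibres_per_mm2,
                 cnt$n_fibres / cnt$inspected_area_mm2)
  }
})

test_that("raising the minimum length never increases the fibre count", {
  fx <- fixture_masks()
  combined <- function(min_length) {
    sum(vapply(fx, function(f) {
      count_fibres(label_objects(binary_mask(f$mask, 0.25)),
                   niosh_params(min_length = min_length))$n_fibres
    }, integer(1)))
  }
  counts <- vapply(c(3, 5, 8, 12), combined, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fibre length histograms bin from the counting threshold", {
  fake <- structure(
    list(
      n_images = 1L, inspected_area_mm2 = 2, n_fibres = 4L,
      fibres_per_mm2 = 2, fibre_lengths = c(6, 7, 9, 10),
      rejected = setNames(integer(5), c("too_short", "too_wide", "low_ar",
                                        "blob", "entangled")),
      n_candidates = 4L, n_absorbed = 0L,
      fibres = tibble::tibble(object_id = 1:4, length_um = c(6, 7, 9, 10),
                              width_um = 0.5, topology = "simple")
    ),
    class = "counting_result"
  )
  h <- fibre_length_histogram(fake)
  expect_identical(h$class, c("5-8", "8-11"))
  expect_identical(h$count, c(2L, 2L))
  expect_equal(h$cumulative_pct, c(50, 100))
  expect_equal(h$per_mm2, c(1, 1))
})

test_that("uniform lengths fill the length classes within multinomial bounds", {
  withr::with_seed(11, {
    lengths <- runif(3000, 5, 14)
  })
  fake <- structure(
    list(
      n_images = 1L, inspected_area_mm2 = 1, n_fibres = length(lengths),
      fibres_per_mm2 = length(lengths), fibre_lengths = lengths,
      rejected = setNames(integer(5), c("too_short", "too_wide", "low_ar",
                                        "blob", "entangled")),
      n_candidates = length(lengths), n_absorbed = 0L,
      fibres = tibble::tibble(object_id = seq_along(lengths),
                              length_um = lengths, width_um = 0.5,
                              topology = "simple")
    ),
    class = "counting_result"
  )
  h <- fibre_length_histogram(fake, bin_width = 3, start = 5)
  p <- 1 / 3  # three equal classes over [5, 14)
  sigma <- sqrt(3000 * p * (1 - p))
  expect_true(all(abs(h$count - 1000) < 3 * sigma))
})

test_that("straight-rod skeleton length agrees with the rectangle length", {
  # the two length definitions coincide for straight rods
  withr::with_seed(3, {
    for (k in 1:5) {
      L <- runif(1, 6, 12)
      a <- runif(1, 0, 180)
      mask <- rod_mask(L, 1, a, ps = 0.25, side = L + 4)
      rect_len <- measure_objects(label_objects(
        binary_mask(mask, 0.25)
      ))$length_um
      skel_len <- sum(skeletonize_object(mask, 0.25)$edges$path_length)
      # within the cap-erosion / staircase quantisation scale at 0.25 um/px
      expect_lt(abs(rect_len - skel_len), 1.2)
    }
  })
})
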