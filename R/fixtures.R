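# Constructed binary test objects with hand-assigned expected NIOSH counts.
# Geometry is drawn with the same capsule rasterizer the simulator uses.

blank_canvas <- function(side_um, ps) {
  n <- ceiling(side_um / ps)
  matrix(FALSE, n, n)
}

draw_capsule <- function(mask, x, y, length, width, angle_deg, ps) {
  m <- rasterize_capsule(
    matrix(as.numeric(mask), nrow(mask), ncol(mask)),
    x, y, length, width, angle_deg * pi / 180, ps, 1
  )
  m > 0
}

draw_disc <- function(mask, x, y, diameter, ps) {
  draw_capsule(mask, x, y, diameter, diameter, 0, ps)
}

# Polyline fibre: consecutive capsules through the given vertices.
draw_polyline <- function(mask, xs, ys, width, ps) {
  for (i in seq_len(length(xs) - 1)) {
    mx <- (xs[i] + xs[i + 1]) / 2
    my <- (ys[i] + ys[i + 1]) / 2
    seg_len <- sqrt((xs[i + 1] - xs[i])^2 + (ys[i + 1] - ys[i])^2)
    ang <- atan2(ys[i + 1] - ys[i], xs[i + 1] - xs[i]) * 180 / pi
    # width added to length so consecutive segments fuse seamlessly
    mask <- draw_capsule(mask, mx, my, seg_len + width, width, ang, ps)
  }
  mask
}

#' Constructed topology fixtures for the fibre-counting rules
#'
#' Builds a named set of binary masks covering the counting-rule case
#' catalogue - straight rods of varying size, crossings (X), branches
#' (Y, T, H), bends, a closed ring, attached-particle (blob) rods, and an
#' entangled clump - each with the hand-assigned number of countable fibres
#' a manual NIOSH count would give.
#'
#' @param pixel_size Micrometres per pixel (default 0.25).
#' @return A named list; each element has `mask` (logical matrix),
#'   `expected_fibres` (integer) and `note`.
#' @export
fixture_masks <- function(pixel_size = 0.25) {
  ps <- pixel_size
  fx <- list()
  add <- function(name, mask, expected, note) {
    fx[[name]] <<- list(mask = mask, expected_fibres = expected, note = note)
  }

  rod <- function(len, wid, ang = 0, side = max(len + 6, 14)) {
    draw_capsule(blank_canvas(side, ps), side / 2, side / 2, len, wid, ang, ps)
  }

  add("rod_8x05", rod(8, 0.5), 1L, "straight countable rod")
  add("rod_12x05_30deg", rod(12, 0.5, 30), 1L, "long rod at 30 degrees")
  add("rod_6x05_120deg", rod(6, 0.5, 120), 1L, "short but countable rod")
  add("rod_4x05", rod(4, 0.5), 0L, "rejected: shorter than 5 um")
  add("rod_10x35", rod(10, 3.5), 0L, "rejected: wider than 3 um")
  add("rod_6x25", rod(6, 2.5), 0L, "rejected: aspect ratio below 3")
  add("square_5", {
    m <- blank_canvas(12, ps)
    m[ceiling(3.5 / ps):ceiling(8.5 / ps), ceiling(3.5 / ps):ceiling(8.5 / ps)] <- TRUE
    m
  }, 0L, "compact square, not fibrous")
  add("disc_2", draw_disc(blank_canvas(8, ps), 4, 4, 2, ps), 0L,
      "small round particle")

  cross <- function(l1, l2, ang, side = max(l1, l2) + 6) {
    m <- blank_canvas(side, ps)
    m <- draw_capsule(m, side / 2, side / 2, l1, 0.5, 0, ps)
    draw_capsule(m, side / 2, side / 2, l2, 0.5, ang, ps)
  }
  add("x_90", cross(8, 8, 90), 2L, "perpendicular crossing: 2 fibres")
  add("x_60", cross(8, 8, 60), 2L, "oblique crossing: 2 fibres")
  add("x_uneq", cross(12, 8, 70), 2L, "unequal crossing: 2 fibres")

  add("y_663", {
    m <- blank_canvas(18, ps)
    cx <- 9; cy <- 9
    for (br in list(c(90, 6), c(210, 6), c(330, 3))) {
      a <- br[1] * pi / 180
      m <- draw_polyline(m, c(cx, cx + br[2] * cos(a)),
                         c(cy, cy + br[2] * sin(a)), 0.5, ps)
    }
    m
  }, 1L, "Y branch (6,6,3 um): one fibre")
  add("t_83", {
    m <- blank_canvas(14, ps)
    m <- draw_capsule(m, 7, 7, 8, 0.5, 0, ps)
    draw_polyline(m, c(7, 7), c(7, 10), 0.5, ps)
  }, 1L, "T branch: one fibre")
  add("h_shape", {
    m <- blank_canvas(14, ps)
    m <- draw_capsule(m, 5.5, 7, 8, 0.5, 90, ps)
    m <- draw_capsule(m, 8.5, 7, 8, 0.5, 90, ps)
    draw_polyline(m, c(5.5, 8.5), c(7, 7), 0.5, ps)
  }, 2L, "H: two fibres, short crossbar absorbed")

  add("ring_d8", {
    th <- seq(0, 2 * pi, length.out = 73)
    draw_polyline(blank_canvas(14, ps), 7 + 4 * cos(th), 7 + 4 * sin(th),
                  0.5, ps)
  }, 1L, "closed ring: one curled fibre")

  add("bent_120", {
    a <- 30 * pi / 180
    draw_polyline(blank_canvas(16, ps), c(8 - 5 * cos(a), 8, 8 - 5 * cos(a)),
                  c(8 - 5 * sin(a), 8, 8 + 5 * sin(a)), 0.5, ps)
  }, 1L, "120-degree elbow: one bent fibre")
  add("arc_gentle", {
    th <- seq(-pi / 6, pi / 6, length.out = 25)
    draw_polyline(blank_canvas(24, ps), 4 + 10 * cos(th), 12 + 10 * sin(th),
                  0.5, ps)
  }, 1L, "gentle arc: one curved fibre")
  add("v_open", {
    m <- blank_canvas(16, ps)
    m <- draw_polyline(m, c(8, 8 + 6 * cos(150 * pi / 180)),
                       c(4, 4 + 6 * sin(150 * pi / 180)), 0.5, ps)
    draw_polyline(m, c(8, 8 + 6 * cos(30 * pi / 180)),
                  c(4, 4 + 6 * sin(30 * pi / 180)), 0.5, ps)
  }, 1L, "open V joined at one end: one bent fibre")

  add("blob_rod", {
    m <- rod(10, 0.5, 0, 16)
    draw_disc(m, 10, 8, 4, ps)
  }, 0L, "rejected: attached particle larger than 3 um")
  add("blob_rod_small", {
    m <- rod(10, 0.5, 0, 16)
    draw_disc(m, 10, 8, 1.5, ps)
  }, 1L, "small attached particle tolerated")

  add("pair_rods", {
    m <- blank_canvas(16, ps)
    m <- draw_capsule(m, 8, 5, 8, 0.5, 0, ps)
    draw_capsule(m, 8, 11, 8, 0.5, 10, ps)
  }, 2L, "two separate rods: 2 fibres")

  add("clump", {
    m <- blank_canvas(18, ps)
    angs <- c(0, 30, 60, 95, 125, 155)
    offx <- c(0, 1.5, -1.2, 0.8, -1.8, 1.1)
    offy <- c(0, -1.3, 1.6, 0.9, -0.7, 1.9)
    for (i in seq_along(angs)) {
      m <- draw_capsule(m, 9 + offx[i], 9 + offy[i], 10, 0.5, angs[i], ps)
    }
    m
  }, 0L, "entangled clump: not counted")

  fx
}

#' Write the package's fixture set to disk
#'
#' Materialises the constructed topology masks from [fixture_masks()] plus
#' two small simulated drop/micro-drop image pairs with their ground truth,
#' as TIFFs with JSON sidecars, ground-truth CSVs and a `manifest.csv`
#' listing every file with its expected fibre count (masks) and MD5 hash.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the simulated pairs.
#' @param pixel_size Micrometres per pixel for the masks.
#' @return The manifest tibble, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1, pixel_size = 0.25) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fx <- fixture_masks(pixel_size)
  rows <- list()
  for (nm in names(fx)) {
    path <- file.path(out_dir, paste0("mask_", nm, ".tif"))
    img <- raster_image(
      matrix(as.numeric(fx[[nm]]$mask) * 255, nrow(fx[[nm]]$mask)),
      pixel_size
    )
    write_raster(img, path)
    rows[[length(rows) + 1L]] <- tibble(
      file = basename(path), kind = "mask",
      expected_fibres = fx[[nm]]$expected_fibres,
      note = fx[[nm]]$note,
      md5 = unname(tools::md5sum(path))
    )
  }
  fibres <- sample_fibres(400, seed = seed)
  sims <- list(
    drop = deposit_drop(fibres, stain_model(drop_radius_initial = 150),
                        seed = seed + 1L),
    microdrop = deposit_microdrop(
      fibres, droplet_grid(n_x = 5, n_y = 5, step_x = 60, step_y = 60),
      mean_fibres_per_droplet = 3, seed = seed + 2L
    )
  )
  for (i in c(1L, 2L)) {
    for (m in names(sims)) {
      rendered <- render_field(
        sims[[m]], render_params(psf_sigma = 0.3, noise_sd = 5),
        seed = seed + 10L * i
      )
      path <- file.path(out_dir, sprintf("sim_%s_%d.tif", m, i))
      write_raster(rendered$image, path)
      truth_path <- sub("\\.tif$", "_truth.csv", path)
      readr::write_csv(rendered$ground_truth, truth_path)
      rows[[length(rows) + 1L]] <- tibble(
        file = basename(path), kind = "simulated_image",
        expected_fibres = NA_integer_,
        note = sprintf("%s deposition, ground truth in %s", m,
                       basename(truth_path)),
        md5 = unname(tools::md5sum(path))
      )
    }
  }
  manifest <- bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}
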