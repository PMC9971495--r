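#' Sample a synthetic population of needle-like fibres
#'
#' Draws fibre lengths and widths emulating a powder of thin, needle-like
#' amphibole crystals (lengths of a few to tens of micrometres, widths below
#' one micrometre). By default both dimensions are uniform over their ranges;
#' a truncated lognormal alternative is available for more realistic
#' right-skewed powders.
#'
#' @param n Number of fibres (non-negative integer).
#' @param length_range Numeric pair, fibre length range in micrometres.
#' @param width_range Numeric pair, fibre width range in micrometres.
#' @param distribution `"uniform"` (default) or `"lognormal"` (lognormal with
#'   the geometric mid-range as median, truncated to the range).
#' @param seed Optional integer seed; fixed seeds give identical populations.
#'
#' @return A tibble with columns `id`, `length_um`, `width_um`. Widths never
#'   exceed lengths.
#' @export
#' @examples
#' sample_fibres(5, seed = 1)
sample_fibres <- function(n, length_range = c(5, 15), width_range = c(0.3, 1),
                          distribution = c("uniform", "lognormal"),
                          seed = NULL) {
  check_scalar_number(n, "n", min = 0)
  if (n != floor(n)) abort("`n` must be an integer count.")
  check_range(length_range, "length_range")
  check_range(width_range, "width_range")
  distribution <- match.arg(distribution)
  n <- as.integer(n)
  if (n == 0) {
    return(tibble(id = integer(), length_um = numeric(), width_um = numeric()))
  }
  draw <- function(k, range) {
    if (distribution == "uniform" || range[1] == range[2]) {
      runif(k, range[1], range[2])
    } else {
      meanlog <- mean(log(range))
      sdlog <- diff(log(range)) / 4
      x <- rlnorm_truncated(k, meanlog, sdlog, range)
      x
    }
  }
  with_seed_or_not(seed, {
    len <- draw(n, length_range)
    wid <- draw(n, width_range)
    tibble(
      id = seq_len(n),
      length_um = pmax(len, wid),
      width_um = pmin(len, wid)
    )
  })
}

rlnorm_truncated <- function(n, meanlog, sdlog, range) {
  lo <- stats::plnorm(range[1], meanlog, sdlog)
  hi <- stats::plnorm(range[2], meanlog, sdlog)
  stats::qlnorm(runif(n, lo, hi), meanlog, sdlog)
}

#' Droplet grid for micro-drop deposition
#'
#' Describes the programmed X-Y pattern of picolitre droplets dispensed by an
#' inkjet-style micro-dispenser: an `n_x` by `n_y` grid with fixed steps, a
#' droplet volume (180 pL for a 70 um nozzle), a wetted footprint radius on
#' the substrate, and the Gaussian positioning jitter of the stage
#' (about +-1 um).
#'
#' @param n_x,n_y Droplet counts along x and y.
#' @param step_x,step_y Grid spacing in micrometres.
#' @param origin_x,origin_y Centre of the first droplet in micrometres; `NULL`
#'   lets [deposit_microdrop()] pad the substrate automatically.
#' @param droplet_volume Droplet volume in picolitres.
#' @param footprint_radius Radius (um) of the wetted spot a droplet dries
#'   into; fibres land uniformly within this disc.
#' @param placement_jitter_sd Gaussian positioning jitter (um, sd).
#' @return An object of class `droplet_grid`.
#' @export
droplet_grid <- function(n_x = 10, n_y = 10, step_x = 60, step_y = 60,
                         origin_x = NULL, origin_y = NULL,
                         droplet_volume = 180, footprint_radius = 30,
                         placement_jitter_sd = 1) {
  check_scalar_number(n_x, "n_x", min = 1)
  check_scalar_number(n_y, "n_y", min = 1)
  check_scalar_number(step_x, "step_x", min = 0, strict_min = TRUE)
  check_scalar_number(step_y, "step_y", min = 0, strict_min = TRUE)
  check_scalar_number(droplet_volume, "droplet_volume", min = 0, strict_min = TRUE)
  check_scalar_number(footprint_radius, "footprint_radius", min = 0, strict_min = TRUE)
  check_scalar_number(placement_jitter_sd, "placement_jitter_sd", min = 0)
  structure(
    list(
      n_x = as.integer(n_x), n_y = as.integer(n_y),
      step_x = step_x, step_y = step_y,
      origin_x = origin_x, origin_y = origin_y,
      droplet_volume = droplet_volume,
      footprint_radius = footprint_radius,
      placement_jitter_sd = placement_jitter_sd
    ),
    class = "droplet_grid"
  )
}

#' Stain-effect model for conventional drop deposition
#'
#' Minimal geometric realisation of the deposition of particles from a
#' sessile drop evaporating on a hydrophobic substrate: the contact area
#' shrinks at constant contact angle, dragging suspended fibres towards the
#' centre and aggregating them into bundles. Final radial positions follow
#' `r_final = R * (r/R)^(1 + compression_exponent)`; a fibre landing within
#' `bundle_capture_radius` of an earlier fibre joins its bundle and aligns to
#' it (Gaussian angular noise `bundle_alignment_sd`). An exponent of 0 with
#' zero capture radius reduces to uniform independent deposition.
#'
#' @param drop_radius_initial Initial drop contact radius (um).
#' @param compression_exponent Dimensionless radial contraction strength
#'   (>= 0; 0 = no stain effect).
#' @param bundle_capture_radius Centroid distance (um) within which a fibre is
#'   captured by an earlier-placed fibre's bundle.
#' @param bundle_alignment_sd Angular sd (radians) of captured-fibre
#'   orientations about the bundle orientation.
#' @return An object of class `stain_model`.
#' @export
stain_model <- function(drop_radius_initial = 500, compression_exponent = 2,
                        bundle_capture_radius = 5, bundle_alignment_sd = 0.2) {
  check_scalar_number(drop_radius_initial, "drop_radius_initial",
                      min = 0, strict_min = TRUE)
  check_scalar_number(compression_exponent, "compression_exponent", min = 0)
  check_scalar_number(bundle_capture_radius, "bundle_capture_radius", min = 0)
  check_scalar_number(bundle_alignment_sd, "bundle_alignment_sd", min = 0)
  structure(
    list(
      drop_radius_initial = drop_radius_initial,
      compression_exponent = compression_exponent,
      bundle_capture_radius = bundle_capture_radius,
      bundle_alignment_sd = bundle_alignment_sd
    ),
    class = "stain_model"
  )
}

new_deposition_field <- function(fibres, substrate_width, substrate_height,
                                 model_tag) {
  structure(
    list(
      fibres = fibres,
      substrate_width = substrate_width,
      substrate_height = substrate_height,
      model_tag = model_tag
    ),
    class = "deposition_field"
  )
}

#' @export
print.deposition_field <- function(x, ...) {
  cat(sprintf(
    "<deposition_field> %s model, %d fibres on %.0f x %.0f um substrate\n",
    x$model_tag, nrow(x$fibres), x$substrate_width, x$substrate_height
  ))
  invisible(x)
}

#' Deposit fibres as an inkjet micro-drop grid
#'
#' Places fibres droplet by droplet on a programmed X-Y grid: the number of
#' fibres per droplet is Poisson with mean `mean_fibres_per_droplet`, each
#' fibre lands uniformly within the droplet footprint disc plus Gaussian
#' stage jitter, and orientations are uniform on `[0, pi)`. Fibre geometries
#' are resampled (with replacement) from the supplied population.
#'
#' @param fibres Tibble from [sample_fibres()] (columns `length_um`,
#'   `width_um`); must be non-empty unless the rate is 0.
#' @param grid A [droplet_grid()].
#' @param mean_fibres_per_droplet Poisson mean per droplet (>= 0).
#' @param seed Optional integer seed.
#' @param avoid_overlap If `TRUE`, re-draw each fibre's position within its
#'   droplet (up to 200 attempts) until its capsule outline keeps at least
#'   `min_separation` clearance from all previously placed fibres; attempts
#'   exhausted leave the fibre at its last position with a warning attribute.
#' @param min_separation Clearance (um) used when `avoid_overlap = TRUE`.
#'
#' @return A `deposition_field`: fibre tibble (`id`, `length_um`, `width_um`,
#'   `x`, `y`, `orientation`, `bundle_id`, `droplet`) plus substrate extent
#'   and `model_tag = "microdrop"`.
#' @export
deposit_microdrop <- function(fibres, grid = droplet_grid(),
                              mean_fibres_per_droplet = 3, seed = NULL,
                              avoid_overlap = FALSE, min_separation = 1) {
  stopifnot(inherits(grid, "droplet_grid"))
  check_scalar_number(mean_fibres_per_droplet, "mean_fibres_per_droplet", min = 0)
  pad <- grid$footprint_radius + 4 * grid$placement_jitter_sd +
    (if (nrow(fibres)) max(fibres$length_um) / 2 else 0)
  origin_x <- grid$origin_x %||% pad
  origin_y <- grid$origin_y %||% pad
  width <- origin_x + (grid$n_x - 1) * grid$step_x + pad
  height <- origin_y + (grid$n_y - 1) * grid$step_y + pad

  centres <- expand.grid(ix = seq_len(grid$n_x), iy = seq_len(grid$n_y))
  cx <- origin_x + (centres$ix - 1) * grid$step_x
  cy <- origin_y + (centres$iy - 1) * grid$step_y
  n_drop <- length(cx)

  out <- with_seed_or_not(seed, {
    counts <- rpois(n_drop, mean_fibres_per_droplet)
    total <- sum(counts)
    if (total == 0) {
      placed <- tibble(
        id = integer(), length_um = numeric(), width_um = numeric(),
        x = numeric(), y = numeric(), orientation = numeric(),
        bundle_id = integer(), droplet = integer()
      )
    } else {
      if (nrow(fibres) == 0) {
        abort("`fibres` is empty but the Poisson draw requested fibres.")
      }
      pick <- sample.int(nrow(fibres), total, replace = TRUE)
      droplet <- rep.int(seq_len(n_drop), counts)
      place_one <- function(dc_x, dc_y) {
        r <- grid$footprint_radius * sqrt(runif(1))
        th <- runif(1, 0, 2 * pi)
        c(dc_x + r * cos(th) + rnorm(1, 0, grid$placement_jitter_sd),
          dc_y + r * sin(th) + rnorm(1, 0, grid$placement_jitter_sd))
      }
      xs <- ys <- numeric(total)
      ors <- runif(total, 0, pi)
      for (i in seq_len(total)) {
        d <- droplet[i]
        pos <- place_one(cx[d], cy[d])
        if (avoid_overlap && i > 1) {
          ok <- function(p) {
            s <- fibre_segment(p[1], p[2], fibres$length_um[pick[i]],
                               fibres$width_um[pick[i]], ors[i])
            for (j in seq_len(i - 1)) {
              # bounding prune
              if (sqrt((p[1] - xs[j])^2 + (p[2] - ys[j])^2) >
                  (fibres$length_um[pick[i]] + fibres$length_um[pick[j]]) / 2 +
                  min_separation + 1) next
              sj <- fibre_segment(xs[j], ys[j], fibres$length_um[pick[j]],
                                  fibres$width_um[pick[j]], ors[j])
              dmin <- segment_segment_distance(
                c(s$ax, s$ay), c(s$bx, s$by), c(sj$ax, sj$ay), c(sj$bx, sj$by)
              )
              if (dmin < (fibres$width_um[pick[i]] + fibres$width_um[pick[j]]) / 2 +
                  min_separation) return(FALSE)
            }
            TRUE
          }
          tries <- 0
          while (!ok(pos) && tries < 200) {
            pos <- place_one(cx[d], cy[d])
            tries <- tries + 1
          }
        }
        xs[i] <- pos[1]
        ys[i] <- pos[2]
      }
      placed <- tibble(
        id = seq_len(total),
        length_um = fibres$length_um[pick],
        width_um = fibres$width_um[pick],
        x = pmin(pmax(xs, 0), width),
        y = pmin(pmax(ys, 0), height),
        orientation = ors,
        bundle_id = seq_len(total),
        droplet = droplet
      )
    }
    placed
  })
  new_deposition_field(out, width, height, "microdrop")
}

#' Deposit fibres as a conventional evaporating drop
#'
#' Places all supplied fibres under the stain-effect model: initial positions
#' uniform in the drop contact disc, radial contraction
#' `r_final = R (r/R)^(1+gamma)` towards the drop centre, and sequential
#' bundle capture (a fibre landing within the capture radius of an
#' earlier-placed fibre joins that fibre's bundle and takes its orientation
#' plus Gaussian noise).
#'
#' @param fibres Tibble from [sample_fibres()].
#' @param stain A [stain_model()].
#' @param centre Drop centre (um pair); `NULL` centres the drop on a square
#'   substrate that just contains it.
#' @param seed Optional integer seed.
#' @return A `deposition_field` with `model_tag = "drop"`.
#' @export
deposit_drop <- function(fibres, stain = stain_model(), centre = NULL,
                         seed = NULL) {
  stopifnot(inherits(stain, "stain_model"))
  R <- stain$drop_radius_initial
  pad <- if (nrow(fibres)) max(fibres$length_um) / 2 else 0
  side <- 2 * (R + pad)
  centre <- centre %||% c(side / 2, side / 2)
  n <- nrow(fibres)
  out <- with_seed_or_not(seed, {
    r0 <- R * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    rf <- R * (r0 / R)^(1 + stain$compression_exponent)
    xs <- centre[1] + rf * cos(th)
    ys <- centre[2] + rf * sin(th)
    ors <- runif(n, 0, pi)
    bundle <- seq_len(n)
    if (stain$bundle_capture_radius > 0 && n > 1) {
      for (i in 2:n) {
        d2 <- (xs[seq_len(i - 1)] - xs[i])^2 + (ys[seq_len(i - 1)] - ys[i])^2
        j <- which.min(d2)
        if (sqrt(d2[j]) <= stain$bundle_capture_radius) {
          bundle[i] <- bundle[j]
          ors[i] <- (ors[bundle[i]] +
                       rnorm(1, 0, stain$bundle_alignment_sd)) %% pi
        }
      }
    }
    tibble(
      id = seq_len(n),
      length_um = fibres$length_um,
      width_um = fibres$width_um,
      x = pmin(pmax(xs, 0), side),
      y = pmin(pmax(ys, 0), side),
      orientation = ors,
      bundle_id = bundle,
      droplet = NA_integer_
    )
  })
  new_deposition_field(out, side, side, "drop")
}

#' Rendering parameters for synthetic micrographs
#'
#' @param pixel_size Calibration in micrometres per pixel.
#' @param psf_sigma Gaussian point-spread sd (um); 0 disables blurring.
#' @param background_level,foreground_level Intensities (native bit-depth
#'   units) of substrate and fibre material; foreground must exceed
#'   background.
#' @param noise_sd Additive Gaussian noise sd (intensity units).
#' @param bit_depth 8 or 16.
#' @return An object of class `render_params`.
#' @export
render_params <- function(pixel_size = 0.25, psf_sigma = 0,
                          background_level = 30, foreground_level = 200,
                          noise_sd = 0, bit_depth = 8) {
  check_scalar_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  check_scalar_number(psf_sigma, "psf_sigma", min = 0)
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  if (!bit_depth %in% c(8, 16)) abort("`bit_depth` must be 8 or 16.")
  if (foreground_level <= background_level) {
    abort("`foreground_level` must exceed `background_level`.")
  }
  maxval <- 2^bit_depth - 1
  if (background_level < 0 || foreground_level > maxval) {
    abort("intensity levels must lie within the bit-depth range.")
  }
  structure(
    list(
      pixel_size = pixel_size, psf_sigma = psf_sigma,
      background_level = background_level,
      foreground_level = foreground_level,
      noise_sd = noise_sd, bit_depth = bit_depth
    ),
    class = "render_params"
  )
}

# Rasterize one capsule (total length L, width W) into `img`, returning the
# modified matrix. Pixel (r, c) centre is at x = (c - 0.5) ps, y = (r - 0.5) ps.
rasterize_capsule <- function(img, x, y, length, width, orientation, ps,
                              value) {
  seg <- fibre_segment(x, y, length, width, orientation)
  radius <- max(width / 2, ps / 2)
  r0 <- max(1L, floor((min(seg$ay, seg$by) - radius) / ps - 1))
  r1 <- min(nrow(img), ceiling((max(seg$ay, seg$by) + radius) / ps + 1))
  c0 <- max(1L, floor((min(seg$ax, seg$bx) - radius) / ps - 1))
  c1 <- min(ncol(img), ceiling((max(seg$ax, seg$bx) + radius) / ps + 1))
  if (r0 > r1 || c0 > c1) return(img)
  rows <- r0:r1
  cols <- c0:c1
  py <- (rows - 0.5) * ps
  px <- (cols - 0.5) * ps
  gx <- rep(px, each = length(py))
  gy <- rep(py, times = length(px))
  d <- point_segment_distance(gx, gy, seg$ax, seg$ay, seg$bx, seg$by)
  hit <- d <= radius
  if (any(hit)) {
    idx <- cbind(
      rep(rows, times = length(cols))[hit],
      rep(cols, each = length(rows))[hit]
    )
    img[idx] <- value
  }
  img
}

# Connected clusters of overlapping fibres (capsule outlines intersect).
overlap_clusters <- function(fb) {
  n <- nrow(fb)
  if (n == 0) return(integer())
  parent <- uf_new(n)
  segs <- fibre_segment(fb$x, fb$y, fb$length_um, fb$width_um, fb$orientation)
  for (i in seq_len(n)) {
    if (i == 1) next
    for (j in seq_len(i - 1)) {
      if (sqrt((fb$x[i] - fb$x[j])^2 + (fb$y[i] - fb$y[j])^2) >
          (fb$length_um[i] + fb$length_um[j]) / 2 + 1) next
      dmin <- segment_segment_distance(
        c(segs$ax[i], segs$ay[i]), c(segs$bx[i], segs$by[i]),
        c(segs$ax[j], segs$ay[j]), c(segs$bx[j], segs$by[j])
      )
      if (dmin <= (fb$width_um[i] + fb$width_um[j]) / 2) {
        ri <- uf_find(parent, i)
        rj <- uf_find(parent, j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  match(roots, unique(roots))
}

#' Render a deposition field to a calibrated grayscale image
#'
#' Rasterizes each fibre as a capsule (rotated rectangle with semicircular
#' end-caps; total extent equal to the fibre length), applies a Gaussian
#' point-spread blur and additive Gaussian noise, and quantises to the
#' requested bit depth. The returned ground truth lists each fibre's true
#' geometry, its overlap cluster (fibres whose outlines touch share a
#' `cluster_id`) and whether it extends past the substrate edge
#' (`touches_border`; such fibres are clipped in the image but kept in the
#' truth table).
#'
#' @param field A `deposition_field`.
#' @param params A [render_params()].
#' @param seed Optional integer seed (noise only).
#' @return A list with elements `image` (a [raster_image()]) and
#'   `ground_truth` (tibble: `id`, `x`, `y`, `length_um`, `width_um`,
#'   `orientation_rad`, `bundle_id`, `cluster_id`, `touches_border`). Fibres
#'   narrower than one pixel are rendered one pixel wide and listed in the
#'   `"render_warnings"` attribute of the image.
#' @export
render_field <- function(field, params = render_params(), seed = NULL) {
  stopifnot(inherits(field, "deposition_field"))
  stopifnot(inherits(params, "render_params"))
  ps <- params$pixel_size
  nr <- max(1L, ceiling(field$substrate_height / ps))
  nc <- max(1L, ceiling(field$substrate_width / ps))
  img <- matrix(params$background_level, nr, nc)
  fb <- field$fibres
  warnings <- character()
  if (nrow(fb)) {
    for (i in seq_len(nrow(fb))) {
      if (fb$width_um[i] < ps) {
        warnings <- c(warnings, sprintf(
          "fibre %d: width %.3g um below pixel size %.3g um; rendered 1 px wide",
          fb$id[i], fb$width_um[i], ps
        ))
      }
      img <- rasterize_capsule(
        img, fb$x[i], fb$y[i], fb$length_um[i], fb$width_um[i],
        fb$orientation[i], ps, params$foreground_level
      )
    }
  }
  if (params$psf_sigma > 0) {
    img <- EBImage::imageData(EBImage::gblur(
      EBImage::Image(img), sigma = params$psf_sigma / ps,
      boundary = "replicate"
    ))
  }
  maxval <- 2^params$bit_depth - 1
  img <- with_seed_or_not(seed, {
    if (params$noise_sd > 0) img <- img + rnorm(length(img), 0, params$noise_sd)
    img
  })
  img <- round(pmin(pmax(img, 0), maxval))
  image <- raster_image(img, pixel_size = ps, bit_depth = params$bit_depth)
  attr(image, "render_warnings") <- warnings

  truth <- if (nrow(fb)) {
    half_l <- fb$length_um / 2
    tibble(
      id = fb$id, x = fb$x, y = fb$y,
      length_um = fb$length_um, width_um = fb$width_um,
      orientation_rad = fb$orientation, bundle_id = fb$bundle_id,
      cluster_id = overlap_clusters(fb),
      touches_border =
        fb$x - half_l < 0 | fb$x + half_l > field$substrate_width |
        fb$y - half_l < 0 | fb$y + half_l > field$substrate_height
    )
  } else {
    tibble(
      id = integer(), x = numeric(), y = numeric(), length_um = numeric(),
      width_um = numeric(), orientation_rad = numeric(),
      bundle_id = integer(), cluster_id = integer(), touches_border = logical()
    )
  }
  list(image = image, ground_truth = truth)
}
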