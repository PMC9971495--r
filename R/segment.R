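#' Calibrated grayscale raster image
#'
#' @param pixels Numeric matrix of intensities (rows = y, columns = x).
#' @param pixel_size Calibration in micrometres per pixel.
#' @param bit_depth 8 or 16; intensities must lie in `[0, 2^bit_depth - 1]`.
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(pixels, pixel_size, bit_depth = 8) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.")
  }
  check_scalar_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  if (!bit_depth %in% c(8, 16)) abort("`bit_depth` must be 8 or 16.")
  if (min(pixels) < 0 || max(pixels) > 2^bit_depth - 1) {
    abort("intensities outside the bit-depth range.")
  }
  structure(
    list(pixels = pixels, pixel_size = pixel_size, bit_depth = bit_depth),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf(
    "<raster_image> %d x %d px, %g um/px, %d-bit, range [%g, %g]\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$bit_depth,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' Binary foreground mask
#'
#' @param pixels Logical matrix (TRUE = foreground).
#' @param pixel_size Micrometres per pixel.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, pixel_size) {
  if (!is.matrix(pixels) || !is.logical(pixels)) {
    abort("`pixels` must be a logical matrix.")
  }
  check_scalar_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  structure(
    list(pixels = pixels, pixel_size = pixel_size),
    class = "binary_mask"
  )
}

#' Smooth a grayscale image
#'
#' Gaussian smoothing with a physical-scale bandwidth: the kernel sd is
#' `smooth_sigma / pixel_size` pixels, so the same `smooth_sigma` denoises
#' comparably across magnifications. `smooth_sigma = 0` returns the input
#' unchanged.
#'
#' @param image A [raster_image()].
#' @param smooth_sigma Gaussian sd in micrometres (>= 0).
#' @return A [raster_image()] of the same shape and calibration.
#' @export
preprocess <- function(image, smooth_sigma = 0.5) {
  stopifnot(inherits(image, "raster_image"))
  check_scalar_number(smooth_sigma, "smooth_sigma", min = 0)
  if (smooth_sigma == 0) return(image)
  px <- EBImage::imageData(EBImage::gblur(
    EBImage::Image(image$pixels), sigma = smooth_sigma / image$pixel_size,
    boundary = "replicate"
  ))
  px <- pmin(pmax(px, 0), 2^image$bit_depth - 1)
  raster_image(px, image$pixel_size, image$bit_depth)
}

#' Binarize a grayscale image
#'
#' Bright-objects-on-dark-background convention. `method = "otsu"` picks the
#' threshold maximising between-class variance over the image histogram
#' (foreground = intensities strictly above it); `method = "fixed"` keeps the
#' intensities inside a user-supplied closed range, mirroring a manually
#' chosen thresholding band.
#'
#' @param image A [raster_image()].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold_range Intensity pair `c(lo, hi)`; required for
#'   `method = "fixed"`.
#' @return A [binary_mask()]; the threshold actually used is stored in the
#'   `"threshold"` attribute.
#' @export
binarize <- function(image, method = c("otsu", "fixed"),
                     threshold_range = NULL) {
  stopifnot(inherits(image, "raster_image"))
  method <- match.arg(method)
  maxval <- 2^image$bit_depth - 1
  if (method == "fixed") {
    if (is.null(threshold_range)) {
      abort("`threshold_range` must be supplied for method = \"fixed\".")
    }
    if (length(threshold_range) != 2 || threshold_range[1] > threshold_range[2]) {
      abort("`threshold_range` must be c(lo, hi) with lo <= hi.")
    }
    fg <- image$pixels >= threshold_range[1] & image$pixels <= threshold_range[2]
    thr <- threshold_range
  } else {
    thr <- EBImage::otsu(
      EBImage::Image(image$pixels / maxval),
      range = c(0, 1), levels = 2^image$bit_depth
    ) * maxval
    fg <- image$pixels > thr
  }
  out <- binary_mask(fg, image$pixel_size)
  attr(out, "threshold") <- thr
  out
}

# Linear indices of foreground neighbours under 4- or 8-connectivity,
# returned as a 2-column matrix of index pairs (each pair once).
mask_adjacency <- function(mask, connectivity) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(matrix(integer(), 0, 2))
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
  pairs <- lapply(shifts, function(s) {
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    r2 <- r + s[1]
    c2 <- c + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- mask[j]
    cbind(idx[ok][keep], j[keep])
  })
  do.call(rbind, pairs)
}

# Label foreground pixels of a logical matrix; returns an integer matrix with
# labels 1..k in first-pixel (column-major) order.
label_components <- function(mask, connectivity = 8) {
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0) return(lab)
  edges <- mask_adjacency(mask, connectivity)
  g <- igraph::graph_from_edgelist(
    matrix(match(as.vector(edges), idx), ncol = 2), directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  # relabel so labels appear in scan order
  first <- vapply(split(seq_along(idx), comp), min, integer(1))
  relab <- integer(length(first))
  relab[order(first)] <- seq_along(first)
  lab[idx] <- relab[comp]
  lab
}

#' Label connected foreground objects
#'
#' Connected-component labeling of a binary mask under 4- or 8-connectivity,
#' with small-object suppression and an explicit policy for objects touching
#' the image border. Surviving objects are relabeled consecutively
#' `1..n_objects` in scan order.
#'
#' @param mask A [binary_mask()].
#' @param connectivity 4 or 8 (default 8: diagonally touching thin fibres
#'   stay one object).
#' @param min_pixels Minimum component size in pixels (default 4, suppressing
#'   single-pixel noise while keeping the sub-2-um particle class).
#' @param border_policy `"flag"` (keep and mark, default), `"keep"`, or
#'   `"drop"` objects touching the image border.
#' @return An object of class `label_map`: integer `pixels` matrix
#'   (0 = background), `n_objects`, `pixel_size`, and an `objects` tibble
#'   (`label`, `n_pixels`, `touches_border`).
#' @export
label_objects <- function(mask, connectivity = 8, min_pixels = 4,
                          border_policy = c("flag", "keep", "drop")) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  check_scalar_number(min_pixels, "min_pixels", min = 1)
  border_policy <- match.arg(border_policy)
  lab <- label_components(mask$pixels, connectivity)
  n0 <- max(lab)
  if (n0 > 0) {
    sizes <- tabulate(lab[lab > 0L], nbins = n0)
    nr <- nrow(lab)
    nc <- ncol(lab)
    border_labels <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
    border_labels <- border_labels[border_labels > 0L]
    keep <- sizes >= min_pixels
    if (border_policy == "drop") keep[border_labels] <- FALSE
    relab <- integer(n0)
    relab[keep] <- seq_len(sum(keep))
    lab[lab > 0L] <- relab[lab[lab > 0L]]
    objects <- tibble(
      label = seq_len(sum(keep)),
      n_pixels = sizes[keep],
      touches_border = if (border_policy == "keep") {
        FALSE
      } else {
        which(keep) %in% border_labels
      }
    )
  } else {
    objects <- tibble(
      label = integer(), n_pixels = integer(), touches_border = logical()
    )
  }
  structure(
    list(
      pixels = lab, n_objects = nrow(objects),
      pixel_size = mask$pixel_size, objects = objects
    ),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf(
    "<label_map> %d objects in %d x %d px (%g um/px)\n",
    x$n_objects, nrow(x$pixels), ncol(x$pixels), x$pixel_size
  ))
  invisible(x)
}
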