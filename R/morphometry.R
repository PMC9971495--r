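# Minimum-area enclosing rectangle of a 2-D point set, by rotating calipers:
# the optimal rectangle has a side collinear with a convex-hull edge, so it
# suffices to test each hull-edge direction. Returns sides (long, short) and
# the angle (radians) of the long side.
min_area_rect <- function(x, y) {
  if (length(x) == 1) {
    return(list(length = 0, width = 0, angle = 0))
  }
  h <- grDevices::chull(x, y)
  hx <- x[h]
  hy <- y[h]
  k <- length(hx)
  if (k == 1) return(list(length = 0, width = 0, angle = 0))
  if (k == 2) {
    d <- sqrt(diff(hx)^2 + diff(hy)^2)
    return(list(
      length = d, width = 0,
      angle = atan2(hy[2] - hy[1], hx[2] - hx[1]) %% pi
    ))
  }
  ex <- c(diff(hx), hx[1] - hx[k])
  ey <- c(diff(hy), hy[1] - hy[k])
  angles <- unique(atan2(ey, ex) %% (pi / 2))
  best <- NULL
  for (a in angles) {
    ca <- cos(a)
    sa <- sin(a)
    u <- hx * ca + hy * sa
    v <- -hx * sa + hy * ca
    du <- max(u) - min(u)
    dv <- max(v) - min(v)
    area <- du * dv
    if (is.null(best) || area < best$area) {
      long_along_u <- du >= dv
      best <- list(
        area = area,
        length = max(du, dv),
        width = min(du, dv),
        angle = if (long_along_u) a %% pi else (a + pi / 2) %% pi
      )
    }
  }
  list(length = best$length, width = best$width, angle = best$angle)
}

# Corner points (pixel-square vertices) of a set of pixels given by row/col.
pixel_corners <- function(rows, cols, ps) {
  xc <- (cols - 0.5) * ps
  yc <- (rows - 0.5) * ps
  h <- ps / 2
  list(
    x = c(xc - h, xc + h, xc - h, xc + h),
    y = c(yc - h, yc - h, yc + h, yc + h)
  )
}

#' Measure per-object morphometry
#'
#' Computes, for every labeled object, its area (pixel count times the pixel
#' area), the minimum-area enclosing rectangle of its pixel-corner convex
#' hull, the rectangle's longer and shorter sides as length and width, and
#' the elongation factor EF = length / width (the length/diameter ratio used
#' to demarcate fibrous particles at EF > 3). Objects shorter than 2 um are
#' flagged `small_class`, mirroring the practice of pooling particles that
#' cannot be discriminated from background into one class.
#'
#' @param labels A [label_objects()] result.
#' @param length_definition `"side"` (default; length = longer rectangle
#'   side) or `"diagonal"` (length = rectangle diagonal).
#' @return A tibble (one row per object): `object_id`, `area_um2`,
#'   `length_um`, `width_um`, `ef`, `orientation_rad`, `centroid_x_um`,
#'   `centroid_y_um`, `touches_border`, `small_class`. Attributes:
#'   `pixel_size` (um/px) and `imaged_area_mm2`.
#' @export
measure_objects <- function(labels, length_definition = c("side", "diagonal")) {
  stopifnot(inherits(labels, "label_map"))
  length_definition <- match.arg(length_definition)
  ps <- labels$pixel_size
  lab <- labels$pixels
  n <- labels$n_objects
  res <- vector("list", n)
  if (n > 0) {
    idx <- which(lab > 0L)
    by_obj <- split(idx, lab[idx])
    nr <- nrow(lab)
    for (i in seq_len(n)) {
      px <- by_obj[[as.character(i)]]
      rows <- ((px - 1L) %% nr) + 1L
      cols <- ((px - 1L) %/% nr) + 1L
      corners <- pixel_corners(rows, cols, ps)
      rect <- min_area_rect(corners$x, corners$y)
      len <- rect$length
      wid <- max(rect$width, ps)  # degenerate 1-px-thin objects
      if (length_definition == "diagonal") len <- sqrt(len^2 + wid^2)
      len <- max(len, ps)
      res[[i]] <- tibble(
        object_id = i,
        area_um2 = length(px) * ps^2,
        length_um = len,
        width_um = wid,
        ef = len / wid,
        orientation_rad = rect$angle,
        centroid_x_um = mean((cols - 0.5) * ps),
        centroid_y_um = mean((rows - 0.5) * ps),
        touches_border = labels$objects$touches_border[i]
      )
    }
  }
  out <- if (n > 0) bind_rows(res) else tibble(
    object_id = integer(), area_um2 = numeric(), length_um = numeric(),
    width_um = numeric(), ef = numeric(), orientation_rad = numeric(),
    centroid_x_um = numeric(), centroid_y_um = numeric(),
    touches_border = logical()
  )
  out$small_class <- out$length_um < 2
  attr(out, "pixel_size") <- ps
  attr(out, "imaged_area_mm2") <-
    nrow(labels$pixels) * ncol(labels$pixels) * ps^2 / 1e6
  class(out) <- c("object_table", class(out))
  out
}

#' Foreground coverage of a mask
#'
#' @param mask A [binary_mask()].
#' @return Percentage of image pixels that are foreground.
#' @export
coverage_fraction <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  100 * sum(mask$pixels) / length(mask$pixels)
}
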