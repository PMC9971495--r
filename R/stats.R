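#' Classification scheme for object histograms
#'
#' Defines ordered class bins for a morphometric variable with open-ended
#' extreme classes: interior bins are half-open `[lo, hi)`, the first class
#' is everything below the first edge and the last everything at or above
#' the last edge.
#'
#' @param variable One of `"ef"`, `"area"`, `"length"`, `"fibre_length"`.
#' @param edges Strictly increasing numeric vector of interior edges.
#' @param labels Optional class labels; defaults to `"<e1"`,
#'   `"e1-e2"`, ..., `">ek"`.
#' @return An object of class `class_scheme`.
#' @export
#' @examples
#' class_scheme("ef", c(1.8, 2.2, 2.6, 3))
class_scheme <- function(variable = c("ef", "area", "length", "fibre_length"),
                         edges, labels = NULL) {
  variable <- match.arg(variable)
  if (!is.numeric(edges) || length(edges) < 1 || is.unsorted(edges, strictly = TRUE)) {
    abort("`edges` must be strictly increasing numbers.")
  }
  k <- length(edges)
  if (is.null(labels)) {
    labels <- c(
      paste0("<", edges[1]),
      if (k > 1) paste0(edges[-k], "-", edges[-1]),
      paste0(">", edges[k])
    )
  }
  if (length(labels) != k + 1) {
    abort("`labels` must have length(edges) + 1 entries.")
  }
  structure(
    list(variable = variable, edges = edges, labels = labels),
    class = "class_scheme"
  )
}

#' Built-in class schemes
#'
#' The elongation-factor, area and length class boundaries used throughout
#' the reporting tables: EF classes `<1.8, 1.8-2.2, 2.2-2.6, 2.6-3, >3`
#' (the last containing fibrous particles), area classes
#' `<2, 2-5, 5-10, 10-15, 15-20, >20` um^2, and length classes
#' `0-2, 2-3, 3-4, 4-5, >5` um (the first pooling the sub-2-um particles).
#'
#' @return A `class_scheme`.
#' @export
scheme_ef <- function() class_scheme("ef", c(1.8, 2.2, 2.6, 3))

#' @rdname scheme_ef
#' @export
scheme_area <- function() class_scheme("area", c(2, 5, 10, 15, 20))

#' @rdname scheme_ef
#' @export
scheme_length <- function() {
  class_scheme("length", c(2, 3, 4, 5),
               labels = c("0-2", "2-3", "3-4", "4-5", ">5"))
}

#' Class histogram with per-square-millimetre normalisation
#'
#' Bins values into the scheme's classes (half-open `[lo, hi)` interior
#' bins, open extremes), normalises counts to 1 mm^2 of inspected area and
#' accumulates running percentages.
#'
#' @param values Numeric vector of per-object values (EF, area, length...).
#' @param scheme A [class_scheme()].
#' @param imaged_area Inspected area in mm^2 (> 0).
#' @return A tibble of class `class_histogram`: `class`, `count`, `per_mm2`,
#'   `cumulative_pct` (NA throughout when `values` is empty). The scheme and
#'   area are kept as attributes.
#' @export
#' @examples
#' histogram_by_class(c(1.5, 2.0, 2.4, 3.5), scheme_ef(), imaged_area = 1)
histogram_by_class <- function(values, scheme, imaged_area) {
  stopifnot(inherits(scheme, "class_scheme"))
  check_scalar_number(imaged_area, "imaged_area", min = 0, strict_min = TRUE)
  if (anyNA(values)) abort("`values` must not contain NA.")
  counts <- as.integer(
    tabulate(findInterval(values, scheme$edges) + 1L,
             nbins = length(scheme$edges) + 1L)
  )
  total <- sum(counts)
  out <- tibble(
    class = scheme$labels,
    count = counts,
    per_mm2 = counts / imaged_area,
    cumulative_pct = if (total > 0) 100 * cumsum(counts) / total else
      rep(NA_real_, length(counts))
  )
  attr(out, "scheme") <- scheme
  attr(out, "imaged_area_mm2") <- imaged_area
  class(out) <- c("class_histogram", class(out))
  out
}

#' Batch summary of per-image counts and coverage
#'
#' Aggregates per-image object counts (and optionally coverages and areas)
#' into the homogeneity summary used to compare deposition methods: the
#' arithmetic mean, the relative standard deviation (population SD, divisor
#' n, over the mean), totals, and an objects-per-mm^2 density when per-image
#' areas are supplied. `rsd_count_report` follows the summary-table
#' convention of dividing the SD by the integer-rounded mean (see the
#' package vignette); `rsd_count` is the exact value.
#'
#' @param per_image_counts Integer vector of object counts, one per image.
#' @param per_image_coverage Optional per-image coverage percentages.
#' @param per_image_area Optional per-image inspected areas (mm^2).
#' @return An object of class `batch_summary` with a `per_image` tibble and
#'   scalar fields `n_images`, `mean_count`, `rsd_count`, `rsd_count_report`,
#'   `total_count`, `mean_coverage`, `rsd_coverage`, `density_per_mm2`.
#'   RSDs are `NA` (flagged) when the mean is zero.
#' @export
batch_summary <- function(per_image_counts, per_image_coverage = NULL,
                          per_image_area = NULL) {
  if (length(per_image_counts) < 1) abort("need at least one image.")
  n <- length(per_image_counts)
  for (arg in list(per_image_coverage, per_image_area)) {
    if (!is.null(arg) && length(arg) != n) {
      abort("per-image vectors must have equal length.")
    }
  }
  m <- mean(per_image_counts)
  rsd <- pop_rsd(per_image_counts)
  rsd_report <- if (m == 0) NA_real_ else
    100 * pop_sd(per_image_counts) / round(m)
  structure(
    list(
      per_image = tibble(
        image = seq_len(n),
        count = per_image_counts,
        coverage_pct = per_image_coverage %||% rep(NA_real_, n),
        area_mm2 = per_image_area %||% rep(NA_real_, n)
      ),
      n_images = n,
      mean_count = m,
      rsd_count = rsd,
      rsd_count_report = rsd_report,
      total_count = sum(per_image_counts),
      mean_coverage = if (is.null(per_image_coverage)) NA_real_ else
        mean(per_image_coverage),
      rsd_coverage = if (is.null(per_image_coverage)) NA_real_ else
        pop_rsd(per_image_coverage),
      density_per_mm2 = if (is.null(per_image_area)) NA_real_ else
        sum(per_image_counts) / sum(per_image_area)
    ),
    class = "batch_summary"
  )
}

#' @export
print.batch_summary <- function(x, ...) {
  cat(sprintf(
    "<batch_summary> %d images | mean %d objects (RSD %s%%) | total %d%s%s\n",
    x$n_images, round(x$mean_count),
    ifelse(is.na(x$rsd_count_report), "NA", round(x$rsd_count_report)),
    x$total_count,
    if (!is.na(x$mean_coverage)) {
      sprintf(" | coverage %.1f%%", x$mean_coverage)
    } else "",
    if (!is.na(x$density_per_mm2)) {
      sprintf(" | %d objects/mm^2", round(x$density_per_mm2))
    } else ""
  ))
  invisible(x)
}

#' Object or fibre density per square millimetre
#'
#' @param total_count Total number of objects or fibres.
#' @param total_area Total inspected area in mm^2 (> 0).
#' @return Objects per mm^2 (full precision; report tables round to
#'   integers).
#' @export
#' @examples
#' fibre_density(330, 3.59)
fibre_density <- function(total_count, total_area) {
  check_scalar_number(total_count, "total_count", min = 0)
  check_scalar_number(total_area, "total_area", min = 0, strict_min = TRUE)
  total_count / total_area
}

#' Tile-wise homogeneity of a deposition
#'
#' Grids the substrate (or image) into square tiles, counts objects per tile
#' by centroid, and returns the population relative standard deviation of
#' the per-tile counts: 0% for a perfectly even deposition, growing as the
#' deposition concentrates. Partial tiles at the right/bottom edge are
#' discarded so all tiles have equal area.
#'
#' @param x A `deposition_field` or an `object_table` from
#'   [measure_objects()].
#' @param tile_size Tile side in micrometres.
#' @return RSD (%) of per-tile counts, with the per-tile counts in the
#'   `"tile_counts"` attribute.
#' @export
tile_homogeneity <- function(x, tile_size) {
  check_scalar_number(tile_size, "tile_size", min = 0, strict_min = TRUE)
  if (inherits(x, "deposition_field")) {
    cx <- x$fibres$x
    cy <- x$fibres$y
    w <- x$substrate_width
    h <- x$substrate_height
  } else if (inherits(x, "object_table")) {
    cx <- x$centroid_x_um
    cy <- x$centroid_y_um
    area <- attr(x, "imaged_area_mm2") * 1e6
    ps <- attr(x, "pixel_size")
    # object_table stores total area; recover extent assuming the recorded
    # image dimensions (area = w * h not separable) -> use bounding square
    w <- h <- sqrt(area)
  } else {
    abort("`x` must be a deposition_field or object_table.")
  }
  nx <- floor(w / tile_size)
  ny <- floor(h / tile_size)
  if (nx * ny < 2) abort("`tile_size` leaves fewer than 2 tiles.")
  ix <- floor(cx / tile_size)
  iy <- floor(cy / tile_size)
  inside <- ix < nx & iy < ny & ix >= 0 & iy >= 0
  counts <- tabulate(iy[inside] * nx + ix[inside] + 1L, nbins = nx * ny)
  out <- pop_rsd(counts)
  attr(out, "tile_counts") <- counts
  out
}
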