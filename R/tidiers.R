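#' Tidy a class histogram
#'
#' @param x A `class_histogram`.
#' @param ... Unused.
#' @return A plain tibble: `class`, `count`, `per_mm2`, `cumulative_pct`.
#' @method tidy class_histogram
#' @export
tidy.class_histogram <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' Tidy / glance a batch summary
#'
#' `tidy()` returns the per-image table; `glance()` the one-row summary
#' (mean, exact and report-convention RSD, totals, coverage, density).
#'
#' @param x A `batch_summary`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy batch_summary
#' @export
tidy.batch_summary <- function(x, ...) x$per_image

#' @rdname tidy.batch_summary
#' @method glance batch_summary
#' @export
glance.batch_summary <- function(x, ...) {
  tibble(
    n_images = x$n_images,
    mean_count = x$mean_count,
    rsd_count = x$rsd_count,
    rsd_count_report = x$rsd_count_report,
    total_count = x$total_count,
    mean_coverage = x$mean_coverage,
    rsd_coverage = x$rsd_coverage,
    density_per_mm2 = x$density_per_mm2
  )
}

#' Tidy / glance a fibre-counting result
#'
#' `tidy()` returns one row per accepted fibre; `glance()` the counting
#' summary with the rejection tally.
#'
#' @param x A `counting_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy counting_result
#' @export
tidy.counting_result <- function(x, ...) x$fibres

#' @rdname tidy.counting_result
#' @method glance counting_result
#' @export
glance.counting_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble(
      n_fibres = x$n_fibres,
      inspected_area_mm2 = x$inspected_area_mm2,
      fibres_per_mm2 = x$fibres_per_mm2,
      n_candidates = x$n_candidates
    ),
    as_tibble(as.list(setNames(
      as.integer(x$rejected), paste0("rejected_", names(x$rejected))
    )))
  )
}

#' Tidy a deposition field
#'
#' @param x A `deposition_field`.
#' @param ... Unused.
#' @return The fibre tibble (`id`, `length_um`, `width_um`, `x`, `y`,
#'   `orientation`, `bundle_id`, `droplet`).
#' @method tidy deposition_field
#' @export
tidy.deposition_field <- function(x, ...) x$fibres

#' @rdname tidy.deposition_field
#' @method glance deposition_field
#' @export
glance.deposition_field <- function(x, ...) {
  tibble(
    model = x$model_tag,
    n_fibres = nrow(x$fibres),
    n_bundles = dplyr::n_distinct(x$fibres$bundle_id),
    substrate_width_um = x$substrate_width,
    substrate_height_um = x$substrate_height
  )
}

#' Tidy a comparison report
#'
#' @param x A `comparison_report`.
#' @param ... Unused.
#' @return One row per method with the headline statistics.
#' @method tidy comparison_report
#' @export
tidy.comparison_report <- function(x, ...) {
  bind_rows(lapply(names(x$per_method), function(m) {
    pm <- x$per_method[[m]]
    dplyr::bind_cols(
      tibble(method = m),
      glance(pm$summary),
      tibble(
        niosh_fibres = pm$n_fibres,
        fibre_density_per_mm2 = pm$fibre_density_per_mm2,
        tile_rsd = pm$tile_rsd
      )
    )
  }))
}

#' @rdname tidy.comparison_report
#' @method glance comparison_report
#' @export
glance.comparison_report <- function(x, ...) {
  if (is.null(x$ratios)) {
    tibble(mean_count_ratio = NA_real_, density_ratio = NA_real_,
           tile_rsd_ratio = NA_real_)
  } else {
    x$ratios
  }
}
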