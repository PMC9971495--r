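#' Write a calibrated image as TIFF with a JSON sidecar
#'
#' The grayscale image is written as a single-channel TIFF at its native bit
#' depth; the pixel-size calibration and bit depth go into `<path>.json`, so
#' the calibration travels with the file.
#'
#' @param image A [raster_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(image, path) {
  stopifnot(inherits(image, "raster_image"))
  maxval <- 2^image$bit_depth - 1
  tiff::writeTIFF(
    image$pixels / maxval, path,
    bits.per.sample = image$bit_depth, compression = "none"
  )
  jsonlite::write_json(
    list(pixel_size_um = image$pixel_size, bit_depth = image$bit_depth),
    paste0(path, ".json"),
    auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a calibrated image from TIFF or PNG
#'
#' @param path Image path (`.tif`/`.tiff`/`.png`).
#' @param pixel_size Micrometres per pixel; taken from the `<path>.json`
#'   sidecar when `NULL`. An error is raised when neither is available.
#' @param bit_depth Intensity quantisation; sidecar value wins.
#' @return A [raster_image()].
#' @export
read_raster <- function(path, pixel_size = NULL, bit_depth = 8) {
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    pixel_size <- pixel_size %||% meta$pixel_size_um
    bit_depth <- meta$bit_depth %||% bit_depth
  }
  if (is.null(pixel_size)) {
    abort("no pixel size: supply `pixel_size` or a JSON sidecar.")
  }
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("reading PNG requires the png package.")
    }
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(px)) == 3) px <- px[, , 1]  # first channel of RGB(A)
  raster_image(round(px * (2^bit_depth - 1)), pixel_size, bit_depth)
}

#' Write an object table to CSV
#'
#' @param objects An `object_table` from [measure_objects()].
#' @param path Output CSV path.
#' @param image_id Identifier recorded in the `image_id` column.
#' @return `path`, invisibly.
#' @export
write_object_table <- function(objects, path, image_id = "image") {
  out <- dplyr::bind_cols(tibble(image_id = image_id), as_tibble(objects))
  readr::write_csv(out, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the parameters of every stage (simulation, rendering,
#' segmentation, fibre counting) plus the master seed. All per-image seeds
#' are derived deterministically from `seed`, so a rerun with the same
#' configuration is byte-identical.
#'
#' @param seed Master integer seed.
#' @param n_images Simulated images per method.
#' @param n_fibres Fibre population size available to each drop deposition.
#' @param length_range,width_range Fibre dimension ranges (um).
#' @param stain A [stain_model()] for the drop method.
#' @param grid A [droplet_grid()] for the micro-drop method.
#' @param mean_fibres_per_droplet Poisson mean per droplet.
#' @param render A [render_params()].
#' @param smooth_sigma Preprocessing Gaussian sd (um).
#' @param threshold_method,threshold_range Passed to [binarize()].
#' @param connectivity,min_pixels,border_policy Passed to [label_objects()].
#' @param niosh A [niosh_params()].
#' @param tile_size Tile side (um) for [tile_homogeneity()].
#' @param out_dir Output directory for CSV/JSON artifacts (`NULL` = none).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_images = 3, n_fibres = 300,
                            length_range = c(5, 15), width_range = c(0.3, 1),
                            stain = stain_model(),
                            grid = droplet_grid(),
                            mean_fibres_per_droplet = 3,
                            render = render_params(psf_sigma = 0.3,
                                                   noise_sd = 5),
                            smooth_sigma = 0.3,
                            threshold_method = "otsu", threshold_range = NULL,
                            connectivity = 8, min_pixels = 4,
                            border_policy = "flag",
                            niosh = niosh_params(),
                            tile_size = 60,
                            out_dir = NULL) {
  check_scalar_number(seed, "seed")
  check_scalar_number(n_images, "n_images", min = 1)
  check_range(length_range, "length_range")
  check_range(width_range, "width_range")
  cfg <- structure(
    list(
      seed = as.integer(seed), n_images = as.integer(n_images),
      n_fibres = n_fibres, length_range = length_range,
      width_range = width_range, stain = stain, grid = grid,
      mean_fibres_per_droplet = mean_fibres_per_droplet, render = render,
      smooth_sigma = smooth_sigma, threshold_method = threshold_method,
      threshold_range = threshold_range, connectivity = connectivity,
      min_pixels = min_pixels, border_policy = border_policy,
      niosh = niosh, tile_size = tile_size, out_dir = out_dir
    ),
    class = "pipeline_config"
  )
  cfg
}

analyse_image <- function(image, cfg, image_id) {
  sm <- preprocess(image, cfg$smooth_sigma)
  mask <- binarize(sm, method = cfg$threshold_method,
                   threshold_range = cfg$threshold_range)
  labels <- label_objects(mask, connectivity = cfg$connectivity,
                          min_pixels = cfg$min_pixels,
                          border_policy = cfg$border_policy)
  objects <- measure_objects(labels)
  counting <- count_fibres(labels, cfg$niosh)
  list(
    image_id = image_id,
    mask = mask,
    labels = labels,
    objects = objects,
    coverage = coverage_fraction(mask),
    counting = counting,
    threshold = attr(mask, "threshold")
  )
}

simulate_method_image <- function(method, cfg, img_seed) {
  if (method == "drop") {
    fibres <- sample_fibres(cfg$n_fibres, cfg$length_range, cfg$width_range,
                            seed = img_seed)
    field <- deposit_drop(fibres, cfg$stain, seed = img_seed + 1L)
  } else {
    fibres <- sample_fibres(cfg$n_fibres, cfg$length_range, cfg$width_range,
                            seed = img_seed)
    field <- deposit_microdrop(fibres, cfg$grid,
                               cfg$mean_fibres_per_droplet,
                               seed = img_seed + 1L)
  }
  rendered <- render_field(field, cfg$render, seed = img_seed + 2L)
  list(field = field, image = rendered$image,
       ground_truth = rendered$ground_truth)
}

#' Run the full drop vs micro-drop comparison pipeline
#'
#' For each deposition method, simulates (or loads) images, runs
#' segmentation, morphometry, class statistics and NIOSH counting, and
#' aggregates a comparison report: per-method batch summaries, EF/area/
#' length class histograms, fibre counting results, tile-homogeneity RSDs,
#' and (when both methods are present) the mean-count and fibre-density
#' ratios. With `out_dir` set, writes `summary.csv`,
#' `classes_<variable>_<method>.csv`, `fibres_<method>.csv`,
#' `counting_summary.json` and `run_log.json` (package version, config
#' hash, and the defaults actually used).
#'
#' @param config A [pipeline_config()].
#' @param images Optional named list (`drop`, `microdrop`) of image file
#'   paths to analyse instead of simulating; files that fail to read are
#'   skipped with a warning and logged.
#' @param methods Which methods to run.
#' @return An object of class `comparison_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), images = NULL,
                         methods = c("drop", "microdrop")) {
  stopifnot(inherits(config, "pipeline_config"))
  methods <- match.arg(methods, several.ok = TRUE)
  per_method <- list()
  failures <- character()
  for (m in methods) {
    results <- list()
    fields <- list()
    if (!is.null(images)) {
      paths <- images[[m]]
      if (is.null(paths)) next
      for (i in seq_along(paths)) {
        img <- tryCatch(read_raster(paths[i]), error = function(e) e)
        if (inherits(img, "error")) {
          warn(sprintf("skipping unreadable image %s: %s", paths[i],
                       conditionMessage(img)))
          failures <- c(failures, paths[i])
          next
        }
        results[[length(results) + 1L]] <-
          analyse_image(img, config, basename(paths[i]))
      }
    } else {
      for (i in seq_len(config$n_images)) {
        img_seed <- config$seed * 1000L + 10L * i +
          if (m == "drop") 0L else 5L
        sim <- simulate_method_image(m, config, img_seed)
        fields[[i]] <- sim$field
        results[[i]] <- analyse_image(sim$image, config,
                                      sprintf("%s_%02d", m, i))
      }
    }
    if (length(results) == 0) next
    counts <- vapply(results, function(r) nrow(r$objects), integer(1))
    coverage <- vapply(results, function(r) r$coverage, numeric(1))
    areas <- vapply(results, function(r) attr(r$objects, "imaged_area_mm2"),
                    numeric(1))
    all_objects <- bind_rows(lapply(results, function(r) {
      dplyr::bind_cols(tibble(image_id = r$image_id), as_tibble(r$objects))
    }))
    total_area <- sum(areas)
    histograms <- list(
      ef = histogram_by_class(all_objects$ef, scheme_ef(), total_area),
      area = histogram_by_class(all_objects$area_um2, scheme_area(),
                                total_area),
      length = histogram_by_class(all_objects$length_um, scheme_length(),
                                  total_area)
    )
    n_fibres <- sum(vapply(results, function(r) r$counting$n_fibres,
                           integer(1)))
    fibres <- bind_rows(lapply(results, function(r) {
      if (nrow(r$counting$fibres) == 0) return(r$counting$fibres)
      dplyr::bind_cols(tibble(image_id = r$image_id), r$counting$fibres)
    }))
    rejected <- Reduce(`+`, lapply(results, function(r) r$counting$rejected))
    tile_rsd <- if (length(fields)) {
      mean(vapply(fields, function(f) {
        as.numeric(tile_homogeneity(f, config$tile_size))
      }, numeric(1)))
    } else NA_real_
    per_method[[m]] <- list(
      summary = batch_summary(counts, coverage, areas),
      histograms = histograms,
      fibres = fibres,
      n_fibres = n_fibres,
      fibre_density_per_mm2 = fibre_density(n_fibres, total_area),
      rejected = rejected,
      tile_rsd = tile_rsd,
      thresholds = vapply(results, function(r) r$threshold[1], numeric(1)),
      objects = all_objects
    )
  }
  ratios <- if (all(c("drop", "microdrop") %in% names(per_method))) {
    tibble(
      mean_count_ratio =
        per_method$microdrop$summary$mean_count /
        per_method$drop$summary$mean_count,
      density_ratio =
        per_method$microdrop$fibre_density_per_mm2 /
        per_method$drop$fibre_density_per_mm2,
      tile_rsd_ratio =
        per_method$microdrop$tile_rsd / per_method$drop$tile_rsd
    )
  } else NULL
  report <- structure(
    list(
      per_method = per_method,
      ratios = ratios,
      config = config,
      failures = failures,
      version = as.character(utils::packageVersion("fibredep")),
      # hash of the scientific configuration; the output location is not
      # part of the experiment identity
      config_hash = rlang::hash(config[setdiff(names(config), "out_dir")])
    ),
    class = "comparison_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  for (m in names(x$per_method)) {
    pm <- x$per_method[[m]]
    cat(sprintf(
      "  %-9s mean %d objects/image (RSD %.0f%%), %d NIOSH fibres (%.0f /mm^2)%s\n",
      m, round(pm$summary$mean_count), pm$summary$rsd_count, pm$n_fibres,
      pm$fibre_density_per_mm2,
      if (!is.na(pm$tile_rsd)) sprintf(", tile RSD %.0f%%", pm$tile_rsd) else ""
    ))
  }
  if (!is.null(x$ratios)) {
    cat(sprintf(
      "  microdrop/drop: mean-count ratio %.1f, fibre-density ratio %.1f\n",
      x$ratios$mean_count_ratio, x$ratios$density_ratio
    ))
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- tibble(
    package_version = report$version,
    config_hash = report$config_hash
  )
  summaries <- bind_rows(lapply(names(report$per_method), function(m) {
    s <- report$per_method[[m]]$summary
    dplyr::bind_cols(
      tibble(method = m),
      glance(s),
      tibble(
        niosh_fibres = report$per_method[[m]]$n_fibres,
        fibre_density_per_mm2 = report$per_method[[m]]$fibre_density_per_mm2,
        tile_rsd = report$per_method[[m]]$tile_rsd
      ),
      meta
    )
  }))
  readr::write_csv(summaries, file.path(out_dir, "summary.csv"))
  for (m in names(report$per_method)) {
    for (v in names(report$per_method[[m]]$histograms)) {
      h <- report$per_method[[m]]$histograms[[v]]
      readr::write_csv(
        dplyr::bind_cols(as_tibble(h), meta),
        file.path(out_dir, sprintf("classes_%s_%s.csv", v, m))
      )
    }
    readr::write_csv(
      dplyr::bind_cols(report$per_method[[m]]$fibres, meta),
      file.path(out_dir, sprintf("fibres_%s.csv", m))
    )
  }
  counting <- lapply(report$per_method, function(pm) {
    list(
      n_fibres = pm$n_fibres,
      fibre_density_per_mm2 = pm$fibre_density_per_mm2,
      rejected = as.list(pm$rejected)
    )
  })
  jsonlite::write_json(
    counting, file.path(out_dir, "counting_summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  log <- list(
    package_version = report$version,
    config_hash = report$config_hash,
    defaults_used = list(
      threshold_method = report$config$threshold_method,
      thresholds = lapply(report$per_method, function(pm) pm$thresholds),
      connectivity = report$config$connectivity,
      min_pixels = report$config$min_pixels,
      border_policy = report$config$border_policy,
      rsd_convention = "population sd (divisor n); report RSD over rounded mean"
    ),
    unreadable_images = report$failures
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
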