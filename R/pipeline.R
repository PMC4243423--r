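#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()].
#' Unknown keys are rejected so that typos do not silently fall back to
#' defaults.
#'
#' @param config named list (e.g. from [read_pipeline_config()]) with any
#'   of the sections `input`, `phantom`, `median`, `pattern`, `roi`,
#'   `references`, `threshold`, `morph`, `output`, `seed`.
#' @return the completed configuration list, class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  defaults <- list(
    input = NULL,                  # path to an ENVI .hdr file
    phantom = NULL,                # TRUE or a phantom_spec: synthetic input
    median = list(mask_rows = 3L, mask_cols = 3L, edge_policy = "reflect"),
    pattern = list(expected_rows = 80L, tolerance = 5L, p_r = "auto"),
    roi = "auto",                  # "auto", "phantom", or c(m0, n0, h, w)
    roi_size = 150L,
    references = "phantom",        # named list of CSV paths, or "phantom"
    threshold = list(policy = "flat_region", manual_value = NULL,
                     s_tol = 0.05, reference = NULL),
    morph = list(p_we = 0.5, p_wd = 0.5, p_mn = "selected",
                 iterations = 5L, order = "sequential", se_size = 5L),
    output = NULL,                 # directory for artifacts, NULL = none
    seed = 1L)
  unknown <- setdiff(names(config), names(defaults))
  hs_assert(length(unknown) == 0, "hs_config_error",
            "unknown configuration key(s): %s", toString(unknown))
  for (sec in c("median", "pattern", "threshold", "morph")) {
    if (!is.null(config[[sec]])) {
      bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
      hs_assert(length(bad) == 0, "hs_config_error",
                "unknown key(s) in '%s': %s", sec, toString(bad))
    }
  }
  out <- modifyList(defaults, config)
  class(out) <- "pipeline_config"
  out
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  hs_assert(file.exists(path), "hs_io_error", "config file not found: %s", path)
  pipeline_config(yaml::read_yaml(path))
}

#' Run the full calibration and segmentation pipeline
#'
#' Chains the processing stages: read (or synthesize) the raw cube, median
#' filtering, automatic stripe detection and reflectance calibration, ROI
#' band statistics and sequence normalization, reference-spectrum distance
#' maps, threshold selection, multi-class segmentation and conditional
#' morphological refinement, plus error accounting against the ground
#' truth when the input is a phantom.  Every resolved parameter (gradient
#' threshold, filled contour columns, selected `p_w`, threshold fallback,
#' morphology settings) is recorded in the returned `log`.
#'
#' @param config a [pipeline_config()], a plain named list, or a YAML path.
#' @return invisibly, a list with the intermediate objects (`cube_raw`,
#'   `cube_filtered`, `cube_calibrated`, `cube_normalized`, `profile`,
#'   `roi`, `stats`, `references`, `distance_maps`, `curve`, `p_w`,
#'   `labels_raw`, `labels`, `report`, `log`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  truth <- NULL; phantom_refs <- NULL; phantom_roi <- NULL
  if (!is.null(config$phantom)) {
    spec <- if (inherits(config$phantom, "phantom_spec")) config$phantom
            else default_study_phantom(seed = config$seed)
    scene <- make_phantom(spec)
    cube <- scene$cube
    truth <- scene$truth
    phantom_refs <- scene$references
    phantom_roi <- scene$roi
    config$pattern$expected_rows <- spec$stripe_rows
    note("input: phantom %d x %d x %d, seed %d", spec$M, spec$N, spec$K,
         spec$seed)
  } else {
    hs_assert(!is.null(config$input), "hs_config_error",
              "config needs either 'input' or 'phantom'")
    cube <- read_cube(config$input)
    note("input: %s (%s)", config$input,
         paste(dim(cube), collapse = " x "))
  }

  mspec <- median_spec(config$median$mask_rows, config$median$mask_cols,
                       config$median$edge_policy)
  filtered <- median_filter_cube(cube, mspec)
  note("median filter: %d x %d, edges %s", mspec$mask_rows, mspec$mask_cols,
       mspec$edge_policy)

  pspec <- pattern_search_spec(config$pattern$expected_rows,
                               config$pattern$tolerance, config$pattern$p_r)
  profile <- fit_calibration(filtered, pspec)
  note("stripe contour: rows %d..%d, p_r = %.4g, %d column(s) filled in",
       min(profile$contour), max(profile$contour), attr(profile, "p_r"),
       length(attr(profile$contour, "filled")))
  calibrated <- calibrate_cube(filtered, profile)

  roi <- if (identical(config$roi, "phantom")) {
    hs_assert(!is.null(phantom_roi), "hs_config_error",
              "roi = 'phantom' requires a phantom input")
    phantom_roi
  } else if (identical(config$roi, "auto")) {
    if (!is.null(phantom_roi)) phantom_roi
    else auto_roi(calibrated, profile$contour, size = config$roi_size)
  } else {
    r <- unlist(config$roi)
    roi_spec(r[1], r[2], r[3], r[4])
  }
  note("ROI: %d x %d at (%d, %d)", roi$height, roi$width, roi$m0, roi$n0)
  stats <- roi_band_stats(calibrated, roi, profile$contour)
  normalized <- normalize_sequence(calibrated, stats)
  note("normalization: target 0.50, ROI grand mean %.4f", mean(stats$mean))

  refs <- if (identical(config$references, "phantom")) {
    hs_assert(!is.null(phantom_refs), "hs_config_error",
              "references = 'phantom' requires a phantom input")
    phantom_refs
  } else {
    hs_assert(is.list(config$references) && length(config$references) > 0,
              "hs_config_error", "references must name at least one CSV")
    lapply(stats::setNames(names(config$references), names(config$references)),
           function(nm) read_reference_csv(config$references[[nm]], nm))
  }
  refs <- lapply(refs, function(r) {
    r <- if (!is.null(r$wavelengths_nm)) resample_reference(r, cube$wavelengths_nm) else r
    normalize_reference(r, normalized)
  })
  note("references: %s", toString(names(refs)))

  dmaps <- lapply(refs, function(r) distance_map(normalized, r))
  thr_ref <- config$threshold$reference
  if (is.null(thr_ref)) thr_ref <- if ("skin" %in% names(dmaps))
    "skin" else names(dmaps)[1]
  curve <- area_curve(dmaps[[thr_ref]])
  p_w <- tryCatch(
    select_threshold(curve, config$threshold$policy,
                     manual_value = config$threshold$manual_value,
                     dmap = dmaps[[thr_ref]],
                     s_tol = config$threshold$s_tol),
    hs_no_flat_region = function(e) {
      note("threshold: no flat region, falling back to Otsu")
      select_threshold(curve, "otsu", dmap = dmaps[[thr_ref]])
    })
  note("threshold: policy %s on '%s' -> p_w = %.4f",
       config$threshold$policy, thr_ref, p_w)

  labels_raw <- multiclass_segment(normalized, refs, p_w)
  p_mn <- if (identical(config$morph$p_mn, "selected")) p_w else config$morph$p_mn
  cspec <- cond_morph_spec(p_mn = p_mn, p_we = config$morph$p_we,
                           p_wd = config$morph$p_wd,
                           se = disk_se(config$morph$se_size),
                           iterations = config$morph$iterations,
                           order = config$morph$order)
  labels <- refine_labels(labels_raw, dmaps, cspec)
  note("morphology: p_we = %.2f, p_wd = %.2f, p_mn = %.4f, %d iteration(s), %s order",
       cspec$p_we, cspec$p_wd, p_mn, cspec$iterations, cspec$order)

  report <- NULL
  if (!is.null(truth)) {
    report <- class_report(labels, truth)
    note("max per-class delta_w vs truth: %.1f%%",
         max(report$delta_w_pct, na.rm = TRUE))
  }

  result <- list(cube_raw = cube, cube_filtered = filtered,
                 cube_calibrated = calibrated, cube_normalized = normalized,
                 profile = profile, roi = roi, stats = stats,
                 references = refs, distance_maps = dmaps, curve = curve,
                 p_w = p_w, labels_raw = labels_raw, labels = labels,
                 truth = truth, report = report, log = log)

  if (!is.null(config$output)) .write_pipeline_artifacts(result, config$output)
  invisible(result)
}

.write_pipeline_artifacts <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(res$curve),
            file.path(dir, "area_curve.csv"), row.names = FALSE)
  write.csv(as.data.frame(res$stats),
            file.path(dir, "roi_band_stats.csv"), row.names = FALSE)
  write_calibration_profile(res$profile, file.path(dir, "calibration"))
  write_labels_png(res$labels, file.path(dir, "labels.png"))
  jsonlite::write_json(label_counts(res$labels),
                       file.path(dir, "label_counts.json"), digits = NA)
  if (!is.null(res$report))
    write.csv(res$report, file.path(dir, "class_report.csv"),
              row.names = FALSE)
  writeLines(c(sprintf("p_w = %.6f", res$p_w), res$log),
             file.path(dir, "pipeline_log.txt"))
  invisible(dir)
}
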