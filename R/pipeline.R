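#' Pipeline configuration
#'
#' A single configuration object for the end-to-end run: paths (or in-memory
#' objects), the frame-discard count, the smoothing kernel, and the nested
#' decomposition / DICI / growth / seed settings.
#'
#' @param bold path to a 4D NIfTI, or a [series4d()].
#' @param anat optional path to a 3D NIfTI, or a [volume3d()]; used for
#'   template growth and overlays.
#' @param template optional path to a template NIfTI, or a
#'   [binary_mask()] / `tumor_template`. If absent, `growth` must be given.
#' @param out_dir output directory.
#' @param n_discard_frames frames dropped from the start of the series
#'   (default 4, the usual equilibration allowance).
#' @param fwhm_mm smoothing kernel FWHM in mm (default 6); 0 skips smoothing.
#' @param mask_frac brain-mask threshold fraction (see
#'   [compute_brain_mask()]).
#' @param decomposition a [decomposition_config()].
#' @param dici a [dici_config()].
#' @param growth optional [growth_params()] for template generation.
#' @param seed optional [seed_spec()]; runs the seed-correlation baseline.
#' @param rng_seed integer master seed recorded in the manifest.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(bold, anat = NULL, template = NULL,
                            out_dir = "boldica_out",
                            n_discard_frames = 4L, fwhm_mm = 6,
                            mask_frac = 0.2,
                            decomposition = decomposition_config(
                              tncs = 10L, n_runs = 25L),
                            dici = dici_config(),
                            growth = NULL, seed = NULL,
                            rng_seed = 1L) {
  if (is.null(template) && is.null(growth))
    stop(paste("no tumor template: supply either `template` or `growth`",
               "parameters to derive one from the anatomical image"),
         call. = FALSE)
  if (is.null(template) && is.null(anat))
    stop("template growth requires an anatomical image (`anat`)",
         call. = FALSE)
  structure(list(bold = bold, anat = anat, template = template,
                 out_dir = out_dir,
                 n_discard_frames = as.integer(n_discard_frames),
                 fwhm_mm = fwhm_mm, mask_frac = mask_frac,
                 decomposition = decomposition, dici = dici,
                 growth = growth, seed = seed,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Discard equilibration frames, mask and smooth a series
#'
#' Drops the first `n_discard_frames` frames, derives the brain mask from the
#' temporal mean of the remaining frames, and smooths (if `fwhm_mm > 0`).
#'
#' @param series a [series4d()].
#' @param n_discard_frames leading frames to drop (default 4).
#' @param fwhm_mm smoothing FWHM in mm; 0 skips smoothing with a warning.
#' @param mask_frac threshold fraction for [compute_brain_mask()].
#' @return A list with `series` (preprocessed [series4d()]), `mask`
#'   ([binary_mask()]) and `mean_img` ([volume3d()]).
#' @export
preprocess <- function(series, n_discard_frames = 4L, fwhm_mm = 6,
                       mask_frac = 0.2) {
  stopifnot(inherits(series, "series4d"))
  nd <- as.integer(n_discard_frames)
  if (nd < 0L || nd >= series$n_frames)
    stop(sprintf("cannot discard %d of %d frames", nd, series$n_frames),
         call. = FALSE)
  if (series$n_frames - nd < 2L)
    stop("fewer than 2 frames would remain after discarding", call. = FALSE)
  kept <- series4d(series$values[, , , (nd + 1L):series$n_frames,
                                 drop = FALSE],
                   series$grid, series$tr_seconds)
  mean_img <- mean_volume(kept)
  mask <- compute_brain_mask(mean_img, frac = mask_frac)
  if (fwhm_mm > 0) {
    kept <- smooth_gaussian(kept, fwhm_mm, mask)
  } else {
    warning("fwhm_mm is 0; smoothing skipped")
  }
  list(series = kept, mask = mask, mean_img = mean_img)
}

#' Gate a run on externally supplied rigid-body motion estimates
#'
#' Motion correction itself happens upstream; this applies the conventional
#' exclusion rule: fail when any translation exceeds 3 mm or any rotation
#' exceeds 3 degrees.
#'
#' @param params a data frame or matrix with 6 columns (3 translations in
#'   mm, 3 rotations in degrees), one row per frame.
#' @param max_translation_mm,max_rotation_deg exclusion thresholds.
#' @return A one-row tibble: `pass`, `max_abs_translation_mm`,
#'   `max_abs_rotation_deg`, `n_frames`.
#' @export
motion_gate <- function(params, max_translation_mm = 3,
                        max_rotation_deg = 3) {
  params <- tryCatch(as.matrix(params), error = function(e) NULL)
  if (is.null(params) || nrow(params) == 0L || ncol(params) != 6L ||
      !is.numeric(params) || anyNA(params))
    stop(paste("malformed motion-parameter table: need a numeric matrix",
               "with 6 columns (3 translations mm, 3 rotations deg)"),
         call. = FALSE)
  mt <- max(abs(params[, 1:3]))
  mr <- max(abs(params[, 4:6]))
  tibble::tibble(pass = mt <= max_translation_mm & mr <= max_rotation_deg,
                 max_abs_translation_mm = mt,
                 max_abs_rotation_deg = mr,
                 n_frames = nrow(params))
}

resolve_series <- function(x) {
  if (inherits(x, "series4d")) return(x)
  read_volume(x)
}

resolve_volume <- function(x) {
  if (is.null(x) || inherits(x, "volume3d")) return(x)
  read_volume(x)
}

resolve_template <- function(x, grid) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "tumor_template")) return(x)
  if (inherits(x, "binary_mask")) return(as_tumor_template(x))
  vol <- read_volume(x)
  as_tumor_template(binary_mask(vol$values > 0.5, vol$grid), id = x)
}

#' Run the full detection pipeline
#'
#' preprocess, then template growth (when no template is given), the
#' model-order sweep with DICI selection, report writing, overlay rendering,
#' and (optionally) the seed-correlation baseline. Every output is written
#' under `cfg$out_dir` and listed with an md5 checksum in the returned
#' manifest; identical configuration and seed reproduce the TSV/JSON outputs
#' byte for byte.
#'
#' @param cfg a [pipeline_config()].
#' @return An object of class `run_manifest`: a list with the `selection`,
#'   the `config`, per-stage wall times, and an `outputs` tibble
#'   (`name`, `path`, `md5`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  series <- stage("read", resolve_series(cfg$bold))
  anat <- resolve_volume(cfg$anat)
  prep <- stage("preprocess",
                preprocess(series, cfg$n_discard_frames, cfg$fwhm_mm,
                           cfg$mask_frac))

  template <- resolve_template(cfg$template, series$grid)
  if (is.null(template)) {
    template <- stage("template", grow_voi(anat, cfg$growth))
    p <- file.path(cfg$out_dir, "template.nii.gz")
    write_volume(template$mask, p)
    outputs$template <- p
  }

  dcfg <- cfg$decomposition
  dcfg$base_rng_seed <- cfg$rng_seed
  sel <- stage("sweep_and_select",
               sweep_and_select(prep$series, prep$mask, template, dcfg,
                                cfg$dici))

  best_map <- best_component_map(sel)
  p_map <- file.path(cfg$out_dir, "best_component_zmap.nii.gz")
  write_volume(best_map, p_map)
  outputs$best_component_zmap <- p_map
  p_bin <- file.path(cfg$out_dir, "best_component_binarized.nii.gz")
  write_volume(binarize_component(best_map, cfg$dici), p_bin)
  outputs$best_component_binarized <- p_bin

  p_rep <- file.path(cfg$out_dir, "dici_report.tsv")
  stage("report", write_dici_report(sel, p_rep))
  outputs$dici_report <- p_rep
  outputs$dici_summary <- sub("\\.tsv$", ".json", p_rep)

  bg <- if (!is.null(anat)) anat else prep$mean_img
  ov <- stage("overlay",
              render_overlay(best_map, bg, cfg$dici,
                             file.path(cfg$out_dir, "overlay")))
  outputs$overlay <- ov[[1]]
  outputs$overlay_unthresholded <- ov[[2]]

  if (!is.null(cfg$seed)) {
    cmap <- stage("seed_baseline",
                  seed_correlation(prep$series, prep$mask, cfg$seed))
    for (thr in cfg$seed$r_thresholds) {
      p <- file.path(cfg$out_dir,
                     sprintf("seedcorr_r%s.nii.gz",
                             sub("\\.", "p", format(thr))))
      write_volume(threshold_correlation(cmap, thr), p)
      outputs[[sprintf("seedcorr_r%s", sub("\\.", "p", format(thr)))]] <- p
    }
  }

  paths <- unlist(outputs)
  manifest <- structure(list(
    selection = sel,
    config = cfg,
    timings = tibble::tibble(stage = names(timings),
                             seconds = unlist(timings)),
    outputs = tibble::tibble(name = names(paths), path = unname(paths),
                             md5 = unname(tools::md5sum(paths)))),
    class = "run_manifest")
  mpath <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(list(
    rng_seed = cfg$rng_seed,
    optimal_tncs = sel$optimal_tncs,
    best_component_index = sel$best$component_index[[1]],
    best_dici = sel$best$dici[[1]],
    outputs = manifest$outputs,
    timings = manifest$timings),
    mpath, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest$manifest_path <- mpath
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  print(x$selection)
  cat("  outputs:\n")
  for (i in seq_len(nrow(x$outputs)))
    cat("    ", x$outputs$path[[i]], "\n", sep = "")
  invisible(x)
}
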