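#' Configuration of DICI scoring and model-order selection
#'
#' @param z_threshold z cut for binarizing component maps (default 1; any
#'   value between roughly 0.5 and 3 selects the same component on
#'   well-behaved data).
#' @param min_cluster_voxels connected clusters must be strictly larger than
#'   this to survive (default 20).
#' @param connectivity 6, 18 or 26; adjacency used for the cluster filter.
#' @param tncs_grid ordered model orders to sweep (default 10 to 100 by 10).
#' @param viz_threshold stricter z cut used only for overlays (default 1.5).
#' @return An object of class `dici_config`.
#' @export
dici_config <- function(z_threshold = 1, min_cluster_voxels = 20L,
                        connectivity = 26L,
                        tncs_grid = seq(10L, 100L, by = 10L),
                        viz_threshold = 1.5) {
  if (!is.finite(z_threshold) || z_threshold <= 0)
    stop("`z_threshold` must be > 0", call. = FALSE)
  if (min_cluster_voxels < 0L)
    stop("`min_cluster_voxels` must be >= 0", call. = FALSE)
  tncs_grid <- as.integer(tncs_grid)
  if (any(diff(tncs_grid) <= 0))
    stop("`tncs_grid` must be strictly increasing", call. = FALSE)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  structure(list(z_threshold = z_threshold,
                 min_cluster_voxels = as.integer(min_cluster_voxels),
                 connectivity = as.integer(connectivity),
                 tncs_grid = tncs_grid,
                 viz_threshold = viz_threshold),
            class = "dici_config")
}

#' Binarize a z-standardised component map
#'
#' Keeps the positive tail (`z > z_threshold`), then removes connected
#' clusters whose size is not strictly greater than `min_cluster_voxels`.
#' An empty result is legal.
#'
#' @param map a [volume3d()] z-map (e.g. from [component_map()]).
#' @param cfg a [dici_config()].
#' @return A [binary_mask()].
#' @export
binarize_component <- function(map, cfg = dici_config()) {
  stopifnot(inherits(map, "volume3d"), inherits(cfg, "dici_config"))
  supra <- map$values > cfg$z_threshold
  if (any(supra) && cfg$min_cluster_voxels > 0L) {
    lab <- label_components(supra, cfg$connectivity)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes > cfg$min_cluster_voxels)
    supra <- array(lab %in% keep, dim(lab))
  }
  binary_mask(supra, map$grid)
}

clamp_rate <- function(count, n) {
  # degenerate 0 or 1 rates are pulled half a count inward so the normal
  # quantile stays finite; other rates are untouched
  r <- count / n
  if (r <= 0) 1 / (2 * n) else if (r >= 1) 1 - 1 / (2 * n) else r
}

#' Score one binarized component against the tumor template
#'
#' Over brain voxels: the hit rate HR is the fraction of template voxels the
#' component covers; the false-alarm rate FAR is the fraction of
#' non-template brain voxels it covers. Both are mapped through the standard
#' normal quantile function and combined as `DICI = z(HR) - z(FAR)`, the
#' classic discriminability index d'. Rates of exactly 0 or 1 are clamped
#' half a count inward so the quantile stays finite; a fully empty binarized
#' map is marked invalid instead of being scored.
#'
#' @param bin a [binary_mask()] (binarized component).
#' @param template a `tumor_template` or [binary_mask()].
#' @param brain the [binary_mask()] of in-analysis voxels.
#' @param tncs,component_index bookkeeping recorded in the result.
#' @return A one-row tibble (fields `tncs`, `component_index`, `hr`, `far`,
#'   `z_hr`, `z_far`, `dici`, `n_supra_voxels`, `valid`).
#' @export
score_component <- function(bin, template, brain,
                            tncs = NA_integer_,
                            component_index = NA_integer_) {
  tmask <- if (inherits(template, "tumor_template")) template$mask
           else template
  stopifnot(inherits(bin, "binary_mask"), inherits(tmask, "binary_mask"),
            inherits(brain, "binary_mask"))
  stopifnot_same_grid(bin$grid, brain$grid, "component and brain mask")
  stopifnot_same_grid(tmask$grid, brain$grid, "template and brain mask")
  n_t <- sum(tmask$member & brain$member)
  n_nt <- sum(brain$member & !tmask$member)
  if (n_t == 0L || n_nt == 0L)
    stop("degenerate template: it must cover some but not all brain voxels",
         call. = FALSE)
  b <- bin$member & brain$member
  hit <- sum(b & tmask$member)
  fa <- sum(b & !tmask$member)
  if (!any(b)) {
    return(tibble::tibble(tncs = tncs, component_index = component_index,
                          hr = 0, far = 0, z_hr = NA_real_, z_far = NA_real_,
                          dici = NA_real_, n_supra_voxels = 0L,
                          valid = FALSE))
  }
  hr <- clamp_rate(hit, n_t)
  far <- clamp_rate(fa, n_nt)
  z_hr <- stats::qnorm(hr)
  z_far <- stats::qnorm(far)
  tibble::tibble(tncs = tncs, component_index = component_index,
                 hr = hr, far = far, z_hr = z_hr, z_far = z_far,
                 dici = z_hr - z_far, n_supra_voxels = sum(b),
                 valid = TRUE)
}

#' Score every component of a decomposition
#'
#' @param cset a `component_set`.
#' @param template a `tumor_template` or [binary_mask()].
#' @param brain the analysis [binary_mask()].
#' @param cfg a [dici_config()].
#' @return A tibble with one row per component, ordered by component index.
#' @export
score_component_set <- function(cset, template, brain, cfg = dici_config()) {
  stopifnot(inherits(cset, "component_set"))
  purrr::map_dfr(seq_len(ncol(cset$maps)), function(k) {
    bin <- binarize_component(component_map(cset, k), cfg)
    score_component(bin, template, brain,
                    tncs = cset$tncs, component_index = k)
  })
}

#' Decompose a series at every model order of a sweep grid
#'
#' Infeasible grid entries (model order too large for the frame count or
#' mask) are skipped with a warning.
#'
#' @param series a [series4d()].
#' @param mask the analysis [binary_mask()].
#' @param dcfg a [decomposition_config()] template; its `tncs` is replaced by
#'   each grid value in turn.
#' @param tncs_grid integer vector of model orders.
#' @return A named list of `component_set`s (names are the model orders).
#' @export
sweep_components <- function(series, mask, dcfg,
                             tncs_grid = seq(10L, 100L, by = 10L)) {
  stopifnot(inherits(dcfg, "decomposition_config"))
  out <- list()
  for (tncs in as.integer(tncs_grid)) {
    if (tncs >= series$n_frames || tncs >= mask$n_voxels) {
      warning(sprintf(
        "skipping tncs = %d: not feasible with %d frames / %d mask voxels",
        tncs, series$n_frames, mask$n_voxels))
      next
    }
    cfg_t <- dcfg
    cfg_t$tncs <- tncs
    out[[as.character(tncs)]] <- decompose(series, mask, cfg_t)
  }
  if (!length(out))
    stop("no feasible model order in `tncs_grid`", call. = FALSE)
  out
}

#' Select the optimal model order and best tumor component
#'
#' For each decomposition, all components are scored and sorted by
#' descending DICI; the four largest are recorded and the rank-1 component
#' is that model order's candidate. The candidate with the largest DICI
#' across the sweep wins; its model order is the optimal TNCs. Ties break
#' toward the lower model order, then the lower component index. Pairwise
#' DICI differences among the top four at the optimal model order are
#' reported as the separability diagnostic.
#'
#' @param csets a named list of `component_set`s from [sweep_components()].
#' @param template a `tumor_template` or [binary_mask()].
#' @param brain the analysis [binary_mask()].
#' @param cfg a [dici_config()].
#' @return An object of class `dici_selection`: `optimal_tncs`, `best` (a
#'   one-row score tibble), `top4` (ranks 1-4 per model order),
#'   `delta_dici` (pairwise differences at the optimal model order),
#'   `report` (full per-model-order, per-rank listing) and `scores` (every
#'   component's score).
#' @export
select_tumor_component <- function(csets, template, brain,
                                   cfg = dici_config()) {
  scores <- purrr::map_dfr(csets, score_component_set,
                           template = template, brain = brain, cfg = cfg)
  valid <- dplyr::filter(scores, .data$valid)
  if (nrow(valid) == 0L)
    rlang::abort(
      "no valid tumor-related component: every binarized map was empty",
      class = "boldica_no_tumor_component")
  ranked <- valid |>
    dplyr::arrange(.data$tncs, dplyr::desc(.data$dici),
                   .data$component_index) |>
    dplyr::group_by(.data$tncs) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  top4 <- dplyr::filter(ranked, .data$rank <= 4L)
  cand <- dplyr::filter(ranked, .data$rank == 1L)
  best <- cand |>
    dplyr::arrange(dplyr::desc(.data$dici), .data$tncs,
                   .data$component_index) |>
    dplyr::slice(1L)
  opt <- best$tncs[[1]]
  t4 <- dplyr::filter(top4, .data$tncs == opt)
  delta <- if (nrow(t4) >= 2L) {
    pairs <- utils::combn(seq_len(nrow(t4)), 2)
    tibble::tibble(
      rank_a = t4$rank[pairs[1, ]],
      rank_b = t4$rank[pairs[2, ]],
      delta_dici = t4$dici[pairs[1, ]] - t4$dici[pairs[2, ]])
  } else {
    tibble::tibble(rank_a = integer(), rank_b = integer(),
                   delta_dici = numeric())
  }
  structure(list(optimal_tncs = opt,
                 best = best,
                 top4 = top4,
                 delta_dici = delta,
                 report = top4,
                 scores = scores,
                 config = cfg),
            class = "dici_selection")
}

#' Full sweep-and-select pipeline stage
#'
#' Composition of [sweep_components()] and [select_tumor_component()]: one
#' repeated-ICA decomposition per model order on the sweep grid, DICI
#' scoring of every component against the template, and selection of the
#' best-fitted tumor component with its optimal model order.
#'
#' @inheritParams sweep_components
#' @inheritParams select_tumor_component
#' @param keep_components if `TRUE` (default) the decompositions are kept on
#'   the result under `$component_sets` (needed to render maps later).
#' @return A `dici_selection` (see [select_tumor_component()]).
#' @export
sweep_and_select <- function(series, mask, template, dcfg,
                             cfg = dici_config(), keep_components = TRUE) {
  csets <- sweep_components(series, mask, dcfg, cfg$tncs_grid)
  sel <- select_tumor_component(csets, template, brain = mask, cfg = cfg)
  if (keep_components) sel$component_sets <- csets
  sel
}

#' Retrieve the winning component's z-map from a selection
#'
#' @param sel a `dici_selection` carrying `component_sets`.
#' @return A [volume3d()] z-map of the best-fitted tumor component.
#' @export
best_component_map <- function(sel) {
  stopifnot(inherits(sel, "dici_selection"))
  if (is.null(sel$component_sets))
    stop("selection was made with `keep_components = FALSE`", call. = FALSE)
  cset <- sel$component_sets[[as.character(sel$optimal_tncs)]]
  component_map(cset, sel$best$component_index[[1]])
}

#' @export
print.dici_selection <- function(x, ...) {
  cat("<dici_selection>\n",
      "  optimal TNCs: ", x$optimal_tncs,
      ", component ", x$best$component_index[[1]],
      ", DICI ", sprintf("%.3f", x$best$dici[[1]]), "\n",
      "  HR ", sprintf("%.3f", x$best$hr[[1]]),
      ", FAR ", sprintf("%.4f", x$best$far[[1]]), "\n", sep = "")
  invisible(x)
}

#' Write the DICI report
#'
#' Writes a TSV of ranks 1-4 per model order (columns `tncs`, `rank`,
#' `component_index`, `hr`, `far`, `z_hr`, `z_far`, `dici`,
#' `n_supra_voxels`, `valid`) and a JSON summary with the optimal model
#' order, the winning component and the adjacent-rank DICI differences.
#'
#' @param sel a `dici_selection`.
#' @param path output TSV path; the JSON summary goes next to it with
#'   extension `.json`.
#' @return `path`, invisibly.
#' @export
write_dici_report <- function(sel, path) {
  stopifnot(inherits(sel, "dici_selection"))
  cols <- c("tncs", "rank", "component_index", "hr", "far", "z_hr", "z_far",
            "dici", "n_supra_voxels", "valid")
  readr::write_tsv(dplyr::select(sel$report, dplyr::all_of(cols)), path)
  adj <- function(a, b) {
    i <- which(sel$delta_dici$rank_a == a & sel$delta_dici$rank_b == b)
    if (length(i)) sel$delta_dici$delta_dici[[i]] else NA_real_
  }
  summary <- list(
    optimal_tncs = sel$optimal_tncs,
    best_component_index = sel$best$component_index[[1]],
    best_dici = sel$best$dici[[1]],
    delta_dici_1st_2nd = adj(1L, 2L),
    delta_dici_2nd_3rd = adj(2L, 3L),
    delta_dici_3rd_4th = adj(3L, 4L))
  jsonlite::write_json(summary, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
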