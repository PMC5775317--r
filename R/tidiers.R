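#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DICI selection into its per-rank report table
#'
#' @param x a `dici_selection`.
#' @param all if `TRUE`, return every component's score rather than only
#'   ranks 1-4 per model order.
#' @param ... unused.
#' @return A tibble with one row per (model order, rank).
#' @export
tidy.dici_selection <- function(x, all = FALSE, ...) {
  if (all) x$scores else x$report
}

#' One-row summary of a DICI selection
#'
#' @param x a `dici_selection`.
#' @param ... unused.
#' @return A one-row tibble: optimal model order, winning component and its
#'   DICI/HR/FAR, and the adjacent-rank DICI differences.
#' @export
glance.dici_selection <- function(x, ...) {
  adj <- function(a, b) {
    i <- which(x$delta_dici$rank_a == a & x$delta_dici$rank_b == b)
    if (length(i)) x$delta_dici$delta_dici[[i]] else NA_real_
  }
  tibble::tibble(
    optimal_tncs = x$optimal_tncs,
    best_component_index = x$best$component_index[[1]],
    best_dici = x$best$dici[[1]],
    best_hr = x$best$hr[[1]],
    best_far = x$best$far[[1]],
    delta_dici_1st_2nd = adj(1L, 2L),
    delta_dici_2nd_3rd = adj(2L, 3L),
    delta_dici_3rd_4th = adj(3L, 4L),
    n_tncs_evaluated = length(unique(x$scores$tncs)))
}

#' Plot the DICI curve across model orders
#'
#' The classic selection plot: the largest DICI per model order, with the
#' optimum marked; lighter lines trace ranks 2-4 as the separability
#' context.
#'
#' @param object a `dici_selection`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.dici_selection <- function(object, ...) {
  df <- object$top4
  df$rank_f <- factor(df$rank)
  best <- object$best
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tncs, y = .data$dici,
                                   colour = .data$rank_f)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_point(data = best, colour = "red", size = 3,
                        shape = 1, stroke = 1.2) +
    ggplot2::scale_colour_manual(
      values = c("1" = "black", "2" = "grey45", "3" = "grey60",
                 "4" = "grey75"),
      name = "DICI rank") +
    ggplot2::labs(x = "total number of components (TNCs)",
                  y = "DICI = z(HR) - z(FAR)",
                  title = "DICI across the model-order sweep") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Orthogonal-slice overlay of a component on an anatomical image
#'
#' Builds a three-panel montage (axial, coronal, sagittal through the map's
#' peak voxel) of the z-map over the anatomical background. The thresholded
#' panel applies `cfg$viz_threshold` with no cluster filtering; the
#' unthresholded variant shows the full signed map.
#'
#' @param map a [volume3d()] component z-map.
#' @param anat a [volume3d()] anatomical image on the same grid.
#' @param cfg a [dici_config()] (supplies `viz_threshold`).
#' @param thresholded apply the visualization threshold?
#' @return A ggplot object.
#' @export
plot_overlay <- function(map, anat, cfg = dici_config(), thresholded = TRUE) {
  stopifnot(inherits(map, "volume3d"), inherits(anat, "volume3d"))
  if (!same_grid(map$grid, anat$grid))
    stop("component map and anatomical image are on different grids",
         call. = FALSE)
  v <- map$values
  thr <- cfg$viz_threshold
  if (thresholded && !any(v > thr))
    warning("no voxel exceeds the visualization threshold; ",
            "overlay shows background only")
  peak <- arrayInd(which.max(v), dim(v))
  slices <- list(
    axial = list(bg = anat$values[, , peak[3]], ov = v[, , peak[3]]),
    coronal = list(bg = anat$values[, peak[2], ], ov = v[, peak[2], ]),
    sagittal = list(bg = anat$values[peak[1], , ], ov = v[peak[1], , ]))
  df <- purrr::map_dfr(names(slices), function(nm) {
    s <- slices[[nm]]
    d <- dim(s$bg)
    tibble::tibble(view = nm,
                   i = rep(seq_len(d[1]), times = d[2]),
                   j = rep(seq_len(d[2]), each = d[1]),
                   bg = as.vector(s$bg),
                   ov = as.vector(s$ov))
  })
  df$view <- factor(df$view, levels = c("axial", "coronal", "sagittal"))
  if (thresholded) df$ov[df$ov <= thr] <- NA
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$bg)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::facet_wrap(~view, nrow = 1, scales = "free") +
    ggplot2::theme_void() +
    ggplot2::labs(title = if (thresholded)
      sprintf("tumor-related component (z > %.2g)", thr)
      else "tumor-related component (unthresholded)")
  ov_df <- df[!is.na(df$ov) & df$ov != 0, , drop = FALSE]
  if (nrow(ov_df)) {
    p <- p + ggplot2::geom_raster(
      data = ov_df,
      ggplot2::aes(x = .data$i, y = .data$j, alpha = abs(.data$ov)),
      fill = "red", inherit.aes = FALSE) +
      ggplot2::scale_alpha_continuous(range = c(0.3, 1), guide = "none")
  }
  p
}

#' Render overlay PNGs for the winning component
#'
#' Writes both the thresholded (`viz_threshold`) and unthresholded montages.
#'
#' @param map a [volume3d()] component z-map.
#' @param anat a [volume3d()] anatomical image on the same grid.
#' @param cfg a [dici_config()].
#' @param stem output path stem; writes `<stem>.png` and
#'   `<stem>_unthresholded.png`.
#' @return Character vector of written paths, invisibly.
#' @export
render_overlay <- function(map, anat, cfg = dici_config(), stem) {
  p1 <- paste0(stem, ".png")
  p2 <- paste0(stem, "_unthresholded.png")
  ggplot2::ggsave(p1, plot_overlay(map, anat, cfg, thresholded = TRUE),
                  width = 8, height = 3.2, dpi = 120)
  ggplot2::ggsave(p2, plot_overlay(map, anat, cfg, thresholded = FALSE),
                  width = 8, height = 3.2, dpi = 120)
  invisible(c(p1, p2))
}
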