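#' Segment basal-body ROIs inside selected cells
#'
#' Within each cell of the label mask, pixels above the threshold are
#' grouped by 8-connectivity; components smaller than `min_area` are
#' dropped. The threshold is computed per cell by Otsu's method on that
#' cell's intensities (default) or supplied as one fixed value for
#' reproducibility. Components are clipped by the mask, so every ROI
#' belongs to exactly one cell.
#'
#' @param img A [cq_channel()] basal-body staining image.
#' @param mask A [cq_mask()] of the same shape with at least one cell.
#' @param threshold `"otsu"` or a fixed numeric intensity threshold.
#' @param min_area Minimum ROI area in pixels.
#' @return A pixel-level tibble: `roi_id` (global), `cell_id`, `x`
#'   (column), `y` (row), `intensity`. Zero rows when nothing is above
#'   threshold.
#' @export
segment_bb_rois <- function(img, mask, threshold = "otsu", min_area = 3) {
  stopifnot(inherits(img, "cq_channel"), inherits(mask, "cq_mask"))
  check_same_shape(img, mask, "image", "mask")
  cells <- setdiff(sort(unique(as.vector(mask$labels))), 0L)
  if (length(cells) == 0L) stop("mask contains no cells", call. = FALSE)
  H <- nrow(img$pixels)
  out <- list()
  next_roi <- 0L
  for (k in cells) {
    in_cell <- which(mask$labels == k)
    v <- img$pixels[in_cell]
    thr <- if (identical(threshold, "otsu")) otsu_threshold(v)
           else as.numeric(threshold)
    if (!is.finite(thr)) next
    lit <- in_cell[v > thr]
    if (length(lit) == 0L) next
    lab <- label_components_8(lit, H, ncol(img$pixels))
    area <- tabulate(lab)
    keep_lab <- which(area >= min_area)
    if (length(keep_lab) == 0L) next
    sel <- lab %in% keep_lab
    roi <- match(lab[sel], keep_lab) + next_roi
    next_roi <- next_roi + length(keep_lab)
    out[[length(out) + 1L]] <- tibble::tibble(
      roi_id = roi,
      cell_id = k,
      x = (lit[sel] - 1L) %/% H + 1L,
      y = (lit[sel] - 1L) %% H + 1L,
      intensity = img$pixels[lit[sel]]
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L)
    res <- tibble::tibble(roi_id = integer(0), cell_id = integer(0),
                          x = integer(0), y = integer(0), intensity = numeric(0))
  dplyr::arrange(res, .data$roi_id)
}

# Otsu threshold on raw intensities (histogram over the value range)
otsu_threshold <- function(v, levels = 256) {
  rng <- range(v)
  if (diff(rng) == 0) return(NA_real_)
  scaled <- (v - rng[1]) / diff(rng)
  thr01 <- EBImage::otsu(EBImage::Image(matrix(scaled, ncol = 1)),
                         range = c(0, 1), levels = levels)
  rng[1] + thr01 * diff(rng)
}

#' Fit the minimum enclosing ellipse to every segmented ROI
#'
#' Each ROI's pixel corners (see [roi_corner_points()]) are enclosed by
#' the minimum-area ellipse ([min_enclosing_ellipse()]); eccentricity
#' and the major/minor (Mm) axis ratio follow from the semi-axes.
#'
#' @param rois Pixel-level tibble from [segment_bb_rois()].
#' @return A tibble with one row per ROI: `roi_id`, `cell_id`, `cx`,
#'   `cy`, `a`, `b`, `orientation`, `eccentricity`, `mm_ratio`,
#'   `n_pixels`.
#' @export
roi_ellipses <- function(rois) {
  if (nrow(rois) == 0L)
    return(tibble::tibble(roi_id = integer(0), cell_id = integer(0),
                          cx = numeric(0), cy = numeric(0), a = numeric(0),
                          b = numeric(0), orientation = numeric(0),
                          eccentricity = numeric(0), mm_ratio = numeric(0),
                          n_pixels = integer(0)))
  rois |>
    dplyr::group_by(.data$roi_id, .data$cell_id) |>
    dplyr::group_modify(function(px, key) {
      fit <- min_enclosing_ellipse(roi_corner_points(px$x, px$y))
      met <- ellipse_metrics(fit$a, fit$b)
      tibble::tibble(cx = fit$center[1], cy = fit$center[2],
                     a = fit$a, b = fit$b, orientation = fit$orientation,
                     eccentricity = met$eccentricity, mm_ratio = met$mm_ratio,
                     n_pixels = nrow(px))
    }) |>
    dplyr::ungroup()
}

#' Aggregate ROI ellipses to per-cell alignment scores
#'
#' Unweighted means of eccentricity and Mm ratio over each cell's ROIs.
#' Cells present in the mask but carrying no ROI are omitted with a
#' message; the per-ROI table keeps the information needed for any
#' other weighting.
#'
#' @param ellipses Per-ROI tibble from [roi_ellipses()].
#' @param mask Optional [cq_mask()]; when given, cells without ROIs are
#'   reported in the message.
#' @param group_label Label attached to every cell (e.g. `"control"`).
#' @return A tibble with `cell_id`, `mean_eccentricity`,
#'   `mean_mm_ratio`, `n_rois`, `group`.
#' @export
aggregate_cells <- function(ellipses, mask = NULL, group_label = "group") {
  if (nrow(ellipses) == 0L)
    return(tibble::tibble(cell_id = integer(0), mean_eccentricity = numeric(0),
                          mean_mm_ratio = numeric(0), n_rois = integer(0),
                          group = character(0)))
  cells <- ellipses |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(mean_eccentricity = mean(.data$eccentricity),
                     mean_mm_ratio = mean(.data$mm_ratio),
                     n_rois = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(group = group_label)
  if (!is.null(mask)) {
    all_cells <- setdiff(sort(unique(as.vector(mask$labels))), 0L)
    empty <- setdiff(all_cells, cells$cell_id)
    if (length(empty) > 0L)
      message(sprintf("%d cell(s) without ROIs omitted: %s",
                      length(empty), paste(empty, collapse = ", ")))
  }
  cells
}

#' Compare alignment scores between two groups of cells
#'
#' Welch's unequal-variance two-tailed t-test on the per-cell mean Mm
#' ratio and, separately, on the per-cell mean eccentricity.
#'
#' @param cells_a,cells_b Per-cell tibbles from [aggregate_cells()],
#'   each with at least 2 cells.
#' @return A tibble with one row per metric: `metric`, `t_statistic`,
#'   `df`, `p_value`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
compare_groups <- function(cells_a, cells_b) {
  if (nrow(cells_a) < 2L || nrow(cells_b) < 2L)
    stop("each group needs at least 2 cells", call. = FALSE)
  one <- function(metric, va, vb) {
    if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
      # degenerate but well-defined: identical constants are a perfect
      # null, different constants an unambiguous separation
      return(tibble::tibble(metric = metric, t_statistic = NA_real_,
                            df = NA_real_,
                            p_value = as.numeric(mean(va) == mean(vb)),
                            mean_a = mean(va), mean_b = mean(vb),
                            n_a = length(va), n_b = length(vb)))
    }
    tt <- stats::t.test(va, vb, var.equal = FALSE)
    tibble::tibble(metric = metric,
                   t_statistic = unname(tt$statistic),
                   df = unname(tt$parameter),
                   p_value = tt$p.value,
                   mean_a = mean(va), mean_b = mean(vb),
                   n_a = length(va), n_b = length(vb))
  }
  dplyr::bind_rows(
    one("mm_ratio", cells_a$mean_mm_ratio, cells_b$mean_mm_ratio),
    one("eccentricity", cells_a$mean_eccentricity, cells_b$mean_eccentricity)
  )
}

#' Full basal-body alignment pipeline on one image
#'
#' Segmentation, ellipse fitting and per-cell aggregation in one call.
#'
#' @param img A [cq_channel()].
#' @param mask A [cq_mask()].
#' @param threshold,min_area Passed to [segment_bb_rois()].
#' @param group_label Passed to [aggregate_cells()].
#' @return A list with `rois` (per-ROI ellipse tibble) and `cells`
#'   (per-cell tibble).
#' @export
bb_alignment <- function(img, mask, threshold = "otsu", min_area = 3,
                         group_label = "group") {
  px <- segment_bb_rois(img, mask, threshold = threshold, min_area = min_area)
  ell <- roi_ellipses(px)
  list(rois = ell, cells = aggregate_cells(ell, mask, group_label))
}
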