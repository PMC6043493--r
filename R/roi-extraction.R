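# Partial-volume-aware ROI masking and extraction of per-ROI mean metric
# values into the tidy table that feeds the comparison statistics.

#' Threshold a partial-volume map into a binary tissue mask
#'
#' Inclusive at the threshold: a voxel with partial volume exactly 0.95
#' belongs to the mask ("probability 0.95 or higher").
#'
#' @param pv numeric array of tissue fractions in `[0, 1]`.
#' @param threshold inclusion threshold, default 0.95.
#' @return Logical array.
#' @export
threshold_pv <- function(pv, threshold = 0.95) {
  if (any(pv < -1e-9 | pv > 1 + 1e-9, na.rm = TRUE)) {
    stop("partial volumes must lie in [0, 1]", call. = FALSE)
  }
  mask <- !is.na(pv) & pv >= threshold
  if (!any(mask)) warning("thresholded partial-volume mask is empty", call. = FALSE)
  mask
}

#' Tissue mask appropriate for a ROI's tissue class
#'
#' White-matter ROIs use the thresholded WM map and cortical grey ROIs the
#' thresholded GM map. Subcortical grey ROIs use the thresholded WM + GM sum:
#' much of subcortical grey segments as white matter, so a pure-GM mask would
#' empty those ROIs.
#'
#' @param tissue_class one of `"wm"`, `"subcortical_gm"`, `"cortical_gm"`.
#' @param pv list with partial-volume arrays `wm` and `gm`.
#' @param threshold inclusion threshold, default 0.95.
#' @return Logical array.
#' @export
tissue_mask_for <- function(tissue_class, pv, threshold = 0.95) {
  tissue_class <- match.arg(tissue_class, c("wm", "subcortical_gm", "cortical_gm"))
  switch(tissue_class,
    wm = threshold_pv(pv$wm, threshold),
    cortical_gm = threshold_pv(pv$gm, threshold),
    subcortical_gm = threshold_pv(pmin(pv$wm + pv$gm, 1), threshold)
  )
}

#' Extract per-ROI mean metric values into a tidy table
#'
#' For each ROI, averages the metric over the voxels of that ROI that also
#' pass the tissue mask of the ROI's class; invalid (`NA`) metric voxels are
#' excluded. ROIs that the masking empties are dropped from the table (and
#' reported via `message()` and the `"dropped"` attribute) rather than
#' emitted as `NaN` rows, which keeps downstream correlations
#' pairwise-complete.
#'
#' @param metric_map numeric array of the metric.
#' @param label_map integer array of ROI labels (0 = background).
#' @param roi_info tibble with `roi_id`, `roi_name`, `tissue_class`; rows
#'   whose class is not a brain tissue class (reference structures) are
#'   ignored.
#' @param pv list with partial-volume arrays `wm` and `gm`.
#' @param metric_name name recorded in the table.
#' @param subject_id subject identifier recorded in the table.
#' @param threshold partial-volume threshold.
#' @return Tibble with columns subject_id, roi_id, roi_name, tissue_class,
#'   metric_name, mean_value, voxel_count; class `roi_table`.
#' @export
extract_means <- function(metric_map, label_map, roi_info, pv,
                          metric_name, subject_id = "s01", threshold = 0.95) {
  check_same_dim(metric_map, label_map, pv$wm, pv$gm, what = "metric, labels and PV maps")
  rois <- dplyr::filter(roi_info, .data$tissue_class %in% .TISSUE_CLASSES)
  masks <- lapply(.TISSUE_CLASSES, tissue_mask_for, pv = pv, threshold = threshold)
  names(masks) <- .TISSUE_CLASSES

  rows <- purrr::pmap(
    list(rois$roi_id, rois$roi_name, rois$tissue_class),
    function(id, nm, cls) {
      sel <- label_map == id & masks[[cls]]
      vals <- metric_map[sel]
      vals <- vals[is.finite(vals)]
      tibble::tibble(
        subject_id = subject_id, roi_id = id, roi_name = nm,
        tissue_class = cls, metric_name = metric_name,
        mean_value = if (length(vals)) mean(vals) else NA_real_,
        voxel_count = length(vals)
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  dropped <- dplyr::filter(out, .data$voxel_count == 0)
  if (nrow(dropped) > 0) {
    message(sprintf(
      "extract_means: dropped %d ROI(s) emptied by masking for metric %s: %s",
      nrow(dropped), metric_name, paste(dropped$roi_name, collapse = ", ")
    ))
  }
  out <- dplyr::filter(out, .data$voxel_count > 0)
  attr(out, "dropped") <- dropped
  class(out) <- c("roi_table", class(out))
  out
}

#' Combine per-metric ROI tables
#'
#' @param ... `roi_table` tibbles.
#' @return A single `roi_table`.
#' @export
bind_roi_tables <- function(...) {
  out <- dplyr::bind_rows(...)
  class(out) <- unique(c("roi_table", class(out)))
  out
}
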