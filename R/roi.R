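# ROI-median extraction and report rendering. The canonical nine regions of
# the insect-brain protocol are AL (antennal lobe), Ax_tk (axonal tracts),
# CC (central complex), La (lamina), Lox (lobula complex), MB (mushroom
# body), Me (medulla), MN (midbrain neuropil) and Rt (retina); user-supplied
# mask sets may extend or replace them.

ROI_COLUMN_ORDER <- c("AL", "CC", "Rt", "Me", "MB", "La", "MN", "Lox", "Ax_tk")

#' Median scalar metrics per region of interest
#'
#' For each ROI mask, the median of FA, MD, MK and KA over voxels that are
#' both in the mask and in the fit mask (voxels where the model could not be
#' fitted are excluded rather than counted as zeros). An even voxel count
#' uses the mean of the central pair (the standard sample median).
#'
#' @param maps A `scalar_maps` object.
#' @param roi_masks Named list of logical 3-D arrays on the map grid.
#' @param sample_id Identifier recorded in the report rows.
#' @return A tibble: `sample`, `roi`, `metric`, `median`, `n_voxels`. ROIs
#'   lying entirely outside the fit mask report `NA` with a warning.
#' @export
extract_medians <- function(maps, roi_masks, sample_id = "sample1") {
  stopifnot(is.list(roi_masks), length(roi_masks) > 0)
  out <- list()
  for (nm in names(roi_masks)) {
    m <- roi_masks[[nm]]
    if (!identical(dim(m), maps$dims) && !identical(as.integer(dim(m)),
                                                    as.integer(maps$dims))) {
      abort(sprintf("ROI '%s' grid %s does not match maps grid %s", nm,
                    paste(dim(m), collapse = "x"),
                    paste(maps$dims, collapse = "x")),
            class = "microdki_geometry")
    }
    idx <- which(m & maps$mask)
    if (!length(idx)) {
      warn(sprintf("ROI '%s' has no voxels inside the fit mask", nm))
    }
    for (metric in c("FA", "MD", "MK", "KA")) {
      out[[length(out) + 1]] <- tibble(
        sample = sample_id, roi = nm, metric = metric,
        median = if (length(idx)) median(maps[[metric]][idx]) else NA_real_,
        n_voxels = length(idx))
    }
  }
  dplyr::bind_rows(out)
}

#' Render an ROI report as TSV or Markdown
#'
#' Lays the report out with ROIs as columns (canonical order AL, CC, Rt, Me,
#' MB, La, MN, Lox, Ax_tk; extra ROIs appended alphabetically) and
#' metric-by-sample rows. MD is rendered in scientific notation as
#' `a x 10^-3 mm^2/s`; empty cells render as "NA".
#'
#' @param report Tibble from [extract_medians()].
#' @param format "tsv" or "markdown".
#' @return A character vector of lines (invisibly printable with
#'   `writeLines`).
#' @export
render_report <- function(report, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  stopifnot(nrow(report) > 0)
  rois <- unique(report$roi)
  rois <- c(intersect(ROI_COLUMN_ORDER, rois),
            sort(setdiff(rois, ROI_COLUMN_ORDER)))
  fmt_cell <- function(metric, value) {
    if (is.na(value)) return("NA")
    if (metric == "MD") sprintf("%.2f x 10^-3", value * 1e3)
    else sprintf("%.2f", value)
  }
  lines <- character(0)
  header <- c("sample", "metric", rois)
  sep <- if (format == "tsv") "\t" else " | "
  wrap <- function(cells) {
    if (format == "tsv") paste(cells, collapse = "\t")
    else paste0("| ", paste(cells, collapse = " | "), " |")
  }
  lines <- c(lines, wrap(header))
  if (format == "markdown") {
    lines <- c(lines, wrap(rep("---", length(header))))
  }
  for (sm in unique(report$sample)) {
    for (metric in unique(report$metric)) {
      row <- vapply(rois, function(r) {
        v <- report$median[report$sample == sm & report$roi == r &
                           report$metric == metric]
        if (!length(v)) "NA" else fmt_cell(metric, v[1])
      }, character(1))
      lines <- c(lines, wrap(c(sm, metric, row)))
    }
  }
  lines
}

#' Plot ROI medians
#' @param object Tibble from [extract_medians()].
#' @param ... Unused.
#' @return A ggplot object, one panel per metric.
#' @export
plot_roi_report <- function(object, ...) {
  object$roi <- factor(object$roi,
                       levels = c(intersect(ROI_COLUMN_ORDER,
                                            unique(object$roi)),
                                  sort(setdiff(unique(object$roi),
                                               ROI_COLUMN_ORDER))))
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$roi, .data$median, fill = .data$sample)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "median") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Read ROI masks from NIfTI files
#' @param paths Named character vector of NIfTI paths (names become ROI
#'   names).
#' @return Named list of logical arrays.
#' @export
read_roi_masks <- function(paths) {
  masks <- lapply(paths, function(p) {
    img <- RNifti::readNifti(p)
    array(as.array(img) > 0.5, dim(img))
  })
  names(masks) <- names(paths)
  masks
}
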