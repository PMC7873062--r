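# Deterministic streamline tractography over the fitted principal-direction
# field. Seeds are drawn uniformly at random (seeded RNG) from the FA mask;
# each seed grows bidirectionally by fixed Euler steps along the
# interpolated, sign-aligned eigenvector; streamlines are gated by FA,
# per-step turning angle and total length.

#' Tracking parameters
#'
#' Defaults match a large-tract-focused deterministic protocol: FA threshold
#' 0.15, angle threshold 45 degrees, step 0.05 mm, length range
#' 0.31 to 50 mm, 5000 target streamlines, cubic interpolation. The
#' alternative minimum length 0.18 mm is available as
#' `tracking_params(min_length_mm = 0.18)`.
#'
#' @param fa_threshold FA tracking/stopping threshold in [0, 1].
#' @param angle_threshold_deg Maximum turning angle per step, degrees.
#' @param step_mm Euler step, mm.
#' @param min_length_mm,max_length_mm Kept-length range, mm.
#' @param n_tracts_target Number of streamlines to keep.
#' @param interpolation "cubic" (Keys convolution) or "trilinear".
#' @param seed RNG seed for seeding.
#' @param max_seed_factor Seed budget as a multiple of the target.
#' @return A `tracking_params` list.
#' @export
tracking_params <- function(fa_threshold = 0.15, angle_threshold_deg = 45,
                            step_mm = 0.05, min_length_mm = 0.31,
                            max_length_mm = 50, n_tracts_target = 5000,
                            interpolation = c("cubic", "trilinear"),
                            seed = 1L, max_seed_factor = 100) {
  interpolation <- match.arg(interpolation)
  stopifnot(fa_threshold >= 0, fa_threshold <= 1,
            angle_threshold_deg > 0, angle_threshold_deg <= 90,
            step_mm > 0, min_length_mm < max_length_mm)
  structure(list(fa_threshold = fa_threshold,
                 angle_threshold_deg = angle_threshold_deg,
                 step_mm = step_mm, min_length_mm = min_length_mm,
                 max_length_mm = max_length_mm,
                 n_tracts_target = as.integer(n_tracts_target),
                 interpolation = interpolation, seed = as.integer(seed),
                 max_seed_factor = max_seed_factor),
            class = "tracking_params")
}

#' Deterministic Euler streamline tracking
#'
#' @param maps A `scalar_maps` object (FA and principal-eigenvector field),
#'   or a list with elements `FA` (3-D array) and `e1` (4-D array).
#' @param params A [tracking_params()].
#' @param voxel_mm Voxel dimensions, mm.
#' @return A `tractogram`: `streamlines` (list of n x 3 matrices, mm),
#'   `lengths` (mm), `seed_index`, `params`, `voxel_mm`, `dims`. If no voxel
#'   passes the FA threshold an empty tractogram is returned with a warning.
#' @export
track <- function(maps, params = tracking_params(),
                  voxel_mm = c(1, 1, 1)) {
  fa <- maps$FA
  e1 <- maps$e1
  dm <- dim(fa)
  mask_idx <- which(fa >= params$fa_threshold)
  if (!length(mask_idx)) {
    warn("no voxel passes the FA threshold; empty tractogram")
    return(empty_tractogram(params, voxel_mm, dm))
  }
  n_seeds <- params$n_tracts_target * params$max_seed_factor
  set.seed(params$seed)
  sv <- sample(mask_idx, n_seeds, replace = TRUE)
  co <- arrayInd(sv, dm)
  jitter <- matrix(runif(3 * n_seeds, -0.5, 0.5), n_seeds, 3)
  seeds_mm <- sweep(co - 0.5 + jitter, 2, voxel_mm, `*`)
  res <- track_cpp(as.numeric(fa), as.numeric(e1), as.integer(dm),
                   as.numeric(voxel_mm), seeds_mm,
                   params$fa_threshold, params$angle_threshold_deg,
                   params$step_mm, params$min_length_mm,
                   params$max_length_mm, params$n_tracts_target,
                   params$interpolation == "cubic")
  sl <- res$streamlines
  lens <- vapply(sl, function(m) (nrow(m) - 1) * params$step_mm, numeric(1))
  structure(list(streamlines = sl, lengths = lens,
                 seed_index = res$seed_index, params = params,
                 voxel_mm = voxel_mm, dims = dm),
            class = "tractogram")
}

empty_tractogram <- function(params = tracking_params(),
                             voxel_mm = c(1, 1, 1), dims = c(0L, 0L, 0L)) {
  structure(list(streamlines = list(), lengths = numeric(0),
                 seed_index = integer(0), params = params,
                 voxel_mm = voxel_mm, dims = dims),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  cat(sprintf("tractogram: %d streamlines", length(x$streamlines)))
  if (length(x$lengths)) {
    cat(sprintf(", length %.3g-%.3g mm (median %.3g)",
                min(x$lengths), max(x$lengths), median(x$lengths)))
  }
  cat("\n")
  invisible(x)
}

#' Per-streamline summary of a tractogram
#' @param x A `tractogram`.
#' @param ... Unused.
#' @return A tibble: streamline, n_points, length_mm, seed_index.
#' @export
tidy.tractogram <- function(x, ...) {
  tibble(streamline = seq_along(x$streamlines),
         n_points = vapply(x$streamlines, nrow, integer(1)),
         length_mm = x$lengths,
         seed_index = as.integer(x$seed_index))
}

#' Interpolate the principal-direction field at a point
#'
#' Componentwise cubic (Keys) or trilinear interpolation with per-voxel sign
#' alignment to a reference direction before blending; the result is
#' renormalised unless `renormalize = FALSE` (useful to verify that
#' antipodally stored neighbours do not average to a shortened vector).
#'
#' @param e1 4-D eigenvector array (x, y, z, component).
#' @param point_mm Length-3 position, mm.
#' @param ref_dir Incoming direction for sign alignment.
#' @param method "cubic" or "trilinear".
#' @param voxel_mm Voxel dimensions, mm.
#' @param renormalize Return a unit vector?
#' @return Length-3 vector; `NA`s when the point is outside the grid (a
#'   boundary signal, not an error).
#' @export
interpolate_direction <- function(e1, point_mm, ref_dir = c(1, 0, 0),
                                  method = c("cubic", "trilinear"),
                                  voxel_mm = c(1, 1, 1), renormalize = TRUE) {
  method <- match.arg(method)
  dm <- dim(e1)[1:3]
  interp_dir_cpp(as.numeric(e1), as.integer(dm), as.numeric(voxel_mm),
                 as.numeric(point_mm), as.numeric(ref_dir),
                 method == "cubic", renormalize)
}

#' Filter streamlines by a region of interest
#'
#' @param tract A `tractogram`.
#' @param roi_mask Logical 3-D array on the tracking grid.
#' @param mode "pass-through" keeps streamlines with any point in the mask;
#'   "endpoint" keeps streamlines whose first or last point is in the mask.
#' @return A filtered `tractogram`.
#' @export
roi_filter_tracts <- function(tract, roi_mask,
                              mode = c("pass-through", "endpoint")) {
  mode <- match.arg(mode)
  if (!any(roi_mask)) {
    warn("empty ROI mask; no streamlines kept")
    keep <- logical(length(tract$streamlines))
  } else {
    dm <- dim(roi_mask)
    in_mask <- function(pts) {
      vox <- floor(sweep(pts, 2, tract$voxel_mm, `/`)) + 1
      ok <- vox[, 1] >= 1 & vox[, 1] <= dm[1] &
            vox[, 2] >= 1 & vox[, 2] <= dm[2] &
            vox[, 3] >= 1 & vox[, 3] <= dm[3]
      hit <- logical(nrow(pts))
      hit[ok] <- roi_mask[vox[ok, , drop = FALSE]]
      hit
    }
    keep <- vapply(tract$streamlines, function(m) {
      if (mode == "endpoint") m <- m[c(1, nrow(m)), , drop = FALSE]
      any(in_mask(m))
    }, logical(1))
  }
  tract$streamlines <- tract$streamlines[keep]
  tract$lengths <- tract$lengths[keep]
  tract$seed_index <- tract$seed_index[keep]
  tract
}

#' Plot a tractogram projection
#' @param object A `tractogram`.
#' @param plane "xy", "xz" or "yz".
#' @param max_streamlines Subsample for plotting speed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tractogram <- function(object, plane = "xy",
                                max_streamlines = 500, ...) {
  ax <- switch(plane, xy = c(1, 2), xz = c(1, 3), yz = c(2, 3))
  sl <- object$streamlines
  if (length(sl) > max_streamlines) sl <- sl[seq_len(max_streamlines)]
  df <- purrr::map_dfr(seq_along(sl), function(i) {
    tibble(id = i, a = sl[[i]][, ax[1]], b = sl[[i]][, ax[2]])
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, group = .data$id)) +
    ggplot2::geom_path(alpha = 0.3, linewidth = 0.2) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = paste0(substr(plane, 1, 1), " (mm)"),
                  y = paste0(substr(plane, 2, 2), " (mm)")) +
    ggplot2::theme_minimal()
}
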