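# Scalar maps derived from the fitted tensors: FA, MD, AD, RD from the
# diffusion tensor's eigen-system; MK and KA by averaging the apparent
# kurtosis over a dense, approximately uniform direction set.

#' Diffusion-tensor scalar indices for one voxel
#'
#' Eigen-decomposes the symmetric tensor (eigenvalues sorted descending,
#' negatives clamped to zero before any scalar is computed) and returns
#' fractional anisotropy, mean/axial/radial diffusivity and the principal
#' eigenvector.
#'
#' @param d6 Diffusion tensor as a 6-vector (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
#' @return A tibble: `FA`, `MD`, `AD`, `RD`, `l1`, `l2`, `l3`, `e1x`, `e1y`,
#'   `e1z`, `clamped` (number of negative eigenvalues clamped), `degenerate`.
#' @export
#' @examples
#' tensor_scalars(c(1.5, 0.5, 0.5, 0, 0, 0) * 1e-3)$FA # ~0.603
tensor_scalars <- function(d6) {
  es <- eigen(dt6_to_matrix(d6), symmetric = TRUE)
  lam <- es$values # descending
  clamped <- sum(lam < 0)
  lam <- pmax(lam, 0)
  md <- mean(lam)
  nl <- sqrt(sum(lam^2))
  degenerate <- nl == 0
  fa <- if (degenerate) 0 else sqrt(3 / 2) * sqrt(sum((lam - md)^2)) / nl
  tibble(FA = fa, MD = md, AD = lam[1], RD = (lam[2] + lam[3]) / 2,
         l1 = lam[1], l2 = lam[2], l3 = lam[3],
         e1x = es$vectors[1, 1], e1y = es$vectors[2, 1], e1z = es$vectors[3, 1],
         clamped = clamped, degenerate = degenerate)
}

#' Mean kurtosis and kurtosis anisotropy for one voxel
#'
#' Evaluates the apparent kurtosis K_app(n) on a dense direction set from the
#' fitted (D, W) pair. MK is the arithmetic mean over directions ("the
#' average kurtosis along all directions"); KA is the population standard
#' deviation of the same directional samples.
#'
#' @param d6 Diffusion tensor, 6-vector.
#' @param w15 Kurtosis tensor, 15 unique elements.
#' @param directions Matrix of unit direction vectors (>= 60 recommended);
#'   default [sphere_directions()] with `n_dir` points.
#' @param n_dir Size of the default direction set.
#' @param k_min,k_max Directional K_app samples are projected into this range
#'   before averaging (same projection rule as the fitters).
#' @param ka_normalized If `TRUE`, KA is reported relative to MK (the
#'   literature's alternative definition); the default is the plain standard
#'   deviation of directional kurtosis.
#' @return A tibble: `MK`, `KA`, `undefined` (degenerate D).
#' @export
kurtosis_scalars <- function(d6, w15, directions = NULL, n_dir = 724,
                             k_min = 0, k_max = K_APP_MAX_DEFAULT,
                             ka_normalized = FALSE) {
  if (is.null(directions)) directions <- sphere_directions(n_dir)
  md <- mean(d6[1:3])
  if (md <= 0) {
    return(tibble(MK = NA_real_, KA = NA_real_, undefined = TRUE))
  }
  k <- apparent_kurtosis(directions, d6, w15)
  k <- pmin(pmax(k, k_min), k_max)
  mk <- mean(k)
  ka <- sqrt(mean((k - mk)^2))
  if (ka_normalized) ka <- if (mk > 0) ka / mk else 0
  tibble(MK = mk, KA = ka, undefined = FALSE)
}

#' Compute all six scalar maps from a voxelwise fit
#'
#' Applies [tensor_scalars()] and [kurtosis_scalars()] to every in-mask
#' voxel; out-of-mask voxels are zero-filled. The principal-eigenvector map
#' is returned for tractography and for directionally-encoded-colour
#' rendering.
#'
#' @param fit A `dki_fit` from [fit_dki_volume()].
#' @param directions Direction set for MK/KA; default `n_dir`-point sphere.
#' @param n_dir Default direction-set size.
#' @return A `scalar_maps` object: 3-D arrays `FA`, `MD`, `AD`, `RD`, `MK`,
#'   `KA`; 4-D array `e1` (x, y, z, component); `mask`; `voxel_mm` (taken
#'   from the fit if present); `display_range_diffusivity` (0 to 3e-3
#'   mm^2/s, the conventional display window); `clamp_count`.
#' @export
compute_scalar_maps <- function(fit, directions = NULL, n_dir = 724) {
  stopifnot(inherits(fit, "dki_fit"))
  if (is.null(directions)) directions <- sphere_directions(n_dir)
  dm <- fit$dims
  nvox <- prod(dm)
  zero <- array(0, dm)
  maps <- list(FA = zero, MD = zero, AD = zero, RD = zero, MK = zero,
               KA = zero)
  e1 <- array(0, c(dm, 3))
  idx <- which(fit$mask)
  clamp_count <- 0L
  md_all <- rowMeans(fit$d[, 1:3, drop = FALSE])
  # directional kurtosis for all voxels at once: K matrix = (MD^2/Dapp^2)*W n^4
  if (length(idx)) {
    A6 <- dt6_design(directions)    # ndir x 6
    A15 <- w15_design(directions)   # ndir x 15
    dapp <- fit$d[idx, , drop = FALSE] %*% t(A6)   # nfit x ndir
    wq <- fit$w[idx, , drop = FALSE] %*% t(A15)
    for (j in seq_along(idx)) {
      v <- idx[j]
      ts <- tensor_scalars(fit$d[v, ])
      clamp_count <- clamp_count + ts$clamped
      maps$FA[v] <- ts$FA; maps$MD[v] <- ts$MD
      maps$AD[v] <- ts$AD; maps$RD[v] <- ts$RD
      e1[v] <- ts$e1x; e1[v + nvox] <- ts$e1y; e1[v + 2 * nvox] <- ts$e1z
      if (md_all[v] > 0) {
        k <- md_all[v]^2 / dapp[j, ]^2 * wq[j, ]
        k <- pmin(pmax(k, 0), K_APP_MAX_DEFAULT)
        maps$MK[v] <- mean(k)
        maps$KA[v] <- sqrt(mean((k - mean(k))^2))
      }
    }
  }
  structure(c(maps, list(e1 = e1, mask = fit$mask, dims = dm,
                         display_range_diffusivity = c(0, 3e-3),
                         clamp_count = clamp_count)),
            class = "scalar_maps")
}

#' @export
print.scalar_maps <- function(x, ...) {
  cat(sprintf("scalar_maps: %d x %d x %d; %d voxels in mask; %d eigenvalues clamped\n",
              x$dims[1], x$dims[2], x$dims[3], sum(x$mask), x$clamp_count))
  for (m in c("FA", "MD", "AD", "RD", "MK", "KA")) {
    v <- x[[m]][x$mask]
    if (length(v)) cat(sprintf("  %-2s median %.4g range [%.4g, %.4g]\n",
                               m, median(v), min(v), max(v)))
  }
  invisible(x)
}

#' Directionally encoded colour (DEC) map
#'
#' Maps the principal eigenvector to RGB (red = x, green = y, blue = z,
#' absolute components) modulated by FA.
#'
#' @param maps A `scalar_maps` object.
#' @return 4-D array (x, y, z, rgb) in [0, 1].
#' @export
dec_map <- function(maps) {
  rgb <- abs(maps$e1)
  for (c in 1:3) rgb[, , , c] <- rgb[, , , c] * pmin(maps$FA, 1)
  rgb
}

#' Write scalar maps as NIfTI volumes
#' @param maps A `scalar_maps` object.
#' @param dir Output directory.
#' @param voxel_mm Voxel dimensions for the NIfTI header.
#' @return Invisibly, named vector of paths.
#' @export
write_scalar_maps <- function(maps, dir, voxel_mm = c(1, 1, 1)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (m in c("FA", "MD", "AD", "RD", "MK", "KA")) {
    p <- file.path(dir, paste0(tolower(m), ".nii.gz"))
    img <- RNifti::asNifti(maps[[m]], pixdim = voxel_mm)
    RNifti::writeNifti(img, p)
    paths[m] <- p
  }
  p <- file.path(dir, "dec.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(dec_map(maps), pixdim = voxel_mm), p)
  paths["DEC"] <- p
  invisible(paths)
}

#' Plot one slice of a scalar map
#'
#' @param maps A `scalar_maps` object.
#' @param metric One of "FA", "MD", "AD", "RD", "MK", "KA".
#' @param slice Slice index (default: middle).
#' @return A ggplot object.
#' @export
plot_scalar_map <- function(maps, metric = "FA", slice = NULL) {
  stopifnot(metric %in% c("FA", "MD", "AD", "RD", "MK", "KA"))
  if (is.null(slice)) slice <- ceiling(maps$dims[3] / 2)
  m <- maps[[metric]][, , slice]
  df <- tibble(
    x = rep(seq_len(nrow(m)), ncol(m)),
    y = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.numeric(m)
  )
  lim <- if (metric %in% c("MD", "AD", "RD")) maps$display_range_diffusivity
         else NULL
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = lim, oob = scales_squish) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s, slice %d", metric, slice),
                  fill = metric) +
    ggplot2::theme_minimal()
}

# minimal squish so we need not depend on scales directly
scales_squish <- function(x, range = c(0, 1), ...) {
  pmin(pmax(x, range[1]), range[2])
}

#' @export
autoplot.scalar_maps <- function(object, metric = "FA", slice = NULL, ...) {
  plot_scalar_map(object, metric = metric, slice = slice)
}
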