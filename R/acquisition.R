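# Multi-shell PGSE acquisition: b-value/timing arithmetic and FSL-style
# gradient tables. The scheme object is the single source of truth for
# directions, b-values and pulse timing used by every other stage.

GAMMA_1H <- 2.6752e8 # rad s^-1 T^-1, proton

#' Diffusion weighting (b-value) of a pulsed-gradient spin-echo experiment
#'
#' The diffusion sensitisation of a PGSE sequence with gradient amplitude `G`,
#' pulse duration `delta` and pulse separation `Delta` is
#' \deqn{b = \gamma^2 G^2 \delta^2 \Delta}
#' under the narrow-pulse approximation (\eqn{\delta \ll \Delta}). When the
#' pulses are not narrow the effective diffusion time
#' \eqn{\tau = \Delta - \delta/3} replaces \eqn{\Delta}:
#' \deqn{b = \gamma^2 G^2 \delta^2 \tau.}
#'
#' @param gamma Gyromagnetic ratio, rad s^-1 T^-1 (default: proton).
#' @param G Gradient amplitude, T/m. May be a vector.
#' @param delta Gradient pulse duration, s.
#' @param Delta Pulse separation, s. Must exceed `delta`.
#' @param narrow_pulse If `TRUE`, use `Delta` as the diffusion time; otherwise
#'   use `tau = Delta - delta/3`.
#' @return b-value(s) in s/mm^2.
#' @export
#' @examples
#' compute_bvalue(G = 0.3, delta = 3.1e-3, Delta = 8.502e-3) # ~462 s/mm^2
compute_bvalue <- function(gamma = GAMMA_1H, G, delta, Delta,
                           narrow_pulse = FALSE) {
  if (any(gamma <= 0) || any(delta <= 0) || any(Delta <= 0)) {
    abort("timing and gamma must be positive", class = "microdki_invalid_parameter")
  }
  if (any(G < 0)) {
    abort("gradient amplitude must be nonnegative", class = "microdki_invalid_parameter")
  }
  if (delta >= Delta) {
    abort("pulse duration delta must be smaller than separation Delta",
          class = "microdki_invalid_parameter")
  }
  tdiff <- if (narrow_pulse) Delta else Delta - delta / 3
  gamma^2 * G^2 * delta^2 * tdiff * 1e-6 # s/m^2 -> s/mm^2
}

#' Gradient amplitude needed for a target b-value
#'
#' Inverse of [compute_bvalue()]; used by the phantom to populate the scheme's
#' per-volume gradient amplitudes from nominal shell b-values.
#' @inheritParams compute_bvalue
#' @param b Target b-value(s), s/mm^2.
#' @return Gradient amplitude(s), T/m.
#' @export
gradient_for_bvalue <- function(b, gamma = GAMMA_1H, delta, Delta,
                                narrow_pulse = FALSE) {
  tdiff <- if (narrow_pulse) Delta else Delta - delta / 3
  sqrt(b * 1e6 / (gamma^2 * delta^2 * tdiff))
}

#' Construct a multi-shell acquisition scheme
#'
#' @param bvalues Numeric vector of per-volume b-values, s/mm^2.
#' @param directions Matrix (n x 3) of gradient directions; rows for b0
#'   volumes may be zero. Non-zero rows are normalised to unit length.
#' @param delta,Delta Gradient pulse duration and separation, s.
#' @param gamma Gyromagnetic ratio, rad s^-1 T^-1.
#' @param b0_threshold b-values at or below this are treated as b0 (s/mm^2).
#' @param shell_tolerance b-values within this of each other share a shell.
#' @return An object of class `acquisition_scheme` with elements `table`
#'   (a tibble: volume, bvalue, gx, gy, gz, b0, shell), `delta`, `Delta`,
#'   `tau`, `gamma`, and `shells` (a tibble: shell, bvalue, n_directions).
#' @export
acquisition_scheme <- function(bvalues, directions,
                               delta = 3.1e-3, Delta = 8.502e-3,
                               gamma = GAMMA_1H,
                               b0_threshold = 50, shell_tolerance = 50) {
  directions <- as.matrix(directions)
  if (nrow(directions) != length(bvalues)) {
    abort("bvalues and directions disagree in length",
          class = "microdki_format_error")
  }
  if (any(bvalues < 0)) abort("b-values must be >= 0",
                              class = "microdki_invalid_parameter")
  if (delta >= Delta) abort("delta must be < Delta",
                            class = "microdki_invalid_parameter")
  b0 <- bvalues <= b0_threshold
  nrm <- sqrt(rowSums(directions^2))
  bad <- !b0 & abs(nrm - 1) > 1e-6
  if (any(bad)) directions[bad, ] <- directions[bad, , drop = FALSE] / nrm[bad]
  directions[b0, ] <- 0

  # shell detection: cluster the non-b0 b-values greedily within tolerance
  shell <- integer(length(bvalues))
  ub <- sort(unique(bvalues[!b0]))
  centers <- numeric(0)
  for (b in ub) {
    hit <- which(abs(centers - b) <= shell_tolerance)
    if (length(hit) == 0) centers <- c(centers, b)
  }
  if (length(centers)) {
    for (v in which(!b0)) {
      shell[v] <- which.min(abs(centers - bvalues[v]))
    }
  }
  tab <- tibble(
    volume = seq_along(bvalues),
    bvalue = as.numeric(bvalues),
    gx = directions[, 1], gy = directions[, 2], gz = directions[, 3],
    b0 = b0,
    shell = ifelse(b0, 0L, shell)
  )
  shells <- tab %>%
    filter(!.data$b0) %>%
    group_by(shell = .data$shell) %>%
    summarise(bvalue = centers[.data$shell[1]],
              n_directions = dplyr::n(), .groups = "drop")
  structure(
    list(table = tab, shells = shells,
         delta = delta, Delta = Delta, tau = Delta - delta / 3,
         gamma = gamma),
    class = "acquisition_scheme"
  )
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat(sprintf(
    "acquisition_scheme: %d volumes (%d b0), delta = %.4g ms, Delta = %.4g ms, tau = %.4g ms\n",
    nrow(x$table), sum(x$table$b0), x$delta * 1e3, x$Delta * 1e3, x$tau * 1e3))
  print(x$shells)
  invisible(x)
}

#' Read an FSL-style gradient table
#'
#' `bval` is one whitespace-separated row of b-values; `bvec` is three rows of
#' direction components (x, y, z) with one column per volume.
#'
#' @param bval_path,bvec_path Paths to the two text files.
#' @inheritParams acquisition_scheme
#' @return An [acquisition_scheme()].
#' @export
read_gradient_table <- function(bval_path, bvec_path,
                                delta = 3.1e-3, Delta = 8.502e-3,
                                gamma = GAMMA_1H,
                                b0_threshold = 50, shell_tolerance = 50) {
  parse_rows <- function(path, expected_rows) {
    ln <- readLines(path, warn = FALSE)
    ln <- ln[nzchar(trimws(ln))]
    if (length(ln) != expected_rows) {
      abort(sprintf("%s: expected %d row(s), found %d", path, expected_rows,
                    length(ln)), class = "microdki_format_error")
    }
    rows <- lapply(strsplit(trimws(ln), "\\s+"), function(tok) {
      v <- suppressWarnings(as.numeric(tok))
      if (anyNA(v)) abort(sprintf("%s: non-numeric token", path),
                          class = "microdki_format_error")
      v
    })
    do.call(rbind, rows)
  }
  bvals <- drop(parse_rows(bval_path, 1))
  bvecs <- parse_rows(bvec_path, 3)
  if (ncol(bvecs) != length(bvals)) {
    abort(sprintf("bval has %d volumes but bvec has %d", length(bvals),
                  ncol(bvecs)), class = "microdki_format_error")
  }
  acquisition_scheme(bvals, t(bvecs), delta = delta, Delta = Delta,
                     gamma = gamma, b0_threshold = b0_threshold,
                     shell_tolerance = shell_tolerance)
}

#' Write an acquisition scheme as FSL bval/bvec text files
#' @param scheme An [acquisition_scheme()].
#' @param bval_path,bvec_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_gradient_table <- function(scheme, bval_path, bvec_path) {
  tab <- scheme$table
  writeLines(paste(format(tab$bvalue, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  fmt <- function(v) paste(sprintf("%.10g", v), collapse = " ")
  writeLines(c(fmt(tab$gx), fmt(tab$gy), fmt(tab$gz)), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Voxel geometry from field of view and matrix size
#'
#' @param fov_mm In-plane field of view, length-2 (mm).
#' @param matrix_size In-plane acquisition matrix, length-2 (counts).
#' @param slice_thickness_mm Through-plane voxel extent (mm).
#' @param n_slices Number of slices.
#' @return A tibble with `voxel_x_mm`, `voxel_y_mm`, `voxel_z_mm`,
#'   `extent_z_mm`.
#' @export
#' @examples
#' voxel_geometry(c(7.5, 10), c(96, 128), 0.781, 35) # 0.078125 mm in-plane
voxel_geometry <- function(fov_mm, matrix_size, slice_thickness_mm = NULL,
                           n_slices = NULL) {
  if (any(fov_mm <= 0) || any(matrix_size <= 0)) {
    abort("FOV and matrix size must be positive",
          class = "microdki_invalid_parameter")
  }
  tibble(
    voxel_x_mm = fov_mm[1] / matrix_size[1],
    voxel_y_mm = fov_mm[2] / matrix_size[2],
    voxel_z_mm = slice_thickness_mm %||% NA_real_,
    extent_z_mm = if (!is.null(slice_thickness_mm) && !is.null(n_slices))
      n_slices * slice_thickness_mm else NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
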