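# Shared numerical helpers: direction sets, tensor index bookkeeping,
# rigid transforms and resampling. Everything here is deterministic.

#' Approximately uniform unit vectors on the sphere
#'
#' Deterministic spherical Fibonacci lattice. Used for the direction sets over
#' which mean kurtosis (MK) and kurtosis anisotropy (KA) are averaged, and to
#' build evenly spread acquisition shells for the digital phantom.
#'
#' @param n Number of points.
#' @param hemisphere If `TRUE`, points are folded onto the upper hemisphere
#'   (z >= 0); antipodal pairs are equivalent for even-order diffusion models.
#' @return An `n` x 3 matrix of unit row vectors.
#' @export
#' @examples
#' dirs <- sphere_directions(64)
#' range(rowSums(dirs^2)) # all 1
sphere_directions <- function(n, hemisphere = FALSE) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  m <- cbind(r * cos(phi), r * sin(phi), z)
  if (hemisphere) {
    flip <- m[, 3] < 0
    m[flip, ] <- -m[flip, ]
  }
  m / sqrt(rowSums(m^2))
}

# Unique-element index tables for the symmetric rank-2 tensor D (6 elements)
# and the fully symmetric rank-4 tensor W (15 elements), with multiplicities.
d6_index <- function() {
  cbind(i = c(1, 2, 3, 1, 1, 2),
        j = c(1, 2, 3, 2, 3, 3))
}

d6_mult <- c(1, 1, 1, 2, 2, 2)

w15_index <- function() {
  rbind(
    c(1, 1, 1, 1), c(2, 2, 2, 2), c(3, 3, 3, 3),
    c(1, 1, 1, 2), c(1, 1, 1, 3), c(1, 2, 2, 2),
    c(2, 2, 2, 3), c(1, 3, 3, 3), c(2, 3, 3, 3),
    c(1, 1, 2, 2), c(1, 1, 3, 3), c(2, 2, 3, 3),
    c(1, 1, 2, 3), c(1, 2, 2, 3), c(1, 2, 3, 3)
  )
}

w15_mult <- c(1, 1, 1, 4, 4, 4, 4, 4, 4, 6, 6, 6, 12, 12, 12)

#' Expand 6-vector to symmetric 3x3 diffusion tensor
#' @param d6 Numeric 6-vector ordered (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
#' @return 3x3 symmetric matrix.
#' @export
dt6_to_matrix <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}

#' Collapse symmetric 3x3 tensor to its 6 unique elements
#' @param m Symmetric 3x3 matrix.
#' @return 6-vector (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
#' @export
matrix_to_dt6 <- function(m) {
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}

# n' D n for a matrix of unit row-vectors and D in 6-vector form:
# returns the per-direction design block (length-6 rows, multiplicities baked in).
dt6_design <- function(dirs) {
  cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
        2 * dirs[, 1] * dirs[, 2],
        2 * dirs[, 1] * dirs[, 3],
        2 * dirs[, 2] * dirs[, 3])
}

# Quartic design block: sum over the 15 unique W elements with multiplicity.
w15_design <- function(dirs) {
  idx <- w15_index()
  out <- matrix(0, nrow(dirs), 15)
  for (k in seq_len(15)) {
    out[, k] <- w15_mult[k] *
      dirs[, idx[k, 1]] * dirs[, idx[k, 2]] * dirs[, idx[k, 3]] * dirs[, idx[k, 4]]
  }
  out
}

# Apparent diffusivity n'Dn per direction (dirs: m x 3, d6: 6-vector).
apparent_diffusivity <- function(dirs, d6) {
  drop(dt6_design(dirs) %*% d6)
}

# Apparent kurtosis per direction given D (6) and W (15):
# K_app(n) = MD^2 / D_app(n)^2 * sum W_ijkl n_i n_j n_k n_l
apparent_kurtosis <- function(dirs, d6, w15) {
  md <- mean(d6[1:3])
  dapp <- apparent_diffusivity(dirs, d6)
  wq <- drop(w15_design(dirs) %*% w15)
  md^2 / dapp^2 * wq
}

# Fully symmetric part of D (x) D as a 15-vector, scaled so that
# sum_ijkl W n^4 = (n'Dn)^2.  Used to build constant-K_app ground truths.
sym_outer_dd <- function(d6) {
  D <- dt6_to_matrix(d6)
  idx <- w15_index()
  w <- numeric(15)
  for (k in seq_len(15)) {
    p <- idx[k, ]
    w[k] <- (D[p[1], p[2]] * D[p[3], p[4]] +
             D[p[1], p[3]] * D[p[2], p[4]] +
             D[p[1], p[4]] * D[p[2], p[3]]) / 3
  }
  w
}

# Isotropic rank-4 tensor as 15-vector: sum_ijkl W n^4 = w0 for all unit n.
iso_w15 <- function(w0) {
  idx <- w15_index()
  w <- numeric(15)
  for (k in seq_len(15)) {
    p <- idx[k, ]
    d <- function(a, b) as.numeric(p[a] == p[b])
    w[k] <- w0 * (d(1, 2) * d(3, 4) + d(1, 3) * d(2, 4) + d(1, 4) * d(2, 3)) / 3
  }
  w
}

# --- rigid transforms ------------------------------------------------------

# Rotation matrix from small Euler angles (degrees), order Rz %*% Ry %*% Rx.
euler_rotation <- function(rx_deg = 0, ry_deg = 0, rz_deg = 0) {
  a <- rx_deg * pi / 180; b <- ry_deg * pi / 180; c <- rz_deg * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Rigidly resample a 3-D volume
#'
#' Pulls values from `vol` at the locations obtained by applying the inverse
#' rigid transform (rotation about the grid centre, then translation in
#' voxels) to each output voxel, with trilinear interpolation and zero
#' padding outside the grid.
#'
#' @param vol 3-D numeric array.
#' @param translation Length-3 translation in voxel units (applied to the
#'   image content; a +x translation moves the image towards +x).
#' @param rotation_deg Length-3 Euler angles in degrees (about x, y, z), image
#'   rotated about the grid centre.
#' @param interpolation "linear" (trilinear) or "cubic" (Keys convolution;
#'   sharper, used by the registration metric where interpolation blur would
#'   bias the optimum).
#' @return Resampled array of the same dimensions.
#' @export
rigid_resample <- function(vol, translation = c(0, 0, 0),
                           rotation_deg = c(0, 0, 0),
                           interpolation = c("linear", "cubic")) {
  interpolation <- match.arg(interpolation)
  dm <- dim(vol)
  stopifnot(length(dm) == 3)
  if (all(translation == 0) && all(rotation_deg == 0)) return(vol)
  R <- euler_rotation(rotation_deg[1], rotation_deg[2], rotation_deg[3])
  ctr <- (dm + 1) / 2
  out <- resample_rigid_cpp(as.numeric(vol), as.integer(dm),
                            as.numeric(t(R)), as.numeric(ctr),
                            as.numeric(translation),
                            interpolation == "cubic")
  array(out, dm)
}

# Trilinear interpolation of vol at fractional voxel coordinates (1-based),
# zero outside. pts: m x 3.
trilinear_sample <- function(vol, pts) {
  dm <- dim(vol)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  val <- numeric(nrow(pts))
  at <- function(i, j, k) {
    ok <- i >= 1 & i <= dm[1] & j >= 1 & j <= dm[2] & k >= 1 & k <= dm[3]
    v <- numeric(length(i))
    if (any(ok)) v[ok] <- vol[cbind(i[ok], j[ok], k[ok])]
    v
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
         (if (dz) fz else 1 - fz)
    val <- val + w * at(x0 + dx, y0 + dy, z0 + dz)
  }
  val
}

# Stable per-stage seed derivation from a single pipeline seed: keeps every
# stage individually reproducible while sharing one user-facing seed.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) + 97L * as.integer(h %% 21474L)) %% 2147483647L
}
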