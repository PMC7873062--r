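# Diffusion kurtosis estimation. Everything is linear least squares on the
# log-signal: the quadratic-exponential kurtosis model per direction, the
# full (D, W) tensor model over all shells, and the mono-exponential DTI
# limit. Constraints are applied by post-hoc projection, never by
# constrained optimisation, so fits stay linear and deterministic.

K_APP_MAX_DEFAULT <- 10

#' Fit the directional kurtosis signal model
#'
#' Least-squares fit of \eqn{\ln(S/S_0) = -b D_{app} + \tfrac16 b^2
#' D_{app}^2 K_{app}} along one gradient direction, solved as a linear
#' problem in \eqn{(c_1, c_2) = (D_{app}, D_{app}^2 K_{app}/6)} and then
#' \eqn{K_{app} = 6 c_2 / c_1^2}.
#'
#' @param b b-values, s/mm^2 (needs >= 3 distinct values including b ~ 0).
#' @param S Signal values, same length as `b`.
#' @param S0 Reference signal; if `NULL`, the mean of the b ~ 0 measurements.
#' @param b0_threshold b-values at or below this count as b0.
#' @param k_min,k_max Projection bounds for K_app.
#' @return A tibble: `D_app` (mm^2/s), `K_app`, `residual` (RMS of log-signal
#'   residuals), `clamped` (logical).
#' @export
fit_directional <- function(b, S, S0 = NULL, b0_threshold = 50,
                            k_min = 0, k_max = K_APP_MAX_DEFAULT) {
  if (length(unique(b)) < 3) {
    abort("need >= 3 distinct b-values", class = "microdki_underdetermined")
  }
  is0 <- b <= b0_threshold
  if (is.null(S0)) {
    if (!any(is0)) abort("no b ~ 0 measurement and no S0 given",
                         class = "microdki_underdetermined")
    S0 <- mean(S[is0])
  }
  use <- !is0 & S > 0
  if (sum(use) < 2) abort("need >= 2 positive diffusion-weighted signals",
                          class = "microdki_underdetermined")
  y <- log(S[use] / S0)
  X <- cbind(-b[use], b[use]^2 / 6)
  beta <- qr.solve(X, y)
  d_app <- beta[1]
  # second design column already carries the 1/6, so beta[2] = D_app^2 K_app
  k_app <- if (d_app > 0) beta[2] / d_app^2 else Inf
  clamped <- FALSE
  if (d_app < 0) { d_app <- 0; k_app <- 0; clamped <- TRUE }
  if (is.finite(k_app) && (k_app < k_min || k_app > k_max)) {
    k_app <- min(max(k_app, k_min), k_max); clamped <- TRUE
  }
  res <- sqrt(mean((y - drop(X %*% beta))^2))
  tibble(D_app = d_app, K_app = k_app, residual = res, clamped = clamped)
}

# Design matrix for the full kurtosis-tensor model: per volume,
# [ -b * (n'Dn terms, 6) | (b^2/6) * (quartic terms, 15) | 1 ].
# The 15 fitted quartic coefficients are Wtilde = MD^2 * W.
dki_design <- function(scheme) {
  tab <- scheme$table
  dirs <- cbind(tab$gx, tab$gy, tab$gz)
  b <- tab$bvalue
  cbind(-b * dt6_design(dirs), (b^2 / 6) * w15_design(dirs), 1)
}

check_dki_scheme <- function(scheme) {
  tab <- scheme$table
  nshell <- nrow(scheme$shells)
  ndir <- sum(!tab$b0)
  if (nrow(tab) < 21 || nshell < 2 || ndir < 15) {
    abort(sprintf(
      "kurtosis tensor fit needs >= 21 measurements over >= 2 shells and >= 15 directions; have %d measurements, %d shells, %d directions",
      nrow(tab), nshell, ndir), class = "microdki_conditioning")
  }
  X <- dki_design(scheme)
  if (qr(X)$rank < ncol(X)) {
    abort(sprintf(
      "rank-deficient kurtosis design (%d directions over %d shells give rank %d < 22)",
      ndir, nshell, qr(X)$rank), class = "microdki_conditioning")
  }
  X
}

#' Fit the diffusion kurtosis tensor in one voxel
#'
#' Weighted linear least squares of the log-signal on the 22-parameter
#' kurtosis-tensor design (6 diffusion-tensor elements, 15 kurtosis-tensor
#' elements scaled by MD^2, intercept ln S0). Two passes: the first
#' unweighted, the second weighted by the squared predicted signals of the
#' first (the standard heteroscedasticity correction for log-linearised
#' fits). The kurtosis tensor W is recovered by dividing the fitted quartic
#' coefficients by MD^2 from the same fit's diffusion part (one iteration).
#'
#' @param S Signal vector, one value per scheme volume.
#' @param scheme An [acquisition_scheme()].
#' @return A list: `s0`, `d6` (6-vector, mm^2/s), `w15` (15-vector),
#'   `neg_eigenvalues` (count), `residual`.
#' @export
fit_kurtosis_tensor <- function(S, scheme) {
  X <- check_dki_scheme(scheme)
  if (any(S <= 0)) abort("nonpositive signal: voxel must be masked",
                         class = "microdki_invalid_signal")
  y <- log(S)
  beta <- qr.solve(X, y)
  for (pass in 1) { # second, weighted pass
    w <- exp(2 * drop(X %*% beta))
    Xw <- X * sqrt(w)
    beta <- qr.solve(Xw, y * sqrt(w))
  }
  d6 <- beta[1:6]
  md <- mean(d6[1:3])
  w15 <- if (md > 0) beta[7:21] / md^2 else rep(0, 15)
  ev <- eigen(dt6_to_matrix(d6), symmetric = TRUE, only.values = TRUE)$values
  list(s0 = exp(beta[22]), d6 = d6, w15 = w15,
       neg_eigenvalues = sum(ev < 0),
       residual = sqrt(mean((y - drop(X %*% beta))^2)))
}

#' Fit the mono-exponential (DTI) model in one voxel
#'
#' Linear least squares of \eqn{\ln S} on the six diffusion-tensor terms plus
#' intercept, using only measurements with b below `max_b`. Over an extended
#' b-range in kurtotic tissue this model systematically underestimates
#' diffusivity because the positive quadratic kurtosis term is omitted.
#'
#' @param S Signal vector, one per scheme volume.
#' @param scheme An [acquisition_scheme()].
#' @param max_b Only measurements with b <= `max_b` enter the fit.
#' @return A list: `s0`, `d6`, `residual`.
#' @export
fit_dti <- function(S, scheme, max_b = Inf) {
  tab <- scheme$table
  keep <- tab$bvalue <= max_b & S > 0
  if (sum(keep) < 7 || length(unique(tab$bvalue[keep])) < 2) {
    abort(sprintf("DTI fit underdetermined: %d usable measurements under b <= %g",
                  sum(keep), max_b), class = "microdki_underdetermined")
  }
  dirs <- cbind(tab$gx, tab$gy, tab$gz)[keep, , drop = FALSE]
  b <- tab$bvalue[keep]
  X <- cbind(-b * dt6_design(dirs), 1)
  if (qr(X)$rank < 7) {
    abort("rank-deficient DTI design", class = "microdki_conditioning")
  }
  y <- log(S[keep])
  beta <- qr.solve(X, y)
  list(s0 = exp(beta[7]), d6 = beta[1:6],
       residual = sqrt(mean((y - drop(X %*% beta))^2)))
}

#' Fit the kurtosis tensor over a 4-D volume
#'
#' Applies [fit_kurtosis_tensor()] voxelwise. Voxels outside `mask`, and
#' voxels with any nonpositive signal, are excluded and flagged. The first
#' (unweighted) pass is solved for all voxels in one matrix operation; the
#' weighted pass is per voxel.
#'
#' @param dwi 4-D array (x, y, z, volume).
#' @param scheme An [acquisition_scheme()].
#' @param mask Optional logical 3-D array; default: voxels with positive
#'   signal in every volume.
#' @return A `dki_fit` object: matrices `d` (voxels x 6), `w` (voxels x 15),
#'   vectors `s0`, `residual`, logical array `mask`, `dims`, `scheme`, and a
#'   `diagnostics` list (masked-voxel and negative-eigenvalue counts).
#' @export
fit_dki_volume <- function(dwi, scheme, mask = NULL) {
  X <- check_dki_scheme(scheme)
  dm <- dim(dwi)
  stopifnot(length(dm) == 4, dm[4] == nrow(scheme$table))
  nvox <- prod(dm[1:3])
  sig <- matrix(dwi, nvox, dm[4])
  pos <- matrixStats_all_positive(sig)
  if (is.null(mask)) mask <- array(pos, dm[1:3]) else mask <- mask & array(pos, dm[1:3])
  idx <- which(mask)
  d <- matrix(0, nvox, 6); w <- matrix(0, nvox, 15)
  s0 <- numeric(nvox); resid <- numeric(nvox)
  neg_eig <- 0L
  if (length(idx)) {
    Y <- t(log(sig[idx, , drop = FALSE]))      # nvol x nfit
    qrX <- qr(X)
    B1 <- qr.coef(qrX, Y)                      # 22 x nfit, unweighted pass
    pred <- X %*% B1
    XtX_chol_solve <- function(Xw, yw) qr.solve(Xw, yw)
    for (j in seq_along(idx)) {
      sw <- exp(pred[, j])                     # predicted signals
      Xw <- X * sw
      beta <- XtX_chol_solve(Xw, Y[, j] * sw)
      v <- idx[j]
      d[v, ] <- beta[1:6]
      md <- mean(beta[1:3])
      w[v, ] <- if (md > 0) beta[7:21] / md^2 else 0
      s0[v] <- exp(beta[22])
      resid[v] <- sqrt(mean((Y[, j] - drop(X %*% beta))^2))
      ev <- eigen(dt6_to_matrix(beta[1:6]), symmetric = TRUE,
                  only.values = TRUE)$values
      if (any(ev < 0)) neg_eig <- neg_eig + 1L
    }
  }
  structure(list(d = d, w = w, s0 = s0, residual = resid, mask = mask,
                 dims = dm[1:3], scheme = scheme,
                 diagnostics = list(n_voxels = nvox, n_fitted = length(idx),
                                    n_masked = nvox - length(idx),
                                    n_negative_eigenvalues = neg_eig)),
            class = "dki_fit")
}

matrixStats_all_positive <- function(m) {
  # rowwise all(x > 0) without materialising a logical matrix twice
  out <- m[, 1] > 0
  for (j in seq_len(ncol(m))[-1]) out <- out & (m[, j] > 0)
  out
}

#' @export
print.dki_fit <- function(x, ...) {
  cat(sprintf("dki_fit: %d x %d x %d grid, %d/%d voxels fitted (%d masked)\n",
              x$dims[1], x$dims[2], x$dims[3], x$diagnostics$n_fitted,
              x$diagnostics$n_voxels, x$diagnostics$n_masked))
  cat(sprintf("  negative-eigenvalue voxels: %d\n",
              x$diagnostics$n_negative_eigenvalues))
  invisible(x)
}

#' Tidy a voxelwise kurtosis fit
#'
#' One row per fitted voxel with grid indices, S0, the six diffusion-tensor
#' and fifteen kurtosis-tensor elements, and the log-signal RMS residual.
#' @param x A `dki_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dki_fit <- function(x, ...) {
  idx <- which(x$mask)
  co <- arrayInd(idx, x$dims)
  dn <- paste0("d_", c("xx", "yy", "zz", "xy", "xz", "yz"))
  wi <- w15_index()
  wn <- paste0("w_", apply(wi, 1, paste, collapse = ""))
  out <- as_tibble(cbind(co, x$s0[idx], x$d[idx, , drop = FALSE],
                         x$w[idx, , drop = FALSE], x$residual[idx]),
                   .name_repair = "minimal")
  names(out) <- c("x", "y", "z", "s0", dn, wn, "residual")
  out
}

#' One-row summary of a voxelwise kurtosis fit
#' @param x A `dki_fit`.
#' @param ... Unused.
#' @return A tibble with voxel counts, masked count, negative-eigenvalue
#'   count and median residual.
#' @export
glance.dki_fit <- function(x, ...) {
  idx <- which(x$mask)
  tibble(n_voxels = x$diagnostics$n_voxels,
         n_fitted = x$diagnostics$n_fitted,
         n_masked = x$diagnostics$n_masked,
         n_negative_eigenvalues = x$diagnostics$n_negative_eigenvalues,
         median_residual = if (length(idx)) median(x$residual[idx]) else NA_real_)
}
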