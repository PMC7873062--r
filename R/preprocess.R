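# Preprocessing chain, applied in fixed order: Rician-aware non-local-means
# denoising, Gibbs-ringing removal by local subvoxel shifts, rigid
# eddy-current/misalignment correction against the mean b0 (with b-vector
# rotation). Each stage can be disabled; disabling all is bit-identical
# passthrough.

#' Estimate the Rician noise level of a magnitude volume
#'
#' With a background mask, uses the Rayleigh relation for signal-free
#' magnitude data: sigma = mean(background) / sqrt(pi/2). Without a mask,
#' takes the median local (3x3x3) standard deviation over low-signal voxels
#' (lowest quartile of local mean), corrected for the Rayleigh standard
#' deviation factor sqrt((4 - pi)/2).
#'
#' @param vol 3-D (or 4-D: first volume used) nonnegative array.
#' @param background_mask Optional logical array of signal-free voxels.
#' @return A tibble: `sigma`, `method`, `n_voxels`.
#' @export
estimate_rician_sigma <- function(vol, background_mask = NULL) {
  if (length(dim(vol)) == 4) vol <- vol[, , , 1]
  if (!is.null(background_mask)) {
    idx <- which(background_mask)
    if (!length(idx)) abort("empty background mask",
                            class = "microdki_estimation_error")
    return(tibble(sigma = mean(vol[idx]) / sqrt(pi / 2),
                  method = "background", n_voxels = length(idx)))
  }
  lm <- local_moments(vol)
  low <- lm$mean <= stats::quantile(lm$mean, 0.25)
  sig <- median(lm$sd[low]) / sqrt((4 - pi) / 2)
  tibble(sigma = sig, method = "local-variance", n_voxels = sum(low))
}

# local 3x3x3 mean and sd by shift-and-accumulate
local_moments <- function(vol) {
  dm <- dim(vol)
  s <- array(0, dm); s2 <- array(0, dm); n <- array(0, dm)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    xs <- pmin(pmax(seq_len(dm[1]) + dx, 1), dm[1])
    ys <- pmin(pmax(seq_len(dm[2]) + dy, 1), dm[2])
    zs <- pmin(pmax(seq_len(dm[3]) + dz, 1), dm[3])
    v <- vol[xs, ys, zs]
    s <- s + v; s2 <- s2 + v^2; n <- n + 1
  }
  m <- s / n
  list(mean = m, sd = sqrt(pmax(0, s2 / n - m^2)))
}

#' Rician-aware non-local-means denoising
#'
#' For every voxel, a weighted average over a search neighbourhood with
#' Gaussian weights on the patch distance (noise-compensated: the expected
#' patch distance 2 sigma^2 between identical noisy patches is subtracted
#' before weighting, bandwidth h = `h_factor` * sigma). The average is taken
#' over squared magnitudes and the Rician bias removed as
#' `sqrt(max(0, NL(x^2) - 2 sigma^2))`. `sigma = 0` returns the input
#' unchanged.
#'
#' @param vol 3-D or 4-D array (4-D is denoised volume by volume).
#' @param sigma Noise standard deviation.
#' @param patch_radius,search_radius Patch and search half-widths in voxels.
#' @param h_factor Bandwidth as a multiple of sigma.
#' @return Denoised array, same shape.
#' @export
nlmeans_rician <- function(vol, sigma, patch_radius = 1, search_radius = 3,
                           h_factor = 1) {
  stopifnot(sigma >= 0, patch_radius >= 1, search_radius >= 1)
  if (sigma == 0) return(vol)
  dm <- dim(vol)
  if (length(dm) == 4) {
    for (v in seq_len(dm[4])) {
      vol[, , , v] <- nlmeans_rician(vol[, , , v], sigma, patch_radius,
                                     search_radius, h_factor)
    }
    return(vol)
  }
  out <- nlmeans_rician_cpp(as.numeric(vol), as.integer(dm), sigma,
                            as.integer(patch_radius),
                            as.integer(search_radius), h_factor * sigma)
  array(out, dm)
}

#' Remove Gibbs ringing by local subvoxel shifts
#'
#' For every 1-D line of each axial slice, candidate subvoxel shifts are
#' evaluated through Fourier phase ramps; per voxel the shift minimising the
#' local total variation (oscillation) in a small window is selected and the
#' value linearly resampled from the shifted line. Applied separably along
#' both in-plane axes and averaged.
#'
#' @param vol 3-D or 4-D array.
#' @param n_shifts Number of candidate shifts in (-0.5, 0.5) voxels.
#' @param tv_window Half-width (voxels) of the oscillation window.
#' @return Corrected array, same shape.
#' @export
unring_gibbs <- function(vol, n_shifts = 64, tv_window = 3) {
  dm <- dim(vol)
  if (length(dm) == 4) {
    for (v in seq_len(dm[4])) {
      vol[, , , v] <- unring_gibbs(vol[, , , v], n_shifts, tv_window)
    }
    return(vol)
  }
  for (z in seq_len(dm[3])) {
    sl <- vol[, , z]
    a <- unring_lines(sl, n_shifts, tv_window)          # along x
    b <- t(unring_lines(t(sl), n_shifts, tv_window))    # along y
    vol[, , z] <- (a + b) / 2
  }
  vol
}

# subvoxel-shift unringing of every column of M (lines run down columns)
unring_lines <- function(M, n_shifts = 64, tv_window = 3) {
  n <- nrow(M)
  if (n < 4) return(M)
  Fm <- mvfft(M)
  k <- ifelse(seq_len(n) - 1 <= n / 2, seq_len(n) - 1, seq_len(n) - 1 - n)
  if (n %% 2 == 0) k[n / 2 + 1] <- 0 # drop un-pairable Nyquist phase
  shifts <- seq(-0.5, 0.5, length.out = n_shifts + 1)[-(n_shifts + 1)]
  best_osc <- matrix(Inf, n, ncol(M))
  best_val <- M
  pad_idx <- function(i) pmin(pmax(i, 1), n)
  for (s in shifts) {
    ramp <- exp(2i * pi * k * s / n)
    ls <- Re(mvfft(Fm * ramp, inverse = TRUE)) / n     # line sampled at x + s
    d <- abs(ls[-1, , drop = FALSE] - ls[-n, , drop = FALSE])
    dpad <- rbind(matrix(0, tv_window, ncol(M)), d,
                  matrix(0, tv_window, ncol(M)))
    cs <- apply(dpad, 2, cumsum)
    # total variation of the 2*tv_window diffs centred on each voxel
    osc <- cs[seq_len(n) + 2 * tv_window - 1, , drop = FALSE] -
      rbind(0, cs[seq_len(n - 1), , drop = FALSE])
    # resample the shifted line back to the integer grid
    nb <- if (s >= 0) pad_idx(seq_len(n) - 1) else pad_idx(seq_len(n) + 1)
    val <- (1 - abs(s)) * ls + abs(s) * ls[nb, , drop = FALSE]
    upd <- osc < best_osc
    best_osc[upd] <- osc[upd]
    best_val[upd] <- val[upd]
  }
  best_val
}

# normalized cross-correlation of two arrays
ncc <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

# 2x block-average downsampling
downsample2 <- function(vol) {
  dm <- dim(vol)
  nd <- pmax(1L, dm %/% 2L)
  idx <- arrayInd(seq_along(vol), dm)
  tgt <- pmin(t(ceiling(t(idx) / 2)), matrix(nd, nrow(idx), 3, byrow = TRUE))
  li <- (tgt[, 3] - 1) * nd[1] * nd[2] + (tgt[, 2] - 1) * nd[1] + tgt[, 1]
  sums <- rowsum(as.numeric(vol), li)
  cnts <- rowsum(rep(1, length(li)), li)
  out <- array(0, nd)
  out[as.integer(rownames(sums))] <- sums / cnts
  out
}

# similarity of reference transformed by (t, r) against the moving volume.
# The transform is split symmetrically — half forward on the reference, half
# inverse on the moving image — so the interpolation blur of resampling
# affects both images equally and cannot bias the optimum.
register_score <- function(ref, mov, tr, rot) {
  Rh <- euler_rotation(rot[1] / 2, rot[2] / 2, rot[3] / 2)
  a <- rigid_resample(ref, translation = tr / 2, rotation_deg = rot / 2,
                      interpolation = "cubic")
  b <- rigid_resample(mov, translation = -drop(t(Rh) %*% (tr / 2)),
                      rotation_deg = -rot / 2, interpolation = "cubic")
  ncc(a, b)
}

# separable 1-2-1 smoothing, applied `passes` times: regularises the NCC
# landscape so the quadratic refinement is well-behaved
blur121 <- function(vol, passes = 2) {
  dm <- dim(vol)
  for (i in seq_len(passes)) {
    for (ax in 1:3) {
      lo <- pmax(seq_len(dm[ax]) - 1, 1)
      hi <- pmin(seq_len(dm[ax]) + 1, dm[ax])
      vol <- switch(ax,
        (vol[lo, , , drop = FALSE] + 2 * vol + vol[hi, , , drop = FALSE]) / 4,
        (vol[, lo, , drop = FALSE] + 2 * vol + vol[, hi, , drop = FALSE]) / 4,
        (vol[, , lo, drop = FALSE] + 2 * vol + vol[, , hi, drop = FALSE]) / 4)
    }
  }
  vol
}

# estimate the rigid transform (translation voxels, rotation degrees) that
# maps `ref` onto `mov`: coarse integer translation grid on a smoothed,
# 2x-downsampled pair, then coordinate-wise quadratic refinement of all six
# parameters on the smoothed full-resolution pair (coarse-to-fine, entirely
# deterministic).
estimate_rigid <- function(ref, mov, max_shift = 3, coarse = TRUE,
                           steps = NULL) {
  refs <- blur121(ref)
  movs <- blur121(mov)
  best <- c(0, 0, 0)
  if (coarse) {
    refd <- downsample2(refs); movd <- downsample2(movs)
    bs <- -Inf
    rng <- seq(-ceiling(max_shift / 2), ceiling(max_shift / 2))
    zrng <- if (dim(refd)[3] >= 4) rng else 0
    for (tx in rng) for (ty in rng) for (tz in zrng) {
      s <- register_score(refd, movd, c(tx, ty, tz), c(0, 0, 0))
      if (s > bs) { bs <- s; best <- c(tx, ty, tz) }
    }
    best <- best * 2 # back to full resolution
  }
  par <- c(best, 0, 0, 0) # angles start at 0
  if (is.null(steps)) {
    steps <- list(c(1, 2), c(0.4, 0.8), c(0.15, 0.3), c(0.05, 0.1),
                  c(0.02, 0.05))
  }
  for (st in steps) {
    for (sweep in 1:2) {
      for (p in 1:6) {
        h <- if (p <= 3) st[1] else st[2]
        f <- function(delta) {
          q <- par; q[p] <- q[p] + delta
          register_score(refs, movs, q[1:3], q[4:6])
        }
        s0 <- f(0); sm <- f(-h); sp <- f(h)
        if (max(sm, sp) - s0 < 1e-7 && !(sm < s0 && sp < s0)) next
        denom <- sm - 2 * s0 + sp
        delta <- if (denom < 0) 0.5 * h * (sm - sp) / denom else
          h * (which.max(c(sm, s0, sp)) - 2)
        delta <- min(max(delta, -h), h)
        par[p] <- par[p] + delta
      }
    }
  }
  list(translation = par[1:3], rotation_deg = par[4:6],
       score = register_score(ref, mov, par[1:3], par[4:6]))
}

# voxelwise model prediction of every diffusion-weighted volume, used as the
# contrast-matched registration target: a volume is registered against an
# image with its own directional contrast, not against the b0, so
# directional signal differences between shells cannot bias the transform.
# Predictions are leave-one-out: volume v is predicted from a
# mono-exponential tensor fit that excludes v, so the prediction cannot
# absorb v's own misalignment (which would shrink the recovered transform
# towards zero). The deliberately low-order model keeps the leave-one-out
# problem well conditioned; the omitted kurtosis term is a per-shell
# magnitude offset that NCC is invariant to within homogeneous regions.
# Voxels with any nonpositive signal predict 0.
predict_volumes <- function(dwi, scheme, model = c("dti_loo", "quad_loo")) {
  model <- match.arg(model)
  dm <- dim(dwi)
  nvox <- prod(dm[1:3])
  sig <- matrix(dwi, nvox, dm[4])
  pos <- matrixStats_all_positive(sig)
  tab <- scheme$table
  dirs <- cbind(tab$gx, tab$gy, tab$gz)
  pred <- matrix(0, nvox, dm[4])
  if (!any(pos)) return(array(pred, dm))
  Y <- t(log(sig[pos, , drop = FALSE]))
  A6 <- dt6_design(dirs)
  X <- if (model == "quad_loo") {
    # quadratic-exponential model with the kurtosis term approximated by a
    # quadratic form in the direction: exact for directionally uniform
    # kurtosis, and only the small ell = 4 harmonic of K_app is missed
    cbind(-tab$bvalue * A6, (tab$bvalue^2 / 6) * A6, 1)
  } else {
    cbind(-tab$bvalue * A6, 1)
  }
  B_full <- qr.coef(qr(X), Y)
  for (v in which(!tab$b0)) {
    qv <- qr(X[-v, , drop = FALSE])
    B <- if (qv$rank == ncol(X)) qr.coef(qv, Y[-v, , drop = FALSE])
         else B_full
    pred[pos, v] <- exp(drop(X[v, , drop = FALSE] %*% B))
  }
  array(pred, dm)
}

#' Rigid eddy-current / misalignment correction
#'
#' Model-based rigid registration: a mono-exponential diffusion model is
#' fitted voxelwise to the current volumes and each diffusion-weighted
#' volume is registered (3 translations + 3 rotations) to its own predicted
#' image — a contrast-matched target, so the directional signal differences
#' between shells cannot bias the transform. The similarity metric is
#' normalized cross-correlation under symmetric cubic resampling, maximised
#' by an exhaustive coarse translation search on a downsampled pair followed
#' by deterministic quadratic refinement. Each volume is then resampled with
#' the inverse transform and its b-vector rotated by the recovered rotation.
#'
#' @param dwi 4-D array.
#' @param scheme An [acquisition_scheme()]; needs at least one b0 volume.
#' @param n_iter Maximum model/registration iterations. Each pass registers
#'   every volume to its model prediction and re-resamples from the
#'   *original* data under the accumulated transform (so interpolation blur
#'   never compounds); iteration stops early once no volume moves by more
#'   than 0.01 voxel / 0.01 degree.
#' @return A list: `dwi` (corrected 4-D array), `scheme` (with rotated
#'   b-vectors), `transforms` (tibble: volume, tx/ty/tz voxels, rx/ry/rz
#'   degrees, score; accumulated over iterations).
#' @export
correct_eddy <- function(dwi, scheme, n_iter = 3) {
  tab <- scheme$table
  if (!any(tab$b0)) abort("eddy correction needs at least one b0 volume",
                          class = "microdki_precondition")
  nvol <- dim(dwi)[4]
  orig <- dwi
  tf <- tibble(volume = seq_len(nvol), tx = 0, ty = 0, tz = 0,
               rx = 0, ry = 0, rz = 0, score = NA_real_)
  dirs <- cbind(tab$gx, tab$gy, tab$gz)
  fine <- list(c(0.15, 0.3), c(0.05, 0.1), c(0.02, 0.05))
  # Detection pass: every volume is registered to its leave-one-out
  # mono-exponential prediction (low order, so a grossly misaligned volume
  # cannot corrupt the predictions of the others). Corrections are applied
  # only above a deadband — the registration noise floor on this contrast;
  # sub-threshold corrections would add interpolation blur without
  # measurable benefit and, iterated, let the unconstrained collective
  # motion of the volume set drift.
  # Refinement passes: only the volumes that moved are re-registered, to
  # leave-one-out quadratic-exponential predictions recomputed from the
  # corrected data (these add the kurtosis curvature to the directional
  # contrast).
  deadband_t <- 0.25 # voxels
  deadband_r <- 0.75 # degrees
  dwvols <- which(!tab$b0)
  moved_set <- integer(0)
  for (iter in seq_len(n_iter)) {
    dwis <- dwi
    for (v in seq_len(nvol)) dwis[, , , v] <- blur121(dwi[, , , v])
    model <- if (iter == 1) "dti_loo" else "quad_loo"
    pred <- predict_volumes(dwis, scheme, model = model)
    targets <- if (iter == 1) dwvols else moved_set
    if (!length(targets)) break
    for (v in targets) {
      est <- estimate_rigid(pred[, , , v], dwis[, , , v],
                            coarse = (iter == 1),
                            steps = if (iter == 1) NULL else fine)
      tf[v, "score"] <- est$score
      if (iter == 1 && max(abs(est$translation)) < deadband_t &&
          max(abs(est$rotation_deg)) < deadband_r) next
      if (max(abs(est$translation)) < 0.005 &&
          max(abs(est$rotation_deg)) < 0.005) next
      moved_set <- union(moved_set, v)
      # accumulate: new content transform = residual o previous
      Rres <- euler_rotation(est$rotation_deg[1], est$rotation_deg[2],
                             est$rotation_deg[3])
      Rold <- euler_rotation(tf$rx[v], tf$ry[v], tf$rz[v])
      Rnew <- Rres %*% Rold
      tnew <- drop(Rres %*% c(tf$tx[v], tf$ty[v], tf$tz[v])) +
        est$translation
      # recover Euler angles of Rnew = Rz Ry Rx (row 3 = [-sin ry, ...])
      ry <- asin(max(-1, min(1, -Rnew[3, 1]))) * 180 / pi
      rx <- atan2(Rnew[3, 2], Rnew[3, 3]) * 180 / pi
      rz <- atan2(Rnew[2, 1], Rnew[1, 1]) * 180 / pi
      tf[v, c("tx", "ty", "tz")] <- as.list(tnew)
      tf[v, c("rx", "ry", "rz")] <- as.list(c(rx, ry, rz))
      # resample the original volume with the inverse accumulated transform
      dwi[, , , v] <- rigid_resample(orig[, , , v],
                                     translation = -drop(t(Rnew) %*% tnew),
                                     rotation_deg = -c(rx, ry, rz))
      dirs[v, ] <- drop(t(Rnew) %*% cbind(tab$gx, tab$gy, tab$gz)[v, ])
    }
  }
  newscheme <- acquisition_scheme(tab$bvalue, dirs, delta = scheme$delta,
                                  Delta = scheme$Delta, gamma = scheme$gamma)
  list(dwi = dwi, scheme = newscheme, transforms = tf)
}

#' Run the full preprocessing chain
#'
#' Fixed stage order: denoise, unring, eddy. Any stage can be disabled; with
#' all three disabled the input is returned bit-identically.
#'
#' @param dwi 4-D array.
#' @param scheme An [acquisition_scheme()].
#' @param denoise,unring,eddy Stage toggles.
#' @param sigma Noise level for denoising; `NULL` = estimate from the data.
#' @param patch_radius,search_radius,h_factor NLMeans parameters.
#' @return A list: `dwi`, `scheme`, `sigma`, `transforms` (or `NULL`).
#' @export
preprocess_dwi <- function(dwi, scheme, denoise = TRUE, unring = TRUE,
                           eddy = TRUE, sigma = NULL, patch_radius = 1,
                           search_radius = 3, h_factor = 1) {
  transforms <- NULL
  if (denoise) {
    if (is.null(sigma)) sigma <- estimate_rician_sigma(dwi)$sigma
    dwi <- nlmeans_rician(dwi, sigma, patch_radius, search_radius, h_factor)
  }
  if (unring) dwi <- unring_gibbs(dwi)
  if (eddy) {
    ec <- correct_eddy(dwi, scheme)
    dwi <- ec$dwi; scheme <- ec$scheme; transforms <- ec$transforms
  }
  list(dwi = dwi, scheme = scheme, sigma = sigma, transforms = transforms)
}

#' Write per-volume rigid transforms as plain-text 4x4 matrices
#' @param transforms Tibble from [correct_eddy()].
#' @param path Output file; matrices are stacked, one blank line between.
#' @return Invisibly, `path`.
#' @export
write_transforms <- function(transforms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (v in seq_len(nrow(transforms))) {
    R <- euler_rotation(transforms$rx[v], transforms$ry[v], transforms$rz[v])
    M <- rbind(cbind(R, c(transforms$tx[v], transforms$ty[v],
                          transforms$tz[v])), c(0, 0, 0, 1))
    writeLines(sprintf("# volume %d", v), con)
    utils::write.table(format(M, digits = 10), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
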