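# Digital multi-shell DWI phantom with known ground-truth tensors.
#
# The phantom emulates a micro-imaging acquisition of a small (insect-like)
# brain: concentric anisotropic shells standing in for the optic-lobe
# neuropils (retina, lamina, medulla, lobula), a voxelwise-interleaved
# "chiasm" slab of crossing fibre populations, isotropic central blobs, a
# straight tract bundle for tractography geometry tests, and zero-signal
# "trachea" tubes (air gives no MR signal). Signals are generated from the
# quadratic-exponential kurtosis model itself, so noiseless fitting must
# recover every parameter to numerical precision — this is the pipeline's
# primary oracle.

#' Default multi-shell acquisition emulated by the phantom
#'
#' Three shells at b = 800/1800/2500 s/mm^2 with 6/8/12 evenly spread
#' directions, one b0 per shell (29 volumes, 26 diffusion directions),
#' delta/Delta = 3.1/8.502 ms.
#'
#' @inheritParams acquisition_scheme
#' @return An [acquisition_scheme()].
#' @export
locust_scheme <- function(delta = 3.1e-3, Delta = 8.502e-3, gamma = GAMMA_1H) {
  shells <- list(c(800, 6), c(1800, 8), c(2500, 12))
  bvals <- numeric(0)
  dirs <- matrix(0, 0, 3)
  for (s in shells) {
    bvals <- c(bvals, 0, rep(s[1], s[2]))
    dirs <- rbind(dirs, c(0, 0, 0), sphere_directions(s[2], hemisphere = TRUE))
  }
  acquisition_scheme(bvals, dirs, delta = delta, Delta = Delta, gamma = gamma)
}

#' Phantom specification
#'
#' @param grid_shape Length-3 voxel counts. The full-size mode (96 x 128 x 35)
#'   matches the emulated acquisition matrix; `small = TRUE` selects the fast
#'   32 x 32 x 8 test grid.
#' @param small Convenience switch for the small grid.
#' @param voxel_mm Length-3 voxel dimensions in mm (in-plane 0.078125 mm,
#'   slice thickness 0.781 mm).
#' @param s0 Tissue b0 signal (arbitrary units).
#' @param sigma Rician noise level as a fraction of `s0`. The default 0.05
#'   gives b0 SNR of about 20.
#' @param gibbs_keep Fraction of k-space retained per in-plane axis when the
#'   Gibbs-ringing artefact is simulated; 1 disables truncation.
#' @param misalign_mm Maximum per-volume rigid translation (mm) injected to
#'   emulate eddy-current misalignment; 0 disables.
#' @param misalign_deg Maximum per-volume in-plane rotation (degrees).
#' @param seed RNG seed for noise and misalignment draws.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(96, 128, 35), small = FALSE,
                         voxel_mm = c(0.078125, 0.078125, 0.781),
                         s0 = 1000, sigma = 0.05, gibbs_keep = 1,
                         misalign_mm = 0, misalign_deg = 0, seed = 42L) {
  if (small) grid_shape <- c(32, 32, 8)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4),
            sigma >= 0, gibbs_keep > 0, gibbs_keep <= 1)
  structure(list(grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
                 s0 = s0, sigma = sigma, gibbs_keep = gibbs_keep,
                 misalign_mm = misalign_mm, misalign_deg = misalign_deg,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Region recipe: eigenvalues (mm^2/s), principal-direction policy, kurtosis
# level and how the rank-4 tensor is built from it ("iso" = isotropic W, so
# K_app varies with direction and KA > 0; "const" = symmetrised D (x) D, so
# K_app is the same in every direction). Kurtosis levels are kept inside the
# monotone-decay range b*D_app*K_app < 3 at b = 2500 s/mm^2.
phantom_regions <- function() {
  tibble(
    label = 1:10,
    name = c("Rt", "La", "Ax_tk", "Me", "Lox", "MB", "AL", "MN", "CC", "bundle"),
    l1 = c(1.7, 1.6, 1.6, 0.9, 0.7, 0.8, 0.75, 0.65, 0.75, 1.7) * 1e-3,
    l2 = c(0.35, 0.4, 0.35, 0.35, 0.3, 0.4, 0.45, 0.45, 0.75, 0.3) * 1e-3,
    l3 = c(0.35, 0.4, 0.35, 0.35, 0.3, 0.4, 0.45, 0.45, 0.75, 0.3) * 1e-3,
    dir_policy = c("radial", "tangential", "chiasm", "tangential",
                   "tangential", "fixed_y", "fixed_y", "fixed_x", "none",
                   "fixed_x"),
    k_level = c(0.6, 0.7, 0.65, 1.4, 1.8, 1.2, 1.5, 1.6, 0.5, 0.7),
    w_policy = c("iso", "iso", "iso", "iso", "iso", "iso", "const", "const",
                 "const", "const")
  )
}

# Label volume: concentric elliptical rings in-plane, applied to every slice;
# small central blobs; a straight +x bundle bar; zero-signal trachea tubes
# (label 11). 0 = background (no signal).
phantom_labels <- function(grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  x <- matrix(seq_len(nx), nx, ny)
  y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  r <- sqrt(((x - cx) / (nx / 2))^2 + ((y - cy) / (ny / 2))^2)
  sl <- matrix(0L, nx, ny)
  sl[r <= 0.97] <- 8L                     # MN fills the interior by default
  sl[r > 0.72 & r <= 0.85] <- 1L          # Rt
  sl[r > 0.62 & r <= 0.72] <- 2L          # La
  sl[r > 0.52 & r <= 0.62] <- 3L          # Ax_tk chiasm slab
  sl[r > 0.40 & r <= 0.52] <- 4L          # Me
  sl[r > 0.28 & r <= 0.40] <- 5L          # Lox
  sl[r > 0.10 & r <= 0.20 & x > cx] <- 6L # MB
  sl[r > 0.10 & r <= 0.20 & x <= cx] <- 7L # AL
  sl[r <= 0.10] <- 9L                     # CC
  sl[r > 0.85] <- 0L                      # background ring outside Rt
  lab <- array(rep(sl, nz), dim = c(nx, ny, nz))
  # straight bundle: thin +x bar through the interior on the mid slices
  by <- round(cy + 0.24 * ny / 2); bw <- max(1L, round(ny / 32))
  bz <- unique(pmax(1L, pmin(nz, round(nz / 2) + (-1:1))))
  bx <- seq(from = max(1L, round(cx - 0.38 * nx / 2)),
            to = min(nx, round(cx + 0.38 * nx / 2)))
  lab[bx, by:(by + bw - 1L), bz] <- 10L
  # trachea: air tube along z (zero signal, label 11). The air region
  # (label 12) extends one voxel beyond the labelled tube: the outer shell
  # is partial-volume air, and it keeps the interpolated FA gate below
  # threshold before a streamline can reach a labelled trachea voxel.
  aw <- max(1L, round(nx / 32))
  tx <- round(cx - 0.46 * nx / 2); ty <- round(cy)
  xs <- max(1L, tx - aw):min(nx, tx + aw)
  ys <- max(1L, ty - aw):min(ny, ty + aw)
  lab[xs, ys, ] <- 12L
  if (aw > 1) {
    lab[(tx - aw + 1L):(tx + aw - 1L), (ty - aw + 1L):(ty + aw - 1L), ] <- 11L
  } else {
    lab[tx, ty, ] <- 11L
  }
  lab
}

#' Build the phantom ground truth
#'
#' Produces per-voxel diffusion and kurtosis tensors, the b0 signal map, the
#' region label volume, and one binary ROI mask per named region (the nine
#' report ROIs: AL, Ax_tk, CC, La, Lox, MB, Me, MN, Rt).
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_truth` list: `label` (array), `S0` (array), `D`
#'   (voxels x 6 matrix), `W` (voxels x 15 matrix), `roi_masks` (named list
#'   of logical arrays), `trachea` (logical array), `regions` (tibble),
#'   `spec`.
#' @export
phantom_ground_truth <- function(spec) {
  gs <- spec$grid_shape
  lab <- phantom_labels(gs)
  nvox <- prod(gs)
  nx <- gs[1]; ny <- gs[2]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  vox <- arrayInd(seq_len(nvox), gs)
  dx <- vox[, 1] - cx; dy <- vox[, 2] - cy
  regions <- phantom_regions()

  D <- matrix(0, nvox, 6)
  W <- matrix(0, nvox, 15)
  S0 <- numeric(nvox)
  labv <- as.integer(lab)

  principal_dirs <- function(policy, ii) {
    n <- length(ii)
    e1 <- matrix(0, n, 3)
    if (policy == "radial") {
      v <- cbind(dx[ii], dy[ii], 0)
    } else if (policy == "tangential") {
      v <- cbind(-dy[ii], dx[ii], 0)
    } else if (policy == "chiasm") {
      # voxelwise-interleaved populations: tangent rotated +/- 45 deg
      ang <- atan2(dy[ii], dx[ii]) + pi / 2 +
        ifelse((vox[ii, 1] + vox[ii, 2] + vox[ii, 3]) %% 2 == 0,
               pi / 4, -pi / 4)
      v <- cbind(cos(ang), sin(ang), 0)
    } else if (policy == "fixed_x") {
      v <- matrix(rep(c(1, 0, 0), each = n), n, 3)
    } else if (policy == "fixed_y") {
      v <- matrix(rep(c(0, 1, 0), each = n), n, 3)
    } else { # none (isotropic)
      v <- matrix(rep(c(1, 0, 0), each = n), n, 3)
    }
    nrm <- sqrt(rowSums(v^2))
    zero <- nrm < 1e-12
    v[zero, ] <- matrix(rep(c(1, 0, 0), each = sum(zero)), ncol = 3)
    nrm[zero] <- 1
    v / nrm
  }

  for (k in seq_len(nrow(regions))) {
    rg <- regions[k, ]
    ii <- which(labv == rg$label)
    if (!length(ii)) next
    if (any(c(rg$l1, rg$l2, rg$l3) < 0)) {
      abort("negative ground-truth eigenvalue", class = "microdki_invalid_truth")
    }
    e1 <- principal_dirs(rg$dir_policy, ii)
    # e2 = z unless e1 is z-aligned (never here, policies are in-plane)
    e2 <- matrix(rep(c(0, 0, 1), each = length(ii)), ncol = 3)
    e3 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    # D = l1 e1e1' + l2 e2e2' + l3 e3e3', stored as 6 unique elements
    dt <- function(a, b) rg$l1 * e1[, a] * e1[, b] +
      rg$l2 * e2[, a] * e2[, b] + rg$l3 * e3[, a] * e3[, b]
    D[ii, ] <- cbind(dt(1, 1), dt(2, 2), dt(3, 3), dt(1, 2), dt(1, 3), dt(2, 3))
    S0[ii] <- spec$s0
    if (rg$w_policy == "iso") {
      W[ii, ] <- matrix(rep(iso_w15(rg$k_level), each = length(ii)),
                        ncol = 15)
    } else {
      md2 <- ((rg$l1 + rg$l2 + rg$l3) / 3)^2
      for (v in ii) W[v, ] <- rg$k_level * sym_outer_dd(D[v, ]) / md2
    }
  }
  # trachea: air, zero signal, zero tensors (already zero)

  # smooth multiplicative S0 texture (proton density / coil profile):
  # deterministic given the spec seed, recovered exactly by the fitters
  # (S0 is a per-voxel fitted parameter), and gives rigid registration the
  # irregular structure real tissue has
  set.seed(derive_seed(spec$seed, "s0texture"))
  tex <- array(rnorm(nvox), gs)
  for (i in 1:2) {
    for (ax in 1:3) {
      lo <- pmax(seq_len(gs[ax]) - 1, 1)
      hi <- pmin(seq_len(gs[ax]) + 1, gs[ax])
      tex <- switch(ax,
        (tex[lo, , , drop = FALSE] + 2 * tex + tex[hi, , , drop = FALSE]) / 4,
        (tex[, lo, , drop = FALSE] + 2 * tex + tex[, hi, , drop = FALSE]) / 4,
        (tex[, , lo, drop = FALSE] + 2 * tex + tex[, , hi, drop = FALSE]) / 4)
    }
  }
  tex <- tex / max(abs(tex))
  S0 <- S0 * (1 + 0.15 * as.numeric(tex))

  roi_names <- c("AL", "Ax_tk", "CC", "La", "Lox", "MB", "Me", "MN", "Rt")
  roi_masks <- lapply(roi_names, function(nm) {
    array(labv == regions$label[regions$name == nm], dim = gs)
  })
  names(roi_masks) <- roi_names

  structure(list(label = lab, S0 = array(S0, gs), D = D, W = W,
                 roi_masks = roi_masks,
                 trachea = array(labv == 11L, dim = gs),
                 regions = regions, spec = spec),
            class = "phantom_truth")
}

#' Synthesize noiseless DWI signals from ground truth
#'
#' Per voxel and diffusion direction n the signal follows the
#' quadratic-exponential kurtosis model
#' \deqn{S = S_0 \exp(-b D_{app} + \tfrac16 b^2 D_{app}^2 K_{app})}
#' with \eqn{D_{app} = n^T D n} and
#' \eqn{K_{app} = (MD^2/D_{app}^2) \sum W_{ijkl} n_i n_j n_k n_l}.
#' b0 volumes return S0 exactly.
#'
#' @param truth A [phantom_ground_truth()].
#' @param scheme An [acquisition_scheme()].
#' @param max_b Warn if the scheme exceeds this b-value (model validity).
#' @return 4-D array (x, y, z, volume).
#' @export
synthesize_signal <- function(truth, scheme, max_b = 3000) {
  tab <- scheme$table
  if (any(truth$D[, 1:3] < -1e-15)) {
    abort("ground-truth diffusion tensor has negative diagonal (not PSD)",
          class = "microdki_invalid_truth")
  }
  if (any(tab$bvalue > max_b)) {
    warn(sprintf("scheme contains b > %g s/mm^2; kurtosis model may be invalid",
                 max_b))
  }
  gs <- dim(truth$S0)
  nvox <- prod(gs)
  S0 <- as.numeric(truth$S0)
  md <- rowMeans(truth$D[, 1:3])
  out <- array(0, dim = c(gs, nrow(tab)))
  for (v in seq_len(nrow(tab))) {
    if (tab$b0[v]) {
      out[, , , v] <- truth$S0
      next
    }
    n <- matrix(c(tab$gx[v], tab$gy[v], tab$gz[v]), 1, 3)
    b <- tab$bvalue[v]
    dapp <- drop(truth$D %*% drop(dt6_design(n)))
    wq <- drop(truth$W %*% drop(w15_design(n)))
    # b^2/6 * D_app^2 * K_app = b^2/6 * MD^2 * sum(W n^4)
    expo <- -b * dapp + b^2 / 6 * md^2 * wq
    out[, , , v] <- array(S0 * exp(expo) * (S0 > 0), gs)
  }
  out
}

#' Add Rician noise to a volume
#'
#' Each value S is replaced by `sqrt((S + g1)^2 + g2^2)` with g1, g2 drawn
#' from Normal(0, sigma^2) — the magnitude of a complex signal with Gaussian
#' noise in each channel.
#'
#' @param vol Numeric array (any dimensionality).
#' @param sigma Noise standard deviation (signal units).
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @return Array of the same shape.
#' @export
add_rician_noise <- function(vol, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(vol)
  set.seed(as.integer(seed))
  g1 <- array(rnorm(length(vol), 0, sigma), dim(vol))
  g2 <- array(rnorm(length(vol), 0, sigma), dim(vol))
  sqrt((vol + g1)^2 + g2^2)
}

#' Simulate Gibbs ringing by k-space truncation
#'
#' Per axial slice: 2-D Fourier transform, zero all coefficients outside the
#' central `keep_fraction` of k-space along each in-plane axis, inverse
#' transform, magnitude.
#'
#' @param vol 3-D array (or 4-D; applied per volume).
#' @param keep_fraction Fraction of k-space retained per axis, in (0, 1].
#' @return Array of the same shape.
#' @export
apply_gibbs_truncation <- function(vol, keep_fraction) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  if (keep_fraction == 1) return(vol)
  dm <- dim(vol)
  if (length(dm) == 4) {
    for (v in seq_len(dm[4])) {
      vol[, , , v] <- apply_gibbs_truncation(vol[, , , v], keep_fraction)
    }
    return(vol)
  }
  keep_mask <- function(n) {
    k <- ifelse(seq_len(n) - 1 <= n / 2, seq_len(n) - 1, seq_len(n) - 1 - n)
    abs(k) <= keep_fraction * n / 2
  }
  mx <- keep_mask(dm[1]); my <- keep_mask(dm[2])
  mask2 <- outer(mx, my)
  for (z in seq_len(dm[3])) {
    F <- fft(vol[, , z])
    F[!mask2] <- 0
    vol[, , z] <- Mod(fft(F, inverse = TRUE)) / (dm[1] * dm[2])
  }
  vol
}

#' Apply a rigid misalignment to one volume
#'
#' Emulates eddy-current/motion misalignment: the volume content is shifted
#' and rotated with trilinear resampling. Truth offsets are what the eddy
#' corrector must recover.
#'
#' @param vol 3-D array.
#' @param translation_vox Length-3 translation in voxels.
#' @param rotation_deg Length-3 rotation in degrees (about x, y, z, grid
#'   centre).
#' @param fov_warn_fraction Warn if any translation exceeds this fraction of
#'   the grid.
#' @return Resampled array.
#' @export
apply_misalignment <- function(vol, translation_vox = c(0, 0, 0),
                               rotation_deg = c(0, 0, 0),
                               fov_warn_fraction = 0.1) {
  if (any(abs(translation_vox) > fov_warn_fraction * dim(vol))) {
    warn("misalignment exceeds 10% of the field of view")
  }
  rigid_resample(vol, translation = translation_vox,
                 rotation_deg = rotation_deg)
}

#' Generate the full phantom data set
#'
#' Runs ground truth construction, signal synthesis and the configured
#' artefact chain (Gibbs truncation, per-volume misalignment, Rician noise —
#' in acquisition-physics order: ringing is a reconstruction effect, noise is
#' added last on the magnitude image).
#'
#' @param spec A [phantom_spec()].
#' @param scheme An [acquisition_scheme()]; defaults to [locust_scheme()].
#' @return A list: `dwi` (4-D array), `truth`, `scheme`, `misalignments`
#'   (tibble of injected per-volume offsets: volume, tx/ty/tz voxels,
#'   rx/ry/rz degrees).
#' @export
make_phantom <- function(spec = phantom_spec(small = TRUE),
                         scheme = locust_scheme()) {
  truth <- phantom_ground_truth(spec)
  dwi <- synthesize_signal(truth, scheme)
  nvol <- dim(dwi)[4]
  mis <- tibble(volume = seq_len(nvol),
                tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0)
  if (spec$gibbs_keep < 1) {
    dwi <- apply_gibbs_truncation(dwi, spec$gibbs_keep)
  }
  if (spec$misalign_mm > 0 || spec$misalign_deg > 0) {
    set.seed(derive_seed(spec$seed, "misalign"))
    tmax <- spec$misalign_mm / spec$voxel_mm[1]
    for (v in seq_len(nvol)) {
      if (scheme$table$b0[v]) next # b0s stay put (registration reference)
      tr <- runif(2, -tmax, tmax)
      rz <- runif(1, -spec$misalign_deg, spec$misalign_deg)
      mis[v, c("tx", "ty", "rz")] <- as.list(c(tr, rz))
      dwi[, , , v] <- apply_misalignment(dwi[, , , v],
                                         translation_vox = c(tr, 0),
                                         rotation_deg = c(0, 0, rz))
    }
  }
  if (spec$sigma > 0) {
    dwi <- add_rician_noise(dwi, spec$sigma * spec$s0,
                            seed = derive_seed(spec$seed, "noise"))
  }
  list(dwi = dwi, truth = truth, scheme = scheme, misalignments = mis)
}

#' Write a phantom data set to disk
#'
#' Emits the 4-D DWI NIfTI, FSL bval/bvec, the label map and per-ROI binary
#' masks as NIfTI, and a plain-text ground-truth sidecar (per-voxel tensors
#' in TSV, plus seeds and injected misalignments) for recovery tests.
#'
#' @param phantom Result of [make_phantom()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of paths.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vx <- phantom$truth$spec$voxel_mm
  wn <- function(img, name) {
    p <- file.path(dir, name)
    RNifti::writeNifti(RNifti::asNifti(img, pixdim = vx), p)
    p
  }
  paths <- c(
    dwi = wn(phantom$dwi, "dwi.nii.gz"),
    label = wn(phantom$truth$label + 0, "labels.nii.gz")
  )
  for (nm in names(phantom$truth$roi_masks)) {
    paths[paste0("roi_", nm)] <-
      wn(phantom$truth$roi_masks[[nm]] + 0, paste0("roi_", nm, ".nii.gz"))
  }
  write_gradient_table(phantom$scheme, file.path(dir, "dwi.bval"),
                       file.path(dir, "dwi.bvec"))
  paths["bval"] <- file.path(dir, "dwi.bval")
  paths["bvec"] <- file.path(dir, "dwi.bvec")
  side <- file.path(dir, "ground_truth.tsv")
  gt <- cbind(as.data.frame(arrayInd(seq_len(prod(dim(phantom$truth$S0))),
                                     dim(phantom$truth$S0))),
              label = as.integer(phantom$truth$label),
              S0 = as.numeric(phantom$truth$S0),
              phantom$truth$D, phantom$truth$W)
  colnames(gt) <- c("x", "y", "z", "label", "S0",
                    paste0("D", seq_len(6)), paste0("W", seq_len(15)))
  utils::write.table(gt[gt$label > 0, ], side, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  paths["ground_truth"] <- side
  utils::write.table(as.data.frame(phantom$misalignments),
                     file.path(dir, "misalignments.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  paths["misalignments"] <- file.path(dir, "misalignments.tsv")
  invisible(paths)
}
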