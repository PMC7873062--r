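# phantom signal synthesis and artefact injection

test_that("synthesized signal matches the kurtosis model pointwise", {
  # isotropic Gaussian voxel: S = S0 exp(-b d) in every direction
  sch <- fx_scheme()
  spec <- phantom_spec(small = TRUE, sigma = 0)
  tr <- phantom_ground_truth(spec)
  v <- which(tr$label == 9)[1]                  # CC: isotropic
  co <- arrayInd(v, dim(tr$S0))
  dwi <- fx_phantom_clean()$dwi
  S <- dwi[co[1], co[2], co[3], ]
  d <- tr$D[v, 1]
  k <- 0.5                                      # CC kurtosis level
  pred <- tr$S0[v] * exp(-sch$table$bvalue * d +
                           sch$table$bvalue^2 / 6 * d^2 * k)
  expect_equal(S, pred, tolerance = 1e-12)
  # b0 volumes return S0 exactly
  expect_identical(S[sch$table$b0], rep(tr$S0[v], 3))
})

test_that("single-direction kurtosis signal values match direct evaluation", {
  # D_app = 1e-3, K_app = 1, b = 1000 -> S/S0 = exp(-1 + 1/6)
  d6 <- c(1, 1, 1, 0, 0, 0) * 1e-3
  w15 <- microdki:::iso_w15(1)
  sch <- acquisition_scheme(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  spec <- phantom_spec(grid_shape = c(4, 4, 4), sigma = 0)
  tr <- phantom_ground_truth(spec)
  tr$D[] <- rep(d6, each = nrow(tr$D))
  tr$W[] <- rep(w15, each = nrow(tr$W))
  tr$S0[] <- 1
  S <- synthesize_signal(tr, sch)
  expect_equal(S[1, 1, 1, 2], exp(-1 + 1 / 6), tolerance = 1e-12)
  expect_equal(S[1, 1, 1, 1], 1)
})

test_that("noiseless signals are positive, bounded by S0, and direction-symmetric", {
  ph <- fx_phantom_clean()
  tr <- ph$truth
  tissue <- tr$S0 > 0
  for (v in seq_len(dim(ph$dwi)[4])) {
    vol <- ph$dwi[, , , v]
    expect_true(all(vol[tissue] > 0))
    expect_true(all(vol[tissue] <= tr$S0[tissue] * (1 + 1e-12)))
  }
  # S(n) = S(-n): synthesize with flipped directions
  sch <- ph$scheme
  flipped <- acquisition_scheme(sch$table$bvalue,
                                -cbind(sch$table$gx, sch$table$gy, sch$table$gz),
                                delta = sch$delta, Delta = sch$Delta)
  S2 <- synthesize_signal(tr, flipped)
  expect_equal(ph$dwi, S2, tolerance = 1e-12)
})

test_that("isotropic-Gaussian voxels give direction-independent signal", {
  spec <- phantom_spec(grid_shape = c(4, 4, 4), sigma = 0)
  tr <- phantom_ground_truth(spec)
  tr$D[] <- rep(c(1, 1, 1, 0, 0, 0) * 1e-3, each = nrow(tr$D))
  tr$W[] <- 0
  tr$S0[] <- 1
  S <- synthesize_signal(tr, fx_scheme())
  tab <- fx_scheme()$table
  for (sh in 1:3) {
    idx <- which(tab$shell == sh)
    spread <- apply(S[, , , idx, drop = FALSE], 1:3,
                    function(x) diff(range(x)) / mean(x))
    expect_lt(max(spread), 1e-12)
  }
})

test_that("Rician noise has the Rayleigh mean on zero signal and is seed-stable", {
  z <- array(0, c(100, 100, 100))
  n1 <- add_rician_noise(z, 1, seed = 5)
  # Rayleigh mean = sigma sqrt(pi/2)
  expect_lt(abs(mean(n1) - sqrt(pi / 2)) / sqrt(pi / 2), 0.01)
  n2 <- add_rician_noise(z, 1, seed = 5)
  expect_identical(n1, n2)
  expect_identical(add_rician_noise(z, 0), z)
})

test_that("k-space truncation creates ringing and respects its identities", {
  dm <- c(48, 48, 2)
  box <- array(0, dm); box[12:36, 12:36, ] <- 100
  ring <- apply_gibbs_truncation(box, 0.6)
  # total variation along an edge-crossing profile strictly increases
  tv <- function(v) sum(abs(diff(v)))
  expect_gt(tv(ring[, 24, 1]), tv(box[, 24, 1]))
  # keep_fraction = 1 is the identity
  expect_equal(apply_gibbs_truncation(box, 1), box)
  # constant image only has the DC component
  const <- array(7, dm)
  expect_equal(apply_gibbs_truncation(const, 0.4), const, tolerance = 1e-10)
})

test_that("rigid misalignment moves content as prescribed", {
  dm <- c(21, 21, 9)
  spike <- array(0, dm); spike[11, 11, 5] <- 1
  sh <- apply_misalignment(spike, translation_vox = c(2, 0, 0))
  idx <- which(sh > 1e-9)
  co <- arrayInd(idx, dm)
  cx <- sum(co[, 1] * sh[idx]) / sum(sh[idx])
  expect_equal(cx, 13, tolerance = 1e-9)
  # zero offsets: identity
  expect_identical(apply_misalignment(spike), spike)
  # two half-voxel shifts vs one full voxel shift: difference bounded by
  # twice the single-resampling error, estimated against the analytic
  # (shifted Gaussian) oracle
  gauss <- function(sx) {
    co <- arrayInd(seq_len(prod(dm)), dm)
    array(exp(-((co[, 1] - 11 - sx)^2 + (co[, 2] - 11)^2 +
                  (co[, 3] - 5)^2) / 18), dm)
  }
  smooth <- gauss(0)
  half <- apply_misalignment(smooth, translation_vox = c(0.5, 0, 0))
  err_half <- max(abs(half - gauss(0.5))[5:17, 5:17, 2:8])
  expect_gt(err_half, 0) # a genuine, nonzero interpolation error bound
  twice <- apply_misalignment(half, translation_vox = c(0.5, 0, 0))
  once <- apply_misalignment(smooth, translation_vox = c(1, 0, 0))
  # two resamples accumulate at most ~2x the single-pass error (the second
  # pass acts on an already-smoothed field); 3x is a safe oracle bound
  expect_lt(max(abs(twice - once)[5:17, 5:17, 2:8]), 3 * err_half)
})

test_that("phantom ROI masks are binary, disjoint, and cover the named regions", {
  tr <- fx_phantom_clean()$truth
  expect_setequal(names(tr$roi_masks),
                  c("AL", "Ax_tk", "CC", "La", "Lox", "MB", "Me", "MN", "Rt"))
  tot <- Reduce(`+`, lapply(tr$roi_masks, function(m) m + 0))
  expect_true(all(tot <= 1))
  expect_true(all(vapply(tr$roi_masks, sum, numeric(1)) > 0))
  # D is PSD everywhere
  ev <- apply(tr$D[tr$S0 > 0, ], 1, function(d) {
    min(eigen(dt6_to_matrix(d), symmetric = TRUE, only.values = TRUE)$values)
  })
  expect_true(all(ev > -1e-15))
})

test_that("phantom writes a complete, re-readable artifact set", {
  d <- withr::local_tempdir()
  spec <- phantom_spec(grid_shape = c(12, 12, 4), sigma = 0)
  ph <- make_phantom(spec, fx_scheme())
  paths <- write_phantom(ph, d)
  expect_true(all(file.exists(paths)))
  img <- RNifti::readNifti(paths["dwi"])
  expect_equal(dim(img), c(12, 12, 4, 29))
  sch <- read_gradient_table(paths["bval"], paths["bvec"])
  expect_equal(sch$shells$n_directions, c(6, 8, 12))
  gt <- utils::read.table(paths["ground_truth"], header = TRUE, sep = "\t")
  expect_true(all(c("label", "S0", "D1", "W15") %in% names(gt)))
})
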