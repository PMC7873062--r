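# preprocessing chain: noise estimation, NLMeans, unringing, eddy correction

test_that("Rician sigma estimation recovers the true noise level", {
  # noiseless constant volume with a zero background
  vol <- array(0, c(20, 20, 8)); vol[5:15, 5:15, ] <- 100
  bg <- vol == 0
  expect_equal(estimate_rician_sigma(vol, bg)$sigma, 0)
  # pure Rician background, true sigma = 5
  z <- add_rician_noise(array(0, c(50, 50, 40)), 5, seed = 21)
  est <- estimate_rician_sigma(z, array(TRUE, dim(z)))
  expect_lt(abs(est$sigma - 5) / 5, 0.05)
  # scale equivariance
  est2 <- estimate_rician_sigma(z * 2, array(TRUE, dim(z)))
  expect_equal(est2$sigma, est$sigma * 2, tolerance = 1e-12)
  # maskless local-variance route lands close too
  noisy <- add_rician_noise(vol, 5, seed = 22)
  estl <- estimate_rician_sigma(noisy)
  expect_lt(abs(estl$sigma - 5) / 5, 0.30)
  expect_error(estimate_rician_sigma(vol, array(FALSE, dim(vol))),
               class = "microdki_estimation_error")
})

test_that("NLMeans denoising reduces RMSE by at least 40% at 10% noise", {
  truth <- array(50, c(24, 24, 8)); truth[6:18, 6:18, 3:6] <- 150
  sigma <- 0.10 * 100
  noisy <- add_rician_noise(truth, sigma, seed = 23)
  den <- nlmeans_rician(noisy, sigma)
  rmse_in <- sqrt(mean((noisy - truth)^2))
  rmse_out <- sqrt(mean((den - truth)^2))
  expect_lt(rmse_out, 0.6 * rmse_in)
  # sigma = 0 is the identity
  expect_identical(nlmeans_rician(noisy, 0), noisy)
  # repeated application (with the residual noise level re-estimated, as in
  # real use) does not move further from a constant image
  const <- array(80, c(16, 16, 6))
  n1 <- nlmeans_rician(add_rician_noise(const, 8, seed = 24), 8)
  sig2 <- estimate_rician_sigma(n1)$sigma
  n2 <- nlmeans_rician(n1, sig2)
  expect_lte(sqrt(mean((n2 - const)^2)), sqrt(mean((n1 - const)^2)) + 1e-9)
})

test_that("unringing reduces edge oscillation and leaves clean images alone", {
  dm <- c(48, 48, 2)
  box <- array(0, dm); box[12:36, 12:36, ] <- 100
  ring <- apply_gibbs_truncation(box, 0.6)
  unr <- unring_gibbs(ring)
  tv <- function(img) sum(abs(diff(img[, 24, 1]))) + sum(abs(diff(img[24, , 1])))
  expect_lt(tv(unr), tv(ring))
  # smooth ringing-free image: < 1% RMS change
  sm <- array(outer(sin(seq(0, pi, length.out = 48)),
                    cos(seq(0, 2, length.out = 48))), dm) + 2
  expect_lt(sqrt(mean((unring_gibbs(sm) - sm)^2)) / sqrt(mean(sm^2)), 0.01)
  # constant image unchanged
  const <- array(5, dm)
  expect_equal(unring_gibbs(const), const, tolerance = 1e-10)
})

test_that("eddy correction recovers injected rigid misalignments and rotates b-vectors", {
  ph <- fx_phantom_clean()
  dwi <- ph$dwi
  true_t <- c(1.5, -0.8, 0)
  true_r <- 3
  dwi[, , , 3] <- apply_misalignment(dwi[, , , 3], translation_vox = true_t)
  dwi[, , , 5] <- apply_misalignment(dwi[, , , 5],
                                     rotation_deg = c(0, 0, true_r))
  ec <- correct_eddy(dwi, ph$scheme)
  tf <- ec$transforms
  expect_lt(max(abs(c(tf$tx[3], tf$ty[3], tf$tz[3]) - true_t)), 0.1)
  expect_lt(abs(tf$rz[5] - true_r), 0.3)
  expect_lt(max(abs(c(tf$rx[5], tf$ry[5]))), 0.3)
  # b-vector of the rotated volume is rotated consistently with the truth
  Rtrue <- microdki:::euler_rotation(0, 0, true_r)
  g_old <- unlist(ph$scheme$table[5, c("gx", "gy", "gz")])
  g_expect <- drop(t(Rtrue) %*% g_old)
  g_new <- unlist(ec$scheme$table[5, c("gx", "gy", "gz")])
  expect_gt(sum(g_new * g_expect), 0.9995)
  # eddy demands a b0
  nob0 <- acquisition_scheme(rep(1000, 29),
                             sphere_directions(29))
  expect_error(correct_eddy(dwi, nob0), class = "microdki_precondition")
  # untouched volumes stay put
  others <- setdiff(which(!ph$scheme$table$b0), c(3, 5))
  expect_lt(max(abs(as.matrix(tf[others, c("tx", "ty", "tz")]))), 0.3)
})

test_that("disabling all preprocessing stages is bit-identical passthrough", {
  ph <- fx_phantom_noisy()
  pp <- preprocess_dwi(ph$dwi, ph$scheme, denoise = FALSE, unring = FALSE,
                       eddy = FALSE)
  expect_identical(pp$dwi, ph$dwi)
  expect_identical(pp$scheme$table, ph$scheme$table)
})

test_that("stages preserve shape and nonnegativity", {
  ph <- fx_phantom_noisy()
  sub <- ph$dwi[, , , 1:4, drop = FALSE]
  den <- nlmeans_rician(sub, 0.02 * 1000)
  expect_identical(dim(den), dim(sub))
  expect_true(all(den >= 0))
  unr <- unring_gibbs(sub[, , , 1])
  expect_identical(dim(unr), dim(sub)[1:3])
})

test_that("transform files are valid stacked 4x4 matrices", {
  tf <- tibble::tibble(volume = 1:2, tx = c(0, 1.5), ty = 0, tz = 0,
                       rx = 0, ry = 0, rz = c(0, 3), score = 1)
  f <- withr::local_tempfile()
  write_transforms(tf, f)
  ln <- readLines(f)
  expect_equal(sum(grepl("^# volume", ln)), 2)
  m <- do.call(rbind, strsplit(trimws(ln[!grepl("^#", ln)]), "\\s+"))
  expect_equal(dim(m), c(8, 4))
})
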