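# cumulant oracle and the kurtosis / DTI fitters

test_that("excess kurtosis from samples matches closed-form references", {
  set.seed(101)
  # Gaussian: K = 0
  kg <- excess_kurtosis_from_samples(rnorm(1e6))
  expect_lt(abs(kg$K), 0.02)
  # Laplace: mu4/mu2^2 = 6 -> K = 3
  lap <- function(n) {
    u <- runif(n) - 0.5
    -sign(u) * log(1 - 2 * abs(u))
  }
  kl <- excess_kurtosis_from_samples(lap(1e6))
  expect_lt(abs(kl$K - 3), 0.1)
  # symmetric two-point distribution: mu4 = mu2^2 -> K = -2
  k2 <- excess_kurtosis_from_samples(rep(c(-1, 1), 50))
  expect_equal(k2$K, -2)
  # cumulant identities
  expect_equal(k2$kappa1, k2$mu1)
  expect_equal(k2$kappa2, k2$mu2)
  expect_error(excess_kurtosis_from_samples(rep(1, 10)),
               class = "microdki_degenerate")
  expect_error(excess_kurtosis_from_samples(c(1, 2)),
               class = "microdki_underdetermined")
})

test_that("propagator signal is the characteristic function of the displacement EAP", {
  Delta <- 8.502e-3 - 3.1e-3 / 3
  D <- 1e-3
  q <- seq(0, 60, length.out = 8)[-1]
  sig <- signal_from_propagator(gaussian_propagator(D, Delta), q, Delta,
                                n_samples = 4e5, seed = 9)
  # Gaussian propagator: ln S = -b D with b = Delta (2 pi q)^2
  slope <- -coef(lm(log(sig$signal) ~ 0 + sig$b))[[1]]
  expect_lt(abs(slope - D) / D, 0.02)
  # q = 0 normalisation and vanishing imaginary part
  s0 <- signal_from_propagator(gaussian_propagator(D, Delta), 0, Delta,
                               n_samples = 1e4, seed = 9)
  expect_equal(s0$signal, 1)
  expect_lt(max(abs(sig$signal_imag)), 5e-3)
})

test_that("kappa4 of the isotropic propagator equals 4 K D^2 Delta^2", {
  Delta <- 7.468667e-3
  f <- 0.5; D1 <- 0.5e-3; D2 <- 1.5e-3
  set.seed(31)
  R <- bigaussian_propagator(f, D1, D2, Delta)(2e6)
  ck <- excess_kurtosis_from_samples(R)
  Dbar <- (D1 + D2) / 2
  # kappa2 = 2 Dbar Delta, and kappa4 = K kappa2^2 = 4 K Dbar^2 Delta^2
  expect_rel_equal(ck$kappa2, 2 * Dbar * Delta, tol = 0.01)
  expect_rel_equal(ck$kappa4, 4 * ck$K * Dbar^2 * Delta^2, tol = 0.05)
})

test_that("directional fit inverts the generating model exactly and respects the DTI limit", {
  b <- c(0, 800, 1800, 2500)
  d <- 0.7e-3; k <- 1.2
  S <- exp(-b * d + b^2 / 6 * d^2 * k)
  fit <- fit_directional(b, S)
  expect_rel_equal(fit$D_app, d, tol = 1e-10)
  expect_rel_equal(fit$K_app, k, tol = 1e-10)
  # mono-exponential signals: K_app = 0
  S0k <- exp(-b * d)
  fit0 <- fit_directional(b, S0k)
  expect_rel_equal(fit0$D_app, d, tol = 1e-10)
  expect_lt(abs(fit0$K_app), 1e-10)
  # PDF contract of the fitted model: variance = D_app^2 K_app / 3
  expect_equal(fit$D_app^2 * fit$K_app / 3, d^2 * k / 3, tolerance = 1e-8)
  expect_error(fit_directional(c(800, 800, 800), c(1, 1, 1)),
               class = "microdki_underdetermined")
})

test_that("bi-Gaussian mixture: fitted K_app agrees with the cumulant oracle and closed form", {
  f <- 0.5; D1 <- 0.5e-3; D2 <- 1.5e-3
  closed <- mixture_kurtosis(c(f, 1 - f), c(D1, D2))
  expect_equal(closed, 0.75)
  # propagator-sampled estimate (Eq. 2 route)
  Delta <- 7.468667e-3
  set.seed(17)
  R <- bigaussian_propagator(f, D1, D2, Delta)(2e6)
  k_mc <- excess_kurtosis_from_samples(R)$K
  expect_lt(abs(k_mc - closed) / closed, 0.05)
  # signal-domain fit inside the cumulant expansion's low-b regime
  # (b Dbar K <= ~0.6); the quadratic truncation is unbiased only there
  b <- seq(0, 800, length.out = 5)
  S <- biexponential_signal(b, f, D1, D2)
  fit <- fit_directional(b, S)
  expect_lt(abs(fit$K_app - closed) / closed, 0.05)
  expect_lt(abs(fit$K_app - k_mc) / k_mc, 0.05)
  # over the full acquisition b-range the omitted higher cumulants bias the
  # quadratic fit low — a systematic, sign-stable truncation error
  bfull <- c(0, 800, 1800, 2500)
  kfull <- fit_directional(bfull, biexponential_signal(bfull, f, D1, D2))$K_app
  expect_lt(kfull, fit$K_app)
})

test_that("tensor fit recovers all 21 parameters to numerical precision", {
  ph <- fx_phantom_clean()
  fit <- fx_fit_clean()
  tr <- ph$truth
  idx <- which(fit$mask)
  expect_gt(length(idx), 100)
  dscale <- max(abs(tr$D))
  wscale <- max(abs(tr$W))
  expect_lt(max(abs(fit$d[idx, ] - tr$D[idx, ])) / dscale, 1e-8)
  expect_lt(max(abs(fit$w[idx, ] - tr$W[idx, ])) / wscale, 1e-8)
  expect_lt(max(abs(fit$s0[idx] - tr$S0[idx]) / tr$S0[idx]), 1e-8)
  # directional and tensor fits agree along every acquisition direction
  tab <- ph$scheme$table
  dirs <- cbind(tab$gx, tab$gy, tab$gz)[!tab$b0, ]
  v <- idx[1]
  dapp_tensor <- microdki:::apparent_diffusivity(dirs, fit$d[v, ])
  co <- arrayInd(v, fit$dims)
  for (j in c(1, 10, 20)) {
    n1 <- dirs[j, ]
    sub <- !tab$b0 & abs(tab$gx * n1[1] + tab$gy * n1[2] + tab$gz * n1[3]) > 0.9999
    bsub <- c(0, tab$bvalue[sub])
    Ssub <- c(tr$S0[v], ph$dwi[co[1], co[2], co[3], ][sub])
    if (length(bsub) >= 3 && length(unique(bsub)) >= 3) {
      fd <- fit_directional(bsub, Ssub)
      expect_rel_equal(fd$D_app, dapp_tensor[j], tol = 1e-8)
    }
  }
})

test_that("isotropic Gaussian voxel fits to W = 0 and D = d I", {
  sch <- fx_scheme()
  d6 <- c(1, 1, 1, 0, 0, 0) * 1e-3
  tab <- sch$table
  dirs <- cbind(tab$gx, tab$gy, tab$gz)
  S <- 500 * exp(-tab$bvalue * 1e-3)
  fit <- fit_kurtosis_tensor(S, sch)
  expect_rel_equal(fit$d6, d6, tol = 1e-10)
  expect_lt(max(abs(fit$w15)), 1e-10)
  expect_equal(fit$s0, 500, tolerance = 1e-8)
})

test_that("tensor fit under Rician noise keeps directional diffusivity bias small", {
  sch <- fx_scheme()
  tr <- fx_phantom_clean()$truth
  # medulla voxel: representative attenuation (the strongly attenuating
  # outer shells drop to the Rician noise floor at b = 2500, where no
  # unbiased fit is possible without the denoising stage)
  v <- which(tr$label == 4)[3]
  tab <- sch$table
  dirs <- cbind(tab$gx, tab$gy, tab$gz)
  S_true <- {
    co <- arrayInd(v, dim(tr$S0))
    fx_phantom_clean()$dwi[co[1], co[2], co[3], ]
  }
  dapp_true <- microdki:::apparent_diffusivity(dirs[!tab$b0, ], tr$D[v, ])
  reps <- 200
  est <- matrix(0, reps, sum(!tab$b0))
  for (r in seq_len(reps)) {
    Sn <- as.numeric(add_rician_noise(array(S_true, c(1, 1, 1, 29)),
                                      0.02 * tr$S0[v], seed = 1000 + r))
    f <- fit_kurtosis_tensor(Sn, sch)
    est[r, ] <- microdki:::apparent_diffusivity(dirs[!tab$b0, ], f$d6)
  }
  bias <- abs(apply(est, 2, median) - dapp_true) / dapp_true
  expect_lt(max(bias), 0.05)
})

test_that("DTI fit is exact for Gaussian voxels and biased low for kurtotic ones", {
  sch <- fx_scheme()
  tab <- sch$table
  # Gaussian voxel: exact recovery at any max_b
  S <- 300 * exp(-tab$bvalue * 0.8e-3)
  f <- fit_dti(S, sch)
  expect_rel_equal(f$d6[1:3], rep(0.8e-3, 3), tol = 1e-10)
  # kurtotic voxels over the full b-range: diffusivity underestimated
  ph <- fx_phantom_clean()
  tr <- ph$truth
  idx <- which(tr$S0 > 0)
  set.seed(4)
  sub <- sample(idx, 50)
  signs <- vapply(sub, function(v) {
    co <- arrayInd(v, dim(tr$S0))
    fd <- fit_dti(ph$dwi[co[1], co[2], co[3], ], sch, max_b = 2500)
    mean(fd$d6[1:3]) - mean(tr$D[v, 1:3])
  }, numeric(1))
  expect_true(all(signs < 0))
  # empty selection after the max_b filter
  expect_error(fit_dti(S, sch, max_b = -1),
               class = "microdki_underdetermined")
})

test_that("rank-deficient or insufficient designs raise conditioning errors", {
  # single shell: too few shells for the kurtosis design
  one <- acquisition_scheme(c(0, rep(1000, 21)),
                            rbind(c(0, 0, 0), sphere_directions(21)))
  expect_error(fit_kurtosis_tensor(rep(1, 22), one),
               class = "microdki_conditioning")
  expect_error(fit_kurtosis_tensor(c(-1, rep(1, 28)), fx_scheme()),
               class = "microdki_invalid_signal")
})

test_that("volume fit masks nonpositive voxels and reports tidy/glance tables", {
  ph <- fx_phantom_clean()
  fit <- fx_fit_clean()
  g <- glance(fit)
  expect_equal(g$n_voxels, prod(fit$dims))
  expect_equal(g$n_fitted + g$n_masked, g$n_voxels)
  # trachea and background (zero signal) are masked out
  expect_true(all(!fit$mask[ph$truth$trachea]))
  td <- tidy(fit)
  expect_equal(nrow(td), g$n_fitted)
  expect_true(all(c("s0", "d_xx", "w_1111", "residual") %in% names(td)))
})
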