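# streamline tracking, direction interpolation, ROI gating, .trk format

test_that("uniform field in a slab yields straight streamlines spanning it", {
  sl <- fx_slab()
  p <- tracking_params(n_tracts_target = 300, seed = 3)
  tt <- track(sl, p, voxel_mm = sl$voxel_mm)
  expect_equal(length(tt$streamlines), 300)
  lateral <- vapply(tt$streamlines, function(m) {
    max(abs(m[, 2] - m[1, 2])) + max(abs(m[, 3] - m[1, 3]))
  }, numeric(1))
  expect_lt(max(lateral), 1e-6)
  # spans (nearly) the full 10 mm slab width
  spans <- vapply(tt$streamlines, function(m) diff(range(m[, 1])), numeric(1))
  expect_gt(min(spans), 9)
  # deterministic under the seed
  tt2 <- track(sl, p, voxel_mm = sl$voxel_mm)
  expect_identical(tt$streamlines, tt2$streamlines)
})

test_that("sub-threshold FA yields an empty tractogram with a warning", {
  sl <- fx_slab()
  sl$FA[sl$FA > 0] <- 0.1
  expect_warning(tt <- track(sl, tracking_params(n_tracts_target = 10),
                             voxel_mm = sl$voxel_mm),
                 "FA threshold")
  expect_equal(length(tt$streamlines), 0)
})

test_that("streamlines follow a quarter-circle arc without angle terminations", {
  # tangential field around the origin, radius ~2 mm, FA 0.5 inside an annulus
  dims <- c(60, 60, 7)
  vox <- 0.1
  fa <- array(0, dims)
  e1 <- array(0, c(dims, 3))
  idx <- arrayInd(seq_len(prod(dims[1:2])), dims[1:2])
  x <- (idx[, 1] - 0.5) * vox
  y <- (idx[, 2] - 0.5) * vox
  r <- sqrt(x^2 + y^2)
  ann <- r > 1.6 & r < 2.4
  for (z in 2:6) {
    fa[, , z][ann] <- 0.5
    exy <- cbind(-y, x) / r
    e1[, , z, 1][ann] <- exy[ann, 1]
    e1[, , z, 2][ann] <- exy[ann, 2]
  }
  p <- tracking_params(n_tracts_target = 50, seed = 8, min_length_mm = 0.31,
                       max_length_mm = 50, step_mm = 0.05)
  tt <- track(list(FA = fa, e1 = e1), p, voxel_mm = rep(vox, 3))
  expect_gt(length(tt$streamlines), 0)
  # per-step turn on a 2 mm arc is ~1.4 degrees: no angle gate should fire,
  # so radial error stays within 2 steps
  for (m in tt$streamlines[seq_len(min(20, length(tt$streamlines)))]) {
    r0 <- sqrt(m[1, 1]^2 + m[1, 2]^2)
    rr <- sqrt(m[, 1]^2 + m[, 2]^2)
    expect_lt(max(abs(rr - r0)), 2 * p$step_mm)
  }
})

test_that("every emitted streamline satisfies the three gates post hoc", {
  sl <- fx_slab()
  p <- tracking_params(n_tracts_target = 100, seed = 13)
  tt <- track(sl, p, voxel_mm = sl$voxel_mm)
  for (m in tt$streamlines[1:20]) {
    len <- sum(sqrt(rowSums(diff(m)^2)))
    expect_gte(len, p$min_length_mm)
    expect_lte(len, p$max_length_mm + 1e-9)
    if (nrow(m) > 2) {
      seg <- diff(m)
      seg <- seg / sqrt(rowSums(seg^2))
      cosang <- rowSums(seg[-1, , drop = FALSE] * seg[-nrow(seg), , drop = FALSE])
      expect_true(all(cosang >= cos(p$angle_threshold_deg * pi / 180) - 1e-9))
    }
    # FA gate at every point (independent trilinear check at voxel centres)
    vox <- floor(sweep(m, 2, sl$voxel_mm, `/`)) + 1
    expect_true(all(sl$FA[vox] >= p$fa_threshold))
  }
})

test_that("streamline count never exceeds the target and meets it when the budget allows", {
  sl <- fx_slab()
  p <- tracking_params(n_tracts_target = 5000, seed = 2)
  tt <- track(sl, p, voxel_mm = sl$voxel_mm)
  expect_equal(length(tt$streamlines), 5000)
  td <- tidy(tt)
  expect_equal(nrow(td), 5000)
  expect_true(all(td$length_mm <= p$max_length_mm))
})

test_that("direction interpolation is exact at voxel centres and sign-aligned between antipodal neighbours", {
  dims <- c(8, 8, 8)
  e1 <- array(0, c(dims, 3))
  e1[, , , 1] <- 1
  # constant field: same vector anywhere
  v <- interpolate_direction(e1, c(3.3, 4.1, 3.9), method = "cubic")
  expect_equal(v, c(1, 0, 0), tolerance = 1e-9)
  # voxel-centre reproduction (centre of voxel i is at (i - 0.5) mm)
  vset <- sphere_directions(prod(dims))
  e1r <- array(0, c(dims, 3))
  e1r[, , , 1] <- array(vset[, 1], dims)
  e1r[, , , 2] <- array(vset[, 2], dims)
  e1r[, , , 3] <- array(vset[, 3], dims)
  pt <- c(4 - 0.5, 5 - 0.5, 3 - 0.5)
  stored <- e1r[4, 5, 3, ]
  got <- interpolate_direction(e1r, pt, ref_dir = stored, method = "cubic")
  expect_equal(abs(sum(got * stored)), 1, tolerance = 1e-9)
  # antipodal storage: v and -v interleaved must not average to a short vector
  e1a <- array(0, c(dims, 3))
  parity <- array((outer(outer(seq_len(8), seq_len(8), `+`),
                         seq_len(8), `+`)) %% 2, dims)
  e1a[, , , 1] <- ifelse(parity == 0, 1, -1)
  mid <- c(4.0, 4.0, 4.0)
  raw <- interpolate_direction(e1a, mid, ref_dir = c(1, 0, 0),
                               method = "cubic", renormalize = FALSE)
  expect_gt(sqrt(sum(raw^2)), 0.99)
  # out-of-bounds point signals the boundary with NA
  expect_true(all(is.na(interpolate_direction(e1, c(-5, 1, 1)))))
})

test_that("ROI filtering keeps pass-through and endpoint streamlines correctly", {
  sl <- fx_slab()
  p <- tracking_params(n_tracts_target = 100, seed = 4)
  tt <- track(sl, p, voxel_mm = sl$voxel_mm)
  dims <- dim(sl$FA)
  # whole-grid mask: identity
  all_mask <- array(TRUE, dims)
  expect_equal(length(roi_filter_tracts(tt, all_mask)$streamlines),
               length(tt$streamlines))
  # mid-slab plane: every straight streamline crosses it
  mid <- array(FALSE, dims)
  mid[20, , ] <- TRUE
  kept <- roi_filter_tracts(tt, mid)
  expect_equal(length(kept$streamlines), length(tt$streamlines))
  # independent point-in-mask verification
  for (m in kept$streamlines[1:10]) {
    vox <- floor(sweep(m, 2, sl$voxel_mm, `/`)) + 1
    expect_true(any(vox[, 1] == 20))
  }
  # disjoint mask: empty, with warning
  far <- array(FALSE, dims)
  far[1, 1, 1] <- TRUE
  expect_equal(length(roi_filter_tracts(tt, far)$streamlines), 0)
  expect_warning(roi_filter_tracts(tt, array(FALSE, dims)), "empty")
})

test_that("trk round-trip preserves coordinates to float32 precision", {
  sl <- fx_slab()
  tt <- track(sl, tracking_params(n_tracts_target = 20, seed = 6),
              voxel_mm = sl$voxel_mm)
  f <- withr::local_tempfile(fileext = ".trk")
  write_trk(tt, f)
  rt <- read_trk(f)
  expect_equal(length(rt$streamlines), 20)
  for (i in seq_len(20)) {
    expect_lt(max(abs(rt$streamlines[[i]] - tt$streamlines[[i]])),
              max(abs(tt$streamlines[[i]])) * 2^-23 * 4 + 1e-6)
  }
  expect_equal(rt$voxel_mm, sl$voxel_mm, tolerance = 1e-6)
  # empty tractogram: valid file with n_count = 0
  et <- microdki:::empty_tractogram(voxel_mm = c(1, 1, 1), dims = c(2L, 2L, 2L))
  f2 <- withr::local_tempfile(fileext = ".trk")
  write_trk(et, f2)
  expect_equal(file.size(f2), 1000)
  expect_equal(length(read_trk(f2)$streamlines), 0)
  # bad magic
  f3 <- withr::local_tempfile(fileext = ".trk")
  writeBin(c(charToRaw("XXXX"), raw(996)), f3)
  expect_error(read_trk(f3), class = "microdki_format_error")
})

test_that("single 3-point streamline round-trips", {
  m <- matrix(c(0.1, 0.2, 0.3,
                0.4, 0.5, 0.6,
                0.7, 0.8, 0.9), 3, 3, byrow = TRUE)
  tt <- microdki:::empty_tractogram(voxel_mm = c(1, 1, 1),
                                    dims = c(4L, 4L, 4L))
  tt$streamlines <- list(m)
  tt$lengths <- sum(sqrt(rowSums(diff(m)^2)))
  tt$seed_index <- 1L
  f <- withr::local_tempfile(fileext = ".trk")
  write_trk(tt, f)
  rt <- read_trk(f)
  expect_equal(rt$streamlines[[1]], m, tolerance = 1e-6)
})
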