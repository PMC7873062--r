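# Shared fixtures, built once per test run. Everything is deterministic:
# fixed construction seeds, no file I/O.

fixture_env <- new.env(parent = emptyenv())

# memoise expensive fixtures across test files
fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# the emulated three-shell scheme (29 volumes)
fx_scheme <- function() fixture("scheme", locust_scheme)

# noiseless small phantom: the exact-recovery oracle
fx_phantom_clean <- function() fixture("phantom_clean", function() {
  make_phantom(phantom_spec(small = TRUE, sigma = 0), fx_scheme())
})

# noisy small phantom at 2% of S0, fixed seed
fx_phantom_noisy <- function() fixture("phantom_noisy", function() {
  make_phantom(phantom_spec(small = TRUE, sigma = 0.02, seed = 11L),
               fx_scheme())
})

# noiseless kurtosis fit of the clean phantom
fx_fit_clean <- function() fixture("fit_clean", function() {
  ph <- fx_phantom_clean()
  fit_dki_volume(ph$dwi, ph$scheme)
})

# scalar maps of the clean fit (moderate direction set for speed)
fx_maps_clean <- function() fixture("maps_clean", function() {
  compute_scalar_maps(fx_fit_clean(), n_dir = 248)
})

# straight-slab eigenvector field for tracking geometry tests
fx_slab <- function(dims = c(40, 20, 10), voxel = 0.25) {
  fa <- array(0, dims)
  fa[, 5:(dims[2] - 4), 3:(dims[3] - 2)] <- 0.5
  e1 <- array(0, c(dims, 3))
  e1[, , , 1] <- 1
  list(FA = fa, e1 = e1, voxel_mm = rep(voxel, 3), dims = dims)
}

expect_rel_equal <- function(actual, expected, tol) {
  scale <- max(abs(expected), .Machine$double.eps)
  expect_lt(max(abs(actual - expected)) / scale, tol)
}
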