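test_that("the analytic cone mask has the right geometry", {
  g <- grid_spec(c(64, 64, 64), 0.1)
  expect_equal(sum(analytic_cone_mask(g, 0)$mask), 0)
  m <- analytic_cone_mask(g, 29.8)$mask
  # inversion symmetry by construction
  expect_identical(m, auglam:::reflect3(m))
  # DC excluded
  expect_false(m[33, 33, 33])
  # voxel-counted solid angle matches the closed form within 2%
  expect_equal(auglam:::cone_mask_fraction(g, 29.8),
               missing_cone_fraction(29.8), tolerance = 0.02)
  # the banded mask never leaves the CT ball
  mb <- analytic_cone_mask(g, 29.8, ct_band_radius = 0.2)
  kg <- auglam:::freq_grids(c(64L, 64L, 64L), 0.1)
  expect_true(all(kg$k[mb$mask] <= 0.2 / (2 * 0.1) + 1e-12))
})

test_that("resampling under the identity transform is exact", {
  v <- tiny_phantom()
  out <- resample_to_grid(v, list(), grid_of(v))
  expect_equal(out$data, v$data)
  expect_identical(attr(out, "n_outside"), 0L)
})

test_that("integer-voxel translations shift values exactly in the interior", {
  v <- tiny_phantom()
  tr <- list(translation = c(2, -1, 3) * v$voxel_size)
  out <- resample_to_grid(v, tr, grid_of(v))
  expect_equal(out$data[10:25, 10:25, 10:25],
               v$data[10:25 - 2, 10:25 + 1, 10:25 - 3])
})

test_that("degenerate transforms are rejected", {
  v <- tiny_phantom()
  expect_error(resample_to_grid(v, list(scale = 0), grid_of(v)),
               "degenerate")
})

test_that("a known-transform resampled pair registers to < 0.25 voxel", {
  # the same object sampled at voxel sizes in the ratio 8.28 / 5.16, with a
  # known shift, resampled back onto the fine grid: the correlation peak
  # must sit within a quarter voxel of zero offset
  fine <- make_phantom(flat_specimen_preset(seed = 3, nx = 64), supersample = 2)
  ratio <- (1135 / 137) / (1135 / 220)       # 8.28 / 5.16
  coarse_grid <- grid_spec(c(40L, 40L, 12L), fine$voxel_size * ratio)
  shift <- c(0.7, -0.4, 0.3) * fine$voxel_size
  coarse <- resample_to_grid(fine, list(translation = shift), coarse_grid)
  back <- resample_to_grid(coarse, list(translation = -shift), grid_of(fine))
  # parabolic interpolation of the correlation peak along each axis
  cc <- function(dx, dy, dz) {
    i <- 8:56; j <- 8:56; k <- 4:12
    a <- fine$data[i, j, k]
    b <- back$data[i + dx, j + dy, k + dz]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  for (ax in 1:3) {
    d0 <- d1 <- dm <- c(0L, 0L, 0L)
    d1[ax] <- 1L; dm[ax] <- -1L
    c0 <- cc(d0[1], d0[2], d0[3])
    cp <- cc(d1[1], d1[2], d1[3])
    cm <- cc(dm[1], dm[2], dm[3])
    peak <- 0.5 * (cm - cp) / (cm - 2 * c0 + cp)
    expect_lt(abs(peak), 0.25)
  }
})

test_that("intensity matching recovers affine relations in closed form", {
  v <- tiny_phantom()
  same <- match_intensity(v, v)
  expect_equal(attr(same, "coefficients"), c(a = 1, b = 0), tolerance = 1e-10)
  ct <- volume3d(2 * v$data + 0.5, v$voxel_size, v$origin)
  m <- match_intensity(ct, v)
  expect_equal(attr(m, "coefficients"), c(a = 0.5, b = -0.25),
               tolerance = 0.01)
  expect_equal(m$data, v$data, tolerance = 1e-6)
  flat <- volume3d(array(1, dim(v$data)), v$voxel_size, v$origin)
  expect_error(match_intensity(flat, v), "zero-variance")
})

test_that("intensity matching reduces the low-frequency discrepancy", {
  sim <- cached_sim(1L)
  raw_ct <- resample_to_grid(sim$ct, list(), grid_of(sim$cl))
  matched <- match_intensity(raw_ct, sim$cl, theta = 29.8)
  lp_rms <- function(ct) {
    kg <- auglam:::freq_grids(dim(ct$data), ct$voxel_size)
    keep <- kg$k <= 0.1 / (2 * ct$voxel_size) &
      kg$kz <= kg$k * cos(29.8 * pi / 180)
    Fd <- auglam:::fftshift3(stats::fft(ct$data - sim$cl$data))
    sqrt(mean(Mod(Fd)[keep]^2))
  }
  expect_lt(lp_rms(matched), lp_rms(raw_ct))
})

test_that("mask estimation is empty for identical volumes and warns", {
  v <- tiny_phantom()
  expect_warning(m <- estimate_mask(v, v, fusion_config(tau = 0.9)),
                 "all-false")
  expect_equal(sum(m$mask), 0)
})

test_that("median_size = 1 with raw amplitudes reproduces the threshold rule", {
  set.seed(5)
  a <- volume3d(array(stats::rnorm(16^3), c(16, 16, 16)), 0.1)
  b <- volume3d(array(stats::rnorm(16^3), c(16, 16, 16)), 0.1)
  cfg <- fusion_config(tau = 0.7, median_size = 1L, smooth_size = 1L,
                       ct_band_radius = 0.5)
  m <- estimate_mask(a, b, cfg)
  # independent re-derivation of the rule
  A <- Mod(auglam:::fftshift3(stats::fft(a$data)))
  B <- Mod(auglam:::fftshift3(stats::fft(b$data)))
  kg <- auglam:::freq_grids(c(16L, 16L, 16L), 0.1)
  want <- (A < 0.7 * B) & kg$k <= 0.5 / (2 * 0.1) & kg$k > 0
  want <- want | auglam:::reflect3(want)
  want[9, 9, 9] <- FALSE
  expect_identical(m$mask, want)
  expect_identical(m$mask, auglam:::reflect3(m$mask))
})

test_that("fusion with an empty mask or identical inputs is the identity", {
  v <- tiny_phantom()
  w <- volume3d(v$data * 0.5 + 0.01, v$voxel_size, v$origin)
  empty <- analytic_cone_mask(grid_of(v), 0)
  expect_equal(fuse(v, w, empty)$data, v$data, tolerance = 1e-12)
  full <- analytic_cone_mask(grid_of(v), 45, ct_band_radius = 1)
  expect_equal(fuse(v, v, full)$data, v$data, tolerance = 1e-12)
})

test_that("fusion rejects masks that would break realness", {
  v <- tiny_phantom()
  m <- analytic_cone_mask(grid_of(v), 30)
  m$mask[4, 7, 9] <- !m$mask[4, 7, 9]     # break inversion symmetry
  expect_error(fuse(v, volume3d(v$data * 2, v$voxel_size, v$origin), m),
               "asymmetric")
})

test_that("hard-mask fusion is idempotent and preserves out-of-mask spectra", {
  v <- tiny_phantom()
  w <- volume3d(0.7 * v$data + 0.005, v$voxel_size, v$origin)
  m <- analytic_cone_mask(grid_of(v), 35, ct_band_radius = 0.6)
  al <- fuse(v, w, m, apodization_width = 0)
  al2 <- fuse(al, w, m, apodization_width = 0)
  expect_equal(al2$data, al$data, tolerance = 1e-12)
  F_al <- auglam:::fftshift3(stats::fft(al$data))
  F_cl <- auglam:::fftshift3(stats::fft(v$data))
  F_ct <- auglam:::fftshift3(stats::fft(w$data))
  expect_equal(sum(Mod(F_al)[!m$mask]^2), sum(Mod(F_cl)[!m$mask]^2),
               tolerance = 1e-10)
  expect_equal(F_al[m$mask], F_ct[m$mask], tolerance = 1e-10)
})

test_that("apodized fusion stays real and keeps weights in [0, 1]", {
  v <- tiny_phantom()
  w <- volume3d(0.7 * v$data + 0.005, v$voxel_size, v$origin)
  m <- analytic_cone_mask(grid_of(v), 35, ct_band_radius = 0.6)
  al <- fuse(v, w, m, apodization_width = 2)
  expect_true(all(is.finite(al$data)))
  sm <- auglam:::apodize_mask(m$mask * 1.0, 2)
  expect_true(all(sm >= 0 & sm <= 1))
  expect_equal(sm, auglam:::reflect3(sm), tolerance = 1e-12)
})

test_that("mask persistence round-trips through MetaImage", {
  m <- analytic_cone_mask(grid_spec(c(24, 24, 12), 0.05), 29.8,
                          ct_band_radius = 0.3)
  path <- file.path(tempdir(), "mask.mha")
  write_mask(m, path, fusion_config())
  m2 <- read_mask(path)
  expect_identical(m2$mask, m$mask)
  expect_equal(m2$theta, 29.8)
  expect_equal(m2$ct_band_radius, 0.3)
})
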