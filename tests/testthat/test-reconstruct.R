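test_that("the ramp filter suppresses the zero-frequency component", {
  # DC response of the discrete ramp: the truncated kernel keeps only an
  # O(1/N) residual relative to the Nyquist response
  for (N in c(128L, 256L, 1024L)) {
    H <- auglam:::ramp_response(N, 0.1, "ram-lak")
    expect_lt(H[1], 0.01 * max(H))
    expect_gt(H[1], 0)  # kept positive on purpose (no uniform row shift)
  }
  # a periodic constant (circularly filtered) maps to its DC residual only:
  # mean of a wide frame's central region is far below the input level
  g <- ct_geometry(n_projections = 2L, detector = c(4L, 256L))
  st <- auglam:::projection_stack(array(1, c(4, 256, 2)), c(0, 180),
                                  "line_integral", g)
  fl <- ramp_filter(st)
  expect_lt(abs(mean(fl$frames[, 97:160, ])), 0.05 * max(st$frames))
  expect_error(ramp_filter(auglam:::projection_stack(
    array(1, c(8, 3, 2)), c(0, 180), "line_integral",
    ct_geometry(2L, c(8L, 3L)))), "at least 4 pixels")
})

test_that("the impulse response matches the closed-form Ram-Lak kernel", {
  g <- scan_geometry("CT", sdd = 100, sod = 100, detector_pixel = 0.1,
                     detector_shape = c(3L, 64L), n_projections = 1L)
  du <- effective_voxel_size(g)
  imp <- array(0, c(3, 64, 1)); imp[2, 33, 1] <- 1
  st <- auglam:::projection_stack(imp, 0, "line_integral", g)
  got <- ramp_filter(st)$frames[2, , 1]
  n <- (1:64) - 33
  h <- ifelse(n == 0, 1 / (4 * du^2),
              ifelse(n %% 2 != 0, -1 / (pi^2 * n^2 * du^2), 0)) * du
  expect_equal(got, h, tolerance = 1e-3)
})

test_that("ramp filtering is linear and the Shepp-Logan window apodizes", {
  g <- ct_geometry(n_projections = 2L, detector = c(8L, 32L))
  f1 <- array(stats::runif(8 * 32 * 2), c(8, 32, 2))
  f2 <- array(stats::runif(8 * 32 * 2), c(8, 32, 2))
  mk <- function(f) auglam:::projection_stack(f, c(0, 180), "line_integral", g)
  q1 <- ramp_filter(mk(f1))$frames
  q2 <- ramp_filter(mk(f2))$frames
  q12 <- ramp_filter(mk(2 * f1 + 5 * f2))$frames
  expect_equal(q12, 2 * q1 + 5 * q2, tolerance = 1e-10)
  # the window damps high frequencies: smaller output energy
  qs <- ramp_filter(mk(f1), window = "shepp-logan")$frames
  expect_lt(sum(qs^2), sum(q1^2))
})

test_that("FBP recovers the attenuation of a uniform sphere at 180 angles", {
  v <- sphere_phantom(n = 64, r = 20, mu = 0.05, voxel = 0.1)
  g <- ct_geometry(n_projections = 180L)
  rec <- reconstruct_fbp(forward_project(v, g), g, grid_of(v))
  expect_equal(rec$data[33, 33, 33], 0.05, tolerance = 0.05)
  # interior mean is also close
  expect_equal(mean(rec$data[27:39, 27:39, 27:39]), 0.05, tolerance = 0.05)
})

test_that("theta=0 FBP matches an independent direct implementation", {
  # reference: closed-form Ram-Lak convolution in the spatial domain and a
  # plain R backprojection loop with bilinear detector sampling
  v <- tiny_phantom()
  g <- scan_geometry("CT", sdd = 100, sod = 100, detector_pixel = 0.1,
                     detector_shape = c(36L, 36L), n_projections = 30L)
  st <- forward_project(v, g)
  du <- effective_voxel_size(g)
  nc <- 36L
  lag <- -(nc - 1):(nc - 1)
  h <- ifelse(lag == 0, 1 / (4 * du^2),
              ifelse(lag %% 2 != 0, -1 / (pi^2 * lag^2 * du^2), 0))
  ref_filter <- function(p) du * vapply(seq_len(nc), function(m)
    sum(p * h[(m - seq_len(nc)) + nc]), numeric(1))
  phis <- st$angles * pi / 180
  d <- c(32L, 32L, 32L)
  ref <- array(0, d)
  centre <- (d - 1) / 2
  u0 <- -(nc - 1) / 2 * du
  xs <- ((seq_len(d[1]) - 1) - centre[1]) * v$voxel_size
  for (a in seq_along(phis)) {
    Q <- t(apply(st$frames[, , a], 1, ref_filter))   # rows filtered along u
    for (k in seq_len(d[3])) {
      vv <- ((k - 1) - centre[3]) * v$voxel_size
      r <- (vv - u0) / du
      r0 <- floor(r); fr <- r - r0
      for (j in seq_len(d[2])) {
        uu <- xs * cos(phis[a]) - ((j - 1) - centre[2]) * v$voxel_size *
          sin(phis[a])
        c1 <- (uu - u0) / du
        inside <- c1 >= 0 & c1 <= nc - 1
        c0 <- pmin(pmax(floor(c1), 0), nc - 2); fc <- c1 - c0
        qrow0 <- Q[r0 + 1, ]; qrow1 <- Q[r0 + 2, ]
        val0 <- qrow0[c0 + 1] * (1 - fc) + qrow0[c0 + 2] * fc
        val1 <- qrow1[c0 + 1] * (1 - fc) + qrow1[c0 + 2] * fc
        ref[, j, k] <- ref[, j, k] + (val0 * (1 - fr) + val1 * fr) * inside
      }
    }
  }
  ref <- ref * pi / length(phis)
  got <- reconstruct_fbp(st, g, grid_spec(d, v$voxel_size), upsample = 1L)
  rel <- sqrt(mean((got$data - ref)^2)) / sqrt(mean(ref^2))
  expect_lt(rel, 1e-6)
})

test_that("theta=0 reconstruction commutes with in-plane 90-degree rotations", {
  v <- tiny_phantom()
  # detector wide enough to cover the rotating grid corners at every angle
  g <- ct_geometry(n_projections = 72L, detector = c(96L, 96L))
  rec <- function(vol) reconstruct_fbp(forward_project(vol, g), g,
                                       grid_of(vol))$data
  r1 <- rec(v)
  vr <- volume3d(aperm(v$data[, dim(v$data)[2]:1, ], c(2, 1, 3)),
                 v$voxel_size)
  r2 <- rec(vr)
  back <- aperm(r2, c(2, 1, 3))[, dim(r2)[2]:1, ]
  expect_lt(max(abs(back - r1)), 0.03 * diff(range(r1)))
})

test_that("doubling the number of projections does not increase sphere RMSE", {
  v <- sphere_phantom(n = 48, r = 14, mu = 0.05, voxel = 0.1)
  err <- vapply(c(90L, 180L), function(np) {
    g <- ct_geometry(n_projections = np, detector = c(72L, 72L))
    rmse(reconstruct_fbp(forward_project(v, g), g, grid_of(v)), v)
  }, numeric(1))
  expect_lte(err[2], err[1])
})

test_that("cone energy ratio behaves at its limits and for white noise", {
  v <- tiny_phantom()
  expect_identical(cone_energy_ratio(v, 0), 0)
  noise <- withr::with_seed(3, volume3d(array(stats::rnorm(48^3),
                                              c(48, 48, 48)), 0.1))
  for (th in c(29.8, 45)) {
    expect_equal(cone_energy_ratio(noise, th), missing_cone_fraction(th),
                 tolerance = 0.05)
  }
})

test_that("the laminographic reconstruction suppresses in-cone content", {
  sim <- cached_sim(1L)
  cl_ratio <- cone_energy_ratio(sim$cl, 29.8)
  truth_ratio <- cone_energy_ratio(sim$truth, 29.8)
  # most of the flat phantom's energy is in the cone; the CL scan cannot
  # acquire it, so its in-cone share collapses (what remains is the
  # finite-window leakage floor of discrete backprojection)
  expect_lt(cl_ratio, 0.4 * truth_ratio)
  # and fusion restores in-cone energy
  expect_gt(cone_energy_ratio(sim$al, 29.8), cl_ratio)
})
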