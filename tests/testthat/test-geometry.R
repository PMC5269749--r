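test_that("magnification reproduces the reference setups and rejects bad geometry", {
  g_ct <- scan_geometry("CT", sdd = 1135, sod = 220)
  g_cl <- scan_geometry("CL", sdd = 1135, sod = 137, theta = 29.8)
  expect_equal(round(magnification(g_ct), 2), 5.16)
  expect_equal(round(magnification(g_cl), 2), 8.28)
  expect_equal(magnification(scan_geometry("CT", sdd = 500, sod = 500)), 1)
  expect_error(scan_geometry("CT", sdd = 500, sod = 0), "sdd >= sod > 0")
  expect_error(scan_geometry("CT", sdd = 500, sod = 600), "sdd >= sod > 0")
  expect_error(scan_geometry("CT", sdd = 500, sod = 100, theta = 20), "theta")
})

test_that("magnification is invariant under joint rescaling of SDD and SOD", {
  for (f in c(0.5, 2, 17.3)) {
    g1 <- scan_geometry("CL", sdd = 1135, sod = 137, theta = 10)
    g2 <- scan_geometry("CL", sdd = 1135 * f, sod = 137 * f, theta = 10)
    expect_equal(magnification(g1), magnification(g2))
  }
})

test_that("effective voxel size is the demagnified detector pitch", {
  expect_equal(effective_voxel_size(scan_geometry("CT", 500, 500,
                                                  detector_pixel = 0.2)), 0.2)
  # oracle: direct division 0.2 * sod / sdd
  expect_equal(effective_voxel_size(scan_geometry("CT", sdd = 1135, sod = 220,
                                                  detector_pixel = 0.2)),
               0.2 * 220 / 1135)
  expect_equal(round(effective_voxel_size(
    scan_geometry("CT", sdd = 1135, sod = 220, detector_pixel = 0.2)), 5),
    0.03877)
  expect_equal(round(effective_voxel_size(
    scan_geometry("CL", sdd = 1135, sod = 137, theta = 29.8,
                  detector_pixel = 0.2)), 5), 0.02414)
})

test_that("missing cone fraction has the right limits and monotonicity", {
  expect_equal(missing_cone_fraction(0), 0)
  expect_equal(missing_cone_fraction(90), 1)
  # frozen Monte-Carlo oracle: fraction of 3e6 random unit vectors within
  # 29.8 deg of the axis (seed 42) = 0.132396
  expect_equal(missing_cone_fraction(29.8), 0.132396, tolerance = 0.005)
  th <- seq(0, 90, by = 5)
  expect_true(all(diff(missing_cone_fraction(th)) > 0))
  expect_error(missing_cone_fraction(91), "\\[0, 90\\]")
  expect_error(missing_cone_fraction(-1), "\\[0, 90\\]")
})

test_that("cone fraction agrees with the voxel-counted analytic mask", {
  g <- grid_spec(c(64, 64, 64), 1)
  for (th in c(20, 29.8, 45)) {
    expect_equal(auglam:::cone_mask_fraction(g, th), missing_cone_fraction(th),
                 tolerance = 0.02)
  }
})

test_that("CT sampling check matches the stated truncation cases", {
  # detector 81.92 mm wide at M = 5.16
  g <- scan_geometry("CT", sdd = 1135, sod = 220, detector_pixel = 0.2,
                     detector_shape = c(410L, 410L))
  ok <- check_ct_sampling(10, 5, g)
  expect_true(ok$valid)
  expect_identical(ok$limiting_condition, "none")
  bad <- check_ct_sampling(100, 5, g)       # magnified extent 516 mm > 82 mm
  expect_false(bad$valid)
  expect_match(bad$limiting_condition, "overlap")
  expect_error(check_ct_sampling(-1, 5, g), "positive")
})

test_that("CL tilt admits laterally extended flat objects that CT rejects", {
  g_ct <- scan_geometry("CT", sdd = 1135, sod = 137, detector_pixel = 0.2,
                        detector_shape = c(410L, 410L))
  g_cl <- scan_geometry("CL", sdd = 1135, sod = 137, theta = 29.8,
                        detector_pixel = 0.2, detector_shape = c(410L, 410L))
  # 100 mm wide, 0.8 mm thin: hopeless for CT at M = 8.28, fine for CL
  expect_false(check_ct_sampling(100, 0.8, g_ct)$valid)
  expect_true(check_ct_sampling(100, 0.8, g_cl)$valid)
  # a thick object defeats the tilt as well
  expect_false(check_ct_sampling(100, 30, g_cl)$valid)
})

test_that("sampling check agrees with a brute-force shadow sweep", {
  # independent oracle: sample the bounding cylinder's surface, project at
  # 1 degree steps, and test the two conditions directly from the shadows
  brute <- function(D, Th, g, r_roi) {
    M <- magnification(g)
    W <- g$detector_shape[2] * g$detector_pixel / M
    H <- g$detector_shape[1] * g$detector_pixel / M
    phis <- 0:359
    bb <- auglam:::beam_basis(g$theta, phis)
    a <- seq(0, 2 * pi, length.out = 73)[-73]
    grid <- expand.grid(rho = seq(0, D / 2, length.out = 21)[-1], a = a,
                        z = c(-Th / 2, 0, Th / 2))
    pts <- cbind(grid$rho * cos(grid$a), grid$rho * sin(grid$a), grid$z)
    u <- t(pts %*% bb$u)  # angle x point
    v <- t(pts %*% bb$v)
    v_roi <- r_roi * sin(g$theta * pi / 180) + Th / 2 * cos(g$theta * pi / 180)
    roi_on <- r_roi <= W / 2 && v_roi <= H / 2
    # points that leave the detector at some angle
    off <- apply(abs(u) > W / 2 | abs(v) > H / 2, 2, any)
    rho <- sqrt(pts[, 1]^2 + pts[, 2]^2)
    # does any leaving point's shadow ever intersect the ROI shadow?
    overlap <- FALSE
    if (any(off)) {
      hits <- abs(u[, off, drop = FALSE]) <= r_roi &
        abs(v[, off, drop = FALSE]) <= v_roi
      overlap <- any(hits)
    }
    list(valid = roi_on && !overlap, roi_on = roi_on, no_overlap = !overlap)
  }
  g_cl <- scan_geometry("CL", sdd = 1135, sod = 137, theta = 29.8,
                        detector_pixel = 0.2, detector_shape = c(410L, 410L))
  g_ct <- scan_geometry("CT", sdd = 1135, sod = 220, detector_pixel = 0.2,
                        detector_shape = c(410L, 410L))
  cases <- list(list(100, 0.8, g_cl), list(100, 5, g_cl), list(100, 30, g_cl),
                list(10, 5, g_ct), list(100, 5, g_ct), list(8, 2, g_cl))
  for (cs in cases) {
    got <- check_ct_sampling(cs[[1]], cs[[2]], cs[[3]])
    want <- brute(cs[[1]], cs[[2]], cs[[3]], got$roi_radius)
    expect_identical(got$valid, want$valid,
                     label = sprintf("D=%g Th=%g theta=%g closed-form",
                                     cs[[1]], cs[[2]], cs[[3]]$theta))
  }
})

test_that("geometry serializes through the sidecar list form", {
  g <- scan_geometry("CL", sdd = 1135, sod = 137, theta = 29.8,
                     detector_pixel = 0.2, detector_shape = c(128L, 256L),
                     n_projections = 7L, angular_range = 180)
  expect_equal(geometry_from_list(geometry_to_list(g)), g)
  lst <- geometry_to_list(g)
  expect_named(lst, c("mode", "sdd_mm", "sod_mm", "theta_deg",
                      "detector_pixel_mm", "detector_shape",
                      "n_projections", "angular_range_deg"))
})
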