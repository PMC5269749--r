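#' Fusion configuration
#'
#' Parameters of the Fourier-domain CL/CT fusion: the amplitude-ratio
#' threshold `tau` used to detect the empty laminographic cones, the edge
#' size of the binary median filter that cleans the raw mask, the width of
#' the raised-cosine apodization at the mask boundary, the upper radial
#' limit of trusted CT information (`ct_band_radius`, as a fraction of the
#' CL Nyquist frequency), and the mask mode.
#'
#' @param tau Amplitude-ratio threshold, > 0 (default 0.9): a frequency is
#'   declared missing in CL when its (smoothed) amplitude falls below
#'   `tau` times the CT amplitude. After gain matching, frequencies the CL
#'   scan samples have an amplitude ratio of about 1 or above, while the
#'   in-cone ratio is the reconstruction's leakage floor (well below 1), so
#'   the default sits just under 1.
#' @param median_size Median-filter kernel edge along the finest-sampled
#'   frequency axis (1 = no filtering); see [estimate_mask()] for how
#'   anisotropic grids are handled.
#' @param apodization_width Raised-cosine boundary width, voxels (0 = hard
#'   binary mask, the fidelity reference).
#' @param ct_band_radius Fraction of the CL Nyquist radius below which CT
#'   coefficients are trusted. The default 0.16 derates the nominal
#'   five-fold voxel-size ratio (1/5) by 80%, since any reconstruction's
#'   modulation transfer is unusable at its own Nyquist limit.
#' @param smooth_size Box half-width (finest axis) for smoothing the
#'   amplitude envelopes before thresholding (1 = raw per-bin amplitudes).
#'   Single-bin Fourier amplitudes fluctuate strongly; comparing local
#'   envelopes stabilizes the ratio.
#' @param mask_mode `"data_driven"` (threshold + median filter, the default)
#'   or `"analytic"` (geometric cone).
#' @export
fusion_config <- function(tau = 0.9, median_size = 3L, apodization_width = 2,
                          ct_band_radius = 0.16, smooth_size = 5L,
                          mask_mode = c("data_driven", "analytic")) {
  mask_mode <- match.arg(mask_mode)
  stopifnot(tau > 0, apodization_width >= 0)
  median_size <- as.integer(median_size)
  smooth_size <- as.integer(smooth_size)
  if (median_size < 1 || median_size %% 2 == 0)
    stop("median_size must be an odd integer >= 1")
  if (smooth_size < 1 || smooth_size %% 2 == 0)
    stop("smooth_size must be an odd integer >= 1")
  if (!(ct_band_radius > 0 && ct_band_radius <= 1))
    stop("ct_band_radius must lie in (0, 1]")
  structure(list(tau = tau, median_size = median_size,
                 apodization_width = apodization_width,
                 ct_band_radius = ct_band_radius, smooth_size = smooth_size,
                 mask_mode = mask_mode),
            class = "fusion_config")
}

new_fourier_mask <- function(mask, theta = NA_real_, ct_band_radius = 1) {
  structure(list(mask = mask, theta = theta,
                 ct_band_radius = ct_band_radius),
            class = "fourier_mask")
}

#' @export
print.fourier_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<fourier_mask> %d x %d x %d, %d coefficients flagged (%.3f%%)\n",
              d[1], d[2], d[3], sum(x$mask), 100 * mean(x$mask)))
  if (!is.na(x$theta)) cat(sprintf("  analytic cone, theta = %g deg\n", x$theta))
  cat(sprintf("  CT band radius: %g of Nyquist\n", x$ct_band_radius))
  invisible(x)
}

mask_is_symmetric <- function(mask) identical(mask, reflect3(mask))

#' Analytic missing-cone mask
#'
#' Marks the frequencies inside the double cone of half-angle `theta` about
#' the k_z axis, restricted to the ball `|k| <= ct_band_radius * Nyquist`
#' (no filling beyond the CT band) and excluding DC. The mask is centered
#' (DC at `floor(n/2)+1`) and inversion-symmetric by construction.
#'
#' @param grid A [grid_spec()] or [volume3d()] defining dimensions and voxel
#'   size.
#' @param theta Cone half-angle, degrees, in `[0, 90)`; 0 gives an empty
#'   mask.
#' @param ct_band_radius Fraction of the (smallest per-axis) Nyquist radius.
#' @return A `fourier_mask`.
#' @export
analytic_cone_mask <- function(grid, theta, ct_band_radius = 1) {
  if (inherits(grid, "volume3d")) grid <- grid_of(grid)
  if (!(theta >= 0 && theta < 90)) stop("theta must lie in [0, 90)")
  kg <- freq_grids(grid$dim, grid$voxel_size)
  nyq <- 1 / (2 * grid$voxel_size)
  m <- (kg$kz > kg$k * cos(theta * pi / 180)) &
    (kg$k <= ct_band_radius * nyq) & (kg$k > 0)
  if (theta == 0) m[] <- FALSE
  new_fourier_mask(m, theta = theta, ct_band_radius = ct_band_radius)
}

# Voxel-counted solid-angle fraction of the cone within the Nyquist ball,
# the discrete counterpart of missing_cone_fraction().
cone_mask_fraction <- function(grid, theta) {
  if (inherits(grid, "volume3d")) grid <- grid_of(grid)
  kg <- freq_grids(grid$dim, grid$voxel_size)
  nyq <- 1 / (2 * grid$voxel_size)
  ball <- kg$k <= nyq & kg$k > 0
  cone <- ball & (kg$kz > kg$k * cos(theta * pi / 180))
  sum(cone) / sum(ball)
}

#' Resample a volume onto a target grid under a rigid + scale transform
#'
#' Maps the moving volume into the target's physical frame by
#' `p_target = scale * R * p_moving + translation` and trilinearly resamples
#' it onto the target grid. Voxels falling outside the moving volume's
#' support are set to `fill` and counted (attribute `"n_outside"`).
#'
#' @param moving A [volume3d()].
#' @param transform A list `list(scale = 1, rotation = c(0,0,0),
#'   translation = c(0,0,0))`: isotropic scale, intrinsic z-y-x Euler angles
#'   in degrees, translation in mm. Defaults to the identity.
#' @param target A [grid_spec()] or [volume3d()].
#' @param fill Fill value for out-of-support voxels.
#' @return A [volume3d()] on the target grid.
#' @export
resample_to_grid <- function(moving, transform = list(), target, fill = 0) {
  stopifnot(inherits(moving, "volume3d"))
  if (inherits(target, "volume3d")) target <- grid_of(target)
  tr <- utils::modifyList(list(scale = 1, rotation = c(0, 0, 0),
                               translation = c(0, 0, 0)), transform)
  if (!(is.numeric(tr$scale) && tr$scale > 0))
    stop("degenerate transform: scale must be positive")
  R <- euler_zyx(tr$rotation)
  # target voxel index q (0-based) -> physical -> inverse map -> moving index
  # p_mov = R^-1 ((p_tgt - t) / scale); index = (p - origin)/voxel
  Ainv <- t(R) / tr$scale
  M <- Ainv %*% diag(rep(target$voxel_size, 3))
  b <- Ainv %*% (target$origin - tr$translation)
  A_idx <- M / moving$voxel_size
  b_idx <- (b - moving$origin) / moving$voxel_size
  res <- resample_affine_cpp(as.numeric(moving$data), dim(moving$data),
                             target$dim, A_idx, as.numeric(b_idx), fill)
  out <- volume3d(array(res$data, dim = target$dim), target$voxel_size,
                  target$origin)
  attr(out, "n_outside") <- as.integer(res$n_outside)
  out
}

euler_zyx <- function(angles_deg) {
  a <- angles_deg * pi / 180
  Rz <- rbind(c(cos(a[1]), -sin(a[1]), 0), c(sin(a[1]), cos(a[1]), 0),
              c(0, 0, 1))
  Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0),
              c(-sin(a[2]), 0, cos(a[2])))
  Rx <- rbind(c(1, 0, 0), c(0, cos(a[3]), -sin(a[3])),
              c(0, sin(a[3]), cos(a[3])))
  Rz %*% Ry %*% Rx
}

#' Match the intensity scale of a CT volume to a CL volume
#'
#' CT and CL reconstructions of the same object can sit on different
#' grey-value scales (different dynamic ranges, normalizations). This fits
#' `a * ct + b` to `cl` and returns the rescaled CT. The gain `a` minimizes
#' the squared Fourier-amplitude mismatch over the low-frequency annulus
#' both scans sample reliably - radii `annulus` (fractions of Nyquist),
#' excluding (when `theta` is given) the CL missing cone, where the CL scan
#' carries no signal and would drag the fitted gain towards zero. Matching
#' amplitudes rather than complex coefficients keeps the fit insensitive to
#' phase-decorrelated reconstruction artifacts. The offset `b` aligns the
#' volume means.
#'
#' @param ct,cl [volume3d()] objects on the same grid.
#' @param annulus Inner and outer radius of the matching annulus as
#'   fractions of the Nyquist frequency; default `c(0.02, 0.1)` (the lower
#'   half of a 1/5 CT band, away from DC).
#' @param theta Laminographic angle of the CL scan, degrees; `NULL`
#'   compares the full annulus.
#' @return The rescaled CT volume, with fitted `c(a, b)` in attribute
#'   `"coefficients"`.
#' @export
match_intensity <- function(ct, cl, annulus = c(0.02, 0.1), theta = NULL) {
  stop_if_grid_mismatch(ct, cl)
  kg <- freq_grids(dim(cl$data), cl$voxel_size)
  nyq <- 1 / (2 * cl$voxel_size)
  keep <- kg$k > annulus[1] * nyq & kg$k <= annulus[2] * nyq
  if (!is.null(theta))
    keep <- keep & (kg$kz <= kg$k * cos(theta * pi / 180))
  A_ct <- Mod(fftshift3(fft3(ct$data)))[keep]
  A_cl <- Mod(fftshift3(fft3(cl$data)))[keep]
  if (sum(A_ct^2) < .Machine$double.eps)
    stop("zero-variance CT input: cannot match intensities")
  a <- sum(A_cl * A_ct) / sum(A_ct^2)
  b <- mean(cl$data) - a * mean(ct$data)
  out <- volume3d(a * ct$data + b, ct$voxel_size, ct$origin)
  attr(out, "coefficients") <- c(a = a, b = b)
  out
}

#' Estimate the missing-cone mask from the data
#'
#' Implements the amplitude-comparison rule: a frequency belongs to the
#' missing region when the CL spectrum is much weaker than the CT spectrum,
#' `|F_cl(k)| < tau * |F_ct(k)|`, restricted to the CT band. Amplitude
#' envelopes are first smoothed with a box of edge `smooth_size`
#' (`smooth_size = 1` compares raw per-bin amplitudes). The raw binary mask
#' is cleaned with a 3D median filter (`median_size = 1` reproduces the
#' unfiltered threshold mask), symmetrized by `mask(k) | mask(-k)` so
#' fusion preserves realness, and DC is always excluded.
#'
#' `median_size` and `smooth_size` are kernel edges along the axis with the
#' finest frequency sampling; on grids with anisotropic frequency steps
#' (e.g. a flat volume, whose k_z bins are several times coarser than k_x
#' bins) the per-axis edges shrink proportionally so the kernels stay
#' frequency-isotropic instead of swallowing the thin cone.
#'
#' @param cl,ct Intensity-matched [volume3d()] objects on the same grid.
#' @param config A [fusion_config()].
#' @return A `fourier_mask`.
#' @export
estimate_mask <- function(cl, ct, config = fusion_config()) {
  stop_if_grid_mismatch(cl, ct)
  d <- dim(cl$data)
  dk <- 1 / (d * cl$voxel_size)             # per-axis frequency step
  aniso_sizes <- function(size) {
    s <- pmax(1L, as.integer(round(size * min(dk) / dk)))
    s + (1L - s %% 2L)                      # keep every edge odd
  }
  A_cl <- Mod(fftshift3(fft3(cl$data)))
  A_ct <- Mod(fftshift3(fft3(ct$data)))
  if (config$smooth_size > 1) {
    sw <- aniso_sizes(config$smooth_size)
    A_cl <- box_smooth3(A_cl, sw)
    A_ct <- box_smooth3(A_ct, sw)
  }
  kg <- freq_grids(d, cl$voxel_size)
  nyq <- 1 / (2 * cl$voxel_size)
  band <- kg$k <= config$ct_band_radius * nyq & kg$k > 0
  m <- (A_cl < config$tau * A_ct) & band
  if (all(m) || !any(m))
    warning("estimate_mask: raw threshold mask is all-",
            if (all(m)) "true" else "false")
  if (config$median_size > 1) {
    m <- array(binary_median3d_cpp(m, d, aniso_sizes(config$median_size)),
               dim = d)
    m <- m & band                      # median filtering must not leave the band
  }
  m <- m | reflect3(m)
  cc <- floor(d / 2) + 1
  m[cc[1], cc[2], cc[3]] <- FALSE
  new_fourier_mask(m, ct_band_radius = config$ct_band_radius)
}

# Circular box smoothing with odd per-axis window edges, via separable
# running means (wrap-around matches the spectrum's periodicity).
box_smooth3 <- function(A, sizes) {
  kern <- array(0, dim(A))
  cc <- floor(dim(A) / 2) + 1
  h <- (sizes - 1L) / 2L
  kern[(cc[1] - h[1]):(cc[1] + h[1]), (cc[2] - h[2]):(cc[2] + h[2]),
       (cc[3] - h[3]):(cc[3] + h[3])] <- 1 / prod(sizes)
  Re(ifft3(fft3(A) * fft3(ifftshift3(kern))))
}

#' Fuse CL and CT volumes in the Fourier domain (augmented laminography)
#'
#' Replaces the CL spectrum inside the mask by the CT spectrum:
#' `F_al = (1 - w) F_cl + w F_ct`, where `w` is the binary mask optionally
#' smoothed by convolution with a raised-cosine kernel of the given width
#' (in frequency voxels); with width 0 the substitution is hard
#' (`w` in {0, 1}), the fidelity reference. The fused volume is the real
#' part of the inverse transform; realness is guaranteed by the mask's
#' inversion symmetry and verified (imaginary RMS below 1e-8 of the output
#' RMS), and asymmetric masks are rejected.
#'
#' @param cl,ct_aligned [volume3d()] objects on the same grid (CT aligned,
#'   resampled and intensity-matched beforehand).
#' @param mask A `fourier_mask` (from [estimate_mask()] or
#'   [analytic_cone_mask()]).
#' @param apodization_width Raised-cosine smoothing width, voxels (0 =
#'   hard mask).
#' @return The fused [volume3d()].
#' @export
fuse <- function(cl, ct_aligned, mask, apodization_width = 0) {
  stop_if_grid_mismatch(cl, ct_aligned)
  stopifnot(inherits(mask, "fourier_mask"))
  m <- mask$mask
  if (!identical(dim(m), dim(cl$data)))
    stop("mask grid does not match the volumes")
  if (!mask_is_symmetric(m))
    stop("asymmetric mask: fusion would produce a complex-valued volume")
  w <- m * 1.0
  if (apodization_width > 0) {
    w <- apodize_mask(w, apodization_width)
  }
  F_cl <- fft3(cl$data)
  F_ct <- fft3(ct_aligned$data)
  wf <- ifftshift3(w)
  F_al <- (1 - wf) * F_cl + wf * F_ct
  al <- ifft3(F_al)
  re <- Re(al); im <- Im(al)
  rms <- function(x) sqrt(mean(x^2))
  if (rms(im) > 1e-8 * max(rms(re), .Machine$double.eps))
    stop("fusion lost realness: imaginary residual too large")
  volume3d(re, cl$voxel_size, cl$origin)
}

# Smooth a centered binary mask with a normalized radial raised-cosine
# kernel of the given width (voxels), by circular FFT convolution; the
# result stays in [0, 1] and keeps the mask's inversion symmetry.
apodize_mask <- function(w, width) {
  d <- dim(w)
  r <- sqrt(outer(outer((seq_len(d[1]) - (floor(d[1] / 2) + 1))^2,
                        (seq_len(d[2]) - (floor(d[2] / 2) + 1))^2, "+"),
                  (seq_len(d[3]) - (floor(d[3] / 2) + 1))^2, "+"))
  kern <- ifelse(r <= width, 0.5 * (1 + cos(pi * r / width)), 0)
  kern <- kern / sum(kern)
  sm <- fftshift3(Re(ifft3(fft3(ifftshift3(w)) * fft3(ifftshift3(kern)))))
  pmin(pmax(sm, 0), 1)
}
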