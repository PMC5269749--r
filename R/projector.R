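#' Projection stack container
#'
#' Per-angle 2D detector frames stored as an array `(rows, cols, angles)`,
#' together with the rotation angles phi (degrees) and the acquisition
#' geometry. `kind` distinguishes attenuation line-integral images from raw
#' detector intensities.
#'
#' @param frames Numeric array `(rows, cols, n_angles)`.
#' @param angles Rotation angles phi, degrees.
#' @param kind `"line_integral"` or `"raw_intensity"`.
#' @param geometry The [scan_geometry()] the stack was acquired with.
#' @export
projection_stack <- function(frames, angles, kind = c("line_integral",
                                                      "raw_intensity"),
                             geometry) {
  kind <- match.arg(kind)
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (length(angles) != dim(frames)[3])
    stop("length(angles) must equal the number of frames")
  if (length(angles) != geometry$n_projections)
    stop("frame count must equal geometry$n_projections")
  if (kind == "line_integral" && min(frames) < -1e-9)
    stop("line integrals of a nonnegative attenuation field must be >= 0")
  structure(list(frames = frames, angles = as.numeric(angles), kind = kind,
                 geometry = geometry),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<projection_stack> %d frames of %d x %d px, kind = %s\n",
              d[3], d[1], d[2], x$kind))
  invisible(x)
}

#' Suggest a detector shape that covers a volume's projections
#'
#' Bounds the projected footprint of the volume over all rotation angles:
#' laterally by the in-plane half-diagonal, axially by the support function
#' of the bounding box along the tilted detector axis, and returns an
#' even `(rows, cols)` with `margin` pixels of padding per side.
#'
#' @param volume A [volume3d()].
#' @param geometry A [scan_geometry()]; its `detector_shape` is replaced.
#' @param margin Padding in detector pixels per side.
#' @return The geometry with an updated `detector_shape`.
#' @export
fit_detector <- function(volume, geometry, margin = 4L) {
  d <- dim(volume$data)
  s <- volume$voxel_size
  du <- effective_voxel_size(geometry)
  th <- geometry$theta * pi / 180
  r_lat <- sqrt((d[1] * s)^2 + (d[2] * s)^2) / 2
  hz <- d[3] * s / 2
  u_max <- r_lat
  v_max <- sin(th) * r_lat + cos(th) * hz
  cols <- 2L * (as.integer(ceiling(u_max / du)) + margin)
  rows <- 2L * (as.integer(ceiling(v_max / du)) + margin)
  geometry$detector_shape <- c(rows, cols)
  geometry
}

#' Parallel-beam forward projection about a tilted rotation axis
#'
#' Computes line integrals of the attenuation volume along the beam
#' direction for every rotation angle phi. The object is held fixed; the
#' beam and detector basis rotate about the object z axis, which is tilted
#' by the laminographic angle theta relative to the conventional-CT
#' orientation (the two views are equivalent). Integrals use
#' trilinear-interpolated ray stepping with a step of `step` voxels
#' (must be <= 1), and rays are clipped to the volume's bounding box.
#'
#' Detector pixels have the effective (object-scale) pitch
#' `detector_pixel / M`; frames are dimensionless (mu times length).
#'
#' @param volume A [volume3d()].
#' @param geometry A [scan_geometry()].
#' @param step Ray sampling step in voxel units; default 0.5.
#' @return A [projection_stack()] of kind `"line_integral"`.
#' @export
forward_project <- function(volume, geometry, step = 0.5) {
  stopifnot(inherits(volume, "volume3d"), inherits(geometry, "scan_geometry"))
  if (step > 1) stop("ray step must not exceed one voxel")
  phis <- projection_angles(geometry)
  basis <- beam_basis(geometry$theta, phis)
  du <- effective_voxel_size(geometry)
  nr <- geometry$detector_shape[1]
  nc <- geometry$detector_shape[2]
  raw <- forward_project_cpp(as.numeric(volume$data), dim(volume$data),
                             volume$voxel_size, basis$u, basis$v, basis$d,
                             nr, nc, du, step)
  frames <- array(raw, dim = c(nr, nc, length(phis)))
  frames[frames < 0] <- 0  # guard against -0 / rounding
  projection_stack(frames, phis, "line_integral", geometry)
}

#' Simulate raw detector intensities from line integrals
#'
#' Applies the Beer-Lambert law per pixel:
#' `I = (flat - dark) * exp(-p) + dark`, optionally with Poisson noise on
#' the pre-dark term. Also returns the flat-field and dark-current
#' calibration frames needed to undo the transform.
#'
#' @param stack A line-integral [projection_stack()].
#' @param flat_level Mean flat-field counts (must exceed `dark_level`).
#' @param dark_level Dark-current counts, >= 0.
#' @param poisson Apply Poisson noise to the transmitted counts?
#' @param seed Seed for the noise (required when `poisson = TRUE`).
#' @return List with elements `stack` (kind `"raw_intensity"`), `flat` and
#'   `dark` (calibration frames).
#' @export
simulate_raw <- function(stack, flat_level = 1e4, dark_level = 100,
                         poisson = FALSE, seed = 1L) {
  stopifnot(inherits(stack, "projection_stack"))
  if (stack$kind != "line_integral")
    stop("simulate_raw expects a line-integral stack")
  if (!(flat_level > dark_level && dark_level >= 0))
    stop("need flat_level > dark_level >= 0")
  trans <- (flat_level - dark_level) * exp(-stack$frames)
  if (poisson) {
    trans <- withr::with_seed(seed, {
      array(stats::rpois(length(trans), trans), dim = dim(trans))
    })
  }
  raw <- trans + dark_level
  d <- dim(stack$frames)[1:2]
  list(stack = projection_stack(raw, stack$angles, "raw_intensity",
                                stack$geometry),
       flat = matrix(flat_level, d[1], d[2]),
       dark = matrix(dark_level, d[1], d[2]))
}

#' Flat-field / dark-current normalization
#'
#' Recovers attenuation line integrals from raw intensities:
#' `p = -log((I - dark) / (flat - dark))`. Pixels with nonpositive
#' transmittance (possible under noise at strong attenuation) are clamped to
#' `max_attenuation` and counted; the count is reported via a message and
#' the `"n_clamped"` attribute.
#'
#' @param raw A raw-intensity [projection_stack()].
#' @param flat Flat-field frame (matrix matching the detector shape).
#' @param dark Dark-current frame.
#' @param max_attenuation Clamp value for nonpositive transmittance.
#' @return A [projection_stack()] of kind `"line_integral"`.
#' @export
normalize_flat_dark <- function(raw, flat, dark, max_attenuation = 20) {
  stopifnot(inherits(raw, "projection_stack"))
  if (raw$kind != "raw_intensity")
    stop("normalize_flat_dark expects a raw-intensity stack")
  gain <- flat - dark
  if (any(gain <= 0))
    stop("degenerate calibration: flat must exceed dark at every pixel")
  d <- dim(raw$frames)
  trans <- sweep(sweep(raw$frames, 1:2, dark, "-"), 1:2, gain, "/")
  bad <- trans <= 0
  n_clamped <- sum(bad)
  trans[bad] <- exp(-max_attenuation)
  p <- -log(trans)
  p[p < 0] <- 0  # noise can push I slightly above flat
  if (n_clamped > 0)
    message("normalize_flat_dark: clamped ", n_clamped,
            " pixels with nonpositive transmittance to p = ", max_attenuation)
  out <- projection_stack(p, raw$angles, "line_integral", raw$geometry)
  attr(out, "n_clamped") <- n_clamped
  out
}
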