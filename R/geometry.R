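#' Acquisition geometry for CT and computed laminography (CL)
#'
#' Describes a parallel-beam tomographic acquisition with a possibly tilted
#' rotation axis. The laminographic angle \code{theta} is the tilt of the
#' rotation axis away from the conventional-CT orientation (axis perpendicular
#' to the beam): \code{theta = 0} is conventional CT, \code{theta = 90} would
#' degenerate into a sequence of rotated radiographs. Cone-beam magnification
#' enters only through the effective voxel size
#' (\code{detector_pixel / magnification}); rays themselves are parallel.
#'
#' @param mode `"CT"` or `"CL"`. CT forces `theta = 0`.
#' @param sdd Source-to-detector distance, mm.
#' @param sod Source-to-object distance, mm. Must satisfy `0 < sod <= sdd`.
#' @param theta Laminographic angle in degrees, `0 <= theta < 90`.
#' @param detector_pixel Detector pixel pitch, mm (0.2 mm in a typical
#'   flat-panel setup).
#' @param detector_shape Integer vector `(rows, cols)` of detector pixels.
#' @param n_projections Number of projections over `angular_range`.
#' @param angular_range Total rotation, degrees, in `(0, 360]`.
#' @return An object of class `scan_geometry`.
#' @examples
#' g <- scan_geometry("CL", sdd = 1135, sod = 137, theta = 29.8,
#'                    detector_pixel = 0.2, detector_shape = c(256, 256),
#'                    n_projections = 360)
#' magnification(g)
#' @export
scan_geometry <- function(mode = c("CT", "CL"), sdd, sod, theta = 0,
                          detector_pixel = 0.2,
                          detector_shape = c(256L, 256L),
                          n_projections = 360L, angular_range = 360) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(sdd), is.numeric(sod), length(sdd) == 1, length(sod) == 1)
  if (!(sod > 0 && sdd >= sod))
    stop("invalid geometry: need sdd >= sod > 0 (got sdd=", sdd, ", sod=", sod, ")")
  if (!(theta >= 0 && theta < 90))
    stop("theta must lie in [0, 90) degrees")
  if (mode == "CT" && theta != 0)
    stop("mode = 'CT' implies theta = 0; use mode = 'CL' for a tilted axis")
  detector_shape <- as.integer(detector_shape)
  if (length(detector_shape) != 2 || any(detector_shape < 1))
    stop("detector_shape must be two positive integers (rows, cols)")
  if (detector_pixel <= 0) stop("detector_pixel must be positive")
  n_projections <- as.integer(n_projections)
  if (n_projections < 1) stop("n_projections must be >= 1")
  if (!(angular_range > 0 && angular_range <= 360))
    stop("angular_range must lie in (0, 360]")
  structure(list(mode = mode, sdd = sdd, sod = sod, theta = theta,
                 detector_pixel = detector_pixel,
                 detector_shape = detector_shape,
                 n_projections = n_projections,
                 angular_range = angular_range),
            class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("<scan_geometry> %s: SDD %g mm, SOD %g mm (M = %.3f), theta %g deg\n",
              x$mode, x$sdd, x$sod, magnification(x), x$theta))
  cat(sprintf("  detector %d x %d px @ %g mm (effective voxel %.5f mm)\n",
              x$detector_shape[1], x$detector_shape[2], x$detector_pixel,
              effective_voxel_size(x)))
  cat(sprintf("  %d projections over %g deg\n", x$n_projections, x$angular_range))
  invisible(x)
}

#' Geometric magnification M = SDD / SOD
#'
#' @param geometry A [scan_geometry()].
#' @return The dimensionless magnification factor.
#' @export
magnification <- function(geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  geometry$sdd / geometry$sod
}

#' Effective voxel size of the reconstruction
#'
#' The detector pixel pitch demagnified to the object plane:
#' `detector_pixel / M`.
#'
#' @inheritParams magnification
#' @return Length in mm.
#' @export
effective_voxel_size <- function(geometry) {
  geometry$detector_pixel / magnification(geometry)
}

#' Solid-angle fraction of the missing double cone
#'
#' In the parallel-beam model a spatial frequency direction is sampled if and
#' only if it is perpendicular to some beam direction on the acquisition cone.
#' Tilting the rotation axis by `theta` leaves exactly the double cone of
#' half-angle `theta` about the axis direction unsampled; its solid-angle
#' fraction of the unit sphere is `1 - cos(theta)`. At `theta = 0` the cones
#' vanish (conventional CT samples the full Fourier space); at `theta = 90`
#' only the central plane - a measure-zero set - remains, the radiography
#' limit.
#'
#' @param theta Laminographic angle, degrees, in `[0, 90]`.
#' @return Fraction in `[0, 1]`.
#' @export
missing_cone_fraction <- function(theta) {
  if (any(theta < 0 | theta > 90)) stop("theta must lie in [0, 90] degrees")
  1 - cos(theta * pi / 180)
}

# Beam / detector basis unit vectors in the object frame at rotation angle
# phi (degrees), for laminographic tilt theta (degrees). The rotation axis is
# the object z axis; the object is held fixed and the directions rotate.
# d: beam direction; u: horizontal detector axis (in the x-y plane);
# v: axial detector axis (projection of z onto the detector plane).
beam_basis <- function(theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  list(d = rbind(cos(th) * sin(ph), cos(th) * cos(ph),
                 rep(sin(th), length(ph))),
       u = rbind(cos(ph), -sin(ph), rep(0, length(ph))),
       v = rbind(-sin(th) * sin(ph), -sin(th) * cos(ph),
                 rep(cos(th), length(ph))))
}

projection_angles <- function(geometry) {
  seq(0, geometry$angular_range, length.out = geometry$n_projections + 1)[
    seq_len(geometry$n_projections)]
}

#' Truncation-free sampling check for a rotating flat specimen
#'
#' Evaluates the two conditions for reconstructing a region of interest (ROI)
#' without truncation artifacts: (1) the projected ROI must never leave the
#' detector while the specimen rotates, and (2) none of the object regions
#' that leave the detector may overlap (in projection) with the ROI during
#' rotation. The object is modelled as a centred cylinder of diameter
#' `object_lateral_extent` and height `object_thickness` rotating about the
#' (possibly tilted) axis; the ROI is a centred cylinder of radius
#' `roi_radius` through the full thickness.
#'
#' For conventional CT the second condition fails as soon as the magnified
#' lateral extent exceeds the detector width: every laterally excluded point
#' periodically projects back onto the ROI's shadow. With a tilted axis an
#' off-FOV point's shadow acquires an axial offset proportional to
#' `sin(theta)` times its lateral radius, so for thin specimens only an
#' annulus of width about `thickness / tan(theta)` around the ROI can
#' contaminate it, and arbitrarily wide flat objects pass.
#'
#' @param object_lateral_extent Object diameter, mm.
#' @param object_thickness Object height along the rotation axis, mm.
#' @param geometry A [scan_geometry()].
#' @param roi_radius ROI radius, mm (object scale). Default: a quarter of the
#'   effective detector width, leaving filtering margin inside the FOV.
#' @return A `sampling_report` list with fields `roi_on_detector`,
#'   `no_overlap`, `valid` and `limiting_condition`.
#' @export
check_ct_sampling <- function(object_lateral_extent, object_thickness,
                              geometry, roi_radius = NULL) {
  if (object_lateral_extent <= 0 || object_thickness <= 0)
    stop("object extents must be positive")
  M <- magnification(geometry)
  # detector size at object scale (parallel model with magnification
  # bookkeeping): physical size / M
  W <- geometry$detector_shape[2] * geometry$detector_pixel / M
  H <- geometry$detector_shape[1] * geometry$detector_pixel / M
  th <- geometry$theta * pi / 180
  R <- object_lateral_extent / 2
  Th <- object_thickness
  if (is.null(roi_radius)) roi_radius <- W / 4
  r_roi <- min(roi_radius, R)
  v_roi <- r_roi * sin(th) + Th / 2 * cos(th)

  cond1 <- (2 * r_roi <= W) && (2 * v_roi <= H)

  # largest lateral radius whose shadow stays on the detector at every phi
  rho_stay_u <- W / 2
  rho_stay_v <- if (sin(th) > 0) (H / 2 - Th / 2 * cos(th)) / sin(th) else Inf
  rho_stay <- min(rho_stay_u, max(rho_stay_v, 0))
  if (geometry$theta == 0 && Th > H) rho_stay <- 0  # leaves axially at all phi

  # largest lateral radius whose shadow can still intersect the ROI shadow:
  # need |u| <= r_roi and sin(th) sqrt(rho^2 - r_roi^2) - Th/2 cos(th) <= v_roi
  rho_contam <- if (sin(th) > 0) {
    sqrt(r_roi^2 + ((v_roi + Th / 2 * cos(th)) / sin(th))^2)
  } else Inf
  cond2 <- (R <= rho_stay) || (rho_contam <= rho_stay)

  limiting <- if (cond1 && cond2) {
    "none"
  } else if (!cond1) {
    "ROI projection leaves the detector"
  } else {
    "regions leaving the detector overlap the projected ROI"
  }
  structure(list(roi_on_detector = cond1, no_overlap = cond2,
                 valid = cond1 && cond2, limiting_condition = limiting,
                 roi_radius = r_roi, rho_stay = rho_stay,
                 rho_contam = rho_contam,
                 fov_width = W, fov_height = H),
            class = "sampling_report")
}

#' @export
print.sampling_report <- function(x, ...) {
  cat(sprintf("<sampling_report> valid: %s\n", x$valid))
  cat(sprintf("  ROI stays on detector: %s; no overlap: %s\n",
              x$roi_on_detector, x$no_overlap))
  cat(sprintf("  limiting condition: %s\n", x$limiting_condition))
  invisible(x)
}

#' Serialize / deserialize a scan geometry
#'
#' The list form uses the unit-suffixed keys `mode`, `sdd_mm`, `sod_mm`,
#' `theta_deg`, `detector_pixel_mm`, `detector_shape`, `n_projections`,
#' `angular_range_deg`, and is embedded verbatim in JSON sidecars and YAML
#' configurations.
#'
#' @param geometry A [scan_geometry()].
#' @return `geometry_to_list`: a named list; `geometry_from_list`: a
#'   [scan_geometry()].
#' @export
geometry_to_list <- function(geometry) {
  list(mode = geometry$mode, sdd_mm = geometry$sdd, sod_mm = geometry$sod,
       theta_deg = geometry$theta,
       detector_pixel_mm = geometry$detector_pixel,
       detector_shape = as.integer(geometry$detector_shape),
       n_projections = geometry$n_projections,
       angular_range_deg = geometry$angular_range)
}

#' @rdname geometry_to_list
#' @param x A list as produced by `geometry_to_list`.
#' @export
geometry_from_list <- function(x) {
  scan_geometry(mode = x$mode, sdd = x$sdd_mm, sod = x$sod_mm,
                theta = x$theta_deg, detector_pixel = x$detector_pixel_mm,
                detector_shape = unlist(x$detector_shape),
                n_projections = x$n_projections,
                angular_range = x$angular_range_deg)
}
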