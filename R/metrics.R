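#' Volume comparison metrics
#'
#' Root-mean-square error and peak signal-to-noise ratio between two volumes
#' on the same grid. The PSNR peak defaults to the combined data range, so
#' two constant volumes separated by the data range score 0 dB.
#'
#' @param a,b [volume3d()] objects (or plain arrays) on the same grid.
#' @param peak Peak value for PSNR; default `diff(range(a, b))`.
#' @return `rmse`: scalar in the volume's units; `psnr`: decibels.
#' @export
rmse <- function(a, b) {
  ab <- as_data_pair(a, b)
  sqrt(mean((ab$a - ab$b)^2))
}

#' @rdname rmse
#' @export
psnr <- function(a, b, peak = NULL) {
  ab <- as_data_pair(a, b)
  if (is.null(peak)) peak <- diff(range(ab$a, ab$b))
  mse <- mean((ab$a - ab$b)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

as_data_pair <- function(a, b) {
  if (inherits(a, "volume3d") && inherits(b, "volume3d")) {
    stop_if_grid_mismatch(a, b)
    list(a = a$data, b = b$data)
  } else {
    da <- if (inherits(a, "volume3d")) a$data else a
    db <- if (inherits(b, "volume3d")) b$data else b
    if (!identical(dim(da), dim(db))) stop("inputs must share dimensions")
    list(a = da, b = db)
  }
}

#' 10-90% edge width of a line profile
#'
#' Measures the rise distance of an edge-spread profile: the profile is
#' normalized to its plateau levels (means of `plateau` samples at each
#' end), monotonized by a running maximum, and the positions where it
#' crosses 10% and 90% are found by linear interpolation between samples.
#' The result is in sample (voxel) units; a sharpness-limited edge sampled
#' on the voxel lattice cannot report below 0.8 (the 10-90 span of a rise
#' completed within one sample interval).
#'
#' @param profile Numeric vector, rising edge (falling profiles are
#'   flipped automatically).
#' @param plateau Samples averaged at each end for the plateau levels.
#' @return Width in voxels.
#' @export
edge_width <- function(profile, plateau = 2L) {
  stopifnot(length(profile) >= 4)
  if (profile[1] > profile[length(profile)]) profile <- rev(profile)
  lo <- mean(utils::head(profile, plateau))
  hi <- mean(utils::tail(profile, plateau))
  if (hi - lo <= 0) stop("edge_width needs a rising profile")
  p <- cummax((profile - lo) / (hi - lo))
  crossing <- function(level) {
    i <- which(p >= level)[1]
    if (is.na(i)) return(length(p))
    if (i == 1) return(1)
    i - 1 + (level - p[i - 1]) / (p[i] - p[i - 1])
  }
  crossing(0.9) - crossing(0.1)
}

#' Quantitative CL / CT / AL comparison report
#'
#' Computes, for each method volume against the ground truth: RMSE, PSNR,
#' in-plane and axial 10-90% edge widths (from profiles through the
#' phantom's fixed edge box, averaged over a small transverse patch), and
#' the spectral energy fraction inside the missing cone. All volumes must
#' share the CL grid (upsample the CT first). This is the quantitative
#' analogue of the usual qualitative method-comparison table: CL should
#' show the widest axial edges, CT the widest in-plane edges, and AL should
#' combine in-plane sharpness with reduced axial blur.
#'
#' The in-plane width is the 10-90% rise ([edge_width()]) across a lateral
#' face of the phantom's fixed central box. The axial width is measured at
#' the slab's top surface - a laterally extended edge whose spectrum lies
#' in the missing cone - as `0.8 * C / max |dP/dz|`, where `C` is the
#' ground-truth edge contrast: a local slope-based estimate that agrees
#' with the 10-90% convention for clean ramps but remains meaningful when
#' laminographic blur spreads the edge beyond the measurement window.
#'
#' @param truth Ground-truth [volume3d()] (from [make_phantom()]; its
#'   attached spec supplies the edge positions).
#' @param cl,ct,al Reconstructions on the truth grid.
#' @param theta Laminographic angle, degrees (for the cone energy column).
#' @return A `data.frame` with one row per method (truth, cl, ct, al).
#' @export
method_report <- function(truth, cl, ct, al, theta) {
  vols <- list(truth = truth, cl = cl, ct = ct, al = al)
  for (v in vols[-1]) stop_if_grid_mismatch(truth, v)
  spec <- attr(truth, "spec")
  edges <- if (!is.null(spec)) edge_box_profiles_spec(spec) else NULL
  contrast <- if (!is.null(edges))
    diff(range(extract_profile(truth, edges$axial))) else NA_real_
  rows <- lapply(names(vols), function(nm) {
    v <- vols[[nm]]
    ew <- c(inplane = NA_real_, axial = NA_real_)
    if (!is.null(edges)) {
      ew["inplane"] <- tryCatch(edge_width(extract_profile(v, edges$inplane)),
                                error = function(e) NA_real_)
      prof <- extract_profile(v, edges$axial)
      ew["axial"] <- 0.8 * contrast / max(abs(diff(prof)))
    }
    data.frame(method = nm,
               rmse = rmse(v, truth),
               psnr = psnr(v, truth),
               edge_inplane = unname(ew["inplane"]),
               edge_axial = unname(ew["axial"]),
               cone_energy = cone_energy_ratio(v, theta),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Profile definitions for a phantom spec. The in-plane profile crosses a
# lateral face of the first (fixed, central box) primitive - a compact
# structure whose sharpness laminography preserves. The axial profile
# crosses the slab's top surface, a laterally extended z-edge whose
# spectrum lives in the missing cone (the structure CL blurs and CT
# restores), at the lateral corner farthest from every primitive.
edge_box_profiles_spec <- function(spec) {
  pr <- spec$primitives[[1]]
  if (pr$kind != "box") return(NULL)
  ctr <- pr$center; sz <- pr$size; d <- spec$grid_shape
  span_x <- round(ctr[1] + sz[1] * c(0.4, 1.6))
  z_top <- if (length(spec$layers))
    max(vapply(spec$layers, function(l) l$z[2], numeric(1))) else d[3]
  corners <- rbind(c(0.06, 0.06), c(0.06, 0.94), c(0.94, 0.06),
                   c(0.94, 0.94)) * rep(d[1:2], each = 4)
  prim_xy <- do.call(rbind, lapply(spec$primitives,
                                   function(p) p$center[1:2]))
  dmin <- apply(corners, 1, function(cn)
    min(sqrt(colSums((t(prim_xy) - cn)^2))))
  at_xy <- round(corners[which.max(dmin), ])
  list(inplane = list(axis = 1,
                      range = c(max(1, span_x[1]), min(d[1], span_x[2])),
                      at = round(ctr)),
       axial = list(axis = 3,
                    range = c(max(1, round(z_top - 5)), d[3]),
                    at = c(at_xy, NA), patch = 2L))
}

# Average profile along one axis over a patch of neighbouring lines.
extract_profile <- function(volume, def) {
  v <- volume$data
  idx <- def$range[1]:def$range[2]
  at <- def$at
  p <- if (is.null(def$patch)) 1L else def$patch
  d <- dim(v)
  lat <- setdiff(1:3, def$axis)
  p <- min(p, at[lat] - 1, d[lat] - at[lat])  # keep the patch inside the grid
  offs <- -p:p
  acc <- 0
  for (o1 in offs) for (o2 in offs) {
    acc <- acc + switch(def$axis,
      `1` = v[idx, at[2] + o1, at[3] + o2],
      `2` = v[at[1] + o1, idx, at[3] + o2],
      `3` = v[at[1] + o1, at[2] + o2, idx])
  }
  acc / length(offs)^2
}

#' Write / read a method report as CSV
#'
#' @param report A data.frame from [method_report()].
#' @param path Output CSV path.
#' @export
write_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
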