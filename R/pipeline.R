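#' End-to-end CL / CT / AL simulation
#'
#' Runs the full augmented-laminography experiment on synthetic data:
#' generate a flat layered phantom, simulate a high-magnification CL scan
#' (tilted axis) and a lower-magnification CT scan of the same object,
#' reconstruct both by filtered backprojection, upsample and
#' intensity-match the CT to the CL grid, estimate the missing-cone mask,
#' implant the CT Fourier coefficients, and score all three volumes against
#' the ground truth.
#'
#' Default acquisition parameters follow the reference setup: SDD 1135 mm
#' with SOD 137 mm for CL (M = 8.28, effective voxel 0.2/8.28 mm, 0.2 mm
#' detector pixels) and a laminographic angle of 29.8 degrees; the CT scan
#' uses `mag_ratio` (default 5) times lower magnification, i.e. 5x coarser
#' voxels, and is reconstructed on a correspondingly coarser grid before
#' upsampling. Both scans cover 360 degrees; `n_projections` defaults to
#' 360, which satisfies the angular Nyquist criterion (about pi/2 times the
#' lateral grid size) for the default 128-wide phantom.
#'
#' @param seed Seed for phantom generation (and noise, when enabled).
#' @param theta Laminographic angle, degrees.
#' @param mag_ratio CL-to-CT magnification (voxel size) ratio.
#' @param n_projections Projections per scan over 360 degrees.
#' @param aspect_ratio,nx Flat-phantom shape parameters
#'   (see [flat_specimen_preset()]).
#' @param config A [fusion_config()]; its `ct_band_radius` defaults to
#'   `1 / mag_ratio`.
#' @param noise Simulate Poisson counting noise through the raw-intensity /
#'   flat-dark chain (off for the noiseless reference experiment).
#' @param flat_level Flat-field counts when `noise = TRUE`.
#' @param step Ray-integration step, voxels.
#' @return A list with the phantom (`truth`), reconstructions (`cl`,
#'   `ct`, `ct_up`, `al`), the masks (`mask`, `mask_analytic`), the
#'   geometries, the fusion config and the metrics `report`.
#' @export
run_al_simulation <- function(seed = 1L, theta = 29.8, mag_ratio = 5,
                              n_projections = 360L, aspect_ratio = 4,
                              nx = 128L, config = NULL, noise = FALSE,
                              flat_level = 1e5, step = 0.5) {
  if (is.null(config))
    config <- fusion_config(ct_band_radius = 0.8 / mag_ratio)
  spec <- flat_specimen_preset(aspect_ratio = aspect_ratio, seed = seed,
                               nx = nx)
  truth <- make_phantom(spec)

  geom_cl <- scan_geometry("CL", sdd = 1135, sod = 137, theta = theta,
                           detector_pixel = 0.2,
                           n_projections = n_projections)
  # same source-detector distance, mag_ratio-times lower magnification
  geom_ct <- scan_geometry("CT", sdd = 1135, sod = 137 * mag_ratio,
                           detector_pixel = 0.2,
                           n_projections = n_projections)
  # phantom voxels match the CL effective voxel size
  stopifnot(abs(effective_voxel_size(geom_cl) - truth$voxel_size) <
              1e-9 * truth$voxel_size)
  geom_cl <- fit_detector(truth, geom_cl)
  geom_ct <- fit_detector(truth, geom_ct)

  acquire <- function(geom, sub_seed) {
    p <- forward_project(truth, geom, step = step)
    if (noise) {
      sim <- simulate_raw(p, flat_level = flat_level, dark_level = 100,
                          poisson = TRUE, seed = sub_seed)
      p <- suppressMessages(
        normalize_flat_dark(sim$stack, sim$flat, sim$dark))
    }
    p
  }
  proj_cl <- acquire(geom_cl, seed * 2L + 1L)
  proj_ct <- acquire(geom_ct, seed * 2L + 2L)

  d <- dim(truth$data)
  cl <- reconstruct_fbp(proj_cl, geom_cl, grid_of(truth))
  ct_grid <- grid_spec(pmax(2L, as.integer(ceiling(d / mag_ratio))),
                       effective_voxel_size(geom_ct))
  ct <- reconstruct_fbp(proj_ct, geom_ct, ct_grid)

  ct_up <- resample_to_grid(ct, list(), grid_of(truth))
  ct_up <- match_intensity(ct_up, cl, theta = theta)

  mask <- if (config$mask_mode == "analytic") {
    analytic_cone_mask(grid_of(cl), theta, config$ct_band_radius)
  } else {
    estimate_mask(cl, ct_up, config)
  }
  mask_analytic <- analytic_cone_mask(grid_of(cl), theta,
                                      config$ct_band_radius)
  al <- fuse(cl, ct_up, mask, apodization_width = config$apodization_width)

  report <- method_report(truth, cl, ct_up, al, theta)
  list(truth = truth, cl = cl, ct = ct, ct_up = ct_up, al = al,
       mask = mask, mask_analytic = mask_analytic,
       geometry_cl = geom_cl, geometry_ct = geom_ct,
       config = config, seed = seed, report = report)
}

#' Write the outputs of a simulation run to a directory
#'
#' Persists the phantom, the three reconstructions, the fusion mask, the
#' CSV metrics report, a machine-readable provenance file (`provenance.json`
#' with seeds, geometries and configuration - sufficient to regenerate the
#' run) and, when the `png` package is available, a three-column slice
#' montage (CL | AL | CT) through the volume centre.
#'
#' @param sim Result of [run_al_simulation()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gcl <- geometry_to_list(sim$geometry_cl)
  gct <- geometry_to_list(sim$geometry_ct)
  write_volume(sim$truth, file.path(outdir, "truth.mha"),
               sidecar = list(role = "phantom", seed = sim$seed))
  write_volume(sim$cl, file.path(outdir, "cl.mha"),
               sidecar = list(role = "CL reconstruction", geometry = gcl))
  write_volume(sim$ct, file.path(outdir, "ct.mha"),
               sidecar = list(role = "CT reconstruction", geometry = gct))
  write_volume(sim$al, file.path(outdir, "al.mha"),
               sidecar = list(role = "AL fusion", geometry = gcl))
  write_mask(sim$mask, file.path(outdir, "mask.mha"), sim$config)
  write_report(sim$report, file.path(outdir, "report.csv"))
  prov <- list(package = "auglam",
               version = as.character(utils::packageVersion("auglam")),
               seed = sim$seed, geometry_cl = gcl, geometry_ct = gct,
               fusion = unclass(sim$config),
               phantom_spec = serialize_spec(attr(sim$truth, "spec")))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_montage(sim, file.path(outdir, "montage.png"))
  invisible(outdir)
}

serialize_spec <- function(spec) {
  if (is.null(spec)) return(NULL)
  unclass(spec)
}

#' Persist a Fourier mask as an 8-bit-style MetaImage volume
#'
#' The binary mask is stored as a float volume of 0/1 (centered indexing),
#' with the fusion configuration in the sidecar.
#'
#' @param mask A `fourier_mask`.
#' @param path Output `.mha` path.
#' @param config Optional [fusion_config()] recorded in the sidecar.
#' @export
write_mask <- function(mask, path, config = NULL) {
  v <- volume3d(array(as.numeric(mask$mask), dim = dim(mask$mask)), 1)
  write_volume(v, path,
               sidecar = list(role = "fourier_mask", centered = TRUE,
                              theta_deg = mask$theta,
                              ct_band_radius = mask$ct_band_radius,
                              fusion = if (!is.null(config)) unclass(config)))
  invisible(path)
}

#' Read a Fourier mask written by [write_mask()]
#' @param path The `.mha` path.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  sc <- attr(v, "sidecar")
  new_fourier_mask(array(v$data > 0.5, dim = dim(v$data)),
                   theta = if (!is.null(sc$theta_deg) &&
                               !is.na(sc$theta_deg)) sc$theta_deg else NA_real_,
                   ct_band_radius = if (!is.null(sc$ct_band_radius))
                     sc$ct_band_radius else 1)
}

# Central-slice montage (CL | AL | CT per plane) as an 8-bit PNG; skipped
# silently when the png package is unavailable.
write_montage <- function(sim, path) {
  if (!requireNamespace("png", quietly = TRUE)) return(invisible(NULL))
  d <- dim(sim$truth$data)
  vols <- list(CL = sim$cl$data, AL = sim$al$data, CT = sim$ct_up$data)
  rng <- range(sim$truth$data)
  norm <- function(m) {
    m <- (m - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
    pmin(pmax(m, 0), 1)
  }
  xy <- lapply(vols, function(v) norm(v[, , ceiling(d[3] / 2)]))
  xz <- lapply(vols, function(v) norm(v[, ceiling(d[2] / 2), ]))
  row1 <- do.call(cbind, xy)
  row2 <- do.call(cbind, xz)
  canvas <- matrix(0, nrow(row1), ncol(row1) + ncol(row2) + 4)
  canvas[, seq_len(ncol(row1))] <- row1
  canvas[seq_len(nrow(row2)), ncol(row1) + 4 + seq_len(ncol(row2))] <- row2
  png::writePNG(t(canvas), path)
  invisible(path)
}
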