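# Shared fixtures: built in code at test time, kept small.

# A 32^3 phantom with two primitives on a mildly attenuating background;
# smooth enough for spectral tests, sharp enough for edge tests.
tiny_phantom <- function(voxel = 0.1) {
  make_phantom(phantom_spec(
    c(32, 32, 32), voxel_size = voxel, background_mu = 0.01,
    primitives = list(
      list(kind = "sphere", center = c(17, 15, 16), size = 6, mu = 0.05),
      list(kind = "box", center = c(10, 20, 18), size = c(3, 4, 2),
           mu = 0.08))))
}

# Centred sphere for analytic chord / recovery tests.
sphere_phantom <- function(n = 64, r = 20, mu = 0.05, voxel = 0.1) {
  make_phantom(phantom_spec(
    c(n, n, n), voxel_size = voxel, background_mu = 0,
    primitives = list(list(kind = "sphere",
                           center = rep((n + 1) / 2, 3), size = r, mu = mu))))
}

ct_geometry <- function(n_projections = 180L, detector = c(96L, 96L),
                        pixel = 0.1) {
  # M = 2 so the effective pitch is half the detector pixel
  scan_geometry("CT", sdd = 1000, sod = 500, detector_pixel = pixel,
                detector_shape = detector, n_projections = n_projections)
}

# One cached full-scale simulation per seed, shared across test files
# (the acceptance checks reuse seed 1).
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(seed = 1L) {
  key <- as.character(seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- suppressWarnings(run_al_simulation(seed = seed))
  .sim_cache[[key]]
}

jaccard <- function(a, b) sum(a & b) / max(1L, sum(a | b))
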