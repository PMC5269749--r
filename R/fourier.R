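# FFT helpers shared by reconstruction, masking and fusion.
#
# Convention: "centered" arrays have the zero-frequency (DC) coefficient at
# index floor(n/2) + 1 along each axis; fftshift3 moves FFT-ordered output to
# centered order, ifftshift3 inverts it (they differ for odd sizes). All
# masks in this package live in centered order.

fftshift3 <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) {
    c((floor(n / 2) + 1):n, 1:floor(n / 2))
  })
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

ifftshift3 <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) {
    c((n - floor(n / 2) + 1):n, 1:(n - floor(n / 2)))
  })
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

fft3 <- function(x) stats::fft(x)
ifft3 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Centered physical frequency coordinates (cycles / mm) for an (nx,ny,nz)
# grid of voxel size s: along each axis, (i - c)/ (n * s) with c the DC index.
freq_axes <- function(dims, voxel_size) {
  lapply(dims, function(n) {
    ((seq_len(n) - (floor(n / 2) + 1)) / (n * voxel_size))
  })
}

# |k| and |kz| arrays (centered) for a grid; used for cones and radial bands.
freq_grids <- function(dims, voxel_size) {
  ax <- freq_axes(dims, voxel_size)
  kx2 <- array(rep(ax[[1]]^2, times = dims[2] * dims[3]), dim = dims)
  ky2 <- array(rep(rep(ax[[2]]^2, each = dims[1]), times = dims[3]), dim = dims)
  kz2 <- array(rep(ax[[3]]^2, each = dims[1] * dims[2]), dim = dims)
  list(k = sqrt(kx2 + ky2 + kz2), kz = sqrt(kz2))
}

# Index permutation implementing k -> -k on a centered grid (the unmatched
# Nyquist plane of an even axis maps to itself, its own alias).
reflect_index <- function(n) {
  cc <- floor(n / 2) + 1
  ((2 * cc - seq_len(n) - 1) %% n) + 1
}

reflect3 <- function(x) {
  d <- dim(x)
  x[reflect_index(d[1]), reflect_index(d[2]), reflect_index(d[3]),
    drop = FALSE]
}
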