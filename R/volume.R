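#' 3D attenuation volume
#'
#' A scalar field of linear attenuation coefficients mu (1/mm) on a regular
#' voxel grid. The z axis is the rotation-axis / specimen-normal direction.
#' The default origin centres the grid on the rotation centre, so voxel
#' `(i, j, k)` sits at `origin + (i-1, j-1, k-1) * voxel_size` (mm).
#'
#' @param data Numeric 3D array of attenuation values, 1/mm.
#' @param voxel_size Voxel edge length, mm (isotropic).
#' @param origin Physical position of voxel (1,1,1), mm; default centres the
#'   volume on the origin.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, voxel_size, origin = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!all(is.finite(data))) stop("volume values must all be finite")
  if (!(is.numeric(voxel_size) && length(voxel_size) == 1 && voxel_size > 0))
    stop("voxel_size must be a positive scalar (mm)")
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * voxel_size
  stopifnot(length(origin) == 3)
  structure(list(data = data, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels @ %.5g mm (extent %.3g x %.3g x %.3g mm)\n",
              d[1], d[2], d[3], x$voxel_size,
              d[1] * x$voxel_size, d[2] * x$voxel_size, d[3] * x$voxel_size))
  cat(sprintf("  mu range [%.4g, %.4g] 1/mm\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Grid description of a volume
#'
#' @param x A [volume3d()] or a list with `dim`, `voxel_size`, `origin`.
#' @return A `grid_spec` list (`dim`, `voxel_size`, `origin`).
#' @export
grid_of <- function(x) {
  if (inherits(x, "volume3d"))
    return(structure(list(dim = dim(x$data), voxel_size = x$voxel_size,
                          origin = x$origin), class = "grid_spec"))
  stopifnot(all(c("dim", "voxel_size") %in% names(x)))
  origin <- if (is.null(x$origin)) -(x$dim - 1) / 2 * x$voxel_size else x$origin
  structure(list(dim = as.integer(x$dim), voxel_size = x$voxel_size,
                 origin = origin), class = "grid_spec")
}

#' Construct a centred grid specification
#'
#' @param dim Integer triple `(nx, ny, nz)`.
#' @param voxel_size Voxel edge length, mm.
#' @param origin Optional origin; default centres the grid.
#' @export
grid_spec <- function(dim, voxel_size, origin = NULL) {
  grid_of(list(dim = dim, voxel_size = voxel_size, origin = origin))
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(what, " must share the same grid (dimensions, voxel size, origin)")
  invisible(TRUE)
}
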