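#' 3D gray-level volume with isotropic voxel size
#'
#' The basic unit all filters, segmentation and registration operate on: a 3D
#' array of gray values plus an isotropic voxel size in nanometres. Arrays are
#' indexed `[i, j, k]` for (x, y, z), 1-based as usual in R; the centre of
#' voxel `(i, j, k)` lies at `origin_um + (c(i, j, k) - 0.5) * voxel_size_nm /
#' 1000` micrometres in the parent frame. Pores (lacunae, canaliculi, canals)
#' are darker than the mineralized matrix throughout the package.
#'
#' @param values numeric 3D array of gray levels.
#' @param voxel_size_nm isotropic voxel size in nanometres (> 0).
#' @param origin_um physical position (micrometres) of the volume's corner in
#'   the parent acquisition frame; length-3 numeric.
#' @return an object of class `lcn_volume`.
#' @examples
#' v <- scalar_volume(array(1, c(8, 8, 8)), voxel_size_nm = 120)
#' dim(v$values)
#' volume_extent_um(v)
#' @export
scalar_volume <- function(values, voxel_size_nm, origin_um = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!is.numeric(voxel_size_nm) || length(voxel_size_nm) != 1L || voxel_size_nm <= 0)
    stop("`voxel_size_nm` must be a single positive number")
  if (any(dim(values) < 1L)) stop("grid dimensions must be >= 1 per axis")
  structure(
    list(values = values, voxel_size_nm = as.numeric(voxel_size_nm),
         origin_um = as.numeric(origin_um)),
    class = "lcn_volume"
  )
}

#' @export
print.lcn_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<lcn_volume> %d x %d x %d voxels at %g nm (extent %s um)\n",
              d[1], d[2], d[3], x$voxel_size_nm,
              paste(signif(grid_extent_um(d, x$voxel_size_nm), 4), collapse = " x ")))
  cat(sprintf("  gray range [%g, %g], origin (%s) um\n",
              min(x$values), max(x$values),
              paste(signif(x$origin_um, 4), collapse = ", ")))
  invisible(x)
}

#' Physical extent of a voxel grid
#'
#' Field of view spanned by `n` voxels of size `voxel_size_nm`, in
#' micrometres. A 2048-voxel axis at 30 nm spans 61.44 um; at 120 nm,
#' 245.76 um; a 512-voxel axis at 120 nm spans 61.44 um.
#'
#' @param dims integer vector of grid dimensions (any length).
#' @param voxel_size_nm voxel size in nanometres.
#' @return numeric vector of extents in micrometres.
#' @export
grid_extent_um <- function(dims, voxel_size_nm) {
  as.numeric(dims) * voxel_size_nm / 1000
}

#' @rdname grid_extent_um
#' @param vol an `lcn_volume`.
#' @export
volume_extent_um <- function(vol) grid_extent_um(dim(vol$values), vol$voxel_size_nm)

#' Volume of one voxel in cubic micrometres
#' @param voxel_size_nm voxel size in nanometres.
#' @export
voxel_volume_um3 <- function(voxel_size_nm) (voxel_size_nm / 1000)^3

# internal: check two grids are compatible
check_same_grid <- function(a, b) {
  da <- if (is.array(a)) dim(a) else dim(a$values)
  db <- if (is.array(b)) dim(b) else dim(b$values)
  if (!identical(as.integer(da), as.integer(db)))
    stop("grid dimensions differ: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  invisible(TRUE)
}

# internal: coerce lcn_volume or array to array
vol_values <- function(x) {
  if (inherits(x, "lcn_volume")) x$values else x
}

# internal: voxel centre coordinates (um) along one axis of a volume grid
axis_centers_um <- function(n, voxel_size_nm, origin_um = 0) {
  origin_um + (seq_len(n) - 0.5) * voxel_size_nm / 1000
}
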