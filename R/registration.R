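#' Predicted grid dimensions after repeated 2x (or one k-fold) downsampling
#'
#' A 2048-voxel axis at 30 nm reduced twice by 2x per direction yields 512
#' voxels at 120 nm.
#'
#' @param dims integer grid dimensions.
#' @param factor per-step reduction factor.
#' @param times number of reductions applied.
#' @return integer dimensions after downsampling.
#' @export
downsample_dims <- function(dims, factor = 2, times = 1) {
  d <- as.numeric(dims)
  for (i in seq_len(times)) {
    if (any(d %% factor != 0))
      stop("dimensions not divisible by the downsampling factor")
    d <- d / factor
  }
  as.integer(d)
}

#' Block-mean downsampling
#'
#' Reduces the grid by an integer factor per axis; every output voxel is the
#' mean of its `factor^3` input block and the voxel size is multiplied by
#' `factor`. Dimensions must be divisible by the factor.
#'
#' @param vol an [scalar_volume()].
#' @param factor integer reduction factor (>= 1).
#' @return the reduced [scalar_volume()].
#' @export
downsample <- function(vol, factor) {
  stopifnot(inherits(vol, "lcn_volume"))
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1) return(vol)
  d <- dim(vol$values)
  if (any(d %% factor != 0))
    stop("dimensions not divisible by the downsampling factor")
  dn <- d %/% factor
  a <- array(vol$values, dim = c(factor, dn[1], factor, dn[2], factor, dn[3]))
  a <- colMeans(a)                                  # (nx', f, ny', f, nz')
  a <- colMeans(aperm(a, c(2, 1, 3, 4, 5)))         # (nx', ny', f, nz')
  out <- colMeans(aperm(a, c(3, 1, 2, 4)))          # (nx', ny', nz')
  scalar_volume(out, vol$voxel_size_nm * factor, vol$origin_um)
}

#' Zero-pad a volume to target dimensions
#'
#' Places the input at the origin corner and fills the rest with zeros, the
#' layout expected by [phase_correlate()] so that the correlation peak index
#' equals the crop origin directly.
#'
#' @param vol an [scalar_volume()].
#' @param target_dims integer 3-vector, each `>=` the current dimension.
#' @return the padded [scalar_volume()].
#' @export
zero_pad <- function(vol, target_dims) {
  stopifnot(inherits(vol, "lcn_volume"))
  d <- dim(vol$values)
  target_dims <- as.integer(rep(target_dims, length.out = 3))
  if (any(target_dims < d)) stop("target dimensions smaller than the input")
  if (all(target_dims == d)) return(vol)
  out <- array(0, dim = target_dims)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- vol$values
  v <- scalar_volume(out, vol$voxel_size_nm, vol$origin_um)
  v$padding <- target_dims - d
  v
}

#' Phase correlation between two volumes
#'
#' Computes the inverse Fourier transform of the unit-normalized cross-power
#' spectrum, `p = F^-1[ conj(F(moving)) F(ref) / |conj(F(moving)) F(ref)| ]`
#' (magnitudes below a machine-epsilon-scaled floor are clamped to avoid
#' division by zero), and returns the argmax of `p` as the integer translation
#' of `moving` within `ref`, with indices above half the grid wrapped to
#' negative shifts. The normalization makes `p` invariant to global affine
#' rescaling of the gray levels of either input. In the dual-resolution
#' workflow `moving` is the zero-padded, downsampled fine volume and `ref`
#' the coarse volume, so the peak index is directly the crop origin of the
#' matched VOI.
#'
#' @param ref,moving [scalar_volume()]s with identical grids and voxel size.
#' @return list of class `lcn_offset`: `shift` (integer 3-vector, coarse-grid
#'   voxels) and `peak_value`.
#' @export
phase_correlate <- function(ref, moving) {
  stopifnot(inherits(ref, "lcn_volume"), inherits(moving, "lcn_volume"))
  check_same_grid(ref$values, moving$values)
  Fr <- fft(ref$values)
  Fm <- fft(moving$values)
  X <- Conj(Fm) * Fr
  m <- Mod(X)
  eps <- .Machine$double.eps * max(m)
  p <- Re(fft(X / pmax(m, eps), inverse = TRUE)) / length(X)
  p <- array(p, dim = dim(ref$values))
  idx <- arrayInd(which.max(p), dim(p))[1, ] - 1L
  d <- dim(p)
  shift <- ifelse(idx > d %/% 2, idx - d, idx)
  structure(list(shift = as.integer(shift), peak_value = max(p)),
            class = "lcn_offset")
}

#' @export
print.lcn_offset <- function(x, ...) {
  cat(sprintf("<lcn_offset> shift (%s) voxels, peak %.4f\n",
              paste(x$shift, collapse = ", "), x$peak_value))
  invisible(x)
}

#' Crop the coarse volume at a registered offset
#'
#' Extracts the subvolume starting at `offset` (0-based voxels, no circular
#' wrap) with the requested size: the "PCM volume" sharing the field of view
#' of the fine acquisition. A 512-voxel crop at 120 nm spans 61.44 um per
#' axis.
#'
#' @param coarse an [scalar_volume()].
#' @param offset an `lcn_offset` or integer 3-vector (0-based voxels).
#' @param size integer 3-vector, output dimensions.
#' @return the cropped [scalar_volume()]; its `origin_um` records the crop
#'   position.
#' @export
crop_to_match <- function(coarse, offset, size) {
  stopifnot(inherits(coarse, "lcn_volume"))
  if (inherits(offset, "lcn_offset")) offset <- offset$shift
  offset <- as.integer(rep(offset, length.out = 3))
  size <- as.integer(rep(size, length.out = 3))
  d <- dim(coarse$values)
  for (ax in 1:3) {
    if (offset[ax] < 0 || offset[ax] + size[ax] > d[ax])
      stop(sprintf("crop out of bounds along axis %d: offset %d + size %d > %d",
                   ax, offset[ax], size[ax], d[ax]))
  }
  vals <- coarse$values[offset[1] + seq_len(size[1]),
                        offset[2] + seq_len(size[2]),
                        offset[3] + seq_len(size[3]), drop = FALSE]
  scalar_volume(vals, coarse$voxel_size_nm,
                coarse$origin_um + offset * coarse$voxel_size_nm / 1000)
}

#' Register a fine volume inside a coarse volume and crop the matched VOI
#'
#' Convenience wrapper for the dual-resolution workflow: downsample the fine
#' volume to the coarse voxel size (block mean), zero-pad it to the coarse
#' grid, phase-correlate, and crop the coarse volume at the recovered offset
#' so both cover the same tissue.
#'
#' @param fine fine-resolution [scalar_volume()].
#' @param coarse coarse-resolution [scalar_volume()].
#' @param factor integer voxel-size ratio coarse/fine.
#' @return list with `offset` (`lcn_offset`), `pcm` (the cropped coarse
#'   volume) and `fine_downsampled`.
#' @export
register_pair <- function(fine, coarse, factor) {
  stopifnot(inherits(fine, "lcn_volume"), inherits(coarse, "lcn_volume"))
  fd <- downsample(fine, factor)
  if (abs(fd$voxel_size_nm - coarse$voxel_size_nm) > 1e-6)
    stop("voxel sizes do not match after downsampling")
  padded <- zero_pad(fd, dim(coarse$values))
  off <- phase_correlate(coarse, padded)
  # the peak is a circular shift; as a physical crop origin it is the
  # non-negative index modulo the grid
  crop_at <- off$shift %% dim(coarse$values)
  pcm <- crop_to_match(coarse, crop_at, dim(fd$values))
  list(offset = off, pcm = pcm, fine_downsampled = fd, crop_origin = crop_at)
}
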