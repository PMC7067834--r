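#' 3D median filter
#'
#' Replaces every voxel by the median of its `(2r+1)^3` neighbourhood with
#' mirrored edges. Used to remove speckles (noise or canaliculi cross
#' sections) smaller than lacunae before hysteresis thresholding.
#'
#' @param vol an [scalar_volume()].
#' @param radius_voxels neighbourhood radius in voxels (>= 1).
#' @return the filtered [scalar_volume()]; metadata unchanged.
#' @export
median_filter3 <- function(vol, radius_voxels = 1) {
  stopifnot(inherits(vol, "lcn_volume"))
  radius_voxels <- as.integer(radius_voxels)
  if (radius_voxels < 1) stop("radius must be >= 1")
  d <- dim(vol$values)
  if (radius_voxels >= max(d)) stop("radius larger than every grid dimension")
  out <- .cpp_median_filter3(as.numeric(vol$values), as.integer(d), radius_voxels)
  scalar_volume(array(out, dim = d), vol$voxel_size_nm, vol$origin_um)
}

#' Hysteresis thresholding of dark objects
#'
#' Two-threshold segmentation of dark pores: voxels with gray value
#' `<= t_seed` are high-confidence seeds; the mask is every voxel with value
#' `<= t_keep` that is 26-connected, through voxels `<= t_keep`, to at least
#' one seed. Voxels in the ambiguous band `(t_seed, t_keep]` are kept only
#' when attached to a seeded component. `hysteresis_segment(v, t, t)` is
#' plain thresholding at `t`.
#'
#' @param vol an [scalar_volume()].
#' @param t_seed low (seed) threshold; dark-object convention.
#' @param t_keep high (keep) threshold; must satisfy `t_seed <= t_keep`.
#' @return logical 3D array (the binary mask).
#' @export
hysteresis_segment <- function(vol, t_seed, t_keep) {
  stopifnot(inherits(vol, "lcn_volume"))
  if (t_seed > t_keep) stop("t_seed must be <= t_keep")
  keep <- vol$values <= t_keep
  if (!any(keep)) return(array(FALSE, dim = dim(vol$values)))
  lab <- label_components(keep, connectivity = 26)
  seeded <- unique(lab[vol$values <= t_seed])
  seeded <- seeded[seeded > 0]
  array(lab %in% seeded & keep, dim = dim(vol$values))
}

#' Separate Haversian canals from lacunae by component size
#'
#' Connected components (26-connectivity) whose volume exceeds
#' `max_volume_um3` are abnormal for lacunae and moved to the canal mask;
#' the remainder stays in the lacuna mask. Component volume is voxel count
#' times voxel volume.
#'
#' @param mask logical 3D array of segmented pores.
#' @param voxel_size_nm voxel size (nm).
#' @param max_volume_um3 size cutoff in cubic micrometres. Lacunae measure a
#'   few hundred um^3, Haversian canals orders of magnitude more; the default
#'   2000 um^3 sits well between.
#' @return list with logical arrays `lacunae` and `canals`.
#' @export
split_by_size <- function(mask, voxel_size_nm, max_volume_um3 = 2000) {
  stopifnot(is.array(mask), is.logical(mask))
  if (max_volume_um3 <= 0) stop("max_volume_um3 must be positive")
  canals <- array(FALSE, dim = dim(mask))
  if (!any(mask)) return(list(lacunae = mask, canals = canals))
  lab <- label_components(mask, connectivity = 26)
  sizes <- tabulate(lab[lab > 0], nbins = attr(lab, "n_labels"))
  vox <- voxel_volume_um3(voxel_size_nm)
  big <- which(sizes * vox > max_volume_um3)
  if (length(big)) {
    canal_vox <- lab %in% big
    canals[canal_vox] <- TRUE
    mask <- mask & !canals
  }
  list(lacunae = mask, canals = canals)
}

#' Label lacunae
#'
#' 26-connected components of the lacuna mask with volume at least
#' `min_volume_um3` are labeled 1..N in decreasing volume order (ties broken
#' by raster-scan order of each component's first voxel), so outputs are
#' reproducible.
#'
#' @param mask logical 3D array.
#' @param voxel_size_nm voxel size (nm).
#' @param min_volume_um3 minimum component volume kept (um^3).
#' @return integer 3D array; 0 is background; attribute `n_labels`.
#' @export
label_lacunae <- function(mask, voxel_size_nm, min_volume_um3 = 0) {
  stopifnot(is.array(mask), is.logical(mask))
  if (min_volume_um3 < 0) stop("min_volume_um3 must be >= 0")
  out <- array(0L, dim = dim(mask))
  if (!any(mask)) {
    attr(out, "n_labels") <- 0L
    return(out)
  }
  lab <- label_components(mask, connectivity = 26)
  n <- attr(lab, "n_labels")
  sizes <- tabulate(lab[lab > 0], nbins = n)
  vox <- voxel_volume_um3(voxel_size_nm)
  keep <- which(sizes * vox >= min_volume_um3 & sizes > 0)
  if (!length(keep)) {
    attr(out, "n_labels") <- 0L
    return(out)
  }
  # order kept components by decreasing size; ties keep scan order (stable)
  keep <- keep[order(-sizes[keep])]
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  inside <- lab > 0
  out[inside] <- remap[lab[inside]]
  attr(out, "n_labels") <- length(keep)
  out
}

#' Segment and label lacunae from a gray-level volume
#'
#' The lacunar stage of the pipeline: median filter, hysteresis thresholding,
#' size-based separation of Haversian canals, then component labeling.
#' Thresholds default to histogram percentiles of the filtered volume when
#' not supplied (the pore/matrix gray levels of real acquisitions vary, so
#' thresholds are configuration, not constants).
#'
#' @param vol an [scalar_volume()].
#' @param t_seed,t_keep hysteresis thresholds; defaults are the 0.2% and 2%
#'   gray-level percentiles of the median-filtered volume.
#' @param median_radius radius of the median prefilter (voxels); `NULL`
#'   scales it to the canalicular width, `max(1, ceiling(150 / voxel))`, so
#'   structures up to canalicular calibre are erased at any voxel size while
#'   lacunae survive.
#' @param max_lacuna_volume_um3 Haversian size cutoff, see [split_by_size()].
#' @param min_lacuna_volume_um3 minimum lacuna volume, see [label_lacunae()].
#' @return list with `labels` (integer array), `lacunae`, `canals` (logical
#'   arrays), the thresholds used, and `filtered` (the filtered volume).
#' @export
segment_lacunae <- function(vol, t_seed = NULL, t_keep = NULL,
                            median_radius = NULL,
                            max_lacuna_volume_um3 = 2000,
                            min_lacuna_volume_um3 = 0) {
  stopifnot(inherits(vol, "lcn_volume"))
  if (is.null(median_radius))
    median_radius <- max(1, ceiling(150 / vol$voxel_size_nm))
  filt <- median_filter3(vol, median_radius)
  if (is.null(t_seed)) t_seed <- quantile(filt$values, 0.002, names = FALSE)
  if (is.null(t_keep)) t_keep <- quantile(filt$values, 0.02, names = FALSE)
  mask <- hysteresis_segment(filt, t_seed, t_keep)
  sp <- split_by_size(mask, vol$voxel_size_nm, max_lacuna_volume_um3)
  labels <- label_lacunae(sp$lacunae, vol$voxel_size_nm, min_lacuna_volume_um3)
  list(labels = labels, lacunae = labels > 0, canals = sp$canals,
       t_seed = t_seed, t_keep = t_keep, filtered = filt)
}
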