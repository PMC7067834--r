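#' Default distance grid for the canalicular ramification profile
#'
#' Seven increasing distances from the lacunar surface, 1.2 to 12.0 um.
#' @return numeric vector of distances (um).
#' @export
default_r_grid <- function() c(1.2, 3.0, 4.8, 6.6, 8.4, 10.2, 12.0)

#' Analytic ellipsoidal shell at distance r from a lacunar surface
#'
#' Voxels forming a thin shell centred on the fitted lacunar ellipsoid
#' dilated isotropically by `r`: the dilation is expressed purely by adding
#' `r` to every semi-axis in the quadratic-form matrix (no morphological
#' dilation of the voxel object), so the shell is the set difference of two
#' analytic ellipsoids dilated by `r +- thickness/2` voxels.
#'
#' @param e an [ellipsoid()] (coordinates in the grid frame, um).
#' @param r_um dilation distance (um, >= 0).
#' @param dims grid dimensions.
#' @param voxel_size_nm voxel size (nm).
#' @param thickness_voxels shell thickness in voxels (>= 1).
#' @return logical 3D array; empty (with a warning) if the shell lies outside
#'   the grid.
#' @export
dilated_shell <- function(e, r_um, dims, voxel_size_nm, thickness_voxels = 1) {
  stopifnot(inherits(e, "lcn_ellipsoid"))
  if (r_um < 0) stop("r must be >= 0")
  if (thickness_voxels < 1) stop("thickness must be >= 1 voxel")
  h <- voxel_size_nm / 1000
  dims <- as.integer(rep(dims, length.out = 3))
  half_t <- thickness_voxels * h / 2
  r_out <- r_um + half_t
  r_in <- max(r_um - half_t, 0)
  semi_max <- e$lengths_um[1] / 2 + r_out
  lo <- pmax(1L, floor((e$center_um - semi_max) / h) + 1L)
  hi <- pmin(dims, ceiling((e$center_um + semi_max) / h))
  out <- array(FALSE, dim = dims)
  if (any(lo > hi)) {
    warning("dilated shell lies outside the grid")
    return(out)
  }
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  pts <- cbind(rep((ii - 0.5) * h, times = length(jj) * length(kk)),
               rep(rep((jj - 0.5) * h, each = length(ii)), times = length(kk)),
               rep((kk - 0.5) * h, each = length(ii) * length(jj)))
  inside_out <- ellipsoid_quadform(e, pts, r_out) <= 1
  inside_in <- ellipsoid_quadform(e, pts, r_in) <= 1
  shell <- inside_out & !inside_in
  if (!any(shell)) {
    warning("dilated shell lies outside the grid")
    return(out)
  }
  out[ii, jj, kk] <- array(shell, dim = c(length(ii), length(jj), length(kk)))
  out
}

#' Number of canaliculi crossing the shell at distance r
#'
#' Counts the 26-connected components of the intersection between the
#' canaliculi mask and the analytic shell around the lacuna's fitted
#' ellipsoid dilated by `r`: each connected intersection patch is one
#' canaliculus crossing the bounding surface (a "hole" in that surface).
#' Growth of this count with `r` indicates branching of the network.
#'
#' @param canals logical 3D array of segmented canaliculi.
#' @param e the lacuna's fitted [ellipsoid()].
#' @param r_um distance from the lacunar surface (um).
#' @param voxel_size_nm voxel size (nm).
#' @param thickness_voxels shell thickness (voxels).
#' @return non-negative integer count.
#' @export
count_canaliculi <- function(canals, e, r_um, voxel_size_nm,
                             thickness_voxels = 1) {
  shell <- dilated_shell(e, r_um, dim(canals), voxel_size_nm,
                         thickness_voxels = thickness_voxels)
  inter <- canals & shell
  if (!any(inter)) return(0L)
  lab <- label_components(inter, connectivity = 26)
  as.integer(attr(lab, "n_labels"))
}

#' Canalicular morphometry table
#'
#' Computes the canalicular volumes and porosities and the ramification
#' profile: total canalicular volume (Ca.TV), total LCN volume
#' (LCN.TV = Ca.TV + Lc.TV), the corresponding porosities relative to bone
#' volume, per-Voronoi-cell averages (Ca.V, Ca.V/Cell.V, Ca.V/Lc.V), and the
#' number of canaliculi per lacuna Ca.N(r) with its surface-normalized
#' density Ca.N/Lc.S(r) at each distance of `r_grid_um`.
#'
#' @param canals logical 3D array of segmented canaliculi (disjoint from
#'   lacunae).
#' @param labels integer 3D array of labeled lacunae.
#' @param partition the [voronoi_partition()] of the lacunae.
#' @param ellipsoids fitted [ellipsoid()]s per label ([fit_lacunae()]).
#' @param bv_mm3 bone volume (mm^3).
#' @param voxel_size_nm voxel size (nm).
#' @param r_grid_um distances from the lacunar surface (um).
#' @param lacuna_surfaces_um2 optional per-lacuna surface areas (um^2; from
#'   [lacuna_metrics()]); computed by the Crofton estimator when missing.
#' @param thickness_voxels shell thickness for the crossing count.
#' @return list of class `lcn_canal_metrics` with `summary` (one-row
#'   data.frame: Ca.TV, LCN.TV in mm^3; Ca.TV/BV, LCN.TV/BV, Ca.V/Cell.V,
#'   Ca.V/Lc.V in %; Ca.V in um^3), `ca_n` (per-distance mean counts and
#'   densities) and `per_lacuna_counts` (matrix lacunae x distances).
#' @export
canal_metrics <- function(canals, labels, partition, ellipsoids, bv_mm3,
                          voxel_size_nm, r_grid_um = default_r_grid(),
                          lacuna_surfaces_um2 = NULL, thickness_voxels = 1) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) stop("zero lacunae: canalicular metrics undefined")
  vox <- voxel_volume_um3(voxel_size_nm)
  ca_tv_mm3 <- sum(canals) * vox * 1e-9
  lc_tv_mm3 <- sum(labels > 0) * vox * 1e-9
  lcn_tv_mm3 <- ca_tv_mm3 + lc_tv_mm3

  # per-cell canalicular and lacunar volumes
  cell_ids <- as.character(ids)
  ca_per_cell <- vapply(ids, function(l)
    sum(canals & partition$cells == l) * vox, numeric(1))
  lc_per_cell <- vapply(ids, function(l)
    sum(labels == l) * vox, numeric(1))
  cell_v <- as.numeric(partition$cell_volumes_um3[cell_ids])

  if (is.null(lacuna_surfaces_um2)) {
    lacuna_surfaces_um2 <- vapply(seq_along(ids), function(n) {
      bb <- label_bbox(labels, ids[n], pad = 2)
      surface_area.array(labels[bb$i, bb$j, bb$k, drop = FALSE] == ids[n],
                         voxel_size_nm)
    }, numeric(1))
  }

  counts <- matrix(0L, nrow = length(ids), ncol = length(r_grid_um),
                   dimnames = list(ids, paste0("r=", r_grid_um)))
  for (n in seq_along(ids)) {
    e <- ellipsoids[[as.character(ids[n])]]
    for (m in seq_along(r_grid_um)) {
      counts[n, m] <- count_canaliculi(canals, e, r_grid_um[m], voxel_size_nm,
                                       thickness_voxels = thickness_voxels)
    }
  }
  ca_n <- data.frame(r_um = r_grid_um,
                     "Ca.N" = colMeans(counts),
                     "Ca.N/Lc.S" = colMeans(counts / lacuna_surfaces_um2),
                     check.names = FALSE)
  summary <- data.frame(
    "Ca.TV" = ca_tv_mm3,
    "LCN.TV" = lcn_tv_mm3,
    "Ca.TV/BV" = 100 * ca_tv_mm3 / bv_mm3,
    "LCN.TV/BV" = 100 * lcn_tv_mm3 / bv_mm3,
    "Ca.V" = mean(ca_per_cell),
    "Ca.V/Cell.V" = 100 * mean(ca_per_cell / cell_v),
    "Ca.V/Lc.V" = 100 * mean(ca_per_cell / lc_per_cell),
    check.names = FALSE)
  structure(list(summary = summary, ca_n = ca_n,
                 per_lacuna_counts = counts),
            class = "lcn_canal_metrics")
}

#' @export
print.lcn_canal_metrics <- function(x, ...) {
  cat("<lcn_canal_metrics>\n")
  print(x$summary, row.names = FALSE)
  cat("Ca.N(r):\n")
  print(x$ca_n, row.names = FALSE)
  invisible(x)
}
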