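# Shared fixture builders. Everything is generated in code at test time.

# One spherical lacuna with evenly spread radial tubes; spheres make the
# shell distance equal the arc length along each tube, so crossing counts
# have exact ground truth.
make_counting_scene <- function(n_tubes, branch_at_um = NULL,
                                radius_um = 0.3, length_um = 14,
                                domain_um = 34, seed = 3) {
  cfg <- phantom_config(domain_um = rep(domain_um, 3), n_lacunae = 0,
                        n_canaliculi = n_tubes,
                        canaliculi_radius_um = radius_um,
                        canaliculi_length_um = length_um,
                        branch_at_um = branch_at_um,
                        noise_sigma = 0, tube_directions = "even")
  sc <- build_scene(cfg, seed = seed)
  e <- ellipsoid(rep(domain_um / 2, 3), c(6, 6, 6))
  sc$lacunae <- list(e)
  dirs <- lcnmorph:::fibonacci_directions(n_tubes)
  segs <- list()
  set.seed(seed)
  for (t in seq_len(n_tubes)) {
    u <- dirs[t, ]
    p0 <- lcnmorph:::ellipsoid_surface_point(e, u)
    segs <- c(segs, lcnmorph:::grow_tube(p0, u, length_um, radius_um, 1L,
                                         branch_at = branch_at_um,
                                         branch_angle = 25 * pi / 180,
                                         depth = 0, arc_done = 0))
  }
  sc$canaliculi <- segs
  sc
}

# Small multi-lacuna tissue-like scene used by segmentation tests.
make_tissue_scene <- function(seed = 11, n_lacunae = 2, n_canaliculi = 10,
                              domain_um = 11.52, noise_sigma = 0.05,
                              canaliculi_length_um = 4) {
  cfg <- phantom_config(domain_um = rep(domain_um, 3), n_lacunae = n_lacunae,
                        lacuna_axes_um = c(3.5, 2, 1.4),
                        lacuna_axes_sd_um = c(0.2, 0.15, 0.1),
                        n_canaliculi = n_canaliculi,
                        canaliculi_radius_um = 0.15,
                        canaliculi_length_um = canaliculi_length_um,
                        noise_sigma = noise_sigma)
  build_scene(cfg, seed = seed)
}

# Digitized solid primitives for surface/SMI reference checks.
digitize_ball <- function(radius_um, voxel_nm, pad_voxels = 4) {
  h <- voxel_nm / 1000
  n <- ceiling(2 * radius_um / h) + 2 * pad_voxels
  xs <- (seq_len(n) - (n + 1) / 2) * h
  g <- expand.grid(xs, xs, xs)
  array(rowSums(g^2) <= radius_um^2, dim = c(n, n, n))
}

digitize_cylinder <- function(radius_um, length_um, voxel_nm, pad_voxels = 4) {
  h <- voxel_nm / 1000
  nxy <- ceiling(2 * radius_um / h) + 2 * pad_voxels
  nz <- ceiling(length_um / h) + 2 * pad_voxels
  xy <- (seq_len(nxy) - (nxy + 1) / 2) * h
  zc <- (seq_len(nz) - (nz + 1) / 2) * h
  g <- expand.grid(xy, xy, zc)
  array(g[, 1]^2 + g[, 2]^2 <= radius_um^2 & abs(g[, 3]) <= length_um / 2,
        dim = c(nxy, nxy, nz))
}

digitize_plate <- function(side_um, thickness_um, voxel_nm, pad_voxels = 4) {
  h <- voxel_nm / 1000
  na <- ceiling(side_um / h) + 2 * pad_voxels
  nt <- ceiling(thickness_um / h) + 2 * pad_voxels
  ac <- (seq_len(na) - (na + 1) / 2) * h
  tc <- (seq_len(nt) - (nt + 1) / 2) * h
  g <- expand.grid(ac, ac, tc)
  array(abs(g[, 1]) <= side_um / 2 & abs(g[, 2]) <= side_um / 2 &
          abs(g[, 3]) <= thickness_um / 2, dim = c(na, na, nt))
}

# Circular shift of a 3D array (for registration oracles).
circshift3 <- function(a, s) {
  d <- dim(a)
  idx <- lapply(1:3, function(ax) {
    i <- seq_len(d[ax]) - s[ax]
    ((i - 1) %% d[ax]) + 1
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

dice_overlap <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
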